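# Independent brute-force oracles used to freeze expected values.

# Sample entropy by exhaustive template enumeration (triple loop, no
# vectorisation shared with the implementation).
sampen_brute <- function(x, m, r) {
  n <- length(x)
  count <- function(len) {
    nt <- n - m                     # templates with a continuation
    cnt <- 0L
    for (i in seq_len(nt - 1L)) {
      for (j in (i + 1L):nt) {
        d <- 0
        for (k in 0:(len - 1L)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d <= r) cnt <- cnt + 1L
      }
    }
    cnt
  }
  B <- count(m)
  A <- count(m + 1L)
  if (A == 0L || B == 0L) return(Inf)
  -log(A / B)
}

# Permutation entropy by explicit ordinal-pattern tally.
pe_brute <- function(x, ord, delay) {
  n <- length(x)
  pats <- character(0)
  for (i in seq_len(n - (ord - 1L) * delay)) {
    v <- x[i + (0:(ord - 1L)) * delay]
    pats <- c(pats, paste(order(v, method = "radix"), collapse = "-"))
  }
  p <- table(pats) / length(pats)
  -sum(p * log(p))
}

# Trapezoid quadrature of a fusion-mixture density over a wide split grid,
# written independently of integrate_density().
quad_mixture <- function(params, lo = -60, hi = 60, n_per = 20001L) {
  knots <- if (params$model_class == "GNG") c(-params$xi[1], params$xi[2])
           else params$uniform
  brk <- sort(unique(c(lo, knots, hi)))
  tot <- 0
  for (i in seq_len(length(brk) - 1L)) {
    g <- seq(brk[i] + 1e-9, brk[i + 1L] - 1e-9, length.out = n_per)
    f <- mixture_density(g, params)
    tot <- tot + sum((f[-1] + f[-length(f)]) / 2 * diff(g))
  }
  tot
}

# Two-class, clearly separable Gaussian feature matrix where only the
# informative columns differ between classes.
make_separable_features <- function(n_per_class = 40L, p = 6L,
                                    informative = c(1L, 2L), delta = 3,
                                    seed = 1L) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  x[seq_len(n_per_class), informative] <-
    x[seq_len(n_per_class), informative] + delta
  list(x = x, y = rep(c("a", "b"), each = n_per_class))
}

# Random-search baseline with a fixed evaluation budget.
random_search <- function(fn, bounds, budget, seed) {
  set.seed(seed)
  d <- ncol(bounds)
  best <- Inf
  for (i in seq_len(budget)) {
    x <- bounds[1, ] + runif(d) * (bounds[2, ] - bounds[1, ])
    best <- min(best, fn(x))
  }
  best
}

shuffle_labels <- function(records, seed) {
  set.seed(seed)
  labs <- sample(vapply(records, function(r) r$label, character(1)))
  Map(function(r, l) { r$label <- l; r }, records, labs)
}
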