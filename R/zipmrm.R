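#' Zero-inflated Poisson mixture regression
#'
#' A K-component Poisson regression mixture with log link, concomitant
#' covariates entering the component weights through a multinomial-logit
#' model, and an extra structural-zero mass `psi`: the observed count is 0
#' with probability `psi`, otherwise a component q is drawn with probability
#' `pi_q(v2)` and the count is Poisson with rate
#' `lambda_q = exp(beta0_q + v1' beta_q)`. Fitting is by EM with latent
#' component indicators and a latent structural-zero indicator;
#' classification uses one fitted model per class and Bayes posteriors.
#'
#' @name zipmrm
NULL

#' Poisson probability mass with integer indicator
#'
#' `exp(-lambda) lambda^u / u!` for u in \{0, 1, 2, ...\}; negative or
#' non-integer `u` returns 0 rather than raising an error. Computed in log
#' space for stability.
#'
#' @param u Count values (any numeric).
#' @param lam Positive rate(s).
#' @return Probabilities, same length as `u`.
#' @export
poisson_pmf <- function(u, lam) {
  stopifnot(all(lam > 0))
  ok <- is.finite(u) & u >= 0 & u == floor(u)
  out <- numeric(length(u))
  out[ok] <- stats::dpois(u[ok], rep_len(lam, length(u))[ok])
  out
}

#' Concomitant component weights
#'
#' Softmax over `gamma0_q + v2' gamma_q`; the last component's coefficients
#' are fixed at zero for identifiability. Overflow is guarded by
#' max-subtraction.
#'
#' @param v2 Concomitant covariate matrix (n x p2; may have 0 columns) or a
#'   single covariate vector.
#' @param gamma0 Length-K intercepts (last entry 0).
#' @param gamma p2 x K coefficient matrix (last column 0); may be `NULL`
#'   when `v2` has no columns.
#' @return n x K matrix of weights, each row summing to 1.
#' @export
concomitant_weights <- function(v2, gamma0, gamma = NULL) {
  K <- length(gamma0)
  if (is.null(dim(v2))) v2 <- matrix(v2, nrow = 1L)
  n <- nrow(v2)
  eta <- matrix(gamma0, n, K, byrow = TRUE)
  if (!is.null(gamma) && ncol(v2) > 0L)
    eta <- eta + v2 %*% gamma
  eta <- eta - apply(eta, 1L, max)
  w <- exp(eta)
  w / rowSums(w)
}

#' Construct a ZIPMRM parameter set
#'
#' @param beta0 Length-K component intercepts (log scale).
#' @param beta p1 x K regression coefficient matrix (or `NULL` when there
#'   are no regressor covariates).
#' @param gamma0 Length-K concomitant intercepts, last entry 0.
#' @param gamma p2 x K concomitant coefficients (last column 0) or `NULL`.
#' @param psi Structural-zero probability in `[0, 1]`.
#' @return A `zipmrm_params` object.
#' @export
zipmrm_params <- function(beta0, beta = NULL, gamma0 = rep(0, length(beta0)),
                          gamma = NULL, psi = 0) {
  K <- length(beta0)
  stopifnot(length(gamma0) == K, psi >= 0, psi <= 1)
  if (abs(gamma0[K]) > 1e-12 ||
      (!is.null(gamma) && any(abs(gamma[, K]) > 1e-12)))
    stop("component K concomitant coefficients must be fixed at zero")
  structure(list(K = K, beta0 = as.numeric(beta0), beta = beta,
                 gamma0 = as.numeric(gamma0), gamma = gamma, psi = psi),
            class = "zipmrm_params")
}

component_rates <- function(params, v1, n) {
  K <- params$K
  lam <- matrix(params$beta0, n, K, byrow = TRUE)
  if (!is.null(params$beta) && !is.null(v1) && ncol(as.matrix(v1)) > 0L)
    lam <- lam + as.matrix(v1) %*% params$beta
  exp(lam)
}

#' ZIPMRM density of observed counts
#'
#' `psi * 1{u = 0} + (1 - psi) * sum_q pi_q(v2) Poisson(u; lambda_q(v1))`.
#'
#' @param u Count vector.
#' @param v1 Regressor covariates (n x p1 matrix or `NULL`).
#' @param v2 Concomitant covariates (n x p2 matrix or `NULL`).
#' @param params A [zipmrm_params()] object.
#' @return Probability per observation.
#' @export
zipmrm_density <- function(u, v1 = NULL, v2 = NULL, params) {
  n <- length(u)
  lam <- component_rates(params, v1, n)
  pi_q <- concomitant_weights(
    if (is.null(v2)) matrix(0, n, 0L) else as.matrix(v2),
    params$gamma0, params$gamma)
  mix <- rowSums(pi_q * vapply(seq_len(params$K), function(q)
    poisson_pmf(u, lam[, q]), numeric(n)))
  params$psi * as.numeric(u == 0) + (1 - params$psi) * mix
}

#' Mean and variance of the pure Poisson mixture
#'
#' For `psi = 0`: `E(U) = sum_q pi_q lambda_q` and
#' `Var(U) = E(U) + y` with overdispersion excess
#' `y = sum_q pi_q lambda_q^2 - (sum_q pi_q lambda_q)^2`, which vanishes
#' when all component rates coincide (equidispersion) and is otherwise
#' non-negative.
#'
#' @inheritParams zipmrm_density
#' @return Data frame with columns `mean`, `overdispersion`, `variance`.
#' @export
mixture_moments <- function(params, v1 = NULL, v2 = NULL, n = 1L) {
  lam <- component_rates(params, v1, n)
  pi_q <- concomitant_weights(
    if (is.null(v2)) matrix(0, n, 0L) else as.matrix(v2),
    params$gamma0, params$gamma)
  m <- rowSums(pi_q * lam)
  y <- rowSums(pi_q * lam^2) - m^2
  data.frame(mean = m, overdispersion = y, variance = m + y)
}

#' Equal-frequency discretisation of continuous features into counts
#'
#' Per-feature quantile binning into `{0, ..., levels - 1}`; monotone in the
#' input. Bin edges derived from training data can be reused on new data so
#' the transform never sees held-out rows.
#'
#' @param features Numeric matrix.
#' @param levels Number of count levels, at least 2 (default 16).
#' @param edges Optional list of per-feature edge vectors from a previous
#'   call (training data); when supplied, `levels` is ignored.
#' @return Integer count matrix with attribute `"edges"`.
#' @export
discretize_counts <- function(features, levels = 16L, edges = NULL) {
  features <- as.matrix(features)
  if (is.null(edges)) {
    if (levels < 2L) stop("'levels' must be at least 2")
    edges <- lapply(seq_len(ncol(features)), function(j) {
      if (stats::sd(features[, j]) == 0)
        warning(sprintf("feature %d is constant; all counts 0", j))
      unique(stats::quantile(features[, j],
                             probs = seq_len(levels - 1L) / levels,
                             names = FALSE))
    })
  }
  out <- vapply(seq_len(ncol(features)), function(j)
    findInterval(features[, j], edges[[j]], left.open = TRUE),
    integer(nrow(features)))
  out <- matrix(as.integer(out), nrow = nrow(features),
                dimnames = dimnames(features))
  attr(out, "edges") <- edges
  out
}

obs_loglik_zipmrm <- function(u, v1, v2, params) {
  d <- zipmrm_density(u, v1, v2, params)
  sum(log(pmax(d, .Machine$double.xmin)))
}

#' Fit a ZIPMRM by EM
#'
#' E-step computes posteriors of the structural-zero indicator and the
#' component indicators; the M-step updates `psi` in closed form, solves a
#' responsibility-weighted Poisson regression (Newton/IRLS via
#' `stats::glm.fit`) per component, and refits the concomitant multinomial
#' logit (closed form without covariates, `nnet::multinom` with). The
#' observed-data log-likelihood is non-decreasing across iterations; the
#' loop stops at a relative change below `tol` or at `max_iter`. Components
#' whose total responsibility collapses are re-seeded at a random data
#' quantile.
#'
#' @param u Count vector (non-negative integers).
#' @param v1 Regressor covariates (n x p1 matrix or `NULL`).
#' @param v2 Concomitant covariates (n x p2 matrix or `NULL`).
#' @param K Number of Poisson components.
#' @param psi Starting structural-zero mass, or `NA` to initialise from the
#'   observed zero excess. Set `psi = 0` with `estimate_psi = FALSE` for a
#'   pure Poisson mixture regression.
#' @param estimate_psi Update `psi` during EM (default `TRUE`).
#' @param max_iter EM iteration cap, default 200.
#' @param tol Relative log-likelihood change tolerance, default 1e-6.
#' @param seed Seed for initial responsibilities, default 1.
#' @return A `zipmrm_fit`: `params`, `loglik`, `loglik_trace`, `n_iter`,
#'   `converged`, `responsibilities`, `events`. Components are sorted by
#'   `beta0` so fits are comparable across runs.
#' @export
fit_zipmrm <- function(u, v1 = NULL, v2 = NULL, K = 2L, psi = NA_real_,
                       estimate_psi = TRUE, max_iter = 200L, tol = 1e-6,
                       seed = 1L) {
  u <- as.numeric(u)
  n <- length(u)
  stopifnot(all(u >= 0), all(u == floor(u)))
  if (n < 20 * K) warning(sprintf("only %d observations for K=%d components", n, K))
  v1m <- if (is.null(v1)) matrix(0, n, 0L) else as.matrix(v1)
  v2m <- if (is.null(v2)) matrix(0, n, 0L) else as.matrix(v2)
  set.seed(seed)
  # init: order-based split of counts into K groups, mild jitter
  grp <- if (K == 1L) rep(1L, n) else
    cut(rank(u, ties.method = "random"), K, labels = FALSE)
  if (is.na(psi)) {
    psi <- if (estimate_psi)
      max(0.01, mean(u == 0) - stats::dpois(0, mean(u) + 1e-9)) else 0
  }
  beta0 <- vapply(seq_len(K), function(q) log(mean(u[grp == q]) + 0.1), numeric(1))
  p1 <- ncol(v1m)
  params <- zipmrm_params(beta0 = sort(beta0),
                          beta = if (p1) matrix(0, p1, K) else NULL,
                          gamma0 = rep(0, K),
                          gamma = if (ncol(v2m)) matrix(0, ncol(v2m), K) else NULL,
                          psi = psi)
  events <- character(0)
  ll_trace <- numeric(0)
  ll_old <- obs_loglik_zipmrm(u, v1m, v2m, params)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    lam <- component_rates(params, v1m, n)
    pi_q <- concomitant_weights(v2m, params$gamma0, params$gamma)
    dens_q <- vapply(seq_len(K), function(q) poisson_pmf(u, lam[, q]), numeric(n))
    joint <- (1 - params$psi) * pi_q * dens_q
    jz <- params$psi * as.numeric(u == 0)
    tot <- rowSums(joint) + jz
    tot[tot <= 0] <- .Machine$double.xmin
    r0 <- jz / tot
    rq <- joint / tot
    # M-step
    if (estimate_psi) params$psi <- mean(r0)
    for (q in seq_len(K)) {
      wq <- rq[, q]
      if (sum(wq) < 1e-8) {
        events <- c(events, sprintf("iter %d: component %d re-seeded", iter, q))
        params$beta0[q] <- log(stats::quantile(u, stats::runif(1)) + 0.5)
        next
      }
      fit <- suppressWarnings(stats::glm.fit(
        x = cbind(1, v1m), y = u, weights = wq,
        family = stats::poisson(),
        control = stats::glm.control(epsilon = 1e-10)))
      params$beta0[q] <- fit$coefficients[1L]
      if (p1) params$beta[, q] <- fit$coefficients[-1L]
    }
    # concomitant update (trivial for a single component)
    if (K == 1L) {
      params$gamma0 <- 0
      if (!is.null(params$gamma)) params$gamma[] <- 0
    } else if (ncol(v2m) == 0L) {
      pbar <- colSums(rq) / sum(rq)
      pbar <- pmax(pbar, 1e-12)
      params$gamma0 <- log(pbar / pbar[K])
    } else {
      mfit <- nnet::multinom(rq[, c(K, seq_len(K - 1L)), drop = FALSE] ~ v2m,
                             trace = FALSE, maxit = 200)
      co <- stats::coef(mfit)
      if (is.null(dim(co))) co <- matrix(co, nrow = 1L)
      # multinom baselines the first response column (component K here)
      params$gamma0 <- c(co[, 1L], 0)
      params$gamma <- cbind(t(co[, -1L, drop = FALSE]), 0)
    }
    ll <- obs_loglik_zipmrm(u, v1m, v2m, params)
    ll_trace <- c(ll_trace, ll)
    if (abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # canonical component order: ascending beta0
  ord <- order(params$beta0)
  params$beta0 <- params$beta0[ord]
  if (!is.null(params$beta)) params$beta <- params$beta[, ord, drop = FALSE]
  g0 <- params$gamma0[ord]
  params$gamma0 <- g0 - g0[K]
  if (!is.null(params$gamma)) {
    g <- params$gamma[, ord, drop = FALSE]
    params$gamma <- g - g[, K]
  }
  lam <- component_rates(params, v1m, n)
  pi_q <- concomitant_weights(v2m, params$gamma0, params$gamma)
  dens_q <- vapply(seq_len(K), function(q) poisson_pmf(u, lam[, q]), numeric(n))
  joint <- (1 - params$psi) * pi_q * dens_q
  jz <- params$psi * as.numeric(u == 0)
  tot <- pmax(rowSums(joint) + jz, .Machine$double.xmin)
  structure(
    list(params = params, loglik = utils::tail(ll_trace, 1L),
         loglik_trace = ll_trace, n_iter = iter, converged = converged,
         responsibilities = cbind(zero = jz / tot, joint / tot),
         events = events, n_obs = n),
    class = "zipmrm_fit")
}

#' @export
print.zipmrm_fit <- function(x, ...) {
  cat(sprintf("<zipmrm_fit> K=%d psi=%.4f loglik=%.3f (%d iter%s)\n",
              x$params$K, x$params$psi, x$loglik, x$n_iter,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Class posteriors from per-class ZIPMRM fits
#'
#' Each class has its own generative ZIPMRM (fitted on that class's
#' training rows); a new observation's class posterior is proportional to
#' the class prior times its density under that class's parameters. When a
#' row has density zero (or rows of counts are scored jointly, the product
#' of per-column densities) under every class, the posterior falls back to
#' the priors with a warning.
#'
#' @param fits_by_class Named list of `zipmrm_fit` (or [zipmrm_params()])
#'   objects, one per class.
#' @param u Count vector, or an n x p matrix whose columns are scored as
#'   conditionally independent given the class.
#' @param v1,v2 Covariates passed to [zipmrm_density()] (`NULL` for none).
#' @param priors Class priors; default uniform.
#' @return List with `posterior` (n x classes, rows summing to 1) and
#'   `labels` (argmax class per row).
#' @export
predict_zipmrm <- function(fits_by_class, u, v1 = NULL, v2 = NULL,
                           priors = NULL) {
  classes <- names(fits_by_class)
  stopifnot(length(classes) >= 2L)
  if (is.null(priors)) priors <- rep(1 / length(classes), length(classes))
  priors <- priors / sum(priors)
  um <- if (is.null(dim(u))) matrix(u, ncol = 1L) else as.matrix(u)
  n <- nrow(um)
  loglik <- vapply(fits_by_class, function(f) {
    p <- if (inherits(f, "zipmrm_fit")) f$params else f
    rowSums(matrix(vapply(seq_len(ncol(um)), function(j) {
      d <- zipmrm_density(um[, j], v1, v2, p)
      log(pmax(d, 1e-300))
    }, numeric(n)), nrow = n))
  }, numeric(n))
  loglik <- matrix(loglik, nrow = n)
  lp <- sweep(loglik, 2L, log(priors), `+`)
  lp <- lp - apply(lp, 1L, max)
  post <- exp(lp)
  post <- post / rowSums(post)
  colnames(post) <- classes
  list(posterior = post, labels = classes[max.col(post, "first")])
}

#' Fit one ZIPMRM per class on count features
#'
#' Convenience classifier wrapper: the count matrix is melted to long form
#' with the feature identity entering both as regressor and concomitant
#' one-hot covariates, so each class is described by a single ZIPMRM whose
#' component rates and weights vary by feature.
#'
#' @param counts Integer matrix (observations x features), e.g. from
#'   [discretize_counts()].
#' @param labels Class label per row.
#' @param K Components per class model, default 2.
#' @param ... Passed to [fit_zipmrm()].
#' @return Named list of `zipmrm_fit`, with attribute `"priors"` set to the
#'   training class frequencies.
#' @export
fit_zipmrm_classifier <- function(counts, labels, K = 2L, ...) {
  counts <- as.matrix(counts)
  p <- ncol(counts)
  labels <- as.character(labels)
  feat_onehot <- function(nrep) {
    # feature indicator columns 2..p (first feature is the baseline)
    f <- rep(seq_len(p), each = nrep)
    m <- matrix(0, length(f), p - 1L)
    for (j in 2:p) m[f == j, j - 1L] <- 1
    m
  }
  fits <- lapply(split(seq_along(labels), labels), function(idx) {
    uu <- as.vector(counts[idx, , drop = FALSE])   # column-major: feature blocks
    x <- if (p > 1L) feat_onehot(length(idx)) else NULL
    fit_zipmrm(uu, v1 = x, v2 = x, K = K, ...)
  })
  attr(fits, "priors") <- as.numeric(table(labels)[names(fits)]) / length(labels)
  fits
}

#' Predict classes from per-class long-form ZIPMRM fits
#'
#' Counterpart of [fit_zipmrm_classifier()]: scores each row's counts as
#' the product of per-feature densities under each class model.
#'
#' @param fits Result of [fit_zipmrm_classifier()].
#' @param counts Integer matrix with the same columns as in training.
#' @param priors Class priors; default the training frequencies.
#' @return As [predict_zipmrm()].
#' @export
predict_zipmrm_classifier <- function(fits, counts, priors = attr(fits, "priors")) {
  counts <- as.matrix(counts)
  p <- ncol(counts)
  n <- nrow(counts)
  classes <- names(fits)
  loglik <- vapply(fits, function(f) {
    pr <- f$params
    ll <- numeric(n)
    for (j in seq_len(p)) {
      x <- if (p > 1L) {
        m <- matrix(0, n, p - 1L)
        if (j > 1L) m[, j - 1L] <- 1
        m
      } else NULL
      d <- zipmrm_density(counts[, j], x, x, pr)
      ll <- ll + log(pmax(d, 1e-300))
    }
    ll
  }, numeric(n))
  loglik <- matrix(loglik, nrow = n)
  if (is.null(priors)) priors <- rep(1 / length(classes), length(classes))
  lp <- sweep(loglik, 2L, log(priors / sum(priors)), `+`)
  lp <- lp - apply(lp, 1L, max)
  post <- exp(lp); post <- post / rowSums(post)
  colnames(post) <- classes
  list(posterior = post, labels = classes[max.col(post, "first")])
}
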