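test_that("tail-location plug-ins follow the stated estimator", {
  expect_equal(estimate_tail_locations(c(-2.5, -0.3, 0.4, 1.1)),
               c(xi1 = 0.3, xi2 = 0.4))
  expect_equal(estimate_tail_locations(c(-1, 2)), c(xi1 = 1, xi2 = 2))
  a <- 0.7
  expect_equal(unname(estimate_tail_locations(c(-3, -a, a, 3))), c(a, a))
  expect_error(estimate_tail_locations(c(1, 2, 3)), "negative")
})

test_that("intensity weights are the one-sided neglect function", {
  expect_equal(observation_weights(0), 1)
  expect_equal(observation_weights(-1.5, g = 1.5), 1)   # continuous knot
  expect_equal(observation_weights(-3, g = 1.5), 0.5)
  v <- seq(-10, 3, by = 0.07)
  w <- observation_weights(v)
  expect_true(all(w > 0 & w <= 1))
  # continuity across the knot
  eps <- 1e-9
  expect_lt(abs(observation_weights(-1.5 - eps) -
                  observation_weights(-1.5 + eps)), 1e-8)
})

test_that("SVD intensities rank dim observations lowest and are scale-free", {
  # rank-1 matrix, one row scaled down: that row has the smallest v
  u <- c(1, -2, 1.5)
  m <- rbind(2 * u, 3 * u, 1e-3 * u)
  v <- svd_intensity(m)
  expect_equal(which.min(v), 3L)
  # z-scored, so doubling the matrix changes nothing
  expect_equal(svd_intensity(2 * m), v, tolerance = 1e-9)
  # identical observations: all equal v (zeros)
  expect_equal(svd_intensity(rbind(u, u, u)), rep(0, 3))
  expect_equal(svd_intensity(matrix(0, 3, 4)), rep(0, 3))
})

test_that("component densities evaluate exactly as defined", {
  p <- fhm_params("NUDGE", pi = 0.3, mu = 0, sigma = 1, uniform = c(-2, 2))
  expect_equal(density_f1(0, p), 0.25)
  expect_equal(density_f1(3, p), 0)
  expect_equal(density_f0(0, p), dnorm(0))

  g <- fhm_params("GNG", pi = 0.3, mu = 0, sigma = 1, rho = 1, beta1 = 2,
                  beta2 = 1, xi = c(1, 1))
  expect_equal(density_f1(-3, g), 0.5 * exp(-1))   # shifted exponential
  expect_equal(density_f1(0, g), 0)                # indicator gap
  expect_equal(density_f1(0.5, g), 0)

  # two-component bulk is the weighted sum of normals
  p2 <- fhm_params("eNUDGE", pi = 0, mu = c(-1, 1), sigma = c(1, 1),
                   gamma = c(0.3, 0.7), uniform = c(-5, 5))
  expect_equal(density_f0(0, p2), 0.3 * dnorm(0, -1) + 0.7 * dnorm(0, 1))
  # identical equal-weight components collapse to one
  pid <- fhm_params("eNUDGE", pi = 0, mu = c(2, 2), sigma = c(1.5, 1.5),
                    gamma = c(0.5, 0.5), uniform = c(-5, 5))
  expect_equal(density_f0(1.1, pid), dnorm(1.1, 2, 1.5))

  # mixture boundaries
  z <- seq(-3, 3, by = 0.5)
  p0 <- fhm_params("NUDGE", pi = 0, mu = 0, sigma = 1, uniform = c(-2, 2))
  p1 <- fhm_params("NUDGE", pi = 1, mu = 0, sigma = 1, uniform = c(-2, 2))
  expect_equal(mixture_density(z, p0), density_f0(z, p0))
  expect_equal(mixture_density(z, p1), density_f1(z, p1))
})

test_that("every mixture density integrates to one by quadrature", {
  cases <- list(
    fhm_params("NUDGE", pi = 0.25, mu = 0.3, sigma = 1.2, uniform = c(-4, 6)),
    fhm_params("eNUDGE", pi = 0.15, mu = c(-2, 1), sigma = c(0.5, 2),
               gamma = c(0.4, 0.6), uniform = c(-8, 8)),
    fhm_params("GNG", pi = 0.35, mu = c(0, 2), sigma = c(1, 0.7),
               gamma = c(0.7, 0.3), rho = 0.6, beta1 = 1.4, beta2 = 0.9,
               xi = c(0.8, 1.1)))
  for (p in cases)
    expect_equal(quad_mixture(p), 1, tolerance = 1e-4)
})

test_that("weighted log-likelihood is a weighted sum with -Inf sentinel", {
  p <- fhm_params("NUDGE", pi = 0, mu = 0, sigma = 1, uniform = c(-2, 2))
  expect_equal(weighted_loglik(0, 0.5, p), 0.5 * log(dnorm(0)))
  set.seed(61)
  z <- rnorm(50)
  w <- runif(50, 0.3, 1)
  expect_equal(weighted_loglik(z, 1, p), sum(log(dnorm(z))))
  expect_equal(weighted_loglik(z, w / 2, p), weighted_loglik(z, w, p) / 2)
  # zero density under positive weight
  pu <- fhm_params("NUDGE", pi = 1, mu = 0, sigma = 1, uniform = c(-1, 1))
  ll <- weighted_loglik(c(0, 5), 1, pu)
  expect_identical(as.numeric(ll), -Inf)
  expect_equal(attr(ll, "zero_density_at"), 2L)
})

test_that("weighted EM increases the objective and respects the stop rule", {
  set.seed(71)
  z <- c(rnorm(400), runif(100, -6, 6))
  w <- runif(500, 0.4, 1)
  for (cl in c("NUDGE", "eNUDGE", "GNG")) {
    f <- em_fit(z, w, cl, Q = 2)
    expect_true(all(diff(f$loglik_trace) > -1e-9),
                info = paste("monotone loglik for", cl))
    expect_equal(f$loglik, weighted_loglik(z, w, f$params))
  }
  # eps = Inf stops after a single sweep
  f1 <- em_fit(z, 1, "NUDGE", eps = Inf)
  expect_identical(f1$n_iter, 1L)
  expect_true(f1$converged)
})

test_that("EM recovers known generators", {
  # pure normal data: NUDGE attributes almost nothing to the uniform part
  set.seed(81)
  zn <- rnorm(2000)
  fn <- em_fit(zn, 1, "NUDGE")
  expect_lte(fn$params$pi, 0.05)

  # eNUDGE parameter recovery at n = 5000, 3-sigma separation
  truth <- fhm_params("eNUDGE", pi = 0.2, mu = c(-1.5, 1.5), sigma = c(1, 1),
                      uniform = c(-8, 8))
  z <- gen_mixture_sample(truth, 5000, seed = 42)
  f <- em_fit(z, 1, "eNUDGE", Q = 2)
  expect_lt(abs(f$params$pi - 0.2), 0.05)
  expect_lt(max(abs(sort(f$params$mu) - c(-1.5, 1.5))), 0.1)
})

test_that("model selection prefers the true bulk size and simpler ties", {
  # single-normal data: winner should keep one bulk component
  set.seed(91)
  z <- rnorm(1500)
  win <- select_model(z, 1, Q_max = 3)
  expect_equal(win$params$Q, 1L)
  expect_s3_class(win$candidates, "data.frame")
  expect_true(all(c("NUDGE", "eNUDGE", "GNG") %in% win$candidates$class))
  # retained mask and fdr populated
  expect_length(win$fdr, length(z))
  expect_length(win$retained_mask, length(z))
})

test_that("differential labelling follows the location-scale outlier rule", {
  f <- em_fit(rnorm(200, 0, 1), 1, "NUDGE")
  f$params$mu <- 2; f$params$sigma <- 1
  z2 <- c(-1, 1)                       # IDR = IQR = 2
  expect_true(label_differential(f, z2)) # 2 + 2 > 3
  f$params$mu <- 0; f$params$sigma <- 0.1
  expect_false(label_differential(f, z2)) # 0.2 <= 3
  # degenerate data: IDR 0 makes any spread component differential
  expect_true(label_differential(f, rep(1, 10)))
})

test_that("FDR scores are the non-differential density ratio", {
  set.seed(101)
  z <- rnorm(300)
  f <- em_fit(z, 1, "NUDGE")
  # force pi = 0 and non-differential: FDR must be exactly 1 everywhere
  f$params$pi <- 0
  f$differential_flags <- FALSE
  expect_equal(fdr_scores(z, f), rep(1, length(z)))
  # all components differential: empty numerator
  f$differential_flags <- TRUE
  expect_equal(fdr_scores(z, f), rep(0, length(z)))
  # hand-computed mixture: pi = 0.5, one non-differential normal + uniform
  ph <- fhm_params("NUDGE", pi = 0.5, mu = 0, sigma = 1, uniform = c(-4, 4))
  fh <- f; fh$params <- ph; fh$differential_flags <- FALSE
  expected <- 0.5 * dnorm(0) / (0.5 * dnorm(0) + 0.5 / 8)
  expect_equal(fdr_scores(0, fh), expected)
})

test_that("observation retention is monotone in the threshold", {
  set.seed(111)
  fdr <- runif(50, 0, 2)
  wei <- runif(50, 0.2, 1)
  expect_true(select_observations(0.1, 1, 0.2))
  expect_false(select_observations(0.1, 0.25, 0.2))  # 0.4 > 0.2
  expect_true(all(select_observations(fdr, wei, Inf)))
  prev <- rep(FALSE, 50)
  for (y0 in c(0.01, 0.1, 0.5, 1, 5)) {
    cur <- select_observations(fdr, wei, y0)
    expect_true(all(cur[prev]))   # larger threshold keeps supersets
    prev <- cur
  }
})

test_that("descriptor and fit results are bit-stable across runs", {
  set.seed(121)
  z <- c(rnorm(300), runif(60, -5, 5))
  f1 <- em_fit(z, 1, "eNUDGE", Q = 2)
  f2 <- em_fit(z, 1, "eNUDGE", Q = 2)
  expect_identical(param_vec <- f1$params, f2$params)
  expect_identical(f1$loglik, f2$loglik)
})
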