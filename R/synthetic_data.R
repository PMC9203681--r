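#' Seeded synthetic biosignal generators
#'
#' Generators for every input the pipeline consumes: two-class surrogate
#' EEG-like segments (a stationary AR(2)-plus-sinusoid background, with
#' class-dependent high-amplitude spike bursts mimicking ictal activity),
#' direct draws from the fusion mixture densities, zero-inflated Poisson
#' mixture counts with known latent labels, and standard optimisation
#' benchmark functions. Every generator is a pure function of its
#' specification and seed.
#'
#' @name synthetic_data
NULL

#' Specification of the two-class surrogate signal generator
#'
#' @param n_per_class Segments per class, default 100.
#' @param signal_length Samples per segment, default 512.
#' @param ar AR(2) coefficients of the shared background; must define a
#'   stationary process (roots of `1 - a1 z - a2 z^2` outside the unit
#'   circle).
#' @param sine_freq Sinusoid frequency in cycles/sample, default 0.05.
#' @param sine_amp Sinusoid amplitude, default 2.
#' @param noise_sd Innovation SD of the AR background, default 1.
#' @param spike_rate Expected spikes per sample in class 1, default 0.02;
#'   0 makes the classes statistically indistinguishable.
#' @param spike_amp Spike amplitude, default 10.
#' @param seed Seed, default 1.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_class = 100L, signal_length = 512L,
                           ar = c(0.5, -0.3), sine_freq = 0.05,
                           sine_amp = 2, noise_sd = 1, spike_rate = 0.02,
                           spike_amp = 10, seed = 1L) {
  roots <- polyroot(c(1, -ar))
  if (any(Mod(roots) <= 1))
    stop("AR coefficients define a non-stationary process")
  structure(list(n_per_class = as.integer(n_per_class),
                 signal_length = as.integer(signal_length), ar = ar,
                 sine_freq = sine_freq, sine_amp = sine_amp,
                 noise_sd = noise_sd, spike_rate = spike_rate,
                 spike_amp = spike_amp, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate labelled two-class surrogate signals
#'
#' Class `"background"` segments are a stationary AR(2) process plus a
#' sinusoid; class `"spiking"` segments add intermittent high-amplitude
#' biphasic spike bursts, raising their variance and kurtosis the way ictal
#' EEG differs from background activity. Deterministic given the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List of [signal_record()] with labels `"background"` /
#'   `"spiking"`.
#' @export
gen_two_class_signals <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$signal_length
  one_segment <- function(label, k) {
    base <- as.numeric(stats::arima.sim(list(ar = spec$ar), n,
                                        sd = spec$noise_sd))
    base <- base + spec$sine_amp *
      sin(2 * pi * spec$sine_freq * seq_len(n) + stats::runif(1, 0, 2 * pi))
    if (label == "spiking" && spec$spike_rate > 0) {
      n_spikes <- stats::rpois(1, spec$spike_rate * n)
      if (n_spikes > 0) {
        at <- sample.int(n - 4L, n_spikes, replace = TRUE)
        shape <- c(0.4, 1, -0.7, 0.25)   # short biphasic transient
        for (s in at) {
          amp <- spec$spike_amp * stats::runif(1, 0.7, 1.3) * sample(c(-1, 1), 1)
          idx <- s:(s + 3L)
          base[idx] <- base[idx] + amp * shape
        }
      }
    }
    signal_record(base, channel_id = sprintf("%s_%03d", label, k),
                  label = label)
  }
  c(lapply(seq_len(spec$n_per_class), function(k) one_segment("background", k)),
    lapply(seq_len(spec$n_per_class), function(k) one_segment("spiking", k)))
}

#' Draw observations from a fusion mixture
#'
#' With probability `pi` a draw comes from the overdispersion part f1
#' (uniform, or the two shifted exponential tails for GNG), otherwise from
#' the normal bulk f0.
#'
#' @param params An [fhm_params()] object.
#' @param n Number of draws.
#' @param seed Seed, default 1.
#' @return Numeric vector of length `n` with attribute `"component"`
#'   (`"f1"` or the bulk component index) for recovery tests.
#' @export
gen_mixture_sample <- function(params, n, seed = 1L) {
  stopifnot(inherits(params, "fhm_params"))
  set.seed(seed)
  from_f1 <- stats::runif(n) < params$pi
  z <- numeric(n)
  comp <- character(n)
  n1 <- sum(from_f1)
  if (n1 > 0) {
    if (params$model_class %in% c("NUDGE", "eNUDGE")) {
      z[from_f1] <- stats::runif(n1, params$uniform[1], params$uniform[2])
    } else {
      left <- stats::runif(n1) < params$rho
      d <- numeric(n1)
      d[left] <- -params$xi[1] - stats::rexp(sum(left), rate = 1 / params$beta1)
      d[!left] <- params$xi[2] + stats::rexp(sum(!left), rate = 1 / params$beta2)
      z[from_f1] <- d
    }
    comp[from_f1] <- "f1"
  }
  n0 <- n - n1
  if (n0 > 0) {
    q <- sample.int(params$Q, n0, replace = TRUE, prob = params$gamma)
    z[!from_f1] <- stats::rnorm(n0, params$mu[q], params$sigma[q])
    comp[!from_f1] <- as.character(q)
  }
  attr(z, "component") <- comp
  z
}

#' Draw counts from a zero-inflated Poisson mixture regression model
#'
#' Structural zeros occur with probability `psi`; otherwise a component is
#' drawn by the concomitant weights and the count is Poisson with that
#' component's rate. Latent component labels (0 = structural zero) are
#' returned for recovery tests.
#'
#' @param params A [zipmrm_params()] object.
#' @param v1,v2 Covariate matrices (or `NULL`), recycled to `n` rows.
#' @param n Number of observations.
#' @param seed Seed, default 1.
#' @return List with `u` (counts), `v1`, `v2` and `component` (latent).
#' @export
gen_zip_counts <- function(params, v1 = NULL, v2 = NULL, n, seed = 1L) {
  stopifnot(inherits(params, "zipmrm_params"))
  set.seed(seed)
  v1m <- if (is.null(v1)) NULL else as.matrix(v1)
  v2m <- if (is.null(v2)) matrix(0, n, 0L) else as.matrix(v2)
  lam <- component_rates(params, v1m, n)
  pi_q <- concomitant_weights(v2m, params$gamma0, params$gamma)
  comp <- integer(n)
  u <- integer(n)
  structural <- stats::runif(n) < params$psi
  for (i in which(!structural)) {
    q <- sample.int(params$K, 1L, prob = pi_q[i, ])
    comp[i] <- q
    u[i] <- stats::rpois(1L, lam[i, q])
  }
  list(u = u, v1 = v1m, v2 = if (ncol(v2m)) v2m else NULL, component = comp)
}

#' Standard optimisation benchmark functions
#'
#' @param name One of `"sphere"`, `"rastrigin"`, `"rosenbrock"`.
#' @return List with `fn` (vector-to-scalar objective), `optimum_value`
#'   and `optimum_at` (a function of the dimension).
#' @export
benchmark_function <- function(name = c("sphere", "rastrigin", "rosenbrock")) {
  name <- match.arg(name)
  switch(name,
    sphere = list(
      fn = function(x) sum(x^2),
      optimum_value = 0, optimum_at = function(d) rep(0, d)),
    rastrigin = list(
      fn = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
      optimum_value = 0, optimum_at = function(d) rep(0, d)),
    rosenbrock = list(
      fn = function(x) sum(100 * (x[-1] - x[-length(x)]^2)^2 +
                             (1 - x[-length(x)])^2),
      optimum_value = 0, optimum_at = function(d) rep(1, d)))
}

#' Write Bonn-style text files for generated signals
#'
#' One file per segment (one sample per line) plus a labels CSV mapping
#' file names to class labels.
#'
#' @param records List of [signal_record()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the labels CSV path.
#' @export
write_bonn_dataset <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(seq_along(records), function(i) {
    f <- file.path(dir, sprintf("seg%04d.txt", i))
    writeLines(formatC(records[[i]]$samples, format = "g", digits = 15), f)
    basename(f)
  }, character(1))
  labels <- vapply(records, function(r) as.character(r$label), character(1))
  csv <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(file = files, label = labels), csv,
                   row.names = FALSE)
  invisible(csv)
}
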