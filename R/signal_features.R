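#' Construct a signal record
#'
#' A `signal_record` holds one sampled biosignal segment together with its
#' metadata: the sampling rate (optional, informational only), a channel
#' identifier and a class label (e.g. \code{"ictal"} vs \code{"background"}).
#'
#' @param samples Numeric vector of samples, arbitrary amplitude units.
#'   Must be non-empty and finite.
#' @param sampling_rate Sampling rate in Hz, or `NULL` if unknown.
#' @param channel_id Character scalar naming the channel.
#' @param label Class label (character or factor level), or `NA`.
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(samples, sampling_rate = NULL, channel_id = "ch1",
                          label = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    stop("'samples' must be non-empty")
  if (!all(is.finite(samples)))
    stop("'samples' must be finite")
  structure(
    list(samples = samples,
         sampling_rate = sampling_rate,
         channel_id = as.character(channel_id),
         label = label),
    class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> channel=%s label=%s n=%d%s\n",
              x$channel_id, as.character(x$label), length(x$samples),
              if (is.null(x$sampling_rate)) "" else
                sprintf(" fs=%gHz", x$sampling_rate)))
  invisible(x)
}

#' Split a signal into fixed-length windows
#'
#' Windows are taken left to right with stride
#' `round(window_length * (1 - overlap_fraction))`; a trailing partial
#' window is dropped.
#'
#' @param record A [signal_record()].
#' @param window_length Window length in samples (at least 8).
#' @param overlap_fraction Fraction of overlap between consecutive windows,
#'   in `[0, 1)`. The default 0 gives non-overlapping windows that tile the
#'   signal without gaps.
#' @return A list of `signal_record` windows inheriting the parent metadata.
#' @export
segment_signal <- function(record, window_length, overlap_fraction = 0) {
  stopifnot(inherits(record, "signal_record"))
  n <- length(record$samples)
  window_length <- as.integer(window_length)
  if (window_length < 8L)
    stop("'window_length' must be at least 8 samples")
  if (window_length > n)
    stop(sprintf("window (%d) longer than signal (%d)", window_length, n))
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("'overlap_fraction' must be in [0, 1)")
  stride <- max(1L, as.integer(round(window_length * (1 - overlap_fraction))))
  starts <- seq.int(1L, n - window_length + 1L, by = stride)
  lapply(starts, function(s) {
    w <- record
    w$samples <- record$samples[s:(s + window_length - 1L)]
    w$window_start <- s
    w
  })
}

#' Moment descriptors of a sample vector
#'
#' Returns the mean, unbiased (n-1) variance, skewness and excess kurtosis
#' (so a normal sample is near 0). Skewness and kurtosis use the population
#' central-moment form `m3 / m2^(3/2)` and `m4 / m2^2 - 3`. A constant input
#' has variance 0 and undefined (NA) skewness/kurtosis.
#'
#' @param x Numeric vector of length at least 3.
#' @return Named numeric vector `c(mean, variance, skewness, kurtosis)`.
#' @export
compute_moments <- function(x) {
  if (length(x) < 3L) stop("need at least 3 samples")
  n <- length(x)
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  if (m2 <= 0) {
    return(c(mean = mu, variance = 0, skewness = NA_real_,
             kurtosis = NA_real_))
  }
  c(mean = mu,
    variance = sum(d^2) / (n - 1),
    skewness = mean(d^3) / m2^1.5,
    kurtosis = mean(d^4) / m2^2 - 3)
}

#' Sample entropy
#'
#' `-ln(A/B)` where `B` counts pairs of length-`m` templates within Chebyshev
#' distance `r` of each other and `A` the corresponding count at length
#' `m + 1`; self-matches are excluded. Higher values indicate a less regular
#' signal. If either count is zero the entropy is reported as `Inf` rather
#' than raising an error.
#'
#' @param x Numeric vector, length at least `m + 2`.
#' @param m Template (embedding) length, default 2.
#' @param r Match tolerance; default `0.2 * sd(x)`. Must be positive, so a
#'   constant input needs an explicit `r`.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  m <- as.integer(m)
  if (n < m + 2L) stop("input too short for embedding length m")
  if (!is.finite(r) || r <= 0) stop("'r' must be positive")
  # both template sets range over i = 1..n-m so that every length-m template
  # has a length-(m+1) continuation (the standard convention)
  count_matches <- function(len, nt) {
    tpl <- matrix(x[outer(seq_len(nt), 0:(len - 1L), `+`)], nrow = nt)
    cnt <- 0L
    for (i in seq_len(nt - 1L)) {
      dmax <- abs(tpl[(i + 1L):nt, , drop = FALSE] -
                    matrix(tpl[i, ], nrow = nt - i, ncol = len, byrow = TRUE))
      dmax <- if (len == 1L) as.vector(dmax) else apply(dmax, 1L, max)
      cnt <- cnt + sum(dmax <= r)
    }
    cnt
  }
  B <- count_matches(m, n - m)
  A <- count_matches(m + 1L, n - m)
  if (A == 0L || B == 0L) return(Inf)
  -log(A / B)
}

#' Permutation entropy
#'
#' Shannon entropy (natural log) of the empirical distribution of ordinal
#' patterns of the given order and delay. The maximum is `ln(order!)`; a
#' monotone ramp gives 0. Ties are broken by position (first occurrence
#' ranks lower), the usual convention for sampled signals.
#'
#' @param x Numeric vector of length at least `order * delay + 1`.
#' @param order Pattern order (number of points per pattern), default 3.
#' @param delay Lag between pattern points, default 1.
#' @return Entropy in nats, in `[0, log(factorial(order))]`.
#' @export
permutation_entropy <- function(x, order = 3L, delay = 1L) {
  n <- length(x)
  order <- as.integer(order); delay <- as.integer(delay)
  if (n < order * delay + 1L) stop("input too short for order and delay")
  npat <- n - (order - 1L) * delay
  idx <- outer(seq_len(npat), seq.int(0L, by = delay, length.out = order), `+`)
  pats <- apply(matrix(x[idx], nrow = npat), 1L, function(v)
    paste(order(v, method = "radix"), collapse = ""))
  p <- tabulate(factor(pats)) / npat
  -sum(p * log(p))
}

default_descriptors <- function() {
  list(
    mean = function(x) compute_moments(x)[["mean"]],
    variance = function(x) compute_moments(x)[["variance"]],
    skewness = function(x) compute_moments(x)[["skewness"]],
    kurtosis = function(x) compute_moments(x)[["kurtosis"]],
    sample_entropy = function(x) {
      v <- sample_entropy(x)
      if (is.infinite(v)) NA_real_ else v
    },
    permutation_entropy = function(x) permutation_entropy(x))
}

#' Build the observation-by-descriptor feature matrix
#'
#' Applies each descriptor to each segment, records the mean absolute
#' amplitude of each window as its intensity, and z-scores every column
#' (the normalised values are what the fusion mixture models downstream).
#' Segments on which a descriptor fails or returns a non-finite value are
#' dropped with a warning.
#'
#' @param segments List of [signal_record()] windows.
#' @param descriptors Named list of functions mapping a numeric vector to a
#'   scalar; defaults to the six standard descriptors (mean, variance,
#'   skewness, excess kurtosis, sample entropy, permutation entropy).
#' @param normalize Z-score columns (default `TRUE`). Normalisation of a
#'   single row is degenerate and raises an error.
#' @return A `feature_matrix` object: `values` (normalised), `raw`,
#'   `feature_names`, `intensities`, `labels`, `normalization`
#'   (per-column center/scale), `dropped` (indices of excluded segments).
#' @export
build_feature_matrix <- function(segments, descriptors = default_descriptors(),
                                 normalize = TRUE) {
  if (length(segments) < 1L || length(descriptors) < 1L)
    stop("need at least one segment and one descriptor")
  if (is.null(names(descriptors)))
    names(descriptors) <- paste0("f", seq_along(descriptors))
  raw <- t(vapply(segments, function(s) {
    vapply(descriptors, function(f) {
      v <- tryCatch(f(s$samples), error = function(e) NA_real_)
      if (length(v) != 1L || !is.finite(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  }, numeric(length(descriptors))))
  colnames(raw) <- names(descriptors)
  labels <- vapply(segments, function(s) as.character(s$label), character(1))
  intens <- vapply(segments, function(s) mean(abs(s$samples)), numeric(1))
  bad <- which(rowSums(!is.finite(raw)) > 0L)
  if (length(bad)) {
    warning(sprintf("dropping %d segment(s) with failed descriptors: %s",
                    length(bad), paste(utils::head(bad, 10L), collapse = ", ")))
    raw <- raw[-bad, , drop = FALSE]
    labels <- labels[-bad]
    intens <- intens[-bad]
  }
  norm <- NULL
  values <- raw
  if (normalize) {
    if (nrow(raw) < 2L)
      stop("cannot z-score a single observation (scale undefined)")
    norm <- normalization_constants(raw)
    values <- apply_normalization(raw, norm)
  }
  structure(
    list(values = values, raw = raw, feature_names = colnames(raw),
         intensities = intens, labels = labels, normalization = norm,
         dropped = bad),
    class = "feature_matrix")
}

#' Column centering/scaling constants
#'
#' @param x Numeric matrix.
#' @return List with `center` and `scale` per column; zero-variance columns
#'   get scale 1 so normalisation maps them to 0.
#' @export
normalization_constants <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl <= 0] <- 1
  list(center = ctr, scale = scl)
}

#' Apply stored normalisation constants to new rows
#'
#' Used to transform held-out segments with constants derived from training
#' rows only, so no test information leaks into the normalisation.
#'
#' @param x Numeric matrix (or `feature_matrix$raw`).
#' @param norm List with `center` and `scale` as returned by
#'   [normalization_constants()].
#' @return Matrix of the same shape, columns centred and scaled.
#' @export
apply_normalization <- function(x, norm) {
  sweep(sweep(x, 2L, norm$center, `-`), 2L, norm$scale, `/`)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d observations x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' Read a Bonn-style plain-text signal file
#'
#' One numeric sample per line, ASCII, no header.
#'
#' @param path File path.
#' @inheritParams signal_record
#' @return A [signal_record()].
#' @export
read_bonn <- function(path, sampling_rate = NULL, channel_id = NULL,
                      label = NA_character_) {
  x <- scan(path, what = numeric(), quiet = TRUE)
  signal_record(x, sampling_rate = sampling_rate,
                channel_id = channel_id %||% basename(path), label = label)
}

#' Read a CSV signal matrix (rows = samples, columns = channels)
#'
#' @param path File path. A header row of channel names is optional and
#'   detected automatically.
#' @inheritParams signal_record
#' @return A list of [signal_record()], one per channel.
#' @export
read_signal_csv <- function(path, sampling_rate = NULL, label = NA_character_) {
  first <- readLines(path, n = 1L)
  has_header <- suppressWarnings(
    any(is.na(as.numeric(strsplit(first, ",")[[1]]))))
  d <- utils::read.csv(path, header = has_header)
  lapply(seq_len(ncol(d)), function(j)
    signal_record(d[[j]], sampling_rate = sampling_rate,
                  channel_id = colnames(d)[j], label = label))
}

#' Write a feature matrix as CSV plus a JSON metadata sidecar
#'
#' @param fm A `feature_matrix`.
#' @param csv_path Path for the values CSV (normalised values, header row).
#' @param meta_path Path for the JSON sidecar holding labels, intensities
#'   and normalisation constants; defaults to `csv_path` with `.json`.
#' @return Invisibly, the two paths.
#' @export
write_feature_matrix <- function(fm, csv_path,
                                 meta_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(fm, "feature_matrix"))
  utils::write.csv(as.data.frame(fm$values), csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(feature_names = fm$feature_names, labels = fm$labels,
         intensities = fm$intensities, normalization = fm$normalization),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, meta = meta_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
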