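test_that("segmentation covers the signal and enumerates the right starts", {
  r <- signal_record(seq_len(4097))
  w <- segment_signal(r, 256)
  expect_length(w, 16L)           # floor(4097 / 256)
  expect_true(all(vapply(w, function(s) length(s$samples), integer(1)) == 256L))
  # at overlap 0 the windows tile the prefix without gaps
  recon <- unlist(lapply(w, `[[`, "samples"))
  expect_identical(recon, as.numeric(seq_len(16 * 256)))

  w1 <- segment_signal(signal_record(seq_len(100)), 100)
  expect_length(w1, 1L)
  expect_identical(w1[[1]]$samples, as.numeric(1:100))

  # overlap 0.5, window 60 on 100 samples: starts 1 and 31 only
  w2 <- segment_signal(signal_record(seq_len(100)), 60, 0.5)
  expect_length(w2, 2L)
  expect_identical(vapply(w2, `[[`, integer(1), "window_start"), c(1L, 31L))

  expect_error(segment_signal(signal_record(1:50), 60), "longer than")
  expect_error(segment_signal(signal_record(1:50), 4), "at least 8")
})

test_that("moments match their definitions and conventions", {
  m <- compute_moments(c(1, 2, 3))
  expect_equal(m[["mean"]], 2)
  expect_equal(m[["variance"]], 1)    # unbiased (n-1) denominator
  expect_equal(m[["skewness"]], 0)

  # mirrored samples have zero skewness
  set.seed(4)
  x <- rexp(200)
  xs <- c(x, -x)                       # symmetric about 0
  expect_equal(compute_moments(xs)[["skewness"]], 0, tolerance = 1e-12)

  # excess-kurtosis convention: standard normal draws near 0
  set.seed(11)
  g <- rnorm(10000)
  expect_lt(abs(compute_moments(g)[["kurtosis"]]), 0.15)

  # constant input: variance 0, undefined higher moments
  cm <- compute_moments(rep(2, 10))
  expect_equal(cm[["variance"]], 0)
  expect_true(is.na(cm[["skewness"]]) && is.na(cm[["kurtosis"]]))

  # agreement with an established implementation
  skip_if_not_installed("e1071")
  set.seed(12)
  y <- rgamma(500, 2)
  expect_equal(compute_moments(y)[["skewness"]],
               e1071::skewness(y, type = 1), tolerance = 1e-12)
  expect_equal(compute_moments(y)[["kurtosis"]],
               e1071::kurtosis(y, type = 1), tolerance = 1e-12)
})

test_that("sample entropy matches brute-force template counting", {
  x <- c(1, 2, 1, 2, 1, 2, 1, 2)
  expect_equal(sample_entropy(x, m = 2, r = 0.1), sampen_brute(x, 2, 0.1))

  set.seed(21)
  y <- rnorm(60)
  for (m in c(1L, 2L, 3L))
    expect_equal(sample_entropy(y, m = m, r = 0.25),
                 sampen_brute(y, m, 0.25))

  # constant sequence: all templates match, -ln(1) = 0
  expect_equal(sample_entropy(rep(3, 30), m = 2, r = 0.5), 0)

  # joint scaling of x and r leaves the value unchanged
  expect_equal(sample_entropy(y, 2, 0.25), sample_entropy(7 * y, 2, 7 * 0.25))

  # no matches at strict tolerance -> Inf sentinel, not an error
  expect_identical(sample_entropy(c(0, 10, -10, 20, -20, 40), 2, 1e-6), Inf)
  expect_error(sample_entropy(1:3, m = 2, r = 1), "too short")

  # independent implementation agrees
  skip_if_not_installed("pracma")
  set.seed(22)
  w <- rnorm(200)
  expect_equal(sample_entropy(w, 2, 0.2 * sd(w)),
               pracma::sample_entropy(w, edim = 2, r = 0.2 * sd(w)),
               tolerance = 1e-12)
})

test_that("permutation entropy matches an explicit ordinal tally", {
  expect_equal(permutation_entropy(1:100), 0)          # single pattern
  set.seed(31)
  y <- rnorm(50)
  expect_equal(permutation_entropy(y, 3, 1), pe_brute(y, 3L, 1L))
  expect_equal(permutation_entropy(y, 4, 2), pe_brute(y, 4L, 2L))
  expect_lte(permutation_entropy(y, 3, 1), log(6))
  # invariant to positive affine maps
  expect_equal(permutation_entropy(2.5 * y + 3), permutation_entropy(y))
  expect_error(permutation_entropy(1:3, order = 4), "too short")
})

test_that("a uniform ordinal-pattern distribution reaches ln 6", {
  # search a seeded pool for a vector whose 6 order-3 patterns (delay 1)
  # are exactly uniform, then check the maximum-entropy value ln 6
  set.seed(33)
  found <- FALSE
  for (k in 1:500) {
    x <- rnorm(8)
    if (abs(permutation_entropy(x, 3, 1) - log(6)) < 1e-12) {
      found <- TRUE
      expect_equal(pe_brute(x, 3L, 1L), log(6))
      break
    }
  }
  expect_true(found)
})

test_that("feature matrix is normalised, deterministic, and guards failures", {
  set.seed(41)
  segs <- lapply(1:8, function(i) signal_record(rnorm(256), label = "a"))
  fm <- build_feature_matrix(segs)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(dim(fm$values), c(8L, 6L))
  expect_true(all(abs(colMeans(fm$values)) < 1e-9))
  expect_true(all(abs(apply(fm$values, 2, sd) - 1) < 1e-9))
  expect_equal(fm$intensities,
               vapply(segs, function(s) mean(abs(s$samples)), numeric(1)))
  expect_true(all(fm$intensities >= 0))

  # duplicate segments give identical raw rows
  fm2 <- build_feature_matrix(c(segs, segs[1]), normalize = FALSE)
  expect_equal(fm2$raw[9, ], fm2$raw[1, ])

  expect_error(build_feature_matrix(segs[1]), "single observation")

  # descriptor failure drops the row with a warning
  bad <- c(segs, list(signal_record(rep(1, 256), label = "a")))  # constant
  expect_warning(fm3 <- build_feature_matrix(bad), "dropping")
  expect_equal(nrow(fm3$values), 8L)
  expect_identical(fm3$dropped, 9L)
})

test_that("normalisation constants transfer to new data without leakage", {
  set.seed(51)
  xtr <- matrix(rnorm(60, 5, 2), 20)
  norm <- normalization_constants(xtr)
  z <- apply_normalization(xtr, norm)
  expect_true(all(abs(colMeans(z)) < 1e-12))
  xte <- matrix(rnorm(30, 5, 2), 10)
  zte <- apply_normalization(xte, norm)
  expect_equal(zte, (xte - rep(norm$center, each = 10)) /
                 rep(norm$scale, each = 10))
})

test_that("Bonn and CSV readers round-trip generated signals", {
  dir <- withr::local_tempdir()
  rec <- signal_record(round(rnorm(100), 6), label = "x")
  f <- file.path(dir, "seg.txt")
  writeLines(format(rec$samples, scientific = FALSE), f)
  back <- read_bonn(f, label = "x")
  expect_equal(back$samples, rec$samples, tolerance = 1e-9)

  csvf <- file.path(dir, "sig.csv")
  m <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("c1", "c2")))
  write.csv(m, csvf, row.names = FALSE)
  chans <- read_signal_csv(csvf)
  expect_length(chans, 2L)
  expect_equal(chans[[2]]$samples, m[, 2], tolerance = 1e-12)
  expect_equal(chans[[1]]$channel_id, "c1")

  # feature matrix writer emits CSV + JSON sidecar
  segs <- lapply(1:5, function(i) signal_record(rnorm(256), label = "a"))
  fm <- build_feature_matrix(segs)
  paths <- write_feature_matrix(fm, file.path(dir, "fm.csv"))
  expect_true(all(file.exists(paths)))
  meta <- jsonlite::read_json(paths[["meta"]], simplifyVector = TRUE)
  expect_equal(meta$normalization$center, unname(fm$normalization$center),
               tolerance = 1e-12)
})
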