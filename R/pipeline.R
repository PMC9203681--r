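#' Stratified k-fold assignment
#'
#' Folds are disjoint, exhaustive, stratified by class and of sizes
#' differing by at most one (within each class); deterministic given the
#' seed. Classes with fewer members than folds are spread best-effort with
#' a warning.
#'
#' @param n Number of observations.
#' @param k Number of folds (between 2 and `n`).
#' @param seed Seed for the shuffling.
#' @param stratify_labels Optional class label per observation.
#' @return Integer fold id (1..k) per observation.
#' @export
kfold_split <- function(n, k, seed = 1L, stratify_labels = NULL) {
  stopifnot(n >= k, k >= 2L)
  set.seed(seed)
  fold <- integer(n)
  groups <- if (is.null(stratify_labels)) list(seq_len(n)) else
    split(seq_len(n), as.character(stratify_labels))
  if (!is.null(stratify_labels) && any(lengths(groups) < k))
    warning("some classes have fewer members than folds; stratification is best-effort")
  offset <- 0L
  for (g in groups) {
    g <- g[sample.int(length(g))]
    # rotate the fold sequence across classes so small classes do not all
    # land in fold 1
    ids <- (rep(seq_len(k), length.out = length(g)) + offset - 1L) %% k + 1L
    fold[g] <- ids
    offset <- offset + length(g)
  }
  fold
}

#' Classification accuracy
#'
#' Fraction of exactly matching labels.
#'
#' @param pred,true Aligned label vectors.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_accuracy <- function(pred, true) {
  if (length(pred) != length(true)) stop("prediction/truth length mismatch")
  mean(as.character(pred) == as.character(true))
}

#' Assemble a pipeline configuration
#'
#' @param window_length Optional window length; when set, each input record
#'   is segmented (see [segment_signal()]) and windows become the
#'   observations. `NULL` treats each record as one observation.
#' @param overlap_fraction Window overlap, default 0.
#' @param Q_max,y0,g,eps,max_iter_em Fusion-mixture settings (see
#'   [select_model()], [observation_weights()]).
#' @param min_retained_per_class If the FDR retention rule leaves fewer
#'   training rows of some class than this, retention falls back to all
#'   training rows for that fold (recorded in the report). Default 10.
#' @param hdpab_NP,hdpab_iter,hdpab_lambda,hdpab_threshold Feature-selection
#'   settings (see [select_features_hdpab()]).
#' @param classifier `"bilstm"`, `"zipmrm"` or `"both"`.
#' @param hidden_size,lr,batch_size,l2,epochs,patience Bi-LSTM settings
#'   (see [train_bilstm()]).
#' @param levels,K Count discretisation levels and mixture components for
#'   the ZIPMRM classifier.
#' @param k Cross-validation folds, default 10. Within each training
#'   portion an inner stratified split holds out one ninth for validation,
#'   so the overall proportions are 80/10/10.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(window_length = NULL, overlap_fraction = 0,
                            Q_max = 3L, y0 = 0.05, g = 1.5, eps = 1e-8,
                            max_iter_em = 300L, min_retained_per_class = 10L,
                            hdpab_NP = 12L, hdpab_iter = 15L,
                            hdpab_lambda = 0.01, hdpab_threshold = 0.5,
                            classifier = c("bilstm", "zipmrm", "both"),
                            hidden_size = 80L, lr = 0.01, batch_size = 40L,
                            l2 = 1e-4, epochs = 30L, patience = 8L,
                            levels = 8L, K = 2L, k = 10L, seed = 1L) {
  classifier <- match.arg(classifier)
  stopifnot(k >= 2L)
  structure(as.list(environment()), class = "pipeline_config")
}

# descriptor rows + window matrix for a list of equal-length segments
segments_to_windows <- function(records, config) {
  segs <- if (is.null(config$window_length)) records else
    unlist(lapply(records, segment_signal,
                  window_length = config$window_length,
                  overlap_fraction = config$overlap_fraction),
           recursive = FALSE)
  lens <- vapply(segs, function(s) length(s$samples), integer(1))
  if (length(unique(lens)) != 1L)
    stop("observations must share a window length; set 'window_length'")
  segs
}

# everything derived from training rows only; returns the artifacts needed
# to transform and classify held-out rows
fit_fold <- function(raw, windows, labels, train, config, fold_seed) {
  norm <- normalization_constants(raw[train, , drop = FALSE])
  ztr <- apply_normalization(raw[train, , drop = FALSE], norm)
  # intensity weights from the training window matrix
  v <- svd_intensity(windows[train, , drop = FALSE])
  wei <- observation_weights(v, config$g)
  # one normalised score per observation: leading principal direction of
  # the training feature matrix
  pc <- svd(ztr, nu = 0L, nv = 1L)$v[, 1L]
  sc <- as.numeric(ztr %*% pc)
  sc_center <- mean(sc); sc_scale <- max(stats::sd(sc), 1e-12)
  z <- (sc - sc_center) / sc_scale
  fhm <- select_model(z, wei, Q_max = config$Q_max, y0 = config$y0,
                      eps = config$eps, max_iter = config$max_iter_em,
                      seed = fold_seed)
  retained <- fhm$retained_mask
  lab_tr <- labels[train]
  keep_ok <- all(table(factor(lab_tr[retained], levels = unique(lab_tr))) >=
                   config$min_retained_per_class)
  retention_used <- keep_ok && any(retained) && !all(retained)
  if (!keep_ok) retained <- rep(TRUE, length(retained))
  feats <- ztr[retained, , drop = FALSE]
  labs <- lab_tr[retained]
  sel <- select_features_hdpab(feats, labs, NP = config$hdpab_NP,
                               max_iter = config$hdpab_iter,
                               lambda = config$hdpab_lambda,
                               threshold = config$hdpab_threshold,
                               seed = fold_seed)
  edges <- NULL
  if (config$classifier %in% c("zipmrm", "both")) {
    cnt <- discretize_counts(feats[, sel$mask, drop = FALSE],
                             levels = config$levels)
    edges <- attr(cnt, "edges")
  }
  list(norm = norm, pc = pc, sc_center = sc_center, sc_scale = sc_scale,
       fhm = fhm, retained = retained, retention_used = retention_used,
       mask = sel$mask, hdpab_history = sel$history, edges = edges,
       train_features = feats, train_labels = labs)
}

train_and_predict <- function(art, raw_test, config, fold_seed) {
  zte <- apply_normalization(raw_test, art$norm)
  xte <- zte[, art$mask, drop = FALSE]
  xtr <- art$train_features[, art$mask, drop = FALSE]
  out <- list()
  if (config$classifier %in% c("bilstm", "both")) {
    inner <- kfold_split(nrow(xtr), 9L, seed = fold_seed,
                         stratify_labels = art$train_labels)
    val <- inner == 1L
    model <- train_bilstm(
      train_x = asplit(xtr[!val, , drop = FALSE], 1L),
      train_y = art$train_labels[!val],
      val_x = asplit(xtr[val, , drop = FALSE], 1L),
      val_y = art$train_labels[val],
      hidden_size = config$hidden_size, lr = config$lr,
      batch_size = config$batch_size, l2 = config$l2,
      epochs = config$epochs, patience = config$patience, seed = fold_seed)
    out$bilstm <- predict_bilstm(model, asplit(xte, 1L))$labels
  }
  if (config$classifier %in% c("zipmrm", "both")) {
    ctr <- discretize_counts(xtr, edges = art$edges)
    cte <- discretize_counts(xte, edges = art$edges)
    fits <- fit_zipmrm_classifier(ctr, art$train_labels, K = config$K,
                                  seed = fold_seed)
    out$zipmrm <- predict_zipmrm_classifier(fits, cte)$labels
  }
  out
}

#' Run the full cross-validated classification pipeline
#'
#' For each outer fold the fusion mixture, the observation-retention rule,
#' the normalisation constants, the HDPAB feature mask and (for the ZIPMRM
#' classifier) the count bin edges are derived from the training rows only;
#' the held-out fold is transformed with those artifacts and classified.
#' Within each training portion a stratified one-ninth split provides the
#' Bi-LSTM validation set, giving overall 80/10/10 proportions inside the
#' outer 10-fold loop.
#'
#' @param records List of [signal_record()] (or a [synthetic_spec()], which
#'   is expanded with [gen_two_class_signals()]).
#' @param config A [pipeline_config()].
#' @return An `evaluation_report`: `folds` (per-fold accuracy per
#'   classifier), `mean_accuracy`, `confusion`, `masks`, `artifacts`
#'   (per-fold training-derived objects for audit), `config`, `seed`.
#' @export
run_pipeline <- function(records, config = pipeline_config()) {
  if (inherits(records, "synthetic_spec")) records <- gen_two_class_signals(records)
  segs <- segments_to_windows(records, config)
  labels <- vapply(segs, function(s) as.character(s$label), character(1))
  if (length(unique(labels)) < 2L) stop("need at least two classes")
  windows <- t(vapply(segs, function(s) s$samples,
                      numeric(length(segs[[1]]$samples))))
  fm <- build_feature_matrix(segs, normalize = FALSE)
  if (length(fm$dropped)) {
    keep <- setdiff(seq_len(nrow(windows)), fm$dropped)
    windows <- windows[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  raw <- fm$raw
  n <- nrow(raw)
  fold <- kfold_split(n, config$k, seed = config$seed,
                      stratify_labels = labels)
  classifiers <- if (config$classifier == "both") c("bilstm", "zipmrm") else
    config$classifier
  acc <- matrix(NA_real_, config$k, length(classifiers),
                dimnames = list(NULL, classifiers))
  confusion <- list()
  artifacts <- vector("list", config$k)
  failures <- character(0)
  for (f in seq_len(config$k)) {
    fold_seed <- config$seed + 1000L * f
    res <- tryCatch({
      train <- fold != f
      art <- fit_fold(raw, windows, labels, train, config, fold_seed)
      preds <- train_and_predict(art, raw[!train, , drop = FALSE], config,
                                 fold_seed)
      list(art = art, preds = preds, truth = labels[!train])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("fold %d: %s", f, conditionMessage(res)))
      next
    }
    artifacts[[f]] <- res$art[c("norm", "fhm", "mask", "edges", "retained",
                                "retention_used", "sc_center", "sc_scale")]
    for (cl in classifiers) {
      acc[f, cl] <- evaluate_accuracy(res$preds[[cl]], res$truth)
      confusion[[cl]] <- add_confusion(confusion[[cl]], res$preds[[cl]],
                                       res$truth, sort(unique(labels)))
    }
  }
  structure(list(
    folds = data.frame(fold = seq_len(config$k), acc, check.names = FALSE),
    mean_accuracy = colMeans(acc, na.rm = TRUE),
    confusion = confusion,
    masks = lapply(artifacts, function(a) a$mask),
    artifacts = artifacts, failures = failures,
    n_obs = n, config = config, seed = config$seed),
    class = "evaluation_report")
}

add_confusion <- function(cm, pred, truth, classes) {
  t0 <- table(factor(truth, classes), factor(pred, classes))
  if (is.null(cm)) t0 else cm + t0
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d observations, %d-fold CV (seed %d)\n",
              x$n_obs, x$config$k, x$seed))
  for (cl in names(x$mean_accuracy))
    cat(sprintf("  %-8s mean accuracy %.3f\n", cl, x$mean_accuracy[[cl]]))
  if (length(x$failures))
    cat("  failed folds:", length(x$failures), "\n")
  invisible(x)
}

#' Cross-validated baseline classifiers on a fixed feature matrix
#'
#' Applies the same stratified k-fold protocol to a set of standard
#' classifiers from optional packages (linear/quadratic discriminants,
#' RBF-kernel SVM, naive Bayes, Gaussian mixture discriminant analysis) and
#' a built-in nearest-centroid baseline. Baselines whose package is not
#' installed are skipped with a notice.
#'
#' @param features Numeric observations x features matrix.
#' @param labels Class label per observation.
#' @param k Folds, default 10.
#' @param seed Seed, default 1.
#' @return Data frame with one row per attempted classifier (`classifier`,
#'   `mean_accuracy`, `available`).
#' @export
compare_baselines <- function(features, labels, k = 10L, seed = 1L) {
  labels <- factor(as.character(labels))
  fold <- kfold_split(nrow(features), k, seed = seed,
                      stratify_labels = labels)
  runners <- list(
    nearest_centroid = function(xtr, ytr, xte) {
      cls <- levels(ytr)
      cent <- matrix(vapply(cls, function(cl)
        colMeans(xtr[ytr == cl, , drop = FALSE]), numeric(ncol(xtr))),
        nrow = ncol(xtr))
      d2 <- vapply(seq_along(cls), function(ci)
        rowSums(sweep(xte, 2L, cent[, ci], `-`)^2), numeric(nrow(xte)))
      cls[max.col(-matrix(d2, ncol = length(cls)), "first")]
    },
    lda = if (requireNamespace("MASS", quietly = TRUE))
      function(xtr, ytr, xte)
        as.character(stats::predict(MASS::lda(xtr, ytr), xte)$class),
    qda = if (requireNamespace("MASS", quietly = TRUE))
      function(xtr, ytr, xte)
        as.character(stats::predict(MASS::qda(xtr, ytr), xte)$class),
    svm_rbf = if (requireNamespace("e1071", quietly = TRUE))
      function(xtr, ytr, xte)
        as.character(stats::predict(e1071::svm(xtr, ytr, kernel = "radial"), xte)),
    naive_bayes = if (requireNamespace("e1071", quietly = TRUE))
      function(xtr, ytr, xte)
        as.character(stats::predict(e1071::naiveBayes(xtr, ytr), xte)),
    gmm_da = if (requireNamespace("mclust", quietly = TRUE))
      function(xtr, ytr, xte) {
        fit <- mclust::MclustDA(xtr, ytr, verbose = FALSE)
        as.character(stats::predict(fit, xte)$classification)
      })
  out <- lapply(names(runners), function(nm) {
    fn <- runners[[nm]]
    if (is.null(fn)) {
      message(sprintf("baseline '%s' skipped: package not installed", nm))
      return(data.frame(classifier = nm, mean_accuracy = NA_real_,
                        available = FALSE))
    }
    accs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      pred <- tryCatch(
        fn(features[tr, , drop = FALSE], droplevels(labels[tr]),
           features[!tr, , drop = FALSE]),
        error = function(e) rep(NA_character_, sum(!tr)))
      mean(pred == as.character(labels[!tr]), na.rm = FALSE)
    }, numeric(1))
    data.frame(classifier = nm, mean_accuracy = mean(accs, na.rm = TRUE),
               available = TRUE)
  })
  do.call(rbind, out)
}
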