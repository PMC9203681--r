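#' Hybrid differential-evolution / particle-swarm / bee-colony optimizer
#'
#' HDPAB chains the primary operators of three metaheuristics in a fixed
#' loop - a greedy DE generation, a PSO velocity/position update, and an
#' ABC scout re-seeding of stagnant members - while preserving the best
#' solution ever seen (elitism). Control parameters left unset are drawn
#' once, at the start of a run, from standard ranges.
#'
#' @name hdpab
NULL

#' Assemble an HDPAB configuration
#'
#' @param NP Population size (at least 4, so DE can draw three distinct
#'   partners).
#' @param dims Problem dimensionality.
#' @param bounds 2 x dims matrix (rows: lower, upper) or a length-2 vector
#'   recycled over dimensions. Bounds must be finite with lower <= upper.
#' @param G DE scale factor; `NULL` draws from `param_ranges$G`.
#' @param CR DE crossover rate in `[0, 1]`; `NULL` draws from range.
#' @param q_inertia PSO inertia; `NULL` draws from range.
#' @param w1,w2 PSO attraction coefficients toward the personal and global
#'   bests; `NULL` draws from range.
#' @param limit ABC abandonment count; default `NP * dims / 2` (at least 1).
#' @param max_iter Number of DE->PSO->ABC cycles.
#' @param seed RNG seed; every run is deterministic given the seed.
#' @param stochastic_pso If `TRUE` (the default), multiply the PSO
#'   attraction terms by elementwise Uniform(0,1) factors - the canonical
#'   update, which keeps the swarm inside the PSO stability region for the
#'   whole attraction-coefficient range the parameters are drawn from.
#'   `FALSE` applies the deterministic update exactly as written in
#'   [pso_step()], which can diverge when `w1 + w2 > 2 (1 + q)`.
#' @param param_ranges Named list of length-2 ranges for the unset control
#'   parameters.
#' @return A list of class `hdpab_config`.
#' @export
hdpab_config <- function(NP, dims, bounds, G = NULL, CR = NULL,
                         q_inertia = NULL, w1 = NULL, w2 = NULL,
                         limit = NULL, max_iter = 100L, seed = 1L,
                         stochastic_pso = TRUE,
                         param_ranges = list(G = c(0.4, 0.9), CR = c(0.1, 0.9),
                                             q_inertia = c(0.4, 0.9),
                                             w1 = c(1.0, 2.0), w2 = c(1.0, 2.0))) {
  if (NP < 4L) stop("'NP' must be at least 4")
  if (is.matrix(bounds)) {
    stopifnot(nrow(bounds) == 2L, ncol(bounds) == dims)
  } else {
    stopifnot(length(bounds) == 2L)
    bounds <- matrix(rep(as.numeric(bounds), dims), nrow = 2L)
  }
  if (!all(is.finite(bounds)) || any(bounds[1, ] > bounds[2, ]))
    stop("bounds must be finite with lower <= upper")
  structure(list(NP = as.integer(NP), dims = as.integer(dims), bounds = bounds,
                 G = G, CR = CR, q_inertia = q_inertia, w1 = w1, w2 = w2,
                 limit = if (is.null(limit)) max(1L, floor(NP * dims / 2)) else as.integer(limit),
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 stochastic_pso = isTRUE(stochastic_pso),
                 param_ranges = param_ranges),
            class = "hdpab_config")
}

clip_to_bounds <- function(x, bounds) {
  pmin(pmax(x, matrix(bounds[1, ], nrow(x), ncol(x), byrow = TRUE)),
       matrix(bounds[2, ], nrow(x), ncol(x), byrow = TRUE))
}

eval_fitness <- function(fn, positions) {
  v <- apply(positions, 1L, fn)
  v[!is.finite(v)] <- Inf   # non-finite fitness: candidate rejected
  as.numeric(v)
}

#' Initialise the swarm
#'
#' Positions uniform within the bounds (the same draw rule the scout phase
#' reuses), velocities zero, personal/global bests and the elite set from
#' the initial fitness evaluation. Deterministic given the configured seed.
#'
#' @param config An [hdpab_config()].
#' @param fitness_fn Objective to minimise, taking a numeric vector.
#' @return A `swarm_state` list.
#' @export
initialize_population <- function(config, fitness_fn) {
  stopifnot(inherits(config, "hdpab_config"))
  NP <- config$NP; d <- config$dims; b <- config$bounds
  set.seed(config$seed)
  pos <- matrix(b[1, ], NP, d, byrow = TRUE) +
    matrix(stats::runif(NP * d), NP, d) *
    matrix(b[2, ] - b[1, ], NP, d, byrow = TRUE)
  fit <- eval_fitness(fitness_fn, pos)
  gi <- which.min(fit)
  structure(list(positions = pos, velocities = matrix(0, NP, d),
                 fitness = fit, pbest_pos = pos, pbest_val = fit,
                 gbest_pos = pos[gi, ], gbest_val = fit[gi],
                 elite_pos = pos[gi, ], elite_val = fit[gi],
                 trial = integer(NP), bounds = b, n_eval = NP),
            class = "swarm_state")
}

update_bests <- function(state) {
  imp <- state$fitness < state$pbest_val
  state$pbest_val[imp] <- state$fitness[imp]
  state$pbest_pos[imp, ] <- state$positions[imp, , drop = FALSE]
  gi <- which.min(state$pbest_val)
  state$gbest_pos <- state$pbest_pos[gi, ]
  state$gbest_val <- state$pbest_val[gi]
  if (state$gbest_val < state$elite_val) {
    state$elite_val <- state$gbest_val
    state$elite_pos <- state$gbest_pos
  }
  state
}

#' One differential-evolution generation
#'
#' For every member i a mutant `Y = A_x + G (A_z - A_w)` is built from three
#' distinct partners (all different from i), crossed coordinate-wise with
#' the parent (`V_j = Y_j` when `u_j <= CR`, else the parent coordinate;
#' there is no forced crossover index, so `CR = 0` returns the parent
#' unchanged), clipped to the bounds, and accepted only if strictly better.
#'
#' @param state A `swarm_state`.
#' @param G Scale factor.
#' @param CR Crossover rate.
#' @param fitness_fn Objective to minimise.
#' @return Updated `swarm_state`; no member's fitness ever worsens.
#' @export
de_step <- function(state, G, CR, fitness_fn) {
  NP <- nrow(state$positions); d <- ncol(state$positions)
  for (i in seq_len(NP)) {
    partners <- sample(setdiff(seq_len(NP), i), 3L)
    Y <- state$positions[partners[1L], ] +
      G * (state$positions[partners[2L], ] - state$positions[partners[3L], ])
    cross <- stats::runif(d) <= CR
    V <- ifelse(cross, Y, state$positions[i, ])
    V <- pmin(pmax(V, state$bounds[1, ]), state$bounds[2, ])
    fv <- fitness_fn(V)
    if (!is.finite(fv)) fv <- Inf
    state$n_eval <- state$n_eval + 1L
    if (fv < state$fitness[i]) {
      state$positions[i, ] <- V
      state$fitness[i] <- fv
    }
  }
  update_bests(state)
}

#' One particle-swarm update
#'
#' `Velo <- q Velo + w1 (pbest - A) + w2 (gbest - A)`; `A <- A + Velo`,
#' clipped to the bounds, then re-evaluated and the personal/global bests
#' refreshed. By default the update is applied exactly as written, with no
#' stochastic multipliers; `stochastic = TRUE` restores the canonical
#' Uniform(0,1) factors on the two attraction terms.
#'
#' @param state A `swarm_state`.
#' @param q_inertia,w1,w2 Inertia and attraction coefficients.
#' @param fitness_fn Objective to minimise.
#' @param stochastic Use canonical random multipliers (default `FALSE`).
#' @return Updated `swarm_state`.
#' @export
pso_step <- function(state, q_inertia, w1, w2, fitness_fn,
                     stochastic = FALSE) {
  NP <- nrow(state$positions); d <- ncol(state$positions)
  gb <- matrix(state$gbest_pos, NP, d, byrow = TRUE)
  r1 <- if (stochastic) matrix(stats::runif(NP * d), NP, d) else 1
  r2 <- if (stochastic) matrix(stats::runif(NP * d), NP, d) else 1
  state$velocities <- q_inertia * state$velocities +
    w1 * r1 * (state$pbest_pos - state$positions) +
    w2 * r2 * (gb - state$positions)
  state$positions <- clip_to_bounds(state$positions + state$velocities,
                                    state$bounds)
  state$fitness <- eval_fitness(fitness_fn, state$positions)
  state$n_eval <- state$n_eval + NP
  update_bests(state)
}

#' ABC scout phase: re-seed stagnant members
#'
#' Members whose trial counter has reached `limit` are replaced by a fresh
#' uniform draw `a_j = a_min_j + rand(0,1) (a_max_j - a_min_j)`, their
#' counter reset and fitness re-evaluated. The elite is untouched.
#'
#' @param state A `swarm_state`.
#' @param limit Abandonment threshold (at least 1).
#' @param fitness_fn Objective to minimise.
#' @return Updated `swarm_state`.
#' @export
abc_scout_step <- function(state, limit, fitness_fn) {
  stopifnot(limit >= 1)
  idx <- which(state$trial >= limit)
  if (length(idx) == 0L) return(state)
  d <- ncol(state$positions)
  for (i in idx) {
    state$positions[i, ] <- state$bounds[1, ] +
      stats::runif(d) * (state$bounds[2, ] - state$bounds[1, ])
    state$velocities[i, ] <- 0
    fv <- fitness_fn(state$positions[i, ])
    state$fitness[i] <- if (is.finite(fv)) fv else Inf
    state$trial[i] <- 0L
    state$n_eval <- state$n_eval + 1L
  }
  update_bests(state)
}

#' Run the full HDPAB loop
#'
#' Repeats DE -> PSO -> ABC for `max_iter` cycles. A member's trial counter
#' increments when a full DE+PSO sweep fails to improve its fitness and
#' resets on any improvement; the scout phase re-seeds members whose counter
#' reaches the limit. The best solution ever evaluated is preserved across
#' iterations (elitism) and its value recorded per iteration.
#'
#' @param fitness_fn Objective to minimise; must be defined over the whole
#'   box (non-finite values are treated as rejections).
#' @param config An [hdpab_config()]. Unset control parameters are drawn
#'   once from `config$param_ranges`.
#' @return List with `best_position`, `best_value`, `history` (elite value
#'   per iteration, starting from the initial population), `state`, and
#'   `control` (the resolved control parameters).
#' @export
hdpab_optimize <- function(fitness_fn, config) {
  stopifnot(inherits(config, "hdpab_config"))
  state <- initialize_population(config, fitness_fn)   # seeds the RNG
  draw <- function(value, range_name) {
    if (!is.null(value)) return(value)
    r <- config$param_ranges[[range_name]]
    stats::runif(1, r[1], r[2])
  }
  control <- list(G = draw(config$G, "G"), CR = draw(config$CR, "CR"),
                  q_inertia = draw(config$q_inertia, "q_inertia"),
                  w1 = draw(config$w1, "w1"), w2 = draw(config$w2, "w2"),
                  limit = config$limit)
  history <- state$elite_val
  if (config$max_iter > 0L) {
    for (it in seq_len(config$max_iter)) {
      before <- state$fitness
      state <- de_step(state, control$G, control$CR, fitness_fn)
      state <- pso_step(state, control$q_inertia, control$w1, control$w2,
                        fitness_fn, stochastic = config$stochastic_pso)
      improved <- state$fitness < before
      state$trial[improved] <- 0L
      state$trial[!improved] <- state$trial[!improved] + 1L
      state <- abc_scout_step(state, control$limit, fitness_fn)
      history <- c(history, state$elite_val)
    }
  }
  list(best_position = state$elite_pos, best_value = state$elite_val,
       history = history, state = state, control = control)
}

#' Decode a continuous position into a feature mask
#'
#' Feature j is selected iff `sigmoid(position_j) > threshold` (strict, so
#' a coordinate at exactly the logit of the threshold is excluded). An
#' empty mask is remapped to the single highest-scoring feature.
#'
#' @param position Numeric position vector.
#' @param threshold Selection threshold on the sigmoid scale, default 0.5.
#' @return Logical mask with at least one `TRUE`.
#' @export
position_to_mask <- function(position, threshold = 0.5) {
  s <- 1 / (1 + exp(-position))
  mask <- s > threshold
  if (!any(mask)) mask[which.max(s)] <- TRUE
  mask
}

#' Wrapper fitness for feature-subset selection
#'
#' Minimised fitness = `(1 - balanced accuracy)` of a nearest-centroid
#' classifier under internal stratified 5-fold cross-validation on the
#' masked features, plus a sparsity penalty `lambda * selected / total`.
#' Deterministic given `seed`.
#'
#' @param mask Logical feature mask (at least one `TRUE`).
#' @param features Numeric observations x features matrix.
#' @param labels Class label per observation (2 or more classes).
#' @param lambda Sparsity penalty weight, default 0.01.
#' @param folds Internal CV folds, default 5.
#' @param seed Seed for the internal fold assignment, default 1.
#' @return Scalar fitness to minimise.
#' @export
subset_fitness <- function(mask, features, labels, lambda = 0.01,
                           folds = 5L, seed = 1L) {
  stopifnot(any(mask))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("subset fitness needs at least two classes")
  x <- features[, mask, drop = FALSE]
  fold <- kfold_split(nrow(x), folds, seed = seed, stratify_labels = labels)
  classes <- sort(unique(labels))
  correct_by_class <- stats::setNames(numeric(length(classes)), classes)
  total_by_class <- stats::setNames(numeric(length(classes)), classes)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) next
    cent <- matrix(vapply(classes, function(cl)
      colMeans(x[tr & labels == cl, , drop = FALSE]), numeric(ncol(x))),
      nrow = ncol(x))                     # features x classes
    d2 <- vapply(seq_len(ncol(cent)), function(ci)
      rowSums(sweep(x[te, , drop = FALSE], 2L, cent[, ci], `-`)^2),
      numeric(sum(te)))
    d2 <- matrix(d2, ncol = length(classes))
    d2[!is.finite(d2)] <- Inf   # class absent from a training fold
    pred <- classes[max.col(-d2, "first")]
    truth <- labels[te]
    for (cl in classes) {
      total_by_class[cl] <- total_by_class[cl] + sum(truth == cl)
      correct_by_class[cl] <- correct_by_class[cl] + sum(pred == cl & truth == cl)
    }
  }
  balacc <- mean(correct_by_class / pmax(total_by_class, 1))
  (1 - balacc) + lambda * sum(mask) / length(mask)
}

#' Select a feature subset with HDPAB
#'
#' Runs [hdpab_optimize()] over a continuous box, decoding positions with
#' [position_to_mask()] and scoring them with [subset_fitness()].
#'
#' @param features Numeric observations x features matrix.
#' @param labels Class label per observation.
#' @param NP Population size, default 12.
#' @param max_iter Optimizer iterations, default 15.
#' @param lambda Sparsity penalty, default 0.01.
#' @param threshold Mask decoding threshold, default 0.5.
#' @param seed Seed, default 1.
#' @param ... Further arguments to [hdpab_config()].
#' @return List with `mask` (logical per feature), `best_value`, `history`
#'   and the optimizer `result`.
#' @export
select_features_hdpab <- function(features, labels, NP = 12L, max_iter = 15L,
                                  lambda = 0.01, threshold = 0.5, seed = 1L,
                                  ...) {
  p <- ncol(features)
  fit_fn <- function(pos)
    subset_fitness(position_to_mask(pos, threshold), features, labels,
                   lambda = lambda, seed = seed)
  cfg <- hdpab_config(NP = NP, dims = p, bounds = c(-4, 4),
                      max_iter = max_iter, seed = seed, ...)
  res <- hdpab_optimize(fit_fn, cfg)
  list(mask = position_to_mask(res$best_position, threshold),
       best_value = res$best_value, history = res$history, result = res)
}
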