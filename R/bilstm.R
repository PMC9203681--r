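#' Bidirectional LSTM classifier
#'
#' A small, dependency-free bidirectional LSTM: one forward cell reads the
#' sequence left to right, one backward cell right to left, the two final
#' hidden states are concatenated and mapped to class logits by a fully
#' connected layer with softmax output. Training minimises average
#' cross-entropy plus an L2 weight penalty with the Adam optimizer
#' (gradients by exact backpropagation through time). Selected-feature
#' vectors are fed as length-T sequences of scalars by default.
#'
#' @name bilstm
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialise LSTM cell parameters
#'
#' Gate weights act on the concatenation `[h_prev, x_t]`; all weights and
#' biases start uniform in `[-scale, scale]`.
#'
#' @param input_size Input dimension D.
#' @param hidden_size Hidden dimension H.
#' @param scale Initialisation half-width, default 0.08.
#' @return List of gate weight matrices `Wi, Wo, Wf, Wc` (H x (H+D)) and
#'   biases `bi, bo, bf, bc` (length H).
#' @export
lstm_cell_params <- function(input_size, hidden_size, scale = 0.08) {
  H <- hidden_size; D <- input_size
  rmat <- function() matrix(stats::runif(H * (H + D), -scale, scale), H, H + D)
  rvec <- function() stats::runif(H, -scale, scale)
  list(Wi = rmat(), Wo = rmat(), Wf = rmat(), Wc = rmat(),
       bi = rvec(), bo = rvec(), bf = rvec(), bc = rvec(),
       H = H, D = D)
}

#' One LSTM cell step
#'
#' Computes, elementwise over the hidden units,
#' `i = sigma(Wi [h, x] + bi)`, `o = sigma(Wo [h, x] + bo)`,
#' `f = sigma(Wf [h, x] + bf)`,
#' `C_t = f * C_prev + i * tanh(Wc [h, x] + bc)` and
#' `h_t = o * tanh(C_t)`. With all parameters zero the three gates are
#' exactly 0.5 and `C_t = 0.5 C_prev`.
#'
#' Inputs may be single vectors or row-wise batches (matrices with one row
#' per sequence in the batch).
#'
#' @param x_t Input at time t (length D, or B x D matrix).
#' @param h_prev,C_prev Previous hidden and cell state (length H, or B x H).
#' @param params Cell parameters from [lstm_cell_params()].
#' @return List with `h` and `C` (same shape as the inputs) plus the gate
#'   activations `i, o, f, g` used by backpropagation.
#' @export
lstm_cell <- function(x_t, h_prev, C_prev, params) {
  vec_in <- is.null(dim(x_t))
  if (vec_in) {
    x_t <- matrix(x_t, nrow = 1L)
    h_prev <- matrix(h_prev, nrow = 1L)
    C_prev <- matrix(C_prev, nrow = 1L)
  }
  if (ncol(x_t) != params$D || ncol(h_prev) != params$H)
    stop("input/hidden dimensions do not match the cell parameters")
  Z <- cbind(h_prev, x_t)
  i <- sigmoid(sweep(Z %*% t(params$Wi), 2L, params$bi, `+`))
  o <- sigmoid(sweep(Z %*% t(params$Wo), 2L, params$bo, `+`))
  f <- sigmoid(sweep(Z %*% t(params$Wf), 2L, params$bf, `+`))
  g <- tanh(sweep(Z %*% t(params$Wc), 2L, params$bc, `+`))
  C <- f * C_prev + i * g
  h <- o * tanh(C)
  if (vec_in) list(h = drop(h), C = drop(C), i = drop(i), o = drop(o),
                   f = drop(f), g = drop(g))
  else list(h = h, C = C, i = i, o = o, f = f, g = g)
}

#' Build an untrained bidirectional LSTM model
#'
#' @param input_size Input dimension D per time step.
#' @param hidden_size Hidden units H per direction, default 80.
#' @param n_classes Number of output classes.
#' @param classes Optional class labels (character), length `n_classes`.
#' @param seed Seed for the initialisation draw.
#' @param scale Initialisation half-width, default 0.08.
#' @return A `bilstm_model` list: `forward_cell`, `backward_cell`,
#'   `W_out` (C x 2H), `b_out`, `classes`.
#' @export
bilstm_model <- function(input_size, hidden_size = 80L, n_classes = 2L,
                         classes = NULL, seed = 1L, scale = 0.08) {
  set.seed(seed)
  structure(list(
    forward_cell = lstm_cell_params(input_size, hidden_size, scale),
    backward_cell = lstm_cell_params(input_size, hidden_size, scale),
    W_out = matrix(stats::runif(n_classes * 2L * hidden_size, -scale, scale),
                   n_classes, 2L * hidden_size),
    b_out = stats::runif(n_classes, -scale, scale),
    H = hidden_size, D = input_size, C = n_classes,
    classes = classes %||% as.character(seq_len(n_classes))),
    class = "bilstm_model")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# run one direction over a batch array x (B x T x D); returns final h and
# the per-step caches needed for backpropagation through time
run_direction <- function(x, cell, reverse = FALSE) {
  B <- dim(x)[1]; T <- dim(x)[2]
  H <- cell$H
  h <- matrix(0, B, H); C <- matrix(0, B, H)
  steps <- if (reverse) rev(seq_len(T)) else seq_len(T)
  cache <- vector("list", T)
  k <- 0L
  for (t in steps) {
    k <- k + 1L
    x_t <- matrix(x[, t, ], B)
    st <- lstm_cell(x_t, h, C, cell)
    cache[[k]] <- list(Z = cbind(h, x_t), C_prev = C, i = st$i, o = st$o,
                       f = st$f, g = st$g, C = st$C)
    h <- st$h; C <- st$C
  }
  list(h = h, cache = cache)
}

# backprop one direction given the gradient of the loss w.r.t. its final
# hidden state; returns gradients in the same layout as the cell params
backprop_direction <- function(dh_final, cell, cache) {
  H <- cell$H; D <- cell$D
  grads <- list(Wi = 0 * cell$Wi, Wo = 0 * cell$Wo, Wf = 0 * cell$Wf,
                Wc = 0 * cell$Wc, bi = 0 * cell$bi, bo = 0 * cell$bo,
                bf = 0 * cell$bf, bc = 0 * cell$bc)
  dh <- dh_final
  dC <- 0 * dh_final
  for (k in rev(seq_along(cache))) {
    s <- cache[[k]]
    tC <- tanh(s$C)
    do_ <- dh * tC
    dC <- dC + dh * s$o * (1 - tC^2)
    di <- dC * s$g
    dg <- dC * s$i
    df <- dC * s$C_prev
    dC <- dC * s$f
    dai <- di * s$i * (1 - s$i)
    dao <- do_ * s$o * (1 - s$o)
    daf <- df * s$f * (1 - s$f)
    dag <- dg * (1 - s$g^2)
    grads$Wi <- grads$Wi + t(dai) %*% s$Z
    grads$Wo <- grads$Wo + t(dao) %*% s$Z
    grads$Wf <- grads$Wf + t(daf) %*% s$Z
    grads$Wc <- grads$Wc + t(dag) %*% s$Z
    grads$bi <- grads$bi + colSums(dai)
    grads$bo <- grads$bo + colSums(dao)
    grads$bf <- grads$bf + colSums(daf)
    grads$bc <- grads$bc + colSums(dag)
    dZ <- dai %*% cell$Wi + dao %*% cell$Wo + daf %*% cell$Wf +
      dag %*% cell$Wc
    dh <- dZ[, seq_len(H), drop = FALSE]
  }
  grads
}

as_batch_array <- function(sequences, D) {
  B <- length(sequences)
  T <- nrow(sequences[[1]])
  x <- array(0, c(B, T, D))
  for (b in seq_len(B)) x[b, , ] <- sequences[[b]]
  x
}

#' Forward pass of the bidirectional LSTM
#'
#' Runs the forward cell left to right and the backward cell right to left,
#' concatenates the two final hidden states, applies the fully connected
#' layer and softmax. Probabilities sum to 1 per sequence.
#'
#' @param sequence A T x D numeric matrix (or a vector, taken as T x 1),
#'   or a list of such matrices for a batch.
#' @param model A [bilstm_model()].
#' @return For one sequence, a named probability vector over classes; for a
#'   list, a matrix with one row per sequence.
#' @export
bilstm_forward <- function(sequence, model) {
  single <- !is.list(sequence)
  seqs <- if (single) list(as_sequence(sequence, model$D)) else
    lapply(sequence, as_sequence, D = model$D)
  x <- as_batch_array(seqs, model$D)
  fw <- run_direction(x, model$forward_cell, reverse = FALSE)
  bw <- run_direction(x, model$backward_cell, reverse = TRUE)
  logits <- sweep(cbind(fw$h, bw$h) %*% t(model$W_out), 2L, model$b_out, `+`)
  p <- softmax_rows(logits)
  colnames(p) <- model$classes
  if (single) p[1L, ] else p
}

as_sequence <- function(s, D) {
  if (is.null(dim(s)) || length(dim(s)) < 2L) matrix(as.numeric(s), ncol = D)
  else as.matrix(s)
}

#' Cross-entropy loss
#'
#' `-log p_true`, averaged over the batch. Probabilities are clipped at
#' 1e-12 (with a warning) so a confident wrong prediction does not return
#' infinity.
#'
#' @param probs Probability matrix (rows are simplex points) or vector for
#'   a single prediction.
#' @param true_label Integer class indices (1-based) or labels matching the
#'   column names.
#' @return Scalar mean loss.
#' @export
cross_entropy <- function(probs, true_label) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L,
                                           dimnames = list(NULL, names(probs)))
  idx <- if (is.numeric(true_label)) as.integer(true_label) else
    match(as.character(true_label), colnames(probs))
  p <- probs[cbind(seq_len(nrow(probs)), idx)]
  if (any(p < 1e-12)) {
    warning("clipping zero predicted probability for the true class")
    p <- pmax(p, 1e-12)
  }
  mean(-log(p))
}

flatten_model <- function(model) {
  c(stats::setNames(model$forward_cell[c("Wi", "Wo", "Wf", "Wc",
                                         "bi", "bo", "bf", "bc")],
                    paste0("f.", c("Wi", "Wo", "Wf", "Wc", "bi", "bo", "bf", "bc"))),
    stats::setNames(model$backward_cell[c("Wi", "Wo", "Wf", "Wc",
                                          "bi", "bo", "bf", "bc")],
                    paste0("b.", c("Wi", "Wo", "Wf", "Wc", "bi", "bo", "bf", "bc"))),
    list(W_out = model$W_out, b_out = model$b_out))
}

unflatten_model <- function(model, flat) {
  for (nm in c("Wi", "Wo", "Wf", "Wc", "bi", "bo", "bf", "bc")) {
    model$forward_cell[[nm]] <- flat[[paste0("f.", nm)]]
    model$backward_cell[[nm]] <- flat[[paste0("b.", nm)]]
  }
  model$W_out <- flat$W_out
  model$b_out <- flat$b_out
  model
}

# loss and exact gradients for one batch; l2 applies to weight matrices only
bilstm_loss_grads <- function(model, x, y_idx, l2 = 0) {
  B <- dim(x)[1]
  fw <- run_direction(x, model$forward_cell, reverse = FALSE)
  bw <- run_direction(x, model$backward_cell, reverse = TRUE)
  Hcat <- cbind(fw$h, bw$h)
  logits <- sweep(Hcat %*% t(model$W_out), 2L, model$b_out, `+`)
  p <- softmax_rows(logits)
  Y <- matrix(0, B, model$C)
  Y[cbind(seq_len(B), y_idx)] <- 1
  ce <- mean(-log(pmax(p[cbind(seq_len(B), y_idx)], 1e-300)))
  dlogits <- (p - Y) / B
  gW_out <- t(dlogits) %*% Hcat
  gb_out <- colSums(dlogits)
  dH <- dlogits %*% model$W_out
  H <- model$H
  gf <- backprop_direction(dH[, seq_len(H), drop = FALSE],
                           model$forward_cell, fw$cache)
  gb <- backprop_direction(dH[, H + seq_len(H), drop = FALSE],
                           model$backward_cell, bw$cache)
  grads <- c(stats::setNames(gf, paste0("f.", names(gf))),
             stats::setNames(gb, paste0("b.", names(gb))),
             list(W_out = gW_out, b_out = gb_out))
  penalty <- 0
  if (l2 > 0) {
    flat <- flatten_model(model)
    for (nm in names(grads)) {
      if (grepl("W", nm)) {   # weight matrices only, biases unpenalised
        grads[[nm]] <- grads[[nm]] + l2 * flat[[nm]]
        penalty <- penalty + 0.5 * l2 * sum(flat[[nm]]^2)
      }
    }
  }
  list(loss = ce + penalty, ce = ce, grads = grads, probs = p)
}

#' Train a bidirectional LSTM classifier
#'
#' Mini-batch Adam (or plain gradient descent) on average cross-entropy plus
#' an L2 weight penalty, with early stopping on validation loss. Defaults
#' follow common practice for small EEG feature sets: learning rate 0.01,
#' batch size 40, 80 hidden units, L2 rate 1e-4. Deterministic given `seed`.
#'
#' @param train_x List of T x D sequences (or numeric vectors, taken as
#'   T x 1 - the default encoding of selected-feature vectors).
#' @param train_y Class labels.
#' @param val_x,val_y Optional validation split for early stopping; when
#'   omitted, the final-epoch parameters are returned.
#' @param hidden_size Hidden units per direction, default 80.
#' @param lr Learning rate, default 0.01.
#' @param batch_size Mini-batch size, default 40.
#' @param l2 L2 regularisation rate, default 1e-4.
#' @param epochs Epoch budget, default 30.
#' @param patience Early-stopping patience in epochs, default 10.
#' @param optimizer `"adam"` (default) or `"sgd"` for plain gradient
#'   descent.
#' @param seed Seed controlling initialisation and batch shuffling.
#' @return A fitted `bilstm_model` with a `history` data frame (epoch,
#'   training loss, validation loss/accuracy) attached.
#' @export
train_bilstm <- function(train_x, train_y, val_x = NULL, val_y = NULL,
                         hidden_size = 80L, lr = 0.01, batch_size = 40L,
                         l2 = 1e-4, epochs = 30L, patience = 10L,
                         optimizer = c("adam", "sgd"), seed = 1L) {
  optimizer <- match.arg(optimizer)
  classes <- sort(unique(as.character(train_y)))
  if (length(classes) < 2L) stop("need at least 2 classes in training data")
  D <- {
    s1 <- train_x[[1L]]
    if (is.null(dim(s1)) || length(dim(s1)) < 2L) 1L else ncol(s1)
  }
  model <- bilstm_model(D, hidden_size, length(classes), classes, seed = seed)
  x_all <- as_batch_array(lapply(train_x, as_sequence, D = D), D)
  y_idx <- match(as.character(train_y), classes)
  has_val <- !is.null(val_x) && length(val_x) > 0L
  if (has_val) {
    xv <- as_batch_array(lapply(val_x, as_sequence, D = D), D)
    yv <- match(as.character(val_y), classes)
  }
  n <- length(y_idx)
  flat <- flatten_model(model)
  mt <- lapply(flat, function(p) 0 * p)
  vt <- lapply(flat, function(p) 0 * p)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  best <- list(loss = Inf, flat = flat, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_acc = numeric())
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      ids <- ord[start:min(start + batch_size - 1L, n)]
      lg <- bilstm_loss_grads(model, x_all[ids, , , drop = FALSE],
                              y_idx[ids], l2 = l2)
      if (!is.finite(lg$loss))
        stop(sprintf("divergent training loss at epoch %d", ep))
      step <- step + 1L
      flat <- flatten_model(model)
      if (optimizer == "adam") {
        for (nm in names(flat)) {
          g <- lg$grads[[nm]]
          mt[[nm]] <- b1 * mt[[nm]] + (1 - b1) * g
          vt[[nm]] <- b2 * vt[[nm]] + (1 - b2) * g^2
          mhat <- mt[[nm]] / (1 - b1^step)
          vhat <- vt[[nm]] / (1 - b2^step)
          flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      } else {
        for (nm in names(flat))
          flat[[nm]] <- flat[[nm]] - lr * lg$grads[[nm]]
      }
      model <- unflatten_model(model, flat)
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb
    if (has_val) {
      vl <- bilstm_loss_grads(model, xv, yv, l2 = 0)
      val_loss <- vl$ce
      val_acc <- mean(max.col(vl$probs, "first") == yv)
    } else {
      val_loss <- NA_real_; val_acc <- NA_real_
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss,
                                   val_loss = val_loss, val_acc = val_acc))
    track <- if (has_val) val_loss else ep_loss
    if (track < best$loss) best <- list(loss = track,
                                        flat = flatten_model(model),
                                        epoch = ep)
    if (ep - best$epoch >= patience) break
  }
  model <- unflatten_model(model, best$flat)
  model$history <- hist
  model$best_epoch <- best$epoch
  model
}

#' Predict classes with a trained bidirectional LSTM
#'
#' @param model A trained [bilstm_model()].
#' @param sequences List of T x D sequences (or numeric vectors).
#' @return List with `labels` (argmax class per sequence) and
#'   `probabilities` (rows summing to 1).
#' @export
predict_bilstm <- function(model, sequences) {
  p <- bilstm_forward(sequences, model)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L, dimnames = list(NULL, model$classes))
  list(labels = model$classes[max.col(p, "first")], probabilities = p)
}
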