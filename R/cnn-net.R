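# Small 1-D convolutional classifier for coverage arrays.
#
# Architecture: conv(k1, f1 filters) -> ReLU -> max-pool(2) ->
# conv(k2, f2 filters) -> ReLU -> global max-pool -> dense -> sigmoid.
# Written directly on base-R matrix algebra; im2col index matrices are
# precomputed once per geometry so a convolution is a single matrix product.

cnn_config <- function(channels = 3L, width = 160L, k1 = 7L, f1 = 8L,
                       pool = 2L, k2 = 5L, f2 = 16L, lr = 0.01,
                       epochs = 40L, batch = 32L, patience = 6L,
                       val_frac = 0.1) {
  w1 <- width - k1 + 1L
  wp <- w1 %/% pool
  w2 <- wp - k2 + 1L
  stopifnot(w2 > 0L)
  list(channels = channels, width = width, k1 = k1, f1 = f1, pool = pool,
       k2 = k2, f2 = f2, w1 = w1, wp = wp, w2 = w2, lr = lr,
       epochs = epochs, batch = batch, patience = patience,
       val_frac = val_frac)
}

# Index matrix mapping an input (C x W, column-major) to its im2col patch
# matrix ((C*k) x Wout); row order is offset-major, channel-minor.
conv_idx <- function(C, W, k) {
  Wout <- W - k + 1L
  o <- rep(seq_len(k), each = C)
  ch <- rep(seq_len(C), k)
  outer((o - 1L) * C + ch, (seq_len(Wout) - 1L) * C, "+")
}

.init_weights <- function(cfg, seed) {
  with_seed(seed, {
    he <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nc)), nr, nc)
    list(W1 = he(cfg$f1, cfg$channels * cfg$k1), b1 = rep(0, cfg$f1),
         W2 = he(cfg$f2, cfg$f1 * cfg$k2), b2 = rep(0, cfg$f2),
         W3 = he(1L, cfg$f2), b3 = 0)
  })
}

# Forward pass for one example; P1 is the precomputed first-layer patch
# matrix. Returns the probability plus the intermediates backprop needs.
.cnn_forward <- function(wts, cfg, P1, idx2) {
  Z1 <- wts$W1 %*% P1 + wts$b1
  A1 <- Z1 * (Z1 > 0)
  even <- 2L * seq_len(cfg$wp)
  Aa <- A1[, even - 1L, drop = FALSE]
  Ab <- A1[, even, drop = FALSE]
  left_max <- Aa >= Ab
  Ap <- ifelse(left_max, Aa, Ab)
  P2 <- matrix(Ap[idx2], nrow = cfg$f1 * cfg$k2)
  Z2 <- wts$W2 %*% P2 + wts$b2
  A2 <- Z2 * (Z2 > 0)
  jmax <- max.col(A2, ties.method = "first")
  g <- A2[cbind(seq_len(cfg$f2), jmax)]
  z3 <- sum(wts$W3 * g) + wts$b3
  p <- 1 / (1 + exp(-z3))
  list(p = p, g = g, jmax = jmax, Z2 = Z2, P2 = P2, left_max = left_max,
       Z1 = Z1, P1 = P1)
}

# Backward pass; returns gradient list matching the weight list layout.
.cnn_backward <- function(wts, cfg, fw, y) {
  dz3 <- fw$p - y
  dW3 <- dz3 * matrix(fw$g, 1L)
  db3 <- dz3
  dg <- as.numeric(wts$W3) * dz3
  dA2 <- matrix(0, cfg$f2, cfg$w2)
  dA2[cbind(seq_len(cfg$f2), fw$jmax)] <- dg
  dZ2 <- dA2 * (fw$Z2 > 0)
  dW2 <- dZ2 %*% t(fw$P2)
  db2 <- rowSums(dZ2)
  dP2 <- t(wts$W2) %*% dZ2
  dAp <- matrix(0, cfg$f1, cfg$wp)
  for (o in seq_len(cfg$k2)) {
    rows <- (o - 1L) * cfg$f1 + seq_len(cfg$f1)
    cols <- seq_len(cfg$w2) + o - 1L
    dAp[, cols] <- dAp[, cols] + dP2[rows, , drop = FALSE]
  }
  dA1 <- matrix(0, cfg$f1, cfg$w1)
  even <- 2L * seq_len(cfg$wp)
  dA1[, even - 1L] <- dAp * fw$left_max
  dA1[, even] <- dAp * !fw$left_max
  dZ1 <- dA1 * (fw$Z1 > 0)
  dW1 <- dZ1 %*% t(fw$P1)
  db1 <- rowSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

.zero_like <- function(w) lapply(w, function(x) x * 0)

# Adam step, applied in place on the (weights, moments) state.
.adam_step <- function(state, grad, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (nm in names(state$w)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grad[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    state$w[[nm]] <- state$w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

# Coerce dataset to a list of C x W matrices.
.as_array_list <- function(x, cfg) {
  if (is.list(x)) xs <- x
  else if (is.array(x) && length(dim(x)) == 3L)
    xs <- lapply(seq_len(dim(x)[1L]), function(i) x[i, , ])
  else stop("x must be a list of matrices or an n x channels x width array")
  lapply(xs, function(m) {
    if (!all(dim(m) == c(cfg$channels, cfg$width)))
      stop("array dimensions must be ", cfg$channels, " x ", cfg$width)
    unclass(m)
  })
}

# Core training loop on precomputed patch matrices. Optional validation
# split drives early stopping (restores the best weights seen).
.cnn_fit <- function(P1s, y, cfg, seed) {
  n <- length(P1s)
  idx2 <- conv_idx(cfg$f1, cfg$wp, cfg$k2)
  state <- list(w = .init_weights(cfg, seed))
  state$m <- .zero_like(state$w)
  state$v <- .zero_like(state$w)
  n_val <- if (cfg$val_frac > 0 && n >= 20L) max(2L, round(cfg$val_frac * n)) else 0L
  ord <- with_seed(seed + 7L, sample.int(n))
  val <- if (n_val > 0L) ord[seq_len(n_val)] else integer(0)
  tr <- setdiff(ord, val)
  best <- list(loss = Inf, w = state$w, wait = 0L)
  t <- 0L
  for (ep in seq_len(cfg$epochs)) {
    sh <- with_seed(seed + 100L + ep, sample(tr))
    for (b0 in seq(1L, length(sh), by = cfg$batch)) {
      ids <- sh[b0:min(b0 + cfg$batch - 1L, length(sh))]
      grad <- NULL
      for (i in ids) {
        fw <- .cnn_forward(state$w, cfg, P1s[[i]], idx2)
        g <- .cnn_backward(state$w, cfg, fw, y[i])
        grad <- if (is.null(grad)) g
                else Map(`+`, grad, g)
      }
      grad <- lapply(grad, function(x) x / length(ids))
      t <- t + 1L
      state <- .adam_step(state, grad, cfg$lr, t)
    }
    if (n_val > 0L) {
      eps <- 1e-12
      vl <- mean(vapply(val, function(i) {
        p <- .cnn_forward(state$w, cfg, P1s[[i]], idx2)$p
        -(y[i] * log(p + eps) + (1 - y[i]) * log(1 - p + eps))
      }, numeric(1)))
      if (vl < best$loss - 1e-5) {
        best$loss <- vl; best$w <- state$w; best$wait <- 0L
      } else {
        best$wait <- best$wait + 1L
        if (best$wait >= cfg$patience) break
      }
    }
  }
  if (n_val > 0L) best$w else state$w
}

.cnn_prob <- function(wts, cfg, P1s) {
  idx2 <- conv_idx(cfg$f1, cfg$wp, cfg$k2)
  vapply(P1s, function(P1) .cnn_forward(wts, cfg, P1, idx2)$p, numeric(1))
}

#' Evaluate binary IR predictions
#'
#' @param pred predicted probabilities (or 0/1 labels).
#' @param truth true labels (0/1, logical, or `"true-IR"`/`"false-IR"`).
#' @param cutoff probability cutoff (default 0.5).
#' @return named numeric vector: `sensitivity` (TPR), `specificity` (TNR)
#'   and `balanced_accuracy` = (TPR + TNR) / 2.
#' @export
evaluate_predictions <- function(pred, truth, cutoff = 0.5) {
  y <- .as_binary(truth)
  yhat <- as.numeric(pred >= cutoff)
  sens <- if (sum(y == 1)) mean(yhat[y == 1] == 1) else NA_real_
  spec <- if (sum(y == 0)) mean(yhat[y == 0] == 0) else NA_real_
  c(sensitivity = sens, specificity = spec,
    balanced_accuracy = (sens + spec) / 2)
}

.as_binary <- function(y) {
  if (is.character(y) || is.factor(y)) as.numeric(as.character(y) == "true-IR")
  else as.numeric(y)
}

#' Train the convolutional IR filter
#'
#' Stratified k-fold cross-validation (default 10 folds) reporting
#' per-fold sensitivity, specificity and balanced accuracy on the held-out
#' fold, followed by a final fit on the full dataset. Fold assignment,
#' weight initialisation and batch order all derive from `seed`, so the
#' same call reproduces the same model and metrics exactly.
#'
#' @param x coverage arrays: list of `channels x width` matrices or an
#'   `n x channels x width` array.
#' @param y labels: 0/1, logical, or `"true-IR"`/`"false-IR"`.
#' @param folds number of CV folds (>= 2, default 10).
#' @param seed integer seed.
#' @param config optional [cnn_config()] list overriding the default
#'   geometry and optimizer settings.
#' @return A `cnn_model`: list with `config`, `weights`, `seed`,
#'   `fold_metrics` (`data.frame`, one row per fold) and `cv` (mean
#'   sensitivity/specificity/balanced accuracy across folds).
#' @export
train_cnn <- function(x, y, folds = 10L, seed = 1L, config = NULL) {
  y <- .as_binary(y)
  if (length(unique(y)) < 2L)
    stop("training requires both classes to be present")
  if (folds < 2L) stop("folds must be >= 2")
  cfg <- config %||% cnn_config()
  xs <- .as_array_list(x, cfg)
  if (length(xs) != length(y)) stop("x and y lengths differ")
  idx1 <- conv_idx(cfg$channels, cfg$width, cfg$k1)
  P1s <- lapply(xs, function(m) matrix(m[idx1], nrow = cfg$channels * cfg$k1))
  # stratified fold assignment
  fold <- integer(length(y))
  for (cl in unique(y)) {
    ids <- with_seed(seed + 13L * cl, sample(which(y == cl)))
    fold[ids] <- rep_len(seq_len(folds), length(ids))
  }
  met <- vector("list", folds)
  for (f in seq_len(folds)) {
    te <- which(fold == f); tr <- which(fold != f)
    if (length(unique(y[tr])) < 2L || length(te) == 0L) {
      met[[f]] <- c(sensitivity = NA, specificity = NA,
                    balanced_accuracy = NA)
      next
    }
    w <- .cnn_fit(P1s[tr], y[tr], cfg, seed + f)
    met[[f]] <- evaluate_predictions(.cnn_prob(w, cfg, P1s[te]), y[te])
  }
  fm <- data.frame(fold = seq_len(folds), do.call(rbind, met))
  final <- .cnn_fit(P1s, y, cfg, seed)
  structure(list(config = cfg, weights = final, seed = seed,
                 fold_metrics = fm,
                 cv = colMeans(fm[, -1L], na.rm = TRUE)),
            class = "cnn_model")
}

#' Predict IR probabilities with a trained filter
#'
#' @param object a `cnn_model` from [train_cnn()].
#' @param x coverage arrays (list of matrices or 3-D array).
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]` that each array is
#'   a true IR event.
#' @export
predict.cnn_model <- function(object, x, ...) {
  cfg <- object$config
  xs <- .as_array_list(x, cfg)
  idx1 <- conv_idx(cfg$channels, cfg$width, cfg$k1)
  P1s <- lapply(xs, function(m) matrix(m[idx1], nrow = cfg$channels * cfg$k1))
  .cnn_prob(object$weights, cfg, P1s)
}

#' Filter IR candidates by CNN probability
#'
#' @param records candidate record `data.frame` (one row per array).
#' @param probabilities output of [predict.cnn_model()], parallel to
#'   `records`.
#' @param cutoff minimum probability to keep a candidate (default 0.5).
#' @return the retained subset of `records`.
#' @export
apply_cnn_filter <- function(records, probabilities, cutoff = 0.5) {
  stopifnot(nrow(records) == length(probabilities))
  records[probabilities >= cutoff, , drop = FALSE]
}

#' Save / load a trained filter
#'
#' Single-file archive holding config, weights, seed and fold metrics.
#'
#' @param model a `cnn_model`.
#' @param path file path.
#' @return `load_cnn_model` returns the `cnn_model`; `save_cnn_model`
#'   returns `path` invisibly.
#' @export
save_cnn_model <- function(model, path) {
  stopifnot(inherits(model, "cnn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_cnn_model
#' @export
load_cnn_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "cnn_model"))
  m
}
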