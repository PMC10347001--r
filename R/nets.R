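#' Architecture of the LSTM-CNN window classifier
#'
#' The classifier stacks a temporal recurrent front end on a convolutional
#' feature extractor:
#'
#' ```
#' input (20 x C) -> LSTM(128, full sequence) -> LSTM(128, full sequence)
#'   -> Conv1D(64 kernels, width 3, stride 1, same padding, ReLU)
#'   -> MaxPool(width 2, stride 2)
#'   -> Conv1D(128 kernels, width 3, stride 1, same padding, ReLU)
#'   -> MaxPool(width 2, stride 1)
#'   -> flatten -> dense -> softmax over the 4 phases
#' ```
#'
#' Both LSTM layers use tanh cell activations and sigmoid gates and return
#' their full 20-step hidden sequence, which the CNN treats as a 1-D
#' temporal feature map; the 1 x 3 kernels convolve along time. With the
#' default sizes the temporal extent is 20 after the convolutions
#' (same padding), 10 after the first pool and 9 after the second.
#'
#' @param window_len Time steps per window.
#' @param lstm_units Hidden units per LSTM layer.
#' @param lstm_layers Number of stacked LSTM layers.
#' @param conv_filters Kernel counts of the two convolution layers.
#' @param conv_kernel Temporal kernel width.
#' @param pool_width Max-pooling window width.
#' @param pool_strides Strides of the two pooling layers.
#' @param n_classes Output classes (the 4 gait phases).
#' @return A `model_spec` list.
#' @export
model_spec <- function(window_len = 20L, lstm_units = 128L, lstm_layers = 2L,
                       conv_filters = c(64L, 128L), conv_kernel = 3L,
                       pool_width = 2L, pool_strides = c(2L, 1L),
                       n_classes = 4L) {
  spec <- list(window_len = as.integer(window_len),
               lstm_units = as.integer(lstm_units),
               lstm_layers = as.integer(lstm_layers),
               conv_filters = as.integer(conv_filters),
               conv_kernel = as.integer(conv_kernel),
               pool_width = as.integer(pool_width),
               pool_strides = as.integer(pool_strides),
               n_classes = as.integer(n_classes))
  stopifnot(all(unlist(spec) > 0), length(spec$conv_filters) == 2L,
            length(spec$pool_strides) == 2L)
  p1 <- pool_out_len(spec$window_len, spec$pool_width, spec$pool_strides[1])
  p2 <- pool_out_len(p1, spec$pool_width, spec$pool_strides[2])
  if (p2 < 1L) stop("window too short for the pooling stack")
  spec$pooled_len <- c(p1, p2)
  class(spec) <- "model_spec"
  spec
}

pool_out_len <- function(len, width, stride) {
  (len - width) %/% stride + 1L
}

sigmoid <- function(z) 1 / (1 + exp(-z))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained LSTM-CNN model
#'
#' Initializes all parameters (Glorot-uniform weights, zero biases except
#' the forget gate, whose bias starts at 1) for a given input channel
#' count. Construction is deterministic given the seed, and the parameter
#' count is a pure function of the spec and `n_channels`.
#'
#' @param spec A [model_spec()].
#' @param n_channels Input channels (sensor-group size: 2, 4 or 6).
#' @param seed Integer seed for weight initialization.
#' @return An `lstm_cnn` model object (untrained).
#' @export
build_model <- function(spec, n_channels, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  n_channels <- as.integer(n_channels)
  if (n_channels < 1L) stop("unsupported input shape: n_channels must be >= 1")
  H <- spec$lstm_units
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  params <- list()
  cin <- n_channels
  for (l in seq_len(spec$lstm_layers)) {
    b <- numeric(4L * H)
    b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
    params[[paste0("lstm", l, "_Wx")]] <- glorot(cin, 4L * H)
    params[[paste0("lstm", l, "_Wh")]] <- glorot(H, 4L * H)
    params[[paste0("lstm", l, "_b")]] <- b
    cin <- H
  }
  k <- spec$conv_kernel
  f1 <- spec$conv_filters[1]
  f2 <- spec$conv_filters[2]
  params$conv1_W <- glorot(k * H, f1)
  params$conv1_b <- numeric(f1)
  params$conv2_W <- glorot(k * f1, f2)
  params$conv2_b <- numeric(f2)
  flat <- spec$pooled_len[2] * f2
  params$dense_W <- glorot(flat, spec$n_classes)
  params$dense_b <- numeric(spec$n_classes)
  structure(list(spec = spec, n_channels = n_channels, params = params,
                 trained = FALSE, group = NULL, normalizer = NULL,
                 history = NULL, seed = as.integer(seed)),
            class = "lstm_cnn")
}

#' @export
print.lstm_cnn <- function(x, ...) {
  cat("<lstm_cnn>", x$n_channels, "input channels,",
      format(sum(vapply(x$params, length, numeric(1))), big.mark = ","),
      "parameters,", if (isTRUE(x$trained)) "trained" else "untrained", "\n")
  if (!is.null(x$group)) {
    cat("  bound to sensor group", x$group$group_id, "(",
        paste(x$group$sites, collapse = ", "), ")\n")
  }
  invisible(x)
}

# ---- layer forward/backward -------------------------------------------------
#
# All temporal layers operate on "flat" matrices of shape (B*T) x C, rows
# ordered batch-fastest then time (row index b + (t-1)*B). This makes the
# per-step slices, the convolution padding and the final flatten pure
# row-block operations, and lets the input projections run as single BLAS
# calls over all time steps; only the LSTM recurrence h %*% Wh remains in
# the time loop.

time_rows <- function(t, B) ((t - 1L) * B + 1L):(t * B)

lstm_layer_forward <- function(Xf, B, Wx, Wh, b, keep_cache = FALSE) {
  TT <- nrow(Xf) %/% B
  H <- nrow(Wh)
  Zx <- Xf %*% Wx
  Zx <- Zx + rep(b, each = nrow(Xf))
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  Hout <- matrix(0, B * TT, H)
  gates <- if (keep_cache) vector("list", TT) else NULL
  i_idx <- 1:H
  f_idx <- (H + 1):(2 * H)
  o_idx <- (2 * H + 1):(3 * H)
  g_idx <- (3 * H + 1):(4 * H)
  for (t in seq_len(TT)) {
    rows <- time_rows(t, B)
    z <- Zx[rows, , drop = FALSE] + h %*% Wh
    s <- sigmoid(z[, 1:(3 * H), drop = FALSE])
    i <- s[, i_idx, drop = FALSE]
    f <- s[, f_idx, drop = FALSE]
    o <- s[, o_idx, drop = FALSE]
    g <- tanh(z[, g_idx, drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    if (keep_cache) {
      gates[[t]] <- list(i = i, f = f, o = o, g = g, tc = tc, c_prev = c_prev)
    }
    Hout[rows, ] <- h
  }
  list(out = Hout,
       cache = if (keep_cache) list(gates = gates, Xf = Xf, Hout = Hout,
                                    B = B) else NULL)
}

lstm_layer_backward <- function(dHf, cache, Wx, Wh) {
  B <- cache$B
  TT <- nrow(dHf) %/% B
  H <- nrow(Wh)
  dWh <- matrix(0, H, 4 * H)
  dZall <- matrix(0, B * TT, 4 * H)
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  tWh <- t(Wh)
  for (t in rev(seq_len(TT))) {
    gt <- cache$gates[[t]]
    rows <- time_rows(t, B)
    dh <- dHf[rows, , drop = FALSE] + dh_next
    do <- dh * gt$tc
    dc <- dh * gt$o * (1 - gt$tc^2) + dc_next
    dZ <- cbind((dc * gt$g) * gt$i * (1 - gt$i),
                (dc * gt$c_prev) * gt$f * (1 - gt$f),
                do * gt$o * (1 - gt$o),
                (dc * gt$i) * (1 - gt$g^2))
    dZall[rows, ] <- dZ
    h_prev <- if (t > 1L) cache$Hout[time_rows(t - 1L, B), , drop = FALSE] else {
      matrix(0, B, H)
    }
    dWh <- dWh + crossprod(h_prev, dZ)
    dh_next <- dZ %*% tWh
    dc_next <- dc * gt$f
  }
  list(dX = dZall %*% t(Wx),
       dWx = crossprod(cache$Xf, dZall),
       dWh = dWh, db = colSums(dZall))
}

# im2col for 'same' temporal convolution on flat input: zero rows are
# stacked before and after the B*T block, and each kernel tap is a
# contiguous row slice of the padded matrix.
conv_im2col <- function(Xf, B, k) {
  n <- nrow(Xf)
  C <- ncol(Xf)
  pad <- (k - 1L) %/% 2L
  zero <- matrix(0, B * pad, C)
  Xpad <- rbind(zero, Xf, zero)
  col <- matrix(0, n, k * C)
  for (o in seq_len(k)) {
    col[, ((o - 1L) * C + 1L):(o * C)] <-
      Xpad[((o - 1L) * B + 1L):((o - 1L) * B + n), , drop = FALSE]
  }
  col
}

conv_layer_forward <- function(Xf, B, W, b, k, keep_cache = FALSE) {
  col <- conv_im2col(Xf, B, k)
  A <- col %*% W
  A <- A + rep(b, each = nrow(A))
  mask <- A > 0
  A[!mask] <- 0
  list(out = A,
       cache = if (keep_cache) list(col = col, mask = mask, B = B,
                                    C = ncol(Xf)) else NULL)
}

conv_layer_backward <- function(dYf, cache, W, k) {
  B <- cache$B
  C <- cache$C
  n <- nrow(dYf)
  dYf[!cache$mask] <- 0
  dW <- crossprod(cache$col, dYf)
  db <- colSums(dYf)
  dcol <- dYf %*% t(W)
  pad <- (k - 1L) %/% 2L
  dXpad <- matrix(0, n + 2L * B * pad, C)
  for (o in seq_len(k)) {
    rows <- ((o - 1L) * B + 1L):((o - 1L) * B + n)
    dXpad[rows, ] <- dXpad[rows, , drop = FALSE] +
      dcol[, ((o - 1L) * C + 1L):(o * C), drop = FALSE]
  }
  list(dX = dXpad[(B * pad + 1L):(B * pad + n), , drop = FALSE],
       dW = dW, db = db)
}

maxpool_forward <- function(Xf, B, width, stride, keep_cache = FALSE) {
  TT <- nrow(Xf) %/% B
  C <- ncol(Xf)
  P <- pool_out_len(TT, width, stride)
  Y <- matrix(0, B * P, C)
  take <- if (keep_cache) matrix(FALSE, B * P, C) else NULL
  for (p in seq_len(P)) {
    i1 <- (p - 1L) * stride + 1L
    x1 <- Xf[time_rows(i1, B), , drop = FALSE]
    x2 <- Xf[time_rows(i1 + 1L, B), , drop = FALSE]
    t1 <- x1 >= x2  # ties go to the earlier sample
    Y[time_rows(p, B), ] <- x1 * t1 + x2 * (1 - t1)
    if (keep_cache) take[time_rows(p, B), ] <- t1
  }
  list(out = Y,
       cache = if (keep_cache) list(take = take, B = B, TT = TT,
                                    stride = stride) else NULL)
}

maxpool_backward <- function(dYf, cache) {
  B <- cache$B
  P <- nrow(dYf) %/% B
  dX <- matrix(0, cache$TT * B, ncol(dYf))
  for (p in seq_len(P)) {
    i1 <- (p - 1L) * cache$stride + 1L
    rows1 <- time_rows(i1, B)
    rows2 <- time_rows(i1 + 1L, B)
    t1 <- cache$take[time_rows(p, B), , drop = FALSE]
    dy <- dYf[time_rows(p, B), , drop = FALSE]
    dX[rows1, ] <- dX[rows1, , drop = FALSE] + dy * t1
    dX[rows2, ] <- dX[rows2, , drop = FALSE] + dy * (1 - t1)
  }
  dX
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- full network -----------------------------------------------------------

net_forward <- function(params, spec, X, keep_cache = FALSE) {
  d <- dim(X)
  B <- d[1]
  caches <- list(B = B)
  h <- matrix(X, B * d[2], d[3])
  for (l in seq_len(spec$lstm_layers)) {
    r <- lstm_layer_forward(h, B, params[[paste0("lstm", l, "_Wx")]],
                            params[[paste0("lstm", l, "_Wh")]],
                            params[[paste0("lstm", l, "_b")]], keep_cache)
    caches[[paste0("lstm", l)]] <- r$cache
    h <- r$out
  }
  k <- spec$conv_kernel
  r <- conv_layer_forward(h, B, params$conv1_W, params$conv1_b, k, keep_cache)
  caches$conv1 <- r$cache
  r <- maxpool_forward(r$out, B, spec$pool_width, spec$pool_strides[1],
                       keep_cache)
  caches$pool1 <- r$cache
  r2 <- conv_layer_forward(r$out, B, params$conv2_W, params$conv2_b, k,
                           keep_cache)
  caches$conv2 <- r2$cache
  r2 <- maxpool_forward(r2$out, B, spec$pool_width, spec$pool_strides[2],
                        keep_cache)
  caches$pool2 <- r2$cache
  flat <- r2$out
  caches$flat_dims <- dim(flat)
  dim(flat) <- c(B, prod(caches$flat_dims) / B)  # zero-copy reshape
  logits <- flat %*% params$dense_W
  logits <- logits + rep(params$dense_b, each = B)
  caches$flat <- if (keep_cache) flat else NULL
  list(prob = softmax_rows(logits), logits = logits, caches = caches)
}

net_backward <- function(params, spec, fwd, dlogits) {
  caches <- fwd$caches
  grads <- list()
  grads$dense_W <- crossprod(caches$flat, dlogits)
  grads$dense_b <- colSums(dlogits)
  dflat <- dlogits %*% t(params$dense_W)
  dim(dflat) <- caches$flat_dims
  dC2 <- maxpool_backward(dflat, caches$pool2)
  k <- spec$conv_kernel
  r <- conv_layer_backward(dC2, caches$conv2, params$conv2_W, k)
  grads$conv2_W <- r$dW
  grads$conv2_b <- r$db
  dP1 <- r$dX
  dC1 <- maxpool_backward(dP1, caches$pool1)
  r <- conv_layer_backward(dC1, caches$conv1, params$conv1_W, k)
  grads$conv1_W <- r$dW
  grads$conv1_b <- r$db
  dH <- r$dX
  for (l in rev(seq_len(spec$lstm_layers))) {
    r <- lstm_layer_backward(dH, caches[[paste0("lstm", l)]],
                             params[[paste0("lstm", l, "_Wx")]],
                             params[[paste0("lstm", l, "_Wh")]])
    grads[[paste0("lstm", l, "_Wx")]] <- r$dWx
    grads[[paste0("lstm", l, "_Wh")]] <- r$dWh
    grads[[paste0("lstm", l, "_b")]] <- r$db
    dH <- r$dX
  }
  grads
}

ce_loss <- function(prob, y_idx) {
  -mean(log(pmax(prob[cbind(seq_along(y_idx), y_idx)], 1e-12)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' Hyperparameters for Adam training of the LSTM-CNN. Cross-entropy is the
#' loss; training stops at `max_epochs`, when validation loss drops below
#' `loss_threshold` (the "training considered complete" rule), or when it
#' has not improved by `min_delta` for `patience` consecutive epochs. The
#' parameters from the best validation epoch are kept.
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam moment decay rates.
#' @param batch_size Windows per minibatch.
#' @param max_epochs Upper bound on training epochs.
#' @param validation_fraction Fraction of the training windows held out for
#'   the early-stop criterion (in `(0, 1)`).
#' @param patience Epochs without improvement tolerated before stopping.
#' @param min_delta Minimum validation-loss improvement that resets patience.
#' @param loss_threshold Optional validation-loss level at which training is
#'   considered complete (`NULL` disables).
#' @param seed Seed for weight init, validation split and batch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 64L, max_epochs = 100L,
                         validation_fraction = 0.1, patience = 10L,
                         min_delta = 1e-4, loss_threshold = NULL, seed = 1L) {
  stopifnot(validation_fraction > 0, validation_fraction < 1,
            learning_rate > 0, batch_size >= 1, max_epochs >= 1, patience >= 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 validation_fraction = validation_fraction,
                 patience = as.integer(patience), min_delta = min_delta,
                 loss_threshold = loss_threshold, seed = as.integer(seed)),
            class = "train_config")
}

#' Train the LSTM-CNN on labeled windows
#'
#' Minibatch Adam on cross-entropy with a seeded validation split for early
#' stopping. Fully deterministic given the configuration seed: the same
#' data and seed give identical final weights.
#'
#' @param model An untrained [build_model()] result (its weights are the
#'   starting point).
#' @param windows A labeled, normalized `gait_windows` whose channel count
#'   matches the model.
#' @param config A [train_config()].
#' @return The trained `lstm_cnn`, with a per-epoch `history` data frame
#'   (train/validation loss and accuracy).
#' @export
train <- function(model, windows, config = train_config()) {
  stopifnot(inherits(model, "lstm_cnn"), inherits(windows, "gait_windows"),
            inherits(config, "train_config"))
  X <- windows$x
  if (dim(X)[3] != model$n_channels) {
    stop("windows have ", dim(X)[3], " channels but the model expects ",
         model$n_channels)
  }
  if (is.null(windows$label)) stop("windows are unlabeled")
  y <- as.integer(as_phase(windows$label))
  present <- sort(unique(y))
  if (length(present) < model$spec$n_classes) {
    stop("class(es) absent from training data: ",
         paste(gait_phases()[setdiff(1:4, present)], collapse = ", "))
  }
  n <- length(y)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)

  n_val <- max(1L, round(config$validation_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr_idx, , , drop = FALSE]
  ytr <- y[tr_idx]
  Xval <- X[val_idx, , , drop = FALSE]
  yval <- y[val_idx]
  Yhot <- diag(model$spec$n_classes)

  params <- model$params
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  hist <- list()
  ntr <- length(ytr)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(ntr)
    tl <- 0
    tc <- 0L
    for (b0 in seq.int(1L, ntr, by = config$batch_size)) {
      bi <- ord[b0:min(b0 + config$batch_size - 1L, ntr)]
      Xb <- Xtr[bi, , , drop = FALSE]
      yb <- ytr[bi]
      fwd <- net_forward(params, model$spec, Xb, keep_cache = TRUE)
      tl <- tl + ce_loss(fwd$prob, yb) * length(bi)
      tc <- tc + sum(max.col(fwd$prob, ties.method = "first") == yb)
      dlogits <- (fwd$prob - Yhot[yb, , drop = FALSE]) / length(bi)
      grads <- net_backward(params, model$spec, fwd, dlogits)
      upd <- adam_step(params, grads, opt, config$learning_rate,
                       config$beta1, config$beta2)
      params <- upd$params
      opt <- upd$state
    }
    vfwd <- net_forward(params, model$spec, Xval, keep_cache = FALSE)
    vloss <- ce_loss(vfwd$prob, yval)
    vacc <- mean(max.col(vfwd$prob, ties.method = "first") == yval)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tl / ntr,
                                train_acc = tc / ntr, val_loss = vloss,
                                val_acc = vacc)
    if (!is.finite(vloss)) stop("non-finite validation loss at epoch ", epoch)
    if (vloss < best$loss - config$min_delta) {
      best <- list(loss = vloss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
    }
    if (!is.null(config$loss_threshold) && vloss < config$loss_threshold) break
    if (wait >= config$patience) break
  }
  model$params <- best$params
  model$trained <- TRUE
  model$history <- do.call(rbind, hist)
  model$train_config <- config
  model
}

#' Predict phase probabilities for windows
#'
#' @param model A trained `lstm_cnn`.
#' @param x A single window (matrix, time x channels), a 3-D window array,
#'   or a `gait_windows` object. Windows must already be normalized with the
#'   model's bound parameters and restricted to its sensor group.
#' @return A matrix (windows x 4) of softmax probabilities, columns named
#'   by phase.
#' @export
predict_prob <- function(model, x) {
  stopifnot(inherits(model, "lstm_cnn"))
  if (inherits(x, "gait_windows")) x <- x$x
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  d <- dim(x)
  if (length(d) != 3L || d[2] != model$spec$window_len ||
      d[3] != model$n_channels) {
    stop("window shape (", paste(d[-1], collapse = " x "),
         ") does not match model input (", model$spec$window_len, " x ",
         model$n_channels, ")",
         if (!is.null(model$group)) {
           paste0("; model is bound to sensor group ", model$group$group_id)
         } else "")
  }
  p <- net_forward(model$params, model$spec, x, keep_cache = FALSE)$prob
  colnames(p) <- gait_phases()
  p
}

#' Predict a phase label from a raw 6-channel window
#'
#' Generic used by the model-switching engine: an `lstm_cnn` method selects
#' its bound sensor group's channels from the raw window, applies its bound
#' normalizer and decodes the argmax phase. Mock classifiers (see
#' [mock_classifier()]) implement the same interface for testing.
#'
#' @param model A classifier.
#' @param window A raw (unnormalized) window, time x 6 matrix with site
#'   column names.
#' @param ... Passed to methods.
#' @return A single phase label (character).
#' @export
predict_phase <- function(model, window, ...) UseMethod("predict_phase")

#' @export
predict_phase.lstm_cnn <- function(model, window, ...) {
  if (is.null(model$group) || is.null(model$normalizer)) {
    stop("model is not bound to a sensor group / normalizer")
  }
  missing_sites <- setdiff(model$group$sites, colnames(window))
  if (length(missing_sites)) {
    stop("window lacks channel(s) ", paste(missing_sites, collapse = ", "),
         " required by sensor group ", model$group$group_id)
  }
  w <- apply_normalizer(model$normalizer,
                        window[, model$group$sites, drop = FALSE])
  decode_phase(predict_prob(model, w))
}

#' A scripted classifier for engine tests
#'
#' Wraps a function `fn(window) -> phase label` in the [predict_phase()]
#' interface, so the model-switching engine can be exercised with oracle or
#' adversarial prediction streams without training networks.
#'
#' @param fn Function taking a raw window and returning a phase label.
#' @return A `mock_classifier`.
#' @export
mock_classifier <- function(fn) {
  structure(list(fn = fn), class = "mock_classifier")
}

#' @export
predict_phase.mock_classifier <- function(model, window, ...) model$fn(window)

#' Select a sensor group, normalize, build and train in one step
#'
#' The standard route from a raw 6-channel labeled window set to a
#' deployable model: restrict to the group's channels, normalize with the
#' supplied (training-fit) parameters, train, and bind group + normalizer
#' to the result so that [predict_phase()] can consume raw windows.
#'
#' @param windows Raw labeled `gait_windows` carrying all six channels.
#' @param group A [sensor_group()] or id.
#' @param normalizer Channel normalization fitted on training recordings.
#' @param config A [train_config()].
#' @param spec A [model_spec()].
#' @return A trained, bound `lstm_cnn`.
#' @export
fit_group_model <- function(windows, group, normalizer,
                            config = train_config(), spec = model_spec()) {
  if (!inherits(group, "sensor_group")) group <- sensor_group(group)
  w <- select_channels(windows, group)
  w <- apply_normalizer(normalizer, w)
  model <- build_model(spec, n_channels = length(group$sites),
                       seed = config$seed)
  model <- train(model, w, config)
  model$group <- group
  model$normalizer <- normalizer
  model
}

#' Train the three phase-specialist models
#'
#' Trains the full-sensor model plus the two reduced-placement models used
#' by the model-switching engine: `LSTM-CNN-1` on all six sites (group 7),
#' `LSTM-CNN-2` on shanks+feet (group 6, the best placement for `SW-L`),
#' and `LSTM-CNN-3` on thighs+shanks (group 4, the best placement for
#' `SU-LHS`). The group bindings are configurable.
#'
#' @param windows Raw labeled `gait_windows` with all six channels.
#' @param normalizer Training-fit [fit_normalizer()] parameters.
#' @param config A [train_config()].
#' @param spec A [model_spec()].
#' @param groups Named integer vector mapping model ids to sensor groups.
#' @return Named list of three trained `lstm_cnn` models.
#' @export
train_specialists <- function(windows, normalizer, config = train_config(),
                              spec = model_spec(),
                              groups = c("LSTM-CNN-1" = 7L, "LSTM-CNN-2" = 6L,
                                         "LSTM-CNN-3" = 4L)) {
  if (dim(windows$x)[3] != 6L) {
    stop("specialist training requires all 6 channels")
  }
  models <- lapply(groups, function(g) {
    fit_group_model(windows, sensor_group(g), normalizer, config, spec)
  })
  names(models) <- names(groups)
  models
}

#' Save / load a trained model
#'
#' The checkpoint is an RDS file holding the parameters together with the
#' bound sensor group, normalizer, spec and training history, plus a
#' human-readable JSON sidecar with the binding metadata.
#'
#' @param model A trained `lstm_cnn`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` (write) or the model (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "lstm_cnn"))
  saveRDS(model, path)
  meta <- list(
    n_channels = model$n_channels,
    group_id = if (!is.null(model$group)) model$group$group_id else NULL,
    sites = if (!is.null(model$group)) model$group$sites else NULL,
    spec = unclass(model$spec),
    normalizer = if (!is.null(model$normalizer)) {
      unclass(model$normalizer)
    } else NULL,
    trained = model$trained
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "lstm_cnn"))
  model
}
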