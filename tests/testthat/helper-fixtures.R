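# Shared fixtures: small configurations and independently-coded oracles.

clean_config <- function(...) {
  synth_config(n_subjects = 2L, cycles_per_speed = 5L, noise_sd = 0,
               packet_loss_rate = 0, seed = 11L, ...)
}

subset_rec_first_n <- function(rec, n) {
  rec$time <- rec$time[seq_len(n)]
  rec$angles <- rec$angles[seq_len(n), , drop = FALSE]
  rec$grf <- rec$grf[seq_len(n), , drop = FALSE]
  rec$phase <- rec$phase[seq_len(n)]
  rec$cycle <- rec$cycle[seq_len(n)]
  rec
}

tiny_spec <- function() {
  model_spec(window_len = 10L, lstm_units = 4L, conv_filters = c(3L, 5L))
}

small_spec <- function() {
  model_spec(window_len = 20L, lstm_units = 16L, conv_filters = c(8L, 16L))
}

# A small separable 4-class window set: each class has a distinct
# per-channel sinusoid mean pattern plus mild noise.
separable_windows <- function(n_per_class = 40L, window_len = 20L,
                              n_channels = 4L, noise = 0.15, seed = 42L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  phases <- gait_phases()
  n <- 4L * n_per_class
  x <- array(0, c(n, window_len, n_channels),
             dimnames = list(NULL, NULL, imu_sites()[seq_len(n_channels)]))
  lab <- character(n)
  tgrid <- seq(0, 1, length.out = window_len)
  i <- 0L
  for (cl in 1:4) {
    for (r in seq_len(n_per_class)) {
      i <- i + 1L
      for (ch in seq_len(n_channels)) {
        mu <- sin(2 * pi * (cl * tgrid + ch / n_channels)) * (1 + 0.2 * cl)
        x[i, , ch] <- mu + rnorm(window_len, sd = noise)
      }
      lab[i] <- phases[cl]
    }
  }
  structure(list(x = x, label = factor(lab, levels = phases),
                 start = seq_len(n), cycle_first = NULL, cycle_last = NULL,
                 recording_id = "synthetic", normalized = TRUE),
            class = "gait_windows")
}

# --- independent metric oracles (plain loops, no shared code) ---------------

oracle_confusion <- function(true, pred, levels) {
  C <- matrix(0, length(levels), length(levels),
              dimnames = list(levels, levels))
  counts <- C
  for (i in seq_along(true)) {
    counts[true[i], pred[i]] <- counts[true[i], pred[i]] + 1
  }
  for (r in levels) {
    ni <- sum(counts[r, ])
    if (ni > 0) C[r, ] <- counts[r, ] / ni
  }
  list(C = C, counts = counts)
}

oracle_macro <- function(true, pred, levels) {
  precs <- recs <- f1s <- numeric(0)
  for (cl in levels) {
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    precs <- c(precs, p)
    recs <- c(recs, r)
    f1s <- c(f1s, if (p + r > 0) 2 * p * r / (p + r) else 0)
  }
  mp <- mean(precs)
  mr <- mean(recs)
  list(macro_precision = mp, macro_recall = mr,
       macro_f1 = if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0,
       precision = precs, recall = recs, f1 = f1s)
}

# --- independent network oracles (scalar loops) -----------------------------

# One LSTM cell step, elementwise over units: gates from sigmoid/tanh of
# W_x x + W_h h + b with gate blocks ordered (input, forget, output, cell).
oracle_lstm_step <- function(x, h_prev, c_prev, Wx, Wh, b) {
  H <- length(h_prev)
  z <- as.numeric(x %*% Wx + h_prev %*% Wh) + b
  sig <- function(v) 1 / (1 + exp(-v))
  h <- c_new <- numeric(H)
  for (u in seq_len(H)) {
    i <- sig(z[u])
    f <- sig(z[H + u])
    o <- sig(z[2 * H + u])
    g <- tanh(z[3 * H + u])
    c_new[u] <- f * c_prev[u] + i * g
    h[u] <- o * tanh(c_new[u])
  }
  list(h = h, c = c_new)
}

# Direct temporal convolution (kernel width k, same zero padding, ReLU):
# out[t, j] = relu(b_j + sum_{dt, c} in[t + dt - pad, c] * W[dt, c, j])
oracle_conv <- function(x, W3, b) {
  TT <- nrow(x)
  C <- ncol(x)
  k <- dim(W3)[1]
  FF <- dim(W3)[3]
  pad <- (k - 1) %/% 2
  out <- matrix(0, TT, FF)
  for (t in seq_len(TT)) {
    for (j in seq_len(FF)) {
      acc <- b[j]
      for (dt in seq_len(k)) {
        ts <- t + dt - 1 - pad
        if (ts >= 1 && ts <= TT) {
          for (c in seq_len(C)) acc <- acc + x[ts, c] * W3[dt, c, j]
        }
      }
      out[t, j] <- max(acc, 0)
    }
  }
  out
}
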