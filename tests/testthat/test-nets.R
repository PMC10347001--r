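test_that("one LSTM step matches scalar evaluation of the gate equations", {
  set.seed(5)
  for (rep in 1:5) {
    C <- sample(2:6, 1)
    H <- sample(3:8, 1)
    Wx <- matrix(rnorm(C * 4 * H, sd = 0.5), C, 4 * H)
    Wh <- matrix(rnorm(H * 4 * H, sd = 0.5), H, 4 * H)
    b <- rnorm(4 * H, sd = 0.3)
    x <- rnorm(C)
    # drive the layer for one step from zero state
    out <- dpfgait:::lstm_layer_forward(matrix(x, 1, C), 1L, Wx, Wh, b,
                                        keep_cache = TRUE)
    ref <- oracle_lstm_step(x, numeric(H), numeric(H), Wx, Wh, b)
    expect_equal(as.numeric(out$out), ref$h, tolerance = 1e-5)

    # and a second step carrying hidden/cell state forward
    x2 <- rnorm(C)
    out2 <- dpfgait:::lstm_layer_forward(rbind(x, x2), 1L, Wx, Wh, b)
    ref2 <- oracle_lstm_step(x2, ref$h, ref$c, Wx, Wh, b)
    expect_equal(as.numeric(out2$out[2, ]), ref2$h, tolerance = 1e-5)
  }
})

test_that("the convolution layer matches direct kernel-sum evaluation", {
  set.seed(6)
  for (rep in 1:5) {
    TT <- sample(5:9, 1)
    C <- sample(2:4, 1)
    FF <- sample(2:5, 1)
    k <- 3
    # W3[dt, c, j] laid out to match the im2col column order (taps outermost)
    W3 <- array(rnorm(k * C * FF, sd = 0.7), c(k, C, FF))
    Wmat <- matrix(0, k * C, FF)
    for (dt in 1:k) for (c in 1:C) Wmat[(dt - 1) * C + c, ] <- W3[dt, c, ]
    b <- rnorm(FF, sd = 0.2)
    x <- matrix(rnorm(TT * C), TT, C)
    out <- dpfgait:::conv_layer_forward(x, 1L, Wmat, b, k)$out
    expect_equal(out, oracle_conv(x, W3, b), tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("max pooling halves then shifts the temporal axis (10 then 9)", {
  spec <- model_spec()
  expect_identical(spec$pooled_len, c(10L, 9L))
  # valid pooling arithmetic on a traceable signal
  x <- matrix(c(1, 3, 2, 8, 5, 4, 7, 6), ncol = 1)
  p1 <- dpfgait:::maxpool_forward(x, 1L, 2L, 2L)$out
  expect_equal(as.numeric(p1), c(3, 8, 5, 7))
  p2 <- dpfgait:::maxpool_forward(x, 1L, 2L, 1L)$out
  expect_equal(as.numeric(p2), c(3, 3, 8, 8, 5, 7, 7))
})

test_that("model construction is deterministic with spec-determined size", {
  spec <- small_spec()
  a <- build_model(spec, 4, seed = 3)
  b <- build_model(spec, 4, seed = 3)
  expect_identical(a$params, b$params)
  n_par <- function(m) sum(vapply(m$params, length, numeric(1)))
  expect_identical(n_par(a), n_par(b))
  # parameter count is a pure function of spec and channel count
  c6 <- build_model(spec, 6, seed = 1)
  expect_equal(n_par(c6) - n_par(a),
               (6 - 4) * 4 * spec$lstm_units)  # only lstm1's Wx grows
  expect_error(build_model(spec, 0), "n_channels")
})

test_that("untrained softmax outputs are proper distributions", {
  spec <- small_spec()
  m <- build_model(spec, 6, seed = 2)
  set.seed(1)
  x <- array(rnorm(7 * 20 * 6), c(7, 20, 6))
  p <- predict_prob(m, x)
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("prediction is invariant to batch context", {
  spec <- tiny_spec()
  m <- build_model(spec, 2, seed = 4)
  set.seed(2)
  x <- array(rnorm(5 * 10 * 2), c(5, 10, 2))
  batched <- predict_prob(m, x)
  single <- t(vapply(1:5, function(i) {
    predict_prob(m, matrix(x[i, , ], 10, 2))[1, ]
  }, numeric(4)))
  expect_equal(batched, single, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("shape mismatches are rejected with the expected geometry", {
  m <- build_model(tiny_spec(), 2, seed = 1)
  expect_error(predict_prob(m, matrix(0, 10, 3)), "does not match")
  expect_error(predict_prob(m, matrix(0, 12, 2)), "does not match")
})

test_that("backpropagation matches numerical gradients", {
  spec <- tiny_spec()
  m <- build_model(spec, 2, seed = 7)
  set.seed(8)
  X <- array(rnorm(3 * 10 * 2), c(3, 10, 2))
  y <- c(1L, 3L, 4L)
  lossfn <- function(p) {
    dpfgait:::ce_loss(dpfgait:::net_forward(p, spec, X)$prob, y)
  }
  fwd <- dpfgait:::net_forward(m$params, spec, X, keep_cache = TRUE)
  gr <- dpfgait:::net_backward(m$params, spec, fwd,
                               (fwd$prob - diag(4)[y, ]) / 3)
  eps <- 1e-5
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (j in sample(seq_along(p), min(8, length(p)))) {
      pp <- m$params
      pp[[nm]][j] <- p[j] + eps
      lp <- lossfn(pp)
      pp[[nm]][j] <- p[j] - eps
      lm <- lossfn(pp)
      expect_equal(gr[[nm]][j], (lp - lm) / (2 * eps), tolerance = 1e-6)
    }
  }
})

test_that("training is seeded-deterministic and learns separable classes", {
  w <- separable_windows(n_per_class = 30, n_channels = 4)
  cfg <- train_config(learning_rate = 3e-3, batch_size = 32,
                      max_epochs = 50, patience = 8, seed = 5)
  m0 <- build_model(small_spec(), 4, seed = 5)
  m1 <- train(m0, w, cfg)
  expect_true(all(is.finite(m1$history$train_loss)))
  expect_gte(max(m1$history$train_acc), 0.95)
  expect_lte(nrow(m1$history), 50)

  m2 <- train(m0, w, cfg)
  expect_identical(m1$params, m2$params)
  expect_equal(m1$history, m2$history)

  # held-out windows from the same generative process are classified well
  hw <- separable_windows(n_per_class = 15, n_channels = 4, seed = 99)
  pred <- decode_phase(predict_prob(m1, hw))
  expect_gte(mean(pred == as.character(hw$label)), 0.9)
})

test_that("training rejects degenerate inputs", {
  w <- separable_windows(n_per_class = 5, n_channels = 2,
                         window_len = 10)
  m <- build_model(tiny_spec(), 2, seed = 1)
  w_missing <- w
  keep <- w$label != "SW-R"
  w_missing$x <- w$x[keep, , , drop = FALSE]
  w_missing$label <- w$label[keep]
  expect_error(train(m, w_missing, train_config(seed = 1)), "absent")
  m4 <- build_model(tiny_spec(), 4, seed = 1)
  expect_error(train(m4, w, train_config(seed = 1)), "channels")
})

test_that("specialists bind the documented sensor groups", {
  cfg <- clean_config()
  recs <- lapply(list(simulate_recording(cfg, 1, 1.5, seed = 1),
                      simulate_recording(cfg, 2, 1.5, seed = 2)),
                 interpolate_recording)
  norm <- fit_normalizer(recs)
  ws <- dpfgait:::combine_windows(lapply(recs, segment_windows, stride = 8))
  tc <- train_config(max_epochs = 2, batch_size = 64, seed = 3)
  models <- train_specialists(ws, norm, tc, small_spec())
  expect_identical(names(models), c("LSTM-CNN-1", "LSTM-CNN-2", "LSTM-CNN-3"))
  expect_identical(vapply(models, `[[`, integer(1), "n_channels"),
                   c("LSTM-CNN-1" = 6L, "LSTM-CNN-2" = 4L, "LSTM-CNN-3" = 4L))
  expect_identical(vapply(models, function(m) m$group$group_id, integer(1)),
                   c("LSTM-CNN-1" = 7L, "LSTM-CNN-2" = 6L, "LSTM-CNN-3" = 4L))
  # every specialist consumes raw 6-channel windows through predict_phase
  win <- matrix(recs[[1]]$angles[1:20, ], 20, 6,
                dimnames = list(NULL, imu_sites()))
  for (m in models) {
    expect_true(predict_phase(m, win) %in% gait_phases())
  }
  # checkpoints round-trip
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(models[[1]], path)
  back <- read_model(path)
  expect_identical(back$params, models[[1]]$params)
  expect_true(file.exists(paste0(path, ".json")))
})
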