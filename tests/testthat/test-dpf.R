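# A scripted classifier shared across all model ids: one prediction per
# engine step, read from a fixed label sequence.
scripted_models <- function(labels) {
  i <- 0L
  mk <- mock_classifier(function(w) {
    i <<- i + 1L
    labels[[min(i, length(labels))]]
  })
  list("LSTM-CNN-1" = mk, "LSTM-CNN-2" = mk, "LSTM-CNN-3" = mk)
}

dummy_window <- function() {
  matrix(0, 20, 6, dimnames = list(NULL, imu_sites()))
}

test_that("the phase->model map routes swing and double-support correctly", {
  cfg <- dpf_config()
  expect_identical(model_for_phase("SW-L", cfg), "LSTM-CNN-2")
  expect_identical(model_for_phase("SU-LHS", cfg), "LSTM-CNN-3")
  expect_identical(model_for_phase("SU-RHS", cfg), "LSTM-CNN-1")
  expect_identical(model_for_phase("SW-R", cfg), "LSTM-CNN-1")
  expect_error(model_for_phase("SW-L", dpf_config(
    model_map = c("SU-RHS" = "a", "SW-L" = "b", "SU-LHS" = "c",
                  "SW-R" = "d"))), NA)
  expect_error(dpf_config(model_map = c("SU-RHS" = "a")), "lacks phase")
  expect_error(dpf_config(debounce_k = 0), "debounce_k")
})

test_that("five consecutive identical predictions commit; a flip resets", {
  cfg <- dpf_config()
  models <- scripted_models(rep("SW-L", 10))
  st <- dpf_init(cfg)
  win <- dummy_window()
  for (k in 1:4) {
    r <- dpf_step(st, win, models, cfg)
    st <- r$state
    expect_true(is.na(r$committed))
  }
  r <- dpf_step(st, win, models, cfg)
  expect_identical(r$committed, "SW-L")           # commit on the 5th
  st <- r$state
  expect_identical(st$expected, "SU-LHS")
  expect_identical(st$active, "LSTM-CNN-3")       # model for the next phase

  # A,A,A,A,B: no commit, candidate resets to B with count 1
  models <- scripted_models(c(rep("SW-L", 4), "SU-LHS"))
  st <- dpf_init(cfg)
  for (k in 1:5) {
    r <- dpf_step(st, dummy_window(), models, cfg)
    st <- r$state
  }
  expect_true(is.na(st$committed))
  expect_identical(st$candidate, "SU-LHS")
  expect_identical(st$count, 1L)
})

test_that("with oracle classifiers the committed track lags truth by k-1", {
  rec <- simulate_recording(clean_config(), 1, 1.5, seed = 2)
  w <- segment_windows(rec, stride = 1)
  truth <- as.character(w$label)
  k <- 5L
  stream <- run_stream(rec, scripted_models(truth), dpf_config(debounce_k = k))
  expect_identical(stream$first_commit, k)
  com <- stream$trace$committed
  idx <- seq(stream$first_commit, length(com))
  expect_identical(com[idx], truth[idx - (k - 1L)])
  # committed transitions only along the cyclic order
  chg <- idx[-1][com[idx[-1]] != com[idx[-length(idx)]]]
  if (length(chg)) {
    expect_true(all(com[chg] == next_phase(com[chg - 1L])))
  }
  expect_identical(stream$violations, 0L)
})

test_that("isolated mispredictions never reach the committed track", {
  rec <- simulate_recording(clean_config(), 1, 1.8, seed = 4)
  w <- segment_windows(rec, stride = 1)
  truth <- as.character(w$label)
  corrupted <- truth
  # flip single windows well inside stable segments (so no pending commit
  # is interrupted); the debounce must swallow every one of them
  flip_at <- seq(25, length(truth) - 10, by = 40)
  stable <- vapply(flip_at, function(fa) {
    length(unique(truth[(fa - 6):(fa + 1)])) == 1L
  }, logical(1))
  flip_at <- flip_at[stable]
  expect_gt(length(flip_at), 3)
  corrupted[flip_at] <- next_phase(next_phase(truth[flip_at]))  # 2 ahead
  stream <- run_stream(rec, scripted_models(corrupted), dpf_config())
  com <- stream$trace$committed
  idx <- which(!is.na(com))
  # the flipped phase values never appear at or around the flip windows
  for (fa in flip_at) {
    expect_false(identical(com[fa], corrupted[fa]))
  }
  # and the committed track still equals the k-1 delayed truth
  expect_identical(com[idx], truth[idx - 4L])
})

test_that("an all-single-model map reduces to debounced single-model output", {
  rec <- simulate_recording(clean_config(), 2, 1.2, seed = 6)
  w <- segment_windows(rec, stride = 1)
  truth <- as.character(w$label)
  set.seed(10)
  noisy <- truth
  noise_at <- sample(length(truth), 40)
  noisy[noise_at] <- sample(gait_phases(), 40, replace = TRUE)

  uni <- dpf_config(model_map = c("SU-RHS" = "LSTM-CNN-1",
                                  "SW-L" = "LSTM-CNN-1",
                                  "SU-LHS" = "LSTM-CNN-1",
                                  "SW-R" = "LSTM-CNN-1"))
  stream <- suppressWarnings(run_stream(rec, scripted_models(noisy), uni))

  # reference: plain debounce over the same prediction sequence
  debounce_ref <- function(preds, k) {
    out <- rep(NA_character_, length(preds))
    committed <- NA_character_
    cand <- NA_character_
    cnt <- 0L
    for (i in seq_along(preds)) {
      if (!is.na(cand) && preds[i] == cand) cnt <- cnt + 1L
      else { cand <- preds[i]; cnt <- 1L }
      if (cnt >= k && (is.na(committed) || cand != committed)) committed <- cand
      out[i] <- committed
    }
    out
  }
  expect_identical(stream$trace$committed, debounce_ref(noisy, 5L))
})

test_that("debounce_k = 1 is plain per-window switching", {
  rec <- simulate_recording(clean_config(), 1, 1.5, seed = 8)
  w <- segment_windows(rec, stride = 1)
  truth <- as.character(w$label)
  stream <- run_stream(rec, scripted_models(truth),
                       dpf_config(debounce_k = 1L))
  expect_identical(stream$trace$committed, truth)
  expect_identical(stream$first_commit, 1L)
})

test_that("out-of-sequence commits re-anchor the machine and are counted", {
  cfg <- dpf_config()
  labels <- c(rep("SU-RHS", 5), rep("SU-LHS", 5))  # skips SW-L
  models <- scripted_models(labels)
  st <- dpf_init(cfg)
  for (k in 1:10) {
    r <- dpf_step(st, dummy_window(), models, cfg)
    st <- r$state
  }
  expect_identical(st$committed, "SU-LHS")
  expect_identical(st$violations, 1L)
  expect_identical(st$expected, "SW-R")  # re-anchored downstream
  expect_identical(st$active, "LSTM-CNN-1")
})

test_that("the engine refuses streams it cannot serve", {
  cfg <- dpf_config()
  st <- dpf_init(cfg)
  expect_error(dpf_step(st, dummy_window(), list(), cfg), "active model")
  m <- build_model(tiny_spec(), 2, seed = 1)
  expect_error(predict_phase(m, dummy_window()), "not bound")
})
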