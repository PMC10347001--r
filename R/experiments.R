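#' Desk-scale experiment plan
#'
#' Bundles everything needed to reproduce the two protocols end to end:
#' the synthetic cohort, the cycle-level data split, the seven
#' sensor-placement groups, training hyperparameters and the
#' model-switching configuration. Defaults are desk-scale: 6 subjects x 3
#' speeds x 10 cycles, stride-5 training windows and at most 30 training
#' epochs, which keeps the full ablation within minutes on one CPU while
#' preserving the protocol structure.
#'
#' Splitting is at the gait-cycle level, never the window level: windows
#' overlap heavily at small strides, so a window-level split would leak
#' near-duplicates between training and test. Per recording, the final 20%
#' of cycles are held out as a validation block (contiguous, so streaming
#' inference can run on it); the remaining cycles are split 70/30 into
#' train and test at random. Windows that straddle two splits are dropped.
#'
#' @param synth A [synth_config()] for the cohort.
#' @param groups Sensor groups to include in the ablation.
#' @param window_len Samples per window.
#' @param train_stride Window stride for the training set (thins
#'   near-duplicate windows).
#' @param eval_stride Window stride for test-set evaluation.
#' @param val_fraction Fraction of each recording's cycles held out for
#'   validation (streaming comparison).
#' @param train_fraction Fraction of the remaining cycles used for
#'   training (the rest is the test set).
#' @param spec A [model_spec()].
#' @param train A [train_config()].
#' @param dpf A [dpf_config()].
#' @param seed Master seed for splits and per-group training seeds.
#' @return An `experiment_plan`.
#' @export
experiment_plan <- function(synth = synth_config(n_subjects = 6L),
                            groups = 1:7, window_len = 20L,
                            train_stride = 5L, eval_stride = 5L,
                            val_fraction = 0.2, train_fraction = 0.7,
                            spec = model_spec(),
                            train = train_config(learning_rate = 3e-3,
                                                 batch_size = 128L,
                                                 max_epochs = 20L,
                                                 patience = 5L,
                                                 min_delta = 1e-4,
                                                 loss_threshold = 5e-3),
                            dpf = dpf_config(), seed = 1L) {
  structure(list(synth = synth, groups = groups,
                 window_len = as.integer(window_len),
                 train_stride = as.integer(train_stride),
                 eval_stride = as.integer(eval_stride),
                 val_fraction = val_fraction, train_fraction = train_fraction,
                 spec = spec, train = train, dpf = dpf,
                 seed = as.integer(seed)),
            class = "experiment_plan")
}

#' Split a recording's cycles into train / test / validation sets
#'
#' The last `round(val_fraction * n)` cycles form a contiguous validation
#' block; of the remaining cycles, `round(train_fraction * m)` are sampled
#' (seeded) for training and the rest are the test set. The three sets are
#' disjoint by construction.
#'
#' @param n_cycles Number of cycles in the recording.
#' @param val_fraction,train_fraction Split fractions (see
#'   [experiment_plan()]).
#' @param seed Seed for the train/test draw.
#' @return List of integer cycle-id vectors `train`, `test`, `validation`.
#' @export
split_cycles <- function(n_cycles, val_fraction = 0.2, train_fraction = 0.7,
                         seed = 1L) {
  n_val <- max(1L, round(val_fraction * n_cycles))
  if (n_val >= n_cycles - 1L) stop("too few cycles to split")
  val <- (n_cycles - n_val + 1L):n_cycles
  rest <- seq_len(n_cycles - n_val)
  n_train <- max(1L, round(train_fraction * length(rest)))
  if (n_train >= length(rest)) n_train <- length(rest) - 1L
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  train <- sort(sample(rest, n_train))
  list(train = train, test = setdiff(rest, train), validation = val)
}

subset_recording <- function(recording, cycles) {
  idx <- which(recording$cycle %in% cycles)
  structure(list(
    subject_id = recording$subject_id, speed = recording$speed,
    time = recording$time[idx],
    angles = recording$angles[idx, , drop = FALSE],
    grf = recording$grf[idx, , drop = FALSE],
    phase = recording$phase[idx],
    cycle = recording$cycle[idx]
  ), class = "gait_recording")
}

# Windows fully inside one split's cycle set, pooled over recordings.
build_window_set <- function(recordings, cycle_sets, window_len, stride) {
  parts <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    w <- segment_windows(recordings[[i]], window_len = window_len,
                         stride = stride)
    keep <- w$cycle_first %in% cycle_sets[[i]] &
      w$cycle_last %in% cycle_sets[[i]]
    parts[[i]] <- subset_windows(w, which(keep))
  }
  combine_windows(parts)
}

# programmatic leakage check: no (recording, cycle) pair in two window sets
assert_disjoint_windows <- function(a, b, what = c("sets")) {
  key <- function(w) {
    unique(c(paste(w$recording_id, w$cycle_first),
             paste(w$recording_id, w$cycle_last)))
  }
  shared <- intersect(key(a), key(b))
  if (length(shared)) {
    stop("cycle leakage between ", paste(what, collapse = " and "), ": ",
         paste(utils::head(shared, 3), collapse = "; "))
  }
  invisible(TRUE)
}

predict_windows <- function(model, windows, batch = 256L) {
  n <- dim(windows$x)[1]
  out <- matrix(NA_real_, n, 4L, dimnames = list(NULL, gait_phases()))
  for (b0 in seq.int(1L, n, by = batch)) {
    bi <- b0:min(b0 + batch - 1L, n)
    out[bi, ] <- predict_prob(model, windows$x[bi, , , drop = FALSE])
  }
  out
}

prepare_cohort <- function(plan) {
  cohort <- lapply(simulate_cohort(plan$synth), interpolate_recording)
  splits <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    splits[[i]] <- split_cycles(plan$synth$cycles_per_speed,
                                plan$val_fraction, plan$train_fraction,
                                seed = plan$seed * 131L + i)
  }
  train_ws <- build_window_set(cohort, lapply(splits, `[[`, "train"),
                               plan$window_len, plan$train_stride)
  test_ws <- build_window_set(cohort, lapply(splits, `[[`, "test"),
                              plan$window_len, plan$eval_stride)
  assert_disjoint_windows(train_ws, test_ws, c("train", "test"))
  val_ws <- build_window_set(cohort, lapply(splits, `[[`, "validation"),
                             plan$window_len, 1L)
  assert_disjoint_windows(train_ws, val_ws, c("train", "validation"))
  assert_disjoint_windows(test_ws, val_ws, c("test", "validation"))
  norm_fit <- lapply(seq_along(cohort), function(i) {
    subset_recording(cohort[[i]], splits[[i]]$train)
  })
  normalizer <- fit_normalizer(norm_fit)
  list(cohort = cohort, splits = splits, train_ws = train_ws,
       test_ws = test_ws, normalizer = normalizer)
}

#' Sensor-placement ablation
#'
#' Trains one LSTM-CNN per sensor group on a common synthetic cohort and
#' evaluates all of them on the same held-out test cycles. Fully seeded:
#' re-running the same plan reproduces the numbers.
#'
#' @param plan An [experiment_plan()].
#' @param data Optional result of a previous internal cohort preparation
#'   (reused by [run_dpf_comparison()]); normally NULL.
#' @return List with `summary` (per-group per-phase precision/recall/F1
#'   rows plus one aggregate row per group), `reports` (per-group
#'   [metrics_report()]s), `models`, `normalizer`, `splits` and `cohort`.
#' @export
run_ablation <- function(plan, data = NULL) {
  stopifnot(inherits(plan, "experiment_plan"))
  if (is.null(data)) data <- prepare_cohort(plan)
  reports <- list()
  models <- list()
  rows <- list()
  for (g in plan$groups) {
    cfg <- plan$train
    cfg$seed <- plan$seed * 977L + g
    model <- fit_group_model(data$train_ws, sensor_group(g), data$normalizer,
                             cfg, plan$spec)
    tw <- apply_normalizer(data$normalizer,
                           select_channels(data$test_ws, sensor_group(g)))
    pred <- decode_phase(predict_windows(model, tw))
    rep <- metrics_report(as.character(tw$label), pred)
    key <- paste0("group", g)
    models[[key]] <- model
    reports[[key]] <- rep
    for (ph in gait_phases()) {
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, row = "phase", phase = ph,
        precision = rep$precision[[ph]], recall = rep$recall[[ph]],
        f1 = rep$f1[[ph]], accuracy = NA_real_, macro_f1 = NA_real_)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, row = "aggregate", phase = NA_character_,
      precision = rep$macro_precision, recall = rep$macro_recall,
      f1 = rep$mean_class_f1, accuracy = rep$accuracy,
      macro_f1 = rep$macro_f1)
  }
  list(summary = do.call(rbind, rows), reports = reports, models = models,
       normalizer = data$normalizer, splits = data$splits,
       cohort = data$cohort, data = data)
}

#' Paired comparison: model switching vs the single full-sensor model
#'
#' For every subject, streams the held-out validation cycles through (a)
#' the phase-sequenced switching engine with its three specialists and (b)
#' plain per-window inference with the full-sensor model, on identical
#' window streams. Both methods are scored on their per-window recognition
#' output over the same windows (for the engine, the routed specialist's
#' prediction; its debounced committed track is the switching state and
#' lags transitions by construction).
#'
#' @param plan An [experiment_plan()].
#' @param ablation Optional [run_ablation()] result to reuse trained models
#'   (groups 7, 6 and 4 become `LSTM-CNN-1/2/3`); otherwise specialists are
#'   trained here.
#' @return List with `table` (per-subject accuracy and macro-F1 for both
#'   methods plus an average row), `specialists`, and per-subject paired
#'   label tracks in `detail`.
#' @export
run_dpf_comparison <- function(plan, ablation = NULL) {
  stopifnot(inherits(plan, "experiment_plan"))
  if (!is.null(ablation) &&
      all(c("group7", "group6", "group4") %in% names(ablation$models))) {
    data <- ablation$data
    specialists <- list("LSTM-CNN-1" = ablation$models$group7,
                        "LSTM-CNN-2" = ablation$models$group6,
                        "LSTM-CNN-3" = ablation$models$group4)
  } else {
    data <- if (!is.null(ablation)) ablation$data else prepare_cohort(plan)
    cfg <- plan$train
    cfg$seed <- plan$seed * 977L + 7L
    specialists <- train_specialists(data$train_ws, data$normalizer, cfg,
                                     plan$spec)
  }
  subjects <- sort(unique(vapply(data$cohort, `[[`, integer(1), "subject_id")))
  rows <- list()
  detail <- list()
  for (subj in subjects) {
    truth_all <- character(0)
    dpf_all <- character(0)
    single_all <- character(0)
    for (i in seq_along(data$cohort)) {
      rec <- data$cohort[[i]]
      if (rec$subject_id != subj) next
      val_rec <- subset_recording(rec, data$splits[[i]]$validation)
      stream <- run_stream(val_rec, specialists, plan$dpf,
                           window_len = plan$window_len, stride = 1L)
      w <- segment_windows(val_rec, window_len = plan$window_len, stride = 1L)
      w1 <- apply_normalizer(specialists[["LSTM-CNN-1"]]$normalizer,
                             select_channels(w,
                                             specialists[["LSTM-CNN-1"]]$group))
      single_pred <- decode_phase(predict_windows(specialists[["LSTM-CNN-1"]],
                                                  w1))
      truth_all <- c(truth_all, stream$trace$truth)
      dpf_all <- c(dpf_all, stream$trace$prediction)
      single_all <- c(single_all, single_pred)
    }
    rep_dpf <- metrics_report(truth_all, dpf_all)
    rep_single <- metrics_report(truth_all, single_all)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = as.character(subj),
      acc_single = rep_single$accuracy, macro_f1_single = rep_single$macro_f1,
      acc_dpf = rep_dpf$accuracy, macro_f1_dpf = rep_dpf$macro_f1)
    detail[[as.character(subj)]] <- list(truth = truth_all, dpf = dpf_all,
                                         single = single_all)
  }
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(subject = "average",
                               acc_single = mean(tab$acc_single),
                               macro_f1_single = mean(tab$macro_f1_single),
                               acc_dpf = mean(tab$acc_dpf),
                               macro_f1_dpf = mean(tab$macro_f1_dpf)))
  list(table = tab, specialists = specialists, detail = detail)
}
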