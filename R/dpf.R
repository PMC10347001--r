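#' Configuration of the phase-sequenced model-switching engine
#'
#' The engine (data pre-filtering, DPF) exploits the fixed cyclic phase
#' order: once a phase is committed, the next phase is known, so the
#' specialist model most accurate for that upcoming phase is activated.
#' A phase change is committed only after `debounce_k` consecutive
#' identical predictions, suppressing isolated misclassifications.
#'
#' The default phase-to-model map sends `SW-L` to the shank+foot
#' specialist (`LSTM-CNN-2`), `SU-LHS` to the thigh+shank specialist
#' (`LSTM-CNN-3`), and the two remaining phases to the full six-sensor
#' model (`LSTM-CNN-1`). The map is configurable, so alternative
#' placement-to-phase assignments can be run.
#'
#' @param model_map Named character vector mapping each of the four phases
#'   to a model id.
#' @param debounce_k Consecutive identical predictions required to commit.
#' @param initial_model Model id used before the first commit.
#' @return A `dpf_config`.
#' @export
dpf_config <- function(model_map = c("SU-RHS" = "LSTM-CNN-1",
                                     "SW-L" = "LSTM-CNN-2",
                                     "SU-LHS" = "LSTM-CNN-3",
                                     "SW-R" = "LSTM-CNN-1"),
                       debounce_k = 5L, initial_model = "LSTM-CNN-1") {
  missing_ph <- setdiff(gait_phases(), names(model_map))
  if (length(missing_ph)) {
    stop("model_map lacks phase(s): ", paste(missing_ph, collapse = ", "))
  }
  debounce_k <- as.integer(debounce_k)
  if (debounce_k < 1L) stop("debounce_k must be >= 1")
  structure(list(model_map = model_map, debounce_k = debounce_k,
                 initial_model = initial_model),
            class = "dpf_config")
}

#' Look up the specialist model for a phase
#'
#' @param phase A phase label.
#' @param config A [dpf_config()].
#' @return The model id bound to that phase.
#' @export
model_for_phase <- function(phase, config = dpf_config()) {
  phase <- as.character(phase)
  if (!phase %in% names(config$model_map)) {
    stop("no model mapped for phase ", phase)
  }
  unname(config$model_map[[phase]])
}

#' Initial engine state
#'
#' Nothing is committed yet: the engine reports "undetermined" (NA) and
#' classifies with the initial (full-sensor) model until the first
#' debounced commit anchors the phase sequence.
#'
#' @param config A [dpf_config()].
#' @return A `dpf_state`.
#' @export
dpf_init <- function(config = dpf_config()) {
  structure(list(committed = NA_character_, expected = NA_character_,
                 active = config$initial_model, candidate = NA_character_,
                 count = 0L, violations = 0L),
            class = "dpf_state")
}

#' Advance the engine by one window
#'
#' Runs the active model on the raw 6-channel window (the model selects and
#' normalizes its own channels), updates the debounce counter, and commits
#' the candidate phase once it has been predicted `debounce_k` times in a
#' row. On commit, the expected next phase advances along the cycle and the
#' model mapped to it becomes active. A commit that is not the expected
#' next phase is accepted — the sequence is re-anchored — and counted in
#' `state$violations`.
#'
#' @param state A `dpf_state`.
#' @param window Raw window, time x 6 matrix with site column names.
#' @param models Named list of classifiers covering every id in the map.
#' @param config A [dpf_config()].
#' @return List with `state` (updated), `committed` (last committed phase,
#'   `NA` before the first commit), `prediction` (this window's raw model
#'   output) and `active` (the model id that produced it).
#' @export
dpf_step <- function(state, window, models, config = dpf_config()) {
  stopifnot(inherits(state, "dpf_state"))
  if (is.null(models[[state$active]])) {
    stop("models list lacks the active model ", state$active)
  }
  active <- state$active
  pred <- predict_phase(models[[active]], window)
  if (!is.na(state$candidate) && pred == state$candidate) {
    state$count <- min(state$count + 1L, config$debounce_k)
  } else {
    state$candidate <- pred
    state$count <- 1L
  }
  if (state$count >= config$debounce_k &&
      (is.na(state$committed) || state$candidate != state$committed)) {
    if (!is.na(state$expected) && state$candidate != state$expected) {
      state$violations <- state$violations + 1L
    }
    state$committed <- state$candidate
    state$expected <- next_phase(state$committed)
    state$active <- model_for_phase(state$expected, config)
  }
  list(state = state, committed = state$committed, prediction = pred,
       active = active)
}

#' Run the engine over a whole recording
#'
#' Applies stride-1 sliding windows (configurable) to the recording and
#' advances the engine window by window. When the recording carries ground
#' truth, a [metrics_report()] is computed on the windows from the first
#' commit onward (before it the engine deliberately reports
#' "undetermined").
#'
#' The engine produces two per-window tracks. The *prediction* track is
#' the phase recognized by the routed specialist at each window — the
#' engine's recognition output, scored in `report`. The *committed* track
#' is the debounced switching state: it changes only after `debounce_k`
#' consecutive identical predictions and therefore lags each true
#' transition by `debounce_k - 1` windows by construction; it is scored
#' separately in `report_committed`.
#'
#' @param recording A `gait_recording` with all six angle channels (dropped
#'   samples are interpolated first).
#' @param models Named list of classifiers.
#' @param config A [dpf_config()].
#' @param window_len Samples per window.
#' @param stride Window stride (default 1: per-sample updates).
#' @return List with `trace` (one row per window: start index, active model
#'   id, routed prediction, committed phase, truth label if available),
#'   `report` (metrics of the routed predictions, or NULL without truth),
#'   `report_committed` (metrics of the debounced committed track over the
#'   windows where it is defined), `first_commit` (window index of the
#'   first commit) and `violations` (out-of-sequence commits).
#' @export
run_stream <- function(recording, models, config = dpf_config(),
                       window_len = 20L, stride = 1L) {
  stopifnot(inherits(recording, "gait_recording"))
  if (anyNA(recording$angles)) recording <- interpolate_recording(recording)
  w <- segment_windows(recording, window_len = window_len, stride = stride)
  nw <- length(w$start)
  state <- dpf_init(config)
  committed <- character(nw)
  prediction <- character(nw)
  active <- character(nw)
  sites <- dimnames(w$x)[[3]]
  for (i in seq_len(nw)) {
    win <- matrix(w$x[i, , ], window_len, length(sites),
                  dimnames = list(NULL, sites))
    r <- dpf_step(state, win, models, config)
    state <- r$state
    committed[i] <- if (is.na(r$committed)) NA_character_ else r$committed
    prediction[i] <- r$prediction
    active[i] <- r$active
  }
  if (state$violations > 0L) {
    warning(state$violations, " out-of-sequence commit(s); ",
            "phase machine re-anchored each time")
  }
  trace <- data.frame(window = seq_len(nw), start = w$start, active = active,
                      prediction = prediction, committed = committed,
                      stringsAsFactors = FALSE)
  report <- NULL
  report_committed <- NULL
  first_commit <- NA_integer_
  done <- which(!is.na(committed))
  if (length(done)) first_commit <- done[1L]
  if (!is.null(w$label)) {
    trace$truth <- as.character(w$label)
    report <- metrics_report(trace$truth, prediction)
    if (length(done)) {
      report_committed <- metrics_report(trace$truth[done], committed[done])
    }
  }
  list(trace = trace, report = report, report_committed = report_committed,
       first_commit = first_commit, violations = state$violations)
}

#' Write a stream trace as JSON lines
#'
#' One JSON object per window: index, active model, raw prediction,
#' committed phase (and truth when known).
#'
#' @param stream Result of [run_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stream_trace <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(stream$trace))) {
    writeLines(jsonlite::toJSON(as.list(stream$trace[i, ]),
                                auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}
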