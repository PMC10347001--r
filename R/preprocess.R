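#' Linearly interpolate dropped samples
#'
#' Replaces each missing value at position `x` by
#' `y = (x - x0)/(x1 - x0) * (y1 - y0) + y0`, where `(x0, y0)` and
#' `(x1, y1)` are the nearest present neighbors on either side (delegated
#' to `stats::approx`, which implements the same formula). Present samples
#' are unchanged; the operation is idempotent on complete series.
#'
#' @param y Numeric vector with `NA` marking dropped samples.
#' @param x Sample positions (default: equally spaced indices).
#' @return `y` with all `NA`s filled in.
#' @export
interpolate_missing <- function(y, x = seq_along(y)) {
  miss <- is.na(y)
  if (!any(miss)) return(y)
  if (miss[1L] || miss[length(y)]) {
    stop("cannot interpolate: series endpoint is missing")
  }
  y[miss] <- stats::approx(x[!miss], y[!miss], xout = x[miss],
                           method = "linear")$y
  y
}

#' Fill all dropped angle samples in a recording
#'
#' Applies [interpolate_missing()] to each of the six angle channels.
#'
#' @param recording A `gait_recording`.
#' @return The recording with a complete `angles` matrix.
#' @export
interpolate_recording <- function(recording) {
  stopifnot(inherits(recording, "gait_recording"))
  for (ch in colnames(recording$angles)) {
    recording$angles[, ch] <- interpolate_missing(recording$angles[, ch],
                                                  recording$time)
  }
  recording
}

#' Fit per-channel min-max normalization parameters
#'
#' Records each channel's minimum and maximum over the training recordings.
#' [apply_normalizer()] then maps values affinely so that the training
#' minimum goes to -1 and the training maximum to +1. Fit on training data
#' only; test-set values outside the training range map outside `[-1, 1]`
#' (no clamping — the map is affine, not saturating).
#'
#' @param recordings A `gait_recording` or list of them (angle channels must
#'   be complete; interpolate first).
#' @return A `gait_normalizer`: list with named vectors `x_min`, `x_max`.
#' @export
fit_normalizer <- function(recordings) {
  if (inherits(recordings, "gait_recording")) recordings <- list(recordings)
  mats <- lapply(recordings, function(r) {
    stopifnot(inherits(r, "gait_recording"))
    r$angles
  })
  all_angles <- do.call(rbind, mats)
  if (anyNA(all_angles)) {
    stop("angle channels contain NA; run interpolate_recording() first")
  }
  x_min <- apply(all_angles, 2, min)
  x_max <- apply(all_angles, 2, max)
  flat <- names(x_min)[x_max <= x_min]
  if (length(flat)) {
    stop("cannot normalize constant channel(s): ", paste(flat, collapse = ", "))
  }
  structure(list(x_min = x_min, x_max = x_max, y_min = -1, y_max = 1),
            class = "gait_normalizer")
}

#' Apply min-max normalization
#'
#' `x_norm = (x - x_min) / (x_max - x_min) * (y_max - y_min) + y_min` per
#' channel, with `y_min = -1`, `y_max = +1`.
#'
#' @param params A `gait_normalizer` from [fit_normalizer()].
#' @param x A named-column matrix (samples x channels), a 3-D window array
#'   (windows x time x channels with channel dimnames), or a
#'   `gait_windows` object.
#' @return Object of the same shape with normalized values.
#' @export
apply_normalizer <- function(params, x) {
  stopifnot(inherits(params, "gait_normalizer"))
  scale_ch <- function(v, ch) {
    if (!ch %in% names(params$x_min)) {
      stop("normalizer has no parameters for channel ", ch)
    }
    (v - params$x_min[[ch]]) / (params$x_max[[ch]] - params$x_min[[ch]]) *
      (params$y_max - params$y_min) + params$y_min
  }
  if (inherits(x, "gait_windows")) {
    x$x <- apply_normalizer(params, x$x)
    x$normalized <- TRUE
    return(x)
  }
  if (is.matrix(x)) {
    for (ch in colnames(x)) x[, ch] <- scale_ch(x[, ch], ch)
    return(x)
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    chs <- dimnames(x)[[3]]
    if (is.null(chs)) stop("window array lacks channel dimnames")
    for (k in seq_along(chs)) x[, , k] <- scale_ch(x[, , k], chs[k])
    return(x)
  }
  stop("unsupported input to apply_normalizer")
}

#' Save / load normalizer parameters as JSON
#' @param params A `gait_normalizer`.
#' @param path JSON file path.
#' @return `path` (write) or a `gait_normalizer` (read).
#' @export
write_normalizer <- function(params, path) {
  stopifnot(inherits(params, "gait_normalizer"))
  out <- list(x_min = as.list(params$x_min), x_max = as.list(params$x_max),
              y_min = params$y_min, y_max = params$y_max)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normalizer
#' @export
read_normalizer <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(x_min = unlist(p$x_min), x_max = unlist(p$x_max),
                 y_min = p$y_min, y_max = p$y_max),
            class = "gait_normalizer")
}

#' The seven IMU placement groups
#'
#' Channel subsets used in the sensor-placement ablation:
#'
#' | group | sites |
#' |-------|-------|
#' | 1 | left and right thighs |
#' | 2 | left and right shanks |
#' | 3 | left and right feet |
#' | 4 | left and right thighs and shanks |
#' | 5 | left and right thighs and feet |
#' | 6 | left and right shanks and feet |
#' | 7 | all six sites |
#'
#' @param group_id Integer in 1..7.
#' @return A `sensor_group`: list with `group_id` and `sites` (in the fixed
#'   site order of [imu_sites()]).
#' @export
sensor_group <- function(group_id) {
  group_id <- as.integer(group_id)
  if (is.na(group_id) || group_id < 1L || group_id > 7L) {
    stop("group_id must be an integer in 1..7")
  }
  sets <- list(
    c("L_thigh", "R_thigh"),
    c("L_shank", "R_shank"),
    c("L_foot", "R_foot"),
    c("L_thigh", "R_thigh", "L_shank", "R_shank"),
    c("L_thigh", "R_thigh", "L_foot", "R_foot"),
    c("L_shank", "R_shank", "L_foot", "R_foot"),
    imu_sites()
  )
  structure(list(group_id = group_id, sites = sets[[group_id]]),
            class = "sensor_group")
}

#' Cut sliding windows from a recording
#'
#' Windows of `window_len` consecutive samples starting at indices
#' `1, 1 + stride, 1 + 2*stride, ...`; the number of windows is
#' `floor((L - window_len)/stride) + 1`. When the recording carries
#' ground-truth phases, each window is labeled with the phase of its final
#' sample (causal rule; see [label_window()]).
#'
#' @param recording A `gait_recording` with complete angle channels.
#' @param window_len Samples per window (default 20).
#' @param stride Step between window starts (default 1).
#' @param label How to label windows from the recording's phase track:
#'   `"last"` (final-sample phase, causal, the default), `"majority"`, or
#'   `"none"`.
#' @return A `gait_windows` object: `x` (windows x time x channels array),
#'   `label` (factor or NULL), `start` (1-based start index per window),
#'   `cycle_first`/`cycle_last` (cycle span per window, if available), and
#'   `recording_id` (subject/speed tag).
#' @export
segment_windows <- function(recording, window_len = 20L, stride = 1L,
                            label = c("last", "majority", "none")) {
  stopifnot(inherits(recording, "gait_recording"))
  label <- match.arg(label)
  L <- nrow(recording$angles)
  window_len <- as.integer(window_len)
  stride <- as.integer(stride)
  if (L < window_len) {
    stop("recording (", L, " samples) shorter than window_len (", window_len, ")")
  }
  if (anyNA(recording$angles)) {
    stop("angle channels contain NA; run interpolate_recording() first")
  }
  starts <- seq.int(1L, L - window_len + 1L, by = stride)
  nw <- length(starts)
  x <- array(NA_real_, dim = c(nw, window_len, 6L),
             dimnames = list(NULL, NULL, imu_sites()))
  for (i in seq_len(nw)) {
    x[i, , ] <- recording$angles[starts[i]:(starts[i] + window_len - 1L), ]
  }
  lab <- NULL
  if (label != "none" && !is.null(recording$phase)) {
    lab <- as_phase(vapply(starts, function(s) {
      label_window(s, window_len, recording$phase, rule = label)
    }, character(1)))
  }
  structure(list(
    x = x,
    label = lab,
    start = starts,
    cycle_first = if (!is.null(recording$cycle)) recording$cycle[starts] else NULL,
    cycle_last = if (!is.null(recording$cycle)) {
      recording$cycle[starts + window_len - 1L]
    } else NULL,
    recording_id = paste0("S", recording$subject_id, "_v", recording$speed),
    normalized = FALSE
  ), class = "gait_windows")
}

#' @export
print.gait_windows <- function(x, ...) {
  d <- dim(x$x)
  cat("<gait_windows>", d[1], "windows of", d[2], "samples x", d[3],
      "channels", if (isTRUE(x$normalized)) "(normalized)" else "(raw)", "\n")
  if (!is.null(x$label)) print(table(x$label))
  invisible(x)
}

#' Restrict windows to a sensor group's channels
#'
#' Keeps only the group's sites, in the fixed site order. Group 7 is the
#' identity selection.
#'
#' @param windows A `gait_windows` object (or a plain 3-D window array with
#'   channel dimnames).
#' @param group A [sensor_group()] or group id 1..7.
#' @return Windows with `C = length(group$sites)` channels.
#' @export
select_channels <- function(windows, group) {
  if (!inherits(group, "sensor_group")) group <- sensor_group(group)
  pick <- function(arr) {
    have <- dimnames(arr)[[3]]
    missing_sites <- setdiff(group$sites, have)
    if (length(missing_sites)) {
      stop("windows lack required site(s): ",
           paste(missing_sites, collapse = ", "))
    }
    arr[, , group$sites, drop = FALSE]
  }
  if (inherits(windows, "gait_windows")) {
    windows$x <- pick(windows$x)
    windows$group <- group
    return(windows)
  }
  if (is.array(windows) && length(dim(windows)) == 3L) return(pick(windows))
  stop("unsupported input to select_channels")
}

# rbind-style combination of window sets (same window_len and channels)
combine_windows <- function(wlist) {
  wlist <- wlist[!vapply(wlist, is.null, logical(1))]
  stopifnot(length(wlist) > 0)
  xs <- lapply(wlist, `[[`, "x")
  d <- dim(xs[[1]])
  nw <- vapply(xs, function(a) dim(a)[1], integer(1))
  x <- array(NA_real_, dim = c(sum(nw), d[2], d[3]),
             dimnames = list(NULL, NULL, dimnames(xs[[1]])[[3]]))
  at <- 0L
  for (a in xs) {
    x[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  labels <- lapply(wlist, `[[`, "label")
  lab <- if (all(!vapply(labels, is.null, logical(1)))) {
    as_phase(unlist(lapply(labels, as.character)))
  } else NULL
  structure(list(
    x = x, label = lab,
    start = unlist(lapply(wlist, `[[`, "start")),
    cycle_first = unlist(lapply(wlist, `[[`, "cycle_first")),
    cycle_last = unlist(lapply(wlist, `[[`, "cycle_last")),
    recording_id = unlist(lapply(wlist, function(w) {
      rep(w$recording_id[1], length(w$start))
    })),
    normalized = isTRUE(wlist[[1]]$normalized)
  ), class = "gait_windows")
}

subset_windows <- function(windows, idx) {
  structure(list(
    x = windows$x[idx, , , drop = FALSE],
    label = if (!is.null(windows$label)) windows$label[idx] else NULL,
    start = windows$start[idx],
    cycle_first = windows$cycle_first[idx],
    cycle_last = windows$cycle_last[idx],
    recording_id = if (length(windows$recording_id) > 1L) {
      windows$recording_id[idx]
    } else windows$recording_id,
    normalized = windows$normalized,
    group = windows$group
  ), class = "gait_windows")
}
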