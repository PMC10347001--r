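#' Detect foot-ground contact from plantar force
#'
#' A foot is in contact whenever its vertical ground reaction force is at
#' least the threshold (20 N by default). Force exactly at the threshold
#' counts as contact, making the condition closed and deterministic on
#' boundary samples.
#'
#' @param grf Numeric vector of vertical GRF in newtons (must be >= 0).
#' @param threshold Contact threshold in newtons.
#' @return Logical vector, `TRUE` where the foot is in contact.
#' @export
detect_contact <- function(grf, threshold = 20) {
  if (any(grf < 0, na.rm = TRUE)) stop("GRF must be non-negative")
  grf >= threshold
}

#' Derive the four-phase track from bilateral contact
#'
#' A finite-state reading of the contact tracks: a right-contact rising
#' edge (with the left foot loaded) starts `SU-RHS`; a left falling edge
#' starts `SW-L`; a left rising edge (right loaded) starts `SU-LHS`; a
#' right falling edge starts `SW-R`. Samples before the first recognizable
#' event carry the label implied by backward extension (the predecessor of
#' the first event's phase). Samples with both feet off the ground — which
#' steady walking should never produce — keep the previous phase and raise
#' a warning.
#'
#' @param left_contact,right_contact Logical contact tracks of equal length
#'   (from [detect_contact()]).
#' @return Factor of per-sample phase labels.
#' @export
derive_phases <- function(left_contact, right_contact) {
  n <- length(left_contact)
  if (length(right_contact) != n) stop("contact tracks differ in length")
  if (n < 2L) stop("contact tracks too short")
  l <- as.logical(left_contact)
  r <- as.logical(right_contact)

  t2 <- 2:n
  r_rise <- t2[r[t2] & !r[t2 - 1L]]
  r_fall <- t2[!r[t2] & r[t2 - 1L]]
  l_rise <- t2[l[t2] & !l[t2 - 1L]]
  l_fall <- t2[!l[t2] & l[t2 - 1L]]

  if (!length(c(r_rise, r_fall, l_rise, l_fall))) {
    stop("cannot anchor phase machine: no contact changes in the tracks")
  }
  if (any(!l & !r)) {
    warning("both feet off the ground at ", sum(!l & !r),
            " sample(s); holding previous phase (non-walking data?)")
  }
  if (length(r_rise) && any(!l[r_rise])) {
    warning("right heel strike without left support at sample(s) ",
            paste(utils::head(r_rise[!l[r_rise]], 3), collapse = ", "),
            "; treating as SU-RHS onset anyway")
  }
  if (length(l_rise) && any(!r[l_rise])) {
    warning("left heel strike without right support at sample(s) ",
            paste(utils::head(l_rise[!r[l_rise]], 3), collapse = ", "),
            "; treating as SU-LHS onset anyway")
  }

  ev_at <- c(r_rise, l_fall, l_rise, r_fall)
  ev_ph <- rep(c("SU-RHS", "SW-L", "SU-LHS", "SW-R"),
               times = c(length(r_rise), length(l_fall),
                         length(l_rise), length(r_fall)))
  o <- order(ev_at)
  ev_at <- ev_at[o]
  ev_ph <- ev_ph[o]

  phase <- character(n)
  # backward extension before the first event: predecessor of its phase
  ph <- gait_phases()
  first_ph <- ev_ph[1L]
  pred <- ph[(match(first_ph, ph) - 2L) %% 4L + 1L]
  phase[seq_len(ev_at[1L] - 1L)] <- pred
  bounds <- c(ev_at, n + 1L)
  for (k in seq_along(ev_at)) {
    phase[ev_at[k]:(bounds[k + 1L] - 1L)] <- ev_ph[k]
  }
  as_phase(phase)
}

#' Label a recording from its GRF channels
#'
#' Convenience wrapper: thresholds both GRF channels with
#' [detect_contact()] and runs [derive_phases()].
#'
#' @param recording A `gait_recording`.
#' @param threshold Contact threshold in newtons.
#' @return The recording with its `phase` field replaced by the derived
#'   track.
#' @export
label_recording <- function(recording, threshold = 20) {
  stopifnot(inherits(recording, "gait_recording"))
  recording$phase <- derive_phases(
    detect_contact(recording$grf[, "left"], threshold),
    detect_contact(recording$grf[, "right"], threshold)
  )
  recording
}

#' Assign a phase label to one window
#'
#' Default rule: the phase of the window's final sample — a causal rule
#' suited to real-time recognition, where the newest sample defines the
#' current state. A majority rule is available as an alternative.
#'
#' @param start 1-based index of the window's first sample.
#' @param window_len Window length in samples.
#' @param phases Per-sample phase track (factor or character).
#' @param rule `"last"` (default) or `"majority"` (ties broken toward the
#'   later phase in the window).
#' @return A single phase label (character).
#' @export
label_window <- function(start, window_len, phases, rule = c("last", "majority")) {
  rule <- match.arg(rule)
  end <- start + window_len - 1L
  if (start < 1L || end > length(phases)) {
    stop("window [", start, ", ", end, "] outside the phase track")
  }
  win <- as.character(phases[start:end])
  if (rule == "last") return(win[window_len])
  tab <- table(win)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) return(winners)
  # tie: prefer the phase occurring latest in the window (causal bias)
  win[max(which(win %in% winners))]
}
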