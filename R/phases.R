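#' The four-phase gait alphabet
#'
#' A full gait cycle is segmented into four phases that repeat in fixed
#' cyclic order:
#'
#' * `SU-RHS` — double-support phase beginning at right heel strike,
#' * `SW-L`   — left-leg swing (only the right foot is loaded),
#' * `SU-LHS` — double-support phase beginning at left heel strike,
#' * `SW-R`   — right-leg swing (only the left foot is loaded).
#'
#' `gait_phases()` returns the labels in cyclic order; the position in this
#' vector is a phase's cyclic index (1-based).
#'
#' @return Character vector of the four phase labels, in cyclic order.
#' @export
gait_phases <- function() c("SU-RHS", "SW-L", "SU-LHS", "SW-R")

#' The six lower-limb IMU sites, in fixed channel order
#'
#' Joint-angle channels are always stored and selected in this order:
#' left/right thigh, left/right shank, left/right foot.
#'
#' @return Character vector of the six site names.
#' @export
imu_sites <- function() {
  c("L_thigh", "R_thigh", "L_shank", "R_shank", "L_foot", "R_foot")
}

as_phase <- function(x) {
  ph <- gait_phases()
  if (is.factor(x)) x <- as.character(x)
  bad <- !is.na(x) & !(x %in% ph)
  if (any(bad)) {
    stop("unknown gait phase label(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  factor(x, levels = ph)
}

#' Successor phase in the gait cycle
#'
#' Phases always advance along `SU-RHS -> SW-L -> SU-LHS -> SW-R -> SU-RHS`.
#' Applying `next_phase()` four times is the identity.
#'
#' @param phase Character or factor phase label(s).
#' @return The following phase label(s) as character.
#' @export
#' @examples
#' next_phase("SU-RHS") # "SW-L"
#' next_phase("SW-R")   # wraps to "SU-RHS"
next_phase <- function(phase) {
  ph <- gait_phases()
  i <- as.integer(as_phase(phase))
  ph[i %% 4L + 1L]
}

#' One-hot encoding of gait phases
#'
#' Each phase maps to a 4-vector with a single 1 at its cyclic index:
#' `SU-RHS = (1,0,0,0)`, `SW-L = (0,1,0,0)`, `SU-LHS = (0,0,1,0)`,
#' `SW-R = (0,0,0,1)`.
#'
#' @param phase Character or factor vector of phase labels.
#' @return A numeric matrix with one row per input label and 4 columns
#'   named by phase.
#' @export
one_hot <- function(phase) {
  f <- as_phase(phase)
  if (anyNA(f)) stop("cannot one-hot encode NA phases")
  m <- diag(4)[as.integer(f), , drop = FALSE]
  colnames(m) <- gait_phases()
  rownames(m) <- NULL
  m
}

#' Decode phase probabilities by argmax
#'
#' Inverse of [one_hot()] on pure one-hot vectors; on soft (e.g. softmax)
#' outputs picks the most probable phase. Ties are broken deterministically
#' in favor of the lowest cyclic index, with a warning.
#'
#' @param prob Numeric 4-vector, or a matrix with 4 columns (one row per
#'   prediction).
#' @return Character vector of decoded phase labels.
#' @export
decode_phase <- function(prob) {
  if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1)
  if (ncol(prob) != 4L) stop("expected 4 phase probabilities per row")
  idx <- apply(prob, 1L, function(p) {
    w <- which(p == max(p))
    if (length(w) > 1L) warning("argmax tie; choosing lowest cyclic index")
    w[1L]
  })
  gait_phases()[idx]
}
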