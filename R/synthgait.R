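#' Configuration for the synthetic gait generator
#'
#' Defines the study conditions the generator emulates: a cohort walking at
#' three speeds on an instrumented walkway, sampled at 100 Hz, with
#' stance occupying about 60% of each gait cycle and the two double-support
#' sub-phases about 10% each. Joint angles are smooth phase-locked periodic
#' waveforms; plantar ground reaction force (GRF) is a stance-only
#' double-bump profile whose 20 N crossings mark heel strike and toe-off.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param speeds Walking speeds in m/s.
#' @param cycles_per_speed Gait cycles recorded per subject per speed.
#' @param cycle_duration Either a number (seconds) or a function of speed.
#'   The default, `1.8 / speed`, gives plausible cadence scaling (1.5 s at
#'   1.2 m/s down to 1.0 s at 1.8 m/s).
#' @param stance_fraction Fraction of the cycle each foot spends in stance.
#' @param double_support_fraction Fraction of the cycle occupied by each of
#'   the two double-support phases. Must satisfy
#'   `2 * double_support_fraction < stance_fraction < 1`.
#' @param sample_rate Sampling frequency in Hz.
#' @param noise_sd Standard deviation (degrees) of additive Gaussian sensor
#'   noise on the angle channels.
#' @param packet_loss_rate Per-sample probability that an angle sample is
#'   dropped in transmission (encoded as `NA`). Must be `< 1`.
#' @param peak_grf Nominal peak vertical GRF in newtons (scaled per subject
#'   by about +/-10% to mimic body-weight variation).
#' @param phase_cue_gain Amplitude (degrees) of the phase-locked waveform
#'   components that make shank+foot channels especially informative for
#'   `SW-L` and thigh+shank channels for `SU-LHS`, emulating the
#'   sensor-placement specialization seen in real gait data.
#' @param distractor_sd Standard deviation (degrees) of the per-cycle
#'   random-amplitude waveform variability injected on the *complementary*
#'   channels during those same phases (thighs during `SW-L`, feet during
#'   `SU-LHS`). Real thigh motion is variable and weakly phase-locked in
#'   mid-swing, and foot orientation wobbles during weight transfer;
#'   classifiers that consume those channels must average this variability
#'   out, which is why reduced sensor sets can recognize specific phases
#'   better. Set to 0 to disable.
#' @param seed Master seed for subject-level variability.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 20L,
                         speeds = c(1.2, 1.5, 1.8),
                         cycles_per_speed = 10L,
                         cycle_duration = function(speed) 1.8 / speed,
                         stance_fraction = 0.6,
                         double_support_fraction = 0.1,
                         sample_rate = 100,
                         noise_sd = 1.5,
                         packet_loss_rate = 0.01,
                         peak_grf = 700,
                         phase_cue_gain = 6,
                         distractor_sd = 8,
                         seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), speeds = speeds,
    cycles_per_speed = as.integer(cycles_per_speed),
    cycle_duration = cycle_duration,
    stance_fraction = stance_fraction,
    double_support_fraction = double_support_fraction,
    sample_rate = sample_rate, noise_sd = noise_sd,
    packet_loss_rate = packet_loss_rate, peak_grf = peak_grf,
    phase_cue_gain = phase_cue_gain, distractor_sd = distractor_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!(2 * cfg$double_support_fraction < cfg$stance_fraction &&
        cfg$stance_fraction < 1)) {
    stop("invalid configuration: need 2*double_support_fraction < ",
         "stance_fraction < 1")
  }
  if (cfg$sample_rate <= 0) stop("invalid configuration: sample_rate must be > 0")
  if (cfg$packet_loss_rate < 0 || cfg$packet_loss_rate >= 1) {
    stop("invalid configuration: packet_loss_rate must be in [0, 1)")
  }
  if (cfg$n_subjects < 1L || cfg$cycles_per_speed < 1L) {
    stop("invalid configuration: counts must be positive")
  }
  if (cfg$noise_sd < 0) stop("invalid configuration: noise_sd must be >= 0")
  dur <- cycle_duration_for(cfg, cfg$speeds[1])
  if (!is.finite(dur) || dur <= 0) {
    stop("invalid configuration: cycle_duration must be positive")
  }
  invisible(cfg)
}

cycle_duration_for <- function(cfg, speed) {
  if (is.function(cfg$cycle_duration)) cfg$cycle_duration(speed)
  else cfg$cycle_duration
}

# Base truncated-Fourier coefficients (order 3) per site type, in degrees.
# a0 + sum_k a_k cos(2 pi k phi) + b_k sin(2 pi k phi), phi = cycle fraction
# from the ipsilateral heel strike. Values are plausible sagittal-plane
# joint-angle excursions; only their smoothness, periodicity and
# between-phase contrast matter to the method.
.site_fourier <- list(
  thigh = list(a0 = 10, a = c(-12, 4, 1.5), b = c(16, -3, 1)),
  shank = list(a0 = -25, a = c(18, -8, 2), b = c(-22, 6, -2)),
  foot  = list(a0 = -5, a = c(6, -4, 3), b = c(10, 8, -2))
)

# Raised-cosine bump supported on [lo, hi) of the cycle: 0 with zero slope
# at both edges, 1 in the middle.
raised_cosine_cue <- function(phi, lo, hi) {
  inside <- phi >= lo & phi < hi
  out <- numeric(length(phi))
  out[inside] <- 0.5 * (1 - cos(2 * pi * (phi[inside] - lo) / (hi - lo)))
  out
}

# Per-cycle boundary sample indices (0-based within the cycle):
#   [0, b1)  SU-RHS   (right heel strike opens the cycle)
#   [b1, b2) SW-L     (left toe-off at b1)
#   [b2, b3) SU-LHS   (left heel strike at b2)
#   [b3, n)  SW-R     (right toe-off at b3)
cycle_boundaries <- function(n_cycle, stance_fraction, ds_fraction) {
  c(b1 = round(ds_fraction * n_cycle),
    b2 = round((stance_fraction - ds_fraction) * n_cycle),
    b3 = round(stance_fraction * n_cycle))
}

# Double-bump GRF over one contiguous stance run of m samples: exactly
# threshold newtons at both run endpoints, strictly above it inside.
stance_grf_profile <- function(m, peak, threshold = 20) {
  if (m == 1L) return(threshold)
  s <- seq(0, 1, length.out = m)
  bump <- 0.7 * 0.5 * (1 - cos(4 * pi * s)) + 0.3 * sin(pi * s)
  threshold + (peak - threshold) * bump / max(bump)
}

fill_grf <- function(contact, peak, threshold = 20) {
  grf <- numeric(length(contact))
  r <- rle(contact)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k]) {
      grf[starts[k]:ends[k]] <- stance_grf_profile(r$lengths[k], peak, threshold)
    }
  }
  grf
}

# Deterministic per-subject perturbation stream, independent of the
# per-recording noise seed so a subject keeps one body across speeds.
subject_rng <- function(cfg, subject_id) {
  (cfg$seed * 7919L + as.integer(subject_id) * 104729L) %% 2147483011L
}

#' Simulate one synthetic gait recording
#'
#' Generates `cycles_per_speed` full gait cycles for one subject at one
#' speed: six smooth phase-locked joint-angle channels (truncated Fourier
#' series per site, left/right half-cycle offset, per-subject +/-10%
#' coefficient jitter) with additive Gaussian noise and optional packet
#' loss, plus bilateral stance-only GRF whose 20 N crossings coincide
#' exactly with the ground-truth heel-strike/toe-off instants, so that
#' threshold-based labeling reproduces the embedded truth phases.
#'
#' @param config A [synth_config()].
#' @param subject_id Integer subject index (determines subject-level
#'   waveform jitter and peak GRF).
#' @param speed Walking speed in m/s; must be one of `config$speeds`.
#' @param seed Integer seed for the recording-level randomness (sensor
#'   noise and packet loss).
#' @return A `gait_recording`: list with `subject_id`, `speed`, `time`,
#'   `angles` (n x 6 matrix, `NA` marks dropped samples), `grf` (n x 2
#'   matrix, left/right, newtons), `phase` (ground-truth factor) and
#'   `cycle` (integer cycle index per sample).
#' @export
simulate_recording <- function(config, subject_id, speed, seed = config$seed) {
  validate_synth_config(config)
  if (!any(abs(speed - config$speeds) < 1e-12)) {
    stop("speed ", speed, " is not one of config$speeds")
  }
  dur <- cycle_duration_for(config, speed)
  n_cycle <- round(dur * config$sample_rate)
  if (n_cycle < 8L) stop("cycle too short at this sample_rate")
  n <- config$cycles_per_speed * n_cycle
  ds <- config$double_support_fraction
  b <- cycle_boundaries(n_cycle, config$stance_fraction, ds)

  j <- rep(seq_len(n_cycle) - 1L, times = config$cycles_per_speed)
  phi_r <- j / n_cycle                 # right-side cycle fraction
  phi_l <- (phi_r + 0.5) %% 1         # left side is half a cycle ahead

  phase <- character(n)
  phase[j < b["b1"]] <- "SU-RHS"
  phase[j >= b["b1"] & j < b["b2"]] <- "SW-L"
  phase[j >= b["b2"] & j < b["b3"]] <- "SU-LHS"
  phase[j >= b["b3"]] <- "SW-R"

  right_contact <- j < b["b3"]
  left_contact <- j >= b["b2"] | j < b["b1"]

  # subject-level body: coefficient jitter and peak GRF scale
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(subject_rng(config, subject_id))
  jitter <- stats::runif(6 * 7, min = 0.9, max = 1.1)  # 6 sites x 7 coeffs
  grf_scale <- stats::runif(2, min = 0.9, max = 1.1)

  site_type <- c(L_thigh = "thigh", R_thigh = "thigh",
                 L_shank = "shank", R_shank = "shank",
                 L_foot = "foot", R_foot = "foot")
  sites <- imu_sites()
  angles <- matrix(0, n, 6, dimnames = list(NULL, sites))
  cue_swl <- raised_cosine_cue(phi_r, ds, config$stance_fraction - ds)
  cue_sulhs <- raised_cosine_cue(phi_r, config$stance_fraction - ds,
                                 config$stance_fraction)
  for (s in seq_along(sites)) {
    site <- sites[s]
    base <- .site_fourier[[site_type[site]]]
    jit <- jitter[(s - 1) * 7 + 1:7]
    phi <- if (startsWith(site, "L_")) phi_l else phi_r
    w <- base$a0 * jit[1]
    for (k in 1:3) {
      w <- w + base$a[k] * jit[1 + k] * cos(2 * pi * k * phi) +
        base$b[k] * jit[4 + k] * sin(2 * pi * k * phi)
    }
    # phase-locked cues: shanks+feet carry an SW-L signature, thighs+shanks
    # an SU-LHS signature (left and right with opposite sign)
    sgn <- if (startsWith(site, "L_")) -1 else 1
    if (site_type[site] %in% c("shank", "foot")) {
      w <- w + sgn * config$phase_cue_gain * cue_swl
    }
    if (site_type[site] %in% c("thigh", "shank")) {
      w <- w + sgn * config$phase_cue_gain * cue_sulhs
    }
    angles[, site] <- w
  }

  set.seed(seed)
  cyc_idx <- rep(seq_len(config$cycles_per_speed), each = n_cycle)
  if (config$distractor_sd > 0) {
    # Per-cycle random-amplitude variability, one region per site family:
    # thigh motion is weakly phase-locked during left swing, foot
    # orientation wobbles during the left-heel-strike weight transfer, and
    # shank motion is variable through the right-swing interior (the shank
    # region ends early enough that no window labeled SU-RHS contains it).
    sw_r_end <- config$stance_fraction + 0.6 * (1 - config$stance_fraction)
    cue_swr <- raised_cosine_cue(phi_r, config$stance_fraction, sw_r_end)
    regions <- list(L_thigh = cue_swl, R_thigh = cue_swl,
                    L_shank = cue_swr, R_shank = cue_swr,
                    L_foot = cue_sulhs, R_foot = cue_sulhs)
    for (ch in names(regions)) {
      amps <- stats::rnorm(config$cycles_per_speed, sd = config$distractor_sd)
      angles[, ch] <- angles[, ch] + amps[cyc_idx] * regions[[ch]]
    }
  }
  if (config$noise_sd > 0) {
    angles <- angles + matrix(stats::rnorm(n * 6, sd = config$noise_sd), n, 6)
  }

  grf <- cbind(
    left = fill_grf(left_contact, config$peak_grf * grf_scale[1]),
    right = fill_grf(right_contact, config$peak_grf * grf_scale[2])
  )

  rec <- structure(list(
    subject_id = as.integer(subject_id),
    speed = speed,
    time = (seq_len(n) - 1L) / config$sample_rate,
    angles = angles,
    grf = grf,
    phase = as_phase(phase),
    cycle = rep(seq_len(config$cycles_per_speed), each = n_cycle)
  ), class = "gait_recording")

  if (config$packet_loss_rate > 0) {
    loss_seed <- (seed + 499979L) %% 2147483011L
    rec <- inject_packet_loss(rec, config$packet_loss_rate, seed = loss_seed)
  }
  rec
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Mark angle samples as dropped (packet loss)
#'
#' Each angle sample is independently marked missing (`NA`) with the given
#' probability, except the first and last sample of every channel, which
#' are always kept so linear interpolation is bounded on both sides. GRF
#' channels are never masked (they come from the force platform, not the
#' wireless IMU link).
#'
#' @param recording A `gait_recording`.
#' @param rate Per-sample drop probability in `[0, 1)`.
#' @param seed Integer seed for the mask.
#' @return The recording with `NA` holes in its `angles` matrix.
#' @export
inject_packet_loss <- function(recording, rate, seed = 1L) {
  stopifnot(inherits(recording, "gait_recording"))
  if (rate < 0 || rate >= 1) stop("packet loss rate must be in [0, 1)")
  if (rate == 0) return(recording)
  n <- nrow(recording$angles)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  mask <- matrix(stats::runif(n * 6) < rate, n, 6)
  mask[1L, ] <- FALSE
  mask[n, ] <- FALSE
  recording$angles[mask] <- NA_real_
  recording
}

#' Simulate a full synthetic cohort
#'
#' One recording per subject per speed, with recording-level seeds derived
#' deterministically from the configuration's master seed.
#'
#' @param config A [synth_config()].
#' @return A list of `gait_recording` objects.
#' @export
simulate_cohort <- function(config) {
  validate_synth_config(config)
  recs <- list()
  for (subj in seq_len(config$n_subjects)) {
    for (si in seq_along(config$speeds)) {
      seed <- (config$seed * 1009L + subj * 131L + si * 17L) %% 2147483011L
      recs[[length(recs) + 1L]] <-
        simulate_recording(config, subj, config$speeds[si], seed = seed)
    }
  }
  recs
}

#' @export
print.gait_recording <- function(x, ...) {
  n <- length(x$time)
  cat("<gait_recording> subject", x$subject_id, "at", x$speed, "m/s:",
      n, "samples,", length(unique(x$cycle)), "cycles,",
      sum(is.na(x$angles)), "dropped angle samples\n")
  invisible(x)
}

#' Write a gait recording to CSV
#'
#' Columns: `time`, the six angle channels, `grf_left`, `grf_right`, and,
#' when present, `phase` and `cycle`. Dropped samples are written as empty
#' fields. Subject id and speed are kept in a `#`-prefixed header line.
#'
#' @param recording A `gait_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "gait_recording"))
  df <- data.frame(time = recording$time, recording$angles,
                   grf_left = recording$grf[, "left"],
                   grf_right = recording$grf[, "right"],
                   check.names = FALSE)
  if (!is.null(recording$phase)) df$phase <- as.character(recording$phase)
  if (!is.null(recording$cycle)) df$cycle <- recording$cycle
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# subject_id=%d speed=%g", recording$subject_id,
                     recording$speed), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a gait recording from CSV
#'
#' @param path CSV file written by [write_recording()] (or any CSV with the
#'   same columns; the `#` metadata line is optional).
#' @return A `gait_recording`.
#' @export
read_recording <- function(path) {
  first <- readLines(path, n = 1L)
  subject_id <- NA_integer_
  speed <- NA_real_
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("subject_id=(\\d+) speed=([0-9.]+)", first))[[1]]
    if (length(m) == 3L) {
      subject_id <- as.integer(m[2])
      speed <- as.numeric(m[3])
    }
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  sites <- imu_sites()
  missing_cols <- setdiff(c("time", sites, "grf_left", "grf_right"), names(df))
  if (length(missing_cols)) {
    stop("recording CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  rec <- structure(list(
    subject_id = subject_id, speed = speed,
    time = df$time,
    angles = as.matrix(df[, sites]),
    grf = cbind(left = df$grf_left, right = df$grf_right),
    phase = if ("phase" %in% names(df)) as_phase(df$phase) else NULL,
    cycle = if ("cycle" %in% names(df)) as.integer(df$cycle) else NULL
  ), class = "gait_recording")
  rec
}
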