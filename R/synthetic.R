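# Synthetic gait generator: parametric stride waveforms, straight walks,
# TUG-like sequences and multi-subject cohorts with ground-truth labels.

#' Stride waveform parameters
#'
#' The stride is modeled as a sum of smooth Gaussian bump/trough kernels over
#' normalized stride phase u in \[0, 1): the sagittal gyroscope channel `GZ`
#' carries one dominant positive mid-swing peak and negative troughs at both
#' stride borders (the events a human labeler uses to delimit strides), while
#' the accelerometer channels are smooth quasi-periodic waveforms. `AZ`, `GX`
#' and `GY` are kept near-constant, mirroring real foot-worn data where those
#' axes convey little stride information.
#'
#' @param duration_ms nominal stride duration in ms, within \[600, 2500\].
#' @param midswing_gz_peak_dps amplitude of the positive mid-swing `GZ` peak in
#'   degrees/s; well above the 150 deg/s detection threshold for clean presets.
#' @param border_trough_gz_dps (negative) `GZ` amplitude at the stride borders.
#' @param accel_amp_g named amplitudes (g) for `AX`, `AY`, `AZ`.
#' @param gyro_aux_amp_dps named amplitudes (deg/s) for `GX`, `GY`.
#' @param shape_jitter_sd relative s.d. of per-stride amplitude jitter.
#' @param duration_jitter_sd relative s.d. of per-stride duration jitter.
#' @param noise_sd_gyro_dps additive white-noise s.d. on gyro channels (deg/s).
#' @param noise_sd_accel_g additive white-noise s.d. on accel channels (g).
#' @return an object of class `stride_shape_params`.
#' @export
stride_shape_params <- function(duration_ms = 1100,
                                midswing_gz_peak_dps = 350,
                                border_trough_gz_dps = -120,
                                accel_amp_g = c(AX = 0.8, AY = 0.5, AZ = 0.05),
                                gyro_aux_amp_dps = c(GX = 8, GY = 8),
                                shape_jitter_sd = 0,
                                duration_jitter_sd = 0,
                                noise_sd_gyro_dps = 0,
                                noise_sd_accel_g = 0) {
  if (duration_ms < 600 || duration_ms > 2500)
    stop("`duration_ms` must lie in [600, 2500]", call. = FALSE)
  if (midswing_gz_peak_dps <= 0)
    stop("`midswing_gz_peak_dps` must be positive", call. = FALSE)
  if (border_trough_gz_dps >= 0)
    stop("`border_trough_gz_dps` must be negative", call. = FALSE)
  if (shape_jitter_sd < 0 || duration_jitter_sd < 0 ||
      noise_sd_gyro_dps < 0 || noise_sd_accel_g < 0)
    stop("jitter and noise standard deviations must be >= 0", call. = FALSE)
  structure(list(duration_ms = duration_ms,
                 midswing_gz_peak_dps = midswing_gz_peak_dps,
                 border_trough_gz_dps = border_trough_gz_dps,
                 accel_amp_g = accel_amp_g,
                 gyro_aux_amp_dps = gyro_aux_amp_dps,
                 shape_jitter_sd = shape_jitter_sd,
                 duration_jitter_sd = duration_jitter_sd,
                 noise_sd_gyro_dps = noise_sd_gyro_dps,
                 noise_sd_accel_g = noise_sd_accel_g),
            class = "stride_shape_params")
}

# Scale a parameter set by subject/stride multipliers without re-validating
# bounds (clamping keeps durations legal).
scale_params <- function(params, duration_mult = 1, amp_mult = 1) {
  p <- params
  p$duration_ms <- min(2500, max(600, params$duration_ms * duration_mult))
  p$midswing_gz_peak_dps <- params$midswing_gz_peak_dps * amp_mult
  p$border_trough_gz_dps <- params$border_trough_gz_dps * amp_mult
  p$accel_amp_g <- params$accel_amp_g * amp_mult
  p$gyro_aux_amp_dps <- params$gyro_aux_amp_dps * amp_mult
  p
}

gauss_bump <- function(u, center, width) exp(-((u - center) / width)^2 / 2)

#' Generate one synthetic stride segment
#'
#' Draws per-stride duration and amplitude jitter and additive noise from the
#' current RNG state; with all jitter/noise standard deviations zero the
#' output is fully deterministic. `GZ` has exactly one dominant positive
#' mid-swing peak (max within 1% of `midswing_gz_peak_dps` in the noiseless
#' case) and negative values at both borders.
#'
#' @param params a [stride_shape_params()] object.
#' @param sample_rate_hz sampling rate in Hz.
#' @return numeric matrix (samples x 6 channels), in physical units.
#' @export
make_stride <- function(params, sample_rate_hz = 102.4) {
  stopifnot(inherits(params, "stride_shape_params"))
  dur <- params$duration_ms
  if (params$duration_jitter_sd > 0)
    dur <- dur * (1 + rnorm(1, 0, params$duration_jitter_sd))
  dur <- min(2500, max(600, dur))
  n <- ms_to_samples(dur, sample_rate_hz)
  if (n < 2L) stop("stride duration must span at least 2 samples",
                   call. = FALSE)
  amp <- function(a) {
    if (params$shape_jitter_sd > 0) a * (1 + rnorm(1, 0, params$shape_jitter_sd))
    else a
  }
  u <- (seq_len(n) - 1) / n
  gz <- amp(params$midswing_gz_peak_dps) * gauss_bump(u, 0.55, 0.09) +
    amp(params$border_trough_gz_dps) *
      (gauss_bump(u, 0, 0.06) + gauss_bump(u, 1, 0.06))
  aa <- params$accel_amp_g
  ax <- amp(aa[["AX"]]) * (0.6 * sin(2 * pi * u - pi / 2) +
                             0.4 * sin(4 * pi * u + 0.5))
  ay <- amp(aa[["AY"]]) * (0.7 * sin(2 * pi * u + 0.4) +
                             0.3 * sin(4 * pi * u + 1.2))
  az <- amp(aa[["AZ"]]) * sin(2 * pi * u)
  ga <- params$gyro_aux_amp_dps
  gx <- amp(ga[["GX"]]) * sin(2 * pi * u + 0.8)
  gy <- amp(ga[["GY"]]) * sin(2 * pi * u + 2.0)
  m <- cbind(AX = ax, AY = ay, AZ = az, GX = gx, GY = gy, GZ = gz)
  add_noise(m, params)
}

add_noise <- function(m, params) {
  n <- nrow(m)
  if (params$noise_sd_accel_g > 0)
    m[, ACCEL_CHANNELS] <- m[, ACCEL_CHANNELS] +
      matrix(rnorm(3 * n, 0, params$noise_sd_accel_g), n, 3)
  if (params$noise_sd_gyro_dps > 0)
    m[, GYRO_CHANNELS] <- m[, GYRO_CHANNELS] +
      matrix(rnorm(3 * n, 0, params$noise_sd_gyro_dps), n, 3)
  m
}

rest_block <- function(n, params) {
  m <- matrix(0, n, 6, dimnames = list(NULL, IMU_CHANNELS))
  add_noise(m, params)
}

# Sit<->stand transition: low-frequency, high-amplitude accelerometer
# excursion with no GZ mid-swing signature (|GZ| stays below the 150 deg/s
# peak-detection threshold).
transition_block <- function(n, params, amp_mult = 1) {
  u <- (seq_len(n) - 1) / n
  m <- cbind(AX = 0.5 * amp_mult * sin(pi * u),
             AY = 0.3 * amp_mult * sin(2 * pi * u + 0.7),
             AZ = 0.2 * amp_mult * sin(pi * u + 0.3),
             GX = 25 * amp_mult * sin(2 * pi * u),
             GY = 20 * amp_mult * sin(pi * u + 1.1),
             GZ = 60 * amp_mult * sin(2 * pi * u + 0.2))
  add_noise(m, params)
}

#' Generate a homogeneous straight walk with ground-truth labels
#'
#' Emulates a supervised straight-walk gait test: `n_strides` consecutive
#' strides, each pair sharing a border sample, optionally framed by quiet
#' standing (labeled `rest`) at both ends.
#'
#' @param n_strides number of strides (>= 1).
#' @param params a [stride_shape_params()] object.
#' @param sample_rate_hz sampling rate in Hz.
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @param rest_padding_ms duration of quiet standing prepended and appended
#'   (0 for none).
#' @param duration_mult,amp_mult subject-level multipliers applied to all
#'   strides.
#' @param subject_id,foot recording metadata.
#' @return list with elements `rec` (an [imu_recording()]) and `labels`
#'   (a [segment_labels()]).
#' @export
generate_straight_walk <- function(n_strides, params = stride_shape_params(),
                                   sample_rate_hz = 102.4, seed = NULL,
                                   rest_padding_ms = 0, duration_mult = 1,
                                   amp_mult = 1, subject_id = "S1",
                                   foot = "left") {
  if (n_strides < 1L) stop("`n_strides` must be >= 1", call. = FALSE)
  with_seed(seed, {
    p <- scale_params(params, duration_mult, amp_mult)
    pad <- ms_to_samples(rest_padding_ms, sample_rate_hz)
    blocks <- list()
    starts <- integer(); ends <- integer(); classes <- character()
    pos <- 0L
    if (pad > 0L) {
      blocks[[length(blocks) + 1L]] <- rest_block(pad, p)
      starts <- c(starts, pos); ends <- c(ends, pos + pad)
      classes <- c(classes, "rest"); pos <- pos + pad
    }
    for (k in seq_len(n_strides)) {
      s <- make_stride(p, sample_rate_hz)
      blocks[[length(blocks) + 1L]] <- s
      starts <- c(starts, pos); ends <- c(ends, pos + nrow(s))
      classes <- c(classes, "stride"); pos <- pos + nrow(s)
    }
    if (pad > 0L) {
      blocks[[length(blocks) + 1L]] <- rest_block(pad, p)
      starts <- c(starts, pos); ends <- c(ends, pos + pad)
      classes <- c(classes, "rest"); pos <- pos + pad
    }
    rec <- imu_recording(do.call(rbind, blocks), sample_rate_hz,
                         subject_id = subject_id, foot = foot)
    labels <- segment_labels(starts, ends, classes, sample_rate_hz)
    list(rec = rec, labels = labels)
  })
}

#' Recipe for a TUG-like heterogeneous sequence
#'
#' Describes a Timed Up-and-Go style sequence as an ordered list of blocks:
#' by default rest, sit-to-stand transition, straight strides, turning
#' strides, straight strides, stand-to-sit transition, rest. Turning strides
#' are stretched/attenuated straight strides with an added frontal-plane
#' (`GX`) excursion.
#'
#' @param blocks list of blocks; each block is a list with `type` (one of
#'   `"rest"`, `"transition"`, `"straight"`, `"turn"`) and either
#'   `duration_ms` (rest/transition) or `n` strides (straight/turn).
#' @param params base [stride_shape_params()].
#' @param turn_duration_mult,turn_amp_mult multipliers mapping straight-stride
#'   parameters to turning-stride parameters.
#' @param sample_rate_hz sampling rate in Hz.
#' @param seed optional integer seed (stored; used by [generate_tug()]).
#' @return an object of class `sequence_recipe`.
#' @export
tug_recipe <- function(blocks = list(list(type = "rest", duration_ms = 2000),
                                     list(type = "transition", duration_ms = 1500),
                                     list(type = "straight", n = 4),
                                     list(type = "turn", n = 3),
                                     list(type = "straight", n = 4),
                                     list(type = "transition", duration_ms = 1500),
                                     list(type = "rest", duration_ms = 2000)),
                       params = stride_shape_params(),
                       turn_duration_mult = 1.3, turn_amp_mult = 0.75,
                       sample_rate_hz = 102.4, seed = NULL) {
  if (length(blocks) == 0L) stop("recipe must contain at least one block",
                                 call. = FALSE)
  types <- vapply(blocks, function(b) b$type, character(1))
  if (!all(types %in% c("rest", "transition", "straight", "turn")))
    stop("unknown block type in recipe", call. = FALSE)
  if (!any(types %in% c("straight", "turn")))
    stop("recipe must contain at least one stride block", call. = FALSE)
  structure(list(blocks = blocks, params = params,
                 turn_duration_mult = turn_duration_mult,
                 turn_amp_mult = turn_amp_mult,
                 sample_rate_hz = sample_rate_hz, seed = seed),
            class = "sequence_recipe")
}

#' Generate a TUG-like sequence with ground-truth labels
#'
#' @param recipe a [tug_recipe()].
#' @param duration_mult,amp_mult subject-level multipliers.
#' @param subject_id,foot recording metadata.
#' @return list with elements `rec` and `labels` as in
#'   [generate_straight_walk()].
#' @export
generate_tug <- function(recipe = tug_recipe(), duration_mult = 1,
                         amp_mult = 1, subject_id = "S1", foot = "left") {
  stopifnot(inherits(recipe, "sequence_recipe"))
  rate <- recipe$sample_rate_hz
  with_seed(recipe$seed, {
    p <- scale_params(recipe$params, duration_mult, amp_mult)
    p_turn <- scale_params(p, recipe$turn_duration_mult, 1)
    p_turn$midswing_gz_peak_dps <- p$midswing_gz_peak_dps * recipe$turn_amp_mult
    p_turn$border_trough_gz_dps <- p$border_trough_gz_dps * recipe$turn_amp_mult
    p_turn$gyro_aux_amp_dps <- p$gyro_aux_amp_dps * recipe$turn_amp_mult
    blocks <- list(); starts <- integer(); ends <- integer()
    classes <- character(); pos <- 0L
    for (b in recipe$blocks) {
      if (b$type %in% c("rest", "transition")) {
        n <- ms_to_samples(b$duration_ms, rate)
        if (n == 0L) next
        m <- if (b$type == "rest") rest_block(n, p)
             else transition_block(n, p, amp_mult)
        blocks[[length(blocks) + 1L]] <- m
        starts <- c(starts, pos); ends <- c(ends, pos + n)
        classes <- c(classes, b$type); pos <- pos + n
      } else {
        pp <- if (b$type == "turn") p_turn else p
        for (k in seq_len(b$n)) {
          s <- make_stride(pp, rate)
          if (b$type == "turn") {
            u <- (seq_len(nrow(s)) - 1) / nrow(s)
            s[, "GX"] <- s[, "GX"] + 40 * amp_mult * sin(pi * u)
          }
          blocks[[length(blocks) + 1L]] <- s
          starts <- c(starts, pos); ends <- c(ends, pos + nrow(s))
          classes <- c(classes, "stride"); pos <- pos + nrow(s)
        }
      }
    }
    rec <- imu_recording(do.call(rbind, blocks), rate,
                         subject_id = subject_id, foot = foot)
    labels <- segment_labels(starts, ends, classes, rate)
    list(rec = rec, labels = labels, block_types = classes)
  })
}

#' Generate a multi-subject cohort with both feet per subject
#'
#' Subject-level random effects (log-normal duration and amplitude
#' multipliers) are drawn once per subject, before any stride-level
#' randomness, so the cohort structure is stable when only noise settings
#' change. Defaults encode the study conditions used throughout the package:
#' 22 strides per straight-walk recording, 5% stride-duration jitter, 2%
#' amplitude jitter, additive noise of 5 deg/s (gyro) and 0.02 g (accel),
#' 500 ms of quiet standing at both ends, 7%/5% inter-subject
#' duration/amplitude variability.
#'
#' @param n_subjects number of subjects (>= 2; cross-validation needs at
#'   least two).
#' @param preset `"straight"` for homogeneous straight walks or `"tug"` for
#'   heterogeneous TUG-like sequences.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param n_strides strides per straight-walk recording.
#' @param params stride parameters (see Details for the defaults).
#' @param recipe optional [tug_recipe()] overriding the default TUG blocks.
#' @param rest_padding_ms quiet-standing padding for straight walks.
#' @param inter_subject_duration_sd,inter_subject_amp_sd s.d. of the
#'   log-normal subject random effects.
#' @param sample_rate_hz sampling rate in Hz.
#' @return list of cohort entries, each a list with `rec`, `labels`,
#'   `subject_id`, `foot`.
#' @export
generate_cohort <- function(n_subjects, preset = c("straight", "tug"),
                            seed = NULL, n_strides = 22,
                            params = stride_shape_params(
                              duration_jitter_sd = 0.05,
                              shape_jitter_sd = 0.02,
                              noise_sd_gyro_dps = 5,
                              noise_sd_accel_g = 0.02),
                            recipe = NULL, rest_padding_ms = 500,
                            inter_subject_duration_sd = 0.07,
                            inter_subject_amp_sd = 0.05,
                            sample_rate_hz = 102.4) {
  preset <- match.arg(preset)
  if (n_subjects < 2L)
    stop("`n_subjects` must be >= 2 (cross-validation needs >= 2 subjects)",
         call. = FALSE)
  with_seed(seed, {
    dur_mult <- exp(rnorm(n_subjects, 0, inter_subject_duration_sd))
    amp_mult <- exp(rnorm(n_subjects, 0, inter_subject_amp_sd))
    cohort <- list()
    for (s in seq_len(n_subjects)) {
      sid <- sprintf("S%02d", s)
      for (foot in c("left", "right")) {
        if (preset == "straight") {
          g <- generate_straight_walk(n_strides, params, sample_rate_hz,
                                      seed = NULL,
                                      rest_padding_ms = rest_padding_ms,
                                      duration_mult = dur_mult[s],
                                      amp_mult = amp_mult[s],
                                      subject_id = sid, foot = foot)
        } else {
          rc <- if (is.null(recipe))
            tug_recipe(params = params, sample_rate_hz = sample_rate_hz)
          else recipe
          rc$seed <- NULL  # inherit the cohort RNG stream
          g <- generate_tug(rc, duration_mult = dur_mult[s],
                            amp_mult = amp_mult[s], subject_id = sid,
                            foot = foot)
        }
        cohort[[length(cohort) + 1L]] <-
          list(rec = g$rec, labels = g$labels, subject_id = sid, foot = foot)
      }
    }
    cohort
  })
}
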