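# Event-based segmenter: amplitude-thresholded mid-swing peak detection on GZ
# with a refractory period.

#' Peak detection configuration
#'
#' @param amp_threshold_dps minimum `GZ` amplitude (deg/s) for a peak;
#'   default 150.
#' @param min_separation_ms refractory period: the time to the previous and
#'   following accepted peak must exceed this; default 600 ms, the lower bound
#'   of a stride duration.
#' @return an object of class `peak_config`.
#' @export
peak_config <- function(amp_threshold_dps = 150, min_separation_ms = 600) {
  if (amp_threshold_dps <= 0 || min_separation_ms <= 0)
    stop("threshold and separation must be positive", call. = FALSE)
  structure(list(amp_threshold_dps = amp_threshold_dps,
                 min_separation_ms = min_separation_ms,
                 channel = "GZ"),
            class = "peak_config")
}

# 0-based indices of strict local maxima of x; a plateau counts once, at its
# first sample. Signal edges are never local maxima.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  r <- rle(x)
  k <- length(r$lengths)
  if (k < 3L) return(integer())
  first_idx <- cumsum(c(1L, r$lengths[-k]))  # 1-based first index of each run
  keep <- logical(k)
  for (i in 2:(k - 1L))
    keep[i] <- r$values[i] > r$values[i - 1L] && r$values[i] > r$values[i + 1L]
  first_idx[keep] - 1L
}

# 0-based indices of strict local minima (plateau -> first sample).
local_minima <- function(x) local_maxima(-x)

#' Detect mid-swing peaks in the sagittal gyroscope signal
#'
#' A sample is a candidate peak if it is a strict local maximum of `GZ`
#' (plateaus count once, at their first sample) and its amplitude exceeds the
#' threshold. Refractory conflicts are resolved greedily in descending
#' amplitude order: a candidate is accepted only if every already-accepted
#' peak is farther away than the refractory period, so where several
#' candidates compete only the highest amplitude survives.
#'
#' @param rec an [imu_recording()] in physical units (not normalized).
#' @param cfg a [peak_config()].
#' @return a [stride_detection()] with `peaks` set (0-based sample indices,
#'   ascending).
#' @export
detect_peaks <- function(rec, cfg = peak_config()) {
  stopifnot(inherits(rec, "imu_recording"), inherits(cfg, "peak_config"))
  if (isTRUE(rec$meta$normalized))
    stop("peak detection requires physical units; got a normalized recording",
         call. = FALSE)
  gz <- rec$data[, "GZ"]
  cand <- local_maxima(gz)
  cand <- cand[gz[cand + 1L] > cfg$amp_threshold_dps]
  min_sep <- ms_to_samples(cfg$min_separation_ms, rec$sample_rate_hz)
  if (length(cand) > 1L) {
    o <- order(-gz[cand + 1L], cand)  # amplitude desc, ties to earlier sample
    cand <- cand[o]
    accepted <- integer()
    for (p in cand) {
      if (!length(accepted) || all(abs(accepted - p) > min_sep))
        accepted <- c(accepted, p)
    }
    cand <- accepted
  }
  stride_detection("peak", peaks = sort(cand),
                   sample_rate_hz = rec$sample_rate_hz)
}

#' Convert detected peaks to stride intervals
#'
#' Convenience conversion for downstream parameter extraction (never used for
#' scoring, which evaluates peaks directly): each border is placed at the
#' nearest negative `GZ` local minimum on that side of the peak, searching no
#' farther than the maximum stride duration, and clipped to the signal.
#'
#' @param det a peak-mode [stride_detection()].
#' @param rec the [imu_recording()] the peaks were detected in.
#' @param bounds_ms stride duration bounds in ms used to limit the search.
#' @return a [stride_detection()] with `intervals` set.
#' @export
peaks_to_intervals <- function(det, rec, bounds_ms = c(600, 2500)) {
  stopifnot(inherits(det, "stride_detection"), !is.null(det$peaks) ||
              length(det$peaks) == 0L)
  gz <- rec$data[, "GZ"]
  T_ <- length(gz)
  if (!length(det$peaks))
    return(stride_detection(det$method,
                            intervals = data.frame(start = integer(),
                                                   end = integer()),
                            sample_rate_hz = rec$sample_rate_hz))
  max_half <- ms_to_samples(bounds_ms[2], rec$sample_rate_hz)
  mins <- local_minima(gz)
  mins <- mins[gz[mins + 1L] < 0]
  starts <- integer(); ends <- integer()
  for (p in det$peaks) {
    left <- mins[mins < p & p - mins <= max_half]
    right <- mins[mins > p & mins - p <= max_half]
    s <- if (length(left)) max(left) else max(0L, p - max_half)
    e <- if (length(right)) min(right) else min(T_, p + max_half)
    starts <- c(starts, s); ends <- c(ends, e)
  }
  stride_detection(det$method,
                   intervals = data.frame(start = starts, end = ends),
                   sample_rate_hz = rec$sample_rate_hz)
}
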