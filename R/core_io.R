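# Shared data model: recordings, segment labels, detections, unit conversion.

#' Construct an IMU recording
#'
#' A recording holds a fixed-rate 6-channel signal: tri-axial accelerometer
#' (`AX`, `AY`, `AZ`, in g) and tri-axial gyroscope (`GX`, `GY`, `GZ`, in
#' degrees/s). `GZ` is the sagittal-plane angular velocity of the foot, the
#' primary segmentation signal: its dominant positive peak marks mid-swing and
#' its negative troughs mark stride borders.
#'
#' @param data numeric matrix or data frame with the six channels as columns.
#'   Unnamed columns are taken in the order `AX, AY, AZ, GX, GY, GZ`.
#' @param sample_rate_hz sampling rate in Hz (typical foot-worn IMU: 102.4).
#' @param accel_range_g accelerometer full-scale range in g (default 6).
#' @param gyro_range_dps gyroscope full-scale range in degrees/s (default 500).
#' @param subject_id subject identifier.
#' @param foot `"left"` or `"right"`.
#' @param meta free-form named list of metadata.
#' @return an object of class `imu_recording`.
#' @export
imu_recording <- function(data, sample_rate_hz, accel_range_g = 6,
                          gyro_range_dps = 500, subject_id = "",
                          foot = c("left", "right"), meta = list()) {
  foot <- match.arg(foot)
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix or data frame", call. = FALSE)
  if (ncol(data) != 6L)
    stop("recording must have exactly 6 channels, got ", ncol(data),
         call. = FALSE)
  if (is.null(colnames(data))) {
    colnames(data) <- IMU_CHANNELS
  } else {
    if (!all(IMU_CHANNELS %in% colnames(data)))
      stop("channel columns must be named ",
           paste(IMU_CHANNELS, collapse = ", "), call. = FALSE)
    data <- data[, IMU_CHANNELS, drop = FALSE]
  }
  if (nrow(data) < 1L) stop("recording must contain at least one sample",
                            call. = FALSE)
  if (!all(is.finite(data))) stop("all samples must be finite", call. = FALSE)
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz <= 0)
    stop("`sample_rate_hz` must be a positive number", call. = FALSE)
  if (accel_range_g <= 0 || gyro_range_dps <= 0)
    stop("sensor ranges must be positive", call. = FALSE)
  structure(list(data = data, sample_rate_hz = sample_rate_hz,
                 accel_range_g = accel_range_g,
                 gyro_range_dps = gyro_range_dps,
                 subject_id = as.character(subject_id), foot = foot,
                 meta = meta),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d samples @ %.1f Hz (%.1f s), subject '%s' (%s foot)\n",
              nrow(x$data), x$sample_rate_hz, nrow(x$data) / x$sample_rate_hz,
              x$subject_id, x$foot))
  cat(sprintf("  ranges: +/-%g g accel, +/-%g deg/s gyro%s\n", x$accel_range_g,
              x$gyro_range_dps,
              if (isTRUE(x$meta$normalized)) " [normalized]" else ""))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an `imu_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) nrow(rec$data)

#' Read an IMU recording from a delimited text file
#'
#' Expects comma-separated text with one header line naming the six channels
#' (`AX,AY,AZ,GX,GY,GZ`); headerless files with six numeric columns in that
#' order are also accepted.
#'
#' @inheritParams imu_recording
#' @param path file path.
#' @param ... passed to [imu_recording()].
#' @return an `imu_recording` with one sample per file row.
#' @export
read_imu <- function(path, sample_rate_hz, accel_range_g = 6,
                     gyro_range_dps = 500, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    stop("empty input file: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (nrow(dt) == 0L) stop("empty input file: ", path, call. = FALSE)
  if (ncol(dt) != 6L)
    stop("format error: expected 6 columns, found ", ncol(dt), call. = FALSE)
  if (!all(vapply(dt, is.numeric, logical(1))))
    stop("format error: non-numeric channel column in ", path, call. = FALSE)
  if (!all(IMU_CHANNELS %in% names(dt))) names(dt) <- IMU_CHANNELS
  imu_recording(dt, sample_rate_hz, accel_range_g, gyro_range_dps, ...)
}

#' Write an IMU recording to CSV
#'
#' Numeric values are written with round-trip precision so that
#' `read_imu(write_imu(rec))` reproduces the samples exactly.
#'
#' @param rec an `imu_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_imu <- function(rec, path) {
  # 17 significant digits guarantee a bit-exact double round trip
  df <- as.data.frame(rec$data)
  df[] <- lapply(df, function(x) formatC(x, format = "g", digits = 17))
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' Normalize a recording to the sensor range
#'
#' Divides the accelerometer channels by the accelerometer full-scale range and
#' the gyroscope channels by the gyroscope range, then clips to \[-1, 1\]. Used
#' to put recordings on the same scale as DTW stride templates. The operation
#' is recorded in `meta$normalized`; a second application is an error so the
#' signal can never be scaled twice.
#'
#' @param rec an `imu_recording` in physical units.
#' @return the normalized `imu_recording`.
#' @export
normalize_to_sensor_range <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"))
  if (isTRUE(rec$meta$normalized))
    stop("recording is already normalized to sensor range", call. = FALSE)
  if (rec$accel_range_g <= 0 || rec$gyro_range_dps <= 0)
    stop("sensor ranges must be positive", call. = FALSE)
  d <- rec$data
  d[, ACCEL_CHANNELS] <- d[, ACCEL_CHANNELS] / rec$accel_range_g
  d[, GYRO_CHANNELS] <- d[, GYRO_CHANNELS] / rec$gyro_range_dps
  d[d > 1] <- 1
  d[d < -1] <- -1
  rec$data <- d
  rec$meta$normalized <- TRUE
  rec$meta$normalized_ranges <- c(accel_g = rec$accel_range_g,
                                  gyro_dps = rec$gyro_range_dps)
  rec
}

#' Convert a duration in milliseconds to samples
#'
#' The single conversion point used by every module, so thresholds given in
#' milliseconds map to the same sample counts everywhere. Rounds half away
#' from zero.
#'
#' @param ms duration(s) in milliseconds, non-negative.
#' @param sample_rate_hz sampling rate in Hz.
#' @return integer sample count(s).
#' @export
ms_to_samples <- function(ms, sample_rate_hz) {
  if (any(!is.finite(ms)) || any(ms < 0))
    stop("`ms` must be non-negative and finite", call. = FALSE)
  if (sample_rate_hz <= 0) stop("`sample_rate_hz` must be positive",
                                call. = FALSE)
  as.integer(floor(ms * sample_rate_hz / 1000 + 0.5))
}

SEGMENT_CLASSES <- c("stride", "transition", "rest")

#' Construct a set of segment labels
#'
#' Ordered labeled intervals over a recording, in 0-based half-open sample
#' coordinates `[start, end)`. Consecutive strides may share a border sample
#' (the end of one stride coincides with the start of the next), which the
#' half-open convention represents without overlap. Stride segments must not
#' overlap any other segment; segments of the same class must not overlap.
#'
#' @param start,end integer vectors of 0-based segment borders, `start < end`.
#' @param class character vector of classes among `"stride"`, `"transition"`,
#'   `"rest"`.
#' @param sample_rate_hz reference sampling rate in Hz.
#' @return an object of class `segment_labels` (a data frame with columns
#'   `start`, `end`, `class` and attribute `sample_rate_hz`).
#' @export
segment_labels <- function(start, end, class, sample_rate_hz) {
  start <- as.integer(start); end <- as.integer(end)
  class <- as.character(class)
  if (length(start) != length(end) || length(start) != length(class))
    stop("`start`, `end` and `class` must have equal length", call. = FALSE)
  if (length(start) && (any(start < 0) || any(start >= end)))
    stop("segments need 0 <= start < end", call. = FALSE)
  if (!all(class %in% SEGMENT_CLASSES))
    stop("segment classes must be among: ",
         paste(SEGMENT_CLASSES, collapse = ", "), call. = FALSE)
  o <- order(start, end)
  df <- data.frame(start = start[o], end = end[o], class = class[o],
                   stringsAsFactors = FALSE)
  n <- nrow(df)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (df$start[j] >= df$end[i]) break
        same <- df$class[i] == df$class[j]
        stride_vs_other <- xor(df$class[i] == "stride",
                               df$class[j] == "stride")
        if (same || stride_vs_other)
          stop(sprintf("overlapping segments: [%d,%d) %s and [%d,%d) %s",
                       df$start[i], df$end[i], df$class[i],
                       df$start[j], df$end[j], df$class[j]), call. = FALSE)
      }
    }
  }
  structure(df, sample_rate_hz = sample_rate_hz,
            class = c("segment_labels", "data.frame"))
}

#' @export
print.segment_labels <- function(x, ...) {
  tab <- table(factor(x$class, levels = SEGMENT_CLASSES))
  cat(sprintf("<segment_labels> %d segments (%s) @ %.1f Hz\n", nrow(x),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              attr(x, "sample_rate_hz")))
  invisible(x)
}

#' Extract stride intervals from a label set
#' @param labels a `segment_labels` object.
#' @return data frame with columns `start`, `end` (stride segments only).
#' @export
stride_intervals <- function(labels) {
  s <- labels[labels$class == "stride", c("start", "end")]
  rownames(s) <- NULL
  as.data.frame(s)
}

#' Read segment labels from JSON
#' @param path file path written by [write_labels()].
#' @return a `segment_labels` object.
#' @export
read_labels <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$segments) || is.null(x$sample_rate_hz))
    stop("format error: label file needs `sample_rate_hz` and `segments`",
         call. = FALSE)
  seg <- as.data.frame(x$segments)
  if (nrow(seg) == 0L)
    return(segment_labels(integer(), integer(), character(),
                          x$sample_rate_hz))
  segment_labels(seg$start, seg$end, seg$class, x$sample_rate_hz)
}

#' Write segment labels to JSON
#' @param labels a `segment_labels` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  jsonlite::write_json(
    list(sample_rate_hz = attr(labels, "sample_rate_hz"),
         segments = as.data.frame(labels)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct a stride detection
#'
#' The common output container of all segmenters: either a list of stride
#' intervals (`start`, `end`; 0-based half-open) or, for peak detection, a
#' vector of peak sample indices. Intervals must be sorted; consecutive
#' intervals may share a border sample, and small temporal overlaps (as
#' allowed by the DTW post-filter, below 200 ms) are tolerated.
#'
#' @param method one of `"peak"`, `"edtw"`, `"pdtw"`, `"hhmm"`.
#' @param intervals data frame with integer columns `start`, `end`, or `NULL`.
#' @param peaks integer vector of 0-based peak samples, or `NULL`.
#' @param sample_rate_hz sampling rate the indices refer to.
#' @return an object of class `stride_detection`.
#' @export
stride_detection <- function(method = c("peak", "edtw", "pdtw", "hhmm"),
                             intervals = NULL, peaks = NULL,
                             sample_rate_hz = NA_real_) {
  method <- match.arg(method)
  if (!is.null(peaks)) {
    peaks <- sort(as.integer(peaks))
  }
  if (!is.null(intervals)) {
    intervals <- as.data.frame(intervals)
    stopifnot(all(c("start", "end") %in% names(intervals)))
    intervals$start <- as.integer(intervals$start)
    intervals$end <- as.integer(intervals$end)
    o <- order(intervals$start, intervals$end)
    intervals <- intervals[o, , drop = FALSE]
    rownames(intervals) <- NULL
    if (nrow(intervals) && any(intervals$start >= intervals$end))
      stop("detection intervals need start < end", call. = FALSE)
  }
  structure(list(method = method, intervals = intervals, peaks = peaks,
                 sample_rate_hz = sample_rate_hz),
            class = "stride_detection")
}

#' @export
print.stride_detection <- function(x, ...) {
  n <- if (!is.null(x$peaks)) length(x$peaks) else
    if (!is.null(x$intervals)) nrow(x$intervals) else 0L
  what <- if (!is.null(x$peaks)) "peaks" else "strides"
  cat(sprintf("<stride_detection> method %s: %d %s\n", x$method, n, what))
  invisible(x)
}

#' Number of detected strides (or peaks)
#' @param det a `stride_detection`.
#' @return integer count.
#' @export
n_detected <- function(det) {
  if (!is.null(det$peaks)) length(det$peaks)
  else if (!is.null(det$intervals)) nrow(det$intervals)
  else 0L
}
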