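# Multi-subsequence DTW segmentation: template generation (averaged and
# probabilistic), distance matrices, accumulated cost, match extraction and
# the stride post-filters.

#' msDTW configuration
#'
#' @param cost `"euclidean"` (averaged template) or `"probabilistic"`
#'   (per-position Gaussian template).
#' @param threshold match threshold on the matching function. Defaults to the
#'   midpoint of the published grids: 15 for the Euclidean cost on `GZ`
#'   (grids span 10-40 depending on the axes combination) and 11 for the
#'   probabilistic cost (grid 8-15, identical for all axes combinations).
#' @param metric pointwise per-axis distance for the Euclidean cost:
#'   `"manhattan"` (|x - y| per sample pair, the default) or
#'   `"sqeuclidean"`.
#' @param max_overlap_ms maximum allowed pairwise temporal overlap between
#'   reported matches (default 200 ms).
#' @param bounds_ms stride duration bounds in ms: a stride must be strictly
#'   longer than the first and strictly shorter than the second element
#'   (default 600 and 2500).
#' @return an object of class `msdtw_config`.
#' @export
msdtw_config <- function(cost = c("euclidean", "probabilistic"),
                         threshold = NULL,
                         metric = c("manhattan", "sqeuclidean"),
                         max_overlap_ms = 200, bounds_ms = c(600, 2500)) {
  cost <- match.arg(cost)
  metric <- match.arg(metric)
  if (is.null(threshold))
    threshold <- if (cost == "euclidean") 15 else 11
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  if (bounds_ms[1] >= bounds_ms[2])
    stop("`bounds_ms` must satisfy min < max", call. = FALSE)
  structure(list(cost = cost, threshold = threshold, metric = metric,
                 max_overlap_ms = max_overlap_ms, bounds_ms = bounds_ms),
            class = "msdtw_config")
}

#' Extract labeled stride segments from a recording
#'
#' @param rec an [imu_recording()] in physical units.
#' @param labels the matching [segment_labels()].
#' @return list of numeric matrices (samples x 6 channels), one per stride,
#'   with sensor ranges attached as attributes.
#' @export
extract_strides <- function(rec, labels) {
  iv <- stride_intervals(labels)
  lapply(seq_len(nrow(iv)), function(i) {
    m <- rec$data[(iv$start[i] + 1L):iv$end[i], , drop = FALSE]
    attr(m, "accel_range_g") <- rec$accel_range_g
    attr(m, "gyro_range_dps") <- rec$gyro_range_dps
    m
  })
}

# Linearly interpolate each selected axis of a stride to M samples.
interp_stride <- function(stride, M, axes) {
  n <- nrow(stride)
  u <- if (n == 1L) 0 else (seq_len(n) - 1) / (n - 1)
  sapply(axes, function(a)
    approx(u, stride[, a], xout = (seq_len(M) - 1) / (M - 1))$y)
}

normalize_axes <- function(values, axes, accel_range_g, gyro_range_dps) {
  for (j in seq_along(axes)) {
    r <- if (axes[j] %in% ACCEL_CHANNELS) accel_range_g else gyro_range_dps
    values[, j] <- values[, j] / r
  }
  values[values > 1] <- 1
  values[values < -1] <- -1
  values
}

#' Build an averaged stride template
#'
#' Each training stride is linearly interpolated to `M` samples per axis, the
#' interpolated strides are averaged position by position, and the average is
#' normalized to the sensor range. The default axes are `AX`, `AY`, `GZ`; the
#' remaining axes are nearly constant in foot-worn gait data and convey no
#' stride information.
#'
#' @param strides list of stride matrices as returned by [extract_strides()].
#' @param M template length in samples (default 200).
#' @param axes character vector of template axes.
#' @param accel_range_g,gyro_range_dps sensor ranges used for normalization;
#'   taken from the stride attributes when `NULL`.
#' @return an object of class `stride_template` with fields `M`, `axes`,
#'   `values` (M x length(axes), in \[-1, 1\]).
#' @export
build_average_template <- function(strides, M = 200,
                                   axes = c("AX", "AY", "GZ"),
                                   accel_range_g = NULL,
                                   gyro_range_dps = NULL) {
  if (!length(strides)) stop("need at least one training stride",
                             call. = FALSE)
  if (M < 2L) stop("`M` must be >= 2", call. = FALSE)
  stopifnot(all(axes %in% IMU_CHANNELS))
  if (any(vapply(strides, nrow, integer(1)) < 2L))
    stop("every training stride needs >= 2 samples", call. = FALSE)
  if (is.null(accel_range_g))
    accel_range_g <- attr(strides[[1]], "accel_range_g") %||% 6
  if (is.null(gyro_range_dps))
    gyro_range_dps <- attr(strides[[1]], "gyro_range_dps") %||% 500
  interp <- lapply(strides, interp_stride, M = M, axes = axes)
  avg <- Reduce(`+`, interp) / length(interp)
  values <- normalize_axes(avg, axes, accel_range_g, gyro_range_dps)
  colnames(values) <- axes
  structure(list(M = M, axes = axes, values = values,
                 accel_range_g = accel_range_g,
                 gyro_range_dps = gyro_range_dps),
            class = "stride_template")
}

#' @export
print.stride_template <- function(x, ...) {
  cat(sprintf("<stride_template> M = %d, axes: %s\n", x$M,
              paste(x$axes, collapse = ", ")))
  invisible(x)
}

#' Build a probabilistic (per-position Gaussian) stride template
#'
#' Training strides are interpolated to `M` samples, normalized to the sensor
#' range, and the sample vector at each position `m` is modeled by a Gaussian
#' with positionwise mean and (floored) positionwise variance, diagonal
#' across axes.
#'
#' @inheritParams build_average_template
#' @param var_floor minimum variance in normalized units (default 1e-4);
#'   prevents degenerate Gaussians on nearly identical training strides.
#' @return an object of class `prob_template` with fields `M`, `axes`,
#'   `mean` and `var` (each M x length(axes)).
#' @export
build_probabilistic_template <- function(strides, M = 200,
                                         axes = c("AX", "AY", "GZ"),
                                         var_floor = 1e-4,
                                         accel_range_g = NULL,
                                         gyro_range_dps = NULL) {
  if (length(strides) < 2L)
    stop("probabilistic template needs >= 2 training strides", call. = FALSE)
  if (var_floor <= 0) stop("`var_floor` must be positive", call. = FALSE)
  if (M < 2L) stop("`M` must be >= 2", call. = FALSE)
  if (is.null(accel_range_g))
    accel_range_g <- attr(strides[[1]], "accel_range_g") %||% 6
  if (is.null(gyro_range_dps))
    gyro_range_dps <- attr(strides[[1]], "gyro_range_dps") %||% 500
  interp <- lapply(strides, function(s)
    normalize_axes(interp_stride(s, M, axes), axes, accel_range_g,
                   gyro_range_dps))
  arr <- simplify2array(interp)               # M x axes x n
  mu <- apply(arr, c(1, 2), mean)
  v <- apply(arr, c(1, 2), var)
  v[v < var_floor] <- var_floor
  colnames(mu) <- colnames(v) <- axes
  structure(list(M = M, axes = axes, mean = mu, var = v,
                 var_floor = var_floor, accel_range_g = accel_range_g,
                 gyro_range_dps = gyro_range_dps),
            class = "prob_template")
}

#' @export
print.prob_template <- function(x, ...) {
  cat(sprintf("<prob_template> M = %d, axes: %s, var floor %g\n", x$M,
              paste(x$axes, collapse = ", "), x$var_floor))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Euclidean-cost distance matrix
#'
#' `D[m, t]` is the pointwise per-axis distance between template position `m`
#' and sequence sample `t`, summed over the template axes (one distance
#' matrix per axis, all summed up).
#'
#' @param tpl a [build_average_template()] result.
#' @param rec an [imu_recording()] normalized to sensor range.
#' @param metric `"manhattan"` or `"sqeuclidean"` pointwise distance.
#' @return numeric M x T matrix.
#' @export
distance_matrix_euclidean <- function(tpl, rec,
                                      metric = c("manhattan", "sqeuclidean")) {
  stopifnot(inherits(tpl, "stride_template"))
  metric <- match.arg(metric)
  if (!isTRUE(rec$meta$normalized))
    stop("recording must be normalized to sensor range before DTW",
         call. = FALSE)
  if (!all(tpl$axes %in% colnames(rec$data)))
    stop("format error: recording lacks template axes", call. = FALSE)
  D <- 0
  for (j in seq_along(tpl$axes)) {
    diff <- outer(tpl$values[, j], rec$data[, tpl$axes[j]], "-")
    D <- D + if (metric == "manhattan") abs(diff) else diff^2
  }
  D
}

#' Probabilistic-cost distance matrix
#'
#' The per-position similarity is the Gaussian likelihood rescaled by its
#' value at the mean, `P(y) = exp(-0.5 * Mahalanobis^2)`, which lies in
#' (0, 1\] (a raw density does not); the distance is `D = exp(-P)`, so all
#' entries lie in \[exp(-1), 1) and grow monotonically with the Mahalanobis
#' distance from the position mean. Axes combine as a product of per-axis
#' Gaussians (diagonal covariance).
#'
#' @param ptpl a [build_probabilistic_template()] result.
#' @param rec an [imu_recording()] normalized to sensor range.
#' @return numeric M x T matrix.
#' @export
distance_matrix_probabilistic <- function(ptpl, rec) {
  stopifnot(inherits(ptpl, "prob_template"))
  if (!isTRUE(rec$meta$normalized))
    stop("recording must be normalized to sensor range before DTW",
         call. = FALSE)
  if (any(ptpl$var <= 0))
    stop("internal invariant violation: non-positive template variance",
         call. = FALSE)
  maha2 <- 0
  for (j in seq_along(ptpl$axes)) {
    diff <- outer(ptpl$mean[, j], rec$data[, ptpl$axes[j]], "-")
    maha2 <- maha2 + sweep(diff^2, 1, ptpl$var[, j], "/")
  }
  exp(-exp(-0.5 * maha2))
}

#' Accumulated cost matrix for subsequence DTW
#'
#' Subsequence boundary conditions: the first template row is free along the
#' sequence (`C(1, t) = D(1, t)`, so a match may start anywhere) and the
#' first column accumulates down the template (`C(m, 1) = sum_{i<=m}
#' D(i, 1)`). Remaining cells follow the step-pattern recursion
#' `C(m, t) = D(m, t) + min{C(m-1, t-1), C(m-1, t), C(m, t-1)}`.
#'
#' @param D finite numeric M x T distance matrix.
#' @return numeric M x T accumulated cost matrix.
#' @export
accumulate_cost <- function(D) {
  if (!is.matrix(D) || !all(is.finite(D)))
    stop("`D` must be a finite numeric matrix", call. = FALSE)
  cpp_accumulate_cost(D)
}

#' Assemble an msDTW workspace
#'
#' @param D distance matrix (M x T).
#' @param sample_rate_hz sampling rate of the underlying sequence.
#' @param cost cost-function family the matrix was built with.
#' @return an object of class `msdtw_workspace` holding `D`, `C` and the
#'   matching function `delta` (the row of `C` for the full template).
#' @export
msdtw_workspace <- function(D, sample_rate_hz,
                            cost = c("euclidean", "probabilistic")) {
  cost <- match.arg(cost)
  C <- accumulate_cost(D)
  structure(list(D = D, C = C, delta = C[nrow(C), ],
                 sample_rate_hz = sample_rate_hz, cost = cost),
            class = "msdtw_workspace")
}

# Local minima of the matching function: delta[t] must be the minimum over a
# centered window of `radius` samples on each side, with ties broken toward
# the earlier index.
delta_local_minima <- function(delta, radius) {
  T_ <- length(delta)
  out <- integer()
  for (t in seq_len(T_)) {
    lo <- max(1L, t - radius); hi <- min(T_, t + radius)
    w <- delta[lo:hi]
    if (delta[t] > min(w)) next
    ties <- lo - 1L + which(w == delta[t])
    if (ties[1L] == t) out <- c(out, t)
  }
  out
}

interval_overlap <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

#' Extract stride matches from an msDTW workspace
#'
#' Candidate end points are local minima of the matching function (strict
#' minimum within a neighborhood of one minimum stride duration, ties to the
#' earlier index). Each candidate is backtracked through the accumulated cost
#' matrix to the free-start row, giving a warping path and a candidate
#' interval. For the Euclidean cost, candidates with matching-function value
#' below the threshold are kept. For the probabilistic cost every path step
#' costs at least `exp(-1)` by construction, so the threshold is applied to
#' the baseline-adjusted path cost `delta - L * exp(-1)` (L = path length),
#' which is zero for a perfect match; this keeps the published threshold
#' ranges meaningful. Surviving candidates are filtered by the stride
#' duration bounds, and overlap conflicts (pairwise overlap of at least
#' `max_overlap_ms`) are resolved by keeping the lower-cost match.
#'
#' @param ws an [msdtw_workspace()].
#' @param cfg an [msdtw_config()].
#' @return a [stride_detection()] with `intervals`; the per-match matching
#'   costs and warping paths are attached as attributes `match_info` and
#'   `paths`.
#' @export
find_matches <- function(ws, cfg = msdtw_config(cost = ws$cost)) {
  stopifnot(inherits(ws, "msdtw_workspace"))
  rate <- ws$sample_rate_hz
  min_dur <- ms_to_samples(cfg$bounds_ms[1], rate)
  max_dur <- ms_to_samples(cfg$bounds_ms[2], rate)
  max_ov <- ms_to_samples(cfg$max_overlap_ms, rate)
  radius <- max(1L, min_dur %/% 2L)
  cand <- delta_local_minima(ws$delta, radius)
  if (ws$cost == "euclidean")
    cand <- cand[ws$delta[cand] < cfg$threshold]
  rows <- list()
  for (t_end in cand) {
    path <- cpp_backtrack(ws$C, t_end)
    t_start <- path[1L, 2L]
    score <- ws$delta[t_end]
    if (ws$cost == "probabilistic") {
      score <- score - nrow(path) * exp(-1)
      if (score >= cfg$threshold) next
    }
    dur <- t_end - t_start + 1L
    if (dur <= min_dur || dur >= max_dur) next
    rows[[length(rows) + 1L]] <-
      list(start = t_start - 1L, end = t_end, score = score, path = path)
  }
  if (!length(rows)) {
    det <- stride_detection(if (ws$cost == "euclidean") "edtw" else "pdtw",
                            intervals = data.frame(start = integer(),
                                                   end = integer()),
                            sample_rate_hz = rate)
    attr(det, "match_info") <- data.frame(start = integer(), end = integer(),
                                          score = numeric())
    attr(det, "paths") <- list()
    return(det)
  }
  o <- order(vapply(rows, `[[`, numeric(1), "score"))
  keep <- list()
  for (i in o) {
    r <- rows[[i]]
    ok <- TRUE
    for (k in keep) {
      if (interval_overlap(r$start, r$end, k$start, k$end) >= max_ov) {
        ok <- FALSE; break
      }
    }
    if (ok) keep[[length(keep) + 1L]] <- r
  }
  keep <- keep[order(vapply(keep, `[[`, numeric(1), "start"))]
  iv <- data.frame(start = vapply(keep, function(r) r$start, integer(1)),
                   end = vapply(keep, function(r) r$end, integer(1)))
  det <- stride_detection(if (ws$cost == "euclidean") "edtw" else "pdtw",
                          intervals = iv, sample_rate_hz = rate)
  attr(det, "match_info") <- data.frame(
    start = iv$start, end = iv$end,
    score = vapply(keep, function(r) r$score, numeric(1)))
  attr(det, "paths") <- lapply(keep, `[[`, "path")
  det
}

#' Segment a recording with multi-subsequence DTW
#'
#' Normalizes the recording to the sensor range (if not already normalized),
#' builds the distance and accumulated cost matrices for the template's cost
#' family, and extracts matches.
#'
#' @param rec an [imu_recording()].
#' @param template a [build_average_template()] or
#'   [build_probabilistic_template()] result.
#' @param cfg an [msdtw_config()]; its `cost` must agree with the template
#'   type (defaults to the template's family).
#' @return a [stride_detection()].
#' @export
segment_msdtw <- function(rec, template, cfg = NULL) {
  cost <- if (inherits(template, "prob_template")) "probabilistic"
          else "euclidean"
  if (is.null(cfg)) cfg <- msdtw_config(cost = cost)
  if (cfg$cost != cost)
    stop("config cost family does not match the template type", call. = FALSE)
  if (!isTRUE(rec$meta$normalized)) rec <- normalize_to_sensor_range(rec)
  D <- if (cost == "euclidean")
    distance_matrix_euclidean(template, rec, cfg$metric)
  else distance_matrix_probabilistic(template, rec)
  ws <- msdtw_workspace(D, rec$sample_rate_hz, cost)
  find_matches(ws, cfg)
}

#' Write an averaged template to CSV / read it back
#' @param tpl a `stride_template`.
#' @param path file path.
#' @return `path` (write) or a `stride_template` (read).
#' @export
write_template <- function(tpl, path) {
  df <- as.data.frame(tpl$values)
  data.table::fwrite(df, path)
  meta <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(M = tpl$M, axes = tpl$axes,
                            accel_range_g = tpl$accel_range_g,
                            gyro_range_dps = tpl$gyro_range_dps),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  values <- as.matrix(data.table::fread(path, data.table = FALSE))
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  structure(list(M = meta$M, axes = meta$axes, values = values,
                 accel_range_g = meta$accel_range_g,
                 gyro_range_dps = meta$gyro_range_dps),
            class = "stride_template")
}
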