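# Sliding Hann-window feature extraction, feature normalization and PCA for
# the hierarchical HMM segmenter.

#' Feature extraction configuration
#'
#' @param window_len_s sliding window length in seconds. The published search
#'   grid is 0.10-0.70 s in steps of 0.20; the default here is 0.10 s, which
#'   at 50% hop gives roughly 20 frames per typical stride and therefore
#'   supports left-to-right stride sub-chains of up to that many sub-states
#'   (longer windows cap the feasible sub-state count at the frames-per-stride
#'   count).
#' @param hop_frac hop size as a fraction of the window (default 0.5).
#' @param include_raw include the Hann-windowed samples themselves as
#'   features (making the feature dimension window-length dependent; PCA then
#'   standardizes dimensionality). If `FALSE` only the summary features are
#'   used.
#' @param hann_on_stats if `TRUE` (default) the mean/variance/energy/
#'   polynomial features are computed on the Hann-weighted samples; if
#'   `FALSE` they are computed on the unweighted window (the weighting then
#'   applies only to the raw-sample features).
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(window_len_s = 0.1, hop_frac = 0.5,
                           include_raw = TRUE, hann_on_stats = TRUE) {
  if (window_len_s <= 0) stop("`window_len_s` must be positive", call. = FALSE)
  if (hop_frac <= 0 || hop_frac > 1)
    stop("`hop_frac` must lie in (0, 1]", call. = FALSE)
  structure(list(window_len_s = window_len_s, hop_frac = hop_frac,
                 include_raw = include_raw, hann_on_stats = hann_on_stats),
            class = "feature_config")
}

#' Hann window weights
#' @param n window length in samples (>= 2).
#' @return numeric vector of length `n`.
#' @export
hann_window <- function(n) {
  stopifnot(n >= 2L)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' Extract sliding-window features from a recording
#'
#' The signal is cut into hop-spaced frames; each frame of each of the six
#' axes is multiplied by a Hann window (reducing edge effects compared to a
#' rectangular window) and summarized by the windowed samples themselves
#' (optional), their mean, variance, energy (sum of squares) and the three
#' coefficients of a second-order polynomial fit over the window. The final
#' feature vector concatenates all axes.
#'
#' @param rec an [imu_recording()] (raw physical units).
#' @param cfg a [feature_config()].
#' @return numeric matrix (frames x features) with attributes `centers`
#'   (0-based fractional sample index of each frame center), `window`, `hop`
#'   and `sample_rate_hz`.
#' @export
extract_features <- function(rec, cfg = feature_config()) {
  stopifnot(inherits(rec, "imu_recording"), inherits(cfg, "feature_config"))
  rate <- rec$sample_rate_hz
  win <- max(3L, ms_to_samples(cfg$window_len_s * 1000, rate))
  hop <- max(1L, as.integer(floor(win * cfg$hop_frac + 0.5)))
  T_ <- nrow(rec$data)
  if (T_ < win)
    stop("recording shorter than one feature window", call. = FALSE)
  n_frames <- (T_ - win) %/% hop + 1L
  h <- hann_window(win)
  u <- seq(-1, 1, length.out = win)
  B <- cbind(1, u, u^2)
  Pinv <- solve(crossprod(B), t(B))   # least-squares polynomial coefficients
  per_axis <- win * as.integer(cfg$include_raw) + 6L
  out <- matrix(0, n_frames, 6L * per_axis)
  for (f in seq_len(n_frames)) {
    idx <- ((f - 1L) * hop + 1L):((f - 1L) * hop + win)
    x <- rec$data[idx, , drop = FALSE]
    xw <- x * h
    src <- if (cfg$hann_on_stats) xw else x
    feats <- numeric(0)
    for (a in seq_len(6L)) {
      s <- src[, a]
      poly <- as.numeric(Pinv %*% s)
      block <- c(if (cfg$include_raw) xw[, a],
                 mean(s), var(s), sum(s^2), poly)
      feats <- c(feats, block)
    }
    out[f, ] <- feats
  }
  nm <- c(if (cfg$include_raw) paste0("raw", seq_len(win)),
          "mean", "var", "energy", "poly0", "poly1", "poly2")
  colnames(out) <- as.vector(t(outer(IMU_CHANNELS, nm, paste, sep = ".")))
  attr(out, "centers") <- (seq_len(n_frames) - 1L) * hop + (win - 1) / 2
  attr(out, "window") <- win
  attr(out, "hop") <- hop
  attr(out, "sample_rate_hz") <- rate
  out
}

#' Fit the feature normalizer and PCA transform
#'
#' Z-score normalization is fitted on the training frames only, then PCA is
#' fitted on the normalized training frames. Constant feature dimensions get
#' unit scale so they pass through unchanged (and end up with zero PCA
#' loading variance).
#'
#' @param X training feature matrix (frames x features).
#' @param n_components number of principal components to keep.
#' @return an object of class `feature_transform`.
#' @export
fit_feature_transform <- function(X, n_components) {
  stopifnot(is.matrix(X))
  if (n_components > ncol(X))
    stop("`n_components` exceeds the feature dimension", call. = FALSE)
  if (n_components > nrow(X))
    stop("`n_components` exceeds the number of training frames",
         call. = FALSE)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  structure(list(mu = mu, sd = sdv,
                 rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
                 n_components = n_components),
            class = "feature_transform")
}

#' Apply a fitted feature transform
#'
#' @param tf a [fit_feature_transform()] result.
#' @param X feature matrix (frames x features).
#' @return transformed matrix (frames x n_components); frame-mapping
#'   attributes of `X` are preserved.
#' @export
apply_feature_transform <- function(tf, X) {
  stopifnot(inherits(tf, "feature_transform"))
  Z <- sweep(sweep(X, 2, tf$mu), 2, tf$sd, "/")
  out <- Z %*% tf$rotation
  for (a in c("centers", "window", "hop", "sample_rate_hz"))
    attr(out, a) <- attr(X, a)
  out
}

#' Assign a segment class to every feature frame
#'
#' Each frame takes the class of the labeled segment containing its center
#' sample (stride taking precedence at shared borders); frames outside all
#' labeled segments are assigned `"rest"`, the background class.
#'
#' @param labels a [segment_labels()].
#' @param centers frame centers (0-based samples), e.g.
#'   `attr(features, "centers")`.
#' @return character vector of frame classes, with the index of the
#'   containing labeled segment attached as attribute `segment_id` (0 for
#'   background frames). The segment ids let the hHMM initializer slice
#'   sub-states within each labeled segment, which matters when consecutive
#'   strides share borders and therefore form one uninterrupted run of
#'   stride frames.
#' @export
label_frames <- function(labels, centers) {
  cls <- rep("rest", length(centers))
  prio <- c(rest = 1L, transition = 2L, stride = 3L)
  cur <- rep(0L, length(centers))
  seg <- rep(0L, length(centers))
  for (i in seq_len(nrow(labels))) {
    inside <- centers >= labels$start[i] & centers < labels$end[i]
    upgrade <- inside & prio[[labels$class[i]]] > cur
    cls[upgrade] <- labels$class[i]
    cur[upgrade] <- prio[[labels$class[i]]]
    seg[upgrade] <- i
  }
  attr(cls, "segment_id") <- seg
  cls
}
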