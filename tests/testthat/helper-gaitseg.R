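# Shared fixture builders. Everything is generated in code; heavier shared
# objects are built once per test run and memoized here.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# A recording with given GZ samples and zeros elsewhere (physical units).
gz_recording <- function(gz, rate = 102.4) {
  m <- matrix(0, length(gz), 6, dimnames = list(NULL, c("AX", "AY", "AZ",
                                                        "GX", "GY", "GZ")))
  m[, "GZ"] <- gz
  imu_recording(m, rate)
}

# Tiny deterministic recording with arbitrary values on all channels.
random_recording <- function(n = 50, rate = 102.4, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, c("AX", "AY", "AZ", "GX", "GY", "GZ")))
  imu_recording(m, rate)
}

# Noiseless straight walk shared across tests.
clean_walk <- function() memo("clean_walk", function()
  generate_straight_walk(6, stride_shape_params(), seed = 11,
                         rest_padding_ms = 500))

# Small noisy cohort shared across tests (straight preset defaults).
small_cohort <- function() memo("small_cohort", function()
  generate_cohort(4, "straight", seed = 21, n_strides = 8))

# Independent subsequence-DTW oracle: classical full-boundary DTW (same step
# set) between the template and every subsequence Y[s..t]; the matching
# function at t is the minimum over start points s. Independent of the
# package's single-pass recursion (different orientation, per-subsequence
# recomputation).
oracle_subseq_dtw <- function(D) {
  M <- nrow(D); T_ <- ncol(D)
  best <- rep(Inf, T_)
  for (s in seq_len(T_)) {
    # classical DTW anchored at start column s, swept to the right edge
    prev <- cumsum(D[, s])
    best[s] <- min(best[s], prev[M])
    if (s < T_) for (t in (s + 1):T_) {
      cur <- numeric(M)
      cur[1] <- prev[1] + D[1, t]
      for (m in 2:M)
        cur[m] <- D[m, t] + min(prev[m - 1], prev[m], cur[m - 1])
      best[t] <- min(best[t], cur[M])
      prev <- cur
    }
  }
  best
}

# True exhaustive warping-path enumeration (tiny instances only): all
# monotone step sequences from row 1 (any start column) to (M, t).
oracle_enumerate_paths <- function(D, t_end) {
  M <- nrow(D)
  best <- Inf
  recurse <- function(m, t, cost) {
    cost <- cost + D[m, t]
    if (m == 1) { best <<- min(best, cost); return(invisible()) }
    if (t > 1) recurse(m - 1, t - 1, cost)
    recurse(m - 1, t, cost)
    if (t > 1) recurse(m, t - 1, cost)
  }
  recurse(M, t_end, 0)
  best
}

# Brute-force peak oracle: all threshold-passing strict local maxima, then
# greedy refractory resolution by amplitude (ties to the earlier sample).
oracle_peaks <- function(gz, thr, min_sep) {
  cand <- integer()
  for (i in seq_along(gz)) {
    if (i == 1 || i == length(gz)) next
    left <- i - 1
    while (left > 1 && gz[left] == gz[i]) left <- left - 1
    if (gz[left] >= gz[i]) next
    if (left < i - 1 && gz[i - 1] == gz[i]) next  # not first sample of plateau
    right <- i + 1
    while (right < length(gz) && gz[right] == gz[i]) right <- right + 1
    if (gz[right] >= gz[i]) next
    if (gz[i] > thr) cand <- c(cand, i)
  }
  cand <- cand[order(-gz[cand], cand)]
  acc <- integer()
  for (p in cand) if (!length(acc) || all(abs(acc - p) > min_sep))
    acc <- c(acc, p)
  sort(acc) - 1L
}

# Exhaustive Viterbi oracle over all state paths.
oracle_viterbi <- function(logA, logpi, logB) {
  Tn <- nrow(logB); N <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), Tn)))
  score <- apply(paths, 1, function(p) {
    s <- logpi[p[1]] + logB[1, p[1]]
    if (Tn > 1) for (t in 2:Tn)
      s <- s + logA[p[t - 1], p[t]] + logB[t, p[t]]
    s
  })
  list(path = as.integer(paths[which.max(score), ]), loglik = max(score))
}

# Tiny trained hHMM on a short labeled walk, shared across hHMM tests.
tiny_hhmm <- function() memo("tiny_hhmm", function() {
  g <- generate_straight_walk(8, stride_shape_params(noise_sd_gyro_dps = 5,
                                                     noise_sd_accel_g = 0.02,
                                                     duration_jitter_sd = 0.03),
                              seed = 31, rest_padding_ms = 500)
  fcfg <- feature_config()
  feats <- extract_features(g$rec, fcfg)
  fl <- label_frames(g$labels, attr(feats, "centers"))
  tf <- fit_feature_transform(feats, 5)
  X <- apply_feature_transform(tf, feats)
  st <- hhmm_structure(n_substates = c(stride = 4L, rest = 1L), n_gmm = 3L,
                       n_pca = 5L)
  model <- init_hhmm(list(X), list(fl), st, transform = tf, fcfg = fcfg,
                     seed = 5)
  model <- train_bw(model, list(X), list(fl))
  list(model = model, X = X, fl = fl, g = g, feats = feats)
})
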