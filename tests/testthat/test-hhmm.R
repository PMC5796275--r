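# Hierarchical HMM: features, transforms, initialization, semi-supervised
# Baum-Welch, Viterbi and stride extraction.

test_that("feature frames follow the hop arithmetic and zero signals give zero features", {
  rec <- random_recording(n = 100, seed = 14)
  cfg <- feature_config(window_len_s = 0.2, hop_frac = 0.5)
  X <- extract_features(rec, cfg)
  win <- attr(X, "window"); hop <- attr(X, "hop")
  expect_equal(win, 20L)              # 0.2 s at 102.4 Hz -> 20 samples
  expect_equal(hop, 10L)
  expect_equal(nrow(X), (100L - win) %/% hop + 1L)
  expect_equal(attr(X, "centers")[1], (win - 1) / 2)
  expect_error(extract_features(random_recording(n = 5), cfg), "shorter")

  zero <- imu_recording(matrix(0, 60, 6), 102.4)
  Xz <- extract_features(zero, cfg)
  expect_true(all(Xz == 0))
})

test_that("Hann-windowed features match closed forms", {
  # constant channel c: windowed samples are c * h, so the variance feature
  # equals c^2 * var(h) and the energy equals c^2 * sum(h^2)
  cfg <- feature_config(window_len_s = 0.2, hop_frac = 1)
  m <- matrix(0, 20, 6); m[, 6] <- 3
  rec <- imu_recording(m, 102.4)
  X <- extract_features(rec, cfg)
  h <- hann_window(20)
  expect_equal(unname(X[1, "GZ.var"]), 9 * var(h))
  expect_equal(unname(X[1, "GZ.energy"]), 9 * sum(h^2))
  expect_equal(unname(X[1, "GZ.mean"]), 3 * mean(h))
  expect_equal(unname(X[1, "GZ.raw5"]), 3 * h[5])

  # pure quadratic signal, stats on the unweighted window: the second-order
  # fit reconstructs it exactly
  cfg2 <- feature_config(window_len_s = 0.2, hop_frac = 1,
                         hann_on_stats = FALSE)
  u <- seq(-1, 1, length.out = 20)
  m2 <- matrix(0, 20, 6); m2[, 6] <- 2 + 3 * u - 1.5 * u^2
  X2 <- extract_features(imu_recording(m2, 102.4), cfg2)
  co <- X2[1, c("GZ.poly0", "GZ.poly1", "GZ.poly2")]
  expect_equal(unname(co), c(2, 3, -1.5), tolerance = 1e-10)
})

test_that("normalizer and PCA transforms behave as fitted", {
  set.seed(15)
  X <- matrix(rnorm(200 * 6), 200, 6)
  X[, 3] <- X[, 3] * 10 + 5
  tf <- fit_feature_transform(X, 6)
  Z <- apply_feature_transform(tf, X)
  # complete basis: reconstruction error 0
  back <- Z %*% t(tf$rotation)
  Zfull <- sweep(sweep(X, 2, tf$mu), 2, tf$sd, "/")
  expect_equal(unname(back), unname(Zfull), tolerance = 1e-10)
  # z-scoring the training data is idempotent in distribution parameters
  expect_equal(unname(colMeans(Zfull)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(Zfull, 2, sd)), rep(1, 6), tolerance = 1e-12)
  expect_error(fit_feature_transform(X, 7), "exceeds")

  # variance concentrated on one axis after scaling: first component aligns
  Y <- matrix(rnorm(500 * 4, 0, 1e-3), 500, 4)
  Y[, 2] <- rnorm(500, 0, 50)
  tf2 <- fit_feature_transform(Y, 2)
  # transform scales to unit variance, so check on the unscaled covariance
  pc <- prcomp(Y)
  expect_gt(abs(pc$rotation[2, 1]), 0.999)
})

test_that("frame labels track segment classes and carry segment ids", {
  lab <- segment_labels(c(0, 100, 200), c(100, 200, 320),
                        c("rest", "stride", "stride"), 102.4)
  fl <- label_frames(lab, centers = c(10, 99.5, 150, 250, 330))
  expect_equal(as.character(fl), c("rest", "rest", "stride", "stride",
                                   "rest"))
  expect_equal(attr(fl, "segment_id"), c(1L, 1L, 2L, 3L, 0L))
})

test_that("initialization reproduces labeled bigrams and degenerate shapes", {
  # alternating stride/rest in equal runs: symmetric cross transitions,
  # dominant self transitions
  fl <- rep(rep(c("stride", "rest"), 10), each = 10)
  attr(fl, "segment_id") <- rep(seq_len(20), each = 10)
  X <- matrix(rnorm(length(fl) * 3), ncol = 3)
  st <- hhmm_structure(n_substates = c(stride = 2L, rest = 1L), n_gmm = 2L,
                       n_pca = 3L)
  m <- init_hhmm(list(X), list(fl), st, seed = 1)
  A_top <- m$A_top
  expect_gt(A_top["stride", "stride"], A_top["stride", "rest"])
  expect_gt(A_top["rest", "rest"], A_top["rest", "stride"])
  # near-symmetric up to the one unpaired final run
  expect_lt(abs(A_top["stride", "rest"] - A_top["rest", "stride"]), 0.02)

  # single-state labels: top-level transition matrix is [[1]]
  fl1 <- rep("stride", 30)
  attr(fl1, "segment_id") <- rep(1:3, each = 10)
  m1 <- init_hhmm(list(matrix(rnorm(90), ncol = 3)), list(fl1),
                  hhmm_structure(n_substates = c(stride = 3L), n_gmm = 1L,
                                 n_pca = 3L), seed = 1)
  expect_equal(dim(m1$A_top), c(1L, 1L))
  expect_equal(unname(m1$A_top[1, 1]), 1)

  # one sub-state per state reduces to a flat HMM (N = number of states)
  m2 <- init_hhmm(list(X), list(fl),
                  hhmm_structure(n_substates = c(stride = 1L, rest = 1L),
                                 n_gmm = 2L, n_pca = 3L), seed = 1)
  expect_equal(m2$layout$N, 2L)
  expect_true(all(m2$A > 0))

  # a configured state absent from the labels errors by name
  expect_error(init_hhmm(list(X), list(fl),
                         hhmm_structure(n_substates = c(stride = 2L)),
                         seed = 1),
               "rest")
})

test_that("flat transition matrix stays row-stochastic and masked through training", {
  fit <- tiny_hhmm()
  model <- fit$model
  expect_equal(unname(rowSums(model$A)), rep(1, model$layout$N),
               tolerance = 1e-8)
  expect_equal(sum(model$pi), 1, tolerance = 1e-8)
  expect_true(all(model$A[!model$mask] == 0))   # mask respected after BW
  for (g in model$gmms) {
    expect_equal(sum(g$w), 1, tolerance = 1e-8)
    expect_true(all(g$var >= model$structure$cov_floor - 1e-12))
  }
})

test_that("Baum-Welch log-likelihood is non-decreasing and converges", {
  fit <- tiny_hhmm()
  ll <- fit$model$ll_history
  expect_true(all(diff(ll) >= -1e-6 * abs(ll[-length(ll)])))
  # one more iteration on the converged model changes parameters little
  m2 <- fit$model
  m2$structure$max_bw_iterations <- 1L
  m3 <- train_bw(m2, list(fit$X), list(fit$fl))
  expect_equal(m3$A, fit$model$A, tolerance = 1e-2)
  rel <- abs(tail(m3$ll_history, 1) - tail(ll, 1)) / abs(tail(ll, 1))
  expect_lt(rel, 1e-3)
})

test_that("clamped training assigns no responsibility to non-labeled states", {
  fit <- tiny_hhmm()
  post <- hhmm_posteriors(fit$model, fit$X, fit$fl)
  top_of <- fit$model$layout$top_of
  for (s in unique(fit$fl)) {
    frames <- which(fit$fl == s)
    other <- which(top_of != s)
    expect_true(all(post$gamma[frames, other] == 0))
  }
  expect_true(is.finite(post$loglik))
})

test_that("training recovers GMM means of a known two-state generative model", {
  # 2 top states x 1 sub-state, single-component Gaussians, well separated
  set.seed(16)
  mu_true <- c(stride = 4, rest = -4)
  n_seg <- 40; seg_len <- 12
  cls <- rep(rep(c("stride", "rest"), n_seg / 2), each = seg_len)
  X <- matrix(rnorm(length(cls) * 2, mean = mu_true[cls], sd = 1), ncol = 2)
  fl <- cls
  attr(fl, "segment_id") <- rep(seq_len(n_seg), each = seg_len)
  st <- hhmm_structure(n_substates = c(stride = 1L, rest = 1L), n_gmm = 1L,
                       n_pca = 2L)
  m <- init_hhmm(list(X), list(fl), st, seed = 2)
  m <- train_bw(m, list(X), list(fl))
  n_per <- sum(cls == "stride")
  se <- 1 / sqrt(n_per)
  i_stride <- which(m$layout$top_of == "stride")
  i_rest <- which(m$layout$top_of == "rest")
  expect_lt(abs(m$gmms[[i_stride]]$mu[1, 1] - 4), 3 * se)
  expect_lt(abs(m$gmms[[i_rest]]$mu[1, 1] - (-4)), 3 * se)
})

test_that("Viterbi matches brute-force enumeration and dominates random paths", {
  set.seed(17)
  # trivial single-state model decodes everything to that state
  one <- list(logA = matrix(0, 1, 1), logpi = 0)
  # hand instances with <= 3 frames, <= 2 states vs exhaustive enumeration
  for (rep in 1:20) {
    N <- sample(1:2, 1); Tn <- sample(1:3, 1)
    A <- matrix(runif(N * N), N, N); A <- A / rowSums(A)
    p0 <- runif(N); p0 <- p0 / sum(p0)
    logB <- matrix(log(runif(Tn * N)), Tn, N)
    vit <- gaitseg:::cpp_viterbi(log(A), log(p0), logB)
    orc <- oracle_viterbi(log(A), log(p0), logB)
    expect_equal(vit$loglik, orc$loglik)
    expect_equal(vit$path, orc$path)
  }
  # near-deterministic emissions: path equals the emission argmax
  A <- matrix(0.5, 2, 2); p0 <- c(0.5, 0.5)
  logB <- matrix(-1e6, 5, 2)
  truth <- c(1L, 2L, 2L, 1L, 2L)
  for (t in 1:5) logB[t, truth[t]] <- 0
  expect_equal(gaitseg:::cpp_viterbi(log(A), log(p0), logB)$path, truth)

  # decoded likelihood dominates 100 random paths on a real model
  fit <- tiny_hhmm()
  dec <- viterbi_decode(fit$model, fit$X)
  em <- gaitseg:::emission_logB(fit$model, fit$X, NULL)
  logA <- gaitseg:::log_mat(fit$model$A); logpi <- log(fit$model$pi)
  path_ll <- function(p) {
    s <- logpi[p[1]] + em$logB[1, p[1]]
    for (t in 2:length(p)) s <- s + logA[p[t - 1], p[t]] + em$logB[t, p[t]]
    s
  }
  N <- fit$model$layout$N
  for (r in 1:100) {
    rp <- sample(N, nrow(fit$X), replace = TRUE)
    expect_lte(path_ll(rp), attr(dec, "loglik") + 1e-9)
  }
})

test_that("decoded passes become strides with shared borders and duration filtering", {
  # synthetic decoded sequences with a known frame mapping
  mk_dec <- function(states, subs, hop = 5, win = 10) {
    d <- data.frame(frame = seq_along(states), state = states,
                    substate = subs, stringsAsFactors = FALSE)
    attr(d, "centers") <- (seq_along(states) - 1) * hop + (win - 1) / 2
    attr(d, "hop") <- hop
    attr(d, "sample_rate_hz") <- 102.4
    class(d) <- c("hhmm_decoded", "data.frame")
    d
  }
  # rest -> one full pass (~24 frames) -> rest: one stride
  d1 <- mk_dec(c(rep("rest", 3), rep("stride", 24), rep("rest", 3)),
               c(rep(1, 3), rep(1:4, each = 6), rep(1, 3)))
  iv1 <- decode_to_strides(d1)$intervals
  expect_equal(nrow(iv1), 1L)

  # two back-to-back passes share one border sample
  d2 <- mk_dec(c(rep("rest", 2), rep("stride", 48), rep("rest", 2)),
               c(rep(1, 2), rep(rep(1:4, each = 6), 2), rep(1, 2)))
  iv2 <- decode_to_strides(d2)$intervals
  expect_equal(nrow(iv2), 2L)
  expect_equal(iv2$start[2], iv2$end[1])

  # a 300 ms pass is filtered by the duration bounds
  d3 <- mk_dec(c(rep("rest", 5), rep("stride", 6), rep("rest", 5)),
               c(rep(1, 5), 1:6, rep(1, 5)))
  expect_equal(nrow(decode_to_strides(d3)$intervals), 0L)

  # empty decode gives an empty detection
  dec0 <- viterbi_decode(tiny_hhmm()$model, matrix(numeric(), 0, 5))
  expect_equal(nrow(decode_to_strides(dec0,
                                      sample_rate_hz = 102.4)$intervals), 0L)
})

test_that("the end-to-end hHMM recovers clean strides on held-out data", {
  cohort <- small_cohort()
  subj <- vapply(cohort, `[[`, character(1), "subject_id")
  fit <- train_method(method_spec("hhmm", n_substride = 6L, n_gmm = 4L),
                      cohort[subj != "S01"], seed = 3)
  counts <- sum_counts(lapply(which(subj == "S01"), function(i)
    match_strides(predict_method(fit, cohort[[i]]$rec),
                  cohort[[i]]$labels)))
  m <- compute_metrics(counts)
  expect_gte(m$f_score, 0.95)
})

test_that("grid search maximizes the score with smaller-model tie-breaks", {
  grid <- list(list(a = 1), list(a = 2), list(a = 3))
  gs <- grid_search(grid, score_fn = function(g) c(0.5, 0.9, 0.9)[g$a],
                    size_fn = function(g) g$a)
  expect_equal(gs$best$a, 2)            # tie between 2 and 3 -> smaller
  expect_equal(grid_search(list(list(a = 7)),
                           score_fn = function(g) 1)$best$a, 7)
  # adding a strictly worse configuration never changes the winner
  gs2 <- grid_search(c(grid, list(list(a = 4))),
                     score_fn = function(g) c(0.5, 0.9, 0.9, 0.1)[g$a],
                     size_fn = function(g) g$a)
  expect_equal(gs2$best$a, gs$best$a)
  expect_error(grid_search(list(), function(g) 1), "empty")
  # the published grid expands to the full cross product
  expect_length(hhmm_grid(window_len_s = 0.1, n_substride = c(4, 6),
                          n_gmm = 8, n_pca = c(1, 3)), 4L)
})

test_that("hHMM models round trip through JSON serialization", {
  fit <- tiny_hhmm()
  f <- withr::local_tempfile(fileext = ".json")
  write_hhmm(fit$model, f)
  back <- read_hhmm(f)
  expect_equal(back$A, fit$model$A, tolerance = 1e-12)
  expect_equal(back$layout$ns, fit$model$layout$ns)
  dec1 <- viterbi_decode(fit$model, fit$X)
  dec2 <- viterbi_decode(back, fit$X)
  expect_equal(dec2$state, dec1$state)
  expect_equal(dec2$substate, dec1$substate)
})
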