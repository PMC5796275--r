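# Multi-subsequence DTW: templates, distance matrices, accumulated cost,
# match extraction and the end-to-end segmenter.

test_that("average template reproduces, averages and interpolates strides", {
  # single stride already of length M: template equals the normalized stride
  set.seed(2)
  s <- matrix(runif(50 * 6, -400, 400), 50, 6,
              dimnames = list(NULL, c("AX", "AY", "AZ", "GX", "GY", "GZ")))
  s[, 1:3] <- s[, 1:3] / 100       # keep accel within range
  tpl <- build_average_template(list(s), M = 50, axes = "GZ",
                                accel_range_g = 6, gyro_range_dps = 500)
  expect_equal(as.numeric(tpl$values), as.numeric(s[, "GZ"] / 500))

  # two constant strides average to the constant mean
  c1 <- matrix(100, 30, 6, dimnames = dimnames(s)[1:2] -> dn) ; dimnames(c1) <- list(NULL, colnames(s))
  c2 <- c1; c2[] <- 300
  tpl2 <- build_average_template(list(c1, c2), M = 10, axes = "GZ",
                                 accel_range_g = 6, gyro_range_dps = 500)
  expect_equal(as.numeric(tpl2$values), rep(200 / 500, 10))

  # a linear ramp stays a linear ramp under interpolation to M = 200
  ramp <- matrix(0, 100, 6, dimnames = list(NULL, colnames(s)))
  ramp[, "GZ"] <- seq(0, 500, length.out = 100)
  tpl3 <- build_average_template(list(ramp), M = 200, axes = "GZ",
                                 accel_range_g = 6, gyro_range_dps = 500)
  expect_equal(as.numeric(tpl3$values), seq(0, 1, length.out = 200),
               tolerance = 1e-12)

  expect_error(build_average_template(list()), "at least one")
  expect_error(build_average_template(list(s), M = 1), ">= 2")
})

test_that("probabilistic template recovers positionwise moments", {
  # identical strides: variance hits the floor everywhere
  s <- matrix(50, 40, 6, dimnames = list(NULL, c("AX", "AY", "AZ", "GX",
                                                 "GY", "GZ")))
  pt <- build_probabilistic_template(list(s, s), M = 20, axes = "GZ",
                                     accel_range_g = 6, gyro_range_dps = 500)
  expect_true(all(pt$var == 1e-4))
  expect_error(build_probabilistic_template(list(s), M = 20, axes = "GZ"),
               ">= 2")

  # i.i.d. Gaussian strides: means and variances within 3 SE of truth
  set.seed(4)
  M <- 25; nrep <- 500
  mu_true <- 100 * sin(seq(0, 2 * pi, length.out = M))
  sd_true <- 20
  strides <- lapply(seq_len(nrep), function(i) {
    m <- matrix(0, M, 6, dimnames = list(NULL, colnames(s)))
    m[, "GZ"] <- mu_true + rnorm(M, 0, sd_true)
    m
  })
  pt2 <- build_probabilistic_template(strides, M = M, axes = "GZ",
                                      accel_range_g = 6,
                                      gyro_range_dps = 500)
  se_mean <- (sd_true / 500) / sqrt(nrep)
  expect_true(all(abs(pt2$mean - mu_true / 500) < 3 * se_mean + 1e-9))
  v_true <- (sd_true / 500)^2
  se_var <- v_true * sqrt(2 / (nrep - 1))
  expect_true(all(abs(pt2$var - v_true) < 3 * se_var))

  # the probabilistic means equal the average template (shared estimator)
  tpl <- build_average_template(strides, M = M, axes = "GZ",
                                accel_range_g = 6, gyro_range_dps = 500)
  expect_equal(unname(pt2$mean), unname(tpl$values), tolerance = 1e-12)
})

test_that("Euclidean distance matrix is a per-axis sum of pointwise distances", {
  s <- matrix(0, 10, 6, dimnames = list(NULL, c("AX", "AY", "AZ", "GX",
                                                "GY", "GZ")))
  s[, "GZ"] <- 0.5 * 500  # normalizes to 0.5
  tpl <- build_average_template(list(s), M = 5, axes = "GZ",
                                accel_range_g = 6, gyro_range_dps = 500)
  rec <- normalize_to_sensor_range(gz_recording(c(0.1, 0.5) * 500))
  D <- distance_matrix_euclidean(tpl, rec)
  expect_equal(dim(D), c(5L, 2L))
  expect_equal(D[1, 1], 0.4)          # |0.5 - 0.1|
  expect_equal(D[1, 2], 0)            # template row equals sequence sample

  # two axes: distance equals the sum of the single-axis distances
  set.seed(6)
  stride <- matrix(rnorm(20 * 6, 0, 100), 20, 6,
                   dimnames = list(NULL, colnames(s)))
  stride[, 1:3] <- stride[, 1:3] / 50
  seq_rec <- random_recording(n = 15, seed = 60)
  nrec <- normalize_to_sensor_range(seq_rec)
  mk <- function(axes) build_average_template(list(stride), M = 8,
                                              axes = axes, accel_range_g = 6,
                                              gyro_range_dps = 500)
  D2 <- distance_matrix_euclidean(mk(c("AX", "GZ")), nrec)
  expect_equal(D2, distance_matrix_euclidean(mk("AX"), nrec) +
                 distance_matrix_euclidean(mk("GZ"), nrec))
  # raw recordings are rejected
  expect_error(distance_matrix_euclidean(mk("GZ"), seq_rec), "normalized")
})

test_that("probabilistic distance maps likelihood into [exp(-1), 1) monotonically", {
  s1 <- matrix(0, 10, 6, dimnames = list(NULL, c("AX", "AY", "AZ", "GX",
                                                 "GY", "GZ")))
  s2 <- s1; s1[, "GZ"] <- 90; s2[, "GZ"] <- 110   # mean 100, some variance
  pt <- build_probabilistic_template(list(s1, s2), M = 4, axes = "GZ",
                                     accel_range_g = 6, gyro_range_dps = 500)
  at <- function(y) {
    rec <- normalize_to_sensor_range(gz_recording(y))
    unname(distance_matrix_probabilistic(pt, rec)[1, 1])
  }
  expect_equal(at(100), exp(-1))          # at the mean: P = 1, D = exp(-1)
  expect_lt(abs(at(100 + 1e5) - 1), 1e-6) # far away: P -> 0, D -> 1
  # monotone in |y - mean| over a grid (up to double-precision saturation)
  ds <- vapply(seq(100, 200, by = 10), at, numeric(1))
  expect_true(all(diff(ds) > 0))
  expect_true(all(ds >= exp(-1) & ds <= 1))
})

test_that("accumulated cost matches the boundary conditions and oracles", {
  # zero distances give zero cost; M = 1 reduces to the distance row
  expect_true(all(accumulate_cost(matrix(0, 4, 6)) == 0))
  D1 <- matrix(runif(8), 1, 8)
  expect_equal(accumulate_cost(D1), D1)
  expect_error(accumulate_cost(matrix(c(1, Inf), 1, 2)), "finite")

  set.seed(9)
  # tiny instances: exhaustive warping-path enumeration
  for (rep in 1:5) {
    D <- matrix(sample(0:9, 12, replace = TRUE), 3, 4)
    C <- accumulate_cost(D)
    expect_equal(C[1, ], D[1, ])                      # free start
    expect_equal(C[, 1], cumsum(D[, 1]))              # first column
    for (t in 1:4)
      expect_equal(C[3, t], oracle_enumerate_paths(D, t))
  }
  # mid-size instances: independent per-subsequence DTW oracle
  for (rep in 1:5) {
    M <- sample(2:6, 1); T_ <- sample(8:20, 1)
    D <- matrix(runif(M * T_), M, T_)
    expect_equal(accumulate_cost(D)[M, ], oracle_subseq_dtw(D))
  }
})

test_that("warping paths satisfy the step condition and cost consistency", {
  set.seed(10)
  D <- matrix(runif(6 * 30), 6, 30)
  C <- accumulate_cost(D)
  for (t_end in c(6, 15, 30)) {
    path <- gaitseg:::cpp_backtrack(C, t_end)
    expect_equal(path[1, 1], 1L)                       # starts at row 1
    expect_equal(path[nrow(path), ], c(6L, t_end))     # ends at row M
    steps <- diff(path)
    expect_true(all(steps[, 1] %in% 0:1 & steps[, 2] %in% 0:1 &
                      rowSums(steps) >= 1))
    # accumulated cost along the path equals the matching function
    expect_equal(sum(D[path]), C[6, t_end])
  }
})

test_that("find_matches recovers embedded template copies and respects the threshold", {
  # template = one noiseless synthetic stride; sequence = rest, copy, rest,
  # copy, rest (copies separated by far more than 200 ms)
  p <- stride_shape_params()
  s <- make_stride(p)
  quiet <- matrix(0, 80, 6, dimnames = list(NULL, colnames(s)))
  seq_data <- rbind(quiet, s, quiet, s, quiet)
  rec <- imu_recording(seq_data, 102.4)
  tpl <- build_average_template(list(s), M = 200, axes = "GZ",
                                accel_range_g = 6, gyro_range_dps = 500)
  det <- segment_msdtw(rec, tpl, msdtw_config("euclidean", threshold = 5))
  expect_equal(nrow(det$intervals), 2L)
  n <- nrow(s)
  expect_true(all(abs(det$intervals$start - c(80L, 80L + n + 80L)) <= 2))
  expect_true(all(abs(det$intervals$end - c(80L + n, 2L * 80L + 2L * n)) <= 2))

  # probabilistic cost on exact template-length copies of the template mean:
  # every path step sits at the Gaussian mean, so the baseline-adjusted cost
  # is ~ 0 and any positive threshold accepts the matches
  pt <- build_probabilistic_template(list(s, s), M = 200, axes = "GZ",
                                     accel_range_g = 6, gyro_range_dps = 500)
  copyM <- matrix(0, 200, 6, dimnames = list(NULL, colnames(s)))
  copyM[, "GZ"] <- pt$mean[, "GZ"] * 500      # back to physical units
  seqM <- rbind(quiet, copyM, quiet, copyM, quiet)
  recM <- imu_recording(seqM, 102.4)
  detp <- segment_msdtw(recM, pt, msdtw_config("probabilistic",
                                               threshold = 11))
  expect_equal(nrow(detp$intervals), 2L)
  expect_true(all(abs(detp$intervals$start - c(80L, 80L + 200L + 80L)) <= 2))

  # matching function everywhere above threshold: no matches
  det0 <- segment_msdtw(rec, tpl, msdtw_config("euclidean",
                                               threshold = 1e-6))
  expect_equal(nrow(det0$intervals), 0L)
})

test_that("matches are monotone in threshold and invariant to excluded axes", {
  g <- clean_walk()
  strides <- extract_strides(g$rec, g$labels)
  tpl <- build_average_template(strides, axes = "GZ")
  prev <- Inf
  sets <- lapply(c(20, 10, 5, 1), function(thr)
    segment_msdtw(g$rec, tpl, msdtw_config("euclidean", thr))$intervals)
  for (i in seq_along(sets)[-1]) {
    # lowering the threshold never adds matches
    expect_true(nrow(sets[[i]]) <= nrow(sets[[i - 1]]))
    if (nrow(sets[[i]]))
      expect_true(all(do.call(paste, sets[[i]]) %in%
                        do.call(paste, sets[[i - 1]])))
  }
  # corrupting an excluded axis leaves the detection unchanged
  rec2 <- g$rec
  set.seed(12)
  rec2$data[, "GX"] <- rnorm(n_samples(rec2), 0, 300)
  d1 <- segment_msdtw(g$rec, tpl)
  d2 <- segment_msdtw(rec2, tpl)
  expect_equal(d1$intervals, d2$intervals)
})

test_that("end-to-end eDTW achieves a perfect F-score on a clean walk", {
  g <- clean_walk()
  tpl <- build_average_template(extract_strides(g$rec, g$labels))
  det <- segment_msdtw(g$rec, tpl)
  m <- compute_metrics(match_strides(det, g$labels))
  expect_equal(m$f_score, 1)
  # negative control: shuffled-sample noise yields nothing under a tight
  # threshold
  set.seed(13)
  shuf <- g$rec
  shuf$data <- g$rec$data[sample(n_samples(g$rec)), ]
  det0 <- segment_msdtw(shuf, tpl, msdtw_config("euclidean", threshold = 2))
  expect_equal(nrow(det0$intervals), 0L)
})

test_that("template files round trip through CSV", {
  g <- clean_walk()
  tpl <- build_average_template(extract_strides(g$rec, g$labels))
  f <- withr::local_tempfile(fileext = ".csv")
  write_template(tpl, f)
  back <- read_template(f)
  expect_equal(unname(back$values), unname(tpl$values))
  expect_equal(back$axes, tpl$axes)
  expect_equal(back$M, tpl$M)
})
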