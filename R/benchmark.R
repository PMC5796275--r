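# Uniform train/predict interface over the four segmenters, plus the
# benchmark harness that produces a comparison report.

#' Method specification
#'
#' Bundles a segmentation method with its parameters under one interface so
#' the cross-validation harnesses can treat all methods alike.
#'
#' Per-method parameters (all optional):
#' * `peak`: `amp_threshold_dps` (150), `min_separation_ms` (600).
#' * `edtw` / `pdtw`: `axes` (`c("AX","AY","GZ")` subsets; default `"GZ"`),
#'   `M` (200), `threshold` (grid midpoints 15 / 11), `metric`
#'   (`"manhattan"`), `var_floor` (1e-4, pdtw only), `max_overlap_ms` (200),
#'   `bounds_ms` (600, 2500).
#' * `hhmm`: `window_len_s` (0.1), `hop_frac` (0.5), `n_substride` (8),
#'   `n_subtransition` (3), `n_subrest` (1), `n_gmm` (10), `n_pca` (7),
#'   `max_bw_iterations` (20).
#'
#' @param method one of `"peak"`, `"edtw"`, `"pdtw"`, `"hhmm"`.
#' @param ... method parameters overriding the defaults above.
#' @return an object of class `method_spec`.
#' @export
method_spec <- function(method = c("peak", "edtw", "pdtw", "hhmm"), ...) {
  method <- match.arg(method)
  params <- list(...)
  defaults <- switch(method,
    peak = list(amp_threshold_dps = 150, min_separation_ms = 600),
    edtw = list(axes = "GZ", M = 200L, threshold = 15,
                metric = "manhattan", max_overlap_ms = 200,
                bounds_ms = c(600, 2500)),
    pdtw = list(axes = "GZ", M = 200L, threshold = 11, var_floor = 1e-4,
                max_overlap_ms = 200, bounds_ms = c(600, 2500)),
    hhmm = list(window_len_s = 0.1, hop_frac = 0.5, n_substride = 8L,
                n_subtransition = 3L, n_subrest = 1L, n_gmm = 10L,
                n_pca = 7L, max_bw_iterations = 20L))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) for method ", method, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(method = method, params = modifyList(defaults, params)),
            class = "method_spec")
}

merge_spec <- function(spec, overrides) {
  if (!length(overrides)) return(spec)
  do.call(method_spec, c(list(method = spec$method),
                         modifyList(spec$params, overrides)))
}

# Model size for grid-search tie-breaking: smaller is preferred.
spec_size <- function(spec, cfg) {
  p <- modifyList(spec$params, cfg)
  switch(spec$method,
         peak = p$amp_threshold_dps,
         edtw = p$threshold,
         pdtw = p$threshold,
         hhmm = hhmm_param_count(list(n_substride = p$n_substride,
                                      n_gmm = p$n_gmm, n_pca = p$n_pca)))
}

#' Train a segmentation method on a labeled cohort
#'
#' Peak detection needs no training; the DTW methods build their template
#' from the labeled training strides; the hHMM extracts features, fits the
#' normalizer and PCA on the training frames, initializes the two-level
#' model from the labels and runs semi-supervised Baum-Welch.
#'
#' @param spec a [method_spec()].
#' @param cohort list of training entries (`rec`, `labels`, ...).
#' @param seed optional integer seed (hHMM sub-state/GMM initialization).
#' @return a fitted method object of class `method_fit`.
#' @export
train_method <- function(spec, cohort, seed = NULL) {
  stopifnot(inherits(spec, "method_spec"))
  p <- spec$params
  fit <- switch(spec$method,
    peak = list(cfg = peak_config(p$amp_threshold_dps, p$min_separation_ms)),
    edtw = {
      strides <- unlist(lapply(cohort, function(e)
        extract_strides(e$rec, e$labels)), recursive = FALSE)
      tpl <- build_average_template(strides, M = p$M, axes = p$axes)
      list(template = tpl,
           cfg = msdtw_config("euclidean", p$threshold, p$metric,
                              p$max_overlap_ms, p$bounds_ms))
    },
    pdtw = {
      strides <- unlist(lapply(cohort, function(e)
        extract_strides(e$rec, e$labels)), recursive = FALSE)
      tpl <- build_probabilistic_template(strides, M = p$M, axes = p$axes,
                                          var_floor = p$var_floor)
      list(template = tpl,
           cfg = msdtw_config("probabilistic", p$threshold,
                              max_overlap_ms = p$max_overlap_ms,
                              bounds_ms = p$bounds_ms))
    },
    hhmm = {
      fcfg <- feature_config(p$window_len_s, p$hop_frac)
      feats <- lapply(cohort, function(e) extract_features(e$rec, fcfg))
      fl <- lapply(seq_along(cohort), function(i)
        label_frames(cohort[[i]]$labels, attr(feats[[i]], "centers")))
      tf <- fit_feature_transform(do.call(rbind, feats), p$n_pca)
      tfeats <- lapply(feats, function(X) apply_feature_transform(tf, X))
      st <- hhmm_structure(
        n_substates = c(stride = p$n_substride,
                        transition = p$n_subtransition,
                        rest = p$n_subrest),
        n_gmm = p$n_gmm, n_pca = p$n_pca,
        max_bw_iterations = p$max_bw_iterations)
      model <- init_hhmm(tfeats, fl, st, transform = tf, fcfg = fcfg,
                         seed = seed)
      model <- train_bw(model, tfeats, fl)
      list(model = model)
    })
  structure(c(list(method = spec$method, spec = spec), fit),
            class = "method_fit")
}

#' Segment a recording with a fitted method
#'
#' @param fit a [train_method()] result.
#' @param rec an [imu_recording()] in physical units.
#' @return a [stride_detection()].
#' @export
predict_method <- function(fit, rec) {
  stopifnot(inherits(fit, "method_fit"))
  switch(fit$method,
    peak = detect_peaks(rec, fit$cfg),
    edtw = segment_msdtw(rec, fit$template, fit$cfg),
    pdtw = segment_msdtw(rec, fit$template, fit$cfg),
    hhmm = {
      feats <- extract_features(rec, fit$model$fcfg)
      X <- apply_feature_transform(fit$model$transform, feats)
      decode_to_strides(viterbi_decode(fit$model, X))
    })
}

#' Run the full method benchmark on a cohort
#'
#' Evaluates each method with the requested cross-validation scheme and
#' collects a report table (mean +/- sd of precision, recall and F-score
#' across folds, plus pooled values) and pairwise Wilcoxon p-values on the
#' per-fold F-scores.
#'
#' @param cohort list of cohort entries.
#' @param specs list of [method_spec()]s (default: all four methods).
#' @param scheme `"loocv"` or `"nested"`.
#' @param grids optional named list (by method) of grids for the nested
#'   scheme.
#' @param seed integer seed shared by all methods (identical folds).
#' @param tol_ms matching tolerance in ms.
#' @param k_outer,k_inner fold counts for the nested scheme.
#' @return an object of class `benchmark_result`: list with `report` (data
#'   frame), `folds` (per-method `cv_result`s) and `p_values` (matrix).
#' @export
run_benchmark <- function(cohort,
                          specs = list(method_spec("peak"),
                                       method_spec("edtw"),
                                       method_spec("pdtw"),
                                       method_spec("hhmm")),
                          scheme = c("loocv", "nested"), grids = NULL,
                          seed = 1L, tol_ms = 100, k_outer = 4L,
                          k_inner = 4L) {
  scheme <- match.arg(scheme)
  folds <- list()
  for (spec in specs) {
    res <- if (scheme == "loocv")
      run_loocv(cohort, spec, tol_ms = tol_ms, seed = seed)
    else
      run_nested_cv(cohort, spec, grid = grids[[spec$method]],
                    k_outer = k_outer, k_inner = k_inner, seed = seed,
                    tol_ms = tol_ms)
    folds[[spec$method]] <- res
  }
  report <- do.call(rbind, lapply(names(folds), function(m) {
    s <- attr(folds[[m]], "summary")
    p <- attr(folds[[m]], "pooled")
    data.frame(method = m,
               precision_mean = s$mean[1], precision_sd = s$sd[1],
               recall_mean = s$mean[2], recall_sd = s$sd[2],
               f_score_mean = s$mean[3], f_score_sd = s$sd[3],
               precision_pooled = p$precision, recall_pooled = p$recall,
               f_score_pooled = p$f_score, stringsAsFactors = FALSE)
  }))
  pv <- if (length(folds) >= 2L)
    compare_methods(lapply(folds, function(f) f$f_score)) else NULL
  structure(list(report = report, folds = folds, p_values = pv),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  df <- x$report
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-5s P %.3f+/-%.3f  R %.3f+/-%.3f  F %.3f+/-%.3f\n",
                df$method[i], df$precision_mean[i], df$precision_sd[i],
                df$recall_mean[i], df$recall_sd[i], df$f_score_mean[i],
                df$f_score_sd[i]))
  invisible(x)
}
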