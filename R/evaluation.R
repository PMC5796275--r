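# Scoring: tolerance-based stride matching, precision/recall/F-score,
# subject-level cross-validation schemes and pairwise Wilcoxon comparison.

#' Match detected strides against ground truth
#'
#' Interval detections: a detected stride is a true positive iff both its
#' start and end border lie within the tolerance (default +/-100 ms,
#' roughly 10% of a stride time) of an as-yet unmatched ground-truth stride;
#' matching is one-to-one and greedy in temporal order. With a +/-100 ms
#' tolerance and strides longer than 600 ms, ambiguous multi-matches are
#' geometrically impossible, so greedy matching coincides with optimal
#' bipartite matching. Peak-mode detections (which carry no borders) are
#' scored by the peak-in-stride rule: a peak is a true positive iff it falls
#' strictly inside exactly one unmatched ground-truth stride; additional
#' peaks inside the same stride are false positives, and unmatched strides
#' are false negatives.
#'
#' @param detected a [stride_detection()].
#' @param truth a [segment_labels()] on the same sample clock.
#' @param tol_ms border tolerance in ms (default 100).
#' @return an object of class `eval_counts`: list with integers `TP`, `FP`,
#'   `FN`.
#' @export
match_strides <- function(detected, truth, tol_ms = 100) {
  stopifnot(inherits(detected, "stride_detection"),
            inherits(truth, "segment_labels"))
  rate <- attr(truth, "sample_rate_hz")
  if (!is.na(detected$sample_rate_hz) &&
      abs(detected$sample_rate_hz - rate) > 1e-9)
    stop("detection and truth are on different sample clocks", call. = FALSE)
  gt <- stride_intervals(truth)
  n_truth <- nrow(gt)
  if (!is.null(detected$peaks)) {
    peaks <- detected$peaks
    matched <- rep(FALSE, n_truth)
    TP <- 0L; FP <- 0L
    for (p in peaks) {
      inside <- which(gt$start < p & p < gt$end)
      if (length(inside) == 1L && !matched[inside]) {
        matched[inside] <- TRUE; TP <- TP + 1L
      } else FP <- FP + 1L
    }
    return(eval_counts(TP, FP, n_truth - TP))
  }
  tol <- ms_to_samples(tol_ms, rate)
  iv <- detected$intervals
  o <- order(iv$start, iv$end)
  iv <- iv[o, , drop = FALSE]
  matched <- rep(FALSE, n_truth)
  TP <- 0L; FP <- 0L
  for (i in seq_len(nrow(iv))) {
    ok <- which(!matched &
                  abs(iv$start[i] - gt$start) <= tol &
                  abs(iv$end[i] - gt$end) <= tol)
    if (length(ok)) {
      matched[ok[1L]] <- TRUE; TP <- TP + 1L
    } else FP <- FP + 1L
  }
  eval_counts(TP, FP, n_truth - TP)
}

#' Evaluation counts
#' @param TP,FP,FN non-negative integers.
#' @return an object of class `eval_counts`.
#' @export
eval_counts <- function(TP = 0L, FP = 0L, FN = 0L) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 FN = as.integer(FN)),
            class = "eval_counts")
}

#' Sum evaluation counts
#' @param ... `eval_counts` objects (or a list of them).
#' @return the summed `eval_counts`.
#' @export
sum_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1L]], "eval_counts")) xs <- xs[[1L]]
  eval_counts(sum(vapply(xs, `[[`, integer(1), "TP")),
              sum(vapply(xs, `[[`, integer(1), "FP")),
              sum(vapply(xs, `[[`, integer(1), "FN")))
}

#' Precision, recall and F-score from evaluation counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` and the F-score is
#' their harmonic mean. Zero-denominator conventions: when `TP + FP = 0`,
#' precision is 1 if also `FN = 0` (nothing to find, nothing claimed) and 0
#' otherwise; recall analogously; the F-score is 0 when `precision + recall
#' = 0`.
#'
#' @param counts an [eval_counts()].
#' @return list with `precision`, `recall`, `f_score`, each in \[0, 1\].
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "eval_counts"))
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  precision <- if (TP + FP == 0L) as.numeric(FN == 0L) else TP / (TP + FP)
  recall <- if (TP + FN == 0L) as.numeric(FP == 0L) else TP / (TP + FN)
  f_score <- if (precision + recall == 0) 0
             else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f_score = f_score)
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the method is trained on all other subjects and the
#' held-out subject's recordings (both feet) are scored. Counts are summed
#' within each fold before computing metrics; the summary reports their mean
#' and standard deviation across folds, plus pooled metrics from counts
#' summed over all folds.
#'
#' @param cohort list of cohort entries (`rec`, `labels`, `subject_id`,
#'   `foot`), e.g. from [generate_cohort()].
#' @param spec a [method_spec()].
#' @param tol_ms matching tolerance in ms.
#' @param seed optional seed forwarded to method training.
#' @return an object of class `cv_result`: data frame of per-fold metrics
#'   with summary attributes.
#' @export
run_loocv <- function(cohort, spec, tol_ms = 100, seed = NULL) {
  subjects <- unique(vapply(cohort, `[[`, character(1), "subject_id"))
  if (length(subjects) < 2L)
    stop("leave-one-subject-out needs >= 2 subjects", call. = FALSE)
  rows <- list()
  for (s in subjects) {
    test_idx <- which(vapply(cohort, `[[`, character(1), "subject_id") == s)
    train <- cohort[-test_idx]
    fit <- tryCatch(train_method(spec, train, seed = seed),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("fold for subject ", s, " skipped: ", conditionMessage(fit),
              call. = FALSE)
      next
    }
    counts <- sum_counts(lapply(test_idx, function(i)
      match_strides(predict_method(fit, cohort[[i]]$rec),
                    cohort[[i]]$labels, tol_ms)))
    m <- compute_metrics(counts)
    rows[[length(rows) + 1L]] <-
      data.frame(fold = s, TP = counts$TP, FP = counts$FP, FN = counts$FN,
                 precision = m$precision, recall = m$recall,
                 f_score = m$f_score, stringsAsFactors = FALSE)
  }
  finish_cv(do.call(rbind, rows), spec)
}

finish_cv <- function(df, spec, chosen = NULL) {
  pooled <- compute_metrics(eval_counts(sum(df$TP), sum(df$FP), sum(df$FN)))
  structure(df,
            method = spec$method,
            pooled = pooled,
            summary = data.frame(
              metric = c("precision", "recall", "f_score"),
              mean = c(mean(df$precision), mean(df$recall), mean(df$f_score)),
              sd = c(sd(df$precision), sd(df$recall), sd(df$f_score))),
            chosen_params = chosen,
            class = c("cv_result", "data.frame"))
}

#' @export
print.cv_result <- function(x, ...) {
  s <- attr(x, "summary")
  p <- attr(x, "pooled")
  cat(sprintf("<cv_result> method %s, %d folds\n", attr(x, "method"),
              nrow(x)))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s mean %.3f sd %.3f (pooled %.3f)\n", s$metric[i],
                s$mean[i], s$sd[i], p[[s$metric[i]]]))
  invisible(x)
}

# Deterministic subject-level fold assignment: subjects shuffled under the
# seed, then dealt round-robin into k folds. Identical for every method run
# with the same seed.
subject_folds <- function(subjects, k, seed) {
  with_seed(seed, {
    shuffled <- sample(subjects)
    split(shuffled, rep_len(seq_len(k), length(shuffled)))
  })
}

#' Nested subject-level cross-validation with grid search
#'
#' Outer `k_outer`-fold split at the subject level (no subject appears in
#' both training and test of a fold); within each outer training set, an
#' inner `k_inner`-fold cross-validation scores every grid configuration by
#' mean inner-validation F-score, the winner (ties toward the smaller model)
#' is retrained on the whole outer training set, and the outer test fold is
#' scored once. The fold randomization depends only on `seed`, so it is
#' identical across methods.
#'
#' @param cohort list of cohort entries.
#' @param spec a [method_spec()]; grid entries override its parameters.
#' @param grid list of parameter lists to search (`NULL` or length 1 reduces
#'   to plain k-fold cross-validation with `spec`'s parameters).
#' @param k_outer,k_inner fold counts (default 4 and 4).
#' @param seed integer seed controlling the fold assignment.
#' @param tol_ms matching tolerance in ms.
#' @return a `cv_result` with the chosen parameters per fold in attribute
#'   `chosen_params`.
#' @export
run_nested_cv <- function(cohort, spec, grid = NULL, k_outer = 4L,
                          k_inner = 4L, seed = 1L, tol_ms = 100) {
  subjects <- unique(vapply(cohort, `[[`, character(1), "subject_id"))
  if (length(subjects) < k_outer)
    stop("fewer subjects than outer folds", call. = FALSE)
  folds <- subject_folds(subjects, k_outer, seed)
  subj_of <- vapply(cohort, `[[`, character(1), "subject_id")
  rows <- list(); chosen_all <- list()
  for (f in seq_len(k_outer)) {
    test_subj <- folds[[f]]
    train_subj <- setdiff(subjects, test_subj)
    train <- cohort[subj_of %in% train_subj]
    test <- cohort[subj_of %in% test_subj]
    if (is.null(grid) || length(grid) <= 1L) {
      cfg <- if (length(grid) == 1L) grid[[1L]] else list()
    } else {
      inner_folds <- subject_folds(train_subj, min(k_inner,
                                                   length(train_subj)),
                                   seed + f)
      score_fn <- function(cfg) {
        fs <- vapply(seq_along(inner_folds), function(g) {
          val_subj <- inner_folds[[g]]
          itrain <- train[!(vapply(train, `[[`, character(1),
                                   "subject_id") %in% val_subj)]
          ival <- train[vapply(train, `[[`, character(1),
                               "subject_id") %in% val_subj]
          fit <- tryCatch(
            train_method(merge_spec(spec, cfg), itrain, seed = seed),
            error = function(e) NULL)
          if (is.null(fit)) return(0)
          counts <- sum_counts(lapply(ival, function(e)
            match_strides(predict_method(fit, e$rec), e$labels, tol_ms)))
          compute_metrics(counts)$f_score
        }, numeric(1))
        mean(fs)
      }
      gs <- grid_search(grid, score_fn,
                        size_fn = function(cfg) spec_size(spec, cfg))
      cfg <- gs$best
    }
    fit <- train_method(merge_spec(spec, cfg), train, seed = seed)
    counts <- sum_counts(lapply(test, function(e)
      match_strides(predict_method(fit, e$rec), e$labels, tol_ms)))
    m <- compute_metrics(counts)
    rows[[length(rows) + 1L]] <-
      data.frame(fold = paste(test_subj, collapse = "+"),
                 TP = counts$TP, FP = counts$FP, FN = counts$FN,
                 precision = m$precision, recall = m$recall,
                 f_score = m$f_score, stringsAsFactors = FALSE)
    chosen_all[[f]] <- cfg
  }
  finish_cv(do.call(rbind, rows), spec, chosen = chosen_all)
}

#' Wilcoxon signed-rank test with Pratt zero handling
#'
#' Paired two-sided signed-rank test. Zero differences participate in the
#' ranking and are then discarded (Pratt). The null distribution is exact
#' (sign-flip enumeration) for up to 20 non-zero differences, with a normal
#' approximation beyond.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list with `statistic` (W+, the positive-rank sum) and `p_value`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  r <- rank(abs(d))
  nz <- d != 0
  rs <- r[nz]
  signs <- d[nz] > 0
  if (!length(rs)) return(list(statistic = 0, p_value = 1))
  W <- sum(rs[signs])
  m <- length(rs)
  if (m <= 20L) {
    # exact sign-flip enumeration of the W+ distribution
    flips <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    Ws <- as.numeric(flips %*% rs)
    eps <- 1e-9
    p_lo <- mean(Ws <= W + eps)
    p_hi <- mean(Ws >= W - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- sum(rs) / 2
    sig <- sqrt(sum(rs^2) / 4)
    p <- min(1, 2 * pnorm(-abs(W - mu) / sig))
  }
  list(statistic = W, p_value = p)
}

#' Pairwise method comparison with the Wilcoxon signed-rank test
#'
#' Compares methods on paired per-fold scores; no multiplicity correction is
#' applied.
#'
#' @param scores named list of equal-length numeric vectors (per-fold scores
#'   per method) or a data frame with one column per method.
#' @return symmetric matrix of two-sided p-values (diagonal `NA`).
#' @export
compare_methods <- function(scores) {
  if (is.data.frame(scores)) scores <- as.list(scores)
  if (length(scores) < 2L) stop("need >= 2 methods", call. = FALSE)
  lens <- lengths(scores)
  if (length(unique(lens)) != 1L)
    stop("methods must have equal fold counts", call. = FALSE)
  k <- length(scores)
  nm <- names(scores)
  P <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1L))
    for (j in (i + 1L):k) {
      p <- wilcoxon_signed_rank(scores[[i]], scores[[j]])$p_value
      P[i, j] <- P[j, i] <- p
    }
  P
}
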