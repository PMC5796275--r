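# Two-level hierarchical HMM: top-level movement classes (stride /
# transition / rest), each expanded into a left-to-right sub-chain of
# GMM-emitting sub-states. The two-level topology is flattened into one
# sparse transition matrix for training and decoding.

TOP_STATE_ORDER <- c("stride", "transition", "rest")

#' hHMM structure parameters
#'
#' @param n_substates named integer vector: sub-chain length per top-level
#'   state. Defaults are the mid-grid values of the published search ranges
#'   (stride 4-12, transition 2-4, rest 1): stride 8, transition 3, rest 1.
#' @param n_gmm GMM components per sub-state (grid 8-12; default 10).
#' @param n_pca principal components fed to the model (grid 1-15; default 7).
#' @param cov_floor diagonal covariance floor in normalized feature units.
#' @param max_bw_iterations Baum-Welch iteration cap (default 20).
#' @param bw_tol relative log-likelihood convergence tolerance.
#' @return an object of class `hhmm_structure`.
#' @export
hhmm_structure <- function(n_substates = c(stride = 8L, transition = 3L,
                                           rest = 1L),
                           n_gmm = 10L, n_pca = 7L, cov_floor = 1e-6,
                           max_bw_iterations = 20L, bw_tol = 1e-4) {
  stopifnot(all(n_substates >= 1L), n_gmm >= 1L, n_pca >= 1L, cov_floor > 0)
  structure(list(n_substates = n_substates, n_gmm = as.integer(n_gmm),
                 n_pca = as.integer(n_pca), cov_floor = cov_floor,
                 max_bw_iterations = as.integer(max_bw_iterations),
                 bw_tol = bw_tol),
            class = "hhmm_structure")
}

# Flat-state bookkeeping: states present, their sub-chain lengths, and maps
# flat index -> (top state, sub-state).
flat_layout <- function(states, n_substates) {
  ns <- as.integer(n_substates[states])
  if (anyNA(ns))
    stop("no sub-state count configured for state(s): ",
         paste(setdiff(states, names(n_substates)), collapse = ", "),
         call. = FALSE)
  N <- sum(ns)
  top_of <- rep(states, ns)
  sub_of <- unlist(lapply(ns, seq_len), use.names = FALSE)
  first <- cumsum(c(1L, ns[-length(ns)]))
  names(first) <- states
  list(states = states, ns = stats::setNames(ns, states), N = N,
       top_of = top_of, sub_of = sub_of, first = first)
}

# Structural mask of allowed flat transitions: within a sub-chain self or
# next sub-state; the last sub-state may additionally exit to the first
# sub-state of any top-level state (including its own, enabling stride
# re-entry).
flat_mask <- function(layout) {
  N <- layout$N
  mask <- matrix(FALSE, N, N)
  for (i in seq_len(N)) {
    s <- layout$top_of[i]
    last <- layout$sub_of[i] == layout$ns[[s]]
    mask[i, i] <- TRUE
    if (!last) mask[i, i + 1L] <- TRUE
    else mask[i, layout$first] <- TRUE
  }
  mask
}

#' Initialize a two-level hHMM from labeled training data
#'
#' The top-level transition matrix and initial probabilities are estimated
#' from frame-level labeled state bigrams (with a small additive smoothing so
#' every top-level transition stays reachable). Within each labeled segment,
#' frames are assigned to sub-states by uniform temporal slicing; the GMM of
#' each sub-state is initialized from the frames so assigned (k-means
#' centers, within-cluster variances, cluster weights). Second-level
#' transition rows are uniform over the allowed left-to-right entries.
#'
#' @param features list of transformed feature matrices, one per training
#'   recording.
#' @param frame_labels list of character vectors of per-frame top-level
#'   classes (from [label_frames()]), parallel to `features`.
#' @param structure an [hhmm_structure()].
#' @param transform the fitted [fit_feature_transform()], stored in the model.
#' @param fcfg the [feature_config()] used, stored in the model.
#' @param seed optional integer seed for the k-means initialization.
#' @return an object of class `hhmm_model`.
#' @export
init_hhmm <- function(features, frame_labels, structure = hhmm_structure(),
                      transform = NULL, fcfg = NULL, seed = NULL) {
  stopifnot(is.list(features), is.list(frame_labels),
            length(features) == length(frame_labels))
  present <- unique(unlist(frame_labels))
  states <- TOP_STATE_ORDER[TOP_STATE_ORDER %in% present]
  missing <- setdiff(states, names(structure$n_substates))
  if (length(missing))
    stop("no sub-state count configured for state: ",
         paste(missing, collapse = ", "), call. = FALSE)
  layout <- flat_layout(states, structure$n_substates)
  K <- length(states)

  # top-level bigrams and initial distribution, lightly smoothed
  big <- matrix(1e-2, K, K, dimnames = list(states, states))
  pi_top <- stats::setNames(rep(1e-2, K), states)
  for (r in seq_along(frame_labels)) {
    fl <- frame_labels[[r]]
    pi_top[fl[1L]] <- pi_top[fl[1L]] + 1
    if (length(fl) > 1L)
      for (t in 2:length(fl))
        big[fl[t - 1L], fl[t]] <- big[fl[t - 1L], fl[t]] + 1
  }
  A_top <- big / rowSums(big)
  pi_top <- pi_top / sum(pi_top)

  # flat transition matrix: uniform within sub-chains, A_top-weighted exits
  mask <- flat_mask(layout)
  N <- layout$N
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    s <- layout$top_of[i]
    last <- layout$sub_of[i] == layout$ns[[s]]
    if (!last) {
      A[i, i] <- 0.5; A[i, i + 1L] <- 0.5
    } else {
      A[i, i] <- 0.5
      for (s2 in states)
        A[i, layout$first[[s2]]] <- A[i, layout$first[[s2]]] +
          0.5 * A_top[s, s2]
    }
  }
  A <- A / rowSums(A)
  pi_flat <- numeric(N)
  for (s in states)
    pi_flat[layout$first[[s]] + seq_len(layout$ns[[s]]) - 1L] <-
      pi_top[[s]] / layout$ns[[s]]
  pi_flat <- pi_flat / sum(pi_flat)

  # sub-state frame assignment by uniform temporal slicing within each
  # labeled segment (segment ids separate back-to-back strides, which form
  # one uninterrupted run of stride frames)
  d <- ncol(features[[1L]])
  assign_frames <- vector("list", N)
  for (r in seq_along(features)) {
    fl <- frame_labels[[r]]
    seg <- attr(fl, "segment_id") %||% rep(0L, length(fl))
    runs <- rle(paste(fl, seg))
    runs$values <- vapply(strsplit(runs$values, " "), `[`, character(1), 1L)
    pos <- 0L
    for (j in seq_along(runs$lengths)) {
      L <- runs$lengths[j]; s <- runs$values[j]
      if (!(s %in% states)) { pos <- pos + L; next }
      ns <- layout$ns[[s]]
      sub <- pmin(ns, floor((seq_len(L) - 1L) * ns / L) + 1L)
      for (q in seq_len(L)) {
        flat <- layout$first[[s]] + sub[q] - 1L
        assign_frames[[flat]] <-
          c(assign_frames[[flat]], list(features[[r]][pos + q, ]))
      }
      pos <- pos + L
    }
  }
  for (s in states)
    if (sum(frame_labels_count(frame_labels, s)) == 0L)
      stop("top-level state with zero labeled frames: ", s, call. = FALSE)

  gmms <- vector("list", N)
  with_seed(seed, {
    for (i in seq_len(N)) {
      Xi <- do.call(rbind, assign_frames[[i]])
      if (is.null(Xi)) {
        # empty slice (short segments): fall back to all frames of the state
        s <- layout$top_of[i]
        nrows <- vapply(features, nrow, integer(1))
        offset <- c(0L, cumsum(nrows))
        all_idx <- unlist(lapply(seq_along(features), function(r)
          which(frame_labels[[r]] == s) + offset[r]))
        Xall <- do.call(rbind, features)
        Xi <- Xall[all_idx, , drop = FALSE]
      }
      gmms[[i]] <- init_gmm(Xi, structure$n_gmm, structure$cov_floor)
    }
  })

  structure(list(layout = layout, mask = mask, A = A, pi = pi_flat,
                 A_top = A_top, pi_top = pi_top, gmms = gmms,
                 structure = structure, transform = transform, fcfg = fcfg,
                 trained = FALSE, d = d, ll_history = numeric()),
            class = "hhmm_model")
}

frame_labels_count <- function(frame_labels, s)
  vapply(frame_labels, function(fl) sum(fl == s), integer(1))

# k-means GMM initialization with diagonal covariance; the effective number
# of components never exceeds the number of distinct frames.
init_gmm <- function(X, K, cov_floor) {
  X <- as.matrix(X)
  d <- ncol(X)
  n_distinct <- nrow(unique(X))
  Ke <- max(1L, min(K, n_distinct, nrow(X)))
  if (Ke == 1L || nrow(X) < 2L) {
    mu <- matrix(colMeans(X), 1L, d)
    v <- matrix(pmax(apply(X, 2, function(c) var(c)), cov_floor), 1L, d)
    v[!is.finite(v)] <- cov_floor
    return(list(w = 1, mu = mu, var = v))
  }
  km <- suppressWarnings(kmeans(X, Ke, nstart = 2L, iter.max = 25L))
  mu <- km$centers
  v <- matrix(cov_floor, Ke, d)
  for (k in seq_len(Ke)) {
    Xi <- X[km$cluster == k, , drop = FALSE]
    if (nrow(Xi) > 1L) v[k, ] <- pmax(apply(Xi, 2, var), cov_floor)
  }
  v[!is.finite(v)] <- cov_floor
  w <- as.numeric(table(factor(km$cluster, levels = seq_len(Ke))))
  w <- pmax(w / sum(w), 1e-8); w <- w / sum(w)
  list(w = w, mu = mu, var = v)
}

#' @export
print.hhmm_model <- function(x, ...) {
  cat(sprintf("<hhmm_model> states: %s (%s sub-states); %d flat states, %s\n",
              paste(x$layout$states, collapse = "/"),
              paste(x$layout$ns, collapse = "/"), x$layout$N,
              if (x$trained) sprintf("trained (%d BW iterations)",
                                     length(x$ll_history)) else "untrained"))
  invisible(x)
}

# Per-frame log emission density of one GMM, vectorized over frames.
gmm_logdens <- function(gmm, X) {
  n <- nrow(X); K <- length(gmm$w)
  lp <- matrix(0, n, K)
  for (k in seq_len(K)) {
    diff2 <- sweep(X, 2, gmm$mu[k, ])^2
    lp[, k] <- log(gmm$w[k]) -
      0.5 * (sum(log(2 * pi * gmm$var[k, ])) +
               rowSums(sweep(diff2, 2, gmm$var[k, ], "/")))
  }
  mx <- apply(lp, 1, max)
  list(logdens = mx + log(rowSums(exp(lp - mx))), logcomp = lp)
}

# Log emission matrix (frames x flat states); optionally clamped so frames
# may only occupy sub-states of their labeled top-level state.
emission_logB <- function(model, X, frame_labels = NULL) {
  N <- model$layout$N
  logB <- matrix(0, nrow(X), N)
  comp <- vector("list", N)
  for (i in seq_len(N)) {
    g <- gmm_logdens(model$gmms[[i]], X)
    logB[, i] <- g$logdens
    comp[[i]] <- g$logcomp
  }
  if (!is.null(frame_labels)) {
    for (i in seq_len(N)) {
      bad <- frame_labels != model$layout$top_of[i]
      logB[bad, i] <- -Inf
    }
  }
  list(logB = logB, comp = comp)
}

#' Posterior state occupancies for one recording
#'
#' Runs the forward-backward algorithm under the current model, optionally
#' clamped to frame labels (as during semi-supervised training), and returns
#' the per-frame flat-state posteriors.
#'
#' @param model an [init_hhmm()] / [train_bw()] model.
#' @param X transformed feature matrix of one recording.
#' @param frame_labels optional per-frame top-level classes for clamping.
#' @return list with `gamma` (frames x flat states), `loglik`.
#' @export
hhmm_posteriors <- function(model, X, frame_labels = NULL) {
  em <- emission_logB(model, X, frame_labels)
  fb <- cpp_forward_backward(log_mat(model$A), log(model$pi), em$logB)
  list(gamma = fb$gamma, loglik = fb$loglik)
}

log_mat <- function(A) {
  L <- suppressWarnings(log(A))
  L[A <= 0] <- -Inf
  L
}

#' Semi-supervised Baum-Welch training
#'
#' EM on the flattened two-level model. During training each frame's
#' top-level state is clamped to its label (the emission likelihood of all
#' other states' sub-states is set to zero), so the first level is learned
#' supervised while the sub-state alignment and GMM parameters are learned
#' unsupervised. Transition updates respect the left-to-right structural
#' mask (zero entries stay zero). Iterates at most
#' `structure$max_bw_iterations` times (published cap: 20) or until the
#' relative log-likelihood improvement drops below `bw_tol`; the clamped
#' log-likelihood is non-decreasing over iterations.
#'
#' @param model an [init_hhmm()] model.
#' @param features list of transformed feature matrices (one per recording).
#' @param frame_labels list of per-frame top-level classes, parallel to
#'   `features`; `NULL` disables clamping (fully unsupervised EM).
#' @return the trained `hhmm_model`, with the per-iteration log-likelihood in
#'   `$ll_history`.
#' @export
train_bw <- function(model, features, frame_labels = NULL) {
  stopifnot(inherits(model, "hhmm_model"))
  st <- model$structure
  N <- model$layout$N
  d <- model$d
  ll_hist <- numeric()
  for (iter in seq_len(st$max_bw_iterations)) {
    logA <- log_mat(model$A)
    logpi <- log_mat(model$pi)
    xi_acc <- matrix(0, N, N)
    pi_acc <- numeric(N)
    Nk <- lapply(model$gmms, function(g) numeric(length(g$w)))
    Sx <- lapply(model$gmms, function(g) matrix(0, length(g$w), d))
    Sx2 <- lapply(model$gmms, function(g) matrix(0, length(g$w), d))
    total_ll <- 0
    for (r in seq_along(features)) {
      X <- features[[r]]
      fl <- if (is.null(frame_labels)) NULL else frame_labels[[r]]
      em <- emission_logB(model, X, fl)
      fb <- cpp_forward_backward(logA, logpi, em$logB)
      if (!is.finite(fb$loglik))
        stop("non-finite likelihood in Baum-Welch iteration ", iter,
             call. = FALSE)
      total_ll <- total_ll + fb$loglik
      xi_acc <- xi_acc + fb$xi
      pi_acc <- pi_acc + fb$gamma[1L, ]
      for (i in seq_len(N)) {
        g <- fb$gamma[, i]
        sel <- which(g > 0)
        if (!length(sel)) next
        lc <- em$comp[[i]][sel, , drop = FALSE]
        mx <- apply(lc, 1, max)
        post <- exp(lc - mx) / rowSums(exp(lc - mx))
        rw <- post * g[sel]
        Nk[[i]] <- Nk[[i]] + colSums(rw)
        Sx[[i]] <- Sx[[i]] + t(rw) %*% X[sel, , drop = FALSE]
        Sx2[[i]] <- Sx2[[i]] + t(rw) %*% (X[sel, , drop = FALSE]^2)
      }
    }
    ll_hist <- c(ll_hist, total_ll)
    # M step
    A_new <- xi_acc
    A_new[!model$mask] <- 0
    rs <- rowSums(A_new)
    for (i in seq_len(N))
      if (rs[i] > 0) A_new[i, ] <- A_new[i, ] / rs[i]
      else A_new[i, ] <- model$A[i, ]
    model$A <- A_new
    if (sum(pi_acc) > 0) model$pi <- pi_acc / sum(pi_acc)
    for (i in seq_len(N)) {
      tot <- sum(Nk[[i]])
      if (tot <= 1e-10) next
      g <- model$gmms[[i]]
      for (k in seq_along(g$w)) {
        if (Nk[[i]][k] <= 1e-10) next
        g$mu[k, ] <- Sx[[i]][k, ] / Nk[[i]][k]
        g$var[k, ] <- pmax(Sx2[[i]][k, ] / Nk[[i]][k] - g$mu[k, ]^2,
                           st$cov_floor)
      }
      w <- pmax(Nk[[i]] / tot, 1e-8)
      g$w <- w / sum(w)
      model$gmms[[i]] <- g
    }
    if (iter >= 2L) {
      rel <- (ll_hist[iter] - ll_hist[iter - 1L]) /
        max(abs(ll_hist[iter - 1L]), 1e-12)
      if (abs(rel) < st$bw_tol) break
    }
  }
  model$trained <- TRUE
  model$ll_history <- ll_hist
  model
}

#' Viterbi decoding
#'
#' Finds the globally optimal flat state path (log domain) under the
#' flattened two-level transition structure; decoding is unconstrained
#' (labels play no role).
#'
#' @param model a trained [train_bw()] model (an initialized model also
#'   works).
#' @param features transformed feature matrix of one recording (frame-mapping
#'   attributes, if present, are carried along).
#' @return an object of class `hhmm_decoded`: data frame with columns
#'   `frame`, `state`, `substate`, plus attributes `loglik`, `centers`,
#'   `hop`, `sample_rate_hz`.
#' @export
viterbi_decode <- function(model, features) {
  stopifnot(inherits(model, "hhmm_model"))
  if (is.null(dim(features)) || nrow(features) == 0L) {
    out <- data.frame(frame = integer(), state = character(),
                      substate = integer(), stringsAsFactors = FALSE)
    attr(out, "loglik") <- NA_real_
    class(out) <- c("hhmm_decoded", "data.frame")
    return(out)
  }
  em <- emission_logB(model, features, NULL)
  vit <- cpp_viterbi(log_mat(model$A), log_mat(model$pi), em$logB)
  path <- vit$path
  out <- data.frame(frame = seq_along(path),
                    state = model$layout$top_of[path],
                    substate = model$layout$sub_of[path],
                    stringsAsFactors = FALSE)
  attr(out, "loglik") <- vit$loglik
  attr(out, "centers") <- attr(features, "centers")
  attr(out, "hop") <- attr(features, "hop")
  attr(out, "sample_rate_hz") <- attr(features, "sample_rate_hz")
  class(out) <- c("hhmm_decoded", "data.frame")
  out
}

#' Convert a decoded frame sequence to stride intervals
#'
#' Each maximal pass through the stride sub-chain yields one stride: a pass
#' ends when the decoded path leaves the stride state or resets to an earlier
#' sub-state (back-to-back strides). Frame indices are mapped to sample
#' indices at the midpoints between neighboring frame centers, so two
#' back-to-back passes share a border sample. Intervals outside the stride
#' duration bounds are discarded.
#'
#' @param decoded a [viterbi_decode()] result.
#' @param bounds_ms stride duration bounds in ms (default 600 and 2500).
#' @param sample_rate_hz,centers,hop frame-to-sample mapping; taken from
#'   `decoded` attributes when omitted.
#' @return a [stride_detection()] with method `"hhmm"`.
#' @export
decode_to_strides <- function(decoded, bounds_ms = c(600, 2500),
                              sample_rate_hz = attr(decoded, "sample_rate_hz"),
                              centers = attr(decoded, "centers"),
                              hop = attr(decoded, "hop")) {
  if (nrow(decoded) == 0L)
    return(stride_detection("hhmm",
                            intervals = data.frame(start = integer(),
                                                   end = integer()),
                            sample_rate_hz = sample_rate_hz))
  stopifnot(!is.null(centers), !is.null(hop), !is.null(sample_rate_hz))
  is_stride <- decoded$state == "stride"
  sub <- decoded$substate
  n <- nrow(decoded)
  pass_start <- integer(); pass_end <- integer()
  open <- NA_integer_
  for (f in seq_len(n)) {
    if (is_stride[f]) {
      if (is.na(open)) open <- f
      else if (sub[f] < sub[f - 1L]) {      # sub-chain reset: new stride
        pass_start <- c(pass_start, open); pass_end <- c(pass_end, f - 1L)
        open <- f
      }
    } else if (!is.na(open)) {
      pass_start <- c(pass_start, open); pass_end <- c(pass_end, f - 1L)
      open <- NA_integer_
    }
  }
  if (!is.na(open)) {
    pass_start <- c(pass_start, open); pass_end <- c(pass_end, n)
  }
  # frame f's left boundary: midpoint between centers f-1 and f
  left_bound <- function(f)
    if (f == 1L) max(0, centers[1L] - hop / 2) else
      (centers[f - 1L] + centers[f]) / 2
  right_bound <- function(f)
    if (f == n) centers[n] + hop / 2 else (centers[f] + centers[f + 1L]) / 2
  starts <- vapply(pass_start, function(f) floor(left_bound(f) + 0.5),
                   numeric(1))
  ends <- vapply(pass_end, function(f) floor(right_bound(f) + 0.5),
                 numeric(1))
  min_dur <- ms_to_samples(bounds_ms[1], sample_rate_hz)
  max_dur <- ms_to_samples(bounds_ms[2], sample_rate_hz)
  dur <- ends - starts
  keep <- dur > min_dur & dur < max_dur
  stride_detection("hhmm",
                   intervals = data.frame(start = as.integer(starts[keep]),
                                          end = as.integer(ends[keep])),
                   sample_rate_hz = sample_rate_hz)
}

#' Exhaustive grid search
#'
#' Evaluates a scoring function over a list of candidate configurations and
#' returns the best one; ties are broken toward the smaller model.
#'
#' @param grid list of configuration objects (e.g. parameter lists).
#' @param score_fn function(config) -> numeric score to maximize (e.g. mean
#'   validation F-score).
#' @param size_fn optional function(config) -> numeric model size used to
#'   break ties (smaller wins); defaults to the grid position.
#' @return list with `best` (the winning configuration), `index`, and
#'   `scores`.
#' @export
grid_search <- function(grid, score_fn, size_fn = NULL) {
  if (!length(grid)) stop("empty grid", call. = FALSE)
  scores <- vapply(grid, function(g) as.numeric(score_fn(g)), numeric(1))
  sizes <- if (is.null(size_fn)) seq_along(grid)
           else vapply(grid, function(g) as.numeric(size_fn(g)), numeric(1))
  best <- order(-scores, sizes)[1L]
  list(best = grid[[best]], index = best, scores = scores)
}

#' Expand the published hHMM parameter grid
#'
#' @param window_len_s,n_substride,n_gmm,n_pca candidate values (defaults are
#'   the published search ranges).
#' @return list of parameter lists for [grid_search()].
#' @export
hhmm_grid <- function(window_len_s = c(0.1, 0.3, 0.5, 0.7),
                      n_substride = seq(4L, 12L, 2L),
                      n_gmm = seq(8L, 12L, 2L),
                      n_pca = seq(1L, 15L, 2L)) {
  g <- expand.grid(window_len_s = window_len_s, n_substride = n_substride,
                   n_gmm = n_gmm, n_pca = n_pca, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
}

# Total free-parameter count of an hHMM configuration; used as the model
# size for tie-breaking.
hhmm_param_count <- function(cfg, n_states = 3L) {
  nsub <- cfg$n_substride + 3L + 1L   # stride + default transition + rest
  d <- cfg$n_pca
  nsub * cfg$n_gmm * (2L * d + 1L) + nsub^2
}

#' Serialize an hHMM model to structured text (JSON) / read it back
#' @param model an `hhmm_model`.
#' @param path file path.
#' @return `path` (write) or an `hhmm_model` (read).
#' @export
write_hhmm <- function(model, path) {
  ser <- list(
    states = model$layout$states,
    n_substates = as.list(model$layout$ns),
    A = model$A, pi = model$pi, A_top = model$A_top, pi_top = model$pi_top,
    gmms = lapply(model$gmms, function(g)
      list(w = g$w, mu = g$mu, var = g$var)),
    structure = unclass(model$structure),
    transform = if (!is.null(model$transform)) unclass(model$transform),
    fcfg = if (!is.null(model$fcfg)) unclass(model$fcfg),
    trained = model$trained, d = model$d, ll_history = model$ll_history)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hhmm
#' @export
read_hhmm <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nsub <- unlist(x$n_substates)
  st <- do.call(hhmm_structure, c(list(n_substates = nsub),
                                  x$structure[c("n_gmm", "n_pca", "cov_floor",
                                                "max_bw_iterations",
                                                "bw_tol")]))
  layout <- flat_layout(x$states, nsub)
  gmms <- lapply(seq_len(layout$N), function(i) {
    g <- list(w = x$gmms$w[[i]], mu = x$gmms$mu[[i]], var = x$gmms$var[[i]])
    g$mu <- matrix(unlist(g$mu), ncol = x$d)
    g$var <- matrix(unlist(g$var), ncol = x$d)
    g
  })
  tf <- NULL
  if (!is.null(x$transform)) {
    tf <- x$transform
    tf$rotation <- matrix(unlist(tf$rotation), ncol = tf$n_components)
    class(tf) <- "feature_transform"
  }
  fc <- NULL
  if (!is.null(x$fcfg)) { fc <- x$fcfg; class(fc) <- "feature_config" }
  structure(list(layout = layout, mask = flat_mask(layout),
                 A = matrix(unlist(x$A), layout$N, layout$N),
                 pi = x$pi,
                 A_top = matrix(unlist(x$A_top), length(x$states),
                                length(x$states),
                                dimnames = list(x$states, x$states)),
                 pi_top = stats::setNames(x$pi_top, x$states),
                 gmms = gmms, structure = st, transform = tf, fcfg = fc,
                 trained = isTRUE(x$trained), d = x$d,
                 ll_history = x$ll_history %||% numeric()),
            class = "hhmm_model")
}
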