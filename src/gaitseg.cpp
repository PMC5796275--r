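#include <Rcpp.h>
using namespace Rcpp;

// ---- subsequence DTW -------------------------------------------------------

// Accumulated cost matrix for subsequence DTW.
// Row 1 (template start) is free along the sequence: C(1,t) = D(1,t).
// First column accumulates down the template: C(m,1) = sum_{i<=m} D(i,1).
// Elsewhere C(m,t) = D(m,t) + min{C(m-1,t-1), C(m-1,t), C(m,t-1)}.
// [[Rcpp::export]]
NumericMatrix cpp_accumulate_cost(NumericMatrix D) {
  int M = D.nrow(), T = D.ncol();
  NumericMatrix C(M, T);
  for (int t = 0; t < T; ++t) C(0, t) = D(0, t);
  for (int m = 1; m < M; ++m) C(m, 0) = C(m - 1, 0) + D(m, 0);
  for (int t = 1; t < T; ++t) {
    for (int m = 1; m < M; ++m) {
      double best = C(m - 1, t - 1);
      if (C(m - 1, t) < best) best = C(m - 1, t);
      if (C(m, t - 1) < best) best = C(m, t - 1);
      C(m, t) = D(m, t) + best;
    }
  }
  return C;
}

// Backtrack a warping path from (M, end_col) down to row 1.
// Predecessor ties: diagonal, then vertical (m-1, t), then horizontal (m, t-1).
// end_col is 1-based; returns an L x 2 matrix of 1-based (m, t) pairs ordered
// from the path start (row 1) to its end (row M).
// [[Rcpp::export]]
IntegerMatrix cpp_backtrack(NumericMatrix C, int end_col) {
  int M = C.nrow();
  int m = M - 1, t = end_col - 1;
  std::vector<int> ms, ts;
  ms.push_back(m + 1); ts.push_back(t + 1);
  while (m > 0) {
    if (t == 0) {
      --m;
    } else {
      double diag = C(m - 1, t - 1), vert = C(m - 1, t), horiz = C(m, t - 1);
      if (diag <= vert && diag <= horiz) { --m; --t; }
      else if (vert <= horiz) { --m; }
      else { --t; }
    }
    ms.push_back(m + 1); ts.push_back(t + 1);
  }
  int L = (int) ms.size();
  IntegerMatrix path(L, 2);
  for (int i = 0; i < L; ++i) {
    path(L - 1 - i, 0) = ms[i];
    path(L - 1 - i, 1) = ts[i];
  }
  return path;
}

// ---- HMM inference ---------------------------------------------------------

static inline double logsumexp2(const double *v, int n) {
  double mx = R_NegInf;
  for (int i = 0; i < n; ++i) if (v[i] > mx) mx = v[i];
  if (mx == R_NegInf) return R_NegInf;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(v[i] - mx);
  return mx + std::log(s);
}

// Forward-backward in the log domain for a flat HMM.
// logA: N x N log transition, logpi: length N, logB: T x N log emission.
// Returns total log-likelihood, per-frame posteriors gamma (T x N) and the
// summed transition posteriors xi (N x N).
// [[Rcpp::export]]
List cpp_forward_backward(NumericMatrix logA, NumericVector logpi,
                          NumericMatrix logB) {
  int T = logB.nrow(), N = logB.ncol();
  NumericMatrix alpha(T, N), beta(T, N), gamma(T, N);
  NumericMatrix xi(N, N);
  std::vector<double> buf(N);

  for (int j = 0; j < N; ++j) alpha(0, j) = logpi[j] + logB(0, j);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < N; ++j) {
      for (int i = 0; i < N; ++i) buf[i] = alpha(t - 1, i) + logA(i, j);
      alpha(t, j) = logB(t, j) + logsumexp2(buf.data(), N);
    }
  }
  for (int j = 0; j < N; ++j) buf[j] = alpha(T - 1, j);
  double ll = logsumexp2(buf.data(), N);

  for (int j = 0; j < N; ++j) beta(T - 1, j) = 0.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < N; ++i) {
      for (int j = 0; j < N; ++j)
        buf[j] = logA(i, j) + logB(t + 1, j) + beta(t + 1, j);
      beta(t, i) = logsumexp2(buf.data(), N);
    }
  }

  for (int t = 0; t < T; ++t)
    for (int j = 0; j < N; ++j) {
      double g = alpha(t, j) + beta(t, j) - ll;
      gamma(t, j) = (g == R_NegInf) ? 0.0 : std::exp(g);
    }

  if (R_finite(ll)) {
    for (int t = 0; t < T - 1; ++t)
      for (int i = 0; i < N; ++i) {
        if (alpha(t, i) == R_NegInf) continue;
        for (int j = 0; j < N; ++j) {
          double e = alpha(t, i) + logA(i, j) + logB(t + 1, j) +
                     beta(t + 1, j) - ll;
          if (e > R_NegInf) xi(i, j) += std::exp(e);
        }
      }
  }

  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi decoding in the log domain; returns the 1-based optimal state path
// and its log-likelihood.
// [[Rcpp::export]]
List cpp_viterbi(NumericMatrix logA, NumericVector logpi, NumericMatrix logB) {
  int T = logB.nrow(), N = logB.ncol();
  NumericMatrix V(T, N);
  IntegerMatrix back(T, N);
  for (int j = 0; j < N; ++j) V(0, j) = logpi[j] + logB(0, j);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < N; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < N; ++i) {
        double v = V(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      V(t, j) = best + logB(t, j);
      back(t, j) = arg;
    }
  }
  double best = R_NegInf;
  int arg = 0;
  for (int j = 0; j < N; ++j)
    if (V(T - 1, j) > best) { best = V(T - 1, j); arg = j; }
  IntegerVector path(T);
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) path[t - 1] = back(t, path[t]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return List::create(_["path"] = path, _["loglik"] = best);
}
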