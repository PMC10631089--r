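#include <Rcpp.h>
using namespace Rcpp;

// Accumulate the per-window inside counts (row-major: K contiguous
// doubles per window, cache-friendly for the scattered window updates)
// and return the multinomial log likelihood ratio of every window.
// M is the sparse membership pattern (dgCMatrix, windows x regions; the
// stored x values are ignored), X the region x category count matrix.
static void llr_pass(const int *p, const int *ri, int W, int n, int K,
                     const double *X, const double *colTotals, double total,
                     std::vector<double> &A, double *llr) {
  std::fill(A.begin(), A.end(), 0.0);
  for (int j = 0; j < n; ++j) {
    for (int idx = p[j]; idx < p[j + 1]; ++idx) {
      double *aw = &A[(size_t)ri[idx] * K];
      for (int k = 0; k < K; ++k) aw[k] += X[j + (size_t)n * k];
    }
  }
  double nullterm = -total * std::log(total);
  for (int k = 0; k < K; ++k)
    if (colTotals[k] > 0) nullterm += colTotals[k] * std::log(colTotals[k]);
  for (int w = 0; w < W; ++w) {
    const double *aw = &A[(size_t)w * K];
    double Aw = 0.0, s = 0.0;
    for (int k = 0; k < K; ++k) {
      const double a = aw[k], b = colTotals[k] - a;
      Aw += a;
      if (a > 0) s += a * std::log(a);
      if (b > 0) s += b * std::log(b);
    }
    const double B = total - Aw;
    if (Aw == 0 || B == 0) { llr[w] = 0.0; continue; }
    s -= Aw * std::log(Aw) + B * std::log(B);
    const double v = s - nullterm;
    llr[w] = v > 0 ? v : 0.0;
  }
}

// Windows covering no or all cases score 0; results are clamped at 0
// against rounding.
// [[Rcpp::export]]
NumericVector cpp_llr_windows(S4 M, NumericMatrix X,
                              NumericVector colTotals, double total) {
  IntegerVector p = M.slot("p"), ri = M.slot("i");
  IntegerVector dim = M.slot("Dim");
  const int W = dim[0], n = dim[1], K = X.ncol();
  if (X.nrow() != n) stop("membership matrix and count matrix disagree");
  std::vector<double> A((size_t)W * K);
  NumericVector llr(W);
  llr_pass(p.begin(), ri.begin(), W, n, K, X.begin(), colTotals.begin(),
           total, A, REAL(llr));
  return llr;
}

// Maximum llr over all windows for each null replicate table (the tables
// share the margins of the observed data).
// [[Rcpp::export]]
NumericVector cpp_null_max(S4 M, List tables, NumericVector colTotals,
                           double total) {
  IntegerVector p = M.slot("p"), ri = M.slot("i");
  IntegerVector dim = M.slot("Dim");
  const int W = dim[0], n = dim[1], K = colTotals.size();
  const int R = tables.size();
  std::vector<double> A((size_t)W * K), llr(W), Xd((size_t)n * K);
  NumericVector out(R);
  for (int r = 0; r < R; ++r) {
    IntegerMatrix tab = tables[r];
    if (tab.nrow() != n || tab.ncol() != K) stop("null table has wrong shape");
    for (size_t t = 0; t < Xd.size(); ++t) Xd[t] = tab[t];
    llr_pass(p.begin(), ri.begin(), W, n, K, Xd.data(), colTotals.begin(),
             total, A, llr.data());
    out[r] = *std::max_element(llr.begin(), llr.end());
  }
  return out;
}

// Greedy non-overlap ranking: ord lists candidate window indices (1-based,
// best first); a window survives iff its region set is disjoint from every
// earlier survivor. Returns surviving indices in rank order.
// [[Rcpp::export]]
IntegerVector cpp_greedy_nonoverlap(List sets, IntegerVector ord, int n) {
  std::vector<bool> occupied(n + 1, false);
  std::vector<int> kept;
  for (int t = 0; t < ord.size(); ++t) {
    const int w = ord[t];
    IntegerVector s = sets[w - 1];
    bool clash = false;
    for (int j = 0; j < s.size(); ++j)
      if (occupied[s[j]]) { clash = true; break; }
    if (clash) continue;
    for (int j = 0; j < s.size(); ++j) occupied[s[j]] = true;
    kept.push_back(w);
  }
  return wrap(kept);
}
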