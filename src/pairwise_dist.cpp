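#include <Rcpp.h>
using namespace Rcpp;

// Pairwise mean absolute difference between patient rows over jointly
// observed columns; NA where two rows share no observed column. Used for
// the within-test KNN-imputation neighbour search.
// [[Rcpp::export]]
NumericMatrix pairwise_mean_abs_diff(NumericMatrix x) {
  int n = x.nrow(), d = x.ncol();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 0.0;
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0; int m = 0;
      for (int k = 0; k < d; ++k) {
        double a = x(i, k), b = x(j, k);
        if (!NumericMatrix::is_na(a) && !NumericMatrix::is_na(b)) {
          s += std::abs(a - b);
          ++m;
        }
      }
      double v = (m > 0) ? s / m : NA_REAL;
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}

// Fill missing entries of one day-column by the mean of the k nearest
// observed patients (finite distance required); fallback when none.
// [[Rcpp::export]]
NumericVector knn_col_fill(NumericMatrix dist, NumericVector col,
                           double fallback, int k) {
  int n = col.size();
  NumericVector out = clone(col);
  std::vector<int> have;
  for (int i = 0; i < n; ++i)
    if (!NumericVector::is_na(col[i])) have.push_back(i);
  for (int i = 0; i < n; ++i) {
    if (!NumericVector::is_na(col[i])) continue;
    std::vector<std::pair<double,int> > cand;
    for (size_t h = 0; h < have.size(); ++h) {
      double d = dist(i, have[h]);
      if (!NumericMatrix::is_na(d)) cand.push_back(std::make_pair(d, have[h]));
    }
    if (cand.empty()) { out[i] = fallback; continue; }
    int kk = std::min((int)cand.size(), k);
    std::partial_sort(cand.begin(), cand.begin() + kk, cand.end());
    double s = 0.0;
    for (int j = 0; j < kk; ++j) s += col[cand[j].second];
    out[i] = s / kk;
  }
  return out;
}
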