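#include <Rcpp.h>
using namespace Rcpp;

// Mutual information (bits) of every column of X with a reference vector s.
// X and s hold 0-based discrete codes; bx and bs bound the code ranges.
// [[Rcpp::export]]
NumericVector mi_columns(IntegerMatrix X, IntegerVector s, int bx, int bs) {
  const int n = X.nrow(), p = X.ncol();
  if (s.size() != n) stop("length mismatch between matrix rows and reference vector");
  std::vector<double> ps(bs, 0.0);
  for (int i = 0; i < n; ++i) ps[s[i]] += 1.0;
  for (int b = 0; b < bs; ++b) ps[b] /= n;

  NumericVector out(p);
  std::vector<double> joint(bx * bs), px(bx);
  const double log2e = std::log(2.0);
  for (int j = 0; j < p; ++j) {
    std::fill(joint.begin(), joint.end(), 0.0);
    std::fill(px.begin(), px.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      int xv = X(i, j);
      joint[xv * bs + s[i]] += 1.0;
      px[xv] += 1.0;
    }
    double mi = 0.0;
    for (int a = 0; a < bx; ++a) {
      if (px[a] == 0.0) continue;
      const double pa = px[a] / n;
      for (int b = 0; b < bs; ++b) {
        const double pab = joint[a * bs + b] / n;
        if (pab > 0.0) mi += pab * std::log(pab / (pa * ps[b])) / log2e;
      }
    }
    out[j] = mi;
  }
  return out;
}
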