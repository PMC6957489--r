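#include <Rcpp.h>
using namespace Rcpp;

// Assign each sample to a discrete level index (1-based) by nearest level,
// with hysteresis: a transition from the current level to a new one is taken
// only when the sample crosses the midpoint between the two levels by an
// extra `hysteresis_frac` of the inter-level gap toward the new level.
// [[Rcpp::export]]
IntegerVector assign_levels_hysteresis(NumericVector x, NumericVector levels,
                                       double hysteresis_frac) {
  const int n = x.size();
  const int m = levels.size();
  IntegerVector out(n);
  if (n == 0 || m == 0) return out;

  int cur = 0;
  double best = std::abs(x[0] - levels[0]);
  for (int j = 1; j < m; ++j) {
    double d = std::abs(x[0] - levels[j]);
    if (d < best) { best = d; cur = j; }
  }
  out[0] = cur + 1;

  for (int i = 1; i < n; ++i) {
    int cand = 0;
    double bd = std::abs(x[i] - levels[0]);
    for (int j = 1; j < m; ++j) {
      double d = std::abs(x[i] - levels[j]);
      if (d < bd) { bd = d; cand = j; }
    }
    if (cand != cur) {
      double gap = levels[cand] - levels[cur];
      double thr = levels[cur] + (0.5 + hysteresis_frac) * gap;
      bool cross = (gap > 0) ? (x[i] >= thr) : (x[i] <= thr);
      if (cross) cur = cand;
    }
    out[i] = cur + 1;
  }
  return out;
}
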