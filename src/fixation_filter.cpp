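#include <Rcpp.h>
using namespace Rcpp;

// Velocity-threshold fixation detection core. Stages (documented on the R
// side in detect_fixations): two-window velocity classification, distance-
// bounded boundary assignment, centroid-distance merging across short
// invalid gaps, minimum-duration pruning. Long-double prefix sums keep the
// window means numerically close to R's mean().
// [[Rcpp::export]]
NumericMatrix detect_fixations_cpp(NumericVector t, NumericVector x,
                                   NumericVector y, LogicalVector ok,
                                   int window, double velocity_threshold,
                                   double distance_threshold,
                                   int min_duration) {
  int n = t.size();
  NumericMatrix empty(0, 5);
  if (n == 0) return empty;

  std::vector<long double> cx(n + 1, 0.0L), cy(n + 1, 0.0L);
  std::vector<int> cn(n + 1, 0), cinv(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    bool o = ok[i];
    cx[i + 1] = cx[i] + (o ? (long double)x[i] : 0.0L);
    cy[i + 1] = cy[i] + (o ? (long double)y[i] : 0.0L);
    cn[i + 1] = cn[i] + (o ? 1 : 0);
    cinv[i + 1] = cinv[i] + (o ? 0 : 1);
  }

  // stage 1: core samples with defined two-window velocity below threshold
  std::vector<char> core(n, 0);
  bool any_core = false;
  for (int i = window; i <= n - window; ++i) {  // 0-based sample index i
    if (cn[i] - cn[i - window] != window) continue;
    if (cn[i + window] - cn[i] != window) continue;
    long double bx = (cx[i] - cx[i - window]) / window;
    long double by = (cy[i] - cy[i - window]) / window;
    long double ax = (cx[i + window] - cx[i]) / window;
    long double ay = (cy[i + window] - cy[i]) / window;
    double v = std::sqrt((double)((ax - bx) * (ax - bx) + (ay - by) * (ay - by)));
    if (v < velocity_threshold) { core[i] = 1; any_core = true; }
  }
  if (!any_core) return empty;

  // core runs
  std::vector<int> run_s, run_e;
  int i = 0;
  while (i < n) {
    if (!core[i]) { ++i; continue; }
    int s = i;
    while (i < n && core[i]) ++i;
    run_s.push_back(s);
    run_e.push_back(i - 1);
  }
  int k = (int)run_s.size();
  double dt2 = distance_threshold * distance_threshold;

  // stage 2: distance-bounded boundary assignment (fixed core centroid;
  // backward first, never crossing the previous run's extended samples)
  std::vector<int> ext_s(k), ext_e(k);
  for (int j = 0; j < k; ++j) {
    int s = run_s[j], e = run_e[j];
    double ccx = (double)((cx[e + 1] - cx[s]) / (e - s + 1));
    double ccy = (double)((cy[e + 1] - cy[s]) / (e - s + 1));
    int lower = (j > 0) ? ext_e[j - 1] + 1 : 0;
    int p = s - 1;
    while (p >= lower && ok[p] &&
           (x[p] - ccx) * (x[p] - ccx) + (y[p] - ccy) * (y[p] - ccy) < dt2)
      --p;
    ext_s[j] = p + 1;
    int upper = (j < k - 1) ? run_s[j + 1] - 1 : n - 1;
    p = e + 1;
    while (p <= upper && ok[p] &&
           (x[p] - ccx) * (x[p] - ccx) + (y[p] - ccy) * (y[p] - ccy) < dt2)
      ++p;
    ext_e[j] = p - 1;
  }

  // stage 3: merge consecutive candidates when centroids are close and the
  // gap holds fewer than `window` invalid samples; members of a merged
  // fixation are the union of the candidates' samples (gap excluded)
  struct Cand {
    long double sx, sy;
    int count, first, last;
  };
  std::vector<Cand> merged;
  Cand cur;
  cur.sx = cx[ext_e[0] + 1] - cx[ext_s[0]];
  cur.sy = cy[ext_e[0] + 1] - cy[ext_s[0]];
  cur.count = ext_e[0] - ext_s[0] + 1;
  cur.first = ext_s[0];
  cur.last = ext_e[0];
  for (int j = 1; j < k; ++j) {
    long double nsx = cx[ext_e[j] + 1] - cx[ext_s[j]];
    long double nsy = cy[ext_e[j] + 1] - cy[ext_s[j]];
    int ncount = ext_e[j] - ext_s[j] + 1;
    int n_invalid = cinv[ext_s[j]] - cinv[cur.last + 1];
    double d2x = (double)(cur.sx / cur.count - nsx / ncount);
    double d2y = (double)(cur.sy / cur.count - nsy / ncount);
    if (d2x * d2x + d2y * d2y < dt2 && n_invalid < window) {
      cur.sx += nsx;
      cur.sy += nsy;
      cur.count += ncount;
      cur.last = ext_e[j];
    } else {
      merged.push_back(cur);
      cur.sx = nsx; cur.sy = nsy; cur.count = ncount;
      cur.first = ext_s[j]; cur.last = ext_e[j];
    }
  }
  merged.push_back(cur);

  // stage 4: minimum duration
  int m = 0;
  for (size_t j = 0; j < merged.size(); ++j)
    if (merged[j].count >= min_duration) ++m;
  NumericMatrix out(m, 5);
  int r = 0;
  for (size_t j = 0; j < merged.size(); ++j) {
    if (merged[j].count < min_duration) continue;
    out(r, 0) = t[merged[j].first];
    out(r, 1) = t[merged[j].last];
    out(r, 2) = (double)(merged[j].sx / merged[j].count);
    out(r, 3) = (double)(merged[j].sy / merged[j].count);
    out(r, 4) = merged[j].count;
    ++r;
  }
  return out;
}
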