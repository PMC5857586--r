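#include <Rcpp.h>
using namespace Rcpp;

// Sequential inter-sample step rejection. A present value is rejected when
// its absolute difference from the previous *retained* value exceeds
// max_step; a rejected value never becomes the reference, so an isolated
// spike does not cascade rejections. The first present value is retained.
// [[Rcpp::export]]
LogicalVector step_reject_cpp(NumericVector x, double max_step) {
  int n = x.size();
  LogicalVector keep(n);
  double last = 0.0;
  bool have = false;
  for (int i = 0; i < n; ++i) {
    if (NumericVector::is_na(x[i])) {
      keep[i] = false;
      continue;
    }
    if (!have || std::abs(x[i] - last) <= max_step) {
      keep[i] = true;
      last = x[i];
      have = true;
    } else {
      keep[i] = false;
    }
  }
  return keep;
}

// Linear interpolation of interior missing runs shorter than max_gap
// samples; longer runs and runs touching either edge stay missing.
// [[Rcpp::export]]
NumericVector interpolate_gaps_cpp(NumericVector x, int max_gap) {
  int n = x.size();
  NumericVector out = clone(x);
  int i = 0;
  while (i < n) {
    if (!NumericVector::is_na(out[i])) {
      ++i;
      continue;
    }
    int s = i;
    while (i < n && NumericVector::is_na(out[i])) ++i;
    int e = i - 1;
    int len = e - s + 1;
    if (s > 0 && e < n - 1 && len < max_gap) {
      double L = out[s - 1], R = out[e + 1];
      for (int j = 0; j < len; ++j)
        out[s + j] = L + (R - L) * (j + 1) / (len + 1);
    }
  }
  return out;
}

// Moving average with an asymmetric window of `back` samples before and
// `fwd` samples after the current one, truncated at the edges of each
// contiguous non-missing segment; output is missing where input is missing.
// [[Rcpp::export]]
NumericVector moving_average_cpp(NumericVector x, int back, int fwd) {
  int n = x.size();
  NumericVector out(n, NA_REAL);
  int i = 0;
  while (i < n) {
    if (NumericVector::is_na(x[i])) {
      ++i;
      continue;
    }
    int s = i;
    while (i < n && !NumericVector::is_na(x[i])) ++i;
    int e = i - 1;  // segment [s, e]
    int len = e - s + 1;
    std::vector<double> cs(len + 1, 0.0);
    for (int j = 0; j < len; ++j) cs[j + 1] = cs[j] + x[s + j];
    for (int j = s; j <= e; ++j) {
      int a = std::max(s, j - back);
      int b = std::min(e, j + fwd);
      out[j] = (cs[b - s + 1] - cs[a - s]) / (b - a + 1);
    }
  }
  return out;
}
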