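#include <Rcpp.h>
using namespace Rcpp;

// Topographic prominence of candidate local maxima: walk outwards from
// each candidate until a strictly higher sample (or the signal edge),
// tracking the lowest sample met on each side; the prominence is the
// peak height minus the higher of the two side minima.
// [[Rcpp::export(name = ".peakProminences")]]
NumericVector peak_prominences(NumericVector x, IntegerVector cand) {
  const int n = x.size();
  NumericVector out(cand.size());
  for (int c = 0; c < cand.size(); ++c) {
    const int i = cand[c] - 1;  // 1-based from R
    const double v = x[i];
    double lmin = v;
    for (int j = i; j > 0 && x[j] <= v;) {
      --j;
      if (x[j] < lmin) lmin = x[j];
    }
    double rmin = v;
    for (int j = i; j < n - 1 && x[j] <= v;) {
      ++j;
      if (x[j] < rmin) rmin = x[j];
    }
    out[c] = v - std::max(lmin, rmin);
  }
  return out;
}
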