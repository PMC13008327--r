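#include <Rcpp.h>
using namespace Rcpp;

static double nth_median(std::vector<double> &w) {
  const int m = w.size();
  std::nth_element(w.begin(), w.begin() + m / 2, w.end());
  double md = w[m / 2];
  if (m % 2 == 0) {
    std::nth_element(w.begin(), w.begin() + m / 2 - 1, w.begin() + m / 2);
    md = (md + w[m / 2 - 1]) / 2.0;
  }
  return md;
}

// Rolling Hampel statistics: for each position i, the median of the centred
// window of half-width k/2 (shrunk at the edges) and the median absolute
// deviation of the window samples from that same window median.
// [[Rcpp::export]]
List rolling_med_mad(NumericVector x, int k) {
  const int n = x.size(), half = k / 2;
  NumericVector med(n), mad(n);
  std::vector<double> w;
  w.reserve(k);
  for (int i = 0; i < n; ++i) {
    const int lo = std::max(0, i - half), hi = std::min(n - 1, i + half);
    w.assign(x.begin() + lo, x.begin() + hi + 1);
    const double md = nth_median(w);
    med[i] = md;
    for (size_t j = 0; j < w.size(); ++j) w[j] = std::fabs(x[lo + j] - md);
    mad[i] = nth_median(w);
  }
  return List::create(_["med"] = med, _["mad"] = mad);
}
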