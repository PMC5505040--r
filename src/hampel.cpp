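#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Sliding-window Hampel outlier replacement.
// Window at index i is [i - h_i, i + h_i] with h_i = min(half_window, i,
// n - 1 - i): edge windows are truncated symmetrically so the centre
// sample stays the window median's centre. A sample is replaced by its
// window median when its absolute deviation strictly exceeds
// n_sigmas * 1.4826 * MAD; the strict inequality keeps samples equal to
// the median (flat segments) while still flagging a lone impulse in an
// otherwise constant window (MAD == 0, deviation > 0).

static double window_median(std::vector<double>& buf) {
  size_t m = buf.size() / 2;
  std::nth_element(buf.begin(), buf.begin() + m, buf.end());
  double med = buf[m];
  if (buf.size() % 2 == 0) {
    std::nth_element(buf.begin(), buf.begin() + m - 1, buf.begin() + m);
    med = 0.5 * (med + buf[m - 1]);
  }
  return med;
}

// [[Rcpp::export(name = ".hampel_cpp")]]
Rcpp::NumericVector hampel_cpp(Rcpp::NumericVector x, int half_window,
                               double n_sigmas) {
  const int n = x.size();
  Rcpp::NumericVector out(Rcpp::clone(x));
  std::vector<double> buf, dev;
  const double k = 1.4826;
  for (int i = 0; i < n; ++i) {
    int h = std::min({half_window, i, n - 1 - i});
    int lo = i - h, hi = i + h;
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    double med = window_median(buf);
    dev.resize(buf.size());
    for (size_t j = 0; j < buf.size(); ++j)
      dev[j] = std::abs(x[lo + (int)j] - med);
    double mad = window_median(dev);
    if (std::abs(x[i] - med) > n_sigmas * k * mad)
      out[i] = med;
  }
  return out;
}
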