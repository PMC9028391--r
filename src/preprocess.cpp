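#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// LLS operator used by SNIP: compresses dynamic range so peaks do not
// dominate the clipping estimate.
static inline double lls(double y) {
  return std::log(std::log(std::sqrt(y + 1.0) + 1.0) + 1.0);
}
static inline double lls_inv(double v) {
  double e1 = std::exp(v) - 1.0;
  double e2 = std::exp(e1) - 1.0;
  return e2 * e2 - 1.0;
}

static void snip_row(std::vector<double>& v, std::vector<double>& w, int iters) {
  int n = (int)v.size();
  for (int m = 1; m <= iters; ++m) {
    if (2 * m >= n) break;
    for (int j = m; j < n - m; ++j) {
      double avg = 0.5 * (v[j - m] + v[j + m]);
      w[j] = avg < v[j] ? avg : v[j];
    }
    for (int j = m; j < n - m; ++j) v[j] = w[j];
  }
}

// Savitzky-Golay smoothing + SNIP baseline subtraction + optional TIC
// normalization, applied row-wise. Rows are pixel spectra on a shared
// m/z grid. Returns the processed matrix and the per-row TIC (total ion
// current before normalization, after baseline subtraction).
// [[Rcpp::export]]
List cpp_preprocess(NumericMatrix X, NumericVector sg_coef, int snip_iters,
                    bool tic_normalize) {
  int nr = X.nrow(), nc = X.ncol();
  int w = sg_coef.size();
  int h = (w - 1) / 2;
  NumericMatrix out(nr, nc);
  NumericVector tic(nr);
  std::vector<double> y(nc), s(nc), v(nc), tmp(nc);

  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) y[j] = X(i, j);
    // smoothing; window shrinks implicitly at the edges (raw values kept)
    for (int j = 0; j < nc; ++j) {
      if (j < h || j >= nc - h) { s[j] = y[j]; continue; }
      double acc = 0.0;
      for (int k = -h; k <= h; ++k) acc += sg_coef[k + h] * y[j + k];
      s[j] = acc;
    }
    for (int j = 0; j < nc; ++j) if (s[j] < 0.0) s[j] = 0.0;
    // SNIP baseline on LLS-transformed intensities
    for (int j = 0; j < nc; ++j) { v[j] = lls(s[j]); tmp[j] = v[j]; }
    snip_row(v, tmp, snip_iters);
    double sum = 0.0;
    for (int j = 0; j < nc; ++j) {
      double r = s[j] - lls_inv(v[j]);
      if (r < 0.0) r = 0.0;
      out(i, j) = r;
      sum += r;
    }
    tic[i] = sum;
    if (tic_normalize && sum > 0.0) {
      for (int j = 0; j < nc; ++j) out(i, j) /= sum;
    }
  }
  return List::create(_["intensity"] = out, _["tic"] = tic);
}

static double mad_noise(std::vector<double> x) {
  size_t n = x.size();
  if (n == 0) return 0.0;
  std::vector<double> tmp(x);
  std::nth_element(tmp.begin(), tmp.begin() + n / 2, tmp.end());
  double med = tmp[n / 2];
  if (n % 2 == 0) {
    std::nth_element(tmp.begin(), tmp.begin() + n / 2 - 1, tmp.end());
    med = 0.5 * (med + tmp[n / 2 - 1]);
  }
  for (size_t j = 0; j < n; ++j) tmp[j] = std::fabs(x[j] - med);
  std::nth_element(tmp.begin(), tmp.begin() + n / 2, tmp.end());
  double m = tmp[n / 2];
  if (n % 2 == 0) {
    std::nth_element(tmp.begin(), tmp.begin() + n / 2 - 1, tmp.end());
    m = 0.5 * (m + tmp[n / 2 - 1]);
  }
  return 1.4826 * m;
}

// Local-maximum peak picking with an SNR filter; the noise level is the
// median absolute deviation of the whole (processed) spectrum. Returns,
// per row, a two-column matrix: 1-based grid index and intensity.
// [[Rcpp::export]]
List cpp_pick_peaks(NumericMatrix X, double snr_threshold) {
  int nr = X.nrow(), nc = X.ncol();
  List res(nr);
  std::vector<double> y(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) y[j] = X(i, j);
    double noise = mad_noise(y);
    std::vector<int> idx;
    std::vector<double> val;
    for (int j = 1; j < nc - 1; ++j) {
      if (y[j] <= 0.0) continue;
      if (y[j] > y[j - 1] && y[j] > y[j + 1]) {
        bool pass = noise > 0.0 ? (y[j] / noise >= snr_threshold)
                                : !std::isinf(snr_threshold);
        if (pass) { idx.push_back(j + 1); val.push_back(y[j]); }
      }
    }
    IntegerVector iv(idx.begin(), idx.end());
    NumericVector vv(val.begin(), val.end());
    res[i] = List::create(_["index"] = iv, _["intensity"] = vv);
  }
  return res;
}
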