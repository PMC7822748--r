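#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Per-pixel statistics over consecutive non-overlapping gate-frame blocks of a
// (H, W, T) stack. The final block may be partial and uses the frames it has.
// Median of an even-sized window is the mean of the two central order
// statistics. Returns an npix x G matrix (pixels in column-major plane order).
// [[Rcpp::export]]
NumericMatrix cpp_grouped_stat(NumericVector stack, int H, int W, int T,
                               int gate, bool median) {
  const R_xlen_t plane = (R_xlen_t)H * W;
  const int G = (T + gate - 1) / gate;
  NumericMatrix out(plane, G);
  const double* dat = REAL(stack);
  std::vector<double> buf(gate);
  for (R_xlen_t p = 0; p < plane; ++p) {
    for (int g = 0; g < G; ++g) {
      const int t0 = g * gate;
      const int t1 = std::min(T, t0 + gate);
      const int m = t1 - t0;
      if (median) {
        for (int t = t0; t < t1; ++t) buf[t - t0] = dat[(R_xlen_t)t * plane + p];
        const int h = m / 2;
        std::nth_element(buf.begin(), buf.begin() + h, buf.begin() + m);
        double med = buf[h];
        if (m % 2 == 0) {
          med = 0.5 * (med + *std::max_element(buf.begin(), buf.begin() + h));
        }
        out(p, g) = med;
      } else {
        double s = 0.0;
        for (int t = t0; t < t1; ++t) s += dat[(R_xlen_t)t * plane + p];
        out(p, g) = s / m;
      }
    }
  }
  return out;
}

// In-place clamp at zero.
// [[Rcpp::export]]
void cpp_clamp0_inplace(NumericVector x) {
  double* p = REAL(x);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) if (p[i] < 0.0) p[i] = 0.0;
}

// Elementwise a - b with optional clamping at zero.
// [[Rcpp::export]]
NumericVector cpp_subtract(NumericVector a, NumericVector b, bool clamp) {
  const R_xlen_t n = a.size();
  NumericVector out(no_init(n));
  const double* pa = REAL(a); const double* pb = REAL(b); double* po = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double v = pa[i] - pb[i];
    po[i] = (clamp && v < 0.0) ? 0.0 : v;
  }
  return out;
}
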