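#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-state blinking: OFF -> ON with probability pOn per frame, ON dwell is
// geometric with mean meanOn frames. Emitters start in the stationary state
// distribution so the per-frame event density is at target from frame 1.
// Photons per on-frame are lognormal(meanlog, sdlog).
// Returns a matrix with columns (frame, x, y, photons); frame is 1-based.
// [[Rcpp::export]]
NumericMatrix cpp_simulate_blinking(NumericVector ex, NumericVector ey,
                                    int n_frames, double p_on, double mean_on,
                                    double meanlog, double sdlog) {
  const int n = ex.size();
  const double p_off = 1.0 / mean_on;           // ON -> OFF per frame
  const double pi_on = p_on / (p_on + p_off);   // stationary P(on)
  std::vector<double> rf, rx, ry, rp;
  rf.reserve(1024); rx.reserve(1024); ry.reserve(1024); rp.reserve(1024);
  for (int i = 0; i < n; ++i) {
    bool on = unif_rand() < pi_on;
    for (int t = 1; t <= n_frames; ++t) {
      if (!on) {
        if (unif_rand() < p_on) on = true;
      } else {
        // dwell continues with prob 1 - p_off (checked after emitting below)
      }
      if (on) {
        double ph = std::exp(meanlog + sdlog * norm_rand());
        rf.push_back((double)t); rx.push_back(ex[i]); ry.push_back(ey[i]);
        rp.push_back(ph);
        if (unif_rand() < p_off) on = false;
      }
    }
  }
  const int m = rf.size();
  NumericMatrix out(m, 4);
  for (int k = 0; k < m; ++k) {
    out(k, 0) = rf[k]; out(k, 1) = rx[k]; out(k, 2) = ry[k]; out(k, 3) = rp[k];
  }
  colnames(out) = CharacterVector::create("frame", "x", "y", "photons");
  return out;
}

static inline double pixint(double edge0, double edge1, double mu, double s) {
  const double is = 1.0 / (s * M_SQRT2);
  return 0.5 * (std::erf((edge1 - mu) * is) - std::erf((edge0 - mu) * is));
}

// Add integrated 2-D Gaussians into a (H, W, T) array of expected counts.
// Positions in nm; pixel (row r, col c) covers x in [c, c+1)*px_nm,
// y in [r, r+1)*px_nm. Events are truncated at +-4.5 sigma.
// [[Rcpp::export]]
void cpp_render_events(NumericVector stack, int H, int W, int T,
                       IntegerVector frame, NumericVector x, NumericVector y,
                       NumericVector photons, double sigma_nm, double px_nm) {
  const double s = sigma_nm / px_nm;
  const int halo = (int)std::ceil(4.5 * s);
  double* dat = REAL(stack);
  const R_xlen_t plane = (R_xlen_t)H * W;
  for (int k = 0; k < frame.size(); ++k) {
    const int t = frame[k] - 1;
    if (t < 0 || t >= T) continue;
    const double cx = x[k] / px_nm, cy = y[k] / px_nm;
    const int c0 = std::max(0, (int)std::floor(cx) - halo);
    const int c1 = std::min(W - 1, (int)std::floor(cx) + halo);
    const int r0 = std::max(0, (int)std::floor(cy) - halo);
    const int r1 = std::min(H - 1, (int)std::floor(cy) + halo);
    double* pl = dat + t * plane;
    for (int c = c0; c <= c1; ++c) {
      const double fx = pixint(c, c + 1, cx, s) * photons[k];
      for (int r = r0; r <= r1; ++r) {
        pl[r + (R_xlen_t)H * c] += fx * pixint(r, r + 1, cy, s);
      }
    }
  }
}

// In-place Poisson draw on an array of expectations.
// [[Rcpp::export]]
void cpp_poisson_inplace(NumericVector x) {
  double* p = REAL(x);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) p[i] = R::rpois(p[i]);
}
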