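#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// --- a-trous B-spline wavelet decomposition -------------------------------
// Separable kernel [1 4 6 4 1]/16; level 2 uses the same kernel dilated with
// holes. Replicate padding at the borders.

static void conv_sep(const std::vector<double>& in, std::vector<double>& out,
                     int H, int W, int step) {
  static const double k[5] = {1.0/16, 4.0/16, 6.0/16, 4.0/16, 1.0/16};
  std::vector<double> tmp((size_t)H * W);
  // rows (vertical)
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double s = 0.0;
      for (int j = -2; j <= 2; ++j) {
        int rr = r + j * step;
        if (rr < 0) rr = 0; else if (rr >= H) rr = H - 1;
        s += k[j + 2] * in[rr + (size_t)H * c];
      }
      tmp[r + (size_t)H * c] = s;
    }
  }
  // cols (horizontal)
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double s = 0.0;
      for (int j = -2; j <= 2; ++j) {
        int cc = c + j * step;
        if (cc < 0) cc = 0; else if (cc >= W) cc = W - 1;
        s += k[j + 2] * tmp[r + (size_t)H * cc];
      }
      out[r + (size_t)H * c] = s;
    }
  }
}

// Returns list(candidates = m x 2 matrix of 0-based (row, col), threshold,
// sd1). Candidates are 8-connected local maxima of the second wavelet plane
// exceeding threshold_mult * SD(first wavelet plane); on plateaus the lowest
// (row, col) in scan order wins. A 'margin'-pixel border is excluded.
// [[Rcpp::export]]
List cpp_wavelet_detect(NumericMatrix frame, double threshold_mult, int margin) {
  const int H = frame.nrow(), W = frame.ncol();
  if (H < 5 || W < 5) stop("frame smaller than the wavelet kernel support");
  std::vector<double> I(REAL(frame), REAL(frame) + (size_t)H * W);
  std::vector<double> V1((size_t)H * W), V2((size_t)H * W);
  conv_sep(I, V1, H, W, 1);
  conv_sep(V1, V2, H, W, 2);
  // W1 = I - V1 ; W2 = V1 - V2
  double mean1 = 0.0, ss1 = 0.0;
  const size_t n = (size_t)H * W;
  for (size_t i = 0; i < n; ++i) { mean1 += I[i] - V1[i]; }
  mean1 /= n;
  for (size_t i = 0; i < n; ++i) {
    const double d = (I[i] - V1[i]) - mean1; ss1 += d * d;
  }
  const double sd1 = std::sqrt(ss1 / n);
  const double thr = threshold_mult * sd1;
  std::vector<int> rows, cols;
  for (int c = margin; c < W - margin; ++c) {
    for (int r = margin; r < H - margin; ++r) {
      const double v = V1[r + (size_t)H * c] - V2[r + (size_t)H * c];
      if (!(v > thr)) continue;
      bool ismax = true;
      for (int dc = -1; dc <= 1 && ismax; ++dc) {
        for (int dr = -1; dr <= 1; ++dr) {
          if (dr == 0 && dc == 0) continue;
          const int rr = r + dr, cc = c + dc;
          const double u = V1[rr + (size_t)H * cc] - V2[rr + (size_t)H * cc];
          const bool earlier = (cc < c) || (cc == c && rr < r);
          if (u > v || (u == v && earlier)) { ismax = false; break; }
        }
      }
      if (ismax) { rows.push_back(r); cols.push_back(c); }
    }
  }
  IntegerMatrix cand(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) { cand(i,0) = rows[i]; cand(i,1) = cols[i]; }
  return List::create(_["candidates"] = cand, _["threshold"] = thr,
                      _["sd1"] = sd1);
}

// --- integrated-Gaussian Poisson MLE --------------------------------------

static inline double pixint(double e0, double e1, double mu, double s) {
  const double is = 1.0 / (s * M_SQRT2);
  return 0.5 * (std::erf((e1 - mu) * is) - std::erf((e0 - mu) * is));
}
static inline double dpix_dmu(double e0, double e1, double mu, double s) {
  const double is = 1.0 / (s * M_SQRT2);
  const double a = (e0 - mu) * is, b = (e1 - mu) * is;
  return (std::exp(-a * a) - std::exp(-b * b)) / (s * std::sqrt(2.0 * M_PI));
}
static inline double dpix_ds(double e0, double e1, double mu, double s) {
  const double is = 1.0 / (s * M_SQRT2);
  const double a = (e0 - mu), b = (e1 - mu);
  const double c = 1.0 / (s * s * std::sqrt(2.0 * M_PI));
  return (a * std::exp(-a * a * is * is) - b * std::exp(-b * b * is * is)) * c;
}

// Fit model mu_rc = b + N * Ex(c) * Ey(r) by Poisson maximum likelihood with
// Fisher scoring and step halving. Window is (2R+1)^2 around each candidate;
// candidates without a full window are dropped. Returns one row per fit:
// (x_px, y_px, N, b, sigma_px, converged, loglik_improve).
// [[Rcpp::export]]
NumericMatrix cpp_fit_spots(NumericMatrix frame, IntegerMatrix cand, int R,
                            double sigma0_px, int maxit, double tol) {
  const int H = frame.nrow(), W = frame.ncol();
  const int L = 2 * R + 1;
  std::vector<double> d((size_t)L * L);
  std::vector<double> Ex(L), Ey(L), dEx(L), dEy(L), sEx(L), sEy(L);
  const int ncand = cand.nrow();
  NumericMatrix out(ncand, 7);
  int nout = 0;
  for (int k = 0; k < ncand; ++k) {
    const int r0 = cand(k, 0), c0 = cand(k, 1);
    if (r0 - R < 0 || r0 + R >= H || c0 - R < 0 || c0 + R >= W) continue;
    double dmin = R_PosInf, dsum = 0.0;
    for (int c = 0; c < L; ++c)
      for (int r = 0; r < L; ++r) {
        const double v = frame(r0 - R + r, c0 - R + c);
        d[r + (size_t)L * c] = v;
        dsum += v; if (v < dmin) dmin = v;
      }
    // init: local-window centroid of background-subtracted counts
    double b = std::max(dmin, 1e-6);
    double N = std::max(dsum - b * L * L, 10.0);
    double cx = 0.0, cy = 0.0, wsum = 0.0;
    for (int c = 0; c < L; ++c)
      for (int r = 0; r < L; ++r) {
        const double w = std::max(d[r + (size_t)L * c] - b, 0.0);
        cx += w * (c + 0.5); cy += w * (r + 0.5); wsum += w;
      }
    double x = wsum > 0 ? cx / wsum : R + 0.5;
    double y = wsum > 0 ? cy / wsum : R + 0.5;
    double s = sigma0_px;
    double ll = R_NegInf, ll0 = R_NegInf;
    bool conv = false;
    for (int it = 0; it < maxit; ++it) {
      // precompute separable factors on the window grid (pixel p covers [p,p+1))
      for (int p = 0; p < L; ++p) {
        Ex[p] = pixint(p, p + 1, x, s);   dEx[p] = dpix_dmu(p, p + 1, x, s);
        sEx[p] = dpix_ds(p, p + 1, x, s);
        Ey[p] = pixint(p, p + 1, y, s);   dEy[p] = dpix_dmu(p, p + 1, y, s);
        sEy[p] = dpix_ds(p, p + 1, y, s);
      }
      // gradient and Fisher information for theta = (x, y, N, b, s)
      double g[5] = {0,0,0,0,0};
      double F[25] = {0};
      ll = 0.0;
      for (int c = 0; c < L; ++c)
        for (int r = 0; r < L; ++r) {
          const double mu = std::max(b + N * Ex[c] * Ey[r], 1e-9);
          const double dd = d[r + (size_t)L * c];
          ll += dd * std::log(mu) - mu;
          const double w = dd / mu - 1.0;
          const double J[5] = { N * dEx[c] * Ey[r], N * Ex[c] * dEy[r],
                                Ex[c] * Ey[r], 1.0,
                                N * (sEx[c] * Ey[r] + Ex[c] * sEy[r]) };
          for (int i = 0; i < 5; ++i) {
            g[i] += w * J[i];
            for (int j = i; j < 5; ++j) F[i * 5 + j] += J[i] * J[j] / mu;
          }
        }
      for (int i = 0; i < 5; ++i)
        for (int j = 0; j < i; ++j) F[i * 5 + j] = F[j * 5 + i];
      if (it > 0 && std::fabs(ll - ll0) < tol * (std::fabs(ll0) + 1e-9)) {
        conv = true; break;
      }
      ll0 = ll;
      // solve F * step = g (Cholesky with ridge)
      double A[25]; std::copy(F, F + 25, A);
      for (int i = 0; i < 5; ++i) A[i * 5 + i] += 1e-8 * (A[i * 5 + i] + 1e-12);
      double Lc[25] = {0};
      bool ok = true;
      for (int i = 0; i < 5 && ok; ++i) {
        for (int j = 0; j <= i; ++j) {
          double sum = A[i * 5 + j];
          for (int m = 0; m < j; ++m) sum -= Lc[i * 5 + m] * Lc[j * 5 + m];
          if (i == j) {
            if (sum <= 0) { ok = false; break; }
            Lc[i * 5 + i] = std::sqrt(sum);
          } else Lc[i * 5 + j] = sum / Lc[j * 5 + j];
        }
      }
      if (!ok) break;
      double zv[5], st[5];
      for (int i = 0; i < 5; ++i) {
        double sum = g[i];
        for (int m = 0; m < i; ++m) sum -= Lc[i * 5 + m] * zv[m];
        zv[i] = sum / Lc[i * 5 + i];
      }
      for (int i = 4; i >= 0; --i) {
        double sum = zv[i];
        for (int m = i + 1; m < 5; ++m) sum -= Lc[m * 5 + i] * st[m];
        st[i] = sum / Lc[i * 5 + i];
      }
      // damped update with parameter bounds
      double step = 1.0;
      for (int half = 0; half < 8; ++half) {
        double xn = x + step * st[0], yn = y + step * st[1];
        double Nn = N + step * st[2], bn = b + step * st[3];
        double sn = s + step * st[4];
        if (xn < 0 || xn > L || yn < 0 || yn > L || Nn < 1.0 ||
            bn < 1e-6 || sn < 0.3 || sn > 5.0) { step *= 0.5; continue; }
        x = xn; y = yn; N = Nn; b = bn; s = sn;
        break;
      }
    }
    out(nout, 0) = (c0 - R) + x;   // px, image coordinates
    out(nout, 1) = (r0 - R) + y;
    out(nout, 2) = N; out(nout, 3) = b; out(nout, 4) = s;
    out(nout, 5) = conv ? 1.0 : 0.0;
    out(nout, 6) = ll;
    ++nout;
  }
  if (nout == 0) return NumericMatrix(0, 7);
  return out(Range(0, nout - 1), _);
}

// --- greedy reblink merging ------------------------------------------------
// Rows must be sorted by frame. An event joins the first open track whose
// photon-weighted running centroid is within radius_nm and whose last frame is
// within max_gap frames; otherwise it opens a new track. Merged row =
// photon-weighted centroid, summed intensity, first frame, photon-weighted
// sigma/uncertainty/offset.
// [[Rcpp::export]]
NumericMatrix cpp_merge_reblinks(IntegerVector frame, NumericVector x,
                                 NumericVector y, NumericVector intensity,
                                 NumericVector sigma, NumericVector unc,
                                 NumericVector offset, double radius_nm,
                                 int max_gap) {
  const int n = frame.size();
  const double r2 = radius_nm * radius_nm;
  struct Track {
    double wx, wy, wsig, wunc, woff, wsum;
    int first, last;
  };
  std::vector<Track> open, done;
  open.reserve(4096); done.reserve(n);
  for (int i = 0; i < n; ++i) {
    const int f = frame[i];
    // retire expired tracks occasionally
    if ((i & 1023) == 0) {
      size_t j = 0;
      while (j < open.size()) {
        if (open[j].last < f - max_gap) {
          done.push_back(open[j]);
          open[j] = open.back(); open.pop_back();
        } else ++j;
      }
    }
    int best = -1; double bestd = R_PosInf;
    for (size_t j = 0; j < open.size(); ++j) {
      if (open[j].last < f - max_gap || open[j].last >= f) continue;
      const double cx = open[j].wx / open[j].wsum;
      const double cy = open[j].wy / open[j].wsum;
      const double dx = x[i] - cx, dy = y[i] - cy;
      const double dd = dx * dx + dy * dy;
      if (dd <= r2 && dd < bestd) { bestd = dd; best = (int)j; }
    }
    const double w = std::max(intensity[i], 1e-12);
    if (best < 0) {
      Track t;
      t.wx = w * x[i]; t.wy = w * y[i]; t.wsig = w * sigma[i];
      t.wunc = w * unc[i]; t.woff = w * offset[i]; t.wsum = w;
      t.first = f; t.last = f;
      open.push_back(t);
    } else {
      Track& t = open[best];
      t.wx += w * x[i]; t.wy += w * y[i]; t.wsig += w * sigma[i];
      t.wunc += w * unc[i]; t.woff += w * offset[i]; t.wsum += w;
      t.last = f;
    }
  }
  for (size_t j = 0; j < open.size(); ++j) done.push_back(open[j]);
  NumericMatrix out(done.size(), 7);
  for (size_t j = 0; j < done.size(); ++j) {
    const Track& t = done[j];
    out(j, 0) = t.first;
    out(j, 1) = t.wx / t.wsum; out(j, 2) = t.wy / t.wsum;
    out(j, 3) = t.wsum;
    out(j, 4) = t.wsig / t.wsum; out(j, 5) = t.wunc / t.wsum;
    out(j, 6) = t.woff / t.wsum;
  }
  colnames(out) = CharacterVector::create("frame", "x", "y", "intensity",
                                          "sigma", "uncertainty", "offset");
  return out;
}
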