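#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Uniform cell grid over point sets for radius queries / nearest neighbours.
struct Grid {
  double cell, x0, y0;
  int nx, ny;
  std::vector<std::vector<int>> bins;
  Grid(const NumericVector& x, const NumericVector& y, double cellsize,
       double minx, double miny, double maxx, double maxy) {
    cell = cellsize; x0 = minx; y0 = miny;
    nx = std::max(1, (int)std::floor((maxx - minx) / cell) + 1);
    ny = std::max(1, (int)std::floor((maxy - miny) / cell) + 1);
    bins.assign((size_t)nx * ny, {});
    for (int i = 0; i < x.size(); ++i) {
      int cx = std::min(nx - 1, std::max(0, (int)std::floor((x[i] - x0) / cell)));
      int cy = std::min(ny - 1, std::max(0, (int)std::floor((y[i] - y0) / cell)));
      bins[cx + (size_t)nx * cy].push_back(i);
    }
  }
};

// Directional nearest-neighbour distances from (ax, ay) to points (bx, by).
// [[Rcpp::export]]
NumericVector cpp_nnd(NumericVector ax, NumericVector ay,
                      NumericVector bx, NumericVector by) {
  const int na = ax.size(), nb = bx.size();
  NumericVector out(na);
  if (nb == 0) stop("comparison set is empty");
  double minx = R_PosInf, miny = R_PosInf, maxx = R_NegInf, maxy = R_NegInf;
  for (int i = 0; i < nb; ++i) {
    minx = std::min(minx, bx[i]); maxx = std::max(maxx, bx[i]);
    miny = std::min(miny, by[i]); maxy = std::max(maxy, by[i]);
  }
  double cell = std::max((maxx - minx + maxy - miny) / 200.0, 1e-6);
  Grid g(bx, by, cell, minx, miny, maxx, maxy);
  for (int i = 0; i < na; ++i) {
    const int cx = (int)std::floor((ax[i] - g.x0) / g.cell);
    const int cy = (int)std::floor((ay[i] - g.y0) / g.cell);
    double best = R_PosInf;
    const int rmaxring = std::max(g.nx, g.ny) + 2 +
      std::max(std::abs(cx), std::abs(cy));
    for (int ring = 0; ring <= rmaxring; ++ring) {
      // once a candidate is found, search one extra ring then stop
      bool any = false;
      for (int dx = -ring; dx <= ring; ++dx) {
        for (int dy = -ring; dy <= ring; ++dy) {
          if (std::max(std::abs(dx), std::abs(dy)) != ring) continue;
          const int ux = cx + dx, uy = cy + dy;
          if (ux < 0 || uy < 0 || ux >= g.nx || uy >= g.ny) continue;
          for (int j : g.bins[ux + (size_t)g.nx * uy]) {
            const double ddx = ax[i] - bx[j], ddy = ay[i] - by[j];
            const double d2 = ddx * ddx + ddy * ddy;
            if (d2 < best) { best = d2; any = true; }
          }
        }
      }
      if (std::isfinite(best) && ring > 0 &&
          (double)(ring - 1) * g.cell >= std::sqrt(best)) break;
      (void)any;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

static void rank_avg(const double* v, int n, double* r) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b){ return v[a] < v[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && v[idx[j + 1]] == v[idx[i]]) ++j;
    const double rr = 0.5 * (i + j) + 1.0;
    for (int m = i; m <= j; ++m) r[idx[m]] = rr;
    i = j + 1;
  }
}

static double spearman(const double* a, const double* b, int n) {
  std::vector<double> ra(n), rb(n);
  rank_avg(a, n, ra.data()); rank_avg(b, n, rb.data());
  double ma = 0, mb = 0;
  for (int i = 0; i < n; ++i) { ma += ra[i]; mb += rb[i]; }
  ma /= n; mb /= n;
  double sab = 0, sa = 0, sb = 0;
  for (int i = 0; i < n; ++i) {
    sab += (ra[i] - ma) * (rb[i] - mb);
    sa  += (ra[i] - ma) * (ra[i] - ma);
    sb  += (rb[i] - mb) * (rb[i] - mb);
  }
  if (sa <= 0 || sb <= 0) return NA_REAL;  // constant profile
  return sab / std::sqrt(sa * sb);
}

// Coordinate-based colocalization (Malkusch style). For each reference point:
// cumulative neighbour counts of the reference set (self included, so the two
// channels are treated symmetrically and self-comparison scores exactly 1)
// and of the
// comparison set in n_bins concentric radii up to rmax, area-normalised
// (divide by total within rmax, scale by rmax^2/r^2); Spearman rank
// correlation between the two radial density profiles, damped by
// exp(-d_nearest/rmax) where d_nearest is the distance to the nearest
// comparison point. Points with no neighbours in both channels (or a constant
// profile) score 0. Returns matrix (cbc, nnd).
// [[Rcpp::export]]
NumericMatrix cpp_cbc(NumericVector ax, NumericVector ay,
                      NumericVector bx, NumericVector by,
                      double rmax, int n_bins) {
  const int na = ax.size(), nb = bx.size();
  if (na == 0 || nb == 0) stop("both point sets must be nonempty");
  double minx = R_PosInf, miny = R_PosInf, maxx = R_NegInf, maxy = R_NegInf;
  for (int i = 0; i < na; ++i) {
    minx = std::min(minx, ax[i]); maxx = std::max(maxx, ax[i]);
    miny = std::min(miny, ay[i]); maxy = std::max(maxy, ay[i]);
  }
  for (int i = 0; i < nb; ++i) {
    minx = std::min(minx, bx[i]); maxx = std::max(maxx, bx[i]);
    miny = std::min(miny, by[i]); maxy = std::max(maxy, by[i]);
  }
  Grid ga(ax, ay, rmax, minx, miny, maxx, maxy);
  Grid gb(bx, by, rmax, minx, miny, maxx, maxy);
  NumericVector dnn = cpp_nnd(ax, ay, bx, by);
  NumericMatrix out(na, 2);
  const double r2max = rmax * rmax;
  std::vector<double> cntA(n_bins), cntB(n_bins), dA(n_bins), dB(n_bins);
  for (int i = 0; i < na; ++i) {
    std::fill(cntA.begin(), cntA.end(), 0.0);
    std::fill(cntB.begin(), cntB.end(), 0.0);
    const int cx = std::min(ga.nx - 1, std::max(0,
                    (int)std::floor((ax[i] - ga.x0) / ga.cell)));
    const int cy = std::min(ga.ny - 1, std::max(0,
                    (int)std::floor((ay[i] - ga.y0) / ga.cell)));
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        const int ux = cx + dx, uy = cy + dy;
        if (ux < 0 || uy < 0 || ux >= ga.nx || uy >= ga.ny) continue;
        for (int j : ga.bins[ux + (size_t)ga.nx * uy]) {
          if (j == i) continue;  // the reference point is not its own neighbour
          const double ddx = ax[i] - ax[j], ddy = ay[i] - ay[j];
          const double d2 = ddx * ddx + ddy * ddy;
          if (d2 <= r2max) {
            int b = (int)std::floor(std::sqrt(d2) / rmax * n_bins);
            if (b >= n_bins) b = n_bins - 1;
            cntA[b] += 1.0;
          }
        }
        for (int j : gb.bins[ux + (size_t)gb.nx * uy]) {
          const double ddx = ax[i] - bx[j], ddy = ay[i] - by[j];
          const double d2 = ddx * ddx + ddy * ddy;
          // a zero-distance match is the event's own image in the other
          // channel; dropping it keeps the channels symmetric, so that
          // self-comparison scores exactly 1
          if (d2 == 0.0) continue;
          if (d2 <= r2max) {
            int b = (int)std::floor(std::sqrt(d2) / rmax * n_bins);
            if (b >= n_bins) b = n_bins - 1;
            cntB[b] += 1.0;
          }
        }
      }
    double totA = 0, totB = 0;
    for (int b = 0; b < n_bins; ++b) { totA += cntA[b]; totB += cntB[b]; }
    double cbc = 0.0;
    if (totA > 0 && totB > 0) {
      double ca = 0, cb = 0;
      for (int b = 0; b < n_bins; ++b) {
        ca += cntA[b]; cb += cntB[b];
        const double r = rmax * (b + 1.0) / n_bins;
        dA[b] = ca / totA * r2max / (r * r);
        dB[b] = cb / totB * r2max / (r * r);
      }
      const double s = spearman(dA.data(), dB.data(), n_bins);
      if (!ISNA(s)) cbc = s * std::exp(-dnn[i] / rmax);
    }
    out(i, 0) = cbc;
    out(i, 1) = dnn[i];
  }
  colnames(out) = CharacterVector::create("cbc", "nnd");
  return out;
}
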