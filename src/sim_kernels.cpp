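#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

inline double wrap(double v, double L) {
  v -= L * std::floor(v / L);
  if (v >= L) v -= L;
  if (v < 0.0) v = 0.0;
  return v;
}

// Cell-list lookup for static, non-overlapping circular domains.
// Domains are at least 2r apart, so a point lies in at most one domain.
struct DomainLookup {
  int n;
  std::vector<double> cx, cy;
  double r, r2, W, H, cell;
  int ncx, ncy;
  std::vector< std::vector<int> > bucket;

  DomainLookup(const NumericVector& cx_, const NumericVector& cy_,
               double r_, double W_, double H_)
    : n(cx_.size()), cx(cx_.begin(), cx_.end()), cy(cy_.begin(), cy_.end()),
      r(r_), r2(r_ * r_), W(W_), H(H_) {
    cell = (r_ > 0.0) ? r_ : std::max(W_, H_);
    ncx = std::max(1, (int) std::ceil(W / cell));
    ncy = std::max(1, (int) std::ceil(H / cell));
    bucket.resize((size_t) ncx * ncy);
    for (int d = 0; d < n; ++d) {
      int i0 = clampi((int) std::floor((cx[d] - r) / cell), 0, ncx - 1);
      int i1 = clampi((int) std::floor((cx[d] + r) / cell), 0, ncx - 1);
      int j0 = clampi((int) std::floor((cy[d] - r) / cell), 0, ncy - 1);
      int j1 = clampi((int) std::floor((cy[d] + r) / cell), 0, ncy - 1);
      for (int i = i0; i <= i1; ++i)
        for (int j = j0; j <= j1; ++j)
          bucket[(size_t) j * ncx + i].push_back(d);
    }
  }

  // index of the domain containing (x, y), or -1
  int find(double x, double y) const {
    if (n == 0) return -1;
    int i = clampi((int) std::floor(x / cell), 0, ncx - 1);
    int j = clampi((int) std::floor(y / cell), 0, ncy - 1);
    const std::vector<int>& b = bucket[(size_t) j * ncx + i];
    for (size_t q = 0; q < b.size(); ++q) {
      int d = b[q];
      double dx = x - cx[d], dy = y - cy[d];
      if (dx * dx + dy * dy < r2) return d;
    }
    return -1;
  }
};

} // namespace

// Brownian stepping with partitioning at domain boundaries.
// Frame 1 is the initial configuration; each later frame follows
// `substeps` Gaussian substeps. Frames after `burnIn` are recorded.
// A substep whose endpoint changes the inside/outside state is accepted
// with probability PIn (entering) or POut (escaping); a blocked substep is
// either cancelled (reflectPolicy = 0) or specularly reflected off the
// domain circle (reflectPolicy = 1). Periodic boundaries conserve count.
// Uses R's RNG: runs are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix pos0, NumericVector cx, NumericVector cy,
                  double radius, double W, double H,
                  int nFrames, int burnIn, int substeps,
                  double frameTime, double DIn, double DOut,
                  double PIn, double POut, int reflectPolicy) {
  const int np = pos0.nrow();
  const int nKeep = nFrames - burnIn;
  if (nKeep <= 0) stop("burn-in must leave at least one retained frame");

  DomainLookup dom(cx, cy, radius, W, H);

  std::vector<double> x(np), y(np);
  std::vector<int> in(np);
  for (int i = 0; i < np; ++i) {
    x[i] = wrap(pos0(i, 0), W);
    y[i] = wrap(pos0(i, 1), H);
    in[i] = dom.find(x[i], y[i]) >= 0 ? 1 : 0;
  }

  const double dt = frameTime / substeps;
  const double sIn = std::sqrt(2.0 * DIn * dt);
  const double sOut = std::sqrt(2.0 * DOut * dt);

  NumericVector posOut(Dimension(np, 2, nKeep));
  LogicalMatrix inOut(np, nKeep);

  int keep = 0;
  for (int f = 1; f <= nFrames; ++f) {
    if (f > 1) {
      for (int s = 0; s < substeps; ++s) {
        for (int i = 0; i < np; ++i) {
          const bool oldin = in[i] != 0;
          const double sd = oldin ? sIn : sOut;
          double nx = wrap(x[i] + sd * norm_rand(), W);
          double ny = wrap(y[i] + sd * norm_rand(), H);
          const int d = dom.find(nx, ny);
          const bool newin = d >= 0;
          if (newin == oldin) { x[i] = nx; y[i] = ny; continue; }
          const double p = oldin ? POut : PIn;
          if (unif_rand() < p) { x[i] = nx; y[i] = ny; in[i] = newin ? 1 : 0; continue; }
          if (reflectPolicy) {
            // reflect across the circle of the domain being entered/left
            const int dref = oldin ? dom.find(x[i], y[i]) : d;
            if (dref >= 0) {
              const double dx = nx - dom.cx[dref], dy = ny - dom.cy[dref];
              const double dd = std::sqrt(dx * dx + dy * dy);
              if (dd > 1e-12) {
                const double fac = (2.0 * radius - dd) / dd;
                const double rx = wrap(dom.cx[dref] + fac * dx, W);
                const double ry = wrap(dom.cy[dref] + fac * dy, H);
                const bool rin = dom.find(rx, ry) >= 0;
                if (rin == oldin) { x[i] = rx; y[i] = ry; }
              }
            }
          }
          // reject_step (or failed reflection): keep pre-step position
        }
      }
    }
    if (f > burnIn) {
      for (int i = 0; i < np; ++i) {
        posOut[i + (size_t) keep * 2 * np] = x[i];
        posOut[i + np + (size_t) keep * 2 * np] = y[i];
        inOut(i, keep) = in[i] != 0;
      }
      ++keep;
    }
  }

  return List::create(_["positions"] = posOut, _["inside"] = inOut);
}

// Gaussian PSF rendering: pixel (i, j) (0-based, x = column i, y = row j)
// samples the PSF at its center; support truncated at truncSigmas * sigma.
// pos has dim (np, 2, nt) in micrometres; output dim (ny, nx, nt).
// [[Rcpp::export]]
NumericVector cpp_render(NumericVector pos, int np, int nt,
                         int nx, int ny, double pixelSize,
                         double sigmaPx, double I0, double truncSigmas) {
  NumericVector out(Dimension(ny, nx, nt));
  if (np == 0 || sigmaPx <= 0.0) return out;
  const double T = truncSigmas * sigmaPx;
  const double inv2s2 = 1.0 / (2.0 * sigmaPx * sigmaPx);
  std::vector<double> wx, wy;
  for (int t = 0; t < nt; ++t) {
    double* frame = &out[(size_t) t * nx * ny];
    for (int n = 0; n < np; ++n) {
      const double px = pos[n + (size_t) t * 2 * np] / pixelSize;
      const double py = pos[n + np + (size_t) t * 2 * np] / pixelSize;
      const int i0 = clampi((int) std::ceil(px - T), 0, nx - 1);
      const int i1 = clampi((int) std::floor(px + T), 0, nx - 1);
      const int j0 = clampi((int) std::ceil(py - T), 0, ny - 1);
      const int j1 = clampi((int) std::floor(py + T), 0, ny - 1);
      if (i1 < i0 || j1 < j0) continue;
      wx.resize(i1 - i0 + 1);
      wy.resize(j1 - j0 + 1);
      for (int i = i0; i <= i1; ++i) {
        const double d = i - px;
        wx[i - i0] = std::exp(-d * d * inv2s2);
      }
      for (int j = j0; j <= j1; ++j) {
        const double d = j - py;
        wy[j - j0] = std::exp(-d * d * inv2s2);
      }
      for (int i = i0; i <= i1; ++i) {
        const double wI0 = I0 * wx[i - i0];
        double* col = frame + (size_t) i * ny;
        for (int j = j0; j <= j1; ++j) col[j] += wI0 * wy[j - j0];
      }
    }
  }
  return out;
}

// Inside/outside flags recomputed from geometry, dim (np, nt).
// [[Rcpp::export]]
LogicalMatrix cpp_inside_flags(NumericVector pos, int np, int nt,
                               NumericVector cx, NumericVector cy,
                               double radius, double W, double H) {
  DomainLookup dom(cx, cy, radius, W, H);
  LogicalMatrix out(np, nt);
  for (int t = 0; t < nt; ++t)
    for (int i = 0; i < np; ++i)
      out(i, t) = dom.find(pos[i + (size_t) t * 2 * np],
                           pos[i + np + (size_t) t * 2 * np]) >= 0;
  return out;
}
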