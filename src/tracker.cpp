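// Inner loop of the Lagrangian particle tracker: RK4 advection of many
// particles through nested fine/coarse gridded velocity fields. The R level
// owns release scheduling, record cadence, settlement/mortality hooks and
// trajectory assembly; this file only advances active particles over a span
// of fixed time steps.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  const double *xs, *ys, *zc, *ts;
  int nx, ny, nl, nt;
  const double *u, *v, *w;   // w may be null
  const int *mask;           // nx*ny, 1 = land (may be null)
  const double *bathy;       // nx*ny (may be null)
  double x0, x1, y0, y1, t0, t1, dx, dy, dth;
  bool has_w;
};

Grid unpack(const List& g) {
  Grid gr;
  const NumericVector xs = g["xs"], ys = g["ys"], zc = g["zc"], ts = g["ts"];
  gr.xs = xs.begin(); gr.ys = ys.begin(); gr.zc = zc.begin(); gr.ts = ts.begin();
  gr.nx = xs.size(); gr.ny = ys.size(); gr.nl = zc.size(); gr.nt = ts.size();
  const NumericVector u = g["u"], v = g["v"];
  gr.u = u.begin(); gr.v = v.begin();
  gr.has_w = !Rf_isNull(g["w"]);
  if (gr.has_w) { const NumericVector w = g["w"]; gr.w = w.begin(); }
  else gr.w = nullptr;
  if (!Rf_isNull(g["mask"])) { const IntegerVector m = g["mask"]; gr.mask = m.begin(); }
  else gr.mask = nullptr;
  if (!Rf_isNull(g["bathy"])) { const NumericVector b = g["bathy"]; gr.bathy = b.begin(); }
  else gr.bathy = nullptr;
  gr.x0 = gr.xs[0]; gr.x1 = gr.xs[gr.nx - 1];
  gr.y0 = gr.ys[0]; gr.y1 = gr.ys[gr.ny - 1];
  gr.t0 = gr.ts[0]; gr.t1 = gr.ts[gr.nt - 1];
  gr.dx = (gr.x1 - gr.x0) / (gr.nx - 1);
  gr.dy = (gr.y1 - gr.y0) / (gr.ny - 1);
  gr.dth = gr.nt > 1 ? (gr.t1 - gr.t0) / (gr.nt - 1) : 1.0;
  return gr;
}

inline bool inside_xy(const Grid& g, double x, double y) {
  return x >= g.x0 && x <= g.x1 && y >= g.y0 && y <= g.y1;
}

// bilinear in x-y of one (layer, time) slice
inline double bil(const double* F, const Grid& g, int k, int it,
                  int ix, int iy, double fx, double fy) {
  const size_t nx = g.nx, ny = g.ny, nl = g.nl;
  size_t base = ix + nx * (iy + ny * (k + nl * (size_t)it));
  double f00 = F[base], f10 = F[base + 1];
  double f01 = F[base + nx], f11 = F[base + nx + 1];
  return f00 * (1 - fx) * (1 - fy) + f10 * fx * (1 - fy) +
         f01 * (1 - fx) * fy + f11 * fx * fy;
}

// full interpolation of one component; z interpolated linearly between
// layer centres (constant beyond the end centres)
inline double interp(const double* F, const Grid& g, double x, double y,
                     double z, double th, bool mode3d) {
  int ix = (int)std::floor((x - g.x0) / g.dx);
  if (ix < 0) ix = 0; if (ix > g.nx - 2) ix = g.nx - 2;
  int iy = (int)std::floor((y - g.y0) / g.dy);
  if (iy < 0) iy = 0; if (iy > g.ny - 2) iy = g.ny - 2;
  double fx = (x - g.xs[ix]) / g.dx, fy = (y - g.ys[iy]) / g.dy;
  int it = 0; double ft = 0;
  if (g.nt > 1) {
    it = (int)std::floor((th - g.t0) / g.dth);
    if (it < 0) it = 0; if (it > g.nt - 2) it = g.nt - 2;
    ft = (th - g.ts[it]) / g.dth;
  }
  int k = 0; double fz = 0;
  if (mode3d && g.nl > 1) {
    if (z <= g.zc[0]) { k = 0; fz = 0; }
    else if (z >= g.zc[g.nl - 1]) { k = g.nl - 2; fz = 1; }
    else {
      while (k < g.nl - 2 && g.zc[k + 1] < z) ++k;
      fz = (z - g.zc[k]) / (g.zc[k + 1] - g.zc[k]);
    }
  }
  double lo0 = bil(F, g, k, it, ix, iy, fx, fy);
  double lo1 = (g.nt > 1) ? bil(F, g, k, it + 1, ix, iy, fx, fy) : lo0;
  double lo = lo0 * (1 - ft) + lo1 * ft;
  if (fz == 0) return lo;
  double hi0 = bil(F, g, k + 1, it, ix, iy, fx, fy);
  double hi1 = (g.nt > 1) ? bil(F, g, k + 1, it + 1, ix, iy, fx, fy) : hi0;
  double hi = hi0 * (1 - ft) + hi1 * ft;
  return lo * (1 - fz) + hi * fz;
}

struct Sampler {
  Grid fine, coarse;
  bool has_fine;
  bool mode3d;
};

// returns false when (x, y) is outside the coarse bounds or t outside range
inline bool sample(const Sampler& s, double x, double y, double z, double th,
                   double& u, double& v, double& w) {
  const Grid* g = nullptr;
  if (s.has_fine && inside_xy(s.fine, x, y)) g = &s.fine;
  else if (inside_xy(s.coarse, x, y)) g = &s.coarse;
  else return false;
  if (th < s.coarse.t0 - 1e-9 || th > s.coarse.t1 + 1e-9) return false;
  u = interp(g->u, *g, x, y, z, th, s.mode3d);
  v = interp(g->v, *g, x, y, z, th, s.mode3d);
  w = (s.mode3d && g->has_w) ? interp(g->w, *g, x, y, z, th, s.mode3d) : 0.0;
  return true;
}

inline const Grid* grid_at(const Sampler& s, double x, double y) {
  if (s.has_fine && inside_xy(s.fine, x, y)) return &s.fine;
  if (inside_xy(s.coarse, x, y)) return &s.coarse;
  return nullptr;
}

inline bool on_land(const Sampler& s, double x, double y) {
  const Grid* g = grid_at(s, x, y);
  if (!g || !g->mask) return false;
  int ix = (int)std::lround((x - g->x0) / g->dx);
  int iy = (int)std::lround((y - g->y0) / g->dy);
  if (ix < 0) ix = 0; if (ix > g->nx - 1) ix = g->nx - 1;
  if (iy < 0) iy = 0; if (iy > g->ny - 1) iy = g->ny - 1;
  return g->mask[ix + (size_t)g->nx * iy] == 1;
}

inline double local_depth(const Sampler& s, double x, double y) {
  const Grid* g = grid_at(s, x, y);
  if (!g || !g->bathy) return R_PosInf;
  int ix = (int)std::floor((x - g->x0) / g->dx);
  if (ix < 0) ix = 0; if (ix > g->nx - 2) ix = g->nx - 2;
  int iy = (int)std::floor((y - g->y0) / g->dy);
  if (iy < 0) iy = 0; if (iy > g->ny - 2) iy = g->ny - 2;
  double fx = (x - g->xs[ix]) / g->dx, fy = (y - g->ys[iy]) / g->dy;
  const double* B = g->bathy;
  size_t nx = g->nx;
  double b = B[ix + nx * iy] * (1 - fx) * (1 - fy) +
             B[ix + 1 + nx * iy] * fx * (1 - fy) +
             B[ix + nx * (iy + 1)] * (1 - fx) * fy +
             B[ix + 1 + nx * (iy + 1)] * fx * fy;
  return b;
}

}  // namespace

// Advance particles by n_steps RK4 steps of dt_s seconds starting at
// t_start_h (hours). status codes: 0 active, 3 exited; other codes are left
// untouched. Positions are modified for active particles only.
// [[Rcpp::export]]
List advance_particles_cpp(NumericVector x, NumericVector y, NumericVector z,
                           IntegerVector status, double t_start_h,
                           int n_steps, double dt_s,
                           SEXP fine, List coarse, bool mode3d) {
  NumericVector X = clone(x), Y = clone(y), Z = clone(z);
  IntegerVector S = clone(status);
  Sampler smp;
  smp.has_fine = !Rf_isNull(fine);
  if (smp.has_fine) smp.fine = unpack(List(fine));
  smp.coarse = unpack(coarse);
  smp.mode3d = mode3d;
  const double dt_h = dt_s / 3600.0;
  const int n = X.size();
  for (int step = 0; step < n_steps; ++step) {
    double th = t_start_h + step * dt_h;
    for (int p = 0; p < n; ++p) {
      if (S[p] != 0) continue;
      double px = X[p], py = Y[p], pz = Z[p];
      double u1, v1, w1, u2, v2, w2, u3, v3, w3, u4, v4, w4;
      bool ok =
        sample(smp, px, py, pz, th, u1, v1, w1) &&
        sample(smp, px + 0.5 * dt_s * u1, py + 0.5 * dt_s * v1,
               pz + 0.5 * dt_s * w1, th + 0.5 * dt_h, u2, v2, w2) &&
        sample(smp, px + 0.5 * dt_s * u2, py + 0.5 * dt_s * v2,
               pz + 0.5 * dt_s * w2, th + 0.5 * dt_h, u3, v3, w3) &&
        sample(smp, px + dt_s * u3, py + dt_s * v3,
               pz + dt_s * w3, th + dt_h, u4, v4, w4);
      if (!ok) { S[p] = 3; continue; }
      double nx_ = px + dt_s / 6.0 * (u1 + 2 * u2 + 2 * u3 + u4);
      double ny_ = py + dt_s / 6.0 * (v1 + 2 * v2 + 2 * v3 + v4);
      double nz_ = pz;
      if (!inside_xy(smp.coarse, nx_, ny_)) { S[p] = 3; continue; }
      if (mode3d) {
        nz_ = pz + dt_s / 6.0 * (w1 + 2 * w2 + 2 * w3 + w4);
        if (nz_ < 0) nz_ = -nz_;                       // surface reflection
        double D = local_depth(smp, nx_, ny_);
        if (R_finite(D) && D > 0 && nz_ > D) nz_ = 2 * D - nz_;
        if (nz_ < 0) nz_ = 0;
        if (R_finite(D) && D > 0 && nz_ > D) nz_ = D;
      }
      if (on_land(smp, nx_, ny_)) continue;  // hold position this step
      X[p] = nx_; Y[p] = ny_; Z[p] = nz_;
    }
  }
  return List::create(_["x"] = X, _["y"] = Y, _["z"] = Z, _["status"] = S);
}
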