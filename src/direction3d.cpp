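// Direction-inference stage: 3-D direction inference by boundary-distance maximisation.
//
// For every voxel, candidate headless directions are scored by the number of
// discretised line steps that stay inside the same inferred bundle (same
// 30-degree azimuth/elevation criteria); planar voxels receive an elevation
// as the length-weighted mean over a 15-degree candidate grid, vertical
// voxels additionally search a 11.25-degree azimuth grid. Voxels are
// processed in decreasing order of a boundary-proximity score so confident
// assignments guide later ones. This is the package's hot loop, hence C++.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const int CAT_EMPTY = 0, CAT_PLANAR = 1, CAT_VERTICAL = 2;

struct Vol {
  const int *cat;
  const double *theta;
  double *vx, *vy, *vz;
  int *assigned;
  int nx, ny, nz;
  bool in(int x, int y, int z) const {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  }
  int idx(int x, int y, int z) const { return x + nx * (y + (long)ny * z); }
};

static inline double mod_pos(double x, double m) { return x - m * std::floor(x / m); }

static inline double d360(double a, double b) {
  double d = std::fabs(a - b);
  d = mod_pos(d, 360.0);
  return d > 180.0 ? 360.0 - d : d;
}
static inline double d180(double a, double b) {
  double d = std::fabs(a - b);
  d = mod_pos(d, 180.0);
  return d > 90.0 ? 180.0 - d : d;
}
static inline double clamp1(double x) { return x > 1 ? 1 : (x < -1 ? -1 : x); }

struct Sph { double t, p; };  // azimuth deg [0,360), elevation deg [-90,90]

static inline Sph vec_sph(double x, double y, double z) {
  Sph s;
  s.p = std::asin(clamp1(z)) * 180.0 / M_PI;
  s.t = std::atan2(y, x) * 180.0 / M_PI;
  if (s.t < 0) s.t += 360.0;
  return s;
}

// Temporary vector of a voxel under probe direction (tv, pv):
// assigned -> own vector aligned with the probe; planar -> (theta_p, pv)
// with theta_p's representative nearest the probe azimuth; vertical -> probe.
static inline Sph temp_vec(const Vol &V, int q, double tv, double pv,
                           double pvx, double pvy, double pvz) {
  Sph u;
  if (V.assigned[q]) {
    double ax = V.vx[q], ay = V.vy[q], az = V.vz[q];
    if (ax * pvx + ay * pvy + az * pvz < 0) { ax = -ax; ay = -ay; az = -az; }
    u = vec_sph(ax, ay, az);
  } else if (V.cat[q] == CAT_PLANAR) {
    double t1 = V.theta[q];
    if (d360(t1, tv) > 90.0) t1 = mod_pos(t1 + 180.0, 360.0);
    u.t = t1; u.p = pv;
  } else {  // vertical
    u.t = tv; u.p = pv;
  }
  return u;
}

// Same-bundle test between current temp vector u and the next voxel q.
static inline bool same_bundle(const Vol &V, const Sph &u, int q) {
  if (V.cat[q] == CAT_EMPTY) return false;
  if (V.assigned[q]) {
    Sph w = vec_sph(V.vx[q], V.vy[q], V.vz[q]);
    if (d360(w.t, u.t) > 90.0) { w.t = mod_pos(w.t + 180.0, 360.0); w.p = -w.p; }
    return d360(w.t, u.t) < 30.0 && std::fabs(w.p - u.p) < 30.0;
  }
  if (V.cat[q] == CAT_PLANAR) return d180(V.theta[q], u.t) < 30.0;
  return std::fabs(u.p) > 30.0;  // vertical neighbour
}

// Discretised two-arm walk from p along +-v; returns the first index at
// which either arm leaves the bundle, capped at Lmax.
static int line_length(const Vol &V, int x0, int y0, int z0,
                       double wx, double wy, double wz, int Lmax) {
  int p0 = V.idx(x0, y0, z0);
  if (V.cat[p0] == CAT_EMPTY) return 0;
  double dl = 1e30;
  if (std::fabs(wx) > 1e-9) dl = std::min(dl, 1.0 / std::fabs(wx));
  if (std::fabs(wy) > 1e-9) dl = std::min(dl, 1.0 / std::fabs(wy));
  if (std::fabs(wz) > 1e-9) dl = std::min(dl, 1.0 / std::fabs(wz));
  if (dl > 1e29) return 0;
  Sph v = vec_sph(wx, wy, wz);
  Sph u[2];
  u[0] = temp_vec(V, p0, v.t, v.p, wx, wy, wz);
  u[1] = u[0];
  int px[2] = {x0, x0}, py[2] = {y0, y0}, pz[2] = {z0, z0};
  for (int i = 1; i <= Lmax; ++i) {
    double lam = i * dl;
    for (int arm = 0; arm < 2; ++arm) {
      double s = arm == 0 ? 1.0 : -1.0;
      int qx = (int)std::llround(x0 + s * lam * wx);
      int qy = (int)std::llround(y0 + s * lam * wy);
      int qz = (int)std::llround(z0 + s * lam * wz);
      if (qx == px[arm] && qy == py[arm] && qz == pz[arm]) continue;
      if (!V.in(qx, qy, qz)) return i;  // leaving the volume is a boundary
      int q = V.idx(qx, qy, qz);
      if (!same_bundle(V, u[arm], q)) return i;
      u[arm] = temp_vec(V, q, v.t, v.p, s * wx, s * wy, s * wz);
      px[arm] = qx; py[arm] = qy; pz[arm] = qz;
    }
  }
  return Lmax;
}

static inline void sph_dir(double theta, double phi, double *v) {
  double t = theta * M_PI / 180.0, p = phi * M_PI / 180.0;
  v[0] = std::cos(t) * std::cos(p);
  v[1] = std::sin(t) * std::cos(p);
  v[2] = std::sin(p);
}

// [[Rcpp::export]]
int cpp_line_length(IntegerVector cat, NumericVector theta,
                    NumericVector vx, NumericVector vy, NumericVector vz,
                    IntegerVector assigned, IntegerVector dims,
                    IntegerVector p0, NumericVector v, int Lmax) {
  Vol V;
  V.cat = INTEGER(cat); V.theta = REAL(theta);
  V.vx = REAL(vx); V.vy = REAL(vy); V.vz = REAL(vz);
  V.assigned = INTEGER(assigned);
  V.nx = dims[0]; V.ny = dims[1]; V.nz = dims[2];
  return line_length(V, p0[0], p0[1], p0[2], v[0], v[1], v[2], Lmax);
}

struct OrderRec { double s; int lin; };
static bool order_cmp(const OrderRec &a, const OrderRec &b) {
  if (a.s != b.s) return a.s > b.s;   // descending score
  return a.lin < b.lin;               // raster order on ties
}

// Elevation average over a candidate grid: phi_bar = sum Li phi_i / sum Li
// over candidates with Li > 2; `fallback` if none qualifies.
static double phi_average(const Vol &V, int x, int y, int z, double theta,
                          const std::vector<double> &phis, double fallback,
                          int Lmax) {
  double num = 0, den = 0, d[3];
  for (size_t i = 0; i < phis.size(); ++i) {
    sph_dir(theta, phis[i], d);
    int L = line_length(V, x, y, z, d[0], d[1], d[2], Lmax);
    if (L > 2) { num += (double)L * phis[i]; den += L; }
  }
  return den > 0 ? num / den : fallback;
}

// [[Rcpp::export]]
List cpp_assign_directions(IntegerVector cat, NumericVector theta,
                           IntegerVector dims, int Lmax) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector vx(n), vy(n), vz(n);
  IntegerVector assigned(n);
  NumericVector score(n);
  IntegerVector lowconf(n);
  Vol V;
  V.cat = INTEGER(cat); V.theta = REAL(theta);
  V.vx = REAL(vx); V.vy = REAL(vy); V.vz = REAL(vz);
  V.assigned = INTEGER(assigned);
  V.nx = nx; V.ny = ny; V.nz = nz;

  std::vector<double> phi_planar, phi_vert;
  for (double p = -60; p <= 60 + 1e-9; p += 15) phi_planar.push_back(p);
  for (double p = 30; p <= 90 + 1e-9; p += 15) phi_vert.push_back(p);

  // ---- planar pass ----
  std::vector<OrderRec> ord;
  double d[3];
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    int q = V.idx(x, y, z);
    if (V.cat[q] != CAT_PLANAR) continue;
    sph_dir(V.theta[q], 60.0, d);
    int Lp = line_length(V, x, y, z, d[0], d[1], d[2], Lmax);
    sph_dir(V.theta[q], -60.0, d);
    int Lm = line_length(V, x, y, z, d[0], d[1], d[2], Lmax);
    OrderRec r; r.s = std::fabs((double)(Lp - Lm)); r.lin = q;
    ord.push_back(r);
    score[q] = r.s;
  }
  std::stable_sort(ord.begin(), ord.end(), order_cmp);
  for (size_t k = 0; k < ord.size(); ++k) {
    int q = ord[k].lin;
    int z = q / (nx * ny), rem = q % (nx * ny);
    int y = rem / nx, x = rem % nx;
    double phi = phi_average(V, x, y, z, V.theta[q], phi_planar, 0.0, Lmax);
    sph_dir(V.theta[q], phi, d);
    vx[q] = d[0]; vy[q] = d[1]; vz[q] = d[2];
    assigned[q] = 1;
  }

  // ---- vertical pass ----
  const double probes[4][3] = {
    { M_SQRT1_2, 0,  M_SQRT1_2}, {-M_SQRT1_2, 0, M_SQRT1_2},
    { 0,  M_SQRT1_2, M_SQRT1_2}, { 0, -M_SQRT1_2, M_SQRT1_2}};
  ord.clear();
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    int q = V.idx(x, y, z);
    if (V.cat[q] != CAT_VERTICAL) continue;
    int L[4];
    for (int j = 0; j < 4; ++j)
      L[j] = line_length(V, x, y, z, probes[j][0], probes[j][1], probes[j][2], Lmax);
    int mx = 0;
    for (int a = 0; a < 4; ++a) for (int b = a + 1; b < 4; ++b)
      mx = std::max(mx, std::abs(L[a] - L[b]));
    OrderRec r; r.s = mx; r.lin = q;
    ord.push_back(r);
    score[q] = r.s;
  }
  std::stable_sort(ord.begin(), ord.end(), order_cmp);
  for (size_t k = 0; k < ord.size(); ++k) {
    int q = ord[k].lin;
    int z = q / (nx * ny), rem = q % (nx * ny);
    int y = rem / nx, x = rem % nx;
    int bestL = -1; double bestTheta = 0, bestPhi = 90;
    for (int m = 0; m < 32; ++m) {
      double th = 11.25 * m;
      double ph = phi_average(V, x, y, z, th, phi_vert, 90.0, Lmax);
      sph_dir(th, ph, d);
      int L = line_length(V, x, y, z, d[0], d[1], d[2], Lmax);
      if (L > bestL) { bestL = L; bestTheta = th; bestPhi = ph; }
    }
    sph_dir(bestTheta, bestPhi, d);
    vx[q] = d[0]; vy[q] = d[1]; vz[q] = d[2];
    assigned[q] = 1;
    if (ord[k].s == 0 && bestL <= 1) lowconf[q] = 1;
  }

  return List::create(_["vx"] = vx, _["vy"] = vy, _["vz"] = vz,
                      _["assigned"] = assigned, _["score"] = score,
                      _["lowconf"] = lowconf);
}
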