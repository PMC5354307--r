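// Elastic registration: per-tile generalised Hough accumulator over
// (theta, t) with angle-compatibility and elasticity bounds. Tight triple
// loop (angles x area pixels x reference pixels), hence C++; reference
// pixels are bucketed by integer angle so only compatible ones are visited.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double hd180(double a, double b) {
  double d = std::fabs(a - b);
  d -= 180.0 * std::floor(d / 180.0);
  return d > 90.0 ? 180.0 - d : d;
}
static inline int mod180i(int a) { int r = a % 180; return r < 0 ? r + 180 : r; }

// [[Rcpp::export]]
List cpp_tile_hough(NumericVector px, NumericVector py, NumericVector pth,
                    NumericVector qx, NumericVector qy, NumericVector qth,
                    double b, double amax, int theta_max) {
  int n1 = px.size(), n0 = qx.size();
  int bi = (int)std::ceil(b);
  int nb = 2 * bi + 1;
  std::vector<int> acc((size_t)nb * nb);
  int best_count = -1, best_tx = 0, best_ty = 0, best_th = 0;
  bool found = false;
  double b2 = b * b;
  int aw = (int)std::ceil(amax);  // half-width of the angle window in bins

  // bucket reference pixels by integer angle (0..179)
  std::vector<int> bin(n0), order(n0), start(181, 0);
  for (int j = 0; j < n0; ++j) {
    int a = (int)std::floor(qth[j]);
    bin[j] = mod180i(a);
  }
  for (int j = 0; j < n0; ++j) ++start[bin[j] + 1];
  for (int a = 0; a < 180; ++a) start[a + 1] += start[a];
  {
    std::vector<int> pos(start.begin(), start.end() - 1);
    for (int j = 0; j < n0; ++j) order[pos[bin[j]]++] = j;
  }

  for (int th = -theta_max; th <= theta_max; ++th) {
    std::fill(acc.begin(), acc.end(), 0);
    double a = th * M_PI / 180.0, ca = std::cos(a), sa = std::sin(a);
    bool any = false;
    for (int i = 0; i < n1; ++i) {
      double rx = ca * px[i] - sa * py[i];
      double ry = sa * px[i] + ca * py[i];
      double ra = pth[i] + th;
      int rab = mod180i((int)std::floor(ra));
      for (int da = -aw; da <= aw; ++da) {
        int ab = mod180i(rab + da);
        for (int k = start[ab]; k < start[ab + 1]; ++k) {
          int j = order[k];
          double dx = qx[j] - rx;
          if (dx > b || dx < -b) continue;
          double dy = qy[j] - ry;
          if (dy > b || dy < -b || dx * dx + dy * dy > b2) continue;
          if (hd180(qth[j], ra) >= amax) continue;
          int ix = (int)std::lround(dx) + bi, iy = (int)std::lround(dy) + bi;
          if (ix < 0 || ix >= nb || iy < 0 || iy >= nb) continue;
          ++acc[(size_t)ix * nb + iy];
          any = true;
        }
      }
    }
    if (!any) continue;
    for (int ix = 0; ix < nb; ++ix) for (int iy = 0; iy < nb; ++iy) {
      int c = acc[(size_t)ix * nb + iy];
      if (c == 0) continue;
      int tx = ix - bi, ty = iy - bi;
      bool better = false;
      if (c > best_count) better = true;
      else if (c == best_count) {
        if (std::abs(th) < std::abs(best_th)) better = true;
        else if (std::abs(th) == std::abs(best_th)) {
          long d2n = (long)tx * tx + (long)ty * ty;
          long d2o = (long)best_tx * best_tx + (long)best_ty * best_ty;
          if (d2n < d2o) better = true;
          else if (d2n == d2o && (tx < best_tx || (tx == best_tx && ty < best_ty)))
            better = true;
        }
      }
      if (better) {
        best_count = c; best_tx = tx; best_ty = ty; best_th = th;
        found = true;
      }
    }
  }
  return List::create(_["found"] = found, _["theta"] = best_th,
                      _["tx"] = best_tx, _["ty"] = best_ty,
                      _["count"] = best_count);
}
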