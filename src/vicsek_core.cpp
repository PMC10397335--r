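#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Mean heading over the neighbor set of every agent (self included):
// atan2 of summed sines over summed cosines, neighbors within radius r
// under the periodic minimum-image convention.  Cell lists give O(N);
// when fewer than 3 cells fit per side the wrapped 3x3 stencil would
// revisit cells, so an all-pairs scan is used instead.
// [[Rcpp::export]]
NumericVector vm_mean_angles(NumericVector x, NumericVector y,
                             NumericVector theta, double L, double r) {
  const int n = x.size();
  NumericVector out(n);
  if (n == 0) return out;
  const double r2 = r * r;
  std::vector<double> s(n), c(n);
  for (int i = 0; i < n; ++i) {
    s[i] = std::sin(theta[i]);
    c[i] = std::cos(theta[i]);
  }
  int nc = (int)std::floor(L / r);
  if (nc < 1) nc = 1;
  // more cells than ~N stop paying off; capping keeps memory bounded for
  // tiny interaction radii (cell width only grows, which stays correct)
  const int nc_cap = std::max(3, (int)std::sqrt((double)n) + 1);
  if (nc > nc_cap) nc = nc_cap;

  if (nc < 3) {
    for (int i = 0; i < n; ++i) {
      double ss = 0.0, cc = 0.0;
      for (int j = 0; j < n; ++j) {
        double dx = x[j] - x[i]; dx -= L * std::nearbyint(dx / L);
        double dy = y[j] - y[i]; dy -= L * std::nearbyint(dy / L);
        if (dx * dx + dy * dy <= r2) { ss += s[j]; cc += c[j]; }
      }
      double a = (ss == 0.0 && cc == 0.0) ? theta[i] : std::atan2(ss, cc);
      if (a < 0) a += 2.0 * M_PI;
      out[i] = a;
    }
    return out;
  }

  const double w = L / nc;  // cell width >= r by construction
  std::vector<int> head(nc * nc, -1), nxt(n, -1), cellx(n), celly(n);
  for (int i = 0; i < n; ++i) {
    int cx = (int)(x[i] / w); if (cx >= nc) cx = nc - 1; if (cx < 0) cx = 0;
    int cy = (int)(y[i] / w); if (cy >= nc) cy = nc - 1; if (cy < 0) cy = 0;
    cellx[i] = cx; celly[i] = cy;
    const int cell = cy * nc + cx;
    nxt[i] = head[cell];
    head[cell] = i;
  }
  for (int i = 0; i < n; ++i) {
    double ss = 0.0, cc = 0.0;
    for (int dy = -1; dy <= 1; ++dy) {
      const int ay = (celly[i] + dy + nc) % nc;
      for (int dx = -1; dx <= 1; ++dx) {
        const int ax = (cellx[i] + dx + nc) % nc;
        for (int j = head[ay * nc + ax]; j != -1; j = nxt[j]) {
          double ddx = x[j] - x[i]; ddx -= L * std::nearbyint(ddx / L);
          double ddy = y[j] - y[i]; ddy -= L * std::nearbyint(ddy / L);
          if (ddx * ddx + ddy * ddy <= r2) { ss += s[j]; cc += c[j]; }
        }
      }
    }
    double a = (ss == 0.0 && cc == 0.0) ? theta[i] : std::atan2(ss, cc);
    if (a < 0) a += 2.0 * M_PI;
    out[i] = a;
  }
  return out;
}
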