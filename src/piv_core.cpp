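#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Normalized cross-correlation search for one frame pair.
//
// For every interrogation grid (Z x Z template in frame `a`, origin given
// 0-based) every integer displacement (k, l) with |k|,|l| <= margin is scored
// with the mean-subtracted, norm-normalized correlation; pixels are accessed
// periodically.  Window means/variances come from summed-area tables so only
// the cross term is a per-pixel loop.  Returns, per grid, the argmax
// displacement (ties: smallest k^2+l^2, then smallest k, then l), the peak
// value, and the four correlation values adjacent to the peak (for subpixel
// refinement in R).
//
// status: 0 ok; 1 grid empty (template or search region all background);
//         2 constant template; 3 no displacement with defined correlation.
// [[Rcpp::export]]
List piv_search_cpp(IntegerMatrix a, IntegerMatrix b, int grid, int margin,
                    IntegerVector row0, IntegerVector col0, int bg) {
  const int nr = a.nrow(), nc = a.ncol();
  const int Z = grid, m = margin, span = 2 * m + 1;
  const int ng = row0.size();
  const double Z2 = (double)Z * (double)Z;

  // periodic pads: template needs Z-1 beyond each edge, windows need m more
  const int pr = nr + Z + 2 * m, pc = nc + Z + 2 * m;
  std::vector<double> Bp((size_t)pr * pc);
  for (int j = 0; j < pc; ++j) {
    const int cj = ((j - m) % nc + nc) % nc;
    for (int i = 0; i < pr; ++i) {
      const int ci = ((i - m) % nr + nr) % nr;
      Bp[(size_t)i + (size_t)j * pr] = (double)b(ci, cj);
    }
  }
  const int ar = nr + Z, ac = nc + Z;
  std::vector<double> Ap((size_t)ar * ac);
  for (int j = 0; j < ac; ++j) {
    const int cj = j % nc;
    for (int i = 0; i < ar; ++i)
      Ap[(size_t)i + (size_t)j * ar] = (double)a(i % nr, cj);
  }

  // summed-area tables over Bp: S(i,j) = sum of Bp[0..i-1, 0..j-1]
  std::vector<double> S1((size_t)(pr + 1) * (pc + 1), 0.0),
                      S2((size_t)(pr + 1) * (pc + 1), 0.0);
  for (int j = 1; j <= pc; ++j) {
    double run1 = 0.0, run2 = 0.0;
    for (int i = 1; i <= pr; ++i) {
      const double v = Bp[(size_t)(i - 1) + (size_t)(j - 1) * pr];
      run1 += v; run2 += v * v;
      S1[(size_t)i + (size_t)j * (pr + 1)] =
        S1[(size_t)i + (size_t)(j - 1) * (pr + 1)] + run1;
      S2[(size_t)i + (size_t)j * (pr + 1)] =
        S2[(size_t)i + (size_t)(j - 1) * (pr + 1)] + run2;
    }
  }
  auto rect = [&](const std::vector<double>& S, int i0, int j0, int h, int w) {
    const size_t P = pr + 1;
    return S[(size_t)(i0 + h) + (size_t)(j0 + w) * P]
         - S[(size_t)i0 + (size_t)(j0 + w) * P]
         - S[(size_t)(i0 + h) + (size_t)j0 * P]
         + S[(size_t)i0 + (size_t)j0 * P];
  };

  IntegerVector status(ng), pk(ng), pl(ng);
  NumericVector peak(ng), ckm(ng), ckp(ng), clm(ng), clp(ng);
  std::vector<double> tdev((size_t)Z * Z), cmap((size_t)span * span);

  for (int g = 0; g < ng; ++g) {
    const int r0 = row0[g], c0 = col0[g];
    status[g] = 0; pk[g] = NA_INTEGER; pl[g] = NA_INTEGER;
    peak[g] = NA_REAL;
    ckm[g] = NA_REAL; ckp[g] = NA_REAL; clm[g] = NA_REAL; clp[g] = NA_REAL;

    // template statistics
    double tsum = 0.0, tsq = 0.0;
    bool t_allbg = true;
    for (int j = 0; j < Z; ++j)
      for (int i = 0; i < Z; ++i) {
        const double v = Ap[(size_t)(r0 + i) + (size_t)(c0 + j) * ar];
        tsum += v; tsq += v * v;
        if (v != (double)bg) t_allbg = false;
      }
    // empty-grid rule: no foreground in the grid at t, or in the search
    // region at t+1
    const double scnt = (double)(Z + 2 * m) * (double)(Z + 2 * m);
    const double ssum = rect(S1, r0, c0, Z + 2 * m, Z + 2 * m);
    const double ssq  = rect(S2, r0, c0, Z + 2 * m, Z + 2 * m);
    const bool s_allbg = (ssum == (double)bg * scnt) &&
                         (ssq == (double)bg * (double)bg * scnt);
    if (t_allbg || s_allbg) { status[g] = 1; continue; }
    const double tvar = tsq - tsum * tsum / Z2;
    if (tvar <= 0.5) { status[g] = 2; continue; }
    const double tmean = tsum / Z2, tnorm = std::sqrt(tvar);
    for (int j = 0; j < Z; ++j)
      for (int i = 0; i < Z; ++i)
        tdev[(size_t)i + (size_t)j * Z] =
          Ap[(size_t)(r0 + i) + (size_t)(c0 + j) * ar] - tmean;

    bool have = false;
    double bC = 0.0; int bk = 0, bl = 0;
    for (int l = -m; l <= m; ++l) {
      for (int k = -m; k <= m; ++k) {
        const int i0 = r0 + m + k, j0 = c0 + m + l;
        const double s1 = rect(S1, i0, j0, Z, Z);
        const double s2 = rect(S2, i0, j0, Z, Z);
        const double wvar = s2 - s1 * s1 / Z2;
        double C;
        if (wvar <= 0.5) {
          C = R_NaN;  // constant window: correlation undefined
        } else {
          double sx = 0.0;
          for (int j = 0; j < Z; ++j) {
            const double* bp = &Bp[(size_t)i0 + (size_t)(j0 + j) * pr];
            const double* tp = &tdev[(size_t)j * Z];
            for (int i = 0; i < Z; ++i) sx += tp[i] * bp[i];
          }
          C = sx / (tnorm * std::sqrt(wvar));
        }
        cmap[(size_t)(k + m) + (size_t)(l + m) * span] = C;
        if (!ISNAN(C)) {
          bool take = !have;
          if (!take && C > bC) take = true;
          if (!take && C == bC) {
            const int d = k * k + l * l, bd = bk * bk + bl * bl;
            if (d < bd || (d == bd && (k < bk || (k == bk && l < bl))))
              take = true;
          }
          if (take) { have = true; bC = C; bk = k; bl = l; }
        }
      }
    }
    if (!have) { status[g] = 3; continue; }
    pk[g] = bk; pl[g] = bl; peak[g] = bC;
    if (bk > -m) ckm[g] = cmap[(size_t)(bk - 1 + m) + (size_t)(bl + m) * span];
    if (bk <  m) ckp[g] = cmap[(size_t)(bk + 1 + m) + (size_t)(bl + m) * span];
    if (bl > -m) clm[g] = cmap[(size_t)(bk + m) + (size_t)(bl - 1 + m) * span];
    if (bl <  m) clp[g] = cmap[(size_t)(bk + m) + (size_t)(bl + 1 + m) * span];
  }

  return List::create(_["status"] = status, _["k"] = pk, _["l"] = pl,
                      _["peak"] = peak, _["ckm"] = ckm, _["ckp"] = ckp,
                      _["clm"] = clm, _["clp"] = clp);
}
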