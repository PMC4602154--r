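#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Stochastic hill climb growing a maximal inscribed ellipsoid inside the
// binary foreground: starting from a small sphere at the seed, propose axis
// dilations, small rotations and small translations; accept a proposal iff a
// fixed quasi-uniform field of surface sample points stays inside the
// foreground, the seed stays inside the ellipsoid, and the volume does not
// decrease. Uses R's RNG so runs are reproducible under set.seed().

static inline bool fg_at(const int *fg, int nx, int ny, int nz,
                         double px, double py, double pz) {
  int ix = (int)std::floor(px), iy = (int)std::floor(py), iz = (int)std::floor(pz);
  if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz) return false;
  return fg[ix + (long long)iy * nx + (long long)iz * nx * ny] != 0;
}

// [[Rcpp::export]]
List cpp_fit_ellipsoid(LogicalVector fg, NumericVector seed_pt,
                       double r0, double step, double max_rot,
                       double max_trans, int n_surf, int max_rejects,
                       int max_iter, int n_refine) {
  IntegerVector d = fg.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int *fgp = LOGICAL(fg);

  // Fibonacci-lattice sample points on the unit sphere
  std::vector<double> ux(n_surf), uy(n_surf), uz(n_surf);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n_surf; ++i) {
    double zc = 1.0 - 2.0 * (i + 0.5) / n_surf;
    double rr = std::sqrt(std::max(0.0, 1.0 - zc * zc));
    double ph = ga * i;
    ux[i] = rr * std::cos(ph); uy[i] = rr * std::sin(ph); uz[i] = zc;
  }

  double c[3] = {seed_pt[0], seed_pt[1], seed_pt[2]};
  double ax[3] = {r0, r0, r0};
  double Q[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};  // column-major

  auto contained = [&](const double cc[3], const double aa[3],
                       const double QQ[9]) -> bool {
    for (int i = 0; i < n_surf; ++i) {
      double lx = aa[0] * ux[i], ly = aa[1] * uy[i], lz = aa[2] * uz[i];
      double px = cc[0] + QQ[0] * lx + QQ[3] * ly + QQ[6] * lz;
      double py = cc[1] + QQ[1] * lx + QQ[4] * ly + QQ[7] * lz;
      double pz = cc[2] + QQ[2] * lx + QQ[5] * ly + QQ[8] * lz;
      if (!fg_at(fgp, nx, ny, nz, px, py, pz)) return false;
    }
    return true;
  };
  auto seed_inside = [&](const double cc[3], const double aa[3],
                         const double QQ[9]) -> bool {
    double dx = seed_pt[0] - cc[0], dy = seed_pt[1] - cc[1], dz = seed_pt[2] - cc[2];
    double y0 = (QQ[0] * dx + QQ[1] * dy + QQ[2] * dz) / aa[0];
    double y1 = (QQ[3] * dx + QQ[4] * dy + QQ[5] * dz) / aa[1];
    double y2 = (QQ[6] * dx + QQ[7] * dy + QQ[8] * dz) / aa[2];
    return y0 * y0 + y1 * y1 + y2 * y2 <= 1.0;
  };

  if (!fg_at(fgp, nx, ny, nz, c[0], c[1], c[2]))
    stop("seed point lies in the background");
  // a thin structure may not admit the requested starting radius
  while (!contained(c, ax, Q) && ax[0] > 0.1)
    ax[0] = ax[1] = ax[2] = ax[0] / 2.0;
  if (!contained(c, ax, Q))
    stop("no starting ellipsoid fits at the seed point");

  RNGScope scope;
  std::vector<double> vols;
  vols.push_back(4.0 / 3.0 * M_PI * ax[0] * ax[1] * ax[2]);

  int rejects = 0, iter = 0, accepted_rots = 0, phase = 0;
  while (iter < max_iter) {
    if (rejects >= max_rejects) {
      // refinement: re-approach the boundary with a finer dilation step
      if (phase >= n_refine) break;
      ++phase;
      step /= 4.0;
      max_trans /= 4.0;
      max_rot /= 2.0;
      rejects = 0;
    }
    ++iter;
    int type = (int)std::floor(unif_rand() * 3.0);
    if (type > 2) type = 2;
    bool ok = false;
    if (type == 0) {  // dilate one axis
      int j = (int)std::floor(unif_rand() * 3.0); if (j > 2) j = 2;
      double na[3] = {ax[0], ax[1], ax[2]};
      na[j] += step;
      if (contained(c, na, Q) && seed_inside(c, na, Q)) {
        ax[j] = na[j]; ok = true;
        vols.push_back(4.0 / 3.0 * M_PI * ax[0] * ax[1] * ax[2]);
      }
    } else if (type == 1) {  // small rotation about a random axis
      double w0 = norm_rand(), w1 = norm_rand(), w2 = norm_rand();
      double wn = std::sqrt(w0 * w0 + w1 * w1 + w2 * w2);
      if (wn < 1e-12) { ++rejects; continue; }
      w0 /= wn; w1 /= wn; w2 /= wn;
      double th = (unif_rand() * 2.0 - 1.0) * max_rot;
      double ct = std::cos(th), st = std::sin(th), vt = 1.0 - ct;
      double R[9] = {
        ct + w0 * w0 * vt,      w1 * w0 * vt + w2 * st, w2 * w0 * vt - w1 * st,
        w0 * w1 * vt - w2 * st, ct + w1 * w1 * vt,      w2 * w1 * vt + w0 * st,
        w0 * w2 * vt + w1 * st, w1 * w2 * vt - w0 * st, ct + w2 * w2 * vt};
      double Qn[9];
      for (int col = 0; col < 3; ++col)
        for (int row = 0; row < 3; ++row)
          Qn[3 * col + row] = R[row] * Q[3 * col] + R[row + 3] * Q[3 * col + 1] +
                              R[row + 6] * Q[3 * col + 2];
      if (contained(c, ax, Qn) && seed_inside(c, ax, Qn)) {
        for (int k = 0; k < 9; ++k) Q[k] = Qn[k];
        ok = true;
        if (++accepted_rots % 64 == 0) {  // re-orthonormalize (Gram-Schmidt)
          double n0 = std::sqrt(Q[0] * Q[0] + Q[1] * Q[1] + Q[2] * Q[2]);
          for (int k = 0; k < 3; ++k) Q[k] /= n0;
          double dp = Q[0] * Q[3] + Q[1] * Q[4] + Q[2] * Q[5];
          for (int k = 0; k < 3; ++k) Q[3 + k] -= dp * Q[k];
          double n1 = std::sqrt(Q[3] * Q[3] + Q[4] * Q[4] + Q[5] * Q[5]);
          for (int k = 0; k < 3; ++k) Q[3 + k] /= n1;
          Q[6] = Q[1] * Q[5] - Q[2] * Q[4];
          Q[7] = Q[2] * Q[3] - Q[0] * Q[5];
          Q[8] = Q[0] * Q[4] - Q[1] * Q[3];
        }
      }
    } else {  // small translation
      double cn[3] = {c[0] + (unif_rand() * 2.0 - 1.0) * max_trans,
                      c[1] + (unif_rand() * 2.0 - 1.0) * max_trans,
                      c[2] + (unif_rand() * 2.0 - 1.0) * max_trans};
      if (contained(cn, ax, Q) && seed_inside(cn, ax, Q)) {
        c[0] = cn[0]; c[1] = cn[1]; c[2] = cn[2]; ok = true;
      }
    }
    if (ok) rejects = 0; else ++rejects;
  }

  NumericMatrix Qm(3, 3);
  for (int col = 0; col < 3; ++col)
    for (int row = 0; row < 3; ++row) Qm(row, col) = Q[3 * col + row];
  return List::create(_["center"] = NumericVector::create(c[0], c[1], c[2]),
                      _["semi_axes"] = NumericVector::create(ax[0], ax[1], ax[2]),
                      _["orientation"] = Qm,
                      _["volumes"] = NumericVector(vols.begin(), vols.end()),
                      _["iterations"] = iter);
}
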