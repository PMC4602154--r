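#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Iso-surface extraction on a voxel grid by marching a uniform Kuhn
// (6-tetrahedra) decomposition of each cube cell. Sharing the main diagonal
// and identically oriented face diagonals across neighbouring cells makes the
// triangulation consistent on shared faces, so the extracted surface is
// crack-free and watertight whenever the grid boundary is background.
//
// Corner numbering within a cell: bit0 = +x, bit1 = +y, bit2 = +z.
// Every tetrahedron is {0, a, a|b, 7}: the six orderings of (+x,+y,+z).
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

// [[Rcpp::export]]
List cpp_mesh_extract(NumericVector vol, double iso) {
  IntegerVector d = vol.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const long long sy = nx, sz = (long long)nx * ny;
  const long long NP = (long long)nx * ny * nz;

  std::unordered_map<long long, int> vmap;
  std::vector<double> V;   // flat xyz triplets
  std::vector<int> F;      // flat 0-based vertex index triplets

  // lattice-point coordinates / ids for the 8 corners of the current cell
  int cx[8], cy[8], cz[8];
  long long cid[8];
  double cv[8];

  // interpolated vertex on the segment between corners a and b (local ids),
  // deduplicated on the canonical (sorted) lattice-point pair
  auto edge_vertex = [&](int a, int b) -> int {
    long long ia = cid[a], ib = cid[b];
    int lo = a, hi = b;
    if (ia > ib) { std::swap(ia, ib); std::swap(lo, hi); }
    long long key = ia * NP + ib;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double v0 = cv[lo], v1 = cv[hi];
    double t = (iso - v0) / (v1 - v0);
    int idx = (int)(V.size() / 3);
    V.push_back(cx[lo] + t * (cx[hi] - cx[lo]));
    V.push_back(cy[lo] + t * (cy[hi] - cy[lo]));
    V.push_back(cz[lo] + t * (cz[hi] - cz[lo]));
    vmap.emplace(key, idx);
    return idx;
  };

  // append a triangle, oriented so its normal points away from `ref`
  auto emit = [&](int v1, int v2, int v3, const double ref[3]) {
    const double *p1 = &V[3 * (size_t)v1], *p2 = &V[3 * (size_t)v2],
                 *p3 = &V[3 * (size_t)v3];
    double u[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
    double w[3] = {p3[0] - p1[0], p3[1] - p1[1], p3[2] - p1[2]};
    double n0 = u[1] * w[2] - u[2] * w[1];
    double n1 = u[2] * w[0] - u[0] * w[2];
    double n2 = u[0] * w[1] - u[1] * w[0];
    double a2 = n0 * n0 + n1 * n1 + n2 * n2;
    if (a2 < 1e-24) return;  // degenerate
    double gx = (p1[0] + p2[0] + p3[0]) / 3.0 - ref[0];
    double gy = (p1[1] + p2[1] + p3[1]) / 3.0 - ref[1];
    double gz = (p1[2] + p2[2] + p3[2]) / 3.0 - ref[2];
    if (n0 * gx + n1 * gy + n2 * gz < 0) std::swap(v2, v3);
    F.push_back(v1); F.push_back(v2); F.push_back(v3);
  };

  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        int nin = 0;
        for (int c = 0; c < 8; ++c) {
          cx[c] = x + (c & 1); cy[c] = y + ((c >> 1) & 1); cz[c] = z + (c >> 2);
          cid[c] = cx[c] + cy[c] * sy + cz[c] * sz;
          cv[c] = vol[cid[c]];
          if (cv[c] >= iso) ++nin;
        }
        if (nin == 0 || nin == 8) continue;
        for (int t = 0; t < 6; ++t) {
          const int *tc = TETS[t];
          int in[4], cnt = 0;
          for (int k = 0; k < 4; ++k) {
            in[k] = cv[tc[k]] >= iso;
            cnt += in[k];
          }
          if (cnt == 0 || cnt == 4) continue;
          // centroid of inside corners: the surface normal points away from it
          double ref[3] = {0, 0, 0};
          int ni = 0;
          for (int k = 0; k < 4; ++k)
            if (in[k]) {
              ref[0] += cx[tc[k]]; ref[1] += cy[tc[k]]; ref[2] += cz[tc[k]];
              ++ni;
            }
          ref[0] /= ni; ref[1] /= ni; ref[2] /= ni;
          if (cnt == 1 || cnt == 3) {
            int apex = -1;
            for (int k = 0; k < 4; ++k)
              if (in[k] == (cnt == 1)) apex = k;
            int e[3], m = 0;
            for (int k = 0; k < 4; ++k)
              if (k != apex) e[m++] = edge_vertex(tc[apex], tc[k]);
            emit(e[0], e[1], e[2], ref);
          } else {  // 2 in, 2 out -> quad
            int i = -1, j = -1, ko = -1, l = -1;
            for (int k = 0; k < 4; ++k) {
              if (in[k]) { if (i < 0) i = k; else j = k; }
              else       { if (ko < 0) ko = k; else l = k; }
            }
            int q0 = edge_vertex(tc[i], tc[ko]);
            int q1 = edge_vertex(tc[i], tc[l]);
            int q2 = edge_vertex(tc[j], tc[l]);
            int q3 = edge_vertex(tc[j], tc[ko]);
            emit(q0, q1, q2, ref);
            emit(q0, q2, q3, ref);
          }
        }
      }

  size_t nv = V.size() / 3, nf = F.size() / 3;
  NumericMatrix verts(nv, 3);
  for (size_t i = 0; i < nv; ++i) {
    verts(i, 0) = V[3 * i]; verts(i, 1) = V[3 * i + 1]; verts(i, 2) = V[3 * i + 2];
  }
  IntegerMatrix faces(nf, 3);
  for (size_t i = 0; i < nf; ++i) {
    faces(i, 0) = F[3 * i] + 1; faces(i, 1) = F[3 * i + 1] + 1;
    faces(i, 2) = F[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
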