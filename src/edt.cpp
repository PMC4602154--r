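#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher's
// separable lower-envelope algorithm), distance measured between voxel
// centers, in voxel units. Foreground voxels get the squared distance to the
// nearest background voxel; background voxels get 0. Voxels outside the stack
// are NOT treated as background here (callers pad if they want that).
static void dt1d(std::vector<double> &f, int n) {
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1), out(n);
  int k = 0;
  v[0] = 0; zb[0] = -INF; zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + q * (double)q) - (f[p] + p * (double)p)) / (2.0 * (q - p));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k; v[k] = q; zb[k] = s; zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    out[q] = dq * dq + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = out[q];
}

// [[Rcpp::export]]
NumericVector cpp_sqedt(LogicalVector fg) {
  IntegerVector d = fg.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const long long sy = nx, sz = (long long)nx * ny;
  // large finite sentinel (not Inf: the parabola intersections must stay
  // finite); any true squared distance is bounded by the stack diagonal
  const double BIG = 1e12;
  NumericVector out(fg.size());
  for (long long i = 0; i < fg.size(); ++i) out[i] = fg[i] ? BIG : 0.0;

  std::vector<double> line;
  line.resize(std::max(nx, std::max(ny, nz)));
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      long long base = y * sy + z * sz;
      for (int x = 0; x < nx; ++x) line[x] = out[base + x];
      dt1d(line, nx);
      for (int x = 0; x < nx; ++x) out[base + x] = line[x];
    }
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      long long base = x + z * sz;
      for (int y = 0; y < ny; ++y) line[y] = out[base + y * sy];
      dt1d(line, ny);
      for (int y = 0; y < ny; ++y) out[base + y * sy] = line[y];
    }
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      long long base = x + y * sy;
      for (int z = 0; z < nz; ++z) line[z] = out[base + z * sz];
      dt1d(line, nz);
      for (int z = 0; z < nz; ++z) out[base + z * sz] = line[z];
    }
  out.attr("dim") = d;
  return out;
}
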