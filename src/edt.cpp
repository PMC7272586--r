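#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher 1D squared-distance transform of a sampled
// function, generalised to a non-unit sample spacing h (parabolas have
// curvature h^2 in index units).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double h2) {
  int k = 0;
  v[0] = 0;
  z[0] = -HUGE_VAL;
  z[1] = HUGE_VAL;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + h2 * (double)q * q) - (f[v[k]] + h2 * (double)v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
      if (k > 0 && s <= z[k]) k--; else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = HUGE_VAL;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)q - v[k];
    d[q] = h2 * dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance transform of a binary grid with anisotropic
// spacing. Returns, for each TRUE voxel, the distance (in physical units)
// to the centre of the nearest FALSE voxel; FALSE voxels map to 0.
// Works for 2D grids by passing nz = 1.
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = (dim.size() > 2) ? dim[2] : 1;
  double sx = spacing[0], sy = spacing[1],
         sz = (spacing.size() > 2) ? spacing[2] : 1.0;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double BIG = 1e30;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; i++) g[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t off = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; i++) f[i] = g[off + i];
      dt1d(f, d, v, z, nx, sx * sx);
      for (int i = 0; i < nx; i++) g[off + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t off = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; j++) f[j] = g[off + (R_xlen_t)j * nx];
      dt1d(f, d, v, z, ny, sy * sy);
      for (int j = 0; j < ny; j++) g[off + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  if (nz > 1) {
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        R_xlen_t off = (R_xlen_t)j * nx + i;
        for (int k = 0; k < nz; k++) f[k] = g[off + (R_xlen_t)k * nx * ny];
        dt1d(f, d, v, z, nz, sz * sz);
        for (int k = 0; k < nz; k++) g[off + (R_xlen_t)k * nx * ny] = d[k];
      }
  }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}
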