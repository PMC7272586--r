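#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shared ellipsoidal-neighbourhood walk: visits every voxel whose centre
// lies within physical radius r of centre voxel (ci,cj,ck) and calls fn.
template <typename F>
static inline void for_sphere(int ci, int cj, int ck, double r,
                              int nx, int ny, int nz,
                              double sx, double sy, double sz, F fn) {
  int ri = (int)std::floor(r / sx), rj = (int)std::floor(r / sy),
      rk = (int)std::floor(r / sz);
  double r2 = r * r;
  for (int dk = -rk; dk <= rk; dk++) {
    int k = ck + dk;
    if (k < 0 || k >= nz) continue;
    double z2 = (double)dk * sz * dk * sz;
    for (int dj = -rj; dj <= rj; dj++) {
      int j = cj + dj;
      if (j < 0 || j >= ny) continue;
      double yz2 = z2 + (double)dj * sy * dj * sy;
      if (yz2 > r2) continue;
      double xr = std::sqrt(r2 - yz2) / sx;
      int di0 = -(int)std::floor(xr), di1 = (int)std::floor(xr);
      for (int di = di0; di <= di1; di++) {
        int i = ci + di;
        if (i < 0 || i >= nx) continue;
        fn((R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i);
      }
    }
  }
}

// Brute-force local thickness map: for every voxel of the phase, the
// diameter of the largest inscribed sphere (fully inside the phase) that
// contains the voxel. `radius` holds the inscribed-sphere radius at every
// voxel (0 outside the phase); `ord` gives 0-based voxel indices sorted by
// decreasing radius. Painting every sphere exhaustively makes this the
// independent verifier for the greedy pore algorithm.
// [[Rcpp::export]]
NumericVector local_thickness_cpp(NumericVector radius, IntegerVector ord,
                                  IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = (dim.size() > 2) ? dim[2] : 1;
  double sx = spacing[0], sy = spacing[1],
         sz = (spacing.size() > 2) ? spacing[2] : 1.0;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector lt(n);
  for (R_xlen_t q = 0; q < ord.size(); q++) {
    R_xlen_t c = ord[q];
    double r = radius[c];
    if (r <= 0) continue;
    double dvox = 2.0 * r;
    int ck = (int)(c / ((R_xlen_t)nx * ny));
    R_xlen_t rem = c - (R_xlen_t)ck * nx * ny;
    int cj = (int)(rem / nx), ci = (int)(rem % nx);
    for_sphere(ci, cj, ck, r, nx, ny, nz, sx, sy, sz, [&](R_xlen_t u) {
      if (lt[u] < dvox) lt[u] = dvox;
    });
  }
  lt.attr("dim") = dim;
  return lt;
}

// Greedy maximal-sphere acceptance for one analysis step. Candidates
// (0-based indices, pre-sorted by decreasing radius then ascending index)
// are accepted iff their centre is not inside any previously accepted
// sphere; each accepted sphere is painted into the coverage mask. The
// number of phase voxels newly covered by each sphere is recorded: since
// spheres are painted in decreasing size order, it equals the number of
// voxels whose largest containing accepted sphere is this one, i.e. the
// sphere's weight in the volume-weighted pore-size distribution.
// Returns accepted centre indices (1-based), radii, newly covered phase
// volume (voxel counts), and the coverage mask (union of accepted
// spheres) used for residual deletion.
// [[Rcpp::export]]
List greedy_spheres_cpp(NumericVector radius, IntegerVector cand,
                        IntegerVector dim, NumericVector spacing,
                        LogicalVector phase) {
  int nx = dim[0], ny = dim[1], nz = (dim.size() > 2) ? dim[2] : 1;
  double sx = spacing[0], sy = spacing[1],
         sz = (spacing.size() > 2) ? spacing[2] : 1.0;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector covered(n);
  std::vector<int> acc;
  std::vector<double> accr, accv;
  for (R_xlen_t q = 0; q < cand.size(); q++) {
    R_xlen_t c = cand[q];
    if (covered[c]) continue;
    double r = radius[c];
    if (r <= 0) continue;
    int ck = (int)(c / ((R_xlen_t)nx * ny));
    R_xlen_t rem = c - (R_xlen_t)ck * nx * ny;
    int cj = (int)(rem / nx), ci = (int)(rem % nx);
    double nnew = 0;
    for_sphere(ci, cj, ck, r, nx, ny, nz, sx, sy, sz, [&](R_xlen_t u) {
      if (!covered[u] && phase[u]) nnew += 1;
      covered[u] = true;
    });
    acc.push_back((int)c + 1);
    accr.push_back(r);
    accv.push_back(nnew);
  }
  covered.attr("dim") = dim;
  return List::create(_["index"] = wrap(acc), _["radius"] = wrap(accr),
                      _["n_new"] = wrap(accv), _["covered"] = covered);
}

// Voxel-wise containment check: are all voxel centres within radius r of
// the given centre inside the phase? Used by invariant tests.
// [[Rcpp::export]]
bool sphere_inside_cpp(LogicalVector phase, IntegerVector dim,
                       NumericVector spacing, IntegerVector centre,
                       double r) {
  int nx = dim[0], ny = dim[1], nz = (dim.size() > 2) ? dim[2] : 1;
  double sx = spacing[0], sy = spacing[1],
         sz = (spacing.size() > 2) ? spacing[2] : 1.0;
  int ci = centre[0] - 1, cj = centre[1] - 1,
      ck = (centre.size() > 2) ? centre[2] - 1 : 0;
  bool ok = true;
  for_sphere(ci, cj, ck, r, nx, ny, nz, sx, sy, sz, [&](R_xlen_t u) {
    if (!phase[u]) ok = false;
  });
  // spheres may not extend outside the grid (faces are solid)
  if (ci * sx < r - sx || cj * sy < r - sy ||
      (nx - 1 - ci) * sx < r - sx || (ny - 1 - cj) * sy < r - sy)
    ok = false;
  if (nz > 1 && (ck * sz < r - sz || (nz - 1 - ck) * sz < r - sz))
    ok = false;
  return ok;
}

// 26-connected (8-connected in 2D) local maxima of a scalar field,
// restricted to positive values; plateaus count as maxima.
// [[Rcpp::export]]
LogicalVector local_maxima_cpp(NumericVector x, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = (dim.size() > 2) ? dim[2] : 1;
  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        R_xlen_t c = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
        double v = x[c];
        if (v <= 0) continue;
        bool mx = true;
        for (int dk = -1; dk <= 1 && mx; dk++) {
          int kk = k + dk;
          if (kk < 0 || kk >= nz) continue;
          for (int dj = -1; dj <= 1 && mx; dj++) {
            int jj = j + dj;
            if (jj < 0 || jj >= ny) continue;
            for (int di = -1; di <= 1; di++) {
              int ii = i + di;
              if (ii < 0 || ii >= nx || (di == 0 && dj == 0 && dk == 0))
                continue;
              if (x[(R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii] > v) {
                mx = false;
                break;
              }
            }
          }
        }
        out[c] = mx;
      }
  out.attr("dim") = dim;
  return out;
}
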