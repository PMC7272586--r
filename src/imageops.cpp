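#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian blur with reflective boundaries; sigma given in voxel
// units per axis (0 disables the pass). Handles 2D via nz = 1.
// [[Rcpp::export]]
NumericVector gauss_blur_cpp(NumericVector img, IntegerVector dim,
                             NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = (dim.size() > 2) ? dim[2] : 1;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(img.begin(), img.end()), b(n);

  int dims[3] = {nx, ny, nz};
  R_xlen_t strides[3] = {1, nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ax++) {
    double s = (ax < sigma.size()) ? sigma[ax] : 0.0;
    if (s <= 0 || dims[ax] == 1) continue;
    int rad = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> ker(2 * rad + 1);
    double sum = 0;
    for (int t = -rad; t <= rad; t++) {
      ker[t + rad] = std::exp(-0.5 * t * t / (s * s));
      sum += ker[t + rad];
    }
    for (double& kv : ker) kv /= sum;
    int len = dims[ax];
    R_xlen_t st = strides[ax];
    // iterate over all lines along axis ax
    for (int k = 0; k < ((ax == 2) ? 1 : nz); k++)
      for (int j = 0; j < ((ax == 1) ? 1 : ny); j++)
        for (int i = 0; i < ((ax == 0) ? 1 : nx); i++) {
          R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
          if (ax == 2) base = (R_xlen_t)j * nx + i;
          for (int p = 0; p < len; p++) {
            double acc = 0;
            for (int t = -rad; t <= rad; t++) {
              int q = p + t;
              if (q < 0) q = -q - 1;          // reflect
              if (q >= len) q = 2 * len - q - 1;
              acc += ker[t + rad] * a[base + (R_xlen_t)q * st];
            }
            b[base + (R_xlen_t)p * st] = acc;
          }
        }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Connected-component labelling (6- or 26-connectivity; 4/8 in 2D).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = (dim.size() > 2) ? dim[2] : 1;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  bool full = connectivity >= 18;
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t c = stack.back();
      stack.pop_back();
      int k = (int)(c / ((R_xlen_t)nx * ny));
      R_xlen_t rem = c - (R_xlen_t)k * nx * ny;
      int j = (int)(rem / nx), i = (int)(rem % nx);
      for (int dk = -1; dk <= 1; dk++) {
        int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; dj++) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; di++) {
            int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            int man = std::abs(di) + std::abs(dj) + std::abs(dk);
            if (man == 0 || (!full && man > 1)) continue;
            R_xlen_t u = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
            if (mask[u] && !lab[u]) {
              lab[u] = next;
              stack.push_back(u);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Rasterise capsules (cylinders with hemispherical caps) given by segment
// endpoints (um) and radii (um) into a voxel mask, by marching along each
// segment and stamping balls.
// [[Rcpp::export]]
LogicalVector raster_fibers_cpp(IntegerVector dim, NumericVector spacing,
                                NumericMatrix p0, NumericMatrix p1,
                                NumericVector radius) {
  int nx = dim[0], ny = dim[1], nz = (dim.size() > 2) ? dim[2] : 1;
  double sx = spacing[0], sy = spacing[1],
         sz = (spacing.size() > 2) ? spacing[2] : 1.0;
  LogicalVector mask((R_xlen_t)nx * ny * nz);
  double hmin = std::min(sx, std::min(sy, nz > 1 ? sz : sx));
  for (int f = 0; f < p0.nrow(); f++) {
    double r = radius[f], r2 = r * r;
    double ax = p0(f, 0), ay = p0(f, 1), az = (nz > 1) ? p0(f, 2) : 0.0;
    double bx = p1(f, 0), by = p1(f, 1), bz = (nz > 1) ? p1(f, 2) : 0.0;
    double len = std::sqrt((bx - ax) * (bx - ax) + (by - ay) * (by - ay) +
                           (bz - az) * (bz - az));
    int nstep = std::max(1, (int)std::ceil(len / (hmin * 0.5)));
    for (int s = 0; s <= nstep; s++) {
      double t = (double)s / nstep;
      double cx = ax + t * (bx - ax), cy = ay + t * (by - ay),
             cz = az + t * (bz - az);
      int i0 = std::max(0, (int)std::floor((cx - r) / sx)),
          i1 = std::min(nx - 1, (int)std::ceil((cx + r) / sx));
      int j0 = std::max(0, (int)std::floor((cy - r) / sy)),
          j1 = std::min(ny - 1, (int)std::ceil((cy + r) / sy));
      int k0 = 0, k1 = 0;
      if (nz > 1) {
        k0 = std::max(0, (int)std::floor((cz - r) / sz));
        k1 = std::min(nz - 1, (int)std::ceil((cz + r) / sz));
      }
      for (int k = k0; k <= k1; k++) {
        double dz = (nz > 1) ? k * sz - cz : 0.0;
        double dz2 = dz * dz;
        if (dz2 > r2) continue;
        for (int j = j0; j <= j1; j++) {
          double dy = j * sy - cy;
          double dyz2 = dz2 + dy * dy;
          if (dyz2 > r2) continue;
          for (int i = i0; i <= i1; i++) {
            double dx = i * sx - cx;
            if (dx * dx + dyz2 <= r2)
              mask[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] = true;
          }
        }
      }
    }
  }
  mask.attr("dim") = dim;
  return mask;
}

// Rasterise a rotated solid ellipsoid: voxel centres x with
// |R^T (x - c)| scaled by the semi-axes <= 1.
// [[Rcpp::export]]
LogicalVector raster_ellipsoid_cpp(IntegerVector dim, NumericVector spacing,
                                   NumericVector centre, NumericVector semi,
                                   NumericMatrix rot) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  LogicalVector mask((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        double d0 = i * sx - centre[0], d1 = j * sy - centre[1],
               d2 = k * sz - centre[2];
        double u0 = rot(0, 0) * d0 + rot(1, 0) * d1 + rot(2, 0) * d2;
        double u1 = rot(0, 1) * d0 + rot(1, 1) * d1 + rot(2, 1) * d2;
        double u2 = rot(0, 2) * d0 + rot(1, 2) * d1 + rot(2, 2) * d2;
        double q = (u0 / semi[0]) * (u0 / semi[0]) +
                   (u1 / semi[1]) * (u1 / semi[1]) +
                   (u2 / semi[2]) * (u2 / semi[2]);
        if (q <= 1.0)
          mask[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] = true;
      }
  mask.attr("dim") = dim;
  return mask;
}

// Add truncated Gaussian blobs (nuclei) to an intensity volume in place.
// [[Rcpp::export]]
NumericVector add_blobs_cpp(NumericVector img, IntegerVector dim,
                            NumericVector spacing, NumericMatrix centres,
                            NumericVector sigma, double amplitude) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  NumericVector out = clone(img);
  double gx = sigma[0], gy = sigma[1], gz = sigma[2];
  for (int b = 0; b < centres.nrow(); b++) {
    double cx = centres(b, 0), cy = centres(b, 1), cz = centres(b, 2);
    int i0 = std::max(0, (int)std::floor((cx - 4 * gx) / sx)),
        i1 = std::min(nx - 1, (int)std::ceil((cx + 4 * gx) / sx));
    int j0 = std::max(0, (int)std::floor((cy - 4 * gy) / sy)),
        j1 = std::min(ny - 1, (int)std::ceil((cy + 4 * gy) / sy));
    int k0 = std::max(0, (int)std::floor((cz - 4 * gz) / sz)),
        k1 = std::min(nz - 1, (int)std::ceil((cz + 4 * gz) / sz));
    for (int k = k0; k <= k1; k++) {
      double ez = (k * sz - cz) / gz;
      for (int j = j0; j <= j1; j++) {
        double ey = (j * sy - cy) / gy;
        for (int i = i0; i <= i1; i++) {
          double ex = (i * sx - cx) / gx;
          out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] +=
              amplitude * std::exp(-0.5 * (ex * ex + ey * ey + ez * ez));
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
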