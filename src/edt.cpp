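#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact squared Euclidean distance transform along one sampled axis with
// physical sample step `s` (Felzenszwalb & Huttenlocher lower-envelope
// algorithm, generalised to non-unit spacing). `f` holds squared distances
// on input and output; `n` samples at positions 0, s, 2s, ...
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double s) {
  const double s2 = s * s;
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double inter;
    while (true) {
      int p = v[k];
      inter = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) /
              (2.0 * s2 * (q - p));
      if (inter <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = inter;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    int p = v[k];
    d[q] = s2 * (q - p) * (q - p) + f[p];
  }
}

// Exact anisotropic Euclidean distance transform of a 3D foreground mask.
// Returns per-voxel minimum distance (mm) to the foreground set, where index
// offsets are weighted by per-axis spacings.
// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector fg, IntegerVector dims,
                        NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (fg.size() != n) stop("mask size does not match dims");
  const double BIG = 1e30;

  NumericVector D(n);
  bool any_fg = false;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (fg[i]) { D[i] = 0.0; any_fg = true; } else D[i] = BIG;
  }
  if (!any_fg) stop("empty foreground");

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (stride 1)
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = D[base + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) D[base + i] = d[i];
    }
  }
  // pass along y (stride nx)
  for (int k = 0; k < nz; ++k) {
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = D[base + (R_xlen_t)j * nx];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) D[base + (R_xlen_t)j * nx] = d[j];
    }
  }
  // pass along z (stride nx*ny)
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = D[base + (R_xlen_t)k * sz];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) D[base + (R_xlen_t)k * sz] = d[k];
    }
  }

  for (R_xlen_t i = 0; i < n; ++i) D[i] = std::sqrt(D[i]);
  return D;
}
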