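#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxels of `sel` (e.g. the fine ring) having at least one 6-neighbour whose
// distance-map value exceeds `ds` and which lies inside `bone`. Neighbours
// outside the lattice never qualify (bone-clipped / grid-clipped faces are
// excluded from evaluation by construction).
// [[Rcpp::export]]
LogicalVector outward_boundary_cpp(LogicalVector sel, NumericVector D,
                                   LogicalVector bone, IntegerVector dims,
                                   double ds) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * sz + (R_xlen_t)j * sy;
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = base + i;
        if (!sel[idx]) continue;
        bool hit = false;
        if (i > 0      && bone[idx - 1]  && D[idx - 1]  > ds) hit = true;
        if (!hit && i < nx - 1 && bone[idx + 1]  && D[idx + 1]  > ds) hit = true;
        if (!hit && j > 0      && bone[idx - sy] && D[idx - sy] > ds) hit = true;
        if (!hit && j < ny - 1 && bone[idx + sy] && D[idx + sy] > ds) hit = true;
        if (!hit && k > 0      && bone[idx - sz] && D[idx - sz] > ds) hit = true;
        if (!hit && k < nz - 1 && bone[idx + sz] && D[idx + sz] > ds) hit = true;
        out[idx] = hit;
      }
    }
  }
  return out;
}

// True voxels with at least one false 6-neighbour (outside the lattice counts
// as false): the one-voxel-thick surface shell of a mask.
// [[Rcpp::export]]
LogicalVector boundary6_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * sz + (R_xlen_t)j * sy;
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = base + i;
        if (!mask[idx]) continue;
        bool edge =
          (i == 0      || !mask[idx - 1])  ||
          (i == nx - 1 || !mask[idx + 1])  ||
          (j == 0      || !mask[idx - sy]) ||
          (j == ny - 1 || !mask[idx + sy]) ||
          (k == 0      || !mask[idx - sz]) ||
          (k == nz - 1 || !mask[idx + sz]);
        out[idx] = edge;
      }
    }
  }
  return out;
}

// All-pairs minimum Euclidean distance from each query point to a reference
// point set. Deliberately exhaustive: serves as the independent oracle
// against spatial-index queries and the distance transform.
// [[Rcpp::export]]
NumericVector min_dist_brute_cpp(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (nr == 0) stop("empty reference point set");
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    const double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    double best = R_PosInf;
    for (int r = 0; r < nr; ++r) {
      const double dx = ref(r, 0) - qx;
      const double dy = ref(r, 1) - qy;
      const double dz = ref(r, 2) - qz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[q] = std::sqrt(best);
  }
  return out;
}
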