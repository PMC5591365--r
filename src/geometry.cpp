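#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// 1D squared-distance transform (Felzenszwalb & Huttenlocher lower envelope),
// generalised to a sample step `h` so anisotropic spacing is honoured:
// out[i] = min_j ( f[j] + h^2 * (i - j)^2 ).
static void dt1d(const double *f, double *out, int n, double h2,
                 std::vector<int> &v, std::vector<double> &z) {
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) { // no finite sample on this line
    for (int q = 0; q < n; ++q) out[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue; // +Inf samples contribute no parabola
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2.0 * h2 * (q - p));
      if (s <= z[k]) { --k; } else break; // all parabolas finite: k stays >= 0
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    int p = v[j];
    double d = (double)q - (double)p;
    out[q] = f[p] + h2 * d * d;
  }
}

// Exact squared Euclidean distance transform of a 3D binary mask with
// anisotropic spacing. Returns, for every voxel, the squared distance (mm^2)
// from its centre to the nearest centre of a TRUE voxel. All-FALSE input
// yields +Inf everywhere.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double hx2 = spacing[0] * spacing[0];
  const double hy2 = spacing[1] * spacing[1];
  const double hz2 = spacing[2] * spacing[2];
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector d(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) d[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index in R column-major order)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double *col = &d[0] + (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      bool any = false;
      for (int i = 0; i < nx; ++i) { f[i] = col[i]; if (R_finite(f[i])) any = true; }
      if (!any) continue;
      dt1d(f.data(), out.data(), nx, hx2, v, z);
      for (int i = 0; i < nx; ++i) col[i] = out[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      bool any = false;
      for (int j = 0; j < ny; ++j) { f[j] = d[base + (R_xlen_t)j * nx]; if (R_finite(f[j])) any = true; }
      if (!any) continue;
      dt1d(f.data(), out.data(), ny, hy2, v, z);
      for (int j = 0; j < ny; ++j) d[base + (R_xlen_t)j * nx] = out[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      bool any = false;
      for (int k = 0; k < nz; ++k) { f[k] = d[base + (R_xlen_t)k * nx * ny]; if (R_finite(f[k])) any = true; }
      if (!any) continue;
      dt1d(f.data(), out.data(), nz, hz2, v, z);
      for (int k = 0; k < nz; ++k) d[base + (R_xlen_t)k * nx * ny] = out[k];
    }
  d.attr("dim") = dim;
  return d;
}

// Maximum pairwise Euclidean distance between rows of an n x 3 coordinate
// matrix (mm). Exact O(n^2) search; callers restrict to boundary voxels,
// which contain the extreme points.
// [[Rcpp::export]]
double cpp_max_pairwise(NumericMatrix pts) {
  const int n = pts.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  }
  return std::sqrt(best);
}
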