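#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Exact squared Euclidean distance transform of a 1-D sampled function
// (Felzenszwalb & Huttenlocher lower-envelope algorithm), with anisotropic
// sample step `w` (mm): d[p] = min_q ( w^2 (p-q)^2 + f[q] ).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, double w2) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  // infinite parabolas (no background on this line yet) are skipped
  int k = 0;
  int first = -1;
  for (int q = 0; q < n; ++q) if (f[q] < INF) { first = q; break; }
  if (first < 0) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  v[0] = first; z[0] = -INF; z[1] = INF; k = 0;
  for (int q = first + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s > z[k]) break;
      --k;
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
    d[q] = w2 * (double)(q - p) * (double)(q - p) + f[p];
  }
}

// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  std::vector<double> g(n);
  // 0 at background (mask == FALSE), INF inside the mask
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  double w2 = spacing[0] * spacing[0];
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx;
      for (int xx = 0; xx < nx; ++xx) f[xx] = g[base + xx];
      f.resize(nx); d.resize(nx);
      dt1d(f, d, v, z, w2);
      for (int xx = 0; xx < nx; ++xx) g[base + xx] = d[xx];
      f.resize(nmax); d.resize(nmax);
    }
  // pass along y
  w2 = spacing[1] * spacing[1];
  for (int zz = 0; zz < nz; ++zz)
    for (int xx = 0; xx < nx; ++xx) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + xx;
      for (int yy = 0; yy < ny; ++yy) f[yy] = g[base + (R_xlen_t)yy * nx];
      f.resize(ny); d.resize(ny);
      dt1d(f, d, v, z, w2);
      for (int yy = 0; yy < ny; ++yy) g[base + (R_xlen_t)yy * nx] = d[yy];
      f.resize(nmax); d.resize(nmax);
    }
  // pass along z
  w2 = spacing[2] * spacing[2];
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int yy = 0; yy < ny; ++yy)
    for (int xx = 0; xx < nx; ++xx) {
      R_xlen_t base = (R_xlen_t)yy * nx + xx;
      for (int zz = 0; zz < nz; ++zz) f[zz] = g[base + (R_xlen_t)zz * nxy];
      f.resize(nz); d.resize(nz);
      dt1d(f, d, v, z, w2);
      for (int zz = 0; zz < nz; ++zz) g[base + (R_xlen_t)zz * nxy] = d[zz];
      f.resize(nmax); d.resize(nmax);
    }

  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = std::isinf(g[i]) ? R_PosInf : std::sqrt(g[i]);
  return out;
}
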