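#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Exact Euclidean distance transform of a binary indicator on an
// anisotropic grid (Felzenszwalb & Huttenlocher lower-envelope algorithm,
// run separably with per-axis physical spacing).

static void dt1d(const std::vector<double> &f, double s, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;  // parabola at infinite height never wins
    double sconst;
    while (true) {
      const int p = v[k];
      const double xq = q * s, xp = p * s;
      sconst = ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2 * xq - 2 * xp);
      if (k > 0 && sconst <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sconst;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * s;
    while (z[k + 1] < xq) ++k;
    const double xp = v[k] * s;
    d[q] = (xq - xp) * (xq - xp) + f[v[k]];
  }
}

// mask: nonzero voxels are the point set; returns squared distances (mm^2)
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dim, NumericVector spc) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *o = out.begin();
  const int *m = mask.begin();
  auto idx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  };
  for (R_xlen_t t = 0; t < out.size(); ++t) o[t] = m[t] ? 0.0 : INF;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      bool any = false;
      for (int i = 0; i < nx; ++i) { f[i] = o[idx(i, j, k)]; if (f[i] < INF) any = true; }
      if (!any) continue;
      f.resize(nx); d.resize(nx);
      dt1d(f, spc[0], d, v, z);
      for (int i = 0; i < nx; ++i) o[idx(i, j, k)] = d[i];
      f.resize(nmax); d.resize(nmax);
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      bool any = false;
      for (int j = 0; j < ny; ++j) { f[j] = o[idx(i, j, k)]; if (f[j] < INF) any = true; }
      if (!any) continue;
      f.resize(ny); d.resize(ny);
      dt1d(f, spc[1], d, v, z);
      for (int j = 0; j < ny; ++j) o[idx(i, j, k)] = d[j];
      f.resize(nmax); d.resize(nmax);
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      bool any = false;
      for (int k = 0; k < nz; ++k) { f[k] = o[idx(i, j, k)]; if (f[k] < INF) any = true; }
      if (!any) continue;
      f.resize(nz); d.resize(nz);
      dt1d(f, spc[2], d, v, z);
      for (int k = 0; k < nz; ++k) o[idx(i, j, k)] = d[k];
      f.resize(nmax); d.resize(nmax);
    }
  return out;
}
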