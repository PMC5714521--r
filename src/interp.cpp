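#include <Rcpp.h>
#include "splines.h"
using namespace Rcpp;

static Vol make_vol(const NumericVector &arr, const IntegerVector &dim,
                    const NumericVector &spc, const NumericVector &org) {
  Vol v;
  v.d = arr.begin();
  v.nx = dim[0]; v.ny = dim[1]; v.nz = dim[2];
  v.sx = spc[0]; v.sy = spc[1]; v.sz = spc[2];
  v.ox = org[0]; v.oy = org[1]; v.oz = org[2];
  return v;
}

static Grid make_grid(bool has, const NumericVector &coef, const IntegerVector &gdim,
                      const NumericVector &gspc, const NumericVector &gorg) {
  Grid g;
  g.valid = has;
  if (has) {
    g.coef = coef.begin();
    g.nx = gdim[0]; g.ny = gdim[1]; g.nz = gdim[2];
    g.sx = gspc[0]; g.sy = gspc[1]; g.sz = gspc[2];
    g.ox = gorg[0]; g.oy = gorg[1]; g.oz = gorg[2];
  } else {
    g.coef = 0; g.nx = g.ny = g.nz = 0;
    g.sx = g.sy = g.sz = 1; g.ox = g.oy = g.oz = 0;
  }
  return g;
}

// ---- cubic B-spline interpolation prefilter (per axis recursive filter) ----

static void filter_line(double *c, int n, double z) {
  if (n == 1) return;
  const double lambda = (1.0 - z) * (1.0 - 1.0 / z);
  for (int i = 0; i < n; ++i) c[i] *= lambda;
  // causal init under mirror boundaries, truncated horizon
  int horizon = (int)std::ceil(std::log(1e-14) / std::log(std::fabs(z)));
  if (horizon > n) horizon = n;
  double sum = c[0], zn = z;
  for (int i = 1; i < horizon; ++i) { sum += zn * c[i]; zn *= z; }
  c[0] = sum;
  for (int i = 1; i < n; ++i) c[i] += z * c[i - 1];
  c[n - 1] = (z / (z * z - 1.0)) * (z * c[n - 2] + c[n - 1]);
  for (int i = n - 2; i >= 0; --i) c[i] = z * (c[i + 1] - c[i]);
}

// [[Rcpp::export]]
NumericVector cpp_bspline_prefilter(NumericVector arr, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(arr);
  const double z = std::sqrt(3.0) - 2.0;
  std::vector<double> line((size_t)std::max(nx, std::max(ny, nz)));
  double *o = out.begin();
  // x lines
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double *p = o + (size_t)nx * ((size_t)j + (size_t)ny * k);
      filter_line(p, nx, z);
    }
  // y lines
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) line[j] = o[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
      filter_line(line.data(), ny, z);
      for (int j = 0; j < ny; ++j) o[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)] = line[j];
    }
  // z lines
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) line[k] = o[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
      filter_line(line.data(), nz, z);
      for (int k = 0; k < nz; ++k) o[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)] = line[k];
    }
  return out;
}

// ---- point interpolation ----

// order 0: nearest neighbour; 1: trilinear; 3: cubic B-spline (arr must be
// prefiltered coefficients).  Returns value and, optionally, the spatial
// gradient (per mm) of the interpolant.
static bool interp_one(const Vol &v, int order, const double *y, double *val,
                       double *grad) {
  const double ux = (y[0] - v.ox) / v.sx;
  const double uy = (y[1] - v.oy) / v.sy;
  const double uz = (y[2] - v.oz) / v.sz;
  const double eps = 1e-9;
  if (ux < -eps || uy < -eps || uz < -eps ||
      ux > v.nx - 1 + eps || uy > v.ny - 1 + eps || uz > v.nz - 1 + eps)
    return false;
  if (order == 0) {
    int i = (int)std::floor(ux + 0.5), j = (int)std::floor(uy + 0.5), k = (int)std::floor(uz + 0.5);
    if (i < 0) i = 0; if (j < 0) j = 0; if (k < 0) k = 0;
    if (i > v.nx - 1) i = v.nx - 1;
    if (j > v.ny - 1) j = v.ny - 1;
    if (k > v.nz - 1) k = v.nz - 1;
    *val = vol_at(v, i, j, k);
    if (grad) grad[0] = grad[1] = grad[2] = 0.0;
    return true;
  }
  if (order == 1) {
    int i = (int)std::floor(ux), j = (int)std::floor(uy), k = (int)std::floor(uz);
    if (i < 0) i = 0; if (j < 0) j = 0; if (k < 0) k = 0;
    if (i > v.nx - 2) i = v.nx - 2;
    if (j > v.ny - 2) j = v.ny - 2;
    if (k > v.nz - 2) k = v.nz - 2;
    if (v.nx == 1) i = 0;
    const double fx = ux - i, fy = uy - j, fz = uz - k;
    double c[2][2][2];
    for (int kk = 0; kk < 2; ++kk)
      for (int jj = 0; jj < 2; ++jj)
        for (int ii = 0; ii < 2; ++ii)
          c[ii][jj][kk] = vol_at(v, std::min(i + ii, v.nx - 1),
                                 std::min(j + jj, v.ny - 1),
                                 std::min(k + kk, v.nz - 1));
    const double wx[2] = {1 - fx, fx}, wy[2] = {1 - fy, fy}, wz[2] = {1 - fz, fz};
    double s = 0, gx = 0, gy = 0, gz = 0;
    for (int kk = 0; kk < 2; ++kk)
      for (int jj = 0; jj < 2; ++jj)
        for (int ii = 0; ii < 2; ++ii) {
          const double cv = c[ii][jj][kk];
          s += cv * wx[ii] * wy[jj] * wz[kk];
          gx += cv * (ii ? 1.0 : -1.0) * wy[jj] * wz[kk];
          gy += cv * wx[ii] * (jj ? 1.0 : -1.0) * wz[kk];
          gz += cv * wx[ii] * wy[jj] * (kk ? 1.0 : -1.0);
        }
    *val = s;
    if (grad) { grad[0] = gx / v.sx; grad[1] = gy / v.sy; grad[2] = gz / v.sz; }
    return true;
  }
  // order 3
  const int i = (int)std::floor(ux), j = (int)std::floor(uy), k = (int)std::floor(uz);
  double wx[4], wy[4], wz[4], dwx[4], dwy[4], dwz[4];
  bspline_w3(ux - i, wx); bspline_w3(uy - j, wy); bspline_w3(uz - k, wz);
  if (grad) { bspline_dw3(ux - i, dwx); bspline_dw3(uy - j, dwy); bspline_dw3(uz - k, dwz); }
  double s = 0, gx = 0, gy = 0, gz = 0;
  for (int kk = 0; kk < 4; ++kk) {
    const int z = mirror_idx(k - 1 + kk, v.nz);
    for (int jj = 0; jj < 4; ++jj) {
      const int yy = mirror_idx(j - 1 + jj, v.ny);
      for (int ii = 0; ii < 4; ++ii) {
        const double cv = vol_at(v, mirror_idx(i - 1 + ii, v.nx), yy, z);
        s += cv * wx[ii] * wy[jj] * wz[kk];
        if (grad) {
          gx += cv * dwx[ii] * wy[jj] * wz[kk];
          gy += cv * wx[ii] * dwy[jj] * wz[kk];
          gz += cv * wx[ii] * wy[jj] * dwz[kk];
        }
      }
    }
  }
  *val = s;
  if (grad) { grad[0] = gx / v.sx; grad[1] = gy / v.sy; grad[2] = gz / v.sz; }
  return true;
}

// [[Rcpp::export]]
List cpp_interp_points(NumericVector arr, IntegerVector dim, NumericVector spc,
                       NumericVector org, NumericMatrix pts, int order,
                       double defaultValue) {
  const Vol v = make_vol(arr, dim, spc, org);
  const int n = pts.nrow();
  NumericVector out(n);
  LogicalVector inside(n);
  for (int s = 0; s < n; ++s) {
    double y[3] = {pts(s, 0), pts(s, 1), pts(s, 2)}, val;
    bool ok = interp_one(v, order, y, &val, 0);
    inside[s] = ok;
    out[s] = ok ? val : defaultValue;
  }
  return List::create(_["values"] = out, _["inside"] = inside);
}

// [[Rcpp::export]]
List cpp_ffd_points(NumericVector coef, IntegerVector gdim, NumericVector gspc,
                    NumericVector gorg, NumericMatrix pts) {
  const Grid g = make_grid(true, coef, gdim, gspc, gorg);
  const int n = pts.nrow();
  NumericMatrix out(n, 3);
  LogicalVector inside(n);
  for (int s = 0; s < n; ++s) {
    double q[3] = {pts(s, 0), pts(s, 1), pts(s, 2)}, d[3];
    bool ok = ffd_disp(g, q, d);
    inside[s] = ok;
    out(s, 0) = d[0]; out(s, 1) = d[1]; out(s, 2) = d[2];
  }
  return List::create(_["disp"] = out, _["inside"] = inside);
}

// [[Rcpp::export]]
NumericMatrix cpp_chain_points(NumericMatrix pts, NumericVector angles,
                               NumericVector center, NumericVector trans,
                               bool hasFFD, NumericVector coef, IntegerVector gdim,
                               NumericVector gspc, NumericVector gorg,
                               int outsideMode) {
  Rigid r;
  rigid_setup(angles.begin(), center.begin(), trans.begin(), r);
  const Grid g = make_grid(hasFFD, coef, gdim, gspc, gorg);
  const int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int s = 0; s < n; ++s) {
    double p[3] = {pts(s, 0), pts(s, 1), pts(s, 2)}, y[3];
    bool ok = chain_map(r, g, p, y, outsideMode);
    if (!ok) stop("point outside the B-spline grid support");
    out(s, 0) = y[0]; out(s, 1) = y[1]; out(s, 2) = y[2];
  }
  return out;
}

// Numerical inverse of the chain: given targets y, find p with chain(p) = y.
// Solves q = y - d(q) by fixed point iteration (contractive while the FFD
// gradient stays below 1), then inverts the rigid part exactly.
// [[Rcpp::export]]
NumericMatrix cpp_invert_chain(NumericMatrix pts, NumericVector angles,
                               NumericVector center, NumericVector trans,
                               bool hasFFD, NumericVector coef, IntegerVector gdim,
                               NumericVector gspc, NumericVector gorg,
                               int maxit, double tol) {
  Rigid r;
  rigid_setup(angles.begin(), center.begin(), trans.begin(), r);
  const Grid g = make_grid(hasFFD, coef, gdim, gspc, gorg);
  const int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int s = 0; s < n; ++s) {
    const double y[3] = {pts(s, 0), pts(s, 1), pts(s, 2)};
    double q[3] = {y[0], y[1], y[2]};
    if (g.valid) {
      for (int it = 0; it < maxit; ++it) {
        double d[3];
        ffd_disp(g, q, d);  // zero displacement outside support
        double qn[3] = {y[0] - d[0], y[1] - d[1], y[2] - d[2]};
        const double delta = std::fabs(qn[0] - q[0]) + std::fabs(qn[1] - q[1]) +
                             std::fabs(qn[2] - q[2]);
        q[0] = qn[0]; q[1] = qn[1]; q[2] = qn[2];
        if (delta < tol) break;
      }
    }
    // p = R^T (q - c - t) + c
    const double vx = q[0] - r.cx - r.tx, vy = q[1] - r.cy - r.ty, vz = q[2] - r.cz - r.tz;
    out(s, 0) = r.R[0] * vx + r.R[3] * vy + r.R[6] * vz + r.cx;
    out(s, 1) = r.R[1] * vx + r.R[4] * vy + r.R[7] * vz + r.cy;
    out(s, 2) = r.R[2] * vx + r.R[5] * vy + r.R[8] * vz + r.cz;
  }
  return out;
}

// Resample the moving image onto the reference grid through the chain.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector movArr, IntegerVector mdim,
                           NumericVector mspc, NumericVector morg,
                           IntegerVector rdim, NumericVector rspc,
                           NumericVector rorg, NumericVector angles,
                           NumericVector center, NumericVector trans,
                           bool hasFFD, NumericVector coef, IntegerVector gdim,
                           NumericVector gspc, NumericVector gorg, int order,
                           double defaultValue) {
  const Vol mv = make_vol(movArr, mdim, mspc, morg);
  Rigid r;
  rigid_setup(angles.begin(), center.begin(), trans.begin(), r);
  const Grid g = make_grid(hasFFD, coef, gdim, gspc, gorg);
  const int nx = rdim[0], ny = rdim[1], nz = rdim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *o = out.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const double p[3] = {rorg[0] + i * rspc[0], rorg[1] + j * rspc[1],
                             rorg[2] + k * rspc[2]};
        double y[3], val;
        chain_map(r, g, p, y, 1);
        bool ok = interp_one(mv, order, y, &val, 0);
        o[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)] =
            ok ? val : defaultValue;
      }
  return out;
}

// ---- Gaussian smoothing + subsampling for the multiresolution pyramid ----

static void gauss_kernel(double sigma, std::vector<double> &ker) {
  int rad = (int)std::ceil(3.0 * sigma);
  if (rad < 1) rad = 1;
  ker.assign(2 * rad + 1, 0.0);
  double sum = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    const double w = std::exp(-0.5 * (i * i) / (sigma * sigma));
    ker[i + rad] = w;
    sum += w;
  }
  for (double &w : ker) w /= sum;
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector arr, IntegerVector dim, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (sigma <= 0) return clone(arr);
  std::vector<double> ker;
  gauss_kernel(sigma, ker);
  const int rad = ((int)ker.size() - 1) / 2;
  NumericVector a = clone(arr), b(arr.size());
  double *pa = a.begin(), *pb = b.begin();
  auto idx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  };
  // three separable passes with edge clamping
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0;
        for (int t = -rad; t <= rad; ++t) {
          int ii = i + t; if (ii < 0) ii = 0; if (ii > nx - 1) ii = nx - 1;
          s += ker[t + rad] * pa[idx(ii, j, k)];
        }
        pb[idx(i, j, k)] = s;
      }
  std::swap(pa, pb);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0;
        for (int t = -rad; t <= rad; ++t) {
          int jj = j + t; if (jj < 0) jj = 0; if (jj > ny - 1) jj = ny - 1;
          s += ker[t + rad] * pa[idx(i, jj, k)];
        }
        pb[idx(i, j, k)] = s;
      }
  std::swap(pa, pb);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0;
        for (int t = -rad; t <= rad; ++t) {
          int kk = k + t; if (kk < 0) kk = 0; if (kk > nz - 1) kk = nz - 1;
          s += ker[t + rad] * pa[idx(i, j, kk)];
        }
        pb[idx(i, j, k)] = s;
      }
  if (pb == b.begin()) return b;
  return a;
}
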