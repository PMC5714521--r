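#include <Rcpp.h>
#include "splines.h"
using namespace Rcpp;

// Joint-histogram NMI from random spatial samples, with the analytic
// gradient through the Parzen window and the moving-image interpolant.
//
// Fixed axis: the sample's fixed intensity is read by trilinear
// interpolation and deposited with a linear (tent) window over two bins.
// Moving axis: the moving intensity, interpolated at chain(p), is deposited
// with a cubic B-spline Parzen window over four bins.  The moving bin
// position is mapped into [1, nbins-2] so the kernel support always lies
// inside the histogram and mass is conserved exactly.
//
// gradMode: 0 = value only, 1 = d/d(rigid params) (chain must have no FFD),
//           2 = d/d(FFD coefficients), returned over the full control grid.

static Vol vol_of(const double *d, const int *dim, const double *spc, const double *org) {
  Vol v;
  v.d = d; v.nx = dim[0]; v.ny = dim[1]; v.nz = dim[2];
  v.sx = spc[0]; v.sy = spc[1]; v.sz = spc[2];
  v.ox = org[0]; v.oy = org[1]; v.oz = org[2];
  return v;
}

// trilinear / cubic interpolation with spatial gradient (per mm)
static bool sample_moving(const Vol &v, int order, const double *y, double *val,
                          double *grad) {
  const double ux = (y[0] - v.ox) / v.sx;
  const double uy = (y[1] - v.oy) / v.sy;
  const double uz = (y[2] - v.oz) / v.sz;
  const double eps = 1e-9;
  if (ux < -eps || uy < -eps || uz < -eps ||
      ux > v.nx - 1 + eps || uy > v.ny - 1 + eps || uz > v.nz - 1 + eps)
    return false;
  if (order == 1) {
    int i = (int)std::floor(ux), j = (int)std::floor(uy), k = (int)std::floor(uz);
    if (i < 0) i = 0; if (j < 0) j = 0; if (k < 0) k = 0;
    if (i > v.nx - 2) i = v.nx - 2;
    if (j > v.ny - 2) j = v.ny - 2;
    if (k > v.nz - 2) k = v.nz - 2;
    const double fx = ux - i, fy = uy - j, fz = uz - k;
    const double wx[2] = {1 - fx, fx}, wy[2] = {1 - fy, fy}, wz[2] = {1 - fz, fz};
    double s = 0, gx = 0, gy = 0, gz = 0;
    for (int kk = 0; kk < 2; ++kk)
      for (int jj = 0; jj < 2; ++jj)
        for (int ii = 0; ii < 2; ++ii) {
          const double cv = vol_at(v, i + ii, j + jj, k + kk);
          s += cv * wx[ii] * wy[jj] * wz[kk];
          if (grad) {
            gx += cv * (ii ? 1.0 : -1.0) * wy[jj] * wz[kk];
            gy += cv * wx[ii] * (jj ? 1.0 : -1.0) * wz[kk];
            gz += cv * wx[ii] * wy[jj] * (kk ? 1.0 : -1.0);
          }
        }
    *val = s;
    if (grad) { grad[0] = gx / v.sx; grad[1] = gy / v.sy; grad[2] = gz / v.sz; }
    return true;
  }
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
List cpp_nmi_metric(NumericVector fixArr, IntegerVector fdim, NumericVector fspc,
                    NumericVector forg, NumericVector movArr, IntegerVector mdim,
                    NumericVector mspc, NumericVector morg, int order,
                    NumericMatrix pts, NumericVector angles, NumericVector center,
                    NumericVector trans, bool hasFFD, NumericVector coef,
                    IntegerVector gdim, NumericVector gspc, NumericVector gorg,
                    int nbins, NumericVector fixRange, NumericVector movRange,
                    int gradMode) {
  const Vol fv = vol_of(fixArr.begin(), fdim.begin(), fspc.begin(), forg.begin());
  const Vol mv = vol_of(movArr.begin(), mdim.begin(), mspc.begin(), morg.begin());
  Rigid r;
  rigid_setup(angles.begin(), center.begin(), trans.begin(), r);
  Grid g;
  if (hasFFD) {
    g.valid = true;
    g.coef = coef.begin();
    g.nx = gdim[0]; g.ny = gdim[1]; g.nz = gdim[2];
    g.sx = gspc[0]; g.sy = gspc[1]; g.sz = gspc[2];
    g.ox = gorg[0]; g.oy = gorg[1]; g.oz = gorg[2];
  } else {
    g.valid = false; g.coef = 0;
  }
  if (gradMode == 1 && hasFFD)
    stop("rigid-parameter gradient is only defined for a chain without FFD");

  const int n = pts.nrow();
  const double fmin = fixRange[0], fmax = fixRange[1];
  const double mmin = movRange[0], mmax = movRange[1];
  const double frange = std::max(fmax - fmin, 1e-12);
  const double mrange = std::max(mmax - mmin, 1e-12);
  const double gammaM = (nbins - 3.0) / mrange;  // d(pos_m)/d(moving value)

  NumericMatrix hist(nbins, nbins);  // rows: fixed bins, cols: moving bins
  // per-sample cache for the gradient pass
  std::vector<int> c_i0(n), c_jb(n);
  std::vector<double> c_a(n), c_t(n), c_q(3 * n), c_g(3 * n), c_p(3 * n);
  std::vector<char> c_ok(n, 0), c_clamped(n, 0);
  int used = 0, skipped = 0;

  const bool wantGrad = gradMode != 0;
  for (int s = 0; s < n; ++s) {
    const double p[3] = {pts(s, 0), pts(s, 1), pts(s, 2)};
    double y[3], q[3];
    if (!chain_map(r, g, p, y, 0, q)) { ++skipped; continue; }
    double F, M, gm[3];
    if (!sample_moving(fv, 1, p, &F, 0)) { ++skipped; continue; }
    if (!sample_moving(mv, order, y, &M, wantGrad ? gm : 0)) { ++skipped; continue; }
    // fixed axis: linear window over two bins
    double tF = (F - fmin) / frange;
    if (tF < 0) tF = 0;
    if (tF > 1) tF = 1;
    double posF = tF * (nbins - 1);
    int i0 = (int)std::floor(posF);
    if (i0 > nbins - 2) i0 = nbins - 2;
    const double aF = posF - i0;
    // moving axis: cubic window over four bins, support kept inside
    double tM = (M - mmin) / mrange;
    bool clamped = false;
    if (tM < 0) { tM = 0; clamped = true; }
    if (tM > 1) { tM = 1; clamped = true; }
    double posM = 1.0 + tM * (nbins - 3);
    int jb = (int)std::floor(posM);
    if (jb > nbins - 3) jb = nbins - 3;
    const double tm = posM - jb;
    double wm[4];
    bspline_w3(tm, wm);
    for (int jj = 0; jj < 4; ++jj) {
      hist(i0, jb - 1 + jj) += (1.0 - aF) * wm[jj];
      hist(i0 + 1, jb - 1 + jj) += aF * wm[jj];
    }
    c_i0[s] = i0; c_a[s] = aF; c_jb[s] = jb; c_t[s] = tm;
    c_ok[s] = 1; c_clamped[s] = clamped ? 1 : 0;
    c_q[3 * s] = q[0]; c_q[3 * s + 1] = q[1]; c_q[3 * s + 2] = q[2];
    c_p[3 * s] = p[0]; c_p[3 * s + 1] = p[1]; c_p[3 * s + 2] = p[2];
    if (wantGrad) { c_g[3 * s] = gm[0]; c_g[3 * s + 1] = gm[1]; c_g[3 * s + 2] = gm[2]; }
    ++used;
  }

  if (used < 2)
    return List::create(_["value"] = NA_REAL, _["hist"] = hist, _["used"] = used,
                        _["skipped"] = skipped, _["grad"] = R_NilValue);

  // entropies of the normalized histogram
  std::vector<double> pf(nbins, 0.0), pm(nbins, 0.0);
  double Hj = 0.0;
  const double inv = 1.0 / used;
  for (int i = 0; i < nbins; ++i)
    for (int j = 0; j < nbins; ++j) {
      const double pij = hist(i, j) * inv;
      pf[i] += pij;
      pm[j] += pij;
      if (pij > 0) Hj -= pij * std::log(pij);
    }
  double Hf = 0.0, Hm = 0.0;
  for (int i = 0; i < nbins; ++i) {
    if (pf[i] > 0) Hf -= pf[i] * std::log(pf[i]);
    if (pm[i] > 0) Hm -= pm[i] * std::log(pm[i]);
  }
  const double value = (Hj > 0) ? (Hf + Hm) / Hj : 2.0;

  SEXP gradOut = R_NilValue;
  if (wantGrad && Hj > 0) {
    // K_ij = d(NMI)/d(P_ij)
    NumericMatrix K(nbins, nbins);
    const double S = Hf + Hm, Hj2 = Hj * Hj;
    for (int i = 0; i < nbins; ++i)
      for (int j = 0; j < nbins; ++j) {
        const double pij = hist(i, j) * inv;
        if (pij <= 0) continue;
        K(i, j) = (-(1.0 + std::log(pm[j])) * Hj + S * (1.0 + std::log(pij))) / Hj2;
      }
    if (gradMode == 1) {
      NumericVector grad(6);  // (rx, ry, rz, tx, ty, tz)
      for (int s = 0; s < n; ++s) {
        if (!c_ok[s] || c_clamped[s]) continue;
        double dwm[4];
        bspline_dw3(c_t[s], dwm);
        double Gs = 0.0;
        for (int jj = 0; jj < 4; ++jj) {
          const int j = c_jb[s] - 1 + jj;
          Gs += dwm[jj] * ((1.0 - c_a[s]) * K(c_i0[s], j) + c_a[s] * K(c_i0[s] + 1, j));
        }
        Gs *= gammaM * inv;
        const double *gm = &c_g[3 * s];
        const double vx = c_p[3 * s] - r.cx, vy = c_p[3 * s + 1] - r.cy,
                     vz = c_p[3 * s + 2] - r.cz;
        for (int a = 0; a < 3; ++a) {
          const double *D = r.dR[a];
          const double dy0 = D[0] * vx + D[1] * vy + D[2] * vz;
          const double dy1 = D[3] * vx + D[4] * vy + D[5] * vz;
          const double dy2 = D[6] * vx + D[7] * vy + D[8] * vz;
          grad[a] += Gs * (gm[0] * dy0 + gm[1] * dy1 + gm[2] * dy2);
        }
        grad[3] += Gs * gm[0];
        grad[4] += Gs * gm[1];
        grad[5] += Gs * gm[2];
      }
      gradOut = grad;
    } else {
      const int ncp = gdim[0] * gdim[1] * gdim[2];
      NumericVector grad(3 * ncp);  // same layout as the coefficient array
      double *gr = grad.begin();
      for (int s = 0; s < n; ++s) {
        if (!c_ok[s] || c_clamped[s]) continue;
        double dwm[4];
        bspline_dw3(c_t[s], dwm);
        double Gs = 0.0;
        for (int jj = 0; jj < 4; ++jj) {
          const int j = c_jb[s] - 1 + jj;
          Gs += dwm[jj] * ((1.0 - c_a[s]) * K(c_i0[s], j) + c_a[s] * K(c_i0[s] + 1, j));
        }
        Gs *= gammaM * inv;
        const double *gm = &c_g[3 * s];
        const double *q = &c_q[3 * s];
        const double gx = (q[0] - g.ox) / g.sx;
        const double gy = (q[1] - g.oy) / g.sy;
        const double gz = (q[2] - g.oz) / g.sz;
        int ix = (int)std::floor(gx), iy = (int)std::floor(gy), iz = (int)std::floor(gz);
        if (ix == g.nx - 2 && gx <= g.nx - 2 + 1e-12) ix = g.nx - 3;
        if (iy == g.ny - 2 && gy <= g.ny - 2 + 1e-12) iy = g.ny - 3;
        if (iz == g.nz - 2 && gz <= g.nz - 2 + 1e-12) iz = g.nz - 3;
        double wx[4], wy[4], wz[4];
        bspline_w3(gx - ix, wx);
        bspline_w3(gy - iy, wy);
        bspline_w3(gz - iz, wz);
        for (int kk = 0; kk < 4; ++kk)
          for (int jj = 0; jj < 4; ++jj) {
            const double wyz = wy[jj] * wz[kk];
            const size_t base =
                (size_t)(ix - 1) +
                (size_t)g.nx * ((size_t)(iy - 1 + jj) + (size_t)g.ny * (iz - 1 + kk));
            for (int ii = 0; ii < 4; ++ii) {
              const double w = wx[ii] * wyz;
              const size_t cp = base + ii;
              gr[cp] += Gs * gm[0] * w;
              gr[cp + (size_t)ncp] += Gs * gm[1] * w;
              gr[cp + 2 * (size_t)ncp] += Gs * gm[2] * w;
            }
          }
      }
      gradOut = grad;
    }
  }
  return List::create(_["value"] = value, _["hist"] = hist, _["used"] = used,
                      _["skipped"] = skipped, _["grad"] = gradOut);
}
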