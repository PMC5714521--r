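#ifndef NMIREG_SPLINES_H
#define NMIREG_SPLINES_H

#include <cmath>
#include <cstddef>

// Cubic B-spline basis on the four support knots, local offset t in [0,1].
// w[0..3] weight control points at cell offsets -1, 0, +1, +2.
inline void bspline_w3(double t, double *w) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (3.0 * t3 - 6.0 * t2 + 4.0) / 6.0;
  w[2] = (-3.0 * t3 + 3.0 * t2 + 3.0 * t + 1.0) / 6.0;
  w[3] = t3 / 6.0;
}

// d/dt of the four basis weights.
inline void bspline_dw3(double t, double *w) {
  const double t2 = t * t;
  w[0] = -(1.0 - 2.0 * t + t2) / 2.0;
  w[1] = (3.0 * t2 - 4.0 * t) / 2.0;
  w[2] = (-3.0 * t2 + 2.0 * t + 1.0) / 2.0;
  w[3] = t2 / 2.0;
}

struct Vol {
  const double *d;
  int nx, ny, nz;
  double sx, sy, sz;  // spacing, mm
  double ox, oy, oz;  // origin (center of voxel 0,0,0), mm
};

inline double vol_at(const Vol &v, int i, int j, int k) {
  return v.d[(std::size_t)i + (std::size_t)v.nx * ((std::size_t)j + (std::size_t)v.ny * k)];
}

// Mirror (reflect-on-boundary) index into [0, n-1]; period 2n-2.
inline int mirror_idx(int i, int n) {
  if (n == 1) return 0;
  const int p = 2 * n - 2;
  i = i % p;
  if (i < 0) i += p;
  return (i < n) ? i : p - i;
}

struct Rigid {
  double R[9];        // row-major rotation
  double dR[3][9];    // dR/d(angle_a)
  double cx, cy, cz;  // center
  double tx, ty, tz;  // translation
};

// Compose R = Rz * Ry * Rx (rotation applied about X first, then Y, then Z)
// and the derivative matrices with respect to each Euler angle.
inline void rigid_setup(const double *ang, const double *center, const double *trans,
                        Rigid &out) {
  const double cx = std::cos(ang[0]), sx = std::sin(ang[0]);
  const double cy = std::cos(ang[1]), sy = std::sin(ang[1]);
  const double cz = std::cos(ang[2]), sz = std::sin(ang[2]);
  double Rx[9] = {1, 0, 0, 0, cx, -sx, 0, sx, cx};
  double Ry[9] = {cy, 0, sy, 0, 1, 0, -sy, 0, cy};
  double Rz[9] = {cz, -sz, 0, sz, cz, 0, 0, 0, 1};
  double dRx[9] = {0, 0, 0, 0, -sx, -cx, 0, cx, -sx};
  double dRy[9] = {-sy, 0, cy, 0, 0, 0, -cy, 0, -sy};
  double dRz[9] = {-sz, -cz, 0, cz, -sz, 0, 0, 0, 0};
  auto mm = [](const double *A, const double *B, double *C) {
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += A[3 * i + k] * B[3 * k + j];
        C[3 * i + j] = s;
      }
  };
  double ZY[9];
  mm(Rz, Ry, ZY);
  mm(ZY, Rx, out.R);
  mm(ZY, dRx, out.dR[0]);
  double ZdY[9];
  mm(Rz, dRy, ZdY);
  mm(ZdY, Rx, out.dR[1]);
  double dZY[9];
  mm(dRz, Ry, dZY);
  mm(dZY, Rx, out.dR[2]);
  out.cx = center[0]; out.cy = center[1]; out.cz = center[2];
  out.tx = trans[0];  out.ty = trans[1];  out.tz = trans[2];
}

inline void rigid_map(const Rigid &r, const double *p, double *q) {
  const double vx = p[0] - r.cx, vy = p[1] - r.cy, vz = p[2] - r.cz;
  q[0] = r.R[0] * vx + r.R[1] * vy + r.R[2] * vz + r.cx + r.tx;
  q[1] = r.R[3] * vx + r.R[4] * vy + r.R[5] * vz + r.cy + r.ty;
  q[2] = r.R[6] * vx + r.R[7] * vy + r.R[8] * vz + r.cz + r.tz;
}

struct Grid {
  const double *coef;  // (nx, ny, nz, 3) column-major; component stride nx*ny*nz
  int nx, ny, nz;
  double sx, sy, sz;
  double ox, oy, oz;
  bool valid;          // false => no FFD in the chain
};

// Cubic FFD displacement at physical point q. Returns false when q is
// outside the grid's full-support region.
inline bool ffd_disp(const Grid &g, const double *q, double *d) {
  d[0] = d[1] = d[2] = 0.0;
  if (!g.valid) return true;
  const double gx = (q[0] - g.ox) / g.sx;
  const double gy = (q[1] - g.oy) / g.sy;
  const double gz = (q[2] - g.oz) / g.sz;
  int ix = (int)std::floor(gx), iy = (int)std::floor(gy), iz = (int)std::floor(gz);
  // allow the exact upper edge of the supported cell range
  if (ix == g.nx - 2 && gx <= g.nx - 2 + 1e-12) ix = g.nx - 3;
  if (iy == g.ny - 2 && gy <= g.ny - 2 + 1e-12) iy = g.ny - 3;
  if (iz == g.nz - 2 && gz <= g.nz - 2 + 1e-12) iz = g.nz - 3;
  if (ix < 1 || ix > g.nx - 3 || iy < 1 || iy > g.ny - 3 || iz < 1 || iz > g.nz - 3)
    return false;
  double wx[4], wy[4], wz[4];
  bspline_w3(gx - ix, wx);
  bspline_w3(gy - iy, wy);
  bspline_w3(gz - iz, wz);
  const std::size_t cs = (std::size_t)g.nx * g.ny * g.nz;
  for (int c = 0; c < 3; ++c) {
    double acc = 0.0;
    const double *base = g.coef + c * cs;
    for (int kk = 0; kk < 4; ++kk) {
      const int z = iz - 1 + kk;
      for (int jj = 0; jj < 4; ++jj) {
        const int y = iy - 1 + jj;
        const double wyz = wy[jj] * wz[kk];
        const double *row = base + (std::size_t)g.nx * ((std::size_t)y + (std::size_t)g.ny * z);
        double s = 0.0;
        for (int ii = 0; ii < 4; ++ii) s += row[ix - 1 + ii] * wx[ii];
        acc += s * wyz;
      }
    }
    d[c] = acc;
  }
  return true;
}

// chain(p) = q + d(q), q = rigid(p).  outside==0: report failure when q is
// outside FFD support; outside==1: treat displacement as zero there.
inline bool chain_map(const Rigid &r, const Grid &g, const double *p, double *y,
                      int outside_mode, double *q_out = 0) {
  double q[3], d[3];
  rigid_map(r, p, q);
  if (q_out) { q_out[0] = q[0]; q_out[1] = q[1]; q_out[2] = q[2]; }
  bool ok = ffd_disp(g, q, d);
  if (!ok && outside_mode == 0) return false;
  if (!ok) { d[0] = d[1] = d[2] = 0.0; }
  y[0] = q[0] + d[0];
  y[1] = q[1] + d[1];
  y[2] = q[2] + d[2];
  return true;
}

#endif
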