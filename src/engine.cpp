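#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "vec3.h"
#include "rng.h"
#include "membrane_core.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// geometry of analytic wall surfaces (bounce-back)
// fluid-phase signed distance: phi > 0 in fluid, < 0 inside a wall
// ---------------------------------------------------------------------------

struct Walls {
  bool has_slab;
  int slab_axis;
  double slab_lo, slab_hi;
  bool has_pipette;
  double pip_xm, pip_rp, pip_yc, pip_zc, pip_xe;
  std::vector<double> obst;  // flattened triangles x1 y1 x2 y2 x3 y3 (xy-plane prisms)
  Walls() : has_slab(false), has_pipette(false) {}
};

static Walls parse_walls(List walls) {
  Walls W;
  for (int k = 0; k < walls.size(); k++) {
    List w = walls[k];
    std::string type = as<std::string>(w["type"]);
    if (type == "slab") {
      W.has_slab = true;
      W.slab_axis = as<int>(w["axis"]);  // 0,1,2
      W.slab_lo = as<double>(w["lo"]);
      W.slab_hi = as<double>(w["hi"]);
    } else if (type == "pipette") {
      W.has_pipette = true;
      W.pip_xm = as<double>(w["xm"]);
      W.pip_rp = as<double>(w["rp"]);
      W.pip_yc = as<double>(w["yc"]);
      W.pip_zc = as<double>(w["zc"]);
      W.pip_xe = as<double>(w["xe"]);
    } else if (type == "obstacles") {
      NumericMatrix tri = w["triangles"];
      for (int i = 0; i < tri.nrow(); i++)
        for (int j = 0; j < 6; j++) W.obst.push_back(tri(i, j));
    } else {
      stop("unknown wall type '%s'", type.c_str());
    }
  }
  return W;
}

// closest point on segment ab to p (2D)
static inline void seg_closest(double px, double py, double ax, double ay, double bx,
                               double by, double &qx, double &qy) {
  double abx = bx - ax, aby = by - ay;
  double t = ((px - ax) * abx + (py - ay) * aby) / (abx * abx + aby * aby);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  qx = ax + t * abx;
  qy = ay + t * aby;
}

// signed 2D distance to triangle (negative inside) and closest boundary point
static double tri2d_sd(const double *T, double px, double py, double &qx, double &qy) {
  double bestd2 = 1e300;
  for (int e = 0; e < 3; e++) {
    double ax = T[2 * e], ay = T[2 * e + 1];
    double bx = T[(2 * e + 2) % 6], by = T[(2 * e + 3) % 6];
    double cx, cy;
    seg_closest(px, py, ax, ay, bx, by, cx, cy);
    double d2 = (px - cx) * (px - cx) + (py - cy) * (py - cy);
    if (d2 < bestd2) { bestd2 = d2; qx = cx; qy = cy; }
  }
  // inside test via consistent edge cross products
  bool pos = false, neg = false;
  for (int e = 0; e < 3; e++) {
    double ax = T[2 * e], ay = T[2 * e + 1];
    double bx = T[(2 * e + 2) % 6], by = T[(2 * e + 3) % 6];
    double cr = (bx - ax) * (py - ay) - (by - ay) * (px - ax);
    if (cr > 0) pos = true;
    if (cr < 0) neg = true;
  }
  double d = std::sqrt(bestd2);
  return (pos && neg) ? d : -d;  // inside if all same sign
}

// Reflect a particle that ended inside a wall back into the fluid, negating
// its velocity (bounce-back).  Returns true if a reflection happened.
static bool wall_reflect(const Walls &W, double *x, double *y, double *z, bool &deep,
                         double rc) {
  bool hit = false;
  deep = false;
  for (int iter = 0; iter < 4; iter++) {
    double worst = 0.0;
    int which = -1;          // 0 slab lo, 1 slab hi, 2 pipette, 3+ obstacle
    double pen = 0.0;
    if (W.has_slab) {
      double c = (W.slab_axis == 0) ? *x : (W.slab_axis == 1) ? *y : *z;
      if (c - W.slab_lo < 0 && W.slab_lo - c > worst) { worst = W.slab_lo - c; which = 0; }
      if (W.slab_hi - c < 0 && c - W.slab_hi > worst) { worst = c - W.slab_hi; which = 1; }
    }
    if (W.has_pipette) {
      double rr = std::sqrt((*y - W.pip_yc) * (*y - W.pip_yc) +
                            (*z - W.pip_zc) * (*z - W.pip_zc));
      // solid = annular block {xm <= x <= xe, r >= rp}; through the periodic
      // wrap its far face (x = xe) is the rear wall of the chamber
      double phi = std::max(std::max(W.pip_xm - *x, W.pip_rp - rr), *x - W.pip_xe);
      if (phi < 0 && -phi > worst) { worst = -phi; which = 2; }
    }
    for (size_t t = 0; t < W.obst.size() / 6; t++) {
      double qx, qy;
      double sd = tri2d_sd(&W.obst[6 * t], *x, *y, qx, qy);
      if (sd < 0 && -sd > worst) { worst = -sd; which = 3 + (int)t; }
    }
    if (which < 0) return hit;
    pen = worst;
    if (pen > rc) { deep = true; return true; }
    if (which == 0) {
      double *c = (W.slab_axis == 0) ? x : (W.slab_axis == 1) ? y : z;
      *c = 2.0 * W.slab_lo - *c;
    } else if (which == 1) {
      double *c = (W.slab_axis == 0) ? x : (W.slab_axis == 1) ? y : z;
      *c = 2.0 * W.slab_hi - *c;
    } else if (which == 2) {
      double dy = *y - W.pip_yc, dz = *z - W.pip_zc;
      double rr = std::sqrt(dy * dy + dz * dz);
      double fx1 = W.pip_xm - *x, fx2 = *x - W.pip_xe, fr = W.pip_rp - rr;
      // reflect across the nearest of the three faces of the solid block
      if (fx1 >= fr && fx1 >= fx2) {
        *x = 2.0 * W.pip_xm - *x;
      } else if (fx2 >= fr) {
        *x = 2.0 * W.pip_xe - *x;
      } else {
        double scale = (2.0 * W.pip_rp - rr) / rr;  // mirror radius about rp
        *y = W.pip_yc + dy * scale;
        *z = W.pip_zc + dz * scale;
      }
    } else {
      const double *T = &W.obst[6 * (which - 3)];
      double qx, qy;
      tri2d_sd(T, *x, *y, qx, qy);
      *x = 2.0 * qx - *x;
      *y = 2.0 * qy - *y;
    }
    hit = true;
  }
  deep = true;  // did not resolve in 4 reflections
  return true;
}

// ---------------------------------------------------------------------------
// neighbor search (cell list over the wrapped box, minimum image)
// ---------------------------------------------------------------------------

struct CellList {
  int nc[3];
  double cw[3];
  std::vector<int> head, next;
  bool per[3];
  double box[3];
  bool degenerate;  // a periodic dimension has < 3 cells: use all-pairs instead

  void build(const double *wx, const double *wy, const double *wz, int n,
             const double *boxv, const bool *periodic, double rc) {
    degenerate = false;
    for (int d = 0; d < 3; d++) {
      box[d] = boxv[d];
      per[d] = periodic[d];
      nc[d] = std::max(1, (int)std::floor(boxv[d] / rc));
      if (per[d] && nc[d] < 3) { nc[d] = 1; degenerate = true; }
      cw[d] = boxv[d] / nc[d];
    }
    head.assign(nc[0] * nc[1] * nc[2], -1);
    next.assign(n, -1);
    for (int i = 0; i < n; i++) {
      int cx = std::min(nc[0] - 1, std::max(0, (int)(wx[i] / cw[0])));
      int cy = std::min(nc[1] - 1, std::max(0, (int)(wy[i] / cw[1])));
      int cz = std::min(nc[2] - 1, std::max(0, (int)(wz[i] / cw[2])));
      int c = (cz * nc[1] + cy) * nc[0] + cx;
      next[i] = head[c];
      head[c] = i;
    }
  }
};

// half-space stencil of 13 forward neighbors + self
static const int STEN[14][3] = {{0, 0, 0}, {1, 0, 0},  {-1, 1, 0}, {0, 1, 0}, {1, 1, 0},
                                {-1, -1, 1}, {0, -1, 1}, {1, -1, 1}, {-1, 0, 1},
                                {0, 0, 1},  {1, 0, 1},  {-1, 1, 1}, {0, 1, 1}, {1, 1, 1}};

// ---------------------------------------------------------------------------

struct KvBonds {
  int n;
  std::vector<int> i, j;
  std::vector<double> ks, kv, l0;
  bool strain_based;
};

static KvBonds parse_kv(List kv) {
  KvBonds K;
  NumericMatrix b = kv["bonds"];  // i j ks kv l0 (1-based)
  K.n = b.nrow();
  K.strain_based = as<bool>(kv["strain_based"]);
  K.i.resize(K.n); K.j.resize(K.n);
  K.ks.resize(K.n); K.kv.resize(K.n); K.l0.resize(K.n);
  for (int q = 0; q < K.n; q++) {
    K.i[q] = (int)b(q, 0) - 1; K.j[q] = (int)b(q, 1) - 1;
    K.ks[q] = b(q, 2); K.kv[q] = b(q, 3); K.l0[q] = b(q, 4);
  }
  return K;
}

struct BodyForce {
  int mode;  // 0 none, 1 uniform on fluid, 2 tube region on fluid,
             // 3 tube region on outer-membrane particles (surface load)
  double dir[3];
  std::vector<double> tk, fk;  // schedule knots (piecewise linear)
  double xa, xb, rp, yc, zc;   // tube region
  double magnitude(double t) const {
    if (tk.empty()) return 0.0;
    if (t <= tk.front()) return fk.front();
    if (t >= tk.back()) return fk.back();
    size_t k = 1;
    while (tk[k] < t) k++;
    double w = (t - tk[k - 1]) / (tk[k] - tk[k - 1]);
    return fk[k - 1] + w * (fk[k] - fk[k - 1]);
  }
};

static BodyForce parse_bf(List bf) {
  BodyForce B;
  std::string mode = as<std::string>(bf["mode"]);
  B.mode = (mode == "none") ? 0 : (mode == "uniform") ? 1
           : (mode == "tube") ? 2 : 3;
  if (B.mode == 0) return B;
  NumericVector dir = bf["dir"];
  for (int d = 0; d < 3; d++) B.dir[d] = dir[d];
  NumericVector tk = bf["t"], fk = bf["f"];
  B.tk.assign(tk.begin(), tk.end());
  B.fk.assign(fk.begin(), fk.end());
  if (B.mode >= 2) {
    B.xa = as<double>(bf["xa"]); B.xb = as<double>(bf["xb"]);
    B.rp = as<double>(bf["rp"]); B.yc = as<double>(bf["yc"]); B.zc = as<double>(bf["zc"]);
  }
  return B;
}

static void eig3_sym(double m[3][3], double ev[3]) {
  // cyclic Jacobi, plenty for a 3x3 gyration tensor
  double a[3][3];
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) a[i][j] = m[i][j];
  for (int sweep = 0; sweep < 50; sweep++) {
    double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
    if (off < 1e-14) break;
    for (int p = 0; p < 2; p++)
      for (int q = p + 1; q < 3; q++) {
        if (std::fabs(a[p][q]) < 1e-18) continue;
        double th = 0.5 * (a[q][q] - a[p][p]) / a[p][q];
        double t = ((th >= 0) ? 1.0 : -1.0) / (std::fabs(th) + std::sqrt(th * th + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 3; k++) {
          double akp = a[k][p], akq = a[k][q];
          a[k][p] = c * akp - s * akq;
          a[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 3; k++) {
          double apk = a[p][k], aqk = a[q][k];
          a[p][k] = c * apk - s * aqk;
          a[q][k] = s * apk + c * aqk;
        }
      }
  }
  ev[0] = a[0][0]; ev[1] = a[1][1]; ev[2] = a[2][2];
}

// ===========================================================================
// main driver: modified velocity-Verlet DPD with membranes, KV bonds, walls
// ===========================================================================

// [[Rcpp::export]]
List cpp_run_dpd(NumericMatrix pos0, NumericMatrix vel0, IntegerVector type,
                 LogicalVector frozen, NumericVector boxv, LogicalVector periodic,
                 List dpd, List membranes, List kvlist, List walls, List bodyforce,
                 List control) {
  const int N = pos0.nrow();
  NumericMatrix aij = dpd["aij"];
  const double rc = as<double>(dpd["rc"]);
  const double gammaD = as<double>(dpd["gamma"]);
  const double sigma = as<double>(dpd["sigma"]);
  const double sexp = as<double>(dpd["s"]);
  const double kBT = as<double>(dpd["kBT"]);
  const double dt = as<double>(dpd["dt"]);
  const double lambda = as<double>(dpd["lambda"]);

  const int nsteps = as<int>(control["nsteps"]);
  const int stride = as<int>(control["sample_every"]);
  const uint64_t seed = (uint64_t)as<double>(control["seed"]);
  const bool meas_mem = as<bool>(control["measure_membranes"]);
  const bool meas_lp = as<bool>(control["measure_lp"]);
  const bool meas_asph = as<bool>(control["measure_asphericity"]);
  const bool meas_com = as<bool>(control["measure_com"]);
  const bool meas_fluidv = as<bool>(control["measure_fluid_velocity"]);
  const bool stop_aspirated = as<bool>(control["stop_when_aspirated"]);

  Rng rng(seed);
  Walls W = parse_walls(walls);
  BodyForce BF = parse_bf(bodyforce);
  KvBonds KV = parse_kv(kvlist);
  std::vector<Mem> mems;
  for (int k = 0; k < membranes.size(); k++) mems.push_back(parse_mem(membranes[k]));

  double box[3] = {boxv[0], boxv[1], boxv[2]};
  bool per[3] = {(bool)periodic[0], (bool)periodic[1], (bool)periodic[2]};

  // unwrapped positions drive bonded forces and measurements
  std::vector<double> ux(N), uy(N), uz(N), vx(N), vy(N), vz(N);
  std::vector<double> wx(N), wy(N), wz(N);
  std::vector<double> fx(N), fy(N), fzv(N), f2x(N), f2y(N), f2z(N);
  std::vector<double> pvx(N), pvy(N), pvz(N);  // lambda-predicted velocities
  std::vector<int> tp(N);
  std::vector<char> frz(N);
  for (int i = 0; i < N; i++) {
    ux[i] = pos0(i, 0); uy[i] = pos0(i, 1); uz[i] = pos0(i, 2);
    vx[i] = vel0(i, 0); vy[i] = vel0(i, 1); vz[i] = vel0(i, 2);
    tp[i] = type[i];
    frz[i] = frozen[i] ? 1 : 0;
    if (frz[i]) { vx[i] = vy[i] = vz[i] = 0.0; }
  }
  int n_cellpart = 0;
  for (int i = 0; i < N; i++)
    if (tp[i] == 2 || tp[i] == 3) n_cellpart++;

  long overlap_warn = 0;
  std::string status = "ok";

  CellList cl;
  std::vector<double> Xu(3 * N);  // column-major scratch of unwrapped positions

  auto wrap_all = [&]() {
    for (int i = 0; i < N; i++) {
      wx[i] = ux[i]; wy[i] = uy[i]; wz[i] = uz[i];
      if (per[0]) wx[i] -= box[0] * std::floor(wx[i] / box[0]);
      if (per[1]) wy[i] -= box[1] * std::floor(wy[i] / box[1]);
      if (per[2]) wz[i] -= box[2] * std::floor(wz[i] / box[2]);
    }
  };

  auto pack_unwrapped = [&]() {
    for (int i = 0; i < N; i++) { Xu[i] = ux[i]; Xu[i + N] = uy[i]; Xu[i + 2 * N] = uz[i]; }
  };

  const double invsqdt = 1.0 / std::sqrt(dt);

  auto compute_forces = [&](double tnow) {
    std::fill(f2x.begin(), f2x.end(), 0.0);
    std::fill(f2y.begin(), f2y.end(), 0.0);
    std::fill(f2z.begin(), f2z.end(), 0.0);
    // --- DPD pair forces over the cell list ---
    wrap_all();
    cl.build(wx.data(), wy.data(), wz.data(), N, box, per, rc);
    auto pair_body = [&](int i, int j) {
      if (frz[i] && frz[j]) return;
      double dxv = wx[i] - wx[j], dyv = wy[i] - wy[j], dzv = wz[i] - wz[j];
      if (per[0]) dxv -= box[0] * std::nearbyint(dxv / box[0]);
      if (per[1]) dyv -= box[1] * std::nearbyint(dyv / box[1]);
      if (per[2]) dzv -= box[2] * std::nearbyint(dzv / box[2]);
      double r2 = dxv * dxv + dyv * dyv + dzv * dzv;
      if (r2 >= rc * rc) return;
      double r = std::sqrt(r2);
      if (r < 1e-10) { overlap_warn++; return; }
      double ex = dxv / r, ey = dyv / r, ez = dzv / r;
      double w = 1.0 - r / rc;
      double wR;
      if (sexp == 0.75) {                 // common case: w^(3/4) via two sqrts
        double t = std::sqrt(w);
        wR = t * std::sqrt(t);
      } else if (sexp == 1.0) {
        wR = w;
      } else if (sexp == 0.5) {
        wR = std::sqrt(w);
      } else {
        wR = std::pow(w, sexp);
      }
      double wD = wR * wR;
      double dvx = pvx[i] - pvx[j], dvy = pvy[i] - pvy[j], dvz = pvz[i] - pvz[j];
      double vdote = dvx * ex + dvy * ey + dvz * ez;
      double theta = rng.normal();
      double frand = sigma * wR * theta * invsqdt;
      double fsc = aij(tp[i], tp[j]) * w - gammaD * wD * vdote + frand;
      f2x[i] += fsc * ex; f2y[i] += fsc * ey; f2z[i] += fsc * ez;
      f2x[j] -= fsc * ex; f2y[j] -= fsc * ey; f2z[j] -= fsc * ez;
    };
    if (cl.degenerate) {
      for (int i = 0; i < N; i++)
        for (int j = i + 1; j < N; j++) pair_body(i, j);
    } else {
      for (int cz = 0; cz < cl.nc[2]; cz++)
        for (int cy = 0; cy < cl.nc[1]; cy++)
          for (int cx = 0; cx < cl.nc[0]; cx++) {
            int c0 = (cz * cl.nc[1] + cy) * cl.nc[0] + cx;
            for (int sgrid = 0; sgrid < 14; sgrid++) {
              int ox = cx + STEN[sgrid][0], oy = cy + STEN[sgrid][1],
                  oz = cz + STEN[sgrid][2];
              if (per[0]) ox = (ox + cl.nc[0]) % cl.nc[0];
              else if (ox < 0 || ox >= cl.nc[0]) continue;
              if (per[1]) oy = (oy + cl.nc[1]) % cl.nc[1];
              else if (oy < 0 || oy >= cl.nc[1]) continue;
              if (per[2]) oz = (oz + cl.nc[2]) % cl.nc[2];
              else if (oz < 0 || oz >= cl.nc[2]) continue;
              int c1 = (oz * cl.nc[1] + oy) * cl.nc[0] + ox;
              bool same = (c1 == c0);
              if (sgrid > 0 && same) continue;
              for (int i = cl.head[c0]; i >= 0; i = cl.next[i]) {
                int jstart = same ? cl.next[i] : cl.head[c1];
                for (int j = jstart; j >= 0; j = cl.next[j]) pair_body(i, j);
              }
            }
          }
    }
    // --- bonded forces on unwrapped coordinates ---
    pack_unwrapped();
    // pass predicted velocities column-major
    std::vector<double> Vl(3 * N);
    for (int i = 0; i < N; i++) { Vl[i] = pvx[i]; Vl[i + N] = pvy[i]; Vl[i + 2 * N] = pvz[i]; }
    std::vector<double> Fm(3 * N, 0.0);
    for (size_t k = 0; k < mems.size(); k++) {
      mem_forces_elastic(Xu.data(), N, mems[k], Fm.data(), 7);
      mem_forces_viscous(Xu.data(), Vl.data(), N, mems[k], Fm.data(), &rng, dt);
    }
    for (int q = 0; q < KV.n; q++) {
      int i = KV.i[q], j = KV.j[q];
      double dxv = ux[i] - ux[j], dyv = uy[i] - uy[j], dzv = uz[i] - uz[j];
      double l = std::sqrt(dxv * dxv + dyv * dyv + dzv * dzv);
      if (l < 1e-12) stop("coincident KV-bonded particles (bond %d)", q + 1);
      double ex = dxv / l, ey = dyv / l, ez = dzv / l;
      double ldot = (pvx[i] - pvx[j]) * ex + (pvy[i] - pvy[j]) * ey + (pvz[i] - pvz[j]) * ez;
      double T;
      if (KV.strain_based)
        T = KV.ks[q] * (l - KV.l0[q]) / KV.l0[q] + KV.kv[q] * ldot / KV.l0[q];
      else
        T = KV.ks[q] * (l - KV.l0[q]) + KV.kv[q] * ldot;
      Fm[i] -= T * ex; Fm[i + N] -= T * ey; Fm[i + 2 * N] -= T * ez;
      Fm[j] += T * ex; Fm[j + N] += T * ey; Fm[j + 2 * N] += T * ez;
    }
    for (int i = 0; i < N; i++) {
      f2x[i] += Fm[i]; f2y[i] += Fm[i + N]; f2z[i] += Fm[i + 2 * N];
    }
    // --- body force on fluid particles ---
    if (BF.mode != 0) {
      double mag = BF.magnitude(tnow);
      if (mag != 0.0) {
        for (int i = 0; i < N; i++) {
          if (frz[i]) continue;
          if (BF.mode == 3) {
            if (tp[i] != 2) continue;  // surface load on outer membrane
          } else if (tp[i] != 0) {
            continue;
          }
          if (BF.mode >= 2) {
            double rr = std::sqrt((wy[i] - BF.yc) * (wy[i] - BF.yc) +
                                  (wz[i] - BF.zc) * (wz[i] - BF.zc));
            if (wx[i] < BF.xa || wx[i] > BF.xb || rr >= BF.rp) continue;
          }
          f2x[i] += mag * BF.dir[0];
          f2y[i] += mag * BF.dir[1];
          f2z[i] += mag * BF.dir[2];
        }
      }
    }
  };

  // initial forces
  for (int i = 0; i < N; i++) { pvx[i] = vx[i]; pvy[i] = vy[i]; pvz[i] = vz[i]; }
  compute_forces(0.0);
  fx = f2x; fy = f2y; fzv = f2z;

  // measurement buffers
  int nsamp_max = nsteps / stride + 2;
  std::vector<double> m_t, m_temp, m_px, m_py, m_pz, m_lp, m_asph, m_comx, m_comy,
      m_comz, m_fv;
  std::vector<std::vector<double>> m_A(mems.size()), m_V(mems.size());
  m_t.reserve(nsamp_max);

  auto measure = [&](int step) {
    double tnow = step * dt;
    m_t.push_back(tnow);
    double ke = 0.0;
    int nfree = 0;
    double px = 0, py = 0, pz = 0;
    for (int i = 0; i < N; i++) {
      if (!frz[i]) {
        ke += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
        nfree++;
      }
      px += vx[i]; py += vy[i]; pz += vz[i];
    }
    m_temp.push_back(nfree > 0 ? ke / (3.0 * nfree) : 0.0);
    m_px.push_back(px); m_py.push_back(py); m_pz.push_back(pz);
    if (meas_mem) {
      pack_unwrapped();
      double out[7];
      for (size_t k = 0; k < mems.size(); k++) {
        mem_energy(Xu.data(), N, mems[k], out);
        m_A[k].push_back(out[5]);
        m_V[k].push_back(out[6]);
      }
    }
    if (meas_lp && W.has_pipette) {
      double mx = -1e300;
      for (int i = 0; i < N; i++)
        if (tp[i] == 2 || tp[i] == 3) mx = std::max(mx, ux[i] - W.pip_xm);
      m_lp.push_back(std::max(0.0, mx));
    }
    if (meas_asph || meas_com) {
      double cx = 0, cy = 0, cz = 0;
      int nc = 0;
      for (int i = 0; i < N; i++)
        if (tp[i] == 2 || tp[i] == 3) { cx += ux[i]; cy += uy[i]; cz += uz[i]; nc++; }
      if (nc > 0) { cx /= nc; cy /= nc; cz /= nc; }
      if (meas_com) { m_comx.push_back(cx); m_comy.push_back(cy); m_comz.push_back(cz); }
      if (meas_asph) {
        double S[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
        for (int i = 0; i < N; i++) {
          if (tp[i] != 2 && tp[i] != 3) continue;
          double d[3] = {ux[i] - cx, uy[i] - cy, uz[i] - cz};
          for (int a = 0; a < 3; a++)
            for (int b = 0; b < 3; b++) S[a][b] += d[a] * d[b] / nc;
        }
        double ev[3];
        eig3_sym(S, ev);
        double tr = ev[0] + ev[1] + ev[2];
        double num = (ev[0] - ev[1]) * (ev[0] - ev[1]) +
                     (ev[1] - ev[2]) * (ev[1] - ev[2]) +
                     (ev[2] - ev[0]) * (ev[2] - ev[0]);
        m_asph.push_back(tr > 0 ? num / (2.0 * tr * tr) : 0.0);
      }
    }
    if (meas_fluidv) {
      double s = 0.0;
      int nf = 0;
      for (int i = 0; i < N; i++)
        if (tp[i] == 0 && !frz[i]) { s += vx[i]; nf++; }
      m_fv.push_back(nf > 0 ? s / nf : 0.0);
    }
  };

  measure(0);

  const double max_disp = rc;
  for (int step = 1; step <= nsteps; step++) {
    if (step % 200 == 0) Rcpp::checkUserInterrupt();
    // position update + velocity prediction
    for (int i = 0; i < N; i++) {
      if (frz[i]) { pvx[i] = pvy[i] = pvz[i] = 0.0; continue; }
      double ddx = dt * vx[i] + 0.5 * dt * dt * fx[i];
      double ddy = dt * vy[i] + 0.5 * dt * dt * fy[i];
      double ddz = dt * vz[i] + 0.5 * dt * dt * fzv[i];
      if (ddx * ddx + ddy * ddy + ddz * ddz > max_disp * max_disp)
        stop("time step too large: particle %d moved %.3f in one step (> r_c)", i + 1,
             std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz));
      ux[i] += ddx; uy[i] += ddy; uz[i] += ddz;
      pvx[i] = vx[i] + lambda * dt * fx[i];
      pvy[i] = vy[i] + lambda * dt * fy[i];
      pvz[i] = vz[i] + lambda * dt * fzv[i];
    }
    // wall bounce-back on wrapped coordinates
    if (W.has_slab || W.has_pipette || !W.obst.empty()) {
      for (int i = 0; i < N; i++) {
        if (frz[i]) continue;
        double xx = ux[i], yy = uy[i], zz = uz[i];
        if (per[0]) xx -= box[0] * std::floor(xx / box[0]);
        if (per[1]) yy -= box[1] * std::floor(yy / box[1]);
        if (per[2]) zz -= box[2] * std::floor(zz / box[2]);
        double ox = xx, oy = yy, oz = zz;
        bool deep = false;
        if (wall_reflect(W, &xx, &yy, &zz, deep, rc)) {
          if (deep)
            stop("particle %d penetrated a wall deeper than r_c; reduce the time step",
                 i + 1);
          ux[i] += xx - ox; uy[i] += yy - oy; uz[i] += zz - oz;
          vx[i] = -vx[i]; vy[i] = -vy[i]; vz[i] = -vz[i];
          pvx[i] = -pvx[i]; pvy[i] = -pvy[i]; pvz[i] = -pvz[i];
        }
      }
    }
    compute_forces(step * dt);
    for (int i = 0; i < N; i++) {
      if (frz[i]) continue;
      vx[i] += 0.5 * dt * (fx[i] + f2x[i]);
      vy[i] += 0.5 * dt * (fy[i] + f2y[i]);
      vz[i] += 0.5 * dt * (fzv[i] + f2z[i]);
    }
    fx = f2x; fy = f2y; fzv = f2z;
    if (step % stride == 0) measure(step);
    if (stop_aspirated && W.has_pipette && n_cellpart > 0) {
      double mn = 1e300;
      for (int i = 0; i < N; i++)
        if (tp[i] == 2 || tp[i] == 3) mn = std::min(mn, ux[i] - W.pip_xm);
      if (mn > 0) { status = "aspirated"; break; }
    }
  }

  NumericMatrix pos(N, 3), vel(N, 3);
  for (int i = 0; i < N; i++) {
    pos(i, 0) = ux[i]; pos(i, 1) = uy[i]; pos(i, 2) = uz[i];
    vel(i, 0) = vx[i]; vel(i, 1) = vy[i]; vel(i, 2) = vz[i];
  }
  List trace = List::create(
      _["time"] = wrap(m_t), _["kbt_kin"] = wrap(m_temp), _["px"] = wrap(m_px),
      _["py"] = wrap(m_py), _["pz"] = wrap(m_pz));
  if (meas_mem) {
    List LA(m_A.size()), LV(m_V.size());
    for (size_t k = 0; k < m_A.size(); k++) { LA[k] = wrap(m_A[k]); LV[k] = wrap(m_V[k]); }
    trace["area"] = LA;
    trace["volume"] = LV;
  }
  if (meas_lp && W.has_pipette) trace["lp"] = wrap(m_lp);
  if (meas_asph) trace["asphericity"] = wrap(m_asph);
  if (meas_com) {
    trace["com_x"] = wrap(m_comx); trace["com_y"] = wrap(m_comy);
    trace["com_z"] = wrap(m_comz);
  }
  if (meas_fluidv) trace["fluid_vx"] = wrap(m_fv);

  return List::create(_["positions"] = pos, _["velocities"] = vel, _["trace"] = trace,
                      _["status"] = status, _["overlap_warnings"] = (double)overlap_warn);
}

// exact pair list with minimum-image distance < rc (cell-list backed)
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, NumericVector boxv,
                                 LogicalVector periodic, double rc) {
  int N = pos.nrow();
  double box[3] = {boxv[0], boxv[1], boxv[2]};
  bool per[3] = {(bool)periodic[0], (bool)periodic[1], (bool)periodic[2]};
  for (int d = 0; d < 3; d++)
    if (per[d] && box[d] < 3.0 * rc)
      stop("periodic box dimension %d (%.3f) is smaller than 3 r_c", d + 1, box[d]);
  std::vector<double> wx(N), wy(N), wz(N);
  for (int i = 0; i < N; i++) {
    wx[i] = pos(i, 0); wy[i] = pos(i, 1); wz[i] = pos(i, 2);
    if (per[0]) wx[i] -= box[0] * std::floor(wx[i] / box[0]);
    if (per[1]) wy[i] -= box[1] * std::floor(wy[i] / box[1]);
    if (per[2]) wz[i] -= box[2] * std::floor(wz[i] / box[2]);
  }
  CellList cl;
  cl.build(wx.data(), wy.data(), wz.data(), N, box, per, rc);
  std::vector<int> pi, pj;
  for (int cz = 0; cz < cl.nc[2]; cz++)
    for (int cy = 0; cy < cl.nc[1]; cy++)
      for (int cx = 0; cx < cl.nc[0]; cx++) {
        int c0 = (cz * cl.nc[1] + cy) * cl.nc[0] + cx;
        for (int sgrid = 0; sgrid < 14; sgrid++) {
          int ox = cx + STEN[sgrid][0], oy = cy + STEN[sgrid][1], oz = cz + STEN[sgrid][2];
          if (per[0]) ox = (ox + cl.nc[0]) % cl.nc[0];
          else if (ox < 0 || ox >= cl.nc[0]) continue;
          if (per[1]) oy = (oy + cl.nc[1]) % cl.nc[1];
          else if (oy < 0 || oy >= cl.nc[1]) continue;
          if (per[2]) oz = (oz + cl.nc[2]) % cl.nc[2];
          else if (oz < 0 || oz >= cl.nc[2]) continue;
          int c1 = (oz * cl.nc[1] + oy) * cl.nc[0] + ox;
          bool same = (c1 == c0);
          if (sgrid > 0 && same) continue;
          for (int i = cl.head[c0]; i >= 0; i = cl.next[i]) {
            int jstart = same ? cl.next[i] : cl.head[c1];
            for (int j = jstart; j >= 0; j = cl.next[j]) {
              double dxv = wx[i] - wx[j], dyv = wy[i] - wy[j], dzv = wz[i] - wz[j];
              if (per[0]) dxv -= box[0] * std::nearbyint(dxv / box[0]);
              if (per[1]) dyv -= box[1] * std::nearbyint(dyv / box[1]);
              if (per[2]) dzv -= box[2] * std::nearbyint(dzv / box[2]);
              if (dxv * dxv + dyv * dyv + dzv * dzv < rc * rc) {
                pi.push_back(std::min(i, j) + 1);
                pj.push_back(std::max(i, j) + 1);
              }
            }
          }
        }
      }
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); k++) { out(k, 0) = pi[k]; out(k, 1) = pj[k]; }
  return out;
}
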