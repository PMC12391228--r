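#ifndef CELLFLOW_MEMBRANE_CORE_H
#define CELLFLOW_MEMBRANE_CORE_H

#include <Rcpp.h>
#include <vector>
#include "vec3.h"
#include "rng.h"

// One triangulated membrane: worm-like-chain in-plane elasticity with a
// per-triangle (1/A_alpha) expansion term, dihedral bending, global area and
// volume constraints, and pairwise bond viscosity with matching thermal noise.
struct Mem {
  int n_edge, n_tri, n_dih;
  std::vector<int> e0, e1;                 // bond endpoints (0-based particle ids)
  std::vector<int> t0, t1, t2;             // triangle vertices, outward-oriented
  std::vector<int> dk, di, dj, dl;         // dihedral quadruple: tris (i,j,k) and (j,i,l)
  std::vector<double> l0, lmax;            // per-bond rest / max length
  double p, kb, theta0, ka, kvol, A0, V0;
  double l0ref;                            // equilibrium-length scale in Eq-11 denominators
  double x0, lmax_tri;                     // scalars for the per-triangle WLC term
  double gammaT, gammaC;                   // membrane viscosity (gammaT = gammaC = gamma)
  double kBT;                              // material energy scale (WLC, constraints)
  double kBT_noise;                        // thermostat temperature of the random force
  double Cq;                               // coefficient of the 1/A_alpha term
  bool thermal;                            // add the random force paired with Eq-12 dissipation

  void precompute() {
    double x2 = x0 * x0;
    Cq = 3.0 * std::sqrt(3.0) * kBT * lmax_tri * lmax_tri * lmax_tri * x2 * x2 *
         (4.0 * x2 - 9.0 * x0 + 6.0) / (64.0 * p * (1.0 - x2));
  }
};

inline Mem parse_mem(const Rcpp::List &m) {
  Mem M;
  Rcpp::IntegerMatrix edges = m["edges"], tris = m["triangles"], dih = m["dihedrals"];
  Rcpp::NumericVector l0 = m["l0"], lmax = m["lmax"];
  M.n_edge = edges.nrow();
  M.n_tri = tris.nrow();
  M.n_dih = dih.nrow();
  M.e0.resize(M.n_edge); M.e1.resize(M.n_edge);
  M.l0.resize(M.n_edge); M.lmax.resize(M.n_edge);
  for (int i = 0; i < M.n_edge; i++) {
    M.e0[i] = edges(i, 0) - 1; M.e1[i] = edges(i, 1) - 1;
    M.l0[i] = l0[i]; M.lmax[i] = lmax[i];
  }
  M.t0.resize(M.n_tri); M.t1.resize(M.n_tri); M.t2.resize(M.n_tri);
  for (int i = 0; i < M.n_tri; i++) {
    M.t0[i] = tris(i, 0) - 1; M.t1[i] = tris(i, 1) - 1; M.t2[i] = tris(i, 2) - 1;
  }
  M.dk.resize(M.n_dih); M.di.resize(M.n_dih); M.dj.resize(M.n_dih); M.dl.resize(M.n_dih);
  for (int i = 0; i < M.n_dih; i++) {
    M.dk[i] = dih(i, 0) - 1; M.di[i] = dih(i, 1) - 1;
    M.dj[i] = dih(i, 2) - 1; M.dl[i] = dih(i, 3) - 1;
  }
  M.p = Rcpp::as<double>(m["p"]);
  M.kb = Rcpp::as<double>(m["kb"]);
  M.theta0 = Rcpp::as<double>(m["theta0"]);
  M.ka = Rcpp::as<double>(m["ka"]);
  M.kvol = Rcpp::as<double>(m["kvol"]);
  M.A0 = Rcpp::as<double>(m["A0"]);
  M.V0 = Rcpp::as<double>(m["V0"]);
  M.l0ref = Rcpp::as<double>(m["l0ref"]);
  M.x0 = Rcpp::as<double>(m["x0"]);
  M.lmax_tri = Rcpp::as<double>(m["lmax_tri"]);
  double g = Rcpp::as<double>(m["gamma"]);
  M.gammaT = g; M.gammaC = g;
  M.kBT = Rcpp::as<double>(m["kBT"]);
  M.kBT_noise = m.containsElementNamed("kBT_noise")
                    ? Rcpp::as<double>(m["kBT_noise"])
                    : M.kBT;
  M.thermal = Rcpp::as<bool>(m["thermal"]);
  M.precompute();
  return M;
}

// column-major accessors into an N x 3 matrix
inline V3 getv(const double *X, int n, int i) { return V3(X[i], X[i + n], X[i + 2 * n]); }
inline void addv(double *F, int n, int i, const V3 &f) {
  F[i] += f.x; F[i + n] += f.y; F[i + 2 * n] += f.z;
}

// signed dihedral angle between the outward normals of triangles (i,j,k) and
// (j,i,l) sharing edge i-j; 0 when coplanar, positive when convex outward.
// Computed as the complement of the torsion angle of the chain k-i-j-l.
inline double dihedral_theta(const V3 &xk, const V3 &xi, const V3 &xj, const V3 &xl,
                             V3 *g = nullptr /* gradients dtheta/d{k,i,j,l} x4 */) {
  V3 b1 = xi - xk, b2 = xj - xi, b3 = xl - xj;
  V3 n1 = cross(b1, b2), n2 = cross(b2, b3);
  double n1sq = norm2(n1), n2sq = norm2(n2), b2n = norm(b2);
  if (n1sq < 1e-24 || n2sq < 1e-24)
    Rcpp::stop("degenerate (zero-area) triangle in dihedral computation");
  double phi = std::atan2(dot(cross(n1, n2), b2) / b2n, dot(n1, n2));
  double theta = phi - M_PI;  // flat -> 0, convex outward -> positive
  if (theta < -M_PI) theta += 2.0 * M_PI;
  if (g) {
    // standard torsion-angle gradient for chain (k,i,j,l); dtheta = +dphi
    V3 gk = (-b2n / n1sq) * n1;       // dphi/dxk
    V3 gl = (b2n / n2sq) * n2;        // dphi/dxl
    double c1 = dot(b1, b2) / (b2n * b2n);
    double c3 = dot(b3, b2) / (b2n * b2n);
    V3 gi = (-(1.0 + c1)) * gk + c3 * gl;
    V3 gj = c1 * gk + (-(1.0 + c3)) * gl;
    g[0] = gk; g[1] = gi; g[2] = gj; g[3] = gl;
  }
  return theta;
}

// energy components: out = {Us_bond, Us_tri, Ub, Ua, Uv, A, V}
inline void mem_energy(const double *X, int n, const Mem &M, double *out) {
  double usb = 0.0, ust = 0.0, ub = 0.0, A = 0.0, V = 0.0;
  for (int b = 0; b < M.n_edge; b++) {
    V3 d = getv(X, n, M.e0[b]) - getv(X, n, M.e1[b]);
    double l = norm(d);
    if (l >= M.lmax[b])
      Rcpp::stop("bond overextension: membrane bond %d has length %.4f >= l_max %.4f",
                 b + 1, l, M.lmax[b]);
    double x = l / M.lmax[b];
    usb += M.kBT * M.lmax[b] / (4.0 * M.p) * (3.0 * x * x - 2.0 * x * x * x) / (1.0 - x);
  }
  for (int t = 0; t < M.n_tri; t++) {
    V3 a = getv(X, n, M.t0[t]), b = getv(X, n, M.t1[t]), c = getv(X, n, M.t2[t]);
    V3 nrm = cross(b - a, c - a);
    double A2 = norm(nrm);
    if (A2 < 1e-24) Rcpp::stop("degenerate (zero-area) triangle %d", t + 1);
    double At = 0.5 * A2;
    ust += M.Cq / At;
    A += At;
    V += dot(a, cross(b, c)) / 6.0;
  }
  for (int d = 0; d < M.n_dih; d++) {
    double th = dihedral_theta(getv(X, n, M.dk[d]), getv(X, n, M.di[d]),
                               getv(X, n, M.dj[d]), getv(X, n, M.dl[d]));
    ub += M.kb * (1.0 - std::cos(th - M.theta0));
  }
  double ua = M.ka * M.kBT * (A - M.A0) * (A - M.A0) / (2.0 * M.l0ref * M.l0ref * M.A0);
  double uv = M.kvol * M.kBT * (V - M.V0) * (V - M.V0) /
              (2.0 * M.l0ref * M.l0ref * M.l0ref * M.V0);
  out[0] = usb; out[1] = ust; out[2] = ub; out[3] = ua; out[4] = uv;
  out[5] = A; out[6] = V;
}

// elastic forces = -grad U; `which` bitmask: 1 in-plane, 2 bending, 4 area+volume
inline void mem_forces_elastic(const double *X, int n, const Mem &M, double *F, int which) {
  if (which & 1) {
    for (int b = 0; b < M.n_edge; b++) {
      int i = M.e0[b], j = M.e1[b];
      V3 d = getv(X, n, i) - getv(X, n, j);
      double l = norm(d);
      if (l >= M.lmax[b])
        Rcpp::stop("bond overextension: membrane bond %d has length %.4f >= l_max %.4f",
                   b + 1, l, M.lmax[b]);
      double x = l / M.lmax[b];
      double omx = 1.0 - x;
      // dU/dl of the WLC bond term
      double dudl = M.kBT / (4.0 * M.p) *
                    (6.0 * x - 9.0 * x * x + 4.0 * x * x * x) / (omx * omx);
      V3 f = (-dudl / l) * d;
      addv(F, n, i, f);
      addv(F, n, j, -1.0 * f);
    }
  }
  // triangle-area-dependent pieces (1/A_alpha term, global area, volume)
  bool need_tri = (which & 1) || (which & 4);
  if (need_tri) {
    double A = 0.0, V = 0.0;
    if (which & 4) {
      for (int t = 0; t < M.n_tri; t++) {
        V3 a = getv(X, n, M.t0[t]), b = getv(X, n, M.t1[t]), c = getv(X, n, M.t2[t]);
        A += 0.5 * norm(cross(b - a, c - a));
        V += dot(a, cross(b, c)) / 6.0;
      }
    }
    double dUdA = (which & 4) ? M.ka * M.kBT * (A - M.A0) / (M.l0ref * M.l0ref * M.A0) : 0.0;
    double dUdV = (which & 4) ? M.kvol * M.kBT * (V - M.V0) /
                                  (M.l0ref * M.l0ref * M.l0ref * M.V0)
                              : 0.0;
    for (int t = 0; t < M.n_tri; t++) {
      int ia = M.t0[t], ib = M.t1[t], ic = M.t2[t];
      V3 a = getv(X, n, ia), b = getv(X, n, ib), c = getv(X, n, ic);
      V3 nrm = cross(b - a, c - a);
      double A2 = norm(nrm);
      if (A2 < 1e-24) Rcpp::stop("degenerate (zero-area) triangle %d", t + 1);
      double At = 0.5 * A2;
      V3 nh = (1.0 / A2) * nrm;
      V3 gA_a = 0.5 * cross(b - c, nh);
      V3 gA_b = 0.5 * cross(c - a, nh);
      V3 gA_c = 0.5 * cross(a - b, nh);
      double coefA = dUdA;
      if (which & 1) coefA += -M.Cq / (At * At);  // d(Cq/A)/dA = -Cq/A^2
      if (coefA != 0.0) {
        addv(F, n, ia, (-coefA) * gA_a);
        addv(F, n, ib, (-coefA) * gA_b);
        addv(F, n, ic, (-coefA) * gA_c);
      }
      if (dUdV != 0.0) {
        addv(F, n, ia, (-dUdV / 6.0) * cross(b, c));
        addv(F, n, ib, (-dUdV / 6.0) * cross(c, a));
        addv(F, n, ic, (-dUdV / 6.0) * cross(a, b));
      }
    }
  }
  if (which & 2) {
    V3 g[4];
    for (int d = 0; d < M.n_dih; d++) {
      int k = M.dk[d], i = M.di[d], j = M.dj[d], l = M.dl[d];
      double th = dihedral_theta(getv(X, n, k), getv(X, n, i),
                                 getv(X, n, j), getv(X, n, l), g);
      double dEdth = M.kb * std::sin(th - M.theta0);
      addv(F, n, k, (-dEdth) * g[0]);
      addv(F, n, i, (-dEdth) * g[1]);
      addv(F, n, j, (-dEdth) * g[2]);
      addv(F, n, l, (-dEdth) * g[3]);
    }
  }
}

// pairwise membrane viscosity (dissipative) and, optionally, the matching
// random force; momentum-conserving by construction.
inline void mem_forces_viscous(const double *X, const double *Vl, int n, const Mem &M,
                               double *F, Rng *rng, double dt) {
  double aT = std::sqrt(2.0 * M.gammaT);
  double aC = std::sqrt(3.0 * M.gammaC - M.gammaT);
  double amp = std::sqrt(2.0 * M.kBT_noise) / dt;
  double sdt = std::sqrt(dt);
  for (int b = 0; b < M.n_edge; b++) {
    int i = M.e0[b], j = M.e1[b];
    V3 d = getv(X, n, i) - getv(X, n, j);
    double l = norm(d);
    if (l < 1e-12) continue;
    V3 eh = (1.0 / l) * d;
    V3 vij = getv(Vl, n, i) - getv(Vl, n, j);
    V3 fD = (-M.gammaT) * vij + (-M.gammaC * dot(vij, eh)) * eh;
    V3 f = fD;
    if (M.thermal && rng) {
      double W[3][3];
      for (int a = 0; a < 3; a++)
        for (int c = 0; c < 3; c++) W[a][c] = rng->normal() * sdt;
      double tr3 = (W[0][0] + W[1][1] + W[2][2]) / 3.0;
      // traceless symmetric part + isotropic trace part, dotted with unit vector
      double e[3] = {eh.x, eh.y, eh.z};
      double fr[3];
      for (int a = 0; a < 3; a++) {
        double s = 0.0;
        for (int c = 0; c < 3; c++) {
          double Ssym = 0.5 * (W[a][c] + W[c][a]);
          double Mac = aT * (Ssym - (a == c ? tr3 : 0.0)) + (a == c ? aC * tr3 : 0.0);
          s += Mac * e[c];
        }
        fr[a] = amp * s;
      }
      f = f + V3(fr[0], fr[1], fr[2]);
    }
    addv(F, n, i, f);
    addv(F, n, j, -1.0 * f);
  }
}

#endif
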