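#include <Rcpp.h>
#include "membrane_core.h"
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_membrane_energy(NumericMatrix pos, List mem) {
  Mem M = parse_mem(mem);
  int n = pos.nrow();
  double out[7];
  mem_energy(REAL(pos), n, M, out);
  return List::create(_["inplane_bond"] = out[0], _["inplane_tri"] = out[1],
                      _["bending"] = out[2], _["area"] = out[3], _["volume"] = out[4],
                      _["A"] = out[5], _["V"] = out[6],
                      _["total"] = out[0] + out[1] + out[2] + out[3] + out[4]);
}

// [[Rcpp::export]]
NumericMatrix cpp_membrane_forces(NumericMatrix pos, List mem, int which) {
  Mem M = parse_mem(mem);
  int n = pos.nrow();
  NumericMatrix F(n, 3);
  mem_forces_elastic(REAL(pos), n, M, REAL(F), which);
  return F;
}

// [[Rcpp::export]]
NumericVector cpp_dihedral_angles(NumericMatrix pos, IntegerMatrix dihedrals) {
  int n = pos.nrow(), m = dihedrals.nrow();
  NumericVector th(m);
  const double *X = REAL(pos);
  for (int d = 0; d < m; d++) {
    th[d] = dihedral_theta(getv(X, n, dihedrals(d, 0) - 1), getv(X, n, dihedrals(d, 1) - 1),
                           getv(X, n, dihedrals(d, 2) - 1), getv(X, n, dihedrals(d, 3) - 1));
  }
  return th;
}

// pair dissipative + random membrane force for a single bond (module surface
// for tests); returns the force on particle i (force on j is its negation).
// [[Rcpp::export]]
NumericVector cpp_membrane_pair_force(NumericVector ri, NumericVector rj,
                                      NumericVector vi, NumericVector vj,
                                      double gammaT, double gammaC, double kBT,
                                      NumericMatrix dW, double dt) {
  V3 d(ri[0] - rj[0], ri[1] - rj[1], ri[2] - rj[2]);
  double l = norm(d);
  if (l < 1e-12) stop("coincident bonded particles");
  V3 eh = (1.0 / l) * d;
  V3 vij(vi[0] - vj[0], vi[1] - vj[1], vi[2] - vj[2]);
  V3 fD = (-gammaT) * vij + (-gammaC * dot(vij, eh)) * eh;
  if (3.0 * gammaC - gammaT < 0)
    stop("3*gamma_C - gamma_T must be non-negative");
  double aT = std::sqrt(2.0 * gammaT), aC = std::sqrt(3.0 * gammaC - gammaT);
  double amp = std::sqrt(2.0 * kBT) / dt;
  double tr3 = (dW(0, 0) + dW(1, 1) + dW(2, 2)) / 3.0;
  double e[3] = {eh.x, eh.y, eh.z}, fr[3];
  for (int a = 0; a < 3; a++) {
    double s = 0.0;
    for (int c = 0; c < 3; c++) {
      double Ssym = 0.5 * (dW(a, c) + dW(c, a));
      double Mac = aT * (Ssym - (a == c ? tr3 : 0.0)) + (a == c ? aC * tr3 : 0.0);
      s += Mac * e[c];
    }
    fr[a] = amp * s;
  }
  return NumericVector::create(fD.x + fr[0], fD.y + fr[1], fD.z + fr[2]);
}
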