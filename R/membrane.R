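#' Membrane material parameters
#'
#' Parameter set of the triangulated-membrane model: worm-like-chain (WLC)
#' in-plane elasticity with persistence length `p` and maximum bond extension
#' `lmax`, bending stiffness `kb` about equilibrium dihedral angle `theta0`,
#' global area/volume constraint coefficients `ka`/`kvol`, and membrane
#' viscosity `gamma` (the translational and central dissipative coefficients
#' are taken equal, `gamma_T = gamma_C = gamma`).  Defaults are the cell and
#' nucleus parameter sets used throughout the package (simulation units):
#' `p = 0.00141`, `gamma = 4`, `l0 = 0.5`, `k_A = 10000` (cell) / `5000`
#' (nucleus), `k_V = 15000`, `lmax = 3` (cell) / `1.2` (nucleus), bending
#' stiffness `65` (cell) / `250` (nucleus).
#'
#' @param kind `"cell"` or `"nucleus"` default set.
#' @param p persistence length.
#' @param gamma membrane viscosity coefficient.
#' @param ka,kvol area and volume constraint coefficients.
#' @param lmax,l0 maximum and equilibrium bond lengths; `0 < l0 < lmax`.
#' @param kb bending stiffness (energy units).
#' @param theta0 equilibrium dihedral angle (radians; default 0 = flat).
#' @param kBT thermal energy.
#' @return object of class `membrane_params`.
#' @export
membrane_params <- function(kind = c("cell", "nucleus"), p = 0.00141, gamma = 4,
                            ka = NULL, kvol = 15000, lmax = NULL, l0 = 0.5,
                            kb = NULL, theta0 = 0, kBT = 0.02) {
  kind <- match.arg(kind)
  if (is.null(ka)) ka <- if (kind == "cell") 10000 else 5000
  if (is.null(lmax)) lmax <- if (kind == "cell") 3 else 1.2
  if (is.null(kb)) kb <- if (kind == "cell") 65 else 250
  stopifnot(p > 0, gamma >= 0, ka >= 0, kvol >= 0, kb >= 0, kBT > 0,
            l0 > 0, l0 < lmax)
  structure(list(kind = kind, p = p, gamma = gamma, ka = ka, kvol = kvol,
                 lmax = lmax, l0 = l0, x0 = l0 / lmax, kb = kb,
                 theta0 = theta0, kBT = kBT),
            class = "membrane_params")
}

#' Bind membrane parameters to a mesh
#'
#' Produces the force-field descriptor used by the energy/force operators and
#' the integrator.  By default each bond keeps its constructed rest length
#' `l0` and a proportional maximum extension `lmax = l0 / x0` (preserving the
#' equilibrium-to-maximum ratio `x0`); `uniform_l0 = TRUE` instead applies
#' the scalar parameter values to every bond.  The reference area `A0` and
#' volume `V0` default to the bound mesh's current geometry.
#'
#' @param mesh a [trimesh()].
#' @param params a [membrane_params()].
#' @param A0,V0 reference area/volume (defaults: current mesh values).
#' @param uniform_l0 use the scalar `l0`/`lmax` for every bond.
#' @param thermal include the random force paired with the membrane
#'   dissipative force during integration.
#' @param index_offset offset added to vertex indices, for membranes embedded
#'   in a larger particle system.
#' @return object of class `membrane`.
#' @export
membrane <- function(mesh, params, A0 = NULL, V0 = NULL, uniform_l0 = FALSE,
                     thermal = TRUE, index_offset = 0L) {
  stopifnot(inherits(mesh, "trimesh"), inherits(params, "membrane_params"))
  g <- mesh_geometry(mesh)
  if (is.null(A0)) A0 <- g$area
  if (is.null(V0)) V0 <- g$volume
  l0e <- if (uniform_l0) rep(params$l0, mesh$n_edges) else mesh$l0
  lmaxe <- l0e / params$x0
  desc <- list(edges = mesh$edges + index_offset,
               triangles = mesh$triangles + index_offset,
               dihedrals = mesh$dihedrals + index_offset,
               l0 = l0e, lmax = lmaxe,
               p = params$p, kb = params$kb, theta0 = params$theta0,
               ka = params$ka, kvol = params$kvol, A0 = A0, V0 = V0,
               l0ref = mean(l0e), x0 = params$x0, lmax_tri = mean(lmaxe),
               gamma = params$gamma, kBT = params$kBT, thermal = thermal)
  structure(list(mesh = mesh, params = params, descriptor = desc,
                 A0 = A0, V0 = V0, index_offset = index_offset),
            class = "membrane")
}

mem_positions <- function(mem, positions) {
  if (is.null(positions)) {
    if (mem$index_offset != 0)
      stop("membrane with index_offset needs explicit system positions")
    mem$mesh$vertices
  } else positions
}

#' Membrane energies and forces
#'
#' `inplane_*` evaluates the WLC in-plane shear energy: a per-bond
#' attractive WLC term plus a per-triangle term proportional to `1/A_alpha`
#' that resists compression.  `bending_*` evaluates
#' `kb [1 - cos(theta - theta0)]` over adjacent-triangle pairs.
#' `area_volume_*` evaluates the global constraints
#' `ka kBT (A - A0)^2 / (2 l0^2 A0)` and `kvol kBT (V - V0)^2 / (2 l0^3 V0)`.
#' All force operators are exact negative gradients of the corresponding
#' energies with respect to vertex positions (including the `1/A_alpha`
#' dependence of the in-plane triangle term).
#'
#' @param mem a bound [membrane()].
#' @param positions optional replacement coordinates (full system matrix when
#'   the membrane has an index offset).
#' @return energies in simulation units; forces as an N x 3 matrix.
#' @name membrane-energy
NULL

#' @rdname membrane-energy
#' @export
inplane_energy <- function(mem, positions = NULL) {
  e <- cpp_membrane_energy(mem_positions(mem, positions), mem$descriptor)
  e$inplane_bond + e$inplane_tri
}

#' @rdname membrane-energy
#' @export
inplane_forces <- function(mem, positions = NULL) {
  cpp_membrane_forces(mem_positions(mem, positions), mem$descriptor, 1L)
}

#' @rdname membrane-energy
#' @export
bending_energy <- function(mem, positions = NULL) {
  cpp_membrane_energy(mem_positions(mem, positions), mem$descriptor)$bending
}

#' @rdname membrane-energy
#' @export
bending_forces <- function(mem, positions = NULL) {
  cpp_membrane_forces(mem_positions(mem, positions), mem$descriptor, 2L)
}

#' @rdname membrane-energy
#' @export
area_volume_energy <- function(mem, positions = NULL) {
  e <- cpp_membrane_energy(mem_positions(mem, positions), mem$descriptor)
  list(area = e$area, volume = e$volume, total = e$area + e$volume)
}

#' @rdname membrane-energy
#' @export
area_volume_forces <- function(mem, positions = NULL) {
  cpp_membrane_forces(mem_positions(mem, positions), mem$descriptor, 4L)
}

#' @rdname membrane-energy
#' @export
membrane_energy <- function(mem, positions = NULL) {
  cpp_membrane_energy(mem_positions(mem, positions), mem$descriptor)
}

#' @rdname membrane-energy
#' @param which bitmask or `"all"`: 1 in-plane, 2 bending, 4 area+volume.
#' @export
membrane_forces <- function(mem, positions = NULL, which = "all") {
  w <- if (identical(which, "all")) 7L else as.integer(which)
  cpp_membrane_forces(mem_positions(mem, positions), mem$descriptor, w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise membrane dissipative and random force
#'
#' The dissipative part is
#' `f_D = -gamma_T v_ij - gamma_C (v_ij . rhat) rhat`; the random part uses
#' the traceless symmetric projection of a 3 x 3 Wiener-increment matrix
#' `dW` (entries `Normal(0,1) * sqrt(dt)`) shared by the bonded pair, with
#' amplitudes `sqrt(2 kBT) sqrt(2 gamma_T)` and
#' `sqrt(2 kBT) sqrt(3 gamma_C - gamma_T)`; under the model assumption
#' `gamma_T = gamma_C = gamma` the second amplitude equals `sqrt(2 gamma)`.
#' The returned pair is antisymmetric, conserving momentum.
#'
#' @param ri,rj,vi,vj positions and velocities of the bonded pair.
#' @param params a [membrane_params()].
#' @param dW 3 x 3 Wiener increment matrix (entries already scaled by
#'   `sqrt(dt)`).
#' @param dt time step.
#' @return list with forces `fi` and `fj = -fi`.
#' @export
membrane_pair_dissipative_random <- function(ri, rj, vi, vj, params, dW, dt) {
  f <- cpp_membrane_pair_force(ri, rj, vi, vj, params$gamma, params$gamma,
                               params$kBT, as.matrix(dW), dt)
  list(fi = f, fj = -f)
}

#' Worm-like-chain bond energy
#'
#' `U(l) = kBT lmax / (4 p) * (3 x^2 - 2 x^3) / (1 - x)` with `x = l / lmax`;
#' strictly increasing on `0 < x < 1` and divergent as `l` approaches `lmax`.
#'
#' @param l bond length(s).
#' @param lmax maximum extension.
#' @param p persistence length.
#' @param kBT thermal energy.
#' @return energy, vectorized over `l`.
#' @export
wlc_bond_energy <- function(l, lmax, p, kBT) {
  x <- l / lmax
  stopifnot(all(x >= 0), all(x < 1))
  kBT * lmax / (4 * p) * (3 * x^2 - 2 * x^3) / (1 - x)
}

#' Sphericity of a closed surface
#'
#' `pi^(1/3) (6 V)^(2/3) / A`; equals 1 for a perfect sphere.
#'
#' @param mesh a [trimesh()], or supply `area`/`volume` directly.
#' @param area,volume surface area and enclosed volume.
#' @return sphericity in (0, 1].
#' @export
sphericity <- function(mesh = NULL, area = NULL, volume = NULL) {
  if (!is.null(mesh)) {
    g <- mesh_geometry(mesh)
    area <- g$area
    volume <- g$volume
  }
  pi^(1 / 3) * (6 * volume)^(2 / 3) / area
}
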