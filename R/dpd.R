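#' DPD interaction and integration parameters
#'
#' Collects the pairwise-force coefficients and integrator settings of the
#' dissipative particle dynamics (DPD) method.  The random-force amplitude is
#' never supplied directly: the fluctuation-dissipation relation
#' `sigma^2 = 2 gamma k_BT` is enforced at construction, and the dissipative
#' and random weight functions are tied by `w_D = (w_R)^2` with
#' `w_R(r) = (1 - r/r_c)^s`.
#'
#' @param kBT thermal energy (simulation units).
#' @param rc interaction cutoff radius.
#' @param gamma dissipative coefficient `gamma_D`.
#' @param s exponent of the generalized weight function (default 0.75).
#' @param dt integration time step.
#' @param lambda velocity-prediction factor of the modified velocity-Verlet
#'   scheme (default 0.5, the standard Groot-Warren choice).
#' @param aij conservative coefficient matrix over particle types
#'   (`fluid`, `wall`, `cell`, `nucleus`).  Defaults to `25 kBT / rc` for all
#'   pairs, doubled between membrane types to provide excluded volume.
#' @return an object of class `dpd_params`.
#' @export
dpd_params <- function(kBT = 0.02, rc = 1, gamma = 4.5, s = 0.75, dt = 0.01,
                       lambda = 0.5, aij = NULL) {
  stopifnot(kBT > 0, rc > 0, gamma >= 0, s > 0, dt > 0)
  if (is.null(aij)) {
    a0 <- 25 * kBT / rc
    aij <- matrix(a0, 4, 4, dimnames = list(PARTICLE_TYPES, PARTICLE_TYPES))
    aij[c("cell", "nucleus"), c("cell", "nucleus")] <- 2 * a0
  }
  stopifnot(is.matrix(aij), nrow(aij) == 4, ncol(aij) == 4,
            isTRUE(all.equal(aij, t(aij))))
  structure(list(kBT = kBT, rc = rc, gamma = gamma,
                 sigma = sqrt(2 * gamma * kBT), s = s, dt = dt,
                 lambda = lambda, aij = aij),
            class = "dpd_params")
}

PARTICLE_TYPES <- c("fluid", "wall", "cell", "nucleus")

#' A system of DPD particles in a (possibly periodic) box
#'
#' @param positions N x 3 matrix of coordinates.
#' @param velocities N x 3 matrix; defaults to zero.
#' @param types character vector (`fluid`, `wall`, `cell`, `nucleus`),
#'   recycled to N.
#' @param box lengths of the simulation box.
#' @param periodic logical length-3, periodicity per dimension.
#' @param frozen logical; frozen particles never move (walls).  Defaults to
#'   `types == "wall"`.
#' @return an object of class `particle_system`.
#' @export
particle_system <- function(positions, velocities = NULL, types = "fluid",
                            box, periodic = c(TRUE, TRUE, TRUE),
                            frozen = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, all(is.finite(positions)),
            length(box) == 3, all(box > 0), length(periodic) == 3)
  n <- nrow(positions)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  velocities <- as.matrix(velocities)
  stopifnot(nrow(velocities) == n, ncol(velocities) == 3)
  types <- rep_len(types, n)
  stopifnot(all(types %in% PARTICLE_TYPES))
  if (is.null(frozen)) frozen <- types == "wall"
  frozen <- rep_len(frozen, n)
  velocities[frozen, ] <- 0
  structure(list(positions = positions, velocities = velocities,
                 types = types, box = as.numeric(box),
                 periodic = as.logical(periodic), frozen = frozen),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat("<particle_system>", nrow(x$positions), "particles;",
      paste(names(table(x$types)), table(x$types), collapse = ", "), "\n")
  cat("  box:", paste(signif(x$box, 4), collapse = " x "),
      " periodic:", paste(ifelse(x$periodic, "T", "F"), collapse = ""), "\n")
  invisible(x)
}

type_codes <- function(types) match(types, PARTICLE_TYPES) - 1L

#' Soft conservative DPD pair force
#'
#' `a_ij (1 - r/r_c) rhat` for `r < r_c`, zero beyond the cutoff.  The force
#' on the second particle of the pair is the exact negation.
#'
#' @param rij displacement vector `r_i - r_j` (length 3).
#' @param params a [dpd_params()] object.
#' @param types character length-2, the interacting particle types.
#' @return force vector on particle i.
#' @export
conservative_force <- function(rij, params, types = c("fluid", "fluid")) {
  stopifnot(length(rij) == 3, all(is.finite(rij)))
  r <- sqrt(sum(rij^2))
  if (r >= params$rc) return(c(0, 0, 0))
  if (r == 0) {
    warning("overlapping particles (r = 0): conservative force direction undefined")
    return(c(0, 0, 0))
  }
  a <- params$aij[types[1], types[2]]
  a * (1 - r / params$rc) * rij / r
}

#' Dissipative plus random DPD pair force
#'
#' Returns `-gamma w_D(r) (rhat . v_ij) rhat + sigma w_R(r) theta dt^(-1/2) rhat`
#' with `w_R(r) = (1 - r/r_c)^s` and `w_D = w_R^2`; zero beyond the cutoff.
#' `theta` must be a single standard-normal draw shared (symmetrically) by
#' the pair so that the pair force is antisymmetric.
#'
#' @param rij displacement vector `r_i - r_j`.
#' @param vij relative velocity `v_i - v_j`.
#' @param params a [dpd_params()] object.
#' @param theta standard normal noise for this pair and step.
#' @return force vector on particle i.
#' @export
dissipative_random_force <- function(rij, vij, params, theta) {
  stopifnot(length(rij) == 3, length(vij) == 3, length(theta) == 1)
  r <- sqrt(sum(rij^2))
  if (r >= params$rc) return(c(0, 0, 0))
  if (r == 0) {
    warning("overlapping particles (r = 0): pair force direction undefined")
    return(c(0, 0, 0))
  }
  e <- rij / r
  wR <- (1 - r / params$rc)^params$s
  wD <- wR^2
  fD <- -params$gamma * wD * sum(e * vij)
  fR <- params$sigma * wR * theta / sqrt(params$dt)
  (fD + fR) * e
}

#' Neighbor pairs within the DPD cutoff
#'
#' Cell-list search returning exactly the particle pairs whose minimum-image
#' distance is below `rc`.
#'
#' @param system a [particle_system()].
#' @param rc cutoff radius (defaults to the box-compatible value 1).
#' @return two-column integer matrix of 1-based pair indices, `i < j`.
#' @export
build_neighbor_lists <- function(system, rc = 1) {
  cpp_neighbor_pairs(system$positions, system$box, system$periodic, rc)
}

#' Analytic wall descriptors for bounce-back reflection
#'
#' Walls are represented by frozen particles (for DPD no-slip interactions)
#' plus an analytic surface used to reflect any particle that crosses it;
#' the reflected particle is mirrored about the surface and its velocity is
#' negated.
#'
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param lo,hi fluid region is `lo < coord < hi`.
#' @name walls
#' @export
wall_slab <- function(axis = "z", lo, hi) {
  stopifnot(hi > lo)
  list(type = "slab", axis = match(axis, c("x", "y", "z")) - 1L, lo = lo, hi = hi)
}

#' @param xm axial position of the pipette mouth plane.
#' @param rp pipette bore radius.
#' @param yc,zc bore axis position.
#' @param xe axial position of the far face of the pipette solid (through a
#'   periodic wrap this face is the rear wall of the chamber); `Inf` for a
#'   semi-infinite solid.
#' @rdname walls
#' @export
wall_pipette <- function(xm, rp, yc, zc, xe = Inf) {
  stopifnot(rp > 0, xe > xm)
  list(type = "pipette", xm = xm, rp = rp, yc = yc, zc = zc, xe = xe)
}

#' @param triangles matrix with rows `(x1, y1, x2, y2, x3, y3)`: triangular
#'   prisms spanning the channel height.
#' @rdname walls
#' @export
wall_obstacles <- function(triangles) {
  triangles <- as.matrix(triangles)
  stopifnot(ncol(triangles) == 6)
  list(type = "obstacles", triangles = triangles)
}

#' Apply bounce-back wall reflection to a particle system
#'
#' Any particle found inside a wall is mirrored about the nearest wall
#' surface and its velocity is negated; states with no crossing are returned
#' unchanged.  This is the same rule the integrator applies after every
#' position update.
#'
#' @param system a [particle_system()].
#' @param walls list of wall descriptors ([wall_slab()], [wall_pipette()],
#'   [wall_obstacles()]).
#' @return the reflected `particle_system`.
#' @export
bounce_back_walls <- function(system, walls) {
  pos <- system$positions
  vel <- system$velocities
  for (i in seq_len(nrow(pos))) {
    if (system$frozen[i]) next
    p <- pos[i, ]
    hit <- FALSE
    for (w in walls) {
      if (w$type == "slab") {
        ax <- w$axis + 1
        if (p[ax] < w$lo) { p[ax] <- 2 * w$lo - p[ax]; hit <- TRUE }
        if (p[ax] > w$hi) { p[ax] <- 2 * w$hi - p[ax]; hit <- TRUE }
      } else if (w$type == "pipette") {
        rr <- sqrt((p[2] - w$yc)^2 + (p[3] - w$zc)^2)
        phi <- max(w$xm - p[1], w$rp - rr)
        if (phi < 0) {
          if (w$xm - p[1] >= w$rp - rr) {
            p[1] <- 2 * w$xm - p[1]
          } else {
            sc <- (2 * w$rp - rr) / rr
            p[2] <- w$yc + (p[2] - w$yc) * sc
            p[3] <- w$zc + (p[3] - w$zc) * sc
          }
          hit <- TRUE
        }
      }
    }
    if (hit) {
      pos[i, ] <- p
      vel[i, ] <- -vel[i, ]
    }
  }
  system$positions <- pos
  system$velocities <- vel
  system
}

#' Run the DPD integrator
#'
#' Advances a particle system with the modified velocity-Verlet scheme:
#' positions are updated with the current force, velocities are predicted
#' with factor `lambda`, forces are recomputed, and velocities are corrected
#' with the mean of old and new forces.  Membrane elasticity/viscosity,
#' Kelvin-Voigt bonds, analytic walls and scheduled body forces are applied
#' when supplied.  All pairwise forces are equal-and-opposite, so an
#' isolated periodic system conserves linear momentum to floating-point
#' accumulation accuracy.
#'
#' @param system a [particle_system()].
#' @param params a [dpd_params()].
#' @param nsteps number of time steps.
#' @param seed integer seed for the engine's random stream (runs are
#'   bit-reproducible given seed and inputs).
#' @param membranes list of bound membranes (see [membrane()]); indices in
#'   their descriptors refer to rows of `system$positions`.
#' @param kv_bonds data frame with columns `i, j, ks, kv, l0`
#'   (1-based particle indices) or `NULL`.
#' @param walls list of wall descriptors.
#' @param body_force `NULL` or a list with `mode` (`"uniform"` or `"tube"`),
#'   `dir`, schedule vectors `t` and `f` (per-particle force magnitude,
#'   linearly interpolated), and for `"tube"` the region `xa, xb, rp, yc, zc`.
#' @param sample_every measurement stride in steps.
#' @param measure character vector among `"membranes"`, `"lp"`,
#'   `"asphericity"`, `"com"`, `"fluid_velocity"`.
#' @param stop_when_aspirated terminate when the whole cell has passed the
#'   pipette mouth plane (status `"aspirated"`).
#' @param kv_strain_based if `TRUE` (default) the Kelvin-Voigt tension is
#'   strain-based, `T = k_s (l - l0)/l0 + k_v (dl/dt)/l0`; otherwise
#'   extension-based.
#' @return list with the advanced `system`, a `trace` data frame of
#'   measurements, the termination `status`, and `overlap_warnings`.
#' @export
dpd_run <- function(system, params, nsteps, seed,
                    membranes = list(), kv_bonds = NULL, walls = list(),
                    body_force = NULL, sample_every = 10L,
                    measure = character(), stop_when_aspirated = FALSE,
                    kv_strain_based = TRUE) {
  stopifnot(inherits(system, "particle_system"), inherits(params, "dpd_params"))
  dpd <- list(aij = unname(params$aij), rc = params$rc, gamma = params$gamma,
              sigma = params$sigma, s = params$s, kBT = params$kBT,
              dt = params$dt, lambda = params$lambda)
  mems <- lapply(membranes, function(m) m$descriptor)
  if (is.null(kv_bonds) || nrow(kv_bonds) == 0) {
    kvb <- matrix(0, 0, 5)
  } else {
    kvb <- as.matrix(kv_bonds[, c("i", "j", "ks", "kv", "l0")])
  }
  bf <- if (is.null(body_force)) list(mode = "none") else body_force
  ctl <- list(nsteps = as.integer(nsteps), sample_every = as.integer(sample_every),
              seed = as.numeric(seed),
              measure_membranes = "membranes" %in% measure,
              measure_lp = "lp" %in% measure,
              measure_asphericity = "asphericity" %in% measure,
              measure_com = "com" %in% measure,
              measure_fluid_velocity = "fluid_velocity" %in% measure,
              stop_when_aspirated = stop_when_aspirated)
  res <- cpp_run_dpd(system$positions, system$velocities,
                     type_codes(system$types), system$frozen,
                     system$box, system$periodic, dpd, mems,
                     list(bonds = kvb, strain_based = kv_strain_based),
                     walls, bf, ctl)
  out_sys <- system
  out_sys$positions <- res$positions
  out_sys$velocities <- res$velocities
  tr <- res$trace
  mem_cols <- list()
  if (!is.null(tr$area)) {
    for (k in seq_along(tr$area)) {
      mem_cols[[paste0("area_", k)]] <- tr$area[[k]]
      mem_cols[[paste0("volume_", k)]] <- tr$volume[[k]]
    }
    tr$area <- NULL
    tr$volume <- NULL
  }
  trace <- as.data.frame(c(tr, mem_cols))
  list(system = out_sys, trace = trace, status = res$status,
       overlap_warnings = res$overlap_warnings)
}

#' Advance a particle system by a single DPD step
#'
#' Convenience wrapper over [dpd_run()] with `nsteps = 1`.
#'
#' @inheritParams dpd_run
#' @param ... passed to [dpd_run()].
#' @return the advanced [particle_system()].
#' @export
integrate_step <- function(system, params, seed = 1, ...) {
  dpd_run(system, params, nsteps = 1, seed = seed, sample_every = 1L, ...)$system
}

#' Fill a region with fluid particles at a given number density
#'
#' Uniform random placement; used to initialize fluid boxes and frozen wall
#' material.
#'
#' @param n number of particles (or use `density` with `volume`).
#' @param lo,hi box corners.
#' @param density number density; `n` is derived from the box volume.
#' @param keep optional predicate `function(xyz_matrix) -> logical` selecting
#'   which sampled points to keep (rejection sampling).
#' @return matrix of positions.
#' @export
fill_region <- function(lo, hi, density = 3, n = NULL, keep = NULL) {
  vol <- prod(hi - lo)
  if (is.null(n)) n <- max(0L, round(density * vol))
  if (n == 0) return(matrix(0, 0, 3))
  pos <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
  if (!is.null(keep)) pos <- pos[keep(pos), , drop = FALSE]
  pos
}

#' Maxwell-Boltzmann velocities at temperature kBT
#'
#' @param n number of particles.
#' @param kBT thermal energy (mass = 1).
#' @return n x 3 matrix with zero mean per component.
#' @export
thermal_velocities <- function(n, kBT) {
  v <- matrix(rnorm(3 * n, sd = sqrt(kBT)), n, 3)
  if (n > 1) v <- sweep(v, 2, colMeans(v))
  v
}
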