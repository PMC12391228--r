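#' Assemble a complete cell model
#'
#' Builds the two concentric triangulated membranes (outer membrane and
#' nucleus), the cytoskeleton network between them, and the internal nucleus
#' network.  The nuclear-cytoplasmic ratio is interpreted as a volume ratio
#' by default: the nucleus radius is `nc_ratio^(1/3)` times the cell radius,
#' and after meshing the nucleus is rescaled so the meshed volume ratio
#' matches `nc_ratio` exactly.  Both surfaces are meshed at the same target
#' edge length, and the bond density `rho` is independent of the cell
#' diameter, which keeps whole-cell mechanics size-invariant.
#'
#' In the combined particle indexing of the returned model, outer-membrane
#' vertices come first (`1..N_outer`) followed by nucleus vertices.
#'
#' @param diameter cell diameter in micrometres.
#' @param nc_ratio nuclear-cytoplasmic ratio in (0, 1) (default 0.29).
#' @param ks,kv_damp cytoskeleton spring stiffness and damper viscosity
#'   (defaults 120 and 10); the nucleus network stiffness is `5 * ks`.
#' @param topology a [topology_spec()] (default M2, `w = 5`, `rho = 0.8`).
#' @param rho_nucl nucleus-network bond density (default 0.8).
#' @param params_cell,params_nucleus [membrane_params()] for each membrane.
#' @param units a [unit_map()] for the micrometre-to-simulation conversion.
#' @param edge_length target mesh edge length in simulation units (defaults
#'   to the membrane equilibrium bond length `l0`).
#' @param ratio_mode interpret `nc_ratio` as a `"volume"` (default) or
#'   `"diameter"` ratio.
#' @param seed seed for the eligibility clustering.
#' @param center cell center in simulation coordinates.
#' @param thermal include membrane thermal noise during integration.
#' @return object of class `cell_model`.
#' @export
build_cell <- function(diameter, nc_ratio = 0.29, ks = 120, kv_damp = 10,
                       topology = topology_spec(), rho_nucl = topology$rho,
                       params_cell = membrane_params("cell"),
                       params_nucleus = membrane_params("nucleus"),
                       units = unit_map(), edge_length = NULL,
                       ratio_mode = c("volume", "diameter"), seed = 1L,
                       center = c(0, 0, 0), thermal = TRUE) {
  ratio_mode <- match.arg(ratio_mode)
  stopifnot(diameter > 0, nc_ratio > 0, nc_ratio < 1)
  r_cell <- diameter / 2 / units$length_um
  r_nuc <- if (ratio_mode == "volume") r_cell * nc_ratio^(1 / 3) else r_cell * nc_ratio
  el_c <- if (is.null(edge_length)) params_cell$l0 else edge_length
  el_n <- if (is.null(edge_length)) params_nucleus$l0 else edge_length
  if (r_nuc <= 1.5 * el_n)
    stop("nucleus radius (", signif(r_nuc, 3),
         ") too small to mesh at edge length ", el_n)
  if (r_cell - r_nuc < el_c)
    stop("nc_ratio ", nc_ratio, " leaves no space between nucleus and membrane")
  outer <- make_sphere_mesh(r_cell, target_edge_length = el_c, center = center)
  nucleus <- make_sphere_mesh(r_nuc, target_edge_length = el_n, center = center)
  # rescale the nucleus so the meshed volume ratio is exact
  vc <- mesh_geometry(outer)$volume
  vn <- mesh_geometry(nucleus)$volume
  if (ratio_mode == "volume") {
    sc <- (nc_ratio * vc / vn)^(1 / 3)
    nucleus$vertices <- sweep(sweep(nucleus$vertices, 2, center) * sc, 2, center, "+")
    nucleus$l0 <- nucleus$l0 * sc
    nucleus$radius <- nucleus$radius * sc
  }
  n_outer <- outer$n_vertices
  n_nuc <- nucleus$n_vertices
  mem_outer <- membrane(outer, params_cell, thermal = thermal)
  mem_nuc <- membrane(nucleus, params_nucleus, thermal = thermal,
                      index_offset = n_outer)
  cyto <- build_cytoskeleton(outer, nucleus, topology, ks, kv_damp, seed = seed)
  nucnet <- build_nucleus_network(nucleus, rho_nucl, ks_cyt = ks,
                                  kv_damp = kv_damp, seed = seed + 1L,
                                  variant = topology$variant, w = topology$w)
  # combined indexing: outer first, nucleus offset
  cyto_c <- cyto
  cyto_c$j <- cyto$j + n_outer
  nuc_c <- nucnet
  nuc_c$i <- nucnet$i + n_outer
  nuc_c$j <- nucnet$j + n_outer
  structure(list(outer = mem_outer, nucleus = mem_nuc,
                 cytoskeleton = cyto_c, nucleus_bonds = nuc_c,
                 diameter_um = diameter, nc_ratio = nc_ratio,
                 ratio_mode = ratio_mode,
                 ks = ks, kv = kv_damp, ks_nuc = nuc_c$ks[1],
                 rho = topology$rho, rho_nucl = rho_nucl,
                 topology = topology, units = units,
                 n_outer = n_outer, n_nucleus = n_nuc,
                 center = center, radius = r_cell, radius_nucleus = nucleus$radius),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model> %g um diameter, NC ratio %.2f (%s)\n",
              x$diameter_um, x$nc_ratio, x$ratio_mode))
  cat(sprintf("  outer: %d vertices; nucleus: %d vertices\n",
              x$n_outer, x$n_nucleus))
  cat(sprintf("  cytoskeleton: %d KV bonds (%s, rho = %g, ks = %g, kv = %g)\n",
              nrow(x$cytoskeleton), x$topology$variant, x$rho, x$ks, x$kv))
  cat(sprintf("  nucleus network: %d KV bonds (ks = %g = 5 x %g)\n",
              nrow(x$nucleus_bonds), x$ks_nuc, x$ks))
  invisible(x)
}

#' Particle positions of a cell model in combined indexing
#'
#' @param cell a [build_cell()] model.
#' @return matrix of membrane particle positions (outer then nucleus).
#' @export
cell_positions <- function(cell) {
  rbind(cell$outer$mesh$vertices, cell$nucleus$mesh$vertices)
}

#' All Kelvin-Voigt bonds of a cell model (combined indexing)
#'
#' @param cell a [build_cell()] model.
#' @return data frame with `i`, `j`, `ks`, `kv`, `l0`.
#' @export
cell_kv_bonds <- function(cell) {
  rbind(cell$cytoskeleton, cell$nucleus_bonds)
}

#' Types of the cell's membrane particles
#'
#' @param cell a [build_cell()] model.
#' @return character vector (`"cell"` for outer, `"nucleus"` for nucleus).
#' @export
cell_types <- function(cell) {
  c(rep("cell", cell$n_outer), rep("nucleus", cell$n_nucleus))
}

#' Relax a cell model in a quiescent (implicit) medium
#'
#' Integrates the membrane and bond forces with the membrane viscous
#' thermostat only (no explicit fluid), tracking area and volume of both
#' surfaces.  Used to audit constraint quality: a relaxed cell holds `A`
#' and `V` within 1% of the reference values.
#'
#' @param cell a [build_cell()] model.
#' @param nsteps number of time steps.
#' @param dt time step.
#' @param seed engine seed.
#' @param sample_every measurement stride.
#' @param params optional [dpd_params()] override for the pair-interaction
#'   parameters (defaults to membrane-membrane soft repulsion only).
#' @return list with the updated `cell`, the measurement `trace`, and
#'   `status`.
#' @export
relax_cell <- function(cell, nsteps = 20000, dt = 0.005, seed = 1L,
                       sample_every = 200L, params = NULL) {
  pos <- cell_positions(cell)
  n <- nrow(pos)
  pad <- 2 + cell$radius
  box <- c(max(pos[, 1]) - min(pos[, 1]), max(pos[, 2]) - min(pos[, 2]),
           max(pos[, 3]) - min(pos[, 3])) + 2 * pad
  pos0 <- sweep(pos, 2, apply(pos, 2, min) - pad)
  if (is.null(params))
    params <- dpd_params(kBT = cell$outer$params$kBT, dt = dt, gamma = 0)
  params$dt <- dt
  sys <- particle_system(pos0, types = cell_types(cell), box = box,
                         periodic = c(FALSE, FALSE, FALSE))
  res <- dpd_run(sys, params, nsteps = nsteps, seed = seed,
                 membranes = list(cell$outer, cell$nucleus),
                 kv_bonds = cell_kv_bonds(cell),
                 sample_every = sample_every,
                 measure = c("membranes", "asphericity"))
  shift <- apply(pos, 2, min) - pad
  newpos <- sweep(res$system$positions, 2, shift, "+")
  cell$outer$mesh$vertices <- newpos[seq_len(cell$n_outer), , drop = FALSE]
  cell$nucleus$mesh$vertices <- newpos[cell$n_outer + seq_len(cell$n_nucleus), ,
                                       drop = FALSE]
  list(cell = cell, trace = res$trace, status = res$status)
}
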