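#' Write a cell model as a LAMMPS data file
#'
#' Emits atoms, bonds (three types: membrane WLC edges, cytoskeleton
#' Kelvin-Voigt bonds, nucleus Kelvin-Voigt bonds), angles (one per membrane
#' triangle, carrying the area-dependent in-plane term) and dihedrals (one
#' per edge-adjacent triangle pair, carrying the bending term).  For closed
#' surfaces the counts satisfy `angles = 2 V_m - 4 S` and
#' `dihedrals = 3 V_m - 6 S` where `V_m` is the total membrane vertex count
#' and `S` the number of closed surfaces.  The header documents the intended
#' interaction styles; the file targets interchange and auditing.
#'
#' @param cell a [build_cell()] model.
#' @param path output file.
#' @return (invisibly) a list of section counts.
#' @export
write_lammps_data <- function(cell, path) {
  pos <- cell_positions(cell)
  n <- nrow(pos)
  tcode <- ifelse(cell_types(cell) == "cell", 1L, 2L)
  me <- rbind(cell$outer$descriptor$edges, cell$nucleus$descriptor$edges)
  cy <- as.matrix(cell$cytoskeleton[, c("i", "j")])
  nu <- as.matrix(cell$nucleus_bonds[, c("i", "j")])
  bonds <- rbind(cbind(1L, me), cbind(2L, cy), cbind(3L, nu))
  tris <- rbind(cell$outer$descriptor$triangles, cell$nucleus$descriptor$triangles)
  dihs <- rbind(cell$outer$descriptor$dihedrals, cell$nucleus$descriptor$dihedrals)
  pad <- 2
  lo <- apply(pos, 2, min) - pad
  hi <- apply(pos, 2, max) + pad
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("LAMMPS data file (cellflow cell model)")
  w("# intended styles: bond wlc + kelvin-voigt, angle area/in-plane, dihedral bending")
  w("")
  w(n, " atoms")
  w(nrow(bonds), " bonds")
  w(nrow(tris), " angles")
  w(nrow(dihs), " dihedrals")
  w("")
  w("2 atom types")
  w("3 bond types")
  w("1 angle types")
  w("1 dihedral types")
  w("")
  w(sprintf("%.8g %.8g xlo xhi", lo[1], hi[1]))
  w(sprintf("%.8g %.8g ylo yhi", lo[2], hi[2]))
  w(sprintf("%.8g %.8g zlo zhi", lo[3], hi[3]))
  w("")
  w("Masses")
  w("")
  w("1 1.0")
  w("2 1.0")
  w("")
  w("Atoms")
  w("")
  writeLines(sprintf("%d 1 %d %.10g %.10g %.10g", seq_len(n), tcode,
                     pos[, 1], pos[, 2], pos[, 3]), con)
  w("")
  w("Bonds")
  w("")
  writeLines(sprintf("%d %d %d %d", seq_len(nrow(bonds)), bonds[, 1],
                     bonds[, 2], bonds[, 3]), con)
  w("")
  w("Angles")
  w("")
  writeLines(sprintf("%d 1 %d %d %d", seq_len(nrow(tris)), tris[, 1],
                     tris[, 2], tris[, 3]), con)
  w("")
  w("Dihedrals")
  w("")
  writeLines(sprintf("%d 1 %d %d %d %d", seq_len(nrow(dihs)), dihs[, 1],
                     dihs[, 2], dihs[, 3], dihs[, 4]), con)
  invisible(list(atoms = n, bonds = nrow(bonds), angles = nrow(tris),
                 dihedrals = nrow(dihs)))
}

#' Read back a LAMMPS data file written by [write_lammps_data()]
#'
#' @param path file to read.
#' @return list with `atoms` (id, type, x, y, z), `bonds` (type, i, j),
#'   `angles`, `dihedrals`, and the header `counts`.
#' @export
read_lammps_data <- function(path) {
  lines <- readLines(path)
  getcount <- function(tag) {
    ln <- grep(paste0("^[0-9]+ ", tag, "$"), lines, value = TRUE)[1]
    as.integer(strsplit(ln, " ")[[1]][1])
  }
  counts <- list(atoms = getcount("atoms"), bonds = getcount("bonds"),
                 angles = getcount("angles"), dihedrals = getcount("dihedrals"))
  section <- function(name, ncol, nrows) {
    start <- which(lines == name) + 2
    dat <- read.table(text = lines[start:(start + nrows - 1)])
    as.matrix(dat[, seq_len(ncol)])
  }
  at <- section("Atoms", 6, counts$atoms)
  atoms <- data.frame(id = at[, 1], type = at[, 3], x = at[, 4], y = at[, 5],
                      z = at[, 6])
  bd <- section("Bonds", 4, counts$bonds)
  an <- section("Angles", 5, counts$angles)
  dh <- section("Dihedrals", 6, counts$dihedrals)
  list(atoms = atoms,
       bonds = data.frame(type = bd[, 2], i = bd[, 3], j = bd[, 4]),
       angles = an[, 3:5, drop = FALSE],
       dihedrals = dh[, 3:6, drop = FALSE],
       counts = counts)
}

#' Write particle positions as a typed XYZ snapshot
#'
#' @param positions N x 3 matrix.
#' @param types character vector of particle types.
#' @param path output file.
#' @param comment second-line comment.
#' @export
write_xyz <- function(positions, types, path, comment = "cellflow snapshot") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(positions)), comment), con)
  writeLines(sprintf("%s %.8g %.8g %.8g", types, positions[, 1],
                     positions[, 2], positions[, 3]), con)
  invisible(path)
}

#' Write a triangulated surface as legacy ASCII VTK poly-data
#'
#' @param mesh a [trimesh()], or supply `positions` and `triangles`.
#' @param path output file.
#' @param positions,triangles explicit geometry (override `mesh`).
#' @export
write_vtk <- function(mesh = NULL, path, positions = NULL, triangles = NULL) {
  if (!is.null(mesh)) {
    positions <- mesh$vertices
    triangles <- mesh$triangles
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "cellflow surface", "ASCII",
               "DATASET POLYDATA",
               paste("POINTS", nrow(positions), "double")), con)
  writeLines(sprintf("%.8g %.8g %.8g", positions[, 1], positions[, 2],
                     positions[, 3]), con)
  nt <- nrow(triangles)
  writeLines(paste("POLYGONS", nt, 4 * nt), con)
  writeLines(sprintf("3 %d %d %d", triangles[, 1] - 1L, triangles[, 2] - 1L,
                     triangles[, 3] - 1L), con)
  invisible(path)
}

#' Write a measurement trace as tab-separated text
#'
#' Column headers carry unit annotations (e.g. `time[sim]`, `time_s[s]`,
#' `pressure_Pa[Pa]`).
#'
#' @param trace data frame of measurements.
#' @param path output file.
#' @export
write_trace <- function(trace, path) {
  units <- c(time = "sim", time_s = "s", pressure_sim = "sim",
             pressure_Pa = "Pa", Lp = "sim", Ln = "1", kbt_kin = "sim",
             px = "sim", py = "sim", pz = "sim", asphericity = "1",
             com_x = "sim", com_y = "sim", com_z = "sim", fluid_vx = "sim")
  hdr <- vapply(names(trace), function(nm) {
    u <- if (nm %in% names(units)) units[[nm]] else "sim"
    paste0(nm, "[", u, "]")
  }, character(1))
  dat <- trace
  names(dat) <- hdr
  write.table(dat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
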