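#' Closed triangulated surface meshes
#'
#' A `trimesh` stores vertex positions, the triangle list (consistently
#' outward-oriented), the undirected edge list with per-edge rest lengths,
#' and the dihedral list: for every edge the two adjacent triangles as an
#' ordered vertex quadruple `(k, i, j, l)`, meaning triangles `(i, j, k)` and
#' `(j, i, l)` share edge `i-j`.  Every generated mesh is a closed orientable
#' genus-0 surface, so `N_e = 3 (N_v - 2)` and `N_t = 2 (N_v - 2)`.
#'
#' @param vertices N x 3 matrix.
#' @param triangles M x 3 integer matrix of 1-based vertex triples.
#' @param center,radius reference sphere (used by subdivision/smoothing).
#' @return object of class `trimesh` with fields `vertices`, `triangles`,
#'   `edges`, `dihedrals`, `l0`, `n_vertices`, `n_edges`, `n_triangles`.
#' @export
trimesh <- function(vertices, triangles, center = c(0, 0, 0), radius = NA) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  topo <- mesh_topology(triangles)
  l0 <- sqrt(rowSums((vertices[topo$edges[, 1], , drop = FALSE] -
                        vertices[topo$edges[, 2], , drop = FALSE])^2))
  m <- structure(list(vertices = vertices, triangles = triangles,
                      edges = topo$edges, dihedrals = topo$dihedrals, l0 = l0,
                      n_vertices = nrow(vertices), n_edges = nrow(topo$edges),
                      n_triangles = nrow(triangles),
                      center = center, radius = radius),
                 class = "trimesh")
  validate_trimesh(m)
  m
}

#' @export
print.trimesh <- function(x, ...) {
  g <- mesh_geometry(x)
  cat(sprintf("<trimesh> N_v = %d, N_e = %d, N_t = %d; A = %.4g, V = %.4g\n",
              x$n_vertices, x$n_edges, x$n_triangles, g$area, g$volume))
  invisible(x)
}

# edge and dihedral extraction from an oriented triangle list
mesh_topology <- function(triangles) {
  de <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  third <- c(triangles[, 3], triangles[, 1], triangles[, 2])
  lo <- pmin(de[, 1], de[, 2])
  hi <- pmax(de[, 1], de[, 2])
  key <- paste(lo, hi)
  tab <- table(key)
  if (any(tab != 2)) {
    bad <- names(tab)[tab != 2][1]
    stop("mesh is not closed/consistently oriented at edge (", bad, ")")
  }
  ord <- order(key, de[, 1] > de[, 2])
  de <- de[ord, , drop = FALSE]
  third <- third[ord]
  odd <- seq(1, nrow(de), by = 2)
  # first of each pair is the (i<j)-directed copy, second the reverse
  if (any(de[odd, 1] != de[odd + 1, 2]) || any(de[odd, 2] != de[odd + 1, 1]))
    stop("mesh orientation inconsistent: an edge is traversed twice in the same direction")
  edges <- de[odd, , drop = FALSE]
  dihedrals <- cbind(third[odd], de[odd, 1], de[odd, 2], third[odd + 1])
  colnames(edges) <- c("i", "j")
  colnames(dihedrals) <- c("k", "i", "j", "l")
  list(edges = edges, dihedrals = dihedrals)
}

#' Audit a trimesh against the closed-surface identities
#'
#' Checks the Euler identities `N_v - N_e + N_t = 2`, `N_e = 3 (N_v - 2)`,
#' `N_t = 2 (N_v - 2)`, that every edge is shared by exactly two triangles
#' with consistent orientation, and that the enclosed volume is positive.
#'
#' @param mesh a [trimesh()].
#' @param check_volume verify positive enclosed volume (outward orientation).
#' @return the mesh, invisibly; errors describe the offending element.
#' @export
validate_trimesh <- function(mesh, check_volume = TRUE) {
  nv <- mesh$n_vertices; ne <- mesh$n_edges; nt <- mesh$n_triangles
  if (nv - ne + nt != 2 || ne != 3 * (nv - 2) || nt != 2 * (nv - 2))
    stop(sprintf("Euler identities violated: N_v=%d N_e=%d N_t=%d", nv, ne, nt))
  if (check_volume && mesh_geometry(mesh)$volume <= 0)
    stop("mesh has non-positive enclosed volume (inverted orientation?)")
  invisible(mesh)
}

#' Surface area, enclosed volume, and per-triangle areas
#'
#' Area is the sum of triangle areas; volume is the signed divergence-theorem
#' sum, positive for outward-oriented surfaces.
#'
#' @param mesh a [trimesh()].
#' @param positions optional replacement vertex coordinates.
#' @return list with `area`, `volume`, `triangle_areas`.
#' @export
mesh_geometry <- function(mesh, positions = NULL) {
  v <- if (is.null(positions)) mesh$vertices else positions
  t1 <- v[mesh$triangles[, 1], , drop = FALSE]
  t2 <- v[mesh$triangles[, 2], , drop = FALSE]
  t3 <- v[mesh$triangles[, 3], , drop = FALSE]
  u <- t2 - t1
  w <- t3 - t1
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  areas <- 0.5 * sqrt(rowSums(cr^2))
  vol <- sum(t1[, 1] * (t2[, 2] * t3[, 3] - t2[, 3] * t3[, 2]) -
             t1[, 2] * (t2[, 1] * t3[, 3] - t2[, 3] * t3[, 1]) +
             t1[, 3] * (t2[, 1] * t3[, 2] - t2[, 2] * t3[, 1])) / 6
  list(area = sum(areas), volume = vol, triangle_areas = areas)
}

# regular icosahedron scaled to `radius`, outward-oriented
icosahedron <- function(radius = 1, center = c(0, 0, 0)) {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
             c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
             c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  v <- v / sqrt(1 + p^2) * radius
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  # enforce outward orientation (convex, centered at origin)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
    n <- crossp(b - a, cc - a)
    if (sum(n * (a + b + cc)) < 0) f[i, ] <- f[i, c(1, 3, 2)]
  }
  v <- sweep(v, 2, center, "+")
  trimesh(v, f, center = center, radius = radius)
}

crossp <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Midpoint (one-to-four) subdivision of a sphere mesh
#'
#' Each triangle is split into four; new vertices are projected onto the
#' reference sphere.  The triangle count is multiplied exactly by four.
#'
#' @param mesh a [trimesh()] with sphere reference (`center`, `radius`).
#' @return the refined [trimesh()].
#' @export
subdivide_mesh <- function(mesh) {
  v <- mesh$vertices
  tri <- mesh$triangles
  nv <- nrow(v)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ek <- key(mesh$edges[, 1], mesh$edges[, 2])
  mid_id <- setNames(nv + seq_along(ek), ek)
  mids <- (v[mesh$edges[, 1], , drop = FALSE] + v[mesh$edges[, 2], , drop = FALSE]) / 2
  if (!is.na(mesh$radius)) {
    d <- sweep(mids, 2, mesh$center)
    mids <- sweep(d / sqrt(rowSums(d^2)) * mesh$radius, 2, mesh$center, "+")
  }
  m12 <- mid_id[key(tri[, 1], tri[, 2])]
  m23 <- mid_id[key(tri[, 2], tri[, 3])]
  m31 <- mid_id[key(tri[, 3], tri[, 1])]
  newtri <- rbind(cbind(tri[, 1], m12, m31), cbind(tri[, 2], m23, m12),
                  cbind(tri[, 3], m31, m23), cbind(m12, m23, m31))
  trimesh(rbind(v, mids), newtri, center = mesh$center, radius = mesh$radius)
}

# split `nsplit` longest edges (in adjacency-disjoint batches), projecting new
# vertices to the reference sphere; preserves closedness and orientation
split_longest_edges <- function(vertices, triangles, nsplit, center, radius) {
  while (nsplit > 0) {
    topo <- mesh_topology(triangles)
    ed <- topo$edges
    dih <- topo$dihedrals
    len <- sqrt(rowSums((vertices[ed[, 1], , drop = FALSE] -
                           vertices[ed[, 2], , drop = FALSE])^2))
    ord <- order(-len)
    # map triangles to ids for adjacency-disjoint selection
    tri_key <- apply(triangles, 1, function(r) paste(sort(r), collapse = "_"))
    tri_id <- setNames(seq_along(tri_key), tri_key)
    used_tri <- logical(nrow(triangles))
    chosen <- integer(0)
    for (e in ord) {
      k <- dih[e, 1]; i <- dih[e, 2]; j <- dih[e, 3]; l <- dih[e, 4]
      t1 <- tri_id[paste(sort(c(i, j, k)), collapse = "_")]
      t2 <- tri_id[paste(sort(c(j, i, l)), collapse = "_")]
      if (used_tri[t1] || used_tri[t2]) next
      used_tri[c(t1, t2)] <- TRUE
      chosen <- c(chosen, e)
      if (length(chosen) >= nsplit) break
    }
    drop_tri <- integer(0)
    add_tri <- matrix(0L, 0, 3)
    for (e in chosen) {
      k <- dih[e, 1]; i <- dih[e, 2]; j <- dih[e, 3]; l <- dih[e, 4]
      w <- (vertices[i, ] + vertices[j, ]) / 2
      if (!is.na(radius)) {
        d <- w - center
        w <- center + d / sqrt(sum(d^2)) * radius
      }
      vertices <- rbind(vertices, w)
      wi <- nrow(vertices)
      t1 <- tri_id[paste(sort(c(i, j, k)), collapse = "_")]
      t2 <- tri_id[paste(sort(c(j, i, l)), collapse = "_")]
      drop_tri <- c(drop_tri, t1, t2)
      add_tri <- rbind(add_tri, c(i, wi, k), c(wi, j, k), c(j, wi, l), c(wi, i, l))
    }
    triangles <- rbind(triangles[-drop_tri, , drop = FALSE], add_tri)
    nsplit <- nsplit - length(chosen)
  }
  list(vertices = vertices, triangles = triangles)
}

# damped tangential Laplacian smoothing with projection to the reference
# sphere; full (undamped) steps destabilize very coarse irregular meshes
smooth_sphere_mesh <- function(vertices, triangles, center, radius, iters,
                               damping = 0.5) {
  if (iters <= 0) return(vertices)
  topo <- mesh_topology(triangles)
  ii <- c(topo$edges[, 1], topo$edges[, 2])
  jj <- c(topo$edges[, 2], topo$edges[, 1])
  deg <- tabulate(ii, nbins = nrow(vertices))
  for (it in seq_len(iters)) {
    s <- rowsum(vertices[jj, , drop = FALSE], ii, reorder = TRUE)
    vertices <- (1 - damping) * vertices + damping * s / deg
    d <- sweep(vertices, 2, center)
    vertices <- sweep(d / sqrt(rowSums(d^2)) * radius, 2, center, "+")
  }
  vertices
}

#' Generate a closed triangulated sphere mesh
#'
#' Builds an icosphere (subdivided icosahedron projected to the sphere) and,
#' when an exact vertex count is requested that no subdivision level matches,
#' splits the longest edges in adjacency-disjoint batches followed by
#' tangential smoothing, so any `n_vertices >= 12` is reachable while all
#' closed-surface invariants hold.  The per-edge rest length `l0` is the
#' constructed edge length.
#'
#' @param radius sphere radius (> 0).
#' @param target_edge_length desired mean edge length (< radius); the vertex
#'   count is derived from the sphere area assuming near-equilateral
#'   triangles.
#' @param n_vertices exact vertex count (overrides `target_edge_length`).
#' @param center sphere center.
#' @param max_vertices safety cap on the resolution.
#' @param smooth_iters tangential smoothing iterations applied when edge
#'   splits were needed.
#' @return a [trimesh()].
#' @export
make_sphere_mesh <- function(radius, target_edge_length = NULL, n_vertices = NULL,
                             center = c(0, 0, 0), max_vertices = 200000L,
                             smooth_iters = 10L) {
  stopifnot(radius > 0)
  if (is.null(n_vertices)) {
    if (is.null(target_edge_length))
      stop("supply either target_edge_length or n_vertices")
    stopifnot(target_edge_length > 0, target_edge_length < radius)
    nt <- 4 * pi * radius^2 / (sqrt(3) / 4 * target_edge_length^2)
    n_vertices <- max(12L, as.integer(round(nt / 2 + 2)))
  }
  if (n_vertices < 12) stop("a closed triangulated sphere needs at least 12 vertices")
  if (n_vertices > max_vertices)
    stop("requested resolution (", n_vertices, " vertices) exceeds max_vertices")
  level <- 0L
  while (10 * 4^(level + 1) + 2 <= n_vertices) level <- level + 1L
  m <- icosahedron(radius, center)
  for (i in seq_len(level)) m <- subdivide_mesh(m)
  extra <- n_vertices - m$n_vertices
  if (extra > 0) {
    sp <- split_longest_edges(m$vertices, m$triangles, extra, center, radius)
    vv <- smooth_sphere_mesh(sp$vertices, sp$triangles, center, radius, smooth_iters)
    m <- trimesh(vv, sp$triangles, center = center, radius = radius)
  }
  m
}
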