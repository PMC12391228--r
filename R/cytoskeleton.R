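#' Cytoskeleton topology specification
#'
#' Wiring scheme of the Kelvin-Voigt bond network between the outer and
#' nucleus membranes.  `M1` connects each eligible outer-membrane vertex to
#' its single nearest eligible nucleus vertex; `M2` connects each eligible
#' outer vertex to its `w` closest eligible nucleus vertices, which
#' distributes stress more uniformly and removes the chain-propagation
#' artifact of `M1`.  The bond density `rho` (bonds per outer-membrane
#' particle) makes network mechanics independent of mesh resolution and cell
#' size.
#'
#' @param variant `"M1"` or `"M2"`.
#' @param w connectivity width (M2 only; default 5).
#' @param rho bond density (default 0.8).
#' @return object of class `topology_spec`.
#' @export
topology_spec <- function(variant = c("M2", "M1"), w = 5L, rho = 0.8) {
  variant <- match.arg(variant)
  w <- as.integer(w)
  stopifnot(rho > 0, w >= 1)
  if (variant == "M1") w <- 1L
  structure(list(variant = variant, w = w, rho = rho), class = "topology_spec")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Select membrane vertices eligible for bonding
#'
#' Runs k-means clustering on the vertex coordinates and keeps, per cluster,
#' the vertex nearest the cluster centroid.  This restricts bonding to a
#' near-uniform subset of membrane particles.  Deterministic given `seed`;
#' if the clustering degenerates it is re-seeded internally (with a message).
#'
#' @param mesh a [trimesh()].
#' @param n_clusters number of clusters, `1 <= n_clusters <= N_v`.
#' @param seed integer seed.
#' @return sorted integer vector of eligible vertex indices.
#' @export
select_eligible <- function(mesh, n_clusters, seed = 1L) {
  nv <- mesh$n_vertices
  stopifnot(n_clusters >= 1, n_clusters <= nv)
  if (n_clusters == nv) return(seq_len(nv))
  v <- mesh$vertices
  km <- NULL
  for (attempt in 0:4) {
    km <- with_seed(seed + attempt, tryCatch(
      kmeans(v, centers = n_clusters, iter.max = 100, nstart = 3),
      error = function(e) NULL))
    if (!is.null(km) && length(unique(km$cluster)) == n_clusters) break
    message("select_eligible: k-means degenerated, re-seeding (attempt ",
            attempt + 1, ")")
    km <- NULL
  }
  if (is.null(km)) stop("k-means clustering failed after re-seeding")
  eligible <- integer(n_clusters)
  for (k in seq_len(n_clusters)) {
    idx <- which(km$cluster == k)
    d2 <- rowSums((v[idx, , drop = FALSE] -
                     matrix(km$centers[k, ], length(idx), 3, byrow = TRUE))^2)
    eligible[k] <- idx[which.min(d2)]  # ties: lowest index via which.min
  }
  sort(eligible)
}

# row-wise squared distances between two point sets
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
}

#' Build the cytoskeleton Kelvin-Voigt bond network
#'
#' Connects eligible outer-membrane vertices to eligible nucleus vertices
#' per the topology spec.  The number of eligible outer vertices is chosen
#' so the total bond count equals `round(rho * N_outer)` exactly (for M2 the
#' last eligible vertex keeps fewer than `w` partners when needed).  The
#' equilibrium length of every bond is its construction-time distance.
#'
#' @param outer,nucleus concentric [trimesh()] surfaces.
#' @param spec a [topology_spec()].
#' @param ks spring stiffness of each bond.
#' @param kv_damp damper viscosity of each bond.
#' @param seed seed for the k-means eligibility selection.
#' @param nucleus_clusters number of eligible nucleus vertices (default per
#'   the topology: outer clusters for M1, `outer clusters * w` capped at the
#'   nucleus vertex count for M2).
#' @return data frame of bonds with columns `i` (outer vertex), `j` (nucleus
#'   vertex, local index), `ks`, `kv`, `l0`.
#' @export
build_cytoskeleton <- function(outer, nucleus, spec, ks, kv_damp, seed = 1L,
                               nucleus_clusters = NULL) {
  stopifnot(inherits(spec, "topology_spec"), ks >= 0, kv_damp >= 0)
  n_outer <- outer$n_vertices
  target <- round(spec$rho * n_outer)
  n_el_out <- as.integer(ceiling(target / spec$w))
  if (n_el_out > n_outer)
    stop("requested bond count ", target, " exceeds w * N_outer (rho > w)")
  if (is.null(nucleus_clusters))
    nucleus_clusters <- min(n_el_out * spec$w, nucleus$n_vertices)
  # each eligible outer vertex needs w distinct nucleus partners; different
  # outer vertices may share nucleus partners (pairs stay unique)
  if (spec$w > nucleus_clusters)
    stop("requested connectivity width w = ", spec$w,
         " exceeds the eligible nucleus vertex count (", nucleus_clusters, ")")
  el_out <- select_eligible(outer, n_el_out, seed)
  el_nuc <- select_eligible(nucleus, nucleus_clusters, seed + 1000L)
  d2 <- cross_dist2(outer$vertices[el_out, , drop = FALSE],
                    nucleus$vertices[el_nuc, , drop = FALSE])
  bonds <- vector("list", length(el_out))
  left <- target
  for (q in seq_along(el_out)) {
    take <- min(spec$w, left)
    if (take == 0) break
    ord <- order(d2[q, ], el_nuc)  # nearest first, ties by lowest index
    part <- el_nuc[ord[seq_len(take)]]
    bonds[[q]] <- cbind(i = el_out[q], j = part)
    left <- left - take
  }
  b <- do.call(rbind, bonds)
  b <- unique(b)
  l0 <- sqrt(rowSums((outer$vertices[b[, 1], , drop = FALSE] -
                        nucleus$vertices[b[, 2], , drop = FALSE])^2))
  out <- data.frame(i = b[, 1], j = b[, 2], ks = ks, kv = kv_damp, l0 = l0)
  attr(out, "spec") <- spec
  attr(out, "target") <- target
  out
}

# per-point k most distant partners within one point set
farthest_partners <- function(points, k = 1) {
  d2 <- cross_dist2(points, points)
  ord <- apply(d2, 1, function(r) order(-r, seq_along(r))[seq_len(k)])
  if (k == 1) matrix(ord, ncol = 1) else t(ord)
}

#' Build the internal nucleus Kelvin-Voigt network
#'
#' Same construction as the cytoskeleton but within the nucleus membrane:
#' since bonded particles belong to the same surface, each eligible vertex
#' is linked to its most distant eligible partners (spanning the nucleus
#' interior) rather than the closest ones.  The nucleus is about five times
#' stiffer than the cytoskeleton, so `ks_nuc = 5 * ks_cyt` is enforced at
#' build time; damper viscosities are shared (`kv_nuc = kv_cyt`).
#'
#' @param nucleus a [trimesh()].
#' @param rho_nucl bond density (bonds per nucleus-membrane particle).
#' @param ks_cyt cytoskeleton spring stiffness; the nucleus network uses
#'   `5 * ks_cyt`.
#' @param kv_damp damper viscosity.
#' @param seed seed for eligibility selection.
#' @param variant,w topology variant mirrored from the cytoskeleton
#'   (`"M2"`, `w = 5` by default).
#' @return data frame of bonds (`i`, `j` nucleus vertex indices, `ks`, `kv`,
#'   `l0`), with `ks = 5 * ks_cyt`.
#' @export
build_nucleus_network <- function(nucleus, rho_nucl = 0.8, ks_cyt = 120,
                                  kv_damp = 10, seed = 1L,
                                  variant = c("M2", "M1"), w = 5L) {
  variant <- match.arg(variant)
  if (variant == "M1") w <- 1L
  stopifnot(rho_nucl > 0)
  ks_nuc <- 5 * ks_cyt
  nv <- nucleus$n_vertices
  target <- round(rho_nucl * nv)
  n_el <- min(nv, as.integer(ceiling(target / w)) * 2L)  # headroom for dedup
  el <- select_eligible(nucleus, n_el, seed)
  pts <- nucleus$vertices[el, , drop = FALSE]
  maxk <- min(length(el) - 1L, max(w * 2L, 8L))
  part <- farthest_partners(pts, maxk)
  seen <- new.env(hash = TRUE)
  ii <- integer(0); jj <- integer(0)
  for (round in seq_len(maxk)) {
    for (q in seq_along(el)) {
      if (length(ii) >= target) break
      a <- el[q]; b <- el[part[q, round]]
      key <- paste(min(a, b), max(a, b))
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      ii <- c(ii, a); jj <- c(jj, b)
    }
    if (length(ii) >= target) break
  }
  if (length(ii) < target)
    stop("could not reach nucleus bond target ", target, " without duplicates")
  l0 <- sqrt(rowSums((nucleus$vertices[ii, , drop = FALSE] -
                        nucleus$vertices[jj, , drop = FALSE])^2))
  data.frame(i = ii, j = jj, ks = ks_nuc, kv = kv_damp, l0 = l0)
}

#' Kelvin-Voigt bond force
#'
#' The bond is a spring and damper in parallel sharing the strain
#' `eps = (l - l0) / l0`, so the total tension is
#' `T = ks eps + kv deps/dt = ks (l - l0)/l0 + kv (dl/dt)/l0` with
#' `dl/dt = rhat . (v_i - v_j)`.  The strain-based form makes the bond's
#' mechanical response independent of its rest length, hence of cell size;
#' an extension-based variant (`T = ks (l - l0) + kv dl/dt`) is available.
#'
#' @param bond list or one-row data frame with `ks`, `kv`, `l0`.
#' @param ri,rj,vi,vj positions and velocities of the bonded pair.
#' @param strain_based use the strain form (default) or the extension form.
#' @return list with `fi`, `fj = -fi`, and the scalar `tension`.
#' @export
kv_bond_force <- function(bond, ri, rj, vi, vj, strain_based = TRUE) {
  d <- ri - rj
  l <- sqrt(sum(d^2))
  if (l == 0) stop("coincident bonded particles: KV bond force undefined")
  e <- d / l
  ldot <- sum(e * (vi - vj))
  tension <- if (strain_based) {
    bond$ks * (l - bond$l0) / bond$l0 + bond$kv * ldot / bond$l0
  } else {
    bond$ks * (l - bond$l0) + bond$kv * ldot
  }
  list(fi = -tension * e, fj = tension * e, tension = tension)
}

#' Creep of a single Kelvin-Voigt bond under constant tension
#'
#' Integrates the overdamped bond dynamics: at each instant the applied
#' tension balances the bond tension, so the damper rate is
#' `deps/dt = (sigma - ks * eps) / kv` where the elastic part is evaluated
#' through [kv_bond_force()].  Fourth-order Runge-Kutta in strain.
#'
#' @param ks,kv,l0 bond parameters.
#' @param sigma applied constant tension (stress units of the bond law).
#' @param t_end,dt integration horizon and step.
#' @param strain_based bond-law variant, as in [kv_bond_force()].
#' @return data frame with `time` and `strain`.
#' @export
kv_creep <- function(ks, kv, l0, sigma, t_end, dt = NULL, strain_based = TRUE) {
  stopifnot(ks > 0, kv > 0, l0 > 0)
  tau <- kv / ks
  if (is.null(dt)) dt <- tau / 200
  elastic_tension <- function(eps) {
    l <- l0 * (1 + eps)
    kv_bond_force(list(ks = ks, kv = kv, l0 = l0),
                  ri = c(l, 0, 0), rj = c(0, 0, 0),
                  vi = c(0, 0, 0), vj = c(0, 0, 0),
                  strain_based = strain_based)$tension
  }
  # strain form: sigma = ks eps + kv deps/dt; extension form picks up an l0
  denom <- if (strain_based) kv else kv * l0
  rate <- function(eps) (sigma - elastic_tension(eps)) / denom
  nt <- ceiling(t_end / dt)
  eps <- numeric(nt + 1)
  for (s in seq_len(nt)) {
    e0 <- eps[s]
    k1 <- rate(e0)
    k2 <- rate(e0 + dt / 2 * k1)
    k3 <- rate(e0 + dt / 2 * k2)
    k4 <- rate(e0 + dt * k3)
    eps[s + 1] <- e0 + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  data.frame(time = seq(0, nt) * dt, strain = eps)
}

#' Straightest stress-propagation chain through the cytoskeleton
#'
#' Diagnostic for the M1 wiring artifact: searches all three-bond chains
#' outer vertex -> nucleus vertex -> (internal nucleus bond) -> nucleus
#' vertex -> outer vertex and reports the maximum straightness, defined as
#' net displacement over path length.  Chains close to 1 connect opposite
#' sides of the cell almost linearly, so stress applied on one side
#' propagates directly to the other (the aspiration artifact of M1); the
#' M2 wiring lowers this.
#'
#' @param cyto cytoskeleton bond data frame (from [build_cytoskeleton()]).
#' @param nuc nucleus bond data frame (from [build_nucleus_network()]).
#' @param outer,nucleus the two meshes.
#' @return maximum chain straightness in (0, 1], or `NA` if no chain exists.
#' @export
cytoskeleton_chains <- function(cyto, nuc, outer, nucleus) {
  # nucleus vertex -> outer vertices bonded to it
  by_nuc <- split(cyto$i, cyto$j)
  best <- NA_real_
  for (q in seq_len(nrow(nuc))) {
    a <- nuc$i[q]; b <- nuc$j[q]
    outs_a <- by_nuc[[as.character(a)]]
    outs_b <- by_nuc[[as.character(b)]]
    if (is.null(outs_a) || is.null(outs_b)) next
    pa <- nucleus$vertices[a, ]; pb <- nucleus$vertices[b, ]
    for (oa in outs_a) for (ob in outs_b) {
      va <- outer$vertices[oa, ]; vb <- outer$vertices[ob, ]
      plen <- sqrt(sum((va - pa)^2)) + sqrt(sum((pa - pb)^2)) +
        sqrt(sum((pb - vb)^2))
      disp <- sqrt(sum((va - vb)^2))
      s <- disp / plen
      if (is.na(best) || s > best) best <- s
    }
  }
  best
}
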