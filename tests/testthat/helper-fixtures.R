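# shared small fixtures, built in code

zero_aij <- function() {
  matrix(0, 4, 4, dimnames = list(c("fluid", "wall", "cell", "nucleus"),
                                  c("fluid", "wall", "cell", "nucleus")))
}

# a small perturbed sphere membrane for gradient checks
perturbed_membrane <- function(n_vertices = 42, radius = 1.5, sd = 0.01,
                               seed = 1, kBT = 0.02) {
  set.seed(seed)
  m <- make_sphere_mesh(radius, n_vertices = n_vertices)
  mem <- membrane(m, membrane_params("cell", kBT = kBT))
  pos <- m$vertices + matrix(rnorm(length(m$vertices), sd = sd), ncol = 3)
  list(mem = mem, pos = pos)
}

# central finite differences of an energy functional
fd_gradient <- function(efun, pos, h = 1e-5) {
  g <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) {
    for (d in 1:3) {
      pp <- pos; pp[i, d] <- pp[i, d] + h
      pm <- pos; pm[i, d] <- pm[i, d] - h
      g[i, d] <- -(efun(pp) - efun(pm)) / (2 * h)
    }
  }
  g
}

# brute-force O(N^2) minimum-image neighbor search
brute_pairs <- function(pos, box, periodic, rc) {
  n <- nrow(pos)
  out <- NULL
  for (i in seq_len(n - 1)) {
    d <- sweep(pos[(i + 1):n, , drop = FALSE], 2, pos[i, ])
    for (k in 1:3) if (periodic[k]) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    hits <- which(rowSums(d^2) < rc^2)
    if (length(hits)) out <- rbind(out, cbind(i, i + hits))
  }
  if (is.null(out)) matrix(0L, 0, 2) else out
}

small_cell <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_cell(diameter = 4, seed = 1)
    cache
  }
})
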