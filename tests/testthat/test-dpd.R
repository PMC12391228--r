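test_that("conservative force has the linear soft-repulsion form with a sharp cutoff", {
  p <- dpd_params(kBT = 0.02)
  a <- p$aij["fluid", "fluid"]
  # at the cutoff boundary the force is exactly zero
  expect_equal(conservative_force(c(p$rc, 0, 0), p), c(0, 0, 0))
  expect_equal(conservative_force(c(0, 1.7 * p$rc, 0), p), c(0, 0, 0))
  # at half the cutoff the magnitude is a/2, along the unit separation
  aij <- zero_aij(); aij[] <- 25
  p25 <- dpd_params(kBT = 0.02, aij = aij)
  f <- conservative_force(c(0.5, 0, 0), p25)
  expect_equal(f, c(12.5, 0, 0))
  # overlapping particles: direction undefined -> zero force with a warning
  expect_warning(f0 <- conservative_force(c(0, 0, 0), p), "overlap")
  expect_equal(f0, c(0, 0, 0))
})

test_that("pairwise forces are antisymmetric so closed systems sum to zero force", {
  set.seed(11)
  p <- dpd_params(kBT = 0.02)
  tot <- c(0, 0, 0)
  for (k in 1:50) {
    rij <- rnorm(3) * 0.4
    vij <- rnorm(3)
    th <- rnorm(1)
    f_ij <- conservative_force(rij, p) + dissipative_random_force(rij, vij, p, th)
    f_ji <- conservative_force(-rij, p) + dissipative_random_force(-rij, -vij, p, th)
    expect_equal(f_ij, -f_ji, tolerance = 1e-12)
    tot <- tot + f_ij + f_ji
  }
  expect_equal(tot, c(0, 0, 0), tolerance = 1e-12)
})

test_that("dissipative weight matches the generalized weighting function", {
  p <- dpd_params(kBT = 0.02, gamma = 4.5, s = 0.75, dt = 0.01)
  # w_D(r_c/2) = ((1 - 1/2)^0.75)^2 = 0.5^1.5
  vij <- c(-1, 0, 0)  # approaching along x
  f <- dissipative_random_force(c(0.5, 0, 0), vij, p, theta = 0)
  expect_equal(f[1], -p$gamma * 0.5^1.5 * (-1), tolerance = 1e-12)
  expect_equal(0.5^1.5, 0.35355, tolerance = 1e-4)
  # zero relative velocity and zero noise -> zero force
  expect_equal(dissipative_random_force(c(0.5, 0.2, 0), c(0, 0, 0), p, 0),
               c(0, 0, 0))
  # fluctuation-dissipation relation is enforced at construction
  expect_equal(p$sigma^2, 2 * p$gamma * p$kBT)
})

test_that("neighbor lists reproduce the brute-force minimum-image pair set", {
  # trivial geometries
  box <- c(6, 6, 6)
  s2 <- particle_system(rbind(c(1, 1, 1), c(2.5, 1, 1)), box = box)
  expect_equal(nrow(build_neighbor_lists(s2, rc = 1)), 0)
  # collinear triple spaced rc/2: the end pair sits exactly at the cutoff,
  # which is excluded (interactions act strictly below r_c)
  s3 <- particle_system(rbind(c(1, 1, 1), c(1.5, 1, 1), c(2, 1, 1)), box = box)
  pr <- build_neighbor_lists(s3, rc = 1)
  expect_equal(nrow(pr), 2)
  expect_true(all(apply(pr, 1, paste, collapse = "-") %in% c("1-2", "2-3")))
  # pulling the ends inside the cutoff adds the third pair
  s4 <- particle_system(rbind(c(1, 1, 1), c(1.45, 1, 1), c(1.9, 1, 1)), box = box)
  expect_equal(nrow(build_neighbor_lists(s4, rc = 1)), 3)
  # random 500-particle box vs O(N^2) oracle
  set.seed(21)
  pos <- fill_region(c(0, 0, 0), box, n = 500)
  sys <- particle_system(pos, box = box)
  got <- build_neighbor_lists(sys, rc = 1)
  want <- brute_pairs(pos, box, c(TRUE, TRUE, TRUE), 1)
  key <- function(m) sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
  expect_identical(key(got), key(want))
  # a periodic box thinner than the cutoff support is rejected
  thin <- particle_system(pos, box = c(2.5, 6, 6))
  expect_error(build_neighbor_lists(thin, rc = 1), "smaller than")
})

test_that("collinear triple yields exactly the two short pairs when the ends are separated", {
  s <- particle_system(rbind(c(1, 3, 3), c(1.6, 3, 3), c(2.2, 3, 3)),
                       box = c(6, 6, 6))
  pr <- build_neighbor_lists(s, rc = 1)
  expect_equal(nrow(pr), 2)
  expect_true(all(apply(pr, 1, paste, collapse = "-") %in% c("1-2", "2-3")))
})

test_that("free streaming advances positions by v dt with no forces", {
  p <- dpd_params(kBT = 0.02, gamma = 0, dt = 0.01, aij = zero_aij())
  v <- matrix(rep(c(0.2, -0.1, 0.05), each = 3), 3, 3)
  sys <- particle_system(matrix(1:9 / 2, 3, 3), velocities = v, box = c(8, 8, 8))
  out <- dpd_run(sys, p, nsteps = 200, seed = 1)
  expect_equal(out$system$positions, sys$positions + 200 * p$dt * v,
               tolerance = 1e-12)
})

test_that("frozen particles never move", {
  p <- dpd_params(kBT = 0.02, dt = 0.01)
  pos <- rbind(c(2, 2, 2), c(2.4, 2, 2), c(3, 3, 3))
  sys <- particle_system(pos, types = c("wall", "fluid", "fluid"),
                         box = c(6, 6, 6))
  out <- dpd_run(sys, p, nsteps = 500, seed = 4)
  expect_identical(out$system$positions[1, ], pos[1, ])
  expect_identical(out$system$velocities[1, ], c(0, 0, 0))
})

test_that("total momentum of an isolated periodic fluid is conserved to accumulation accuracy", {
  set.seed(31)
  n <- 250
  box <- c(5, 5, 5)
  p <- dpd_params(kBT = 0.02, dt = 0.01)
  sys <- particle_system(fill_region(c(0, 0, 0), box, n = n),
                         velocities = thermal_velocities(n, 0.02), box = box)
  out <- dpd_run(sys, p, nsteps = 10000, seed = 7, sample_every = 1000)
  drift <- max(abs(c(tail(out$trace$px, 1), tail(out$trace$py, 1),
                     tail(out$trace$pz, 1))))
  expect_lt(drift / n, 1e-8)
})

test_that("an interacting pair follows an independent small-step reference integration", {
  # conservative force only; reference: classic velocity-Verlet at dt/50
  aij <- zero_aij(); aij[] <- 25
  p <- dpd_params(kBT = 0.02, gamma = 0, dt = 0.01, aij = aij)
  r1 <- c(4.0, 4, 4); r2 <- c(4.6, 4, 4)
  v1 <- c(0.05, 0.02, 0); v2 <- c(-0.05, 0, 0.01)
  sys <- particle_system(rbind(r1, r2), velocities = rbind(v1, v2),
                         box = c(8, 8, 8))
  out <- dpd_run(sys, p, nsteps = 100, seed = 1)
  # reference integrator (independent implementation)
  fpair <- function(ra, rb) {
    d <- ra - rb; r <- sqrt(sum(d^2))
    if (r >= 1) return(c(0, 0, 0))
    25 * (1 - r) * d / r
  }
  h <- p$dt / 50
  ra <- r1; rb <- r2; va <- v1; vb <- v2
  fa <- fpair(ra, rb); fb <- -fa
  for (s in seq_len(100 * 50)) {
    va2 <- va + h / 2 * fa; vb2 <- vb + h / 2 * fb
    ra <- ra + h * va2; rb <- rb + h * vb2
    fa <- fpair(ra, rb); fb <- -fa
    va <- va2 + h / 2 * fa; vb <- vb2 + h / 2 * fb
  }
  expect_equal(out$system$positions[1, ], ra, tolerance = 0.01)
  expect_equal(out$system$positions[2, ], rb, tolerance = 0.01)
})

test_that("bounce-back reflection mirrors position and negates velocity", {
  walls <- list(wall_slab("x", 0, 5))
  sys <- particle_system(rbind(c(5.3, 1, 1), c(2, 2, 2)),
                         velocities = rbind(c(0.7, 0, 0), c(0.1, 0, 0)),
                         box = c(6, 6, 6), periodic = c(FALSE, TRUE, TRUE))
  out <- bounce_back_walls(sys, walls)
  expect_equal(out$positions[1, ], c(4.7, 1, 1))
  expect_equal(out$velocities[1, ], c(-0.7, 0, 0))
  # no crossing: state unchanged
  expect_equal(out$positions[2, ], c(2, 2, 2))
  expect_equal(out$velocities[2, ], c(0.1, 0, 0))
})

test_that("body-driven flow between bounce-back plates vanishes at the walls", {
  set.seed(41)
  box <- c(6, 6, 7)
  z0 <- 1; z1 <- 6
  fluid <- fill_region(c(0, 0, z0), c(6, 6, z1), density = 3)
  wallp <- rbind(fill_region(c(0, 0, 0), c(6, 6, z0), density = 3),
                 fill_region(c(0, 0, z1), c(6, 6, 7), density = 3))
  sys <- particle_system(rbind(fluid, wallp),
                         types = c(rep("fluid", nrow(fluid)),
                                   rep("wall", nrow(wallp))), box = box)
  p <- dpd_params(kBT = 0.02, dt = 0.01)
  bf <- list(mode = "uniform", dir = c(1, 0, 0), t = c(0, 1), f = c(0.05, 0.05))
  out <- dpd_run(sys, p, nsteps = 6000, seed = 9,
                 walls = list(wall_slab("z", z0, z1)), body_force = bf)
  fl <- out$system$positions[seq_len(nrow(fluid)), 3]
  vx <- out$system$velocities[seq_len(nrow(fluid)), 1]
  near_wall <- fl < z0 + 0.5 | fl > z1 - 0.5
  center <- fl > (z0 + z1) / 2 - 0.75 & fl < (z0 + z1) / 2 + 0.75
  # parabolic-like profile: centerline much faster than the wall layer
  expect_gt(mean(vx[center]), 2 * abs(mean(vx[near_wall])))
  expect_gt(mean(vx[center]), 0)
})
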