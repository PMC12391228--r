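test_that("eligibility selection degenerates correctly at the extremes", {
  m <- make_sphere_mesh(1.5, n_vertices = 42)
  expect_identical(select_eligible(m, 42, seed = 1), 1:42)
  e1 <- select_eligible(m, 1, seed = 1)
  expect_length(e1, 1)
  expect_true(e1 %in% 1:42)
})

test_that("eligible vertices are spread near-uniformly over the sphere", {
  m <- make_sphere_mesh(2, n_vertices = 642)
  el <- select_eligible(m, 50, seed = 7)
  expect_length(el, 50)
  pts <- m$vertices[el, ]
  d2 <- cellflow:::cross_dist2(pts, pts)
  diag(d2) <- Inf
  nn <- sqrt(apply(d2, 1, min))
  expect_lt(sd(nn) / mean(nn), 0.35)
})

test_that("bond-count identity holds for M1 and M2 with exact trimming", {
  outer <- make_sphere_mesh(2, n_vertices = 100)
  nucleus <- make_sphere_mesh(1.3, n_vertices = 60)
  b1 <- build_cytoskeleton(outer, nucleus, topology_spec("M1", rho = 0.8),
                           ks = 120, kv_damp = 10, seed = 2)
  expect_equal(nrow(b1), 80)
  b2 <- build_cytoskeleton(outer, nucleus, topology_spec("M2", w = 5, rho = 0.8),
                           ks = 120, kv_damp = 10, seed = 2)
  expect_equal(nrow(b2), 80)
  # M2 uses 16 eligible outer vertices x 5 partners
  expect_equal(length(unique(b2$i)), 16)
  expect_true(all(table(b2$i) == 5))
  # rest lengths are construction-time distances
  d <- sqrt(rowSums((outer$vertices[b2$i, ] - nucleus$vertices[b2$j, ])^2))
  expect_equal(b2$l0, unname(d))
})

test_that("infeasible wiring requests are rejected", {
  outer <- make_sphere_mesh(2, n_vertices = 200)
  nucleus <- make_sphere_mesh(1, n_vertices = 12)
  # width larger than the eligible nucleus set cannot give distinct partners
  expect_error(build_cytoskeleton(outer, nucleus,
                                  topology_spec("M2", w = 5, rho = 0.8),
                                  ks = 1, kv_damp = 1, seed = 1,
                                  nucleus_clusters = 4),
               "exceeds")
  expect_error(topology_spec(rho = -0.5))
  # M1 may share nucleus partners between outer vertices (pairs stay unique)
  b <- build_cytoskeleton(outer, nucleus, topology_spec("M1", rho = 0.8),
                          ks = 1, kv_damp = 1, seed = 1)
  expect_equal(nrow(b), 160)
  expect_equal(anyDuplicated(b[, c("i", "j")]), 0)
})

test_that("nucleus network links most distant partners and enforces the 5x stiffness rule", {
  nucleus <- make_sphere_mesh(1.5, n_vertices = 162)
  nb <- build_nucleus_network(nucleus, rho_nucl = 0.8, ks_cyt = 120,
                              kv_damp = 10, seed = 3)
  expect_equal(nrow(nb), round(0.8 * 162))
  expect_true(all(nb$ks == 600))
  expect_true(all(nb$kv == 10))
  # bonds should span the nucleus: lengths close to the diameter scale
  expect_gt(mean(nb$l0), 1.5 * 1.5)  # > 1.5 x radius
  # no duplicate pairs
  key <- paste(pmin(nb$i, nb$j), pmax(nb$i, nb$j))
  expect_equal(anyDuplicated(key), 0)
})

test_that("the most distant partner on a fine sphere mesh is near the antipode", {
  m <- make_sphere_mesh(1, n_vertices = 642)
  part <- cellflow:::farthest_partners(m$vertices, 1)
  anti <- -m$vertices  # antipodal points of a centered sphere
  d <- sqrt(rowSums((m$vertices[part[, 1], ] - anti)^2))
  expect_lt(max(d) / 2, 0.05)  # within 5% of the diameter
})

test_that("M1 wiring admits straighter through-cell chains than M2", {
  outer <- make_sphere_mesh(2.5, n_vertices = 234)
  nucleus <- make_sphere_mesh(1.65, n_vertices = 104)
  c1 <- build_cytoskeleton(outer, nucleus, topology_spec("M1", rho = 0.8),
                           ks = 120, kv_damp = 10, seed = 5)
  n1 <- build_nucleus_network(nucleus, 0.8, 120, 10, seed = 6, variant = "M1")
  c2 <- build_cytoskeleton(outer, nucleus, topology_spec("M2", w = 5, rho = 0.8),
                           ks = 120, kv_damp = 10, seed = 5)
  n2 <- build_nucleus_network(nucleus, 0.8, 120, 10, seed = 6, variant = "M2")
  s1 <- cytoskeleton_chains(c1, n1, outer, nucleus)
  s2 <- cytoskeleton_chains(c2, n2, outer, nucleus)
  # M1 propagates stress almost linearly from one side to the other
  expect_gt(s1, 0.9)
  expect_gt(s1, s2)
})

test_that("the Kelvin-Voigt bond force follows the shared-strain law", {
  bond <- list(ks = 120, kv = 10, l0 = 2)
  # at rest with no motion: zero force
  f <- kv_bond_force(bond, c(2, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  expect_equal(f$fi, c(0, 0, 0))
  # static stretch: pure spring tension ks * eps
  f <- kv_bond_force(bond, c(2.5, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  expect_equal(f$tension, 120 * 0.25, tolerance = 1e-12)
  expect_equal(f$fi, c(-30, 0, 0), tolerance = 1e-12)
  expect_equal(f$fj, -f$fi)
  # pure closing velocity: damper tension kv * (dl/dt) / l0
  f <- kv_bond_force(bond, c(2, 0, 0), c(0, 0, 0), c(-0.4, 0, 0), c(0, 0, 0))
  expect_equal(f$tension, 10 * (-0.4) / 2, tolerance = 1e-12)
  # coincident particles are rejected
  expect_error(kv_bond_force(bond, c(1, 1, 1), c(1, 1, 1), c(0, 0, 0),
                             c(0, 0, 0)), "coincident")
  # extension-based variant drops the 1/l0 normalization
  f <- kv_bond_force(bond, c(2.5, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),
                     strain_based = FALSE)
  expect_equal(f$tension, 120 * 0.5, tolerance = 1e-12)
})

test_that("single-bond creep under constant tension matches the analytic solution", {
  ks <- 120; kv <- 10; sig <- 0.5
  tau <- kv / ks
  cr <- kv_creep(ks, kv, l0 = 1.7, sigma = sig, t_end = 5 * tau)
  theory <- (sig / ks) * (1 - exp(-cr$time / tau))
  late <- cr$time > 0.05 * tau
  expect_lt(max(abs(cr$strain[late] - theory[late]) / theory[late]), 0.01)
  # step strain held fixed: after the damper term vanishes stress = ks * eps
  f <- kv_bond_force(list(ks = ks, kv = kv, l0 = 1), c(1.2, 0, 0), c(0, 0, 0),
                     c(0, 0, 0), c(0, 0, 0))
  expect_equal(f$tension, ks * 0.2, tolerance = 1e-12)
})

test_that("eligibility and network construction are deterministic given the seed", {
  m <- make_sphere_mesh(1.5, n_vertices = 100)
  expect_identical(select_eligible(m, 20, seed = 11),
                   select_eligible(m, 20, seed = 11))
  nucleus <- make_sphere_mesh(1, n_vertices = 42)
  b1 <- build_cytoskeleton(m, nucleus, topology_spec(), 120, 10, seed = 4)
  b2 <- build_cytoskeleton(m, nucleus, topology_spec(), 120, 10, seed = 4)
  expect_identical(b1, b2)
})
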