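test_that("every membrane force operator is the exact negative energy gradient", {
  # randomized configurations; relative error of the full gradient < 1e-5
  for (seed in 1:5) {
    fx <- perturbed_membrane(n_vertices = 30, sd = 0.02, seed = seed)
    mem <- fx$mem; pos <- fx$pos
    checks <- list(
      list(e = function(p) inplane_energy(mem, p),
           f = function(p) inplane_forces(mem, p)),
      list(e = function(p) bending_energy(mem, p),
           f = function(p) bending_forces(mem, p)),
      list(e = function(p) area_volume_energy(mem, p)$total,
           f = function(p) area_volume_forces(mem, p)),
      list(e = function(p) membrane_energy(mem, p)$total,
           f = function(p) membrane_forces(mem, p)))
    for (ch in checks) {
      g <- fd_gradient(ch$e, pos)
      f <- ch$f(pos)
      expect_lt(max(abs(f - g)) / max(abs(g)), 1e-5)
    }
  }
})

test_that("membrane forces sum to zero (momentum conservation)", {
  fx <- perturbed_membrane(n_vertices = 42, sd = 0.03, seed = 9)
  f <- membrane_forces(fx$mem, fx$pos)
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-10)
})

test_that("WLC bond energy is strictly increasing and diverges near full extension", {
  x <- seq(0.02, 0.95, by = 0.01)
  u <- wlc_bond_energy(x * 3, lmax = 3, p = 0.00141, kBT = 0.02)
  expect_true(all(diff(u) > 0))
  expect_gt(wlc_bond_energy(0.999 * 3, 3, 0.00141, 0.02), 40 * max(u))
  # overextension is rejected with the bond named
  m <- make_sphere_mesh(1, n_vertices = 12)
  mem <- membrane(m, membrane_params("cell"))
  stretched <- m$vertices * 10
  expect_error(inplane_energy(mem, stretched), "overextension")
})

test_that("bending energy is zero at the equilibrium angle and 2 kb at a fold", {
  # flat two-triangle configuration, theta0 = 0
  pos <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  mem_desc <- list(edges = matrix(c(2, 3), 1, 2), l0 = 1, lmax = 10,
                   triangles = matrix(c(2, 3, 1), 1, 3),
                   dihedrals = matrix(c(1, 2, 3, 4), 1, 4),
                   p = 1, kb = 65, theta0 = 0, ka = 0, kvol = 0, A0 = 1,
                   V0 = 1, l0ref = 1, x0 = 0.1, lmax_tri = 10, gamma = 0,
                   kBT = 0.02, thermal = FALSE)
  fake <- structure(list(descriptor = mem_desc, index_offset = 0,
                         mesh = list(vertices = pos)), class = "membrane")
  expect_equal(bending_energy(fake, pos), 0, tolerance = 1e-12)
  expect_equal(max(abs(bending_forces(fake, pos))), 0, tolerance = 1e-10)
  # fold the second triangle back onto the first: theta - theta0 = pi
  folded <- pos
  folded[4, ] <- c(1, -1, 0)
  folded[4, ] <- c(0, 1, 0) + c(1, 0, 0)  # l coincides with k shifted along edge
  th <- cellflow:::cpp_dihedral_angles(folded, mem_desc$dihedrals)
  expect_equal(abs(th), pi, tolerance = 1e-10)
  e <- cellflow:::cpp_membrane_energy(folded, mem_desc)$bending
  expect_equal(e, 2 * 65, tolerance = 1e-8)
})

test_that("area and volume penalties vanish at the reference geometry", {
  m <- make_sphere_mesh(1.2, n_vertices = 42)
  mem <- membrane(m, membrane_params("cell"))
  av <- area_volume_energy(mem)
  expect_equal(av$total, 0, tolerance = 1e-20)
  expect_equal(max(abs(area_volume_forces(mem))), 0, tolerance = 1e-10)
})

test_that("a 10% area dilation gives U_a = 0.005 k_a kBT A0 / l0^2", {
  m <- make_sphere_mesh(1.2, n_vertices = 42)
  pm <- membrane_params("cell", kvol = 0, kBT = 0.02)
  mem <- membrane(m, pm)
  g <- mesh_geometry(m)
  # in-plane scaling of the sphere scales area by s^2
  s <- sqrt(1.1)
  pos <- m$vertices * s
  av <- area_volume_energy(mem, pos)
  A0 <- mem$A0
  l0 <- mem$descriptor$l0ref
  expect_equal(mesh_geometry(m, pos)$area, 1.1 * A0, tolerance = 1e-10)
  expect_equal(av$area, 0.005 * pm$ka * pm$kBT * A0 / l0^2, tolerance = 1e-8)
  expect_equal(av$volume, 0)  # kvol = 0
})

test_that("membrane pair dissipation decomposes into tangential and central parts", {
  pm <- membrane_params("cell", gamma = 4, kBT = 0.02)
  ri <- c(0, 0, 0); rj <- c(1, 0, 0)
  # purely tangential relative velocity: only the -gamma_T v term acts
  vtan <- c(0, 0.3, -0.1)
  f <- membrane_pair_dissipative_random(ri, rj, vtan, c(0, 0, 0), pm,
                                        dW = matrix(0, 3, 3), dt = 0.01)
  expect_equal(f$fi, -pm$gamma * vtan, tolerance = 1e-12)
  expect_equal(f$fj, -f$fi)
  # zero velocity and zero Wiener increments: zero force
  f0 <- membrane_pair_dissipative_random(ri, rj, c(0, 0, 0), c(0, 0, 0), pm,
                                         matrix(0, 3, 3), 0.01)
  expect_equal(f0$fi, c(0, 0, 0))
  # central velocity picks up both coefficients
  vcen <- c(0.4, 0, 0)
  fc <- membrane_pair_dissipative_random(ri, rj, vcen, c(0, 0, 0), pm,
                                         matrix(0, 3, 3), 0.01)
  expect_equal(fc$fi, -2 * pm$gamma * vcen, tolerance = 1e-12)
})

test_that("membrane viscous/random pair forces thermostat a free membrane to kBT", {
  kBT <- 0.02
  m <- make_sphere_mesh(1.5, n_vertices = 162)
  mem <- membrane(m, membrane_params("cell", kBT = kBT), thermal = TRUE)
  p <- dpd_params(kBT = kBT, gamma = 0, dt = 0.002, aij = zero_aij())
  sys <- particle_system(m$vertices + 3, types = "cell", box = c(9, 9, 9),
                         periodic = rep(FALSE, 3))
  r <- dpd_run(sys, p, nsteps = 15000, seed = 2, sample_every = 50,
               membranes = list(mem), measure = "membranes")
  kin <- mean(tail(r$trace$kbt_kin, 150))
  expect_lt(abs(kin - kBT) / kBT, 0.10)
})
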