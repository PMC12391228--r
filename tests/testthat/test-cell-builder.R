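test_that("the built cell honors the nuclear-cytoplasmic volume ratio", {
  cell <- small_cell()
  vr <- mesh_geometry(cell$nucleus$mesh)$volume /
    mesh_geometry(cell$outer$mesh)$volume
  expect_equal(vr, 0.29, tolerance = 0.02)
  # nucleus strictly inside the outer membrane
  d2 <- cellflow:::cross_dist2(cell$outer$mesh$vertices,
                               cell$nucleus$mesh$vertices)
  expect_gt(sqrt(min(d2)), 0)
})

test_that("bond density is independent of cell size", {
  c1 <- build_cell(diameter = 4, seed = 1)
  c2 <- build_cell(diameter = 6, seed = 1)
  expect_equal(nrow(c1$cytoskeleton) / c1$n_outer, 0.8, tolerance = 0.01)
  expect_equal(nrow(c2$cytoskeleton) / c2$n_outer, 0.8, tolerance = 0.01)
})

test_that("the nucleus network stiffness is five times the cytoskeleton stiffness", {
  cell <- build_cell(diameter = 4, ks = 120, seed = 1)
  expect_true(all(cell$cytoskeleton$ks == 120))
  expect_true(all(cell$nucleus_bonds$ks == 600))
  expect_equal(unique(cell$nucleus_bonds$kv), unique(cell$cytoskeleton$kv))
  c2 <- build_cell(diameter = 4, ks = 200, seed = 1)
  expect_true(all(c2$nucleus_bonds$ks == 1000))
})

test_that("degenerate geometries are rejected", {
  expect_error(build_cell(diameter = 4, nc_ratio = 0.98), "space|radius")
  expect_error(build_cell(diameter = 4, nc_ratio = 1.2))
  expect_error(build_cell(diameter = -1))
})

test_that("a relaxed cell keeps its area and volume and stays spherical", {
  cell <- small_cell()
  rl <- relax_cell(cell, nsteps = 8000, dt = 0.005, seed = 2)
  expect_equal(rl$status, "ok")
  tr <- rl$trace
  expect_lt(max(abs(tr$area_1 / cell$outer$A0 - 1)), 0.01)
  expect_lt(max(abs(tr$volume_1 / cell$outer$V0 - 1)), 0.01)
  expect_lt(max(abs(tr$area_2 / cell$nucleus$A0 - 1)), 0.01)
  expect_lt(max(abs(tr$volume_2 / cell$nucleus$V0 - 1)), 0.01)
  g <- mesh_geometry(rl$cell$outer$mesh)
  expect_gt(sphericity(area = g$area, volume = g$volume), 0.98)
  # membranes do not interpenetrate after relaxation
  d2 <- cellflow:::cross_dist2(rl$cell$outer$mesh$vertices,
                               rl$cell$nucleus$mesh$vertices)
  expect_gt(sqrt(min(d2)), 0)
})
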