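test_that("the base icosahedron has the exact closed-surface counts", {
  m <- make_sphere_mesh(1, n_vertices = 12)
  expect_equal(m$n_vertices, 12)
  expect_equal(m$n_edges, 30)
  expect_equal(m$n_triangles, 20)
})

test_that("Euler identities hold for every generated mesh", {
  for (nv in c(12, 42, 100, 257, 642)) {
    m <- make_sphere_mesh(1.3, n_vertices = nv)
    expect_equal(m$n_vertices, nv)
    expect_equal(m$n_edges, 3 * (nv - 2))
    expect_equal(m$n_triangles, 2 * (nv - 2))
    expect_equal(m$n_vertices - m$n_edges + m$n_triangles, 2)
    # every dihedral row describes two triangles sharing an ordered edge
    expect_equal(nrow(m$dihedrals), m$n_edges)
  }
})

test_that("one subdivision multiplies the triangle count by exactly four", {
  m <- make_sphere_mesh(1, n_vertices = 42)
  m2 <- subdivide_mesh(m)
  expect_equal(m2$n_triangles, 4 * m$n_triangles)
  expect_equal(m2$n_edges, 3 * (m2$n_vertices - 2))
})

test_that("mean edge length tracks the requested target", {
  for (target in c(0.3, 0.5, 0.8)) {
    m <- make_sphere_mesh(2, target_edge_length = target)
    expect_lt(abs(mean(m$l0) - target) / target, 0.15)
  }
})

test_that("fine sphere meshes approach the analytic area and volume", {
  m <- make_sphere_mesh(1, target_edge_length = 0.12)
  g <- mesh_geometry(m)
  expect_equal(g$area, 4 * pi, tolerance = 0.02)
  expect_equal(g$volume, 4 * pi / 3, tolerance = 0.02)
})

test_that("area and volume agree with an independent per-triangle summation", {
  m <- make_sphere_mesh(1.7, n_vertices = 77)
  g <- mesh_geometry(m)
  # independent re-summation written out longhand
  A <- 0; V <- 0
  for (t in seq_len(m$n_triangles)) {
    a <- m$vertices[m$triangles[t, 1], ]
    b <- m$vertices[m$triangles[t, 2], ]
    cc <- m$vertices[m$triangles[t, 3], ]
    u <- b - a; w <- cc - a
    cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    A <- A + 0.5 * sqrt(sum(cr^2))
    V <- V + (a[1] * (b[2] * cc[3] - b[3] * cc[2]) -
                a[2] * (b[1] * cc[3] - b[3] * cc[1]) +
                a[3] * (b[1] * cc[2] - b[2] * cc[1])) / 6
  }
  expect_equal(g$area, A, tolerance = 1e-12)
  expect_equal(g$volume, V, tolerance = 1e-12)
})

test_that("inverted orientation is detected as negative enclosed volume", {
  m <- make_sphere_mesh(1, n_vertices = 42)
  flipped <- m$triangles[, c(1, 3, 2)]
  g <- mesh_geometry(list(vertices = m$vertices,
                          triangles = flipped))
  expect_lt(g$volume, 0)
  expect_error(trimesh(m$vertices, flipped), "volume")
})

test_that("a non-closed triangle soup is rejected with the offending edge named", {
  m <- make_sphere_mesh(1, n_vertices = 12)
  expect_error(trimesh(m$vertices, m$triangles[-1, , drop = FALSE]),
               "not closed")
})

test_that("two closed surfaces totalling 7212 vertices carry 14416 triangles and 21624 edges", {
  m1 <- make_sphere_mesh(10, n_vertices = 3606, smooth_iters = 0L)
  nv <- 2 * m1$n_vertices
  expect_equal(nv, 7212)
  expect_equal(2 * m1$n_triangles, 14416)
  expect_equal(2 * m1$n_edges, 21624)
})
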