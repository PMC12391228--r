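# short shared aspiration runs (built once per test session)
asp_cache <- local({
  env <- new.env()
  function(key, make) {
    if (is.null(env[[key]])) env[[key]] <- make()
    env[[key]]
  }
})

test_that("the normalized-length invariant holds at every trace sample", {
  tr <- asp_cache("ramp_short", function() {
    cell <- build_cell(diameter = 4, seed = 1)
    run_aspiration(cell, mode = "ramp", seed = 11, t_hold = 8, t_ramp = 16,
                   sample_every = 40)
  })
  L0 <- attr(tr, "L0")
  rp <- attr(tr, "rp")
  expect_equal(tr$Ln, (tr$Lp - L0) / rp, tolerance = 1e-12)
  expect_true(all(is.finite(tr$Ln)))
  # pressure schedule: constant hold then linear rise
  expect_equal(tr$pressure_Pa[1], tail(tr$pressure_Pa, 1) * 0.3,
               tolerance = 1e-6)
  expect_true(all(diff(tr$pressure_Pa) >= -1e-9))
})

test_that("cell volume is conserved during aspiration", {
  tr <- asp_cache("ramp_short", function() stop("cache miss"))
  post <- tr$time > 8  # after the reference hold
  expect_lt(diff(range(tr$volume_1[post])) / tr$volume_1[1], 0.02)
  expect_lt(diff(range(tr$volume_2[post])) / tr$volume_2[post][1], 0.02)
})

test_that("zero suction leaves the aspiration length at zero within thermal noise", {
  cell <- build_cell(diameter = 4, seed = 1)
  proto <- pipette_protocol(max_pressure_Pa = 1e-9)
  tr <- run_aspiration(cell, proto, mode = "ramp", seed = 13, t_hold = 6,
                       t_ramp = 8, sample_every = 40)
  # max-extent statistic pokes by thermal membrane ripples only
  expect_lt(abs(mean(tr$Ln)), 0.15)
  expect_lt(max(abs(tr$Ln)), 0.4)
})

test_that("creep at constant pressure is non-decreasing (smoothed) toward a plateau", {
  tr <- asp_cache("creep_short", function() {
    cell <- build_cell(diameter = 4, seed = 1)
    run_aspiration(cell, mode = "creep", seed = 17, t_hold = 8, t_ramp = 28,
                   sample_every = 40)
  })
  post <- tr[tr$time > 10, ]
  k <- 7  # moving-average window
  sm <- stats::filter(post$Lp, rep(1 / k, k), sides = 2)
  sm <- sm[!is.na(sm)]
  # smoothed creep never retreats by more than a small thermal tolerance
  expect_gt(min(diff(sm)), -0.05)
  expect_gt(tail(sm, 1), head(sm, 1))
})

test_that("aspiration traces are reproducible given the seed", {
  cell <- build_cell(diameter = 4, seed = 1)
  t1 <- run_aspiration(cell, mode = "ramp", seed = 19, t_hold = 2, t_ramp = 3,
                       sample_every = 40)
  t2 <- run_aspiration(cell, mode = "ramp", seed = 19, t_hold = 2, t_ramp = 3,
                       sample_every = 40)
  expect_identical(t1$Lp, t2$Lp)
})

test_that("channel body-force calibration is linear and self-consistent", {
  dev <- channel_device(gap = 3, height = 6, rows = 2, per_row = 1,
                        row_spacing = 7, base = 3, body_force = 0.3)
  # zero target needs no force
  f0 <- calibrate_body_force(dev, target_velocity = 0)
  expect_equal(as.numeric(f0), 0)
  # linear low-Reynolds response of the simple (standard-compressibility)
  # fluid: doubling the force doubles the velocity within 5%.  The stiff
  # squeezing fluid used for cell transits is deliberately less
  # compressible and shear-thins, so linearity is checked on the plain
  # fluid.
  v1 <- cellflow:::channel_mean_velocity(dev, 0.01, seed = 23, t_run = 20,
                                         a_fluid = 0.5)
  v2 <- cellflow:::channel_mean_velocity(dev, 0.02, seed = 23, t_run = 20,
                                         a_fluid = 0.5)
  expect_equal(v2 / v1, 2, tolerance = 0.05)
  dev$body_force <- 0.3
  f <- calibrate_body_force(dev, target_velocity = 0.4, seed = 23,
                            t_run = 8, tol = 0.05)
  expect_equal(attr(f, "achieved_velocity"), 0.4, tolerance = 0.05)
  # an independent run with a new seed reproduces the target
  d3 <- dev; d3$body_force <- as.numeric(f)
  f2 <- calibrate_body_force(d3, target_velocity = 0.4, seed = 31,
                             t_run = 8, tol = 0.05)
  expect_equal(attr(f2, "achieved_velocity"), 0.4, tolerance = 0.05)
  expect_lte(attr(f2, "iterations"), 3)
})

test_that("device geometry respects the gap and periodic width", {
  dev <- channel_device(gap = 3, height = 6, rows = 2, per_row = 2,
                        row_spacing = 8, base = 3)
  expect_equal(dev$pitch, 6)
  expect_equal(dev$width, 12)
  tri <- cellflow:::device_obstacles(dev)
  expect_equal(nrow(tri), 4)  # 2 rows x 2 obstacles
  # obstacle base width equals `base`, leaving `gap` between neighbors
  expect_equal(max(tri[1, c(4, 6)]) - min(tri[1, c(4, 6)]), 3)
  pd <- channel_device_paper(gap_um = 12)
  expect_equal(pd$rows, 10)
  expect_equal(pd$per_row, 10)
  expect_equal(pd$height, 28)
  expect_equal(pd$row_spacing, 60)
  expect_equal(pd$gap, 12)
})
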