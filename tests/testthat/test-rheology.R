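make_ramp_trace <- function(E, phi = 2.1, n = 60, noise = 0, lnmax = 1.2,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  slope <- E * 2 * pi / (3 * phi)
  Ln <- seq(0.05, lnmax, length.out = n)
  P <- slope * Ln
  Ln_obs <- Ln + rnorm(n, sd = noise * max(Ln))
  data.frame(time = seq_len(n), time_s = seq_len(n), pressure_Pa = P,
             Ln = Ln_obs)
}

test_that("the elastic estimator inverts a noise-free linear ramp exactly", {
  tr <- make_ramp_trace(E = 230)
  est <- theret_elastic(tr)
  expect_equal(est$E_Pa, 230, tolerance = 1e-10)
  expect_equal(est$phi, 2.1)
  # closed-form inversion of an arbitrary slope
  tr2 <- make_ramp_trace(E = 3 * 2.1 * 77 / (2 * pi))
  expect_equal(theret_elastic(tr2)$slope_Pa, 77, tolerance = 1e-10)
})

test_that("the elastic estimate is covered by its standard error under noise", {
  hits <- 0
  for (r in 1:200) {
    tr <- make_ramp_trace(E = 230, noise = 0.05, seed = 1000 + r)
    est <- theret_elastic(tr)
    if (abs(est$E_Pa - 230) <= 2 * est$se_Pa) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.9)
})

test_that("too few samples in the fit window is an error", {
  tr <- make_ramp_trace(E = 230, lnmax = 0.1)
  expect_error(theret_elastic(tr), "fewer than 5")
})

make_creep_trace <- function(mu_Pa_s, k1, a, dP = 90, phi = 2.1, n = 120,
                             t_end = NULL, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k2 <- a * k1 / (1 - a)
  tau <- mu_Pa_s * (k1 + k2) / (k1 * k2)
  if (is.null(t_end)) t_end <- 6 * tau  # resolve the transient on the grid
  C <- 3 * phi * dP / (2 * pi)
  t <- seq(0, t_end, length.out = n)
  Ln <- (C / k1) * (1 - a * exp(-t / tau))
  data.frame(time = t, time_s = t, pressure_Pa = dP,
             Ln = Ln + rnorm(n, sd = noise * max(Ln)))
}

test_that("the creep estimator recovers its generating parameters exactly", {
  tr <- make_creep_trace(mu_Pa_s = 0.01111, k1 = 180, a = 0.6)
  est <- theret_viscous(tr, pressure_Pa = 90)
  expect_equal(est$mu_mPa_s, 11.11, tolerance = 1e-6)
  expect_equal(est$E_Pa, 180, tolerance = 1e-6)
  expect_equal(est$a, 0.6, tolerance = 1e-6)
})

test_that("creep estimates are unbiased within 2 SE under 5% noise", {
  hits <- 0
  for (r in 1:200) {
    tr <- make_creep_trace(mu_Pa_s = 0.0102, k1 = 200, a = 0.55, noise = 0.05,
                           seed = 2000 + r)
    est <- theret_viscous(tr, pressure_Pa = 90)
    if (is.finite(est$se_mPa_s) &&
        abs(est$mu_mPa_s - 10.2) <= 2 * est$se_mPa_s) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.9)
})

test_that("vanishing creep time constant gives a vanishing viscosity", {
  # mu = tau k1 a: as the fitted time constant shrinks, so does the viscosity
  tr <- make_creep_trace(mu_Pa_s = 1e-5, k1 = 180, a = 0.6, n = 400)
  est <- theret_viscous(tr, pressure_Pa = 90)
  expect_equal(est$mu_mPa_s, 0.01, tolerance = 1e-3)
  expect_lt(est$tau_s, 1e-6)
})

test_that("a non-creeping trace is rejected", {
  tr <- make_creep_trace(mu_Pa_s = 0.01, k1 = 180, a = 0.6)
  tr$Ln <- rev(tr$Ln)
  expect_error(theret_viscous(tr, pressure_Pa = 90), "no creep")
})

test_that("the elastic modulus is invariant to time rescaling, the viscosity scales with it", {
  tr <- make_creep_trace(mu_Pa_s = 0.01, k1 = 180, a = 0.6)
  stopifnot(nrow(tr) > 0)
  tr_fast <- tr
  tr_fast$time_s <- tr$time_s / 10  # the same record on a 10x faster clock
  e1 <- theret_viscous(tr, pressure_Pa = 90)
  e2 <- theret_viscous(tr_fast, pressure_Pa = 90)
  expect_equal(e2$E_Pa, e1$E_Pa, tolerance = 1e-6)
  expect_equal(e2$mu_mPa_s, e1$mu_mPa_s / 10, tolerance = 1e-6)
  # elastic fit does not involve the clock at all
  rt <- make_ramp_trace(E = 230)
  rt$time_s <- rt$time_s * 100
  expect_equal(theret_elastic(rt)$E_Pa, 230, tolerance = 1e-10)
})
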