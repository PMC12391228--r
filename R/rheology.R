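#' Elastic modulus from an aspiration ramp (Theret half-space punch model)
#'
#' For a homogeneous incompressible elastic half-space aspirated by a
#' cylindrical pipette, the normalized aspiration length grows linearly with
#' the suction pressure, `L_n = (2 pi / 3 Phi) * dP / E`, where `Phi` is the
#' pipette wall function.  The elastic modulus is therefore recovered from
#' the least-squares slope `S = d(dP)/d(L_n)` of the ramp trace as
#' `E = 3 Phi S / (2 pi)`.
#'
#' @param trace an `aspiration_trace` from [run_aspiration()] (ramp mode),
#'   or any data frame with `pressure_Pa` and `Ln` columns.
#' @param phi Theret wall function (default 2.1; reported in the estimate).
#' @param window fit window on `L_n` (default `[0.2, 1.0]`, the
#'   small-deformation linear regime).
#' @return object of class `modulus_estimate` with fields `E_Pa`, `se_Pa`,
#'   `phi`, `slope_Pa`, `window`, `n`.
#' @export
theret_elastic <- function(trace, phi = 2.1, window = c(0.2, 1.0)) {
  stopifnot(phi > 0, length(window) == 2)
  sel <- is.finite(trace$Ln) & trace$Ln >= window[1] & trace$Ln <= window[2]
  if (!is.null(attr(trace, "t_hold")))
    sel <- sel & trace$time > attr(trace, "t_hold")
  if (sum(sel) < 5)
    stop("fewer than 5 samples with L_n in [", window[1], ", ", window[2],
         "]: cannot fit the aspiration slope")
  fit <- lm(pressure_Pa ~ Ln, data = trace[sel, , drop = FALSE])
  slope <- coef(fit)[["Ln"]]
  se <- summary(fit)$coefficients["Ln", "Std. Error"]
  k <- 3 * phi / (2 * pi)
  structure(list(E_Pa = k * slope, se_Pa = k * se, phi = phi,
                 slope_Pa = slope, window = window, n = sum(sel)),
            class = "modulus_estimate")
}

#' Viscous modulus from constant-pressure creep (Theret standard-solid model)
#'
#' Fits the creep of the normalized aspiration length at constant suction
#' `dP` to the standard-linear-solid solution
#' `L_n(t) = L_inf (1 - a exp(-t / tau))` and converts the fit to the
#' model's moduli: with `C = 3 Phi dP / (2 pi)`, the long-time spring is
#' `k1 = C / L_inf`, the amplitude fraction gives `a = k2 / (k1 + k2)`, and
#' the apparent viscosity is `mu = tau k1 k2 / (k1 + k2) = tau k1 a`.
#'
#' @param trace an `aspiration_trace` from [run_aspiration()] (creep mode):
#'   needs `time_s`, `Ln` and `pressure_Pa` columns.  The fit uses samples
#'   after the pressure step.
#' @param phi Theret wall function (default 2.1).
#' @param pressure_Pa hold pressure; defaults to the trace's final pressure.
#' @return object of class `modulus_estimate` with fields `mu_mPa_s`,
#'   `se_mPa_s`, `E_Pa` (long-time modulus `k1`), `k2_Pa`, `tau_s`,
#'   `L_inf`, `a`, `phi`.
#' @export
theret_viscous <- function(trace, phi = 2.1, pressure_Pa = NULL) {
  stopifnot(phi > 0)
  if (is.null(pressure_Pa)) pressure_Pa <- tail(trace$pressure_Pa, 1)
  th <- attr(trace, "t_hold")
  d <- if (!is.null(th)) trace[trace$time > th + 2, , drop = FALSE] else trace
  if (nrow(d) < 8) stop("too few samples after the pressure step for a creep fit")
  t <- d$time_s - d$time_s[1]
  y <- d$Ln
  nh <- ceiling(length(y) / 4)
  if (mean(tail(y, nh)) <= mean(head(y, nh)))
    stop("trace shows no creep (non-increasing aspiration length)")
  linf0 <- max(mean(tail(y, nh)), 1e-6)
  a0 <- min(0.9, max(0.1, 1 - mean(head(y, 3)) / linf0))
  # initial time constants from slow to fast: very fast transients make the
  # slow start singular, so retry down the ladder
  tau_ladder <- unique(pmax(c(t[length(t)] / 5, t[length(t)] / 50,
                              5 * t[2], t[2]), 1e-12))
  fit <- NULL
  for (tau0 in tau_ladder) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ Linf * (1 - a * exp(-t / tau)),
                        start = list(Linf = linf0, a = a0, tau = tau0),
                        lower = c(1e-9, 1e-6, 1e-12),
                        upper = c(Inf, 1, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("creep fit failed: could not initialize the exponential model")
  cf <- coef(fit)
  C <- 3 * phi * pressure_Pa / (2 * pi)
  k1 <- C / cf[["Linf"]]
  a <- cf[["a"]]
  tau <- cf[["tau"]]
  k2 <- a * k1 / max(1 - a, 1e-12)
  mu <- tau * k1 * a            # Pa * s
  # delta-method standard error from the fit covariance
  se_mu <- tryCatch({
    V <- vcov(fit)
    gr <- c(Linf = -mu / cf[["Linf"]], a = tau * k1, tau = k1 * a)
    sqrt(drop(t(gr) %*% V %*% gr))
  }, error = function(e) NA_real_)
  structure(list(mu_mPa_s = 1000 * mu, se_mPa_s = 1000 * se_mu,
                 E_Pa = k1, k2_Pa = k2, tau_s = tau,
                 L_inf = cf[["Linf"]], a = a, phi = phi),
            class = "modulus_estimate")
}

#' @export
print.modulus_estimate <- function(x, ...) {
  if (!is.null(x$E_Pa) && is.null(x$mu_mPa_s)) {
    cat(sprintf("<modulus_estimate> E = %.4g +/- %.2g Pa (Phi = %g, n = %d)\n",
                x$E_Pa, x$se_Pa, x$phi, x$n))
  } else {
    cat(sprintf(paste0("<modulus_estimate> mu = %.4g +/- %.2g mPa.s ",
                       "(tau = %.3g s, k1 = %.4g Pa, Phi = %g)\n"),
                x$mu_mPa_s, x$se_mPa_s, x$tau_s, x$E_Pa, x$phi))
  }
  invisible(x)
}

#' Elastic modulus from a staircase aspiration trace
#'
#' For traces recorded with a constant-pressure staircase protocol
#' ([run_aspiration()] with `staircase > 0`), groups samples by pressure
#' plateau, averages the normalized aspiration length over the second half
#' of each plateau (the quasi-static part), and fits the Theret line
#' through the plateau means.  Averaging within plateaus suppresses the
#' thermal noise of the instantaneous maximum-extent measurement.
#'
#' @param trace an `aspiration_trace` from a staircase run.
#' @param phi Theret wall function.
#' @param settle_frac fraction of each plateau discarded as equilibration.
#' @return a `modulus_estimate`, as in [theret_elastic()].
#' @export
theret_elastic_steps <- function(trace, phi = 2.1, settle_frac = 0.5) {
  stopifnot(phi > 0)
  d <- trace
  if (!is.null(attr(trace, "t_hold"))) d <- d[d$time > attr(trace, "t_hold"), ]
  lev <- unique(round(d$pressure_Pa, 9))
  means <- vapply(lev, function(p) {
    idx <- which(abs(d$pressure_Pa - p) < 1e-9)
    idx <- idx[idx > idx[1] + floor(settle_frac * length(idx))]
    mean(d$Ln[idx])
  }, numeric(1))
  keep <- is.finite(means)
  if (sum(keep) < 3) stop("fewer than 3 pressure plateaus: cannot fit")
  fit <- lm(P ~ Ln, data = data.frame(P = lev[keep], Ln = means[keep]))
  slope <- coef(fit)[["Ln"]]
  se <- tryCatch(summary(fit)$coefficients["Ln", "Std. Error"],
                 error = function(e) NA_real_)
  k <- 3 * phi / (2 * pi)
  structure(list(E_Pa = k * slope, se_Pa = k * se, phi = phi,
                 slope_Pa = slope, window = NULL, n = sum(keep),
                 plateau_Ln = means[keep], plateau_Pa = lev[keep]),
            class = "modulus_estimate")
}
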