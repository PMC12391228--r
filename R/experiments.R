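#' Micropipette aspiration protocol
#'
#' Physical protocol of the virtual micropipette: pipette radius, linear
#' pressure ramp (for elasticity measurements) and constant-pressure creep
#' (for viscosity measurements).  Defaults are the experimental protocol the
#' model is calibrated against: a 4.25 um diameter pipette with pressure
#' ramped from 0 to 117.72 Pa at 3.27 Pa/s.
#'
#' @param radius_um pipette bore radius in micrometres.
#' @param ramp_rate_Pa_s pressure ramp rate (Pa/s).
#' @param max_pressure_Pa maximum ramp pressure (Pa).
#' @param creep_pressure_Pa constant pressure for creep mode (Pa).
#' @return object of class `pipette_protocol`.
#' @export
pipette_protocol <- function(radius_um = 4.25 / 2, ramp_rate_Pa_s = 3.27,
                             max_pressure_Pa = 117.72,
                             creep_pressure_Pa = 90) {
  stopifnot(radius_um > 0, ramp_rate_Pa_s >= 0, max_pressure_Pa > 0,
            creep_pressure_Pa > 0)
  structure(list(radius_um = radius_um, ramp_rate_Pa_s = ramp_rate_Pa_s,
                 max_pressure_Pa = max_pressure_Pa,
                 creep_pressure_Pa = creep_pressure_Pa),
            class = "pipette_protocol")
}


# interaction matrix of the virtual instruments: a stiff fluid (background
# pressure sustains suction / drives squeezing), soft or zero wall-membrane
# coupling (non-adhesive device walls; bounce-back handles impermeability),
# and soft membrane self-interaction (in-plane cohesion is the bonds' job;
# a stiff self-term would inflate the enclosed volume)
instrument_aij <- function(a_fluid = 25, a_wall_membrane = 0,
                           a_membrane_self = 2.5) {
  aij <- matrix(a_fluid, 4, 4, dimnames = list(PARTICLE_TYPES, PARTICLE_TYPES))
  aij["wall", c("cell", "nucleus")] <- a_wall_membrane
  aij[c("cell", "nucleus"), "wall"] <- a_wall_membrane
  aij["cell", "cell"] <- a_membrane_self
  aij["nucleus", "nucleus"] <- a_membrane_self
  aij
}

# assemble fluid + frozen wall particles around a cell in front of a pipette
aspiration_scene <- function(cell, rp, density, rc = 1) {
  R <- cell$radius
  chamber <- 2 * R + 3
  tube <- max(6, 3 * rp + 4)
  Lx <- chamber + tube
  Ly <- Lz <- 2 * R + 3
  xm <- chamber
  yc <- Ly / 2
  zc <- Lz / 2
  # membrane particles, recentered in front of the mouth
  mpos <- cell_positions(cell)
  shift <- c(xm - R - 0.05, yc, zc) - cell$center
  mpos <- sweep(mpos, 2, shift, "+")
  phi <- function(p) pmax(xm - p[, 1],
                          rp - sqrt((p[, 2] - yc)^2 + (p[, 3] - zc)^2))
  fluid <- fill_region(c(0, 0, 0), c(Lx, Ly, Lz), density = density,
                       keep = function(p) phi(p) > 0.1)
  wallpts <- fill_region(c(xm, 0, 0), c(Lx, Ly, Lz), density = density,
                         keep = function(p) {
                           rr <- sqrt((p[, 2] - yc)^2 + (p[, 3] - zc)^2)
                           rr >= rp & (p[, 1] - xm < rc | rr - rp < rc |
                                         Lx - p[, 1] < rc)
                         })
  pos <- rbind(fluid, wallpts, mpos)
  types <- c(rep("fluid", nrow(fluid)), rep("wall", nrow(wallpts)),
             cell_types(cell))
  n_env <- nrow(fluid) + nrow(wallpts)
  list(pos = pos, types = types, box = c(Lx, Ly, Lz), xm = xm, yc = yc,
       zc = zc, n_env = n_env, shift = shift, Lx = Lx)
}

# shift both membrane descriptors (already in combined cell indexing) so the
# cell's particles sit after n_env environment particles
offset_membranes <- function(cell, n_env) {
  mo <- cell$outer
  mn <- cell$nucleus
  for (f in c("edges", "triangles", "dihedrals")) {
    mo$descriptor[[f]] <- mo$descriptor[[f]] + n_env
    mn$descriptor[[f]] <- mn$descriptor[[f]] + n_env
  }
  list(outer = mo, nucleus = mn)
}

#' Virtual micropipette aspiration
#'
#' Places the cell in a DPD fluid chamber in front of a cylindrical
#' bounce-back pipette (frozen wall particles plus analytic reflection
#' surfaces) and applies the pressure difference as a body force on the
#' fluid inside the tube, scaled so `dP = density * f * L_region`
#' (hydrostatic balance over the forced tube section).  In `ramp` mode the
#' pressure is held at a small value (the reference window defining `L0`)
#' and then ramped linearly to the protocol maximum; in `creep` mode it is
#' stepped to the constant creep pressure and held.  The aspiration length
#' `L_p` is the maximum axial extent of cell particles past the mouth plane
#' and the normalized length is `L_n = (L_p - L0) / R_p`.
#'
#' In scaled mode (the default) the pipette radius is a fixed fraction of
#' the cell radius and the hold/ramp durations are compressed simulated
#' times, so runs complete at desk scale; `scaled = FALSE` uses the
#' physical pipette radius and protocol timing through the unit map.
#'
#' @param cell a [build_cell()] model.
#' @param protocol a [pipette_protocol()].
#' @param mode `"ramp"` or `"creep"`.
#' @param seed engine seed.
#' @param units a [unit_map()].
#' @param scaled scaled instrument geometry/timing (see Details).
#' @param t_hold,t_ramp simulated hold and ramp durations (scaled mode).
#' @param pipette_frac pipette radius as a fraction of cell radius (scaled).
#' @param dt integration time step.
#' @param sample_every measurement stride (steps).
#' @param density fluid number density.
#' @param hold_frac reference pressure as a fraction of the maximum.
#' @param a_fluid conservative coefficient of the instrument's fluid (a
#'   stiff, weakly compressible fluid whose background pressure sustains the
#'   suction without cavitation).
#' @param a_wall_membrane conservative coefficient between walls and
#'   membrane particles (soft: the device walls are non-adhesive and
#'   low-friction).
#' @param method `"fluid"` immerses the cell in the DPD fluid and applies
#'   the suction as a body force on the fluid in the tube; `"surface"`
#'   applies the pressure difference directly as a normal surface load on
#'   the membrane inside the bore (the fluid's sole role in aspiration is to
#'   transmit this load), with no explicit fluid.  The surface method is
#'   deterministic up to membrane thermal noise, free of the desk-scale
#'   fluid's cavitation artifacts, and roughly thirty times faster; it is
#'   the instrument used for parameter sweeps.
#' @param staircase if positive, replace the linear ramp by this many equal
#'   constant-pressure plateaus between the reference hold and the maximum;
#'   time-averaged plateau positions give a quasi-static, low-noise
#'   pressure-extension curve (see [theret_elastic_steps()]).
#' @param thermostat_scale ratio of the instrument temperature to the
#'   material temperature (1 = fully thermal).  Values below 1 reduce
#'   measurement noise; note that a strongly quenched membrane also stiffens
#'   kinetically, so the scale trades noise against response.
#' @return an `aspiration_trace`: data frame with columns `time`, `time_s`,
#'   `pressure_sim`, `pressure_Pa`, `Lp`, `Ln` plus membrane area/volume
#'   columns; attributes `L0`, `rp`, `mode`, `status`, `units`, `protocol`.
#' @export
run_aspiration <- function(cell, protocol = pipette_protocol(),
                           mode = c("ramp", "creep"), seed = 1L,
                           units = cell$units, scaled = TRUE,
                           t_hold = 16, t_ramp = 40, pipette_frac = 0.7,
                           dt = 0.005, sample_every = 80L, density = 3,
                           hold_frac = 0.3, a_fluid = 25, a_wall_membrane = 0,
                           thermostat_scale = 1, staircase = 0L,
                           method = c("fluid", "surface")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  rp <- if (scaled) pipette_frac * cell$radius else protocol$radius_um / units$length_um
  if (2 * rp >= 2 * cell$radius)
    stop("pipette mouth must be smaller than the cell diameter")
  scene <- with_seed(seed, aspiration_scene(cell, rp,
                                            if (method == "fluid") density else 0))
  n_env <- scene$n_env
  mems <- offset_membranes(cell, n_env)
  kvb <- cell_kv_bonds(cell)
  kvb$i <- kvb$i + n_env
  kvb$j <- kvb$j + n_env
  # a stiff (weakly compressible) fluid so the chamber's background pressure
  # sustains the applied suction; walls are soft for the membrane
  # (non-adhesive, low-friction pipette)
  aij <- if (method == "fluid") instrument_aij(a_fluid, a_wall_membrane)
         else instrument_aij(2.5, a_wall_membrane)
  kBT_thermo <- max(thermostat_scale, 1e-8) * cell$outer$params$kBT
  # membrane noise amplitude follows the instrument temperature (the
  # material energy scale in the elastic terms is untouched); a zero scale
  # quenches the dynamics entirely (noise-free overdamped mechanics)
  mems$outer$descriptor$kBT_noise <- kBT_thermo
  mems$nucleus$descriptor$kBT_noise <- kBT_thermo
  if (thermostat_scale == 0) {
    mems$outer$descriptor$thermal <- FALSE
    mems$nucleus$descriptor$thermal <- FALSE
  }
  params <- dpd_params(kBT = kBT_thermo, dt = dt, aij = aij)
  sys <- particle_system(scene$pos, types = scene$types, box = scene$box)
  walls <- list(wall_pipette(scene$xm, rp, scene$yc, scene$zc, xe = scene$Lx))
  # pressure schedule in simulation units
  pmax <- protocol$max_pressure_Pa / units$pressure_Pa
  ph <- hold_frac * pmax
  if (mode == "ramp") {
    if (staircase > 0) {
      # quasi-static staircase: equal pressure plateaus from the hold to the
      # maximum; plateau means give a low-noise Theret slope
      lev <- seq(ph, pmax, length.out = staircase + 1)[-1]
      tstep <- t_ramp / staircase
      tk <- t_hold
      pk <- ph
      for (q in seq_along(lev)) {
        tk <- c(tk, t_hold + (q - 1) * tstep + 1e-6, t_hold + q * tstep)
        pk <- c(pk, lev[q], lev[q])
      }
      tk <- c(0, tk)
      pk <- c(ph, pk)
    } else {
      tk <- c(0, t_hold, t_hold + t_ramp)
      pk <- c(ph, ph, pmax)
    }
    t_end <- t_hold + t_ramp
  } else {
    pc <- protocol$creep_pressure_Pa / units$pressure_Pa
    tk <- c(0, t_hold, t_hold + 2, t_hold + t_ramp)
    pk <- c(ph, ph, pc, pc)
    t_end <- t_hold + t_ramp
  }
  if (method == "fluid") {
    # hydrostatic mapping over the forced tube section
    xa <- scene$xm + 0.5
    xb <- scene$Lx - 0.5
    p_to_f <- 1 / (density * (xb - xa))
    bf <- list(mode = "tube", dir = c(1, 0, 0), t = tk, f = pk * p_to_f,
               xa = xa, xb = xb, rp = rp, yc = scene$yc, zc = scene$zc)
  } else {
    # suction applied as a normal surface load on the membrane plug inside
    # the bore: per-vertex force = dP x (mean membrane area per vertex)
    a_per_vertex <- cell$outer$A0 / cell$n_outer
    bf <- list(mode = "tube_membrane", dir = c(1, 0, 0), t = tk,
               f = pk * a_per_vertex, xa = scene$xm - 0.6, xb = scene$Lx,
               rp = 0.98 * rp, yc = scene$yc, zc = scene$zc)
  }
  nsteps <- ceiling(t_end / dt)
  res <- dpd_run(sys, params, nsteps = nsteps, seed = seed,
                 membranes = mems, kv_bonds = kvb, walls = walls,
                 body_force = bf, sample_every = sample_every,
                 measure = c("lp", "membranes"), stop_when_aspirated = TRUE)
  tr <- res$trace
  p_sim <- approx(tk, pk, xout = pmin(tr$time, max(tk)), rule = 2)$y
  hold_win <- tr$time >= 0.6 * t_hold & tr$time <= t_hold
  L0 <- mean(tr$lp[hold_win])
  out <- data.frame(time = tr$time, time_s = tr$time * units$time_s,
                    pressure_sim = p_sim,
                    pressure_Pa = p_sim * units$pressure_Pa,
                    Lp = tr$lp, Ln = (tr$lp - L0) / rp)
  for (cn in grep("^(area|volume)_", names(tr), value = TRUE)) out[[cn]] <- tr[[cn]]
  structure(out, L0 = L0, rp = rp, mode = mode, status = res$status,
            units = units, protocol = protocol, t_hold = t_hold,
            class = c("aspiration_trace", "data.frame"))
}

#' Obstacle-channel microfluidic device
#'
#' A periodic channel bounded by two plates, containing rows of triangular
#' prism obstacles (apex pointing upstream) separated by gaps the cell must
#' squeeze through.  All dimensions are in simulation units; the physical
#' device (28 um height, 10 rows of 10 obstacles, 60 um row spacing, gaps of
#' 10/12/15 um) maps through a [unit_map()] at full scale via
#' `channel_device_paper()`.
#'
#' @param gap gap between obstacles in a row.
#' @param height channel (fluid) height between the plates.
#' @param rows number of obstacle rows.
#' @param per_row obstacles per row (periodic width = `per_row * (base + gap)`).
#' @param row_spacing axial distance between rows.
#' @param base obstacle triangle base width.
#' @param body_force per-particle driving force (see
#'   [calibrate_body_force()]).
#' @param stagger offset alternate rows by half a pitch (the full device
#'   layout); aligned rows keep a single squeeze lane, which scaled
#'   single-obstacle runs use.
#' @return object of class `channel_device`.
#' @export
channel_device <- function(gap, height, rows = 2, per_row = 1,
                           row_spacing = 8, base = gap, body_force = 0.05,
                           stagger = FALSE) {
  pitch <- base + gap
  stopifnot(gap > 0, gap < pitch, height > 0, rows >= 1)
  structure(list(gap = gap, height = height, rows = rows, per_row = per_row,
                 row_spacing = row_spacing, base = base, pitch = pitch,
                 width = per_row * pitch, length = rows * row_spacing,
                 body_force = body_force, stagger = stagger),
            class = "channel_device")
}

#' @param gap_um gap size in micrometres (10, 12 or 15 in the experiments).
#' @param units a [unit_map()].
#' @param base_um obstacle base width in micrometres (the gap and row
#'   spacing are the documented device dimensions; the obstacle size beyond
#'   them is configurable).
#' @rdname channel_device
#' @export
channel_device_paper <- function(gap_um = 12, units = unit_map(),
                                 base_um = 20, body_force = 0.05) {
  s <- 1 / units$length_um
  channel_device(gap = gap_um * s, height = 28 * s, rows = 10, per_row = 10,
                 row_spacing = 60 * s, base = base_um * s,
                 body_force = body_force, stagger = TRUE)
}

# obstacle triangle list of a device (xy-plane, prisms along z)
device_obstacles <- function(dev) {
  tri <- NULL
  h <- dev$base * sqrt(3) / 2
  for (r in seq_len(dev$rows)) {
    xr <- (r - 0.5) * dev$row_spacing
    off <- if (isTRUE(dev$stagger) && r %% 2 == 0) 0.5 else 0
    for (k in seq_len(dev$per_row)) {
      ykc <- (k - 0.5 + off) * dev$pitch
      yk <- ((ykc - 1e-9) %% dev$width) + 0  # wrap into the periodic width
      tri <- rbind(tri, c(xr - h / 2, yk,
                          xr + h / 2, yk - dev$base / 2,
                          xr + h / 2, yk + dev$base / 2))
    }
  }
  tri
}

build_channel_scene <- function(dev, density = 3, rc = 1, cell = NULL) {
  box <- c(dev$length, dev$width, dev$height + 2 * rc)
  z0 <- rc
  z1 <- rc + dev$height
  tri <- device_obstacles(dev)
  inside_any <- function(p) {
    ins <- rep(FALSE, nrow(p))
    for (q in seq_len(nrow(tri))) {
      a <- tri[q, 1:2]; b <- tri[q, 3:4]; cc <- tri[q, 5:6]
      d1 <- (b[1] - a[1]) * (p[, 2] - a[2]) - (b[2] - a[2]) * (p[, 1] - a[1])
      d2 <- (cc[1] - b[1]) * (p[, 2] - b[2]) - (cc[2] - b[2]) * (p[, 1] - b[1])
      d3 <- (a[1] - cc[1]) * (p[, 2] - cc[2]) - (a[2] - cc[2]) * (p[, 1] - cc[1])
      ins <- ins | (d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0)
    }
    ins
  }
  fluid <- fill_region(c(0, 0, z0), c(box[1], box[2], z1), density = density,
                       keep = function(p) !inside_any(p))
  plates <- rbind(
    fill_region(c(0, 0, 0), c(box[1], box[2], z0), density = density),
    fill_region(c(0, 0, z1), c(box[1], box[2], box[3]), density = density))
  obst <- fill_region(c(0, 0, z0), c(box[1], box[2], z1), density = density,
                      keep = inside_any)
  pos <- rbind(fluid, plates, obst)
  types <- c(rep("fluid", nrow(fluid)), rep("wall", nrow(plates) + nrow(obst)))
  walls <- list(wall_slab("z", z0, z1), wall_obstacles(tri))
  list(pos = pos, types = types, box = box, walls = walls, z0 = z0, z1 = z1,
       tri = tri)
}


# cell-free mean axial fluid velocity in the device at a given body force
channel_mean_velocity <- function(device, f, seed = 1L, t_run = 10, dt = 0.005,
                                  density = 3, kBT = 0.02, a_fluid = 25) {
  scene <- with_seed(seed, build_channel_scene(device, density))
  aij <- matrix(a_fluid, 4, 4, dimnames = list(PARTICLE_TYPES, PARTICLE_TYPES))
  params <- dpd_params(kBT = kBT, dt = dt, aij = aij)
  sys <- particle_system(scene$pos, types = scene$types, box = scene$box)
  bf <- list(mode = "uniform", dir = c(1, 0, 0), t = c(0, 1), f = c(f, f))
  r <- dpd_run(sys, params, nsteps = ceiling(t_run / dt), seed = seed,
               walls = scene$walls, body_force = bf, sample_every = 25L,
               measure = "fluid_velocity")
  v <- r$trace$fluid_vx
  mean(tail(v, ceiling(length(v) / 2)))
}

#' Calibrate the channel driving force to a target mean fluid velocity
#'
#' Runs the cell-free device and adjusts the uniform body force by secant
#' iteration until the mean axial fluid velocity matches the target within
#' the tolerance.  In the low-Reynolds regime the response is linear, so
#' convergence takes a couple of iterations.
#'
#' @param device a [channel_device()].
#' @param target_velocity target mean axial fluid velocity (simulation
#'   units).
#' @param seed engine seed.
#' @param tol relative tolerance (default 2%).
#' @param max_iter maximum secant iterations.
#' @param t_run simulated duration per evaluation.
#' @param dt time step.
#' @param density fluid number density.
#' @param kBT thermal energy of the calibration fluid.
#' @param a_fluid conservative coefficient of the instrument's fluid.
#' @return calibrated per-particle force, with attributes
#'   `achieved_velocity` and `iterations`.
#' @export
calibrate_body_force <- function(device, target_velocity, seed = 1L,
                                 tol = 0.02, max_iter = 8, t_run = 15,
                                 dt = 0.005, density = 3, kBT = 0.02,
                                 a_fluid = 25) {
  if (target_velocity == 0) return(structure(0, achieved_velocity = 0, iterations = 0L))
  measure_v <- function(f, sd) {
    channel_mean_velocity(device, f, seed = sd, t_run = t_run, dt = dt,
                          density = density, kBT = kBT, a_fluid = a_fluid)
  }
  f1 <- device$body_force
  v1 <- measure_v(f1, seed)
  if (abs(v1 - target_velocity) <= tol * abs(target_velocity))
    return(structure(f1, achieved_velocity = v1, iterations = 1L))
  f2 <- f1 * target_velocity / max(v1, 1e-12)
  for (it in seq_len(max_iter)) {
    v2 <- measure_v(f2, seed + it)
    if (abs(v2 - target_velocity) <= tol * abs(target_velocity))
      return(structure(f2, achieved_velocity = v2, iterations = it + 1L))
    slope <- (v2 - v1) / (f2 - f1)
    f1 <- f2; v1 <- v2
    f2 <- f2 + (target_velocity - v2) / slope
    if (f2 <= 0) f2 <- f1 / 2
  }
  stop("body-force calibration did not converge in ", max_iter, " iterations")
}

#' Drive a cell through the obstacle channel
#'
#' Immerses the cell in the flowing device, fully coupled to the DPD fluid,
#' and measures the transit velocity (axial center-of-mass displacement per
#' time), the total transit time over the simulated span, and the
#' relaxation time: after each gap passage, the time until the cell's
#' asphericity returns to within 5% (of the deformation excursion) of its
#' pre-gap baseline.
#'
#' @param cell a [build_cell()] model (diameter should exceed the gap for a
#'   squeezing transit).
#' @param device a [channel_device()] with a calibrated `body_force`.
#' @param seed engine seed.
#' @param t_end simulated duration.
#' @param dt time step.
#' @param sample_every measurement stride.
#' @param density fluid number density.
#' @param units a [unit_map()] for reporting physical velocities.
#' @param relax_frac recovery threshold as a fraction of the asphericity
#'   excursion (default 0.05).
#' @param a_fluid,a_wall_membrane conservative coefficients, as in
#'   [run_aspiration()].
#' @return object of class `transit_measurement`: list with
#'   `transit_velocity` (sim), `transit_velocity_mm_s`, `transit_time`,
#'   `relaxation_time`, `ratio` (relaxation/transit), `status`, `trace`.
#' @export
run_channel_flow <- function(cell, device, seed = 1L, t_end = 120, dt = 0.005,
                             sample_every = 40L, density = 3,
                             units = cell$units, relax_frac = 0.05,
                             a_fluid = 25, a_wall_membrane = 0) {
  scene <- with_seed(seed, build_channel_scene(device, density))
  n_env <- nrow(scene$pos)
  mpos <- cell_positions(cell)
  # start upstream, aligned with the gap of row 1, mid-height
  gap_y <- device$pitch * ceiling(device$per_row / 2)  # between obstacle centers
  start <- c(cell$radius + 0.6, gap_y %% device$width, scene$z0 + device$height / 2)
  mpos <- sweep(mpos, 2, start - cell$center, "+")
  pos <- rbind(scene$pos, mpos)
  types <- c(scene$types, cell_types(cell))
  mems <- offset_membranes(cell, n_env)
  kvb <- cell_kv_bonds(cell)
  kvb$i <- kvb$i + n_env
  kvb$j <- kvb$j + n_env
  aij <- instrument_aij(a_fluid, a_wall_membrane)
  params <- dpd_params(kBT = cell$outer$params$kBT, dt = dt, aij = aij)
  sys <- particle_system(pos, types = types, box = scene$box)
  f <- device$body_force
  bf <- list(mode = "uniform", dir = c(1, 0, 0), t = c(0, 1), f = c(f, f))
  res <- dpd_run(sys, params, nsteps = ceiling(t_end / dt), seed = seed,
                 membranes = mems, kv_bonds = kvb, walls = scene$walls,
                 body_force = bf, sample_every = sample_every,
                 measure = c("com", "asphericity", "membranes",
                             "fluid_velocity"))
  tr <- res$trace
  n <- nrow(tr)
  dx <- tr$com_x[n] - tr$com_x[1]
  ttime <- tr$time[n] - tr$time[1]
  vtransit <- dx / ttime
  # clog detection: negligible advance over the trailing quarter
  tail_idx <- tr$time >= tr$time[n] - 0.25 * ttime
  status <- res$status
  if ((tr$com_x[n] - min(tr$com_x[tail_idx])) < 0.05 * cell$radius)
    status <- "clogged"
  relax <- channel_relaxation(tr, device, cell, relax_frac)
  structure(list(transit_velocity = vtransit,
                 transit_velocity_mm_s = vtransit * units$velocity_mm_s,
                 transit_time = ttime, relaxation_time = relax$time,
                 ratio = if (is.na(relax$time)) NA_real_ else
                   min(1, relax$time / ttime),
                 n_gap_passages = relax$n_events, status = status,
                 trace = tr),
            class = "transit_measurement")
}

# relaxation time from the asphericity time series: for each obstacle-row
# passage, the time from gap exit until the (smoothed) asphericity returns
# to within relax_frac of the deformation excursion above baseline
channel_relaxation <- function(tr, device, cell, relax_frac = 0.05) {
  h <- device$base * sqrt(3) / 2
  centers <- (seq_len(device$rows) - 0.5) * device$row_spacing
  k5 <- 5
  asph <- stats::filter(tr$asphericity, rep(1 / k5, k5), sides = 2)
  asph[is.na(asph)] <- tr$asphericity[is.na(asph)]
  pre <- tr$com_x < centers[1] - h / 2 - cell$radius
  baseline <- if (sum(pre) >= 3) mean(asph[pre]) else min(asph)
  times <- c()
  for (xc in centers) {
    overlap <- tr$com_x > xc - h / 2 - cell$radius &
      tr$com_x < xc + h / 2 + cell$radius
    if (sum(overlap) < 2) next
    peak <- max(asph[overlap])
    k <- which(tr$com_x > xc + h / 2 + 0.5 * cell$radius)[1]
    if (is.na(k)) next
    thr <- baseline + relax_frac * max(peak - baseline, 1e-12)
    rec <- which(asph[k:length(asph)] <= thr)[1]
    if (!is.na(rec)) times <- c(times, tr$time[k + rec - 1] - tr$time[k])
  }
  list(time = if (length(times)) mean(times) else NA_real_,
       n_events = length(times))
}

#' @export
print.transit_measurement <- function(x, ...) {
  cat(sprintf("<transit_measurement> v = %.4g sim (%.3g mm/s), transit %.4g,",
              x$transit_velocity, x$transit_velocity_mm_s, x$transit_time))
  cat(sprintf(" relax %.4g, ratio %.3g [%s]\n",
              x$relaxation_time, x$ratio, x$status))
  invisible(x)
}
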