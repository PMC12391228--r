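#' Mapping between simulation and physical units
#'
#' The model is formulated in reduced simulation units; this object fixes
#' the nominal conversion used by the virtual instruments: `length_um`
#' (micrometres per length unit), `pressure_Pa` (pascals per pressure unit)
#' and `time_s` (seconds per time unit).  Derived factors: velocities map by
#' `length_um / time_s` and viscosities by `pressure_Pa * time_s`.  The
#' defaults are a nominal mapping adequate for scaled (reduced-resolution)
#' studies; quantitative full-scale work should calibrate them against the
#' fluid viscosity and the cell's measured moduli.
#'
#' @param length_um micrometres per simulation length unit.
#' @param pressure_Pa pascals per simulation pressure unit.
#' @param time_s seconds per simulation time unit.
#' @return object of class `unit_map` with derived conversion factors.
#' @export
unit_map <- function(length_um = 1, pressure_Pa = 6, time_s = 1e-5) {
  stopifnot(length_um > 0, pressure_Pa > 0, time_s > 0)
  structure(list(length_um = length_um, pressure_Pa = pressure_Pa,
                 time_s = time_s,
                 velocity_mm_s = length_um * 1e-3 / time_s,
                 viscosity_Pa_s = pressure_Pa * time_s),
            class = "unit_map")
}

#' @export
print.unit_map <- function(x, ...) {
  cat(sprintf(paste0("<unit_map> 1 sim length = %g um, 1 sim pressure = %g Pa, ",
                     "1 sim time = %g s\n"), x$length_um, x$pressure_Pa, x$time_s))
  invisible(x)
}
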