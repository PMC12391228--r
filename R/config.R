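#' Default run configuration
#'
#' Returns the full configuration tree with every parameter at its
#' calibrated default (simulation units): membrane blocks for cell and
#' nucleus (persistence length 0.00141, viscosity gamma 4, k_A 10000/5000,
#' k_V 15000, l_max 3/1.2, l_0 0.5, bending stiffness 65/250), the
#' nuclear-cytoplasmic ratio 0.29, and the cytoskeleton/nucleus network
#' block (k_s 120, nucleus k_s 600 via the five-fold stiffness rule, k_v 10,
#' bond density rho 0.8, topology M2 with w = 5).
#'
#' @return nested named list (class `cellflow_config`).
#' @export
default_config <- function() {
  structure(list(
    schema = "cellflow-config/1",
    seed = 1L,
    resolution = "scaled",
    output_dir = ".",
    cell = list(
      diameter_um = 16,
      nuclear_cytoplasmic_ratio = 0.29,
      ratio_mode = "volume"
    ),
    membrane = list(
      cell = list(persistence_length = 0.00141, gamma = 4, k_A = 10000,
                  k_V = 15000, l_max = 3, l_0 = 0.5,
                  bending_stiffness = 65, theta_0 = 0),
      nucleus = list(persistence_length = 0.00141, gamma = 4, k_A = 5000,
                     k_V = 15000, l_max = 1.2, l_0 = 0.5,
                     bending_stiffness = 250, theta_0 = 0)
    ),
    cytoskeleton = list(k_s = 120, k_v = 10, rho = 0.8, w = 5L,
                        topology = "M2", strain_based = TRUE),
    nucleus_network = list(k_s = NULL, k_v = NULL, rho = 0.8),
    dpd = list(kBT = 0.02, r_c = 1, gamma = 4.5, s = 0.75, dt = 0.01,
               lambda = 0.5, a_fluid_fluid = NULL),
    units = list(length_um = 1, pressure_Pa = 6, time_s = 1e-5),
    aspiration = list(pipette_diameter_um = 4.25, ramp_rate_Pa_s = 3.27,
                      max_pressure_Pa = 117.72, creep_pressure_Pa = 90)
  ), class = "cellflow_config")
}

# recursive merge with unknown-key detection; returns value + provenance
merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = "$")
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    dv <- defaults[[key]]
    uv <- user[[key]]
    if (is.list(dv) && !is.null(names(dv))) {
      if (!is.list(uv)) stop("configuration key ", full, " must be a block")
      defaults[[key]] <- merge_config(dv, uv, c(path, key))
    } else {
      if (!is.null(dv) && !is.null(uv) &&
          !identical(class(uv), class(dv)) &&
          !(is.numeric(uv) && is.numeric(dv)))
        stop("type mismatch for configuration key ", full, ": expected ",
             class(dv)[1], ", got ", class(uv)[1])
      defaults[[key]] <- uv
      attr(defaults, "user_set") <- c(attr(defaults, "user_set"), key)
    }
  }
  defaults
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg)
  for (kind in c("cell", "nucleus")) {
    m <- cfg$membrane[[kind]]
    chk(m$persistence_length > 0, paste(kind, "persistence_length must be > 0"))
    chk(m$l_0 > 0 && m$l_0 < m$l_max,
        paste(kind, "requires 0 < l_0 < l_max"))
    chk(m$k_A >= 0 && m$k_V >= 0 && m$bending_stiffness >= 0,
        paste(kind, "constraint/bending coefficients must be >= 0"))
  }
  chk(cfg$cytoskeleton$rho > 0, "cytoskeleton rho must be > 0")
  chk(cfg$nucleus_network$rho > 0, "nucleus_network rho must be > 0")
  chk(cfg$cytoskeleton$w >= 1, "cytoskeleton w must be >= 1")
  chk(cfg$cell$nuclear_cytoplasmic_ratio > 0 &&
        cfg$cell$nuclear_cytoplasmic_ratio < 1,
      "nuclear_cytoplasmic_ratio must be in (0, 1)")
  chk(cfg$dpd$kBT > 0 && cfg$dpd$dt > 0 && cfg$dpd$r_c > 0 && cfg$dpd$s > 0,
      "dpd block requires positive kBT, dt, r_c, s")
  invisible(cfg)
}

#' Load a run configuration from a YAML file
#'
#' Unset keys take the documented defaults; unknown keys are rejected with
#' an error naming the full key path.  The five-fold nucleus stiffness rule
#' is applied automatically: unless `nucleus_network$k_s` is set explicitly,
#' it becomes `5 * cytoskeleton$k_s`, and `nucleus_network$k_v` defaults to
#' `cytoskeleton$k_v`.  The fully resolved configuration is echoed (as a
#' message) with each key's provenance.
#'
#' @param path YAML file; `NULL` or a missing/empty file yields the
#'   defaults.
#' @param quiet suppress the provenance echo.
#' @return resolved configuration (class `cellflow_config`).
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  cfg <- default_config()
  user <- list()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  cfg <- merge_config(cfg, user)
  user_keys <- collect_user_keys(user)
  # five-fold nucleus stiffness rule
  if (is.null(cfg$nucleus_network$k_s))
    cfg$nucleus_network$k_s <- 5 * cfg$cytoskeleton$k_s
  if (is.null(cfg$nucleus_network$k_v))
    cfg$nucleus_network$k_v <- cfg$cytoskeleton$k_v
  if (is.null(cfg$dpd$a_fluid_fluid))
    cfg$dpd$a_fluid_fluid <- 25 * cfg$dpd$kBT / cfg$dpd$r_c
  validate_config(cfg)
  class(cfg) <- "cellflow_config"
  if (!quiet) {
    flat <- flatten_config(cfg)
    prov <- ifelse(names(flat) %in% user_keys, "user", "default")
    message("resolved configuration:\n",
            paste0("  ", names(flat), " = ", unlist(flat), "  [", prov, "]",
                   collapse = "\n"))
  }
  cfg
}

collect_user_keys <- function(x, path = character()) {
  out <- character()
  for (key in names(x)) {
    v <- x[[key]]
    if (is.list(v) && !is.null(names(v)))
      out <- c(out, collect_user_keys(v, c(path, key)))
    else out <- c(out, paste(c(path, key), collapse = "$"))
  }
  out
}

flatten_config <- function(x, path = character()) {
  out <- list()
  for (key in names(x)) {
    v <- x[[key]]
    if (is.list(v) && !is.null(names(v))) {
      out <- c(out, flatten_config(v, c(path, key)))
    } else {
      out[[paste(c(path, key), collapse = "$")]] <-
        if (is.null(v)) "NULL" else paste(v, collapse = ",")
    }
  }
  out
}

#' Build a cell model from a configuration
#'
#' @param cfg a [load_config()] / [default_config()] configuration.
#' @param diameter_um optional diameter override (micrometres).
#' @return a [build_cell()] model.
#' @export
cell_from_config <- function(cfg, diameter_um = NULL) {
  stopifnot(inherits(cfg, "cellflow_config"))
  mc <- cfg$membrane$cell
  mn <- cfg$membrane$nucleus
  pc <- membrane_params("cell", p = mc$persistence_length, gamma = mc$gamma,
                        ka = mc$k_A, kvol = mc$k_V, lmax = mc$l_max,
                        l0 = mc$l_0, kb = mc$bending_stiffness,
                        theta0 = mc$theta_0, kBT = cfg$dpd$kBT)
  pn <- membrane_params("nucleus", p = mn$persistence_length, gamma = mn$gamma,
                        ka = mn$k_A, kvol = mn$k_V, lmax = mn$l_max,
                        l0 = mn$l_0, kb = mn$bending_stiffness,
                        theta0 = mn$theta_0, kBT = cfg$dpd$kBT)
  topo <- topology_spec(cfg$cytoskeleton$topology, w = cfg$cytoskeleton$w,
                        rho = cfg$cytoskeleton$rho)
  units <- unit_map(cfg$units$length_um, cfg$units$pressure_Pa,
                    cfg$units$time_s)
  cell <- build_cell(diameter = diameter_um %||% cfg$cell$diameter_um,
                     nc_ratio = cfg$cell$nuclear_cytoplasmic_ratio,
                     ks = cfg$cytoskeleton$k_s, kv_damp = cfg$cytoskeleton$k_v,
                     topology = topo, rho_nucl = cfg$nucleus_network$rho,
                     params_cell = pc, params_nucleus = pn, units = units,
                     ratio_mode = cfg$cell$ratio_mode, seed = cfg$seed)
  # honor an explicit nucleus-network stiffness override
  if (!is.null(cfg$nucleus_network$k_s)) {
    cell$nucleus_bonds$ks <- cfg$nucleus_network$k_s
    cell$ks_nuc <- cfg$nucleus_network$k_s
  }
  if (!is.null(cfg$nucleus_network$k_v))
    cell$nucleus_bonds$kv <- cfg$nucleus_network$k_v
  cell
}
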