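#' Run configuration files
#'
#' A run is fully described by a YAML document with the sections
#' `constants`, `species`, `morphology`, `protocol`, `settings`,
#' `phi_rest`, `calibrate_n0` and `influx_species`; every field has a
#' default (the standard parameter set: T = 310 K, c_m = 0.01 F/m^2, Na/K/Cl
#' at 10/140/10 mM, the reference 5/5/4 morphology, dt = 0.1 ns), so an
#' empty file is a valid configuration. Unknown keys are rejected, units
#' are SI throughout.
#'
#' @param path Path to a YAML file.
#' @return An object of class `run_config` (validated, defaults filled,
#'   with a content hash in attribute `"hash"`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  as_run_config(raw)
}

#' @rdname load_config
#' @param config A list of overrides (possibly empty).
#' @export
as_run_config <- function(config = list()) {
  defaults <- default_config()
  known <- names(defaults)
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  cfg <- defaults
  for (nm in names(config)) {
    if (nm %in% c("protocol", "species")) {
      # ordered, unnamed lists: a user-supplied value replaces the default
      cfg[[nm]] <- config[[nm]]
    } else if (is.list(defaults[[nm]]) && is.list(config[[nm]])) {
      cfg[[nm]] <- modifyList(defaults[[nm]], config[[nm]])
    } else {
      cfg[[nm]] <- config[[nm]]
    }
  }
  validate_config(cfg)
  attr(cfg, "hash") <- rlang::hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

default_config <- function() {
  ref <- reference_spine()
  list(
    schema_version = 1L,
    constants = list(T = 310, c_m = 0.01),
    species = list(
      list(name = "Na", z = 1L, D = 0.65e-9, n_rest = 10),
      list(name = "K", z = 1L, D = 1.0e-9, n_rest = 140),
      list(name = "Cl", z = -1L, D = 1.0e-9, n_rest = 10)),
    morphology = list(n_head = 5L, n_neck = 5L, n_dend = 4L, h = 0.1e-6,
                      radius_head = ref$geometry$a[1],
                      radius_neck = 35e-9, radius_dend = 0.25e-6),
    protocol = list(list(duration = 10e-3, I_in = 25e-12, clamp = 0),
                    list(duration = 40e-3, I_in = 0, clamp = 0)),
    settings = list(dt = 1e-10, record_dt = 1e-6, guard_phi = 1),
    phi_rest = -70e-3,
    calibrate_n0 = TRUE,
    influx_species = "Na")
}

validate_config <- function(cfg) {
  m <- cfg$morphology
  check <- function(ok, field)
    if (!isTRUE(all(ok))) stop("invalid configuration field: ", field)
  check(cfg$constants$T > 0, "constants.T")
  check(cfg$constants$c_m > 0, "constants.c_m")
  check(m$h > 0, "morphology.h")
  check(m$radius_head > 0, "morphology.radius_head")
  check(m$radius_neck > 0, "morphology.radius_neck")
  check(m$radius_dend > 0, "morphology.radius_dend")
  check(m$n_head >= 1 && m$n_dend >= 1, "morphology.n_head/n_dend")
  for (s in cfg$species) {
    check(s$D > 0, paste0("species.", s$name, ".D"))
    check(s$n_rest >= 0, paste0("species.", s$name, ".n_rest"))
  }
  for (p in cfg$protocol) check(p$duration > 0, "protocol.duration")
  check(cfg$settings$dt > 0, "settings.dt")
  check(cfg$influx_species %in%
          vapply(cfg$species, `[[`, character(1), "name"),
        "influx_species")
  invisible(cfg)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run a simulation from a configuration
#'
#' @param config A `run_config` (see [load_config()]).
#' @return A `spine_trajectory`; the configuration hash is stored in
#'   attribute `"config_hash"`.
#' @export
run_config_simulation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  const <- physical_constants(config$constants$T, config$constants$c_m)
  species <- lapply(config$species, function(s)
    ion_species(s$name, s$z, s$D, s$n_rest))
  names(species) <- vapply(species, `[[`, character(1), "name")
  m <- config$morphology
  geom <- spine_geometry(m$n_head, m$n_neck, m$n_dend, m$h,
                         m$radius_head, m$radius_neck, m$radius_dend)
  prot <- protocol(lapply(config$protocol, function(p)
    protocol_phase(p$duration, p$I_in %||% 0, p$clamp %||% 0)))
  st <- config$settings
  traj <- run_simulation(
    geom, prot, species = species, const = const,
    phi_rest = config$phi_rest,
    settings = solver_settings(dt = st$dt,
                               record_dt = st$record_dt %||% 1e-6,
                               guard_phi = st$guard_phi %||% 1),
    influx_species = config$influx_species,
    calibrate_n0 = config$calibrate_n0)
  attr(traj, "config_hash") <- attr(config, "hash")
  traj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trajectory CSV serialization
#'
#' Writes/reads the recorded time series in a stable column layout:
#' `time_ms`, then `phi_mV_<segment>` and `<species>_mM_<segment>`.
#' Identical configurations produce bit-identical files (the solver is
#' deterministic).
#'
#' @param traj A `spine_trajectory`.
#' @param path Output file.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @return `read_trajectory`: a data frame (not a full trajectory object).
#' @export
read_trajectory <- function(path) {
  read.csv(path, check.names = FALSE)
}

#' Summarize a run
#'
#' Headline metrics of a trajectory: stability status, rest potential,
#' final and peak head depolarization, boost metrics where the protocol
#' has an injection phase, the drift resistance at the start and end, and
#' the voltage-divider neck resistance at the end of the injection.
#'
#' @param traj A `spine_trajectory`.
#' @return A list (JSON-ready) of metrics in mV/MOhm/ms.
#' @export
summarize_run <- function(traj) {
  N <- traj$geom$n_seg
  head_depol_mV <- (traj$phi[, 1] - traj$phi_rest) * 1e3
  out <- list(
    status = traj$status,
    config_hash = attr(traj, "config_hash"),
    phi_rest_mV = traj$phi_rest * 1e3,
    duration_ms = max(traj$times) * 1e3,
    peak_head_depol_mV = max(head_depol_mV),
    final_head_depol_mV = head_depol_mV[length(traj$times)],
    R_e_start_MOhm = cumulative_resistance(traj, t = 0)$total / 1e6,
    R_e_end_MOhm = cumulative_resistance(traj)$total / 1e6)
  inj <- which(traj$phases$I_in != 0)[1]
  if (!is.na(inj) && traj$status == "stable") {
    # clip the Ohmic sampling time into the injection phase for short runs
    t_ohm <- min(traj$phases$t_start[inj] + 10e-6,
                 traj$phases$t_end[inj])
    bm <- boost_metrics(traj, t_ohm = t_ohm)
    out$V_ohm_mV <- (bm$V_ohm - traj$phi_rest) * 1e3
    out$V_diff_mV <- (bm$V_diff - traj$phi_rest) * 1e3
    out$B <- bm$B
    out$R_n_MOhm <- voltage_divider_neck_resistance(
      traj, I_syn = traj$phases$I_in[inj],
      t = traj$phases$t_end[inj]) / 1e6
  }
  out
}

#' @rdname summarize_run
#' @param path Output JSON file.
#' @export
write_run_summary <- function(traj, path) {
  jsonlite::write_json(summarize_run(traj), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
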