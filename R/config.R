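# Key-value run configuration (YAML).  A config describes a full protocol:
# molecule, force field, thermostat/barostat, optional REMD ladder and
# analysis windows.  Unknown keys are rejected; every applied default is
# recorded so a dumped config reproduces the run.

config_schema <- function() {
  list(
    sequence = list(type = "character", required = TRUE),
    molecule_kind = list(type = "character", default = "protein",
                         choices = c("protein", "rna", "dna")),
    force_field = list(type = "character", required = TRUE,
                       choices = c("hps_urry", "hps_kr", "mpipi", "moff",
                                   "mrg_dna")),
    hps_mu = list(type = "numeric", default = 1),
    hps_delta = list(type = "numeric", default = 0.08),
    salt_mM = list(type = "numeric", default = 100),
    dielectric = list(type = "numeric", default = 80),
    temperature_K = list(type = "numeric", default = 300),
    thermostat = list(type = "character", default = "langevin_middle",
                      choices = c("langevin_middle", "nose_hoover")),
    friction_per_ps = list(type = "numeric", default = 1),
    timestep_ps = list(type = "numeric", default = 0.01),
    n_steps = list(type = "numeric", default = 1e5),
    seed = list(type = "numeric", default = 1),
    n_copies = list(type = "numeric", default = 1),
    box_nm = list(type = "numeric", default = 75, length = c(1, 3)),
    compress_pressure_bar = list(type = "numeric", default = NA),
    compress_temperature_K = list(type = "numeric", default = 150),
    compress_steps = list(type = "numeric", default = 0),
    anneal_from_K = list(type = "numeric", default = NA),
    anneal_steps = list(type = "numeric", default = 0),
    slab_box_nm = list(type = "numeric", default = NA, length = c(1, 3)),
    remd_ladder_K = list(type = "numeric", default = NA, length = NA),
    remd_exchange_interval = list(type = "numeric", default = 1000),
    dense_halfwidth_nm = list(type = "numeric", default = 5),
    dilute_min_z_nm = list(type = "numeric", default = 50),
    bin_width_nm = list(type = "numeric", default = 1),
    cluster_cutoff_nm = list(type = "numeric", default = 5),
    traj_stride = list(type = "numeric", default = 1e4),
    energy_stride = list(type = "numeric", default = 1e3))
}

#' Load and validate a run configuration
#'
#' Reads a YAML key-value file, rejects unknown keys, fills and records
#' documented defaults, and validates values (e.g. a REMD ladder must be
#' strictly increasing).
#'
#' @param path YAML file path.
#' @return A validated `slabsim_config` (named list); the applied
#'   defaults are in `attr(, "defaults_applied")`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  schema <- config_schema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  out <- list(); applied <- character()
  for (key in names(schema)) {
    sc <- schema[[key]]
    if (!is.null(raw[[key]])) {
      val <- raw[[key]]
      if (sc$type == "numeric") val <- as.numeric(val)
      if (!is.null(sc$choices) && !val %in% sc$choices)
        stop(sprintf("config key %s must be one of: %s", key,
                     paste(sc$choices, collapse = ", ")))
      out[[key]] <- val
    } else if (isTRUE(sc$required)) {
      stop("missing required configuration key: ", key)
    } else {
      out[[key]] <- sc$default
      applied <- c(applied, key)
    }
  }
  if (!anyNA(out$remd_ladder_K) && length(out$remd_ladder_K) > 1 &&
      any(diff(out$remd_ladder_K) <= 0))
    stop("remd_ladder_K must be strictly increasing")
  for (key in c("timestep_ps", "temperature_K", "friction_per_ps"))
    if (any(out[[key]] <= 0)) stop(key, " must be positive")
  structure(out, defaults_applied = applied, class = "slabsim_config")
}

#' Write a configuration back to YAML
#'
#' `load_config(dump_config(cfg))` is idempotent.
#'
#' @param config A `slabsim_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  vals <- unclass(config)
  vals <- vals[!vapply(vals, function(v) length(v) == 1 && is.na(v),
                       logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @export
print.slabsim_config <- function(x, ...) {
  cat("slabsim_config:\n")
  for (k in names(x))
    if (!(length(x[[k]]) == 1 && is.na(x[[k]])))
      cat(sprintf("  %s: %s\n", k, paste(x[[k]], collapse = ", ")))
  def <- attr(x, "defaults_applied")
  if (length(def))
    cat("  (defaults applied:", paste(def, collapse = ", "), ")\n")
  invisible(x)
}

config_force_field <- function(cfg) {
  el <- electrostatics_spec(salt_mM = cfg$salt_mM,
                            temperature_K = cfg$temperature_K,
                            dielectric = cfg$dielectric)
  switch(cfg$force_field,
         hps_urry = load_hps("Urry", mu = cfg$hps_mu, delta = cfg$hps_delta,
                             electrostatics = el),
         hps_kr = load_hps("KR", mu = cfg$hps_mu, delta = 0,
                           electrostatics = el),
         mpipi = load_mpipi(electrostatics = el),
         moff = load_moff(electrostatics = el),
         mrg_dna = load_mrg_dna(electrostatics = el))
}
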