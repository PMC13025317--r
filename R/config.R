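#' Default run configuration
#'
#' The baseline configuration: the 50 x 20 domain, weakest screening of the
#' sweep range (kappa = 0.001), drive amplitude 0.01 in the linear-response
#' regime, auto time step (one fifth of the stability bound), zero-mean
#' charge normalization, and a logarithmic frequency grid straddling the
#' domain's dispersion knee. Scale factors map numerical units to physical
#' ones at reporting time only (they never enter the stepper):
#' `length_per_cell` (metres per grid cell) and `time_per_unit` (seconds per
#' numerical time unit; frequencies are labelled Hz under this factor).
#'
#' @return A nested list of class `"edisim_config"`.
#' @export
default_config <- function() {
  structure(list(
    grid = list(nx = 50L, ny = 20L, h = 1),
    model = list(kappa = 0.001, amplitude = 0.01, dt = NULL,
                 normalization = "zero-mean"),
    sweep = list(fmin = 1e-4, fmax = 1e-1, points_per_decade = 3L,
                 frequencies = NULL,
                 transient_periods = 5, measure_periods = 4,
                 min_samples_per_period = 32L, settle_efolds = 4,
                 min_window_steps = 200L),
    kappas = c(0.001, 0.002, 0.003, 0.004, 0.005),
    nx_values = c(25L, 50L, 100L),
    seed = 1L,
    output = "sweep.csv",
    scale = list(length_per_cell = 1, time_per_unit = 1)
  ), class = "edisim_config")
}

# Recursively check that every key of x exists in template; returns the
# first unknown key path or NULL.
unknown_key <- function(x, template, path = character()) {
  for (nm in names(x)) {
    if (!nm %in% names(template)) return(paste(c(path, nm), collapse = "."))
    if (is.list(x[[nm]]) && is.list(template[[nm]]) && !is.null(names(x[[nm]]))) {
      bad <- unknown_key(x[[nm]], template[[nm]], c(path, nm))
      if (!is.null(bad)) return(bad)
    }
  }
  NULL
}

#' Validate a configuration
#'
#' Checks every constraint of the underlying objects (grid, model
#' parameters, protocol, frequencies, scale factors) before any
#' computation, naming the offending key.
#'
#' @param config an `"edisim_config"` list.
#' @return `config`, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(config) {
  ck <- function(ok, key, msg) {
    if (!ok) stop_edisim("edisim_config_error", sprintf("config key '%s': %s", key, msg))
  }
  grid <- tryCatch(grid_spec(config$grid$nx, config$grid$ny, config$grid$h),
                   error = function(e)
                     stop_edisim("edisim_config_error",
                                 sprintf("config key 'grid': %s", conditionMessage(e))))
  params <- tryCatch(model_params(config$model$kappa, config$model$amplitude,
                                  config$model$dt, config$model$normalization),
                     error = function(e)
                       stop_edisim("edisim_config_error",
                                   sprintf("config key 'model': %s", conditionMessage(e))))
  # fail fast on an unstable dt, before any simulation
  tryCatch(resolve_dt(params, grid),
           error = function(e)
             stop_edisim("edisim_config_error",
                         sprintf("config key 'model.dt': %s", conditionMessage(e))))
  s <- config$sweep
  tryCatch(sweep_protocol(s$transient_periods, s$measure_periods,
                          s$min_samples_per_period, s$settle_efolds,
                          s$min_window_steps, config$seed),
           error = function(e)
             stop_edisim("edisim_config_error",
                         sprintf("config key 'sweep': %s", conditionMessage(e))))
  if (!is.null(s$frequencies)) {
    ck(all(s$frequencies > 0) && !is.unsorted(s$frequencies, strictly = TRUE),
       "sweep.frequencies", "must be positive and strictly increasing")
  } else {
    ck(is.numeric(s$fmin) && s$fmin > 0, "sweep.fmin", "must be > 0")
    ck(is.numeric(s$fmax) && s$fmax >= s$fmin, "sweep.fmax", "must be >= fmin")
    ck(s$points_per_decade >= 1, "sweep.points_per_decade", "must be >= 1")
  }
  ck(all(config$kappas >= 0), "kappas", "must be >= 0")
  ck(length(config$kappas) == 1L ||
       !is.unsorted(config$kappas, strictly = TRUE), "kappas", "must be ascending")
  ck(all(config$nx_values >= 3), "nx_values", "must be >= 3")
  ck(config$scale$length_per_cell > 0, "scale.length_per_cell", "must be > 0")
  ck(config$scale$time_per_unit > 0, "scale.time_per_unit", "must be > 0")
  invisible(config)
}

#' Load a run configuration from YAML
#'
#' Reads a (possibly partial) YAML configuration, fills unset keys from
#' [default_config()], rejects unknown keys loudly (naming the key path),
#' and validates every constraint before returning — an invalid time step
#' or grid fails here, not mid-simulation.
#'
#' @param path YAML file path.
#' @return A validated `"edisim_config"` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop_edisim("edisim_io_error", sprintf("no such config file: %s", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e)
                    stop_edisim("edisim_io_error",
                                sprintf("cannot parse %s: %s", path, conditionMessage(e))))
  if (is.null(raw)) raw <- list()
  defaults <- default_config()
  bad <- unknown_key(raw, defaults)
  if (!is.null(bad))
    stop_edisim("edisim_config_error", sprintf("unknown config key '%s'", bad))
  config <- utils::modifyList(defaults, raw)
  # YAML writes the auto time step as null and modifyList drops null
  # entries: restore the key so configs round-trip exactly
  if (!"dt" %in% names(config$model))
    config$model <- append(config$model, list(dt = NULL), after = 2L)
  if (!"frequencies" %in% names(config$sweep))
    config$sweep <- append(config$sweep, list(frequencies = NULL), after = 3L)
  class(config) <- "edisim_config"
  validate_config(config)
  config
}

#' Save a configuration to YAML
#'
#' Round-trips with [load_config()]: `load_config(save_config(x, p))` equals
#' `x`.
#'
#' @param config an `"edisim_config"` list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Materialize the frequency vector of a config.
config_frequencies <- function(config) {
  s <- config$sweep
  if (!is.null(s$frequencies)) as.numeric(s$frequencies)
  else log_frequency_grid(s$fmin, s$fmax, s$points_per_decade)
}

# Materialize grid/params/protocol from a config.
config_grid <- function(config)
  grid_spec(config$grid$nx, config$grid$ny, config$grid$h)
config_params <- function(config)
  model_params(config$model$kappa, config$model$amplitude, config$model$dt,
               config$model$normalization)
config_protocol <- function(config) {
  s <- config$sweep
  sweep_protocol(s$transient_periods, s$measure_periods,
                 s$min_samples_per_period, s$settle_efolds,
                 s$min_window_steps, config$seed)
}
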