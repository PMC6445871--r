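#' Default run configuration
#'
#' The full set of reference parameters as a nested list: neuron constants,
#' simulation grid, synapse initialization bounds, learning settings and
#' benchmark protocol. Every configuration file is merged over these
#' defaults, so an empty file yields exactly this list. The firing-rate
#' band of the adaptive learning rate is stored as the pair of factors
#' applied to the desired output rate (`r_band_factors`, default 0.8 and
#' 1.2).
#'
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    neuron = list(tau_psp = 2, tau_ref = 50, theta = 1, t_abs = 1),
    simulation = list(duration = 200, dt = 0.1),
    synapses = list(w_init_min = 0, w_init_max = 0.5, d_min = 0,
                    d_max = 15, clamp_weights = TRUE),
    learning = list(kernel_scale = 10, metric_scale = 5, eta_star = 0.005,
                    alpha = 3, r_band_factors = c(0.8, 1.2),
                    max_epochs = 500, adapt_weights = TRUE,
                    adapt_delays = TRUE),
    benchmark = list(n_inputs = 500, r_in = 20, r_out = 50, trials = 100,
                     seed_base = 0),
    output = list(dir = ".", verbosity = "info")),
    class = "run_config")
}

merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    here <- c(path, key)
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", paste(here, collapse = "$"),
           call. = FALSE)
    if (is.list(defaults[[key]])) {
      if (!is.list(user[[key]]))
        stop("configuration key ", paste(here, collapse = "$"),
             " must be a section", call. = FALSE)
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], here)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  with(cfg$neuron, srm_params(tau_psp, tau_ref, theta, t_abs))
  with(cfg$simulation, sim_config(duration, dt))
  with(cfg$synapses, {
    if (w_init_min > w_init_max)
      stop("w_init_min must not exceed w_init_max", call. = FALSE)
    if (d_min > d_max) stop("d_min must not exceed d_max", call. = FALSE)
  })
  with(cfg$learning, {
    if (eta_star <= 0) stop("eta_star must be positive", call. = FALSE)
    if (alpha < 0) stop("alpha must be non-negative", call. = FALSE)
    if (max_epochs < 1) stop("max_epochs must be at least 1", call. = FALSE)
    if (length(r_band_factors) != 2 ||
        r_band_factors[1] > r_band_factors[2])
      stop("r_band_factors must be an ordered pair", call. = FALSE)
  })
  with(cfg$benchmark, {
    if (n_inputs < 1) stop("n_inputs must be at least 1", call. = FALSE)
    if (r_in < 0 || r_out < 0)
      stop("firing rates must be non-negative", call. = FALSE)
    if (trials < 1) stop("trials must be at least 1", call. = FALSE)
  })
  cfg
}

#' Load and save run configurations
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON configuration file, merges it
#' over [default_run_config()] (so omitted fields fall back to the
#' reference defaults), rejects unknown keys by name, and validates
#' ranges. `save_config()` writes a config back as YAML; a written default
#' config re-loads identically.
#'
#' @param path Configuration file path.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  user <- tryCatch(
    if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e)
      stop("cannot parse configuration file ", path, ": ",
           conditionMessage(e), call. = FALSE))
  if (is.null(user)) user <- list()  # empty file
  cfg <- merge_config(default_run_config(), user)
  class(cfg) <- "run_config"
  validate_config(cfg)
}

#' @rdname load_config
#' @param config A `run_config` list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build a benchmark specification from a run configuration
#'
#' @param config A `run_config` list (see [load_config()]).
#' @return A [benchmark_spec()].
#' @export
config_to_spec <- function(config) {
  benchmark_spec(
    n_inputs = config$benchmark$n_inputs, r_in = config$benchmark$r_in,
    r_out = config$benchmark$r_out,
    duration = config$simulation$duration,
    trials = config$benchmark$trials,
    max_epochs = config$learning$max_epochs,
    seed_base = config$benchmark$seed_base,
    delay_mode = if (config$learning$adapt_delays) "dynamic" else "static",
    weight_mode = if (config$learning$adapt_weights) "dynamic" else
      "static",
    alpha = config$learning$alpha, eta_star = config$learning$eta_star,
    d_min = config$synapses$d_min, d_max = config$synapses$d_max,
    w_init_min = config$synapses$w_init_min,
    w_init_max = config$synapses$w_init_max,
    clamp_weights = config$synapses$clamp_weights,
    kernel_scale = config$learning$kernel_scale,
    metric_scale = config$learning$metric_scale,
    r_band_factors = config$learning$r_band_factors,
    dt = config$simulation$dt, tau_psp = config$neuron$tau_psp,
    tau_ref = config$neuron$tau_ref, theta = config$neuron$theta,
    t_abs = config$neuron$t_abs)
}
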