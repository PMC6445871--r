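#' Benchmark specification
#'
#' Bundles every parameter of the seeded spike-train-learning benchmark:
#' the network size, Poisson rates for input and desired trains, the
#' simulation interval, the learning settings, and the dynamic/static mode
#' of each plasticity channel. The defaults are the reference benchmark
#' conditions (500 input synapses, 20 Hz inputs, 50 Hz desired train,
#' 200 ms interval, 500-epoch limit, Laplacian learning kernel of scale
#' 10 ms, alpha = 3, delays in [0, 15] ms).
#'
#' @param n_inputs Number of input synapses N_I (default 500).
#' @param r_in Input firing rate in Hz (default 20).
#' @param r_out Desired output firing rate in Hz (default 50).
#' @param duration Spike-train length in ms (default 200).
#' @param trials Number of seeded trials to aggregate (default 100).
#' @param max_epochs Epoch limit per trial (default 500).
#' @param seed_base Base seed; trial `k` uses `seed_base + k` (default 0).
#' @param delay_mode,weight_mode `"dynamic"` (updated by the learning
#'   rule) or `"static"` (frozen at initialization).
#' @param alpha Delay learning rate (default 3).
#' @param eta_star Referenced weight learning rate (default 0.005).
#' @param d_min,d_max Delay bounds in ms (defaults 0, 15); delays are also
#'   initialized uniformly on this interval.
#' @param w_init_min,w_init_max Weight initialization range (defaults 0,
#'   0.5).
#' @param clamp_weights Keep weights inside `[w_init_min, w_init_max]`
#'   during learning (default `TRUE`); set `FALSE` for unbounded weights.
#' @param kernel_scale Learning-kernel (Laplacian) scale in ms (default
#'   10).
#' @param metric_scale Gaussian filter scale of the accuracy measure C in
#'   ms (default 5).
#' @param r_band_factors Ordered pair of factors applied to `r_out` to get
#'   the referenced firing-rate band of the adaptive learning rate
#'   (default `c(0.8, 1.2)`, i.e. 40-60 Hz at the benchmark).
#' @param dt Simulation step in ms (default 0.1).
#' @param tau_psp,tau_ref,theta,t_abs Neuron constants, see
#'   [srm_params()].
#' @return An object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_inputs = 500, r_in = 20, r_out = 50,
                           duration = 200, trials = 100, max_epochs = 500,
                           seed_base = 0, delay_mode = c("dynamic", "static"),
                           weight_mode = c("dynamic", "static"), alpha = 3,
                           eta_star = 0.005, d_min = 0, d_max = 15,
                           w_init_min = 0, w_init_max = 0.5,
                           clamp_weights = TRUE,
                           kernel_scale = 10, metric_scale = 5,
                           r_band_factors = c(0.8, 1.2), dt = 0.1,
                           tau_psp = 2, tau_ref = 50, theta = 1,
                           t_abs = 1) {
  delay_mode <- match.arg(delay_mode)
  weight_mode <- match.arg(weight_mode)
  if (trials < 1) stop("`trials` must be at least 1", call. = FALSE)
  if (r_in < 0 || r_out < 0)
    stop("firing rates must be non-negative", call. = FALSE)
  spec <- list(n_inputs = as.integer(n_inputs), r_in = r_in, r_out = r_out,
               duration = duration, trials = as.integer(trials),
               max_epochs = as.integer(max_epochs),
               seed_base = as.integer(seed_base), delay_mode = delay_mode,
               weight_mode = weight_mode, alpha = alpha,
               eta_star = eta_star, d_min = d_min, d_max = d_max,
               w_init_min = w_init_min, w_init_max = w_init_max,
               clamp_weights = isTRUE(clamp_weights),
               kernel_scale = kernel_scale, metric_scale = metric_scale,
               r_band_factors = r_band_factors,
               dt = dt, tau_psp = tau_psp, tau_ref = tau_ref,
               theta = theta, t_abs = t_abs)
  structure(spec, class = "benchmark_spec")
}

#' @export
print.benchmark_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<benchmark_spec> N_I = %d, r_in = %g Hz, r_out = %g Hz, ",
           "T = %g ms\n  weights %s, delays %s; alpha = %g, ",
           "d in [%g, %g] ms; %d trials x %d epochs\n"),
    x$n_inputs, x$r_in, x$r_out, x$duration, x$weight_mode, x$delay_mode,
    x$alpha, x$d_min, x$d_max, x$trials, x$max_epochs))
  invisible(x)
}

spec_modify <- function(spec, parameter, value) {
  switch(parameter,
         alpha = spec$alpha <- value,
         d_max = spec$d_max <- value,
         max_epochs = spec$max_epochs <- as.integer(value),
         n_inputs = spec$n_inputs <- as.integer(value),
         rate = {
           spec$r_in <- value
           spec$r_out <- value
         },
         duration = spec$duration <- value,
         stop("unknown sweep parameter: ", parameter, call. = FALSE))
  spec
}

#' Run one seeded benchmark trial
#'
#' From `seed`, generates `n_inputs` Poisson input trains and one Poisson
#' desired train, draws the initial weights and delays, and trains the
#' neuron. The generation order is fixed, so trials with the same seed but
#' different mode flags share inputs, desired train and initial state
#' (paired design); a static channel simply freezes that channel during
#' learning.
#'
#' @param spec A [benchmark_spec()].
#' @param seed Integer seed for this trial.
#' @return A [train_neuron()] `trial_result` with `seed` recorded.
#' @export
run_trial <- function(spec, seed) {
  stopifnot(inherits(spec, "benchmark_spec"))
  set.seed(seed)
  inputs <- replicate(spec$n_inputs,
                      poisson_spike_train(spec$r_in, spec$duration),
                      simplify = FALSE)
  desired <- poisson_spike_train(spec$r_out, spec$duration)
  state <- init_synapse_state(spec$n_inputs, d_min = spec$d_min,
                              d_max = spec$d_max,
                              w_init_min = spec$w_init_min,
                              w_init_max = spec$w_init_max,
                              clamp_weights = spec$clamp_weights)
  params <- srm_params(tau_psp = spec$tau_psp, tau_ref = spec$tau_ref,
                       theta = spec$theta, t_abs = spec$t_abs)
  sim <- sim_config(duration = spec$duration, dt = spec$dt)
  cfg <- learning_config(kernel = kernel_spec("laplacian",
                                              spec$kernel_scale),
                         eta_star = spec$eta_star, alpha = spec$alpha,
                         r_min = spec$r_band_factors[1] * spec$r_out,
                         r_max = spec$r_band_factors[2] * spec$r_out,
                         max_epochs = spec$max_epochs,
                         adapt_weights = spec$weight_mode == "dynamic",
                         adapt_delays = spec$delay_mode == "dynamic")
  res <- train_neuron(inputs, desired, state, params, sim, cfg,
                      metric_kernel = kernel_spec("gaussian",
                                                  spec$metric_scale))
  res$seed <- as.integer(seed)
  res
}

trial_seeds <- function(spec) spec$seed_base + seq_len(spec$trials)

trial_record <- function(res) {
  data.frame(seed = res$seed, best_c = res$best_c,
             epoch_of_best_c = res$epoch_of_best_c,
             epochs_run = res$epochs_run, converged = res$converged)
}

#' Aggregate trial results
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of the
#' per-trial best C and of the first epoch attaining it. With a single
#' record the standard deviation is reported as 0 and flagged.
#'
#' @param records A non-empty list of `trial_result`s.
#' @return A list with `mean_best_c`, `sd_best_c`, `mean_epoch_of_best_c`,
#'   `sd_epoch_of_best_c`, `n`, and `sd_defined` (`FALSE` when `n == 1`).
#' @export
aggregate_results <- function(records) {
  if (!length(records)) stop("no trial results to aggregate", call. = FALSE)
  best <- vapply(records, `[[`, numeric(1), "best_c")
  epoch <- vapply(records, `[[`, numeric(1), "epoch_of_best_c")
  one <- length(best) == 1L
  list(mean_best_c = mean(best),
       sd_best_c = if (one) 0 else sd(best),
       mean_epoch_of_best_c = mean(epoch),
       sd_epoch_of_best_c = if (one) 0 else sd(epoch),
       n = length(best), sd_defined = !one)
}

run_trials <- function(spec, seeds = trial_seeds(spec)) {
  lapply(seeds, function(s) run_trial(spec, s))
}

sweep_one_value <- function(spec, parameter, value) {
  sp <- spec_modify(spec, parameter, value)
  results <- run_trials(sp)
  records <- do.call(rbind, lapply(results, trial_record))
  records$parameter <- parameter
  records$value <- value
  records$weight_mode <- sp$weight_mode
  records$delay_mode <- sp$delay_mode
  records
}

summarize_records <- function(records) {
  out <- lapply(split(records, records$value), function(d) {
    data.frame(value = d$value[1L],
               mean_best_c = mean(d$best_c),
               sd_best_c = if (nrow(d) > 1L) sd(d$best_c) else 0,
               mean_epoch_of_best_c = mean(d$epoch_of_best_c),
               sd_epoch_of_best_c = if (nrow(d) > 1L)
                 sd(d$epoch_of_best_c) else 0,
               n = nrow(d))
  })
  out <- do.call(rbind, out)
  out[order(out$value), , drop = FALSE]
}

#' Sweep one benchmark parameter
#'
#' For each value, runs `spec$trials` seeded trials (seeds
#' `seed_base + 1, ..., seed_base + trials`, identical across values) and
#' aggregates the per-trial best C and first-max epoch. The `"rate"`
#' parameter ties the input and desired rates together.
#'
#' @param spec A [benchmark_spec()].
#' @param parameter One of `"alpha"`, `"d_max"`, `"max_epochs"`,
#'   `"n_inputs"`, `"rate"`, `"duration"`.
#' @param values Numeric vector of parameter values.
#' @return An object of class `sweep_result`: a list with `parameter`,
#'   `summary` (one row per value: mean/sd of best C and of first-max
#'   epoch) and `records` (one row per trial).
#' @export
run_sweep <- function(spec, parameter, values) {
  stopifnot(inherits(spec, "benchmark_spec"))
  records <- do.call(rbind, lapply(values, function(v)
    sweep_one_value(spec, parameter, v)))
  structure(list(parameter = parameter, values = values,
                 summary = summarize_records(records), records = records),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> parameter `%s`\n", x$parameter))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Compare dynamic and static delays over a parameter sweep
#'
#' Runs the sweep twice with identical per-trial seeds — once with
#' delays updated by the learning rule and once with delays frozen at
#' their initialization — so each trial is paired: same inputs, desired
#' train and initial state, differing only in delay plasticity. Weights
#' follow `spec$weight_mode` in both arms (dynamic by default).
#'
#' @inheritParams run_sweep
#' @return A list of class `delay_mode_comparison` with elements
#'   `dynamic` and `static`, each a `sweep_result`.
#' @export
compare_delay_modes <- function(spec, parameter, values) {
  stopifnot(inherits(spec, "benchmark_spec"))
  dyn <- spec
  dyn$delay_mode <- "dynamic"
  sta <- spec
  sta$delay_mode <- "static"
  structure(list(dynamic = run_sweep(dyn, parameter, values),
                 static = run_sweep(sta, parameter, values)),
            class = "delay_mode_comparison")
}

#' @export
print.delay_mode_comparison <- function(x, ...) {
  cat("<delay_mode_comparison>\n dynamic delays:\n")
  print(x$dynamic$summary, row.names = FALSE)
  cat(" static delays:\n")
  print(x$static$summary, row.names = FALSE)
  invisible(x)
}

#' 2x2 static/dynamic weight-and-delay ablation
#'
#' Runs the four combinations of frozen/updated weights and delays on
#' shared per-trial seeds and aggregates best C per cell. The
#' static-weights/static-delays cell measures the accuracy of the random
#' initial network.
#'
#' @param spec A [benchmark_spec()]; its mode fields are overridden.
#' @return A list of class `ablation_result` with `summary` (four rows:
#'   `weight_mode`, `delay_mode`, mean/sd of best C, mean epoch of best C,
#'   n) and `records` (per-trial rows).
#' @export
ablation_grid <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  cells <- expand.grid(weight_mode = c("static", "dynamic"),
                       delay_mode = c("static", "dynamic"),
                       stringsAsFactors = FALSE)
  records <- NULL
  summary <- NULL
  for (k in seq_len(nrow(cells))) {
    sp <- spec
    sp$weight_mode <- cells$weight_mode[k]
    sp$delay_mode <- cells$delay_mode[k]
    results <- run_trials(sp)
    agg <- aggregate_results(results)
    rec <- do.call(rbind, lapply(results, trial_record))
    rec$weight_mode <- sp$weight_mode
    rec$delay_mode <- sp$delay_mode
    records <- rbind(records, rec)
    summary <- rbind(summary, data.frame(
      weight_mode = sp$weight_mode, delay_mode = sp$delay_mode,
      mean_best_c = agg$mean_best_c, sd_best_c = agg$sd_best_c,
      mean_epoch_of_best_c = agg$mean_epoch_of_best_c,
      n = agg$n))
  }
  structure(list(summary = summary, records = records),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("<ablation_result> mean best C by weight/delay mode:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Persist sweep or ablation results
#'
#' Writes the per-trial records as CSV (numeric columns at 6 significant
#' digits) and the aggregate summary as JSON next to it.
#'
#' @param x A `sweep_result`, `delay_mode_comparison` or
#'   `ablation_result`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
save_results <- function(x, dir, prefix = "results") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  records <- if (inherits(x, "delay_mode_comparison")) {
    rd <- x$dynamic$records
    rd$arm <- "dynamic"
    rs <- x$static$records
    rs$arm <- "static"
    rbind(rd, rs)
  } else x$records
  summary <- if (inherits(x, "delay_mode_comparison"))
    list(dynamic = x$dynamic$summary, static = x$static$summary)
  else x$summary
  csv_path <- file.path(dir, paste0(prefix, "_trials.csv"))
  json_path <- file.path(dir, paste0(prefix, "_summary.json"))
  num <- vapply(records, is.numeric, logical(1))
  records[num] <- lapply(records[num], signif, digits = 6)
  write.csv(records, csv_path, row.names = FALSE)
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(csv_path, json_path))
}
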