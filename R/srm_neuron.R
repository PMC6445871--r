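#' Spike Response Model parameters
#'
#' Constants of the short-term-memory Spike Response Model (SRM): each input
#' spike contributes an alpha-shaped postsynaptic potential (PSP) with time
#' constant `tau_psp`; after an output spike the potential carries a negative
#' refractoriness term with decay `tau_ref` (only the most recent output
#' spike contributes — the "short-term memory" of the model); the neuron
#' fires when the potential reaches `theta` and a hard absolute refractory
#' period `t_abs` has elapsed since the previous output spike.
#'
#' @param tau_psp PSP decay constant in ms (default 2).
#' @param tau_ref Refractoriness decay constant in ms (default 50).
#' @param theta Firing threshold, dimensionless (default 1).
#' @param t_abs Absolute refractory period in ms (default 1).
#' @return An object of class `srm_params`.
#' @export
srm_params <- function(tau_psp = 2, tau_ref = 50, theta = 1, t_abs = 1) {
  vals <- c(tau_psp = tau_psp, tau_ref = tau_ref, theta = theta,
            t_abs = t_abs)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all SRM parameters must be positive and finite", call. = FALSE)
  structure(as.list(vals), class = "srm_params")
}

#' @export
print.srm_params <- function(x, ...) {
  cat(sprintf(
    "<srm_params> tau_psp = %g ms, tau_ref = %g ms, theta = %g, t_abs = %g ms\n",
    x$tau_psp, x$tau_ref, x$theta, x$t_abs))
  invisible(x)
}

#' Simulation grid configuration
#'
#' @param duration Interval length T in ms (default 200).
#' @param dt Clock-driven time step in ms (default 0.1). `duration` must be
#'   an integer multiple of `dt` (within tolerance).
#' @param psp_cutoff Optional event window in ms after which a PSP
#'   contribution is dropped; `NULL` (default) means `10 * tau_psp` at
#'   simulation time, where the neglected tail is below 1.3e-3.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration = 200, dt = 0.1, psp_cutoff = NULL) {
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0)
    stop("`dt` must be a single positive number (ms)", call. = FALSE)
  if (!is.numeric(duration) || length(duration) != 1L || is.na(duration) ||
      duration <= 0)
    stop("`duration` must be a single positive number (ms)", call. = FALSE)
  k <- duration / dt
  if (abs(k - round(k)) > 1e-8)
    stop("`duration` must be an integer multiple of `dt`", call. = FALSE)
  if (!is.null(psp_cutoff) &&
      (!is.numeric(psp_cutoff) || psp_cutoff <= 0))
    stop("`psp_cutoff` must be NULL or a positive number (ms)",
         call. = FALSE)
  structure(list(duration = as.numeric(duration), dt = as.numeric(dt),
                 psp_cutoff = psp_cutoff), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> duration = %g ms, dt = %g ms\n", x$duration,
              x$dt))
  invisible(x)
}

n_grid_points <- function(sim) as.integer(round(sim$duration / sim$dt)) + 1L

#' Alpha-shaped spike response (PSP) function
#'
#' `eps(s) = (s / tau_psp) * exp(1 - s / tau_psp)` for `s > 0`, else 0.
#' Normalized so its maximum, at `s = tau_psp`, equals 1.
#'
#' @param s Elapsed time since the (delayed) input spike, ms; vectorized.
#' @param tau_psp PSP decay constant in ms.
#' @return PSP value(s), dimensionless.
#' @examples
#' spike_response_eps(2, tau_psp = 2)  # 1, the peak
#' @export
spike_response_eps <- function(s, tau_psp) {
  if (!is.numeric(tau_psp) || tau_psp <= 0)
    stop("`tau_psp` must be positive", call. = FALSE)
  s <- as.numeric(s)
  ifelse(s > 0, (s / tau_psp) * exp(1 - s / tau_psp), 0)
}

#' Refractoriness function
#'
#' `eta(s) = -theta * exp(-s / tau_ref)` for `s > 0`, else 0. Approaches
#' `-theta` immediately after an output spike and relaxes to 0. When the
#' neuron has not fired yet the elapsed time is `+Inf` and the term is 0.
#'
#' @param s Time since the last output spike, ms; vectorized; `Inf` allowed.
#' @param theta Firing threshold.
#' @param tau_ref Refractoriness decay constant in ms.
#' @return Non-positive potential contribution(s).
#' @export
refractoriness_eta <- function(s, theta, tau_ref) {
  if (!is.numeric(theta) || theta <= 0 || !is.numeric(tau_ref) ||
      tau_ref <= 0)
    stop("`theta` and `tau_ref` must be positive", call. = FALSE)
  s <- as.numeric(s)
  ifelse(s > 0, -theta * exp(-s / tau_ref), 0)
}

#' Membrane potential of the SRM neuron
#'
#' Pure function returning
#' `u(t) = sum_i sum_f w_i * eps(t - t_i^f - d_i) + eta(t - t_last)`.
#' Useful as a reference for the compiled simulator and for inspecting
#' potentials at chosen times.
#'
#' @param t Evaluation time(s) in ms; vectorized.
#' @param inputs List of input [spike_train()]s, one per synapse.
#' @param weights Numeric vector of synaptic weights, same length as
#'   `inputs`.
#' @param delays Numeric vector of synaptic delays in ms, same length.
#' @param last_output_spike Time of the most recent output spike in ms, or
#'   `NULL` if the neuron has not fired.
#' @param params [srm_params()].
#' @return Potential value(s) `u(t)`.
#' @export
membrane_potential <- function(t, inputs, weights, delays,
                               last_output_spike = NULL,
                               params = srm_params()) {
  stopifnot(inherits(params, "srm_params"))
  if (length(inputs) != length(weights) ||
      length(inputs) != length(delays))
    stop("`inputs`, `weights` and `delays` must have equal length",
         call. = FALSE)
  t <- as.numeric(t)
  u <- numeric(length(t))
  for (i in seq_along(inputs)) {
    if (weights[i] == 0 || !length(inputs[[i]]$times)) next
    for (tf in inputs[[i]]$times)
      u <- u + weights[i] *
        spike_response_eps(t - tf - delays[i], params$tau_psp)
  }
  s_last <- if (is.null(last_output_spike)) Inf else t - last_output_spike
  u + refractoriness_eta(s_last, params$theta, params$tau_ref)
}

# concatenated arrival times (t_i^f + d_i, continuous, not grid-rounded)
# with per-arrival weights
arrival_times <- function(inputs, delays) {
  times <- lapply(inputs, `[[`, "times")
  n_per <- lengths(times)
  list(times = unlist(times, use.names = FALSE) +
         rep(as.numeric(delays), n_per),
       syn = rep(seq_along(inputs) - 1L, n_per))
}

#' Simulate the SRM neuron on the clock-driven grid
#'
#' Walks the grid `t = 0, dt, ..., T`; at each step the potential is the
#' weighted sum of PSPs from all (delayed) input spikes plus the
#' refractoriness of the most recent output spike. An output spike is
#' registered at a grid time where `u(t) >= theta` and more than `t_abs` ms
#' have passed since the previous output spike. Deterministic.
#'
#' @inheritParams membrane_potential
#' @param sim [sim_config()].
#' @return The actual output [spike_train()] (times on the grid).
#' @examples
#' out <- simulate_srm(list(spike_train(10, 200)), weights = 1, delays = 0)
#' out$times  # 12: the PSP peaks at tau_psp = 2 ms after the input spike
#' @export
simulate_srm <- function(inputs, weights, delays, params = srm_params(),
                         sim = sim_config()) {
  stopifnot(inherits(params, "srm_params"), inherits(sim, "sim_config"))
  if (length(inputs) != length(weights) ||
      length(inputs) != length(delays))
    stop("`inputs`, `weights` and `delays` must have equal length",
         call. = FALSE)
  if (any(delays < 0)) stop("delays must be non-negative", call. = FALSE)
  P <- feedforward_potential(inputs, weights, delays, params, sim)
  times <- srm_fire_cpp(P, sim$dt, params$theta, params$tau_ref,
                        params$t_abs)
  spike_train(times, sim$duration)
}

feedforward_potential <- function(inputs, weights, delays, params, sim) {
  arr <- arrival_times(inputs, delays)
  cutoff <- if (is.null(sim$psp_cutoff)) 10 * params$tau_psp else
    sim$psp_cutoff
  psp_grid_cpp(arr$times, as.numeric(weights)[arr$syn + 1L],
               n_grid_points(sim), sim$dt, params$tau_psp, cutoff)
}

#' Membrane-potential trace over the grid
#'
#' Runs the same walk as [simulate_srm()] but returns the full potential
#' trace (including refractoriness from the spikes produced along the way),
#' mainly for debugging and plotting; optionally written as a two-column
#' CSV.
#'
#' @inheritParams simulate_srm
#' @param path Optional CSV file path (`time_ms,u`).
#' @return A data.frame with columns `time_ms` and `u` (invisibly when
#'   `path` is given).
#' @export
membrane_trace <- function(inputs, weights, delays, params = srm_params(),
                           sim = sim_config(), path = NULL) {
  P <- feedforward_potential(inputs, weights, delays, params, sim)
  out <- srm_fire_cpp(P, sim$dt, params$theta, params$tau_ref, params$t_abs)
  tg <- seq(0, by = sim$dt, length.out = n_grid_points(sim))
  last <- vapply(tg, function(t) {
    prev <- out[out < t]
    if (length(prev)) t - prev[length(prev)] else Inf
  }, numeric(1))
  u <- P + refractoriness_eta(last, params$theta, params$tau_ref)
  df <- data.frame(time_ms = tg, u = u)
  if (!is.null(path)) {
    write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
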