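#' Per-synapse weight and delay state
#'
#' Holds the weight vector, the delay vector and the bounds the learning
#' rules operate on. Delays are always clamped into `[d_min, d_max]` after
#' every update because the upper bound is the maximum allowed synaptic
#' delay of the model. Weights are clamped into `[w_min, w_max]` when
#' those bounds are given (the default in the benchmark harness); pass
#' `NULL` bounds for unbounded weights.
#'
#' @param weights Numeric vector of synaptic efficacies.
#' @param delays Numeric vector of synaptic delays in ms, same length,
#'   each within `[d_min, d_max]`.
#' @param d_min,d_max Delay bounds in ms (defaults 0 and 15).
#' @param w_min,w_max Optional weight bounds; `NULL` (default) leaves
#'   weights unbounded during learning.
#' @return An object of class `synapse_state`.
#' @export
synapse_state <- function(weights, delays, d_min = 0, d_max = 15,
                          w_min = NULL, w_max = NULL) {
  weights <- as.numeric(weights)
  delays <- as.numeric(delays)
  if (length(weights) != length(delays))
    stop("`weights` and `delays` must have equal length", call. = FALSE)
  if (d_min > d_max) stop("`d_min` must not exceed `d_max`", call. = FALSE)
  if (length(delays) && (any(delays < d_min) || any(delays > d_max)))
    stop("every delay must lie within [d_min, d_max]", call. = FALSE)
  if (is.null(w_min) != is.null(w_max))
    stop("give both `w_min` and `w_max`, or neither", call. = FALSE)
  if (!is.null(w_min)) {
    if (w_min > w_max) stop("`w_min` must not exceed `w_max`",
                            call. = FALSE)
    if (length(weights) && (any(weights < w_min) || any(weights > w_max)))
      stop("every weight must lie within [w_min, w_max]", call. = FALSE)
  }
  structure(list(weights = weights, delays = delays,
                 d_min = as.numeric(d_min), d_max = as.numeric(d_max),
                 w_min = if (!is.null(w_min)) as.numeric(w_min),
                 w_max = if (!is.null(w_max)) as.numeric(w_max)),
            class = "synapse_state")
}

#' @export
print.synapse_state <- function(x, ...) {
  cat(sprintf(
    "<synapse_state> %d synapses; delays in [%g, %g] ms\n",
    length(x$weights), x$d_min, x$d_max))
  invisible(x)
}

#' Draw a random initial synapse state
#'
#' Weights uniform on `[w_init_min, w_init_max]`, delays uniform on
#' `[d_min, d_max]`; uses R's global RNG. With `clamp_weights = TRUE`
#' (the default) the initialization range also bounds the weights during
#' learning.
#'
#' @param n Number of synapses.
#' @param d_min,d_max Delay bounds in ms (defaults 0, 15).
#' @param w_init_min,w_init_max Weight initialization range (defaults 0,
#'   0.5).
#' @param clamp_weights Keep weights inside the initialization range
#'   during learning (default `TRUE`).
#' @return A [synapse_state()].
#' @export
init_synapse_state <- function(n, d_min = 0, d_max = 15, w_init_min = 0,
                               w_init_max = 0.5, clamp_weights = TRUE) {
  synapse_state(runif(n, w_init_min, w_init_max), runif(n, d_min, d_max),
                d_min = d_min, d_max = d_max,
                w_min = if (clamp_weights) w_init_min,
                w_max = if (clamp_weights) w_init_max)
}

#' Learning configuration
#'
#' @param kernel Learning [kernel_spec()]; default Laplacian, scale 10 ms.
#' @param eta_star Referenced weight learning rate (default 0.005).
#' @param alpha Delay learning rate (default 3).
#' @param r_min,r_max Referenced output firing-rate band in Hz; `NULL`
#'   (default) resolves to 0.8 and 1.2 times the desired train's nominal
#'   rate when training starts.
#' @param max_epochs Upper limit of learning epochs (default 500).
#' @param adapt_weights,adapt_delays Whether each channel is updated
#'   (both `TRUE` by default); freezing one realizes the static-weight /
#'   static-delay ablations.
#' @param signed_delay_rule Experimental variant that keeps the sign of the
#'   kernel derivative in the delay rule; the default (`FALSE`) is the
#'   rule exactly as printed, whose bracket uses the unsigned kernel.
#' @return An object of class `learning_config`.
#' @export
learning_config <- function(kernel = kernel_spec("laplacian", 10),
                            eta_star = 0.005, alpha = 3, r_min = NULL,
                            r_max = NULL, max_epochs = 500,
                            adapt_weights = TRUE, adapt_delays = TRUE,
                            signed_delay_rule = FALSE) {
  stopifnot(inherits(kernel, "kernel_spec"))
  if (!is.numeric(eta_star) || eta_star <= 0)
    stop("`eta_star` must be positive", call. = FALSE)
  if (!is.numeric(alpha) || alpha < 0)
    stop("`alpha` must be non-negative", call. = FALSE)
  if (!is.null(r_min) && !is.null(r_max) && r_min > r_max)
    stop("`r_min` must not exceed `r_max`", call. = FALSE)
  if (!is.numeric(max_epochs) || max_epochs < 1)
    stop("`max_epochs` must be at least 1", call. = FALSE)
  structure(list(kernel = kernel, eta_star = eta_star, alpha = alpha,
                 r_min = r_min, r_max = r_max,
                 max_epochs = as.integer(max_epochs),
                 adapt_weights = isTRUE(adapt_weights),
                 adapt_delays = isTRUE(adapt_delays),
                 signed_delay_rule = isTRUE(signed_delay_rule)),
            class = "learning_config")
}

#' Weight update for one synapse
#'
#' The closed-form weight rule: the change is the learning rate times the
#' difference of two double sums of kernel values over spike-time
#' differences,
#' `dw = eta * [ sum_g sum_f kappa(t_d^g - t_i^f - d)
#'             - sum_h sum_f kappa(t_o^h - t_i^f - d) ]`,
#' where `t_d` runs over desired, `t_o` over actual output and `t_i` over
#' (delayed) input spikes. Identical desired and actual trains cancel
#' exactly, so a perfectly learned train is a fixed point.
#'
#' @param input Input [spike_train()] of the synapse.
#' @param delay Synaptic delay d in ms.
#' @param desired,actual Desired and actual output [spike_train()]s.
#' @param eta Weight learning rate.
#' @param kernel Learning [kernel_spec()].
#' @return The weight change `dw` (scalar).
#' @export
weight_delta <- function(input, delay, desired, actual, eta,
                         kernel = kernel_spec("laplacian", 10)) {
  stopifnot(is_spike_train(input), is_spike_train(desired),
            is_spike_train(actual), inherits(kernel, "kernel_spec"))
  b <- delta_brackets_cpp(input$times,
                          integer(length(input$times)), 1L,
                          as.numeric(delay), desired$times, actual$times,
                          kernel$scale, kernel_family_code(kernel))
  eta * b[1L]
}

#' Delay update for one synapse
#'
#' The closed-form delay rule for the Laplacian kernel, exactly as printed:
#' `dd = (alpha * w / tau) * [ sum_g sum_f kappa(t_d^g - t_i^f - d)
#'                           - sum_h sum_f kappa(t_o^h - t_i^f - d) ]`
#' with `tau` the learning-kernel scale. The printed derivation drops the
#' sign of the absolute-value derivative; set `signed = TRUE` for the
#' experimental variant that keeps `sign(x)` inside the sums. For a
#' Gaussian learning kernel the generic form is used, with the kernel's
#' derivative with respect to the delay, `(x / scale^2) * kappa(x)`.
#'
#' @inheritParams weight_delta
#' @param weight Synaptic weight w of the synapse.
#' @param alpha Delay learning rate.
#' @param signed Keep the derivative sign (Laplacian only; default
#'   `FALSE`).
#' @return The delay change `dd` in ms (scalar).
#' @export
delay_delta <- function(input, weight, delay, desired, actual, alpha,
                        kernel = kernel_spec("laplacian", 10),
                        signed = FALSE) {
  stopifnot(is_spike_train(input), is_spike_train(desired),
            is_spike_train(actual), inherits(kernel, "kernel_spec"))
  mode <- delay_bracket_mode(kernel, signed)
  b <- delta_brackets_cpp(input$times,
                          integer(length(input$times)), 1L,
                          as.numeric(delay), desired$times, actual$times,
                          kernel$scale, mode)
  alpha * weight * b[1L]
}

delay_bracket_mode <- function(kernel, signed) {
  if (kernel$family == "gaussian") {
    if (signed)
      stop("`signed` applies to the Laplacian kernel only", call. = FALSE)
    4L
  } else if (signed) 3L else 2L
}

#' Firing-rate scaling factor
#'
#' `beta = 1` when the output rate lies in the referenced band
#' `[r_min, r_max]`; below the band it is `(r_min - r) / (r_max - r_min)`,
#' above it `(r - r_max) / (r_max - r_min)`.
#'
#' @param r Actual output firing rate in Hz (>= 0).
#' @param r_min,r_max Referenced firing-rate band in Hz.
#' @return The scaling factor `beta`.
#' @export
scaling_factor_beta <- function(r, r_min, r_max) {
  if (r < 0) stop("`r` must be non-negative", call. = FALSE)
  if (r_min > r_max) stop("`r_min` must not exceed `r_max`", call. = FALSE)
  if (r >= r_min && r <= r_max) return(1)
  if (r_max == r_min)
    stop("degenerate band (r_min == r_max) with r outside it", call. = FALSE)
  if (r < r_min) (r_min - r) / (r_max - r_min)
  else (r - r_max) / (r_max - r_min)
}

#' Adaptive weight learning rate
#'
#' Scales the referenced rate `eta_star` by the firing-rate mismatch:
#' `(1 + beta) * eta_star` below the band, `eta_star` inside it, and
#' `eta_star / (1 + beta)` above it, so that a silent neuron learns faster
#' and a runaway neuron is damped.
#'
#' @inheritParams scaling_factor_beta
#' @param eta_star Referenced learning rate.
#' @return The effective learning rate `eta`.
#' @export
adaptive_rate <- function(r, eta_star, r_min, r_max) {
  if (r >= r_min && r <= r_max) return(eta_star)
  beta <- scaling_factor_beta(r, r_min, r_max)
  if (r < r_min) (1 + beta) * eta_star else eta_star / (1 + beta)
}

#' Apply weight and delay updates to a synapse state
#'
#' Delays are updated and then clamped into `[d_min, d_max]`; weights are
#' clamped into `[w_min, w_max]` when the state carries weight bounds,
#' otherwise updated freely.
#'
#' @param state A [synapse_state()].
#' @param dw,dd Numeric update vectors matching the state's length.
#' @return The updated [synapse_state()].
#' @export
apply_updates <- function(state, dw, dd) {
  stopifnot(inherits(state, "synapse_state"))
  if (length(dw) != length(state$weights) ||
      length(dd) != length(state$weights))
    stop("update vectors must match the number of synapses", call. = FALSE)
  w <- state$weights + dw
  if (!is.null(state$w_min)) w <- pmin(pmax(w, state$w_min), state$w_max)
  synapse_state(w,
                pmin(pmax(state$delays + dd, state$d_min), state$d_max),
                d_min = state$d_min, d_max = state$d_max,
                w_min = state$w_min, w_max = state$w_max)
}

trains_equal_on_grid <- function(a, b, dt) {
  if (length(a$times) != length(b$times)) return(FALSE)
  if (!length(a$times)) return(TRUE)
  all(round(a$times / dt) == round(b$times / dt))
}

#' Train the neuron to reproduce a desired spike train
#'
#' One learning epoch simulates the neuron, records the accuracy C between
#' actual and desired output, derives the adaptive weight learning rate
#' from the output firing rate, computes all per-synapse weight and delay
#' updates from the same snapshot, and applies them simultaneously
#' (delays clamped to their bounds). Training stops when the actual output
#' equals the desired train exactly on the simulation grid (zero network
#' error) or after `max_epochs` epochs. If an epoch leaves the state
#' bit-identical (e.g. both channels frozen), the remaining epochs are
#' filled in without re-simulating, since the dynamics are deterministic.
#'
#' @param inputs List of input [spike_train()]s, one per synapse.
#' @param desired Desired output [spike_train()].
#' @param state Initial [synapse_state()].
#' @param params [srm_params()].
#' @param sim [sim_config()].
#' @param cfg [learning_config()].
#' @param metric_kernel Filter kernel for the accuracy measure C; default
#'   Gaussian with scale 5 ms.
#' @param verbose Print one line per epoch.
#' @param log_path Optional CSV path for the per-epoch log
#'   (`epoch,c,n_output_spikes,eta`).
#' @return An object of class `trial_result` with elements `c_history`,
#'   `best_c`, `epoch_of_best_c` (first epoch attaining the maximum),
#'   `epochs_run`, `final_output`, `final_state`, `converged`, `seed`
#'   (`NA` unless set by the caller).
#' @export
train_neuron <- function(inputs, desired, state, params = srm_params(),
                         sim = sim_config(), cfg = learning_config(),
                         metric_kernel = kernel_spec("gaussian", 5),
                         verbose = FALSE, log_path = NULL) {
  stopifnot(is_spike_train(desired), inherits(state, "synapse_state"),
            inherits(cfg, "learning_config"))
  if (length(inputs) != length(state$weights))
    stop("`inputs` must have one train per synapse", call. = FALSE)
  r_nominal <- firing_rate(desired)
  r_min <- if (is.null(cfg$r_min)) 0.8 * r_nominal else cfg$r_min
  r_max <- if (is.null(cfg$r_max)) 1.2 * r_nominal else cfg$r_max

  arr <- arrival_times(inputs, rep(0, length(inputs)))  # undelayed times
  n_grid <- n_grid_points(sim)
  fd_metric <- signal_on_grid(desired$times, n_grid, sim$dt, metric_kernel)
  fd_norm2 <- sum(fd_metric^2)
  w_mode <- kernel_family_code(cfg$kernel)
  d_mode <- delay_bracket_mode(cfg$kernel, cfg$signed_delay_rule)
  cutoff <- if (is.null(sim$psp_cutoff)) 10 * params$tau_psp else
    sim$psp_cutoff

  c_history <- numeric(cfg$max_epochs)
  eta_log <- numeric(cfg$max_epochs)
  n_out_log <- integer(cfg$max_epochs)
  converged <- FALSE
  actual <- NULL
  epoch <- 0L

  while (epoch < cfg$max_epochs) {
    epoch <- epoch + 1L
    P <- psp_grid_cpp(arr$times + state$delays[arr$syn + 1L],
                      state$weights[arr$syn + 1L], n_grid, sim$dt,
                      params$tau_psp, cutoff)
    out_times <- tryCatch(
      srm_fire_cpp(P, sim$dt, params$theta, params$tau_ref, params$t_abs),
      error = function(e)
        stop("simulation failed in epoch ", epoch, ": ",
             conditionMessage(e), call. = FALSE))
    actual <- spike_train(out_times, sim$duration)

    n_out <- length(out_times)
    cval <- if (n_out == 0L) {
      if (!length(desired$times)) 1 else 0
    } else if (!length(desired$times)) 0 else {
      fo <- signal_on_grid(out_times, n_grid, sim$dt, metric_kernel)
      sum(fd_metric * fo) / sqrt(fd_norm2 * sum(fo^2))
    }
    c_history[epoch] <- cval
    n_out_log[epoch] <- n_out

    r <- 1000 * n_out / sim$duration
    eta <- adaptive_rate(r, cfg$eta_star, r_min, r_max)
    eta_log[epoch] <- eta
    if (verbose)
      message(sprintf("epoch %d: C = %.4f, output spikes = %d, eta = %g",
                      epoch, cval, n_out, eta))

    if (trains_equal_on_grid(actual, desired, sim$dt)) {
      converged <- TRUE
      break
    }

    dw <- if (cfg$adapt_weights) {
      eta * delta_brackets_cpp(arr$times, arr$syn, length(state$weights),
                               state$delays, desired$times, out_times,
                               cfg$kernel$scale, w_mode)
    } else numeric(length(state$weights))
    dd <- if (cfg$adapt_delays) {
      cfg$alpha * state$weights *
        delta_brackets_cpp(arr$times, arr$syn, length(state$weights),
                           state$delays, desired$times, out_times,
                           cfg$kernel$scale, d_mode)
    } else numeric(length(state$weights))
    new_state <- apply_updates(state, dw, dd)

    if (identical(new_state$weights, state$weights) &&
        identical(new_state$delays, state$delays)) {
      # fixed point: every later epoch repeats this one exactly
      if (epoch < cfg$max_epochs) {
        c_history[(epoch + 1L):cfg$max_epochs] <- cval
        n_out_log[(epoch + 1L):cfg$max_epochs] <- n_out
        eta_log[(epoch + 1L):cfg$max_epochs] <- eta
      }
      epoch <- cfg$max_epochs
      break
    }
    state <- new_state
  }

  c_history <- c_history[seq_len(epoch)]
  if (!is.null(log_path))
    write.csv(data.frame(epoch = seq_len(epoch),
                         c = c_history,
                         n_output_spikes = n_out_log[seq_len(epoch)],
                         eta = eta_log[seq_len(epoch)]),
              log_path, row.names = FALSE)
  structure(list(c_history = c_history,
                 best_c = max(c_history),
                 epoch_of_best_c = which.max(c_history),
                 epochs_run = epoch,
                 final_output = actual,
                 final_state = state,
                 converged = converged,
                 seed = NA_integer_),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf(
    "<trial_result> best C = %.4f at epoch %d (of %d run)%s\n",
    x$best_c, x$epoch_of_best_c, x$epochs_run,
    if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Kernel-space spike-train error (diagnostic)
#'
#' The total network error: half the squared L2 distance between the
#' filtered actual and desired signals, integrated over the interval by
#' the trapezoidal rule on the simulation grid. Zero iff the filtered
#' signals coincide. This quantity is diagnostic only; the learning rules
#' use the closed-form double sums.
#'
#' @param desired,actual [spike_train()]s sharing a duration.
#' @param kernel [kernel_spec()] (default the Laplacian learning kernel).
#' @param sim [sim_config()] supplying the grid.
#' @return Non-negative error value.
#' @export
spike_train_error <- function(desired, actual,
                              kernel = kernel_spec("laplacian", 10),
                              sim = sim_config()) {
  stopifnot(is_spike_train(desired), is_spike_train(actual))
  if (!isTRUE(all.equal(desired$duration, actual$duration)))
    stop("trains must share the same duration", call. = FALSE)
  n_grid <- n_grid_points(sim)
  fd <- signal_on_grid(desired$times, n_grid, sim$dt, kernel)
  fo <- signal_on_grid(actual$times, n_grid, sim$dt, kernel)
  d2 <- (fo - fd)^2 / 2
  sim$dt * (sum(d2) - (d2[1L] + d2[n_grid]) / 2)
}
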