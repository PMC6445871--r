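#' Spike-train kernel specification
#'
#' A kernel turns a discrete spike train into a continuous signal by placing
#' one bump at every spike. Two families are supported:
#' * `laplacian`: `kappa(s) = exp(-|s| / scale)` — the learning kernel; its
#'   scale (default 10 ms in the learning rules) is distinct from the PSP
#'   time constant of the neuron model.
#' * `gaussian`: `kappa(s) = exp(-s^2 / (2 scale^2))` — the filter used by
#'   the correlation-based accuracy measure [correlation_c()].
#'
#' @param family `"laplacian"` or `"gaussian"`.
#' @param scale Kernel width parameter in ms (> 0).
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec("laplacian", 10)
#' @export
kernel_spec <- function(family = c("laplacian", "gaussian"), scale = 10) {
  family <- match.arg(family)
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0)
    stop("kernel `scale` must be a single positive number (ms)",
         call. = FALSE)
  structure(list(family = family, scale = as.numeric(scale)),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> %s, scale = %g ms\n", x$family, x$scale))
  invisible(x)
}

kernel_family_code <- function(spec) {
  if (spec$family == "gaussian") 1L else 0L
}

#' Evaluate a spike-train kernel at a time difference
#'
#' @param spec A [kernel_spec()].
#' @param s Time difference(s) in ms; vectorized.
#' @return Kernel value(s); 1 at `s = 0`, symmetric in `s`.
#' @examples
#' kernel_eval(kernel_spec("laplacian", 10), 10)  # exp(-1)
#' @export
kernel_eval <- function(spec, s) {
  stopifnot(inherits(spec, "kernel_spec"))
  s <- as.numeric(s)
  if (spec$family == "laplacian") exp(-abs(s) / spec$scale)
  else exp(-s^2 / (2 * spec$scale^2))
}

#' Kernel-filtered signal of a (delayed) spike train
#'
#' Evaluates `f(t) = sum_f kappa(t - t^f - delay)` — the continuous signal
#' obtained by convolving the train, shifted by a synaptic delay, with the
#' kernel. `t` may be a vector (e.g. a uniform grid); the result is the
#' exact pointwise sum with no truncation.
#'
#' @param train A [spike_train()].
#' @param spec A [kernel_spec()].
#' @param delay Synaptic delay in ms (>= 0), applied to every spike.
#' @param t Evaluation time(s) in ms.
#' @return Numeric vector of signal values, one per element of `t`.
#' @examples
#' tr <- spike_train(c(10, 20), 200)
#' convolved_signal(tr, kernel_spec("laplacian", 10), 0, 20)
#' @export
convolved_signal <- function(train, spec, delay = 0, t) {
  stopifnot(is_spike_train(train), inherits(spec, "kernel_spec"))
  if (!is.numeric(delay) || length(delay) != 1L || is.na(delay) || delay < 0)
    stop("`delay` must be a single non-negative number (ms)", call. = FALSE)
  t <- as.numeric(t)
  if (!length(train$times)) return(numeric(length(t)))
  centers <- train$times + delay
  out <- numeric(length(t))
  for (a in centers) out <- out + kernel_eval(spec, t - a)
  out
}

# filtered signal on the uniform grid {0, dt, ..., n_grid-1 * dt}; compiled
# fast path used by correlation_c and the training loop.
signal_on_grid <- function(times, n_grid, dt, spec) {
  kernel_signal_grid_cpp(as.numeric(times), as.integer(n_grid),
                         as.numeric(dt), spec$scale,
                         kernel_family_code(spec))
}

#' Correlation-based accuracy measure C between two spike trains
#'
#' Both trains are filtered into continuous signals (by default with a
#' Gaussian kernel) and evaluated on the uniform grid `{0, dt, ..., T}`;
#' C is the inner product of the two signals divided by the product of
#' their Euclidean norms. C equals 1 for identical trains and decays
#' toward 0 for unrelated trains. Degenerate cases: both trains empty
#' gives 1 (identical), exactly one empty gives 0.
#'
#' @param desired,actual [spike_train()]s sharing the same duration.
#' @param spec Filter kernel; default Gaussian with scale 5 ms.
#' @param dt Grid step in ms (default 0.1, the simulation step).
#' @return A number in `[0, 1]`.
#' @examples
#' a <- spike_train(c(50, 120), 200)
#' correlation_c(a, a)  # 1
#' @export
correlation_c <- function(desired, actual, spec = kernel_spec("gaussian", 5),
                          dt = 0.1) {
  stopifnot(is_spike_train(desired), is_spike_train(actual),
            inherits(spec, "kernel_spec"))
  if (!isTRUE(all.equal(desired$duration, actual$duration)))
    stop("trains must share the same duration", call. = FALSE)
  nd <- length(desired$times)
  na <- length(actual$times)
  if (nd == 0L && na == 0L) return(1)
  if (nd == 0L || na == 0L) return(0)
  n_grid <- as.integer(round(desired$duration / dt)) + 1L
  fd <- signal_on_grid(desired$times, n_grid, dt, spec)
  fo <- signal_on_grid(actual$times, n_grid, dt, spec)
  sum(fd * fo) / sqrt(sum(fd * fd) * sum(fo * fo))
}
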