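#' Construct a spike train
#'
#' A spike train is an ordered sequence of firing times (ms) observed on the
#' bounded interval `[0, duration]`. It is the universal currency of the
#' package: inputs, desired outputs and simulated outputs are all spike
#' trains. The empty train is valid.
#'
#' @param times Numeric vector of firing times in ms, strictly increasing,
#'   all within `[0, duration]`. May be empty.
#' @param duration Length of the observation interval T in ms (> 0).
#' @return An object of class `spike_train` with elements `times` and
#'   `duration`.
#' @examples
#' spike_train(c(10, 25.5, 90), duration = 200)
#' spike_train(numeric(0), duration = 200)  # empty train
#' @export
spike_train <- function(times, duration) {
  times <- as.numeric(times)
  duration <- as.numeric(duration)
  if (length(duration) != 1L || !is.finite(duration) || duration <= 0)
    stop("`duration` must be a single positive number (ms)", call. = FALSE)
  if (anyNA(times) || any(!is.finite(times)))
    stop("spike times must be finite", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("spike times must be strictly increasing", call. = FALSE)
  if (length(times) && (times[1L] < 0 || times[length(times)] > duration))
    stop("spike times must lie within [0, duration]", call. = FALSE)
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spike%s on [0, %g] ms\n", length(x$times),
              if (length(x$times) == 1L) "" else "s", x$duration))
  if (length(x$times)) {
    shown <- utils::head(x$times, 8L)
    cat("  times:", paste(signif(shown, 6), collapse = ", "),
        if (length(x$times) > 8L) "..." else "", "\n")
  }
  invisible(x)
}

#' @rdname spike_train
#' @param x Object to test.
#' @export
is_spike_train <- function(x) inherits(x, "spike_train")

#' Number of spikes in a train
#'
#' @param train A [spike_train()].
#' @return Integer spike count.
#' @export
n_spikes <- function(train) {
  stopifnot(is_spike_train(train))
  length(train$times)
}

#' Mean firing rate of a train in Hz
#'
#' @param train A [spike_train()].
#' @return Spike count divided by duration, in Hz.
#' @export
firing_rate <- function(train) {
  stopifnot(is_spike_train(train))
  1000 * length(train$times) / train$duration
}

#' Generate a homogeneous Poisson spike train
#'
#' Samples a spike train from a homogeneous Poisson process with constant
#' `rate` on `[0, duration]`: the spike count is Poisson with mean
#' `rate * duration / 1000` and, given the count, spike times are i.i.d.
#' uniform on the interval. Randomness comes from R's global RNG, so results
#' are reproducible under `set.seed()`.
#'
#' @param rate Firing rate in Hz (>= 0).
#' @param duration Interval length in ms (> 0).
#' @return A [spike_train()].
#' @examples
#' set.seed(1)
#' poisson_spike_train(20, 200)
#' @export
poisson_spike_train <- function(rate, duration) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0)
    stop("`rate` must be a single non-negative number (Hz)", call. = FALSE)
  if (!is.numeric(duration) || length(duration) != 1L || is.na(duration) ||
      duration <= 0)
    stop("`duration` must be a single positive number (ms)", call. = FALSE)
  n <- rpois(1L, rate * duration / 1000)
  spike_train(sort(runif(n, 0, duration)), duration)
}

#' Shift all spike times by a constant offset
#'
#' Utility used mainly in tests of time-shift invariance; spikes shifted
#' outside the interval raise an error.
#'
#' @param train A [spike_train()].
#' @param delta Shift in ms (positive or negative).
#' @return The shifted [spike_train()] with the same duration.
#' @export
shift_spike_train <- function(train, delta) {
  stopifnot(is_spike_train(train))
  spike_train(train$times + delta, train$duration)
}

#' Read and write spike trains as JSON
#'
#' The on-disk format is a single JSON object
#' `{"duration_ms": <number>, "times_ms": [<numbers>]}`. Writing keeps full
#' double precision; reading validates ordering and range so a malformed
#' file is rejected with a descriptive error.
#'
#' @param train A [spike_train()].
#' @param path File path.
#' @return `read_spike_train()` returns a [spike_train()];
#'   `write_spike_train()` returns `path` invisibly.
#' @export
write_spike_train <- function(train, path) {
  stopifnot(is_spike_train(train))
  obj <- list(duration_ms = train$duration, times_ms = I(train$times))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path) {
  if (!file.exists(path))
    stop("spike-train file not found: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed spike-train JSON in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || is.null(obj$duration_ms) || is.null(obj$times_ms))
    stop("spike-train JSON must contain `duration_ms` and `times_ms`",
         call. = FALSE)
  spike_train(as.numeric(obj$times_ms), as.numeric(obj$duration_ms))
}
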