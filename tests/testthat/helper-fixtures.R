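# Shared fixtures: small random trains and a reference implementation of
# the double-sum learning brackets (naive four-deep loops), used as the
# independent oracle for the compiled path.

random_train <- function(n, duration = 200) {
  spike_train(sort(runif(n, 0, duration)), duration)
}

# naive nested-loop evaluation of the weight-rule bracket
naive_bracket <- function(input, delay, desired, actual, scale) {
  acc <- 0
  for (tf in input$times) {
    for (tg in desired$times)
      acc <- acc + exp(-abs(tg - tf - delay) / scale)
    for (th in actual$times)
      acc <- acc - exp(-abs(th - tf - delay) / scale)
  }
  acc
}

# pure-R clock-driven simulator used as the oracle for the compiled one;
# no PSP cutoff, direct evaluation at every grid point
reference_simulate <- function(inputs, weights, delays, params, sim) {
  tg <- seq(0, by = sim$dt, length.out = round(sim$duration / sim$dt) + 1)
  arrivals <- numeric(0)
  warr <- numeric(0)
  for (i in seq_along(inputs)) {
    arrivals <- c(arrivals, inputs[[i]]$times + delays[i])
    warr <- c(warr, rep(weights[i], length(inputs[[i]]$times)))
  }
  last <- -Inf
  out <- numeric(0)
  for (t in tg) {
    s <- t - arrivals
    u <- sum(warr * ifelse(s > 0, (s / params$tau_psp) *
                             exp(1 - s / params$tau_psp), 0))
    if (is.finite(last) && t > last)
      u <- u - params$theta * exp(-(t - last) / params$tau_ref)
    if (u >= params$theta - 1e-9 && (t - last) > params$t_abs) {
      out <- c(out, t)
      last <- t
    }
  }
  spike_train(out, sim$duration)
}
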