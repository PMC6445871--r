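test_that("weight rule matches hand-evaluated double sums", {
  lap <- kernel_spec("laplacian", 10)
  inp <- spike_train(0, 200)
  expect_equal(
    weight_delta(inp, 5, spike_train(10, 200), spike_train(20, 200),
                 eta = 0.005, kernel = lap),
    0.005 * (exp(-0.5) - exp(-1.5)), tolerance = 1e-9)
  # identical desired/actual cancel exactly
  d <- spike_train(c(10, 50), 200)
  expect_equal(weight_delta(inp, 3, d, d, 0.01, lap), 0)
  # empty input gives an empty double sum
  expect_equal(weight_delta(spike_train(numeric(0), 200), 0,
                            d, spike_train(numeric(0), 200), 0.01, lap), 0)
})

test_that("delay rule matches hand-evaluated double sums", {
  lap <- kernel_spec("laplacian", 10)
  inp <- spike_train(0, 200)
  expect_equal(
    delay_delta(inp, weight = 0.5, delay = 5, spike_train(10, 200),
                spike_train(20, 200), alpha = 3, kernel = lap),
    (3 * 0.5 / 10) * (exp(-0.5) - exp(-1.5)), tolerance = 1e-9)
  expect_equal(delay_delta(inp, 0, 5, spike_train(10, 200),
                           spike_train(20, 200), 3, lap), 0)
  d <- spike_train(c(10, 50), 200)
  expect_equal(delay_delta(inp, 0.4, 3, d, d, 3, lap), 0)
})

test_that("update rules are linear in their rates and in the weight", {
  set.seed(9)
  inp <- random_train(4)
  des <- random_train(6)
  act <- random_train(5)
  lap <- kernel_spec("laplacian", 10)
  w1 <- weight_delta(inp, 2, des, act, 0.005, lap)
  expect_equal(weight_delta(inp, 2, des, act, 0.015, lap), 3 * w1,
               tolerance = 1e-12)
  d1 <- delay_delta(inp, 0.2, 2, des, act, 3, lap)
  expect_equal(delay_delta(inp, 0.2, 2, des, act, 6, lap), 2 * d1,
               tolerance = 1e-12)
  expect_equal(delay_delta(inp, 0.4, 2, des, act, 3, lap), 2 * d1,
               tolerance = 1e-12)
})

test_that("compiled double sums match the naive nested-loop oracle", {
  set.seed(17)
  lap <- kernel_spec("laplacian", 10)
  worst <- 0
  for (k in 1:100) {
    inp <- random_train(sample(0:6, 1))
    des <- random_train(sample(0:8, 1))
    act <- random_train(sample(0:8, 1))
    delay <- runif(1, 0, 15)
    ref <- naive_bracket(inp, delay, des, act, 10)
    got <- weight_delta(inp, delay, des, act, eta = 1, kernel = lap)
    worst <- max(worst, abs(got - ref))
    got_d <- delay_delta(inp, 1, delay, des, act, alpha = 10, kernel = lap)
    worst <- max(worst, abs(got_d - ref))
  }
  expect_lt(worst, 1e-10)
})

test_that("scaling factor and adaptive rate follow the three branches", {
  expect_equal(scaling_factor_beta(50, 40, 60), 1)
  expect_equal(scaling_factor_beta(40, 40, 60), 1)
  expect_equal(scaling_factor_beta(60, 40, 60), 1)
  expect_equal(scaling_factor_beta(30, 40, 60), 0.5)
  expect_equal(scaling_factor_beta(90, 40, 60), 1.5)
  expect_error(scaling_factor_beta(10, 50, 50), "degenerate")
  expect_error(scaling_factor_beta(-1, 40, 60), "non-negative")

  expect_equal(adaptive_rate(50, 0.005, 40, 60), 0.005)
  expect_equal(adaptive_rate(30, 0.005, 40, 60), 0.0075)
  expect_equal(adaptive_rate(90, 0.005, 40, 60), 0.002)
  # a silent neuron uses the below-band branch
  expect_equal(adaptive_rate(0, 0.005, 40, 60), 0.005 * (1 + 2))
})

test_that("apply_updates clamps delays (and bounded weights) correctly", {
  st <- synapse_state(c(0.1, 0.2, 0.3), c(14.5, 0.2, 7), d_min = 0,
                      d_max = 15)
  same <- apply_updates(st, c(0, 0, 0), c(0, 0, 0))
  expect_equal(same$weights, st$weights)
  expect_equal(same$delays, st$delays)

  up <- apply_updates(st, c(0, 0, 0), c(1, -1, 0))
  expect_equal(up$delays, c(15, 0, 7))
  # unbounded weights move freely
  up2 <- apply_updates(st, c(10, -10, 0), c(0, 0, 0))
  expect_equal(up2$weights, c(10.1, -9.8, 0.3))
  # bounded weights are clamped
  stb <- synapse_state(c(0.1, 0.4), c(1, 2), w_min = 0, w_max = 0.5)
  upb <- apply_updates(stb, c(1, -1), c(0, 0))
  expect_equal(upb$weights, c(0.5, 0))
  expect_error(apply_updates(st, c(0, 0), c(0, 0, 0)), "match")
})

test_that("synapse_state validates bounds", {
  expect_error(synapse_state(1, 20, d_max = 15), "within")
  expect_error(synapse_state(c(1, 2), 1), "equal length")
  expect_error(synapse_state(1, 1, w_min = 0), "both")
  expect_error(synapse_state(0.9, 1, w_min = 0, w_max = 0.5), "within")
})

test_that("a state reproducing the desired train is a fixed point of training", {
  # single synapse, weight 1, input at 10 produces a spike at 12;
  # desire exactly that
  inputs <- list(spike_train(10, 200))
  desired <- spike_train(12, 200)
  st <- synapse_state(1, 0)
  res <- train_neuron(inputs, desired, st, cfg = learning_config(max_epochs = 5))
  expect_true(res$converged)
  expect_equal(res$epochs_run, 1)
  expect_equal(res$final_state$weights, 1)
  expect_equal(res$final_state$delays, 0)
  expect_equal(res$best_c, 1, tolerance = 1e-9)
})

test_that("training with both channels frozen leaves C constant", {
  set.seed(4)
  inputs <- replicate(30, random_train(4, 100), simplify = FALSE)
  desired <- random_train(5, 100)
  st <- init_synapse_state(30)
  res <- train_neuron(inputs, desired, st,
                      sim = sim_config(100, 0.1),
                      cfg = learning_config(max_epochs = 10,
                                            adapt_weights = FALSE,
                                            adapt_delays = FALSE))
  expect_equal(length(res$c_history), 10)
  expect_equal(length(unique(res$c_history)), 1L)
  expect_equal(res$best_c, res$c_history[1])
  expect_equal(res$epoch_of_best_c, 1L)
})

test_that("delays stay inside their bounds after every epoch", {
  set.seed(14)
  inputs <- replicate(40, random_train(3, 100), simplify = FALSE)
  desired <- random_train(5, 100)
  st <- init_synapse_state(40, d_min = 0, d_max = 15)
  res <- train_neuron(inputs, desired, st, sim = sim_config(100, 0.1),
                      cfg = learning_config(max_epochs = 30, alpha = 10))
  expect_true(all(res$final_state$delays >= 0))
  expect_true(all(res$final_state$delays <= 15))
  expect_true(all(res$final_state$weights >= 0))
  expect_true(all(res$final_state$weights <= 0.5))
  expect_lte(res$epoch_of_best_c, res$epochs_run)
  expect_equal(res$best_c, max(res$c_history))
})

test_that("training writes a per-epoch CSV log on request", {
  set.seed(2)
  inputs <- replicate(10, random_train(3, 100), simplify = FALSE)
  desired <- random_train(4, 100)
  path <- withr::local_tempfile(fileext = ".csv")
  res <- train_neuron(inputs, desired, init_synapse_state(10),
                      sim = sim_config(100, 0.1),
                      cfg = learning_config(max_epochs = 5),
                      log_path = path)
  log <- read.csv(path)
  expect_named(log, c("epoch", "c", "n_output_spikes", "eta"))
  expect_equal(nrow(log), res$epochs_run)
  expect_equal(log$c, res$c_history, tolerance = 1e-12)
})

test_that("kernel-space error is zero iff the trains coincide", {
  a <- spike_train(c(20, 60), 200)
  expect_equal(spike_train_error(a, a), 0, tolerance = 1e-12)
  b <- spike_train(c(20, 61), 200)
  expect_gt(spike_train_error(a, b), 0)
})

test_that("signed delay-rule variant flips with the spike-time ordering", {
  lap <- kernel_spec("laplacian", 10)
  inp <- spike_train(50, 200)
  late <- spike_train(60, 200)    # desired after arrival
  early <- spike_train(40, 200)   # desired before arrival
  none <- spike_train(numeric(0), 200)
  dd_late <- delay_delta(inp, 0.5, 0, late, none, 3, lap, signed = TRUE)
  dd_early <- delay_delta(inp, 0.5, 0, early, none, 3, lap, signed = TRUE)
  expect_gt(dd_late, 0)
  expect_lt(dd_early, 0)
  # the as-printed rule has no sign: both positive and equal
  expect_equal(delay_delta(inp, 0.5, 0, late, none, 3, lap),
               delay_delta(inp, 0.5, 0, early, none, 3, lap))
  expect_error(delay_delta(inp, 0.5, 0, late, none, 3,
                           kernel_spec("gaussian", 5), signed = TRUE),
               "Laplacian")
})

test_that("gaussian learning kernel uses the kernel-derivative delay rule", {
  gau <- kernel_spec("gaussian", 5)
  inp <- spike_train(0, 200)
  # single desired spike at 10, arrival at delay 5: x = 5
  dd <- delay_delta(inp, 1, 5, spike_train(10, 200),
                    spike_train(numeric(0), 200), alpha = 1, kernel = gau)
  expect_equal(dd, (5 / 25) * exp(-25 / 50), tolerance = 1e-9)
})
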