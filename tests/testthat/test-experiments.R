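# Harness tests run at deliberately small network sizes (tens of synapses,
# 100 ms trains, few epochs) so the full suite stays fast; the benchmark-
# scale behavior is covered by the acceptance tests.

small_spec <- function(...) {
  args <- list(n_inputs = 30, r_in = 20, r_out = 40, duration = 100,
               trials = 3, max_epochs = 15, seed_base = 500)
  do.call(benchmark_spec, utils::modifyList(args, list(...)))
}

test_that("run_trial is deterministic given its seed", {
  spec <- small_spec()
  a <- run_trial(spec, 7)
  b <- run_trial(spec, 7)
  expect_identical(a$c_history, b$c_history)
  expect_identical(a$final_state$weights, b$final_state$weights)
  expect_identical(a$final_state$delays, b$final_state$delays)
  expect_identical(a$final_output$times, b$final_output$times)
  expect_equal(a$seed, 7)
})

test_that("static/static trials keep the epoch-1 accuracy as best C", {
  spec <- small_spec(weight_mode = "static", delay_mode = "static")
  res <- run_trial(spec, 3)
  expect_equal(res$best_c, res$c_history[1])
  expect_equal(length(unique(res$c_history)), 1L)
  expect_false(res$converged)
})

test_that("mode flags change nothing about a trial's data or initialization", {
  # paired design: same seed, different modes -> same inputs/desired/state
  dyn <- small_spec(delay_mode = "dynamic", max_epochs = 1)
  sta <- small_spec(delay_mode = "static", max_epochs = 1)
  a <- run_trial(dyn, 11)
  b <- run_trial(sta, 11)
  # epoch 1 runs on identical state, so C must coincide
  expect_equal(a$c_history[1], b$c_history[1])
})

test_that("aggregate_results computes sample statistics", {
  fake <- function(best, epoch) {
    structure(list(best_c = best, epoch_of_best_c = epoch), class = "trial_result")
  }
  agg <- aggregate_results(list(fake(0.9, 10), fake(1.0, 20)))
  expect_equal(agg$mean_best_c, 0.95)
  expect_equal(agg$sd_best_c, sd(c(0.9, 1.0)), tolerance = 1e-9)
  expect_equal(agg$mean_epoch_of_best_c, 15)
  expect_true(agg$sd_defined)

  one <- aggregate_results(list(fake(0.8, 5)))
  expect_equal(one$sd_best_c, 0)
  expect_false(one$sd_defined)

  same <- aggregate_results(list(fake(0.7, 3), fake(0.7, 3)))
  expect_equal(same$sd_best_c, 0)
  expect_error(aggregate_results(list()), "no trial")
})

test_that("run_sweep aggregates per value and validates the parameter", {
  spec <- small_spec(trials = 2, max_epochs = 5)
  sw <- run_sweep(spec, "alpha", c(1, 3))
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw$summary), 2)
  expect_equal(sort(sw$summary$value), c(1, 3))
  expect_equal(sw$summary$n, c(2, 2))
  # aggregates recomputable from the per-trial records
  for (v in c(1, 3)) {
    rec <- sw$records[sw$records$value == v, ]
    expect_equal(mean(rec$best_c),
                 sw$summary$mean_best_c[sw$summary$value == v])
  }
  expect_error(run_sweep(spec, "threshold", 1), "unknown sweep parameter")

  # single-value sweep reduces to plain trial aggregation
  sw1 <- run_sweep(spec, "d_max", 10)
  trials <- lapply(spec$seed_base + 1:2, function(s) {
    sp <- spec
    sp$d_max <- 10
    run_trial(sp, s)
  })
  agg <- aggregate_results(trials)
  expect_equal(sw1$summary$mean_best_c, agg$mean_best_c, tolerance = 1e-12)
})

test_that("the rate sweep ties input and desired rates together", {
  spec <- small_spec(trials = 1, max_epochs = 1)
  sw <- run_sweep(spec, "rate", 30)
  # regenerate what the trial saw
  set.seed(spec$seed_base + 1)
  inputs <- replicate(spec$n_inputs, poisson_spike_train(30, 100),
                      simplify = FALSE)
  desired <- poisson_spike_train(30, 100)
  expect_equal(sw$records$best_c[1] >= 0, TRUE)
  # spot-check determinism of the tied-rate generation path
  sp2 <- spec
  sp2$r_in <- 30
  sp2$r_out <- 30
  direct <- run_trial(sp2, spec$seed_base + 1)
  expect_equal(sw$records$best_c[1], direct$best_c)
})

test_that("compare_delay_modes pairs trials and collapses when learning is off", {
  spec <- small_spec(trials = 2, max_epochs = 4,
                     weight_mode = "static", alpha = 0)
  # with static weights and alpha = 0 the two arms are identical
  cmp <- compare_delay_modes(spec, "n_inputs", 20)
  expect_equal(cmp$dynamic$summary$mean_best_c,
               cmp$static$summary$mean_best_c, tolerance = 1e-12)

  # with learning on, both arms still share seeds
  spec2 <- small_spec(trials = 2, max_epochs = 4)
  cmp2 <- compare_delay_modes(spec2, "n_inputs", c(20, 30))
  expect_equal(cmp2$dynamic$records$seed, cmp2$static$records$seed)
})

test_that("ablation_grid runs all four cells on shared seeds", {
  spec <- small_spec(trials = 2, max_epochs = 4)
  ab <- ablation_grid(spec)
  expect_equal(nrow(ab$summary), 4)
  expect_setequal(
    paste(ab$summary$weight_mode, ab$summary$delay_mode),
    c("static static", "static dynamic", "dynamic static",
      "dynamic dynamic"))
  expect_equal(unique(ab$records$seed), spec$seed_base + 1:2)
  # every cell's aggregate is recomputable from its records
  for (k in seq_len(4)) {
    rec <- ab$records[ab$records$weight_mode == ab$summary$weight_mode[k] &
                        ab$records$delay_mode == ab$summary$delay_mode[k], ]
    expect_equal(mean(rec$best_c), ab$summary$mean_best_c[k])
  }
})

test_that("save_results writes trial CSV and summary JSON", {
  dir <- withr::local_tempdir()
  spec <- small_spec(trials = 2, max_epochs = 3)
  sw <- run_sweep(spec, "alpha", 3)
  paths <- save_results(sw, dir, prefix = "sweeptest")
  expect_true(all(file.exists(paths)))
  rec <- read.csv(file.path(dir, "sweeptest_trials.csv"))
  expect_equal(nrow(rec), 2)
  summ <- jsonlite::read_json(file.path(dir, "sweeptest_summary.json"),
                              simplifyVector = TRUE)
  expect_equal(summ$mean_best_c, sw$summary$mean_best_c,
               tolerance = 1e-6)
})
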