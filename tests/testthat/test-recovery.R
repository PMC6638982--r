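cfg_s <- task_config(n_trials = 150)

test_that("posterior predictive band behaves and covers the data plausibly", {
  ses <- simulate_session(cfg_s, "exp_bias", list(alpha = 0.2, w = 0.7),
                          "covert", seed = 61)
  fit <- fit_observer(ses, "exp_bias", n = 10)
  pp <- posterior_predictive(fit, n_param_draws = 200, n_resp_sims = 400,
                             seed = 2)
  expect_equal(nrow(pp$band), 150)
  expect_true(all(pp$band$sd >= 0))
  # calibration: fresh single-draw predictive trajectories should fall
  # inside the mean +/- SD band at roughly the nominal 68% pointwise rate
  cov <- vapply(1:30, function(k) {
    one <- posterior_predictive(fit, n_param_draws = 1, n_resp_sims = 400,
                                seed = 100 + k)
    mean(abs(one$band$mean - pp$band$mean) <= pp$band$sd)
  }, numeric(1))
  expect_gt(mean(cov), 0.68 - 0.15)
  expect_lt(mean(cov), 0.68 + 0.15)
  # determinism
  pp2 <- posterior_predictive(fit, n_param_draws = 200, n_resp_sims = 400,
                              seed = 2)
  expect_identical(pp$band, pp2$band)
})

test_that("overt posterior predictive uses the running-average summary", {
  ses <- simulate_session(cfg_s, "exp", list(alpha = 0.15), "overt", seed = 62)
  fit <- fit_observer(ses, "exp", n = 10)
  pp <- posterior_predictive(fit, n_param_draws = 60, seed = 3)
  inner <- pp$band$sd[is.finite(pp$band$sd)]
  expect_gt(length(inner), 100)
  expect_true(all(inner > 0))
})

test_that("parameter recovery report is reproducible and well-formed", {
  set.seed(71)
  tp <- data.frame(alpha = runif(4, 0.1, 0.3), w = runif(4, 0.5, 0.9))
  r1 <- parameter_recovery("exp_bias", tp, "covert", cfg_s, n = 10, seed = 5)
  r2 <- parameter_recovery("exp_bias", tp, "covert", cfg_s, n = 10, seed = 5)
  expect_identical(r1$estimates, r2$estimates)
  expect_setequal(r1$summary$parameter, c("alpha", "w", "sigma_v"))
  expect_true(all(is.finite(r1$summary$rmse)))
  expect_equal(nrow(r1$estimates), 4 * 3)
})

test_that("a noiseless overt exponential observer is recovered to grid resolution", {
  cfg0 <- task_config(n_trials = 300, lapse_overt = 0)
  ses <- simulate_session(cfg0, "exp", list(alpha = 0.25, sigma_a = 1e-9),
                          "overt", seed = 8)
  # alpha axis with 21 points puts 0.25 exactly on the grid
  fit <- fit_observer(ses, "exp", n = c(21), task = "overt", config = cfg0)
  expect_equal(unname(coef(fit)["alpha"]), 0.25, tolerance = 1e-9)
})

test_that("model recovery bookkeeping: confusion rows sum to the dataset count", {
  mr <- model_recovery(c("fixed", "exp"), n_datasets = 2, task = "covert",
                       config = cfg_s, n = 8, seed = 3)
  expect_equal(unname(rowSums(mr$confusion)), c(2, 2))
  expect_output(print(mr), "confusion")
})

test_that("generating-parameter ranges exist for the standard model set", {
  for (m in c("fixed", "exp", "exp_bias", "bayes_ideal", "bayes_r", "wilson")) {
    rg <- default_recovery_ranges(m, "covert")
    expect_true(all(vapply(rg, length, 1L) == 2))
  }
})
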