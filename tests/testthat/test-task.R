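test_that("probability path respects segment-length bounds and state rules", {
  cfg <- task_config(n_trials = 800)
  for (seed in 1:5) {
    p <- sample_probability_path(cfg, seed = seed)
    expect_length(p$pi, 800)
    expect_true(all(p$pi %in% cfg$state_set))
    nc <- sum(p$change)
    expect_gte(nc, 6)   # ceil(800/120) - 1
    expect_lte(nc, 9)   # ceil(800/80) - 1
    cps <- which(p$change)
    lens <- diff(c(0, cps))
    expect_true(all(lens >= 80 & lens <= 120))
    # the state changes exactly at flagged trials and nowhere else
    changes_at <- which(diff(p$pi) != 0)
    expect_identical(changes_at, cps)
  }
})

test_that("degenerate segment length places change points deterministically", {
  cfg <- task_config(n_trials = 300, run_min = 100, run_max = 100)
  p <- sample_probability_path(cfg, seed = 1)
  expect_identical(which(p$change), c(100L, 200L))
})

test_that("sampled segment lengths have the discrete-uniform mean", {
  cfg <- task_config(n_trials = 60000)
  lens <- unlist(lapply(1:10, function(s) {
    p <- sample_probability_path(cfg, seed = s)
    diff(which(p$change))           # complete interior segments only
  }))
  expect_gt(length(lens), 500)
  expect_lt(abs(mean(lens) - 100), 1.5)
})

test_that("invalid configurations are rejected", {
  expect_error(task_config(run_min = 0), "run_min")
  expect_error(task_config(run_min = 50, run_max = 40), "run_min")
  expect_error(task_config(state_set = c(0.5, 0.2)), "sorted")
  expect_error(task_config(sigma_s = -1), "SD")
})

test_that("category separation yields the requested discriminability", {
  expect_equal(category_separation_for_dprime(10, 10, 1.5), 1.5 * sqrt(200))
  expect_equal(category_separation_for_dprime(10, 0, 1.5), 15)
  d <- category_separation_for_dprime(10, 10, 1.5)
  expect_equal(d / sqrt(10^2 + 10^2), 1.5)
  expect_error(category_separation_for_dprime(-1, 10, 1.5), "positive")
  expect_error(category_separation_for_dprime(10, 10, 0), "positive")
})

test_that("trial generation is reproducible and category frequency tracks pi", {
  cfg <- task_config(n_trials = 4000, run_min = 2000, run_max = 2000)
  t1 <- simulate_trials(cfg, seed = 3)
  t2 <- simulate_trials(cfg, seed = 3)
  expect_identical(t1, t2)
  for (seg in split(t1, t1$pi_t)) {
    ph <- mean(seg$category == "A")
    p0 <- seg$pi_t[1]
    se <- sqrt(p0 * (1 - p0) / nrow(seg))
    expect_lt(abs(ph - p0), 4 * se)
  }
})

test_that("simulated sessions are seed-deterministic end to end", {
  cfg <- task_config(n_trials = 150)
  for (task in c("covert", "overt")) {
    s1 <- simulate_session(cfg, "exp_bias", list(alpha = 0.2, w = 0.7),
                           task, seed = 9)
    s2 <- simulate_session(cfg, "exp_bias", list(alpha = 0.2, w = 0.7),
                           task, seed = 9)
    expect_identical(s1$trials, s2$trials)
  }
  expect_error(simulate_session(cfg, "no_such_model", list(), "covert"),
               "unknown observer model")
})

test_that("fixed observer on symmetric stimuli reports A about half the time", {
  cfg <- task_config(n_trials = 4000, run_min = 4000, run_max = 4000)
  path <- list(pi = rep(0.5, 4000), change = logical(4000))
  tr <- simulate_trials(cfg, seed = 5, path = path)
  ses <- simulate_session(cfg, "fixed", list(), "covert", seed = 6, trials = tr)
  expect_lt(abs(mean(ses$trials$response == "A") - 0.5), 0.03)
})

test_that("noiseless overt reports equal the model criterion exactly", {
  cfg <- task_config(n_trials = 100, lapse_overt = 0)
  ses <- simulate_session(cfg, "exp", list(alpha = 0.1, sigma_a = 0),
                          "overt", seed = 2)
  pi_hat <- probability_traj("exp", list(alpha = 0.1),
                             ses$trials$category, cfg)
  z <- optimal_criterion(pi_hat, category_model(cfg, "overt"))
  expect_equal(as.numeric(ses$trials$response), z)
})
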