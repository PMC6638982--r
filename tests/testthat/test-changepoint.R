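cfg <- task_config()

test_that("hazard of the believed discrete-uniform run length", {
  sp <- changepoint_spec(cfg$state_set, 80, 120)
  expect_equal(hazard(79, sp), 0)
  expect_equal(hazard(80, sp), 1 / 41)
  expect_equal(hazard(120, sp), 1)
  expect_equal(hazard(500, sp), 1)   # clamped above the support
  expect_error(hazard(-1, sp), ">= 0")
})

test_that("conditional state posterior matches hand-computed cases", {
  sp <- changepoint_spec(cfg$state_set, 80, 120, beta = 1)
  # flat prior, no data: uniform over the four non-excluded states
  p0 <- conditional_state_posterior(c(0, 0), 0.5, sp)
  expect_equal(unname(p0), c(0.25, 0.25, 0, 0.25, 0.25))
  # two A's: weights proportional to pi^2 over the remaining states
  p2 <- conditional_state_posterior(c(2, 0), 0.5, sp)
  expect_equal(unname(p2[5]), 0.64 / 1.225)
  expect_error(conditional_state_posterior(c(1, 0), 0.42, sp), "state set")
  # strong equal-probability hyperprior concentrates mass near 0.5
  spb <- changepoint_spec(cfg$state_set, 80, 120, beta = 100)
  pb <- conditional_state_posterior(c(0, 0), NA, spb)
  expect_gt(pb[3], 0.99)
})

test_that("filtered joint posterior equals brute-force enumeration", {
  sp <- changepoint_spec(c(0.2, 0.5, 0.8), 2, 4, beta = 1)
  set.seed(11)
  for (rep in 1:4) {
    lab <- rbinom(10, 1, 0.5)
    expect_lt(max(abs(filter_joint_posterior(lab, sp) -
                        enumerate_joint_posterior(lab, sp))), 1e-10)
  }
  # non-uniform hyperprior and asymmetric states
  sp2 <- changepoint_spec(c(0.25, 0.45, 0.7), 2, 4, beta = 3)
  lab <- rbinom(9, 1, 0.7)
  expect_lt(max(abs(filter_joint_posterior(lab, sp2) -
                      enumerate_joint_posterior(lab, sp2))), 1e-10)
})

test_that("belief stays normalized and predictive stays within the state range", {
  sp <- changepoint_spec(cfg$state_set, 5, 15)
  set.seed(4)
  b <- new_joint_belief(sp)
  for (c in rbinom(60, 1, 0.7)) {
    b <- update_joint_belief(b, c)
    expect_lt(abs(sum(b$w) - 1), 1e-12)
    expect_true(all(b$w >= 0))
    p <- predictive_category_prob(b)
    expect_gte(p, min(sp$states))
    expect_lte(p, max(sp$states))
  }
})

test_that("with no change possible the run length is deterministic", {
  sp <- changepoint_spec(c(0.3, 0.5, 0.7), 50, 60)  # L_min > T: hazard 0
  set.seed(2)
  lab <- rbinom(20, 1, 0.5)
  w <- filter_joint_posterior(lab, sp)
  r_marg <- rowSums(w)
  expect_equal(which(r_marg > 1e-12), 21L)  # row 21 is run length 20
})

test_that("fresh symmetric belief predicts 0.5", {
  sp <- changepoint_spec(cfg$state_set, 80, 120)
  expect_equal(predictive_category_prob(new_joint_belief(sp)), 0.5)
})

test_that("label order within a hazard-free window does not matter", {
  sp <- changepoint_spec(cfg$state_set, 30, 40)
  set.seed(8)
  lab <- rbinom(12, 1, 0.6)
  w1 <- filter_joint_posterior(lab, sp)
  w2 <- filter_joint_posterior(sample(lab), sp)
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("incorrect-belief variants reduce to the ideal observer", {
  lab <- simulate_trials(cfg, seed = 21)$category
  p_ideal <- run_bayes_sequence(lab, belief_spec_for_model("bayes_ideal", list(), cfg))
  p_r <- run_bayes_sequence(lab, belief_spec_for_model("bayes_r", list(r = 120), cfg))
  p_pi <- run_bayes_sequence(lab, belief_spec_for_model("bayes_pi", list(pi_min = 0.2), cfg))
  p_b <- run_bayes_sequence(lab, belief_spec_for_model("bayes_beta", list(beta = 1), cfg))
  expect_equal(p_r, p_ideal, tolerance = 1e-12)
  expect_equal(p_pi, p_ideal, tolerance = 1e-12)
  expect_equal(p_b, p_ideal, tolerance = 1e-12)
})

test_that("a long A streak drives the predictive to the top believed state", {
  pA <- run_bayes_sequence(rep(1, 80),
                           belief_spec_for_model("bayes_ideal", list(), cfg))
  expect_lt(abs(pA[80] - 0.8), 1e-3)
})

test_that("empty label sequence yields empty output", {
  sp <- changepoint_spec(cfg$state_set, 80, 120)
  expect_identical(run_bayes_sequence(integer(0), sp), numeric(0))
})

test_that("belief specification rejects invalid values", {
  expect_error(changepoint_spec(c(0.2, 0.8), 0, 10), "L_min")
  expect_error(changepoint_spec(c(0.2, 0.8), 10, 5), "L_min")
  expect_error(changepoint_spec(c(0.2, 1.2), 1, 5), "\\(0,1\\)")
  expect_error(changepoint_spec(c(0.2, 0.8), 1, 5, beta = 0), "beta")
})
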