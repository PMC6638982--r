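cfg <- task_config()

test_that("exponential averaging follows the delta rule", {
  st <- exp_state(0.04)
  expect_equal(exp_update(st, "A")$estimate, 0.52)
  # memoryless limit: the estimate equals the last label indicator
  st1 <- exp_state(1)
  expect_equal(exp_update(st1, "B")$estimate, 0)
  expect_equal(exp_update(st1, "A")$estimate, 1)
  # time constant of memory decay at a typical smoothing factor
  expect_equal(-1 / log(1 - 0.17), 5.3668, tolerance = 1e-4)
})

test_that("conservative blend interpolates between estimate and 0.5", {
  expect_equal(bias_blend(0.8, 1), 0.8)
  expect_equal(bias_blend(0.8, 0), 0.5)
  expect_equal(bias_blend(0.8, 0.58), 0.674)
  expect_error(bias_blend(1.2, 0.5), "\\[0, 1\\]")
})

test_that("exp and exp_bias with w = 1 produce identical trajectories", {
  set.seed(1)
  lab <- rbinom(400, 1, 0.65)
  expect_identical(probability_traj("exp", list(alpha = 0.3), lab, cfg),
                   probability_traj("exp_bias", list(alpha = 0.3, w = 1), lab, cfg))
})

test_that("Wilson node machinery matches its stated limits", {
  # Eq-5 arithmetic: node at run length 1 with prior strength 2
  st <- wilson_state(c(1, 5, 20), nu_p = 2)
  expect_equal(st$rates[1], 1 / 3)
  # single node pinned at l1 with an explicit rate is the exp model
  set.seed(2)
  lab <- rbinom(300, 1, 0.6)
  w_traj <- critlearn:::wilson_traj(lab, nodes = 1, nu_p = 0, rates = 0.13)
  e_traj <- critlearn:::exp_traj(lab, 0.13)
  expect_equal(w_traj, e_traj, tolerance = 1e-14)
  # zero hazard with all weight on the top node: fixed-rate delta rule
  st <- wilson_state(c(1, 5, 20), nu_p = 2, h = 0, weights = c(0, 0, 1))
  est <- 0.5
  for (c in lab[1:50]) {
    st <- wilson_update(st, c)
    est <- est + (c - est) / 22
    expect_equal(st$weights, c(0, 0, 1))
    expect_equal(st$estimates[3], est)
    expect_equal(wilson_estimate(st), est)
  }
})

test_that("Wilson weights remain a simplex and the estimate is convex", {
  set.seed(3)
  st <- wilson_state(c(1, 12, 100), nu_p = 40)
  for (c in rbinom(500, 1, runif(1))) {
    st <- wilson_update(st, c)
    expect_lt(abs(sum(st$weights) - 1), 1e-12)
    expect_true(all(st$weights >= -1e-15))
    e <- wilson_estimate(st)
    expect_gte(e, min(st$estimates) - 1e-12)
    expect_lte(e, max(st$estimates) + 1e-12)
  }
})

test_that("RL criterion moves only after errors", {
  st <- rl_state(0.26, z = 0)
  expect_equal(rl_update(st, 10, TRUE)$z, 0)
  expect_equal(rl_update(st, 10, FALSE)$z, 2.6)
  st0 <- rl_state(0, z = 0)
  for (i in 1:10) st0 <- rl_update(st0, rnorm(1, 0, 20), FALSE)
  expect_equal(st0$z, 0)
})

test_that("volatility-tracking learner: symmetry and concentration", {
  g <- behrens_grid()
  expect_equal(behrens_estimate(g), 0.5)       # flat prior
  expect_lt(abs(sum(g$p) - 1), 1e-12)
  tr <- critlearn:::behrens_traj(rep(1, 50))
  expect_gt(tail(tr, 1), 0.9)                  # 50 A's concentrate high
  set.seed(4)
  lab <- rbinom(80, 1, 0.3)
  a <- critlearn:::behrens_traj(lab)
  b <- critlearn:::behrens_traj(1 - lab)
  expect_equal(a, 1 - b, tolerance = 1e-12)    # label-swap symmetry
})

test_that("grid mass is conserved across volatility-learner updates", {
  set.seed(5)
  g <- behrens_grid()
  for (c in rbinom(40, 1, 0.7)) {
    g <- behrens_update(g, c)
    expect_lt(abs(sum(g$p) - 1), 1e-9)
  }
})

test_that("all probability estimates stay in [0,1] on arbitrary label streams", {
  set.seed(6)
  streams <- list(rbinom(200, 1, 0.05), rbinom(200, 1, 0.95),
                  rep(c(1, 0), 100), rbinom(200, 1, 0.5))
  cases <- list(
    list("exp", list(alpha = 0.9)),
    list("exp_bias", list(alpha = 0.99, w = 0.99)),
    list("wilson", list(l2 = 3, l3 = 8, nu_p = 1)),
    list("bayes_ideal", list()),
    list("bayes_pi", list(pi_min = 0.05)),
    list("bayes_beta", list(beta = 40)))
  for (lab in streams) for (cs in cases) {
    tr <- probability_traj(cs[[1]], cs[[2]], lab, cfg)
    expect_true(all(tr >= 0 & tr <= 1), label = cs[[1]])
  }
})
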