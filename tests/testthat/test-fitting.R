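cfg <- task_config(n_trials = 400)
ses_cov <- simulate_session(cfg, "exp_bias", list(alpha = 0.2, w = 0.7),
                            "covert", seed = 31)
ses_ov <- simulate_session(cfg, "exp", list(alpha = 0.1), "overt", seed = 32)

test_that("fixed-model covert likelihood equals its direct composition", {
  ll <- sequence_log_likelihood(ses_cov, "fixed", list(sigma_v = 9), "covert", cfg)
  p <- covert_choice_prob(ses_cov$trials$stimulus_deg, 0, 9, cfg$lapse_covert)
  direct <- sum(log(ifelse(ses_cov$trials$response == "A", p, 1 - p)))
  expect_equal(ll, direct)
})

test_that("grid log-likelihood values agree with the scalar likelihood API", {
  g <- grid_log_posterior(ses_cov, "exp_bias", n = 8)
  set.seed(1)
  for (i in 1:4) {
    idx <- vapply(dim(g$loglik), function(d) sample.int(d, 1), 1L)
    u <- vapply(seq_along(g$axes), function(j) g$axes[[j]][idx[j]], 0)
    p <- critlearn:::natural_params(u, g$info, "exp_bias")
    ll <- sequence_log_likelihood(ses_cov, "exp_bias", p, "covert", cfg)
    expect_equal(g$loglik[matrix(idx, 1)], ll, tolerance = 1e-10)
  }
  # the same identity on the overt task
  g2 <- grid_log_posterior(ses_ov, "exp", n = 8)
  idx <- c(3L, 5L)
  u <- c(g2$axes[[1]][3], g2$axes[[2]][5])
  p <- critlearn:::natural_params(u, g2$info, "exp")
  expect_equal(g2$loglik[matrix(idx, 1)],
               sequence_log_likelihood(ses_ov, "exp", p, "overt", cfg),
               tolerance = 1e-10)
})

test_that("trapezoidal marginal likelihood matches a Gaussian closed form", {
  th <- seq(-5, 5, length.out = 100)
  g <- structure(list(axes = list(th = th),
                      loglik = array(dnorm(0.3, th, 1, log = TRUE), 100),
                      log_prior = -log(10)),
                 class = "fit_grid")
  closed <- log((pnorm(5, 0.3, 1) - pnorm(-5, 0.3, 1)) / 10)
  expect_lt(abs(marginal_likelihood(g) - closed), 1e-3)
  # axis reversal leaves the integral unchanged
  g2 <- g
  g2$axes$th <- rev(th)
  g2$loglik <- array(rev(g2$loglik), 100)
  expect_lt(abs(marginal_likelihood(g2) - marginal_likelihood(g)), 1e-6)
  # constant likelihood with a proper prior: LML equals that constant
  gc <- structure(list(axes = list(th = th),
                       loglik = array(-7.5, 100), log_prior = -log(10)),
                  class = "fit_grid")
  expect_equal(marginal_likelihood(gc), -7.5, tolerance = 1e-12)
  g1pt <- structure(list(axes = list(th = 1), loglik = array(0, 1),
                         log_prior = 0), class = "fit_grid")
  expect_error(marginal_likelihood(g1pt), "degenerate")
})

test_that("grid LML is stable under doubling the resolution", {
  l50 <- marginal_likelihood(grid_log_posterior(ses_cov, "exp", n = 50))
  l100 <- marginal_likelihood(grid_log_posterior(ses_cov, "exp", n = 100))
  expect_lt(abs(l50 - l100), 0.1)
})

test_that("grid resolutions follow the fitting protocol and honor overrides", {
  expect_equal(dim(grid_log_posterior(ses_cov, "exp", n = NULL)$loglik)[1], 100)
  pri <- parameter_priors("wilson", "covert")
  expect_equal(nrow(pri), 4)   # sigma + two node spacings + prior strength
  g <- grid_log_posterior(ses_cov, "exp_bias", n = c(alpha = 7, w = 5))
  expect_equal(dim(g$loglik), c(100L, 7L, 5L))
  expect_error(grid_log_posterior(ses_cov, "exp", n = c(bogus = 5)),
               "unknown parameter")
})

test_that("likelihood surface peaks near the generating parameters", {
  cfg8 <- task_config(n_trials = 800)
  lls <- sapply(1:5, function(s) {
    ses <- simulate_session(cfg8, "exp_bias", list(alpha = 0.2, w = 0.7),
                            "covert", seed = 100 + s)
    at <- function(a, w) sequence_log_likelihood(
      ses, "exp_bias", list(alpha = a, w = w, sigma_v = 10), "covert", cfg8)
    at(0.2, 0.7) - max(at(0.4, 0.7), at(0.05, 0.7), at(0.2, 0.5), at(0.2, 0.9))
  })
  expect_gt(mean(lls), 0)
})

test_that("RL Monte-Carlo likelihood is stable across seeds", {
  cfg8 <- task_config(n_trials = 800)
  ses <- simulate_session(cfg8, "rl", list(alpha = 0.26), "covert", seed = 41)
  ll1 <- sequence_log_likelihood(ses, "rl", list(alpha = 0.26, sigma_v = 10),
                                 n_mc = 5000, mc_seed = 1)
  ll2 <- sequence_log_likelihood(ses, "rl", list(alpha = 0.26, sigma_v = 10),
                                 n_mc = 5000, mc_seed = 2)
  expect_lt(abs(ll1 - ll2), 0.5)
})

test_that("per-trial covert probabilities respect the lapse bounds", {
  g <- grid_log_posterior(ses_cov, "fixed", n = 5)
  n <- nrow(ses_cov$trials)
  lo <- n * log(cfg$lapse_covert / 2)
  hi <- n * log(1 - cfg$lapse_covert / 2)
  expect_true(all(g$loglik >= lo & g$loglik <= hi))
})

test_that("noise parameters are task-specific", {
  expect_equal(parameter_priors("exp", "covert")$name[1], "sigma_v")
  expect_equal(parameter_priors("exp", "overt")$name[1], "sigma_a")
  expect_false("sigma_v" %in% parameter_priors("exp", "overt")$name)
})

test_that("high-dimensional models are refused on the grid and sent to MLE", {
  expect_error(grid_log_posterior(ses_cov, "bayes_rpb"), "point_estimates")
  f <- fit_observer(ses_cov, "bayes_rpb", method = "grid", n_starts = 2,
                    seed = 1)
  expect_identical(f$method, "mle")
  expect_true(is.finite(f$max_loglik))
})

test_that("maximum likelihood dominates the grid MAP and obeys AIC/BIC identities", {
  fitg <- fit_observer(ses_cov, "exp_bias", n = 15)
  fitm <- point_estimates(ses_cov, "exp_bias", n_starts = 5, seed = 2)
  expect_gte(fitm$max_loglik, fitg$map_loglik - 1e-6)
  k <- 3; n <- 400
  expect_equal(fitm$aic - fitm$bic, 2 * k - k * log(n))
  expect_equal(2 * 2 - 2 * log(800), -9.37, tolerance = 1e-3)
  expect_equal(coef(fitm), unlist(fitm$mle[fitm$info$natural]))
})

test_that("grid fit exposes a coherent model object", {
  fit <- fit_observer(ses_cov, "exp_bias", n = 15)
  expect_s3_class(fit, "observer_fit")
  expect_true(is.finite(fit$lml))
  # LML can never exceed the best achievable likelihood
  expect_lt(fit$lml, fit$map_loglik)
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 3)
  expect_equal(attr(ll, "nobs"), 400)
  pr <- predict(fit)
  expect_equal(nrow(pr), 400)
  expect_true(all(is.finite(pr$criterion)))
  expect_output(print(fit), "log marginal likelihood")
  r <- residuals(fit)
  expect_length(r, 400)
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "cl_session")
})
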