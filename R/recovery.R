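# Validation machinery: posterior predictive trajectories with credible
# bands, parameter recovery, and model-recovery confusion analysis.

#' Posterior predictive summary trajectory of a grid fit
#'
#' Draws parameter combinations from the grid posterior (with replacement,
#' proportional to posterior mass), simulates the observer on the fitted
#' session's stimuli for each draw, and summarizes the simulated behavior
#' per trial: in the covert task the "excess A responses" trajectory
#' (cumulative A count minus t/2, each trial's choice averaged over
#' `n_resp_sims` Bernoulli draws); in the overt task the 5-trial running
#' average of the reported criterion. The pointwise mean and SD across
#' parameter draws form a 68% credible band.
#'
#' @param fit an `"observer_fit"` with `method = "grid"`.
#' @param n_param_draws posterior parameter draws (default 1000).
#' @param n_resp_sims response simulations per trial and draw (covert;
#'   default 10000).
#' @param seed RNG seed.
#' @return object of class `"posterior_predictive"`: data.frame `$band`
#'   with per-trial `mean` and `sd`, plus the observed summary trajectory
#'   `$observed`.
#' @export
posterior_predictive <- function(fit, n_param_draws = 1000,
                                 n_resp_sims = 10000, seed = 1L) {
  stop_if_not(inherits(fit, "observer_fit") && fit$method == "grid",
              "posterior_predictive needs a grid-based observer_fit")
  g <- fit$grid
  A <- g$loglik + g$log_prior
  post <- exp(A - max(A))
  tot <- sum(post)
  if (!is.finite(tot) || tot <= 0) stop("zero posterior mass", call. = FALSE)
  post <- post / tot
  df <- fit$trials
  n <- nrow(df)
  with_seed(seed, {
    nodes <- sample.int(length(post), n_param_draws, replace = TRUE,
                        prob = as.vector(post))
    idx <- arrayInd(nodes, dim(g$loglik))
    traj <- matrix(NA_real_, n_param_draws, n)
    for (i in seq_len(n_param_draws)) {
      u <- vapply(seq_along(g$axes), function(j) g$axes[[j]][idx[i, j]],
                  numeric(1))
      p <- natural_params(u, g$info, fit$model)
      if (fit$task == "covert") {
        cfg <- fit$config
        cfg$sigma_v <- p$sigma_v %||% cfg$sigma_v
        cm <- category_model(cfg, "covert")
        if (fit$model == "rl") {
          z <- rl_criterion_mc(df, "covert", p$alpha, cfg$sigma_v, fit$config,
                               n_mc = 500)
          pA <- colMeans(sweep(cfg$sigma_v *
                  matrix(stats::rnorm(500 * n), 500), 2, df$stimulus_deg,
                  "+") < z)
          pA <- (1 - fit$config$lapse_covert) * pA + fit$config$lapse_covert / 2
        } else {
          pi_hat <- probability_traj(fit$model, p, df$category, fit$config)
          z <- criterion_from_logodds(stats::qlogis(pi_hat), cm)
          pA <- covert_choice_prob(df$stimulus_deg, z, cfg$sigma_v,
                                   fit$config$lapse_covert)
        }
        aa <- stats::rbinom(n, n_resp_sims, pA) / n_resp_sims
        traj[i, ] <- cumsum(aa) - seq_len(n) / 2
      } else {
        if (fit$model == "rl") {
          zmat <- rl_criterion_mc(df, "overt", p$alpha, fit$config$sigma_v,
                                  fit$config, n_mc = 1)
          z <- zmat[1, ]
        } else {
          cm <- category_model(fit$config, "overt")
          pi_hat <- probability_traj(fit$model, p, df$category, fit$config)
          z <- criterion_from_logodds(stats::qlogis(pi_hat), cm)
        }
        rep_z <- z + stats::rnorm(n, 0, p$sigma_a %||% fit$config$sigma_a)
        traj[i, ] <- as.numeric(stats::filter(rep_z, rep(1 / 5, 5), sides = 2))
      }
    }
    obs <- if (fit$task == "covert")
      cumsum(as_label01(df$response)) - seq_len(n) / 2
    else as.numeric(stats::filter(as.numeric(df$response), rep(1 / 5, 5),
                                  sides = 2))
    structure(list(band = data.frame(trial = seq_len(n),
                                     mean = colMeans(traj),
                                     sd = apply(traj, 2, stats::sd)),
                   observed = obs, task = fit$task, model = fit$model,
                   n_param_draws = n_param_draws,
                   n_resp_sims = n_resp_sims),
              class = "posterior_predictive")
  })
}

#' @export
print.posterior_predictive <- function(x, ...) {
  cat(sprintf(
    "Posterior predictive for '%s' (%s task): %d parameter draws\n",
    x$model, x$task, x$n_param_draws))
  cat(sprintf("  mean band half-width (SD): %.3f\n",
              mean(x$band$sd, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.posterior_predictive <- function(x, ...) {
  b <- x$band
  ok <- is.finite(b$mean) & is.finite(b$sd)
  graphics::plot(b$trial, x$observed, type = "l", col = "grey40",
                 xlab = "trial",
                 ylab = if (x$task == "covert") "excess A responses"
                        else "criterion (deg, 5-trial average)", ...)
  graphics::polygon(c(b$trial[ok], rev(b$trial[ok])),
                    c((b$mean + b$sd)[ok], rev((b$mean - b$sd)[ok])),
                    col = grDevices::adjustcolor("firebrick", 0.3),
                    border = NA)
  graphics::lines(b$trial, b$mean, col = "firebrick")
  invisible(x)
}

#' Parameter-recovery analysis
#'
#' Simulates sessions from known parameter values, refits the generating
#' model, and reports per-parameter bias, RMSE and true-vs-recovered
#' correlation. Parameters whose mean bias exceeds twice its standard error
#' are flagged.
#'
#' @param model observer model id.
#' @param true_params data.frame of generating parameter values, one row
#'   per simulated dataset (column names as in the model's natural
#'   parameters; a noise column `sigma_v`/`sigma_a` may be included).
#' @param task `"covert"` or `"overt"`.
#' @param config a [task_config()] (defines session length and generative
#'   settings).
#' @param n grid resolution passed to [fit_observer()].
#' @param seed RNG seed.
#' @return object of class `"recovery_report"` with `$estimates` (true and
#'   recovered values per dataset) and `$summary` (bias, RMSE, correlation
#'   per parameter).
#' @export
parameter_recovery <- function(model, true_params, task = "covert",
                               config = task_config(), n = 25, seed = 1L) {
  stop_if_not(is.data.frame(true_params) && nrow(true_params) >= 1,
              "true_params must be a data.frame of generating values")
  nd <- nrow(true_params)
  rows <- vector("list", nd)
  for (i in seq_len(nd)) {
    p <- as.list(true_params[i, , drop = FALSE])
    ses <- simulate_session(config, model, p, task, seed = seed + i)
    fit <- fit_observer(ses, model, n = n)
    est <- coef(fit)
    tv <- unlist(p)[names(est)]
    rows[[i]] <- data.frame(dataset = i, parameter = names(est),
                            true = unname(tv), recovered = unname(est),
                            stringsAsFactors = FALSE)
  }
  est <- do.call(rbind, rows)
  # noise defaults used in generation when absent from true_params
  fill <- c(sigma_v = config$sigma_v, sigma_a = config$sigma_a)
  nafix <- is.na(est$true) & est$parameter %in% names(fill)
  est$true[nafix] <- fill[est$parameter[nafix]]
  summ <- do.call(rbind, lapply(split(est, est$parameter), function(d) {
    err <- d$recovered - d$true
    data.frame(parameter = d$parameter[1], bias = mean(err),
               bias_se = stats::sd(err) / sqrt(nrow(d)),
               rmse = sqrt(mean(err^2)),
               correlation = if (stats::sd(d$true) > 0)
                 stats::cor(d$true, d$recovered) else NA_real_,
               flagged = abs(mean(err)) >
                 2 * stats::sd(err) / sqrt(nrow(d)),
               stringsAsFactors = FALSE)
  }))
  structure(list(model = model, task = task, estimates = est,
                 summary = summ, n_datasets = nd),
            class = "recovery_report")
}

#' Model-recovery (confusion) analysis
#'
#' Checks that the candidate models are mutually discriminable on synthetic
#' data: simulates datasets from each generating model (parameters drawn
#' from plausible ranges), fits every candidate to every dataset, and
#' tallies which model attains the best log marginal likelihood.
#'
#' @param models character vector of model ids (>= 2); all are both
#'   generators and candidates.
#' @param n_datasets simulated datasets per generating model.
#' @param task,config task and generative settings.
#' @param n grid resolution for the fits.
#' @param param_ranges named list: for each model, a named list of
#'   `c(lo, hi)` ranges its generating parameters are drawn from; defaults
#'   from [default_recovery_ranges()].
#' @param seed RNG seed.
#' @return `"recovery_report"` whose `$confusion` is the generating x
#'   best-fitting count matrix (rows sum to `n_datasets`).
#' @export
model_recovery <- function(models, n_datasets = 10, task = "covert",
                           config = task_config(), n = 25,
                           param_ranges = NULL, seed = 1L) {
  stop_if_not(length(models) >= 2, "need at least 2 models")
  for (m in models) check_model_id(m)
  conf <- matrix(0L, length(models), length(models),
                 dimnames = list(generator = models, best_fit = models))
  fits_lml <- list()
  for (gi in seq_along(models)) {
    gm <- models[gi]
    ranges <- param_ranges[[gm]] %||% default_recovery_ranges(gm, task)
    for (d in seq_len(n_datasets)) {
      sd_i <- seed + 1000 * gi + d
      p <- with_seed(sd_i, lapply(ranges, function(r)
        stats::runif(1, r[1], r[2])))
      ses <- simulate_session(config, gm, p, task, seed = sd_i)
      lml <- vapply(models, function(cm)
        fit_observer(ses, cm, n = n)$lml, numeric(1))
      best <- which.max(lml)
      conf[gi, best] <- conf[gi, best] + 1L
      fits_lml[[paste(gm, d, sep = "_")]] <- lml
    }
  }
  structure(list(models = models, task = task, confusion = conf,
                 lml = fits_lml, n_datasets = n_datasets),
            class = "recovery_report")
}

#' Plausible generating-parameter ranges for recovery analyses
#'
#' Default ranges reflecting the parameter regimes typical of human
#' observers in this paradigm (smoothing factors of a few percent to a few
#' tens of percent, moderate conservatism, sensory noise near the category
#' SD).
#'
#' @param model observer model id.
#' @param task `"covert"` or `"overt"`.
#' @return named list of `c(lo, hi)` ranges.
#' @export
default_recovery_ranges <- function(model, task = "covert") {
  noise <- if (task == "covert") list(sigma_v = c(8, 12))
           else list(sigma_a = c(12, 20))
  c(noise, switch(model,
    fixed = , bayes_ideal = , behrens = list(),
    exp = , rl = list(alpha = c(0.1, 0.3)),
    exp_bias = list(alpha = c(0.1, 0.3), w = c(0.5, 0.9)),
    behrens_bias = list(w = c(0.3, 0.9)),
    bayes_r = list(r = c(30, 120)),
    bayes_pi = list(pi_min = c(0.1, 0.35)),
    bayes_beta = list(beta = c(1, 30)),
    wilson = list(l2 = c(5, 20), l3 = c(30, 120), nu_p = c(2, 50)),
    stop("no default ranges for model ", model)))
}

#' @export
print.recovery_report <- function(x, ...) {
  if (!is.null(x$confusion)) {
    cat(sprintf("Model-recovery confusion matrix (%s task, %d datasets/model)\n",
                x$task, x$n_datasets))
    print(x$confusion)
  } else {
    cat(sprintf("Parameter recovery for '%s' (%s task, %d datasets)\n",
                x$model, x$task, x$n_datasets))
    print(x$summary, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
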