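# Grid-based Bayesian fitting: unnormalized log posterior on a parameter
# grid, marginal likelihood by trapezoidal integration, MAP; and bounded
# multi-start maximum likelihood with AIC/BIC for high-dimensional models.

#' Parameter priors of an observer model
#'
#' Returns the fitting registry for a model/task pair: one row per free
#' parameter with the space in which its prior is uniform. Noise priors are
#' uniform on `[1, 30]` degrees (`sigma_v` free in covert fits, `sigma_a` in
#' overt fits with `sigma_v` fixed to its known value); `alpha` and `w` are
#' uniform on `[0, 1]`; `r` on `[2, 200]` trials; `pi_min` on (0, 0.5)
#' (evaluated on the effective bounds `[0.005, 0.495]`); `sqrt(beta)` on
#' (0, 10] (effective `[0.05, 10]`); `sqrt(delta_1)` on `[1.01, 5]` and
#' `sqrt(delta_2)` on `[1.01, 14]` for the node spacings `l_2 = 1 + delta_1`,
#' `l_3 = l_2 + delta_2`; and `nu_p` uniform in (natural) log space on
#' `[0, 5]`.
#'
#' @param model observer model id.
#' @param task `"covert"` or `"overt"`.
#' @return data.frame with columns `name` (grid-space parameter name),
#'   `natural` (natural-space name), `lo`, `hi` (grid-space bounds),
#'   `transform` (`identity`, `square` or `exp`), `role` (`noise`/`traj`).
#' @export
parameter_priors <- function(model, task = c("covert", "overt")) {
  task <- match.arg(task)
  check_model_id(model)
  row <- function(name, natural, lo, hi, transform, role)
    data.frame(name = name, natural = natural, lo = lo, hi = hi,
               transform = transform, role = role, stringsAsFactors = FALSE)
  noise <- if (task == "covert") row("sigma_v", "sigma_v", 1, 30, "identity", "noise")
           else row("sigma_a", "sigma_a", 1, 30, "identity", "noise")
  traj <- switch(model,
    fixed = , bayes_ideal = , behrens = NULL,
    exp = , rl = row("alpha", "alpha", 0, 1, "identity", "traj"),
    exp_bias = rbind(row("alpha", "alpha", 0, 1, "identity", "traj"),
                     row("w", "w", 0, 1, "identity", "traj")),
    behrens_bias = row("w", "w", 0, 1, "identity", "traj"),
    bayes_r = row("r", "r", 2, 200, "identity", "traj"),
    bayes_pi = row("pi_min", "pi_min", 0.005, 0.495, "identity", "traj"),
    bayes_beta = row("sqrt_beta", "beta", 0.05, 10, "square", "traj"),
    wilson = rbind(row("sqrt_delta1", "delta1", 1.01, 5, "square", "traj"),
                   row("sqrt_delta2", "delta2", 1.01, 14, "square", "traj"),
                   row("log_nu", "nu_p", 0, 5, "exp", "traj")),
    bayes_rpb = rbind(row("r", "r", 1, 200, "identity", "traj"),
                      row("delta_r", "delta_r", 1, 200, "identity", "traj"),
                      row("pi_min", "pi_min", 0.005, 0.495, "identity", "traj"),
                      row("pi_max", "pi_max", 0.505, 0.995, "identity", "traj"),
                      row("sqrt_beta", "beta", 0.05, 10, "square", "traj"))
  )
  rbind(noise, traj)
}

transform_natural <- function(u, transform) {
  switch(transform, identity = u, square = u^2, exp = exp(u),
         stop("unknown transform: ", transform))
}

# natural-parameter list from a grid-space vector, including derived Wilson
# node positions
natural_params <- function(u, info, model) {
  vals <- mapply(transform_natural, u, info$transform)
  p <- as.list(stats::setNames(vals, info$natural))
  if (model == "wilson") {
    p$l2 <- 1 + p$delta1
    p$l3 <- p$l2 + p$delta2
  }
  p
}

# log likelihood over the noise axis given a criterion log-odds trajectory
noise_axis_loglik <- function(logodds, task, config, noise_axis, df, lapse) {
  s <- df$stimulus_deg
  if (task == "covert") {
    respA <- as_label01(df$response) == 1L
    dmu <- config$mu_B - config$mu_A
    zn <- (config$mu_A + config$mu_B) / 2
    scale <- (config$sigma_s^2 + noise_axis^2) / dmu
    Z <- zn + outer(logodds, scale)                    # T x n_noise
    Q <- sweep(Z - s, 2, noise_axis, "/")
    Q[is.nan(Q)] <- 0                                  # Inf - Inf guard
    P <- (1 - lapse) * stats::pnorm(Q) + lapse / 2
    colSums(log(P[respA, , drop = FALSE])) +
      colSums(log(1 - P[!respA, , drop = FALSE]))
  } else {
    cm <- category_model(config, "overt")
    z <- criterion_from_logodds(logodds, cm)
    resp <- as.numeric(df$response)
    D <- resp - z
    D[!is.finite(z)] <- Inf                            # lapse-only trials
    M <- outer(D, 1 / noise_axis)
    G <- exp(-0.5 * M^2)
    G <- sweep(G, 2, noise_axis * sqrt(2 * pi), "/")
    colSums(log((1 - lapse) * G + lapse / 180))
  }
}

#' Evaluate the unnormalized log posterior on a parameter grid
#'
#' Computes \eqn{\log p^*(\theta) = \log p(\mathrm{data} \mid \theta, M) +
#' \log p(\theta \mid M)} at every node of a cubic grid spanning the prior
#' support, with axes equally spaced in the space where each prior is
#' uniform (see [parameter_priors()]). The default resolution is 100 points
#' per axis (50 for the Wilson model); pass `n` to scale down.
#'
#' @param trials a session from [simulate_session()], or a trial data.frame
#'   with a `response` column.
#' @param model observer model id (models with more than 4 free parameters,
#'   i.e. `bayes_rpb`, are refused: use [point_estimates()]).
#' @param task,config taken from the session when omitted.
#' @param n grid resolution: scalar or named per-parameter vector.
#' @param n_mc,mc_seed Monte-Carlo settings for the RL likelihood.
#' @return object of class `"fit_grid"`: axes (grid space and natural
#'   space), the log-likelihood array, the log prior density, model/task
#'   metadata.
#' @export
grid_log_posterior <- function(trials, model, task = NULL, config = NULL,
                               n = NULL, n_mc = 5000, mc_seed = 1L) {
  if (inherits(trials, "cl_session")) {
    task <- task %||% trials$task
    config <- config %||% trials$config
  }
  stop_if_not(!is.null(task) && !is.null(config),
              "task and config are required when trials is a plain data.frame")
  check_model_id(model)
  df <- as_trials(trials)
  info <- parameter_priors(model, task)
  k <- nrow(info)
  if (k > 4)
    stop("model '", model, "' has ", k, " free parameters: grid evaluation ",
         "is refused above 4 dimensions; use point_estimates()", call. = FALSE)
  n_default <- if (model == "wilson") 50 else 100
  if (is.null(n)) n <- n_default
  nvec <- if (length(n) == 1 && is.null(names(n))) rep(n, k)
          else {
            out <- rep(n_default, k)
            idx <- match(names(n), info$name)
            stop_if_not(!anyNA(idx), "unknown parameter name in grid sizes 'n'")
            out[idx] <- n
            out
          }
  stop_if_not(all(nvec >= 2), "grid axes need at least 2 points")
  axes <- lapply(seq_len(k), function(j) seq(info$lo[j], info$hi[j],
                                             length.out = nvec[j]))
  names(axes) <- info$name
  nat_axes <- lapply(seq_len(k), function(j)
    transform_natural(axes[[j]], info$transform[j]))
  names(nat_axes) <- info$natural

  lapse <- if (task == "covert") config$lapse_covert else config$lapse_overt
  noise_axis <- axes[[1]]
  traj_idx <- which(info$role == "traj")
  ll <- array(NA_real_, dim = nvec)

  if (model == "rl") {
    noise_mat <- with_seed(mc_seed, matrix(stats::rnorm(n_mc * nrow(df)), n_mc))
    sigma_v_fixed <- config$sigma_v
    for (ia in seq_along(axes$alpha)) {
      alpha <- axes$alpha[ia]
      if (task == "covert") {
        for (is in seq_along(noise_axis)) {
          sv <- noise_axis[is]
          z <- rl_criterion_mc(df, task, alpha, sv, config, n_mc, noise_mat)
          x <- sweep(sv * noise_mat, 2, df$stimulus_deg, "+")
          pA <- colMeans(x < z)
          pr <- (1 - lapse) * pA + lapse / 2
          respA <- as_label01(df$response) == 1L
          ll[is, ia] <- sum(log(ifelse(respA, pr, 1 - pr)))
        }
      } else {
        z <- rl_criterion_mc(df, task, alpha, sigma_v_fixed, config, n_mc,
                             noise_mat)
        resp <- as.numeric(df$response)
        for (is in seq_along(noise_axis)) {
          sa <- noise_axis[is]
          g <- vapply(seq_len(nrow(df)), function(t)
            mean(stats::dnorm(resp[t], z[, t], sa)), numeric(1))
          ll[is, ia] <- sum(log((1 - lapse) * g + lapse / 180))
        }
      }
    }
  } else if (!length(traj_idx)) {
    pi_hat <- probability_traj(model, list(), df$category, config)
    ll[] <- noise_axis_loglik(stats::qlogis(pi_hat), task, config, noise_axis,
                              df, lapse)
  } else {
    # separate the conservatism blend (w) from the base trajectory so the
    # base estimate is computed once per base-parameter combination
    w_pos <- which(info$name[traj_idx] == "w")
    base_idx <- if (length(w_pos)) traj_idx[-w_pos] else traj_idx
    w_axis <- if (length(w_pos)) axes[["w"]] else NA
    base_grid <- if (length(base_idx))
      expand.grid(lapply(base_idx, function(j) seq_along(axes[[j]])))
    else data.frame(row.names = 1)
    for (b in seq_len(nrow(base_grid))) {
      u <- numeric(k)
      for (jj in seq_along(base_idx))
        u[base_idx[jj]] <- axes[[base_idx[jj]]][base_grid[b, jj]]
      base_model <- if (model %in% c("exp_bias")) "exp"
                    else if (model == "behrens_bias") "behrens" else model
      bp <- natural_params(u, info, model)
      est <- probability_traj(base_model, bp, df$category, config)
      if (length(w_pos)) {
        for (iw in seq_along(w_axis)) {
          lo <- stats::qlogis(bias_blend(est, w_axis[iw]))
          llv <- noise_axis_loglik(lo, task, config, noise_axis, df, lapse)
          idx <- matrix(1L, length(noise_axis), k)
          idx[, 1] <- seq_along(noise_axis)
          for (jj in seq_along(base_idx))
            idx[, base_idx[jj]] <- base_grid[b, jj]
          idx[, traj_idx[w_pos]] <- iw
          ll[idx] <- llv
        }
      } else {
        llv <- noise_axis_loglik(stats::qlogis(est), task, config, noise_axis,
                                 df, lapse)
        idx <- matrix(1L, length(noise_axis), k)
        idx[, 1] <- seq_along(noise_axis)
        for (jj in seq_along(base_idx))
          idx[, base_idx[jj]] <- base_grid[b, jj]
        ll[idx] <- llv
      }
    }
  }
  log_prior <- -sum(log(info$hi - info$lo))
  structure(list(model = model, task = task, config = config, info = info,
                 axes = axes, natural_axes = nat_axes, loglik = ll,
                 log_prior = log_prior, n_trials = nrow(df)),
            class = "fit_grid")
}

#' Log marginal likelihood of a fitted grid
#'
#' Integrates the unnormalized posterior over all parameter axes by the
#' trapezoidal rule, computed stably in log space (log-sum-exp with
#' trapezoid weights). The prior is uniform in the grid space of each
#' parameter, so the result is the log model evidence
#' \eqn{\log \int p(\mathrm{data}\mid\theta) p(\theta)\, d\theta}.
#'
#' @param grid a `"fit_grid"` from [grid_log_posterior()].
#' @return scalar log marginal likelihood.
#' @export
marginal_likelihood <- function(grid) {
  dims <- dim(grid$loglik) %||% length(grid$loglik)
  lw <- lapply(grid$axes, function(u) {
    if (length(u) < 2) stop("degenerate grid: axis with a single point",
                            call. = FALSE)
    d <- abs(diff(u))
    log(c(d[1] / 2, (d[-1] + d[-length(d)]) / 2, d[length(d)] / 2))
  })
  A <- grid$loglik + grid$log_prior
  W <- array(0, dim = dims)
  for (d in seq_along(lw)) W <- W + lw[[d]][slice.index(A, d)]
  logsumexp(A + W)
}

map_from_grid <- function(grid) {
  i <- arrayInd(which.max(grid$loglik), dim(grid$loglik))
  u <- vapply(seq_along(grid$axes), function(j) grid$axes[[j]][i[j]], numeric(1))
  list(u = stats::setNames(u, names(grid$axes)),
       params = natural_params(u, grid$info, grid$model),
       loglik = max(grid$loglik))
}

#' Maximum-likelihood fit with a bounded multi-start optimizer
#'
#' Maximizes the sequence log likelihood over the prior box in transformed
#' space with `optim(method = "L-BFGS-B")`, taking the best of `n_starts`
#' runs from random starting points (default 20). Used for the
#' `bayes_rpb` model, whose parameter count rules out grid integration, and
#' available for any model. AIC and BIC are computed from the maximum.
#'
#' @inheritParams grid_log_posterior
#' @param n_starts number of optimization restarts.
#' @param seed seed for the restart starting points.
#' @return an object of class `"observer_fit"` with `method = "mle"`.
#' @export
point_estimates <- function(trials, model, task = NULL, config = NULL,
                            n_starts = 20, seed = 1L, n_mc = 5000,
                            mc_seed = 1L) {
  if (inherits(trials, "cl_session")) {
    task <- task %||% trials$task
    config <- config %||% trials$config
  }
  stop_if_not(!is.null(task) && !is.null(config),
              "task and config are required when trials is a plain data.frame")
  check_model_id(model)
  df <- as_trials(trials)
  info <- parameter_priors(model, task)
  k <- nrow(info)
  negll <- function(u) {
    p <- natural_params(u, info, model)
    -sequence_log_likelihood(df, model, p, task, config, n_mc, mc_seed)
  }
  starts <- with_seed(seed, matrix(stats::runif(n_starts * k, info$lo, info$hi),
                                   n_starts, k, byrow = TRUE))
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(n_starts)) {
    res <- tryCatch(
      stats::optim(starts[i, ], negll, method = "L-BFGS-B",
                   lower = info$lo, upper = info$hi),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimization restarts failed", call. = FALSE)
  ll <- -best$value
  n <- nrow(df)
  out <- list(model = model, task = task, config = config, trials = df,
              method = "mle", npar = k, n_trials = n, info = info,
              mle = natural_params(best$par, info, model),
              max_loglik = ll, aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
              lml = NA_real_, map = NULL, map_loglik = NA_real_, grid = NULL,
              converged = any_conv)
  class(out) <- "observer_fit"
  out
}

#' Fit an observer model to a session
#'
#' The central fitting interface. With `method = "grid"` (the default for
#' models with at most 4 free parameters) the unnormalized log posterior is
#' evaluated on a grid over the prior support, yielding the log marginal
#' likelihood (model evidence), the MAP parameter estimate, and the full
#' posterior used by [posterior_predictive()]. With `method = "mle"` a
#' bounded multi-start optimizer returns maximum-likelihood estimates with
#' AIC/BIC (the only route for `bayes_rpb`).
#'
#' @param data a session from [simulate_session()], or a trial data.frame
#'   with a `response` column (then `task` and `config` are required).
#' @param model observer model id; see [observer_models()].
#' @param task,config taken from the session when omitted.
#' @param method `"grid"` or `"mle"`.
#' @param n grid resolution (scalar or named); default 100 per axis, 50 for
#'   the Wilson model.
#' @param n_starts restarts for `method = "mle"`.
#' @param seed seed for optimizer restarts.
#' @param n_mc,mc_seed Monte-Carlo settings for the RL likelihood.
#' @return an object of class `"observer_fit"`; see
#'   [print.observer_fit()], [coef.observer_fit()], [predict.observer_fit()].
#' @examples
#' cfg <- task_config(n_trials = 200)
#' ses <- simulate_session(cfg, "exp_bias", list(alpha = 0.17, w = 0.6),
#'                         task = "covert", seed = 1)
#' fit <- fit_observer(ses, "exp_bias", n = 15)
#' fit
#' coef(fit)
#' @export
fit_observer <- function(data, model, task = NULL, config = NULL,
                         method = c("grid", "mle"), n = NULL, n_starts = 20,
                         seed = 1L, n_mc = 5000, mc_seed = 1L) {
  method <- match.arg(method)
  if (inherits(data, "cl_session")) {
    task <- task %||% data$task
    config <- config %||% data$config
  }
  if (model == "bayes_rpb" && method == "grid") method <- "mle"
  if (method == "mle")
    return(point_estimates(data, model, task, config, n_starts, seed,
                           n_mc, mc_seed))
  grid <- grid_log_posterior(data, model, task, config, n, n_mc, mc_seed)
  mp <- map_from_grid(grid)
  k <- nrow(grid$info)
  n_tr <- grid$n_trials
  out <- list(model = model, task = grid$task, config = grid$config,
              trials = as_trials(data), method = "grid", npar = k,
              n_trials = n_tr, info = grid$info,
              lml = marginal_likelihood(grid), map = mp$params,
              map_u = mp$u, map_loglik = mp$loglik,
              aic = 2 * k - 2 * mp$loglik, bic = k * log(n_tr) - 2 * mp$loglik,
              mle = NULL, max_loglik = NA_real_, grid = grid)
  class(out) <- "observer_fit"
  out
}

#' @export
print.observer_fit <- function(x, ...) {
  cat(sprintf("Observer-model fit: '%s' on the %s-criterion task (%d trials)\n",
              x$model, x$task, x$n_trials))
  if (x$method == "grid") {
    cat(sprintf("  log marginal likelihood: %.2f\n", x$lml))
    cat("  MAP estimates:", fmt_params(x$map), "\n")
    cat(sprintf("  log likelihood at MAP: %.2f (AIC %.1f, BIC %.1f)\n",
                x$map_loglik, x$aic, x$bic))
  } else {
    cat("  MLE:", fmt_params(x$mle), "\n")
    cat(sprintf("  max log likelihood: %.2f (AIC %.1f, BIC %.1f)%s\n",
                x$max_loglik, x$aic, x$bic,
                if (isTRUE(x$converged)) "" else " [optimizer did not converge]"))
  }
  invisible(x)
}

fmt_params <- function(p) {
  paste(names(p), vapply(p, function(v) format(signif(v, 4)), ""),
        sep = " = ", collapse = ", ")
}

#' @export
coef.observer_fit <- function(object, ...) {
  p <- if (object$method == "grid") object$map else object$mle
  unlist(p[object$info$natural])
}

#' @export
logLik.observer_fit <- function(object, ...) {
  ll <- if (object$method == "grid") object$map_loglik else object$max_loglik
  structure(ll, df = object$npar, nobs = object$n_trials, class = "logLik")
}

#' Posterior parameter summaries of a grid fit
#'
#' @param object an `"observer_fit"` from [fit_observer()].
#' @param ... unused.
#' @return invisibly, a data.frame of posterior means and SDs per parameter
#'   (grid fits only), after printing the fit.
#' @export
summary.observer_fit <- function(object, ...) {
  print(object)
  if (object$method != "grid") return(invisible(NULL))
  g <- object$grid
  A <- g$loglik + g$log_prior
  p <- exp(A - max(A))
  p <- p / sum(p)
  tab <- do.call(rbind, lapply(seq_along(g$natural_axes), function(j) {
    vals <- g$natural_axes[[j]]
    m <- apply(p, j, sum)
    mu <- sum(vals * m)
    data.frame(parameter = names(g$natural_axes)[j], post_mean = mu,
               post_sd = sqrt(pmax(0, sum(vals^2 * m) - mu^2)),
               map = coef(object)[[names(g$natural_axes)[j]]])
  }))
  cat("  posterior marginals:\n")
  print(tab, row.names = FALSE, digits = 4)
  invisible(tab)
}

#' Model trajectories at the fitted parameters
#'
#' Returns the per-trial probability estimate and decision criterion implied
#' by the fitted (MAP or MLE) parameters on the fitted session's feedback
#' stream, or on new trials.
#'
#' @param object an `"observer_fit"`.
#' @param newdata optional trial data.frame (defaults to the fitted trials).
#' @param ... unused.
#' @return data.frame with columns `trial`, `pi_hat`, `criterion` (and, for
#'   the covert task, `p_respond_A`).
#' @export
predict.observer_fit <- function(object, newdata = NULL, ...) {
  df <- as_trials(newdata %||% object$trials, need_response = FALSE)
  p <- as.list(coef(object))
  if (object$model == "wilson") {
    p$l2 <- 1 + p$delta1
    p$l3 <- p$l2 + p$delta2
  }
  cfg <- object$config
  if (object$task == "covert" && !is.null(p$sigma_v)) cfg$sigma_v <- p$sigma_v
  cm <- category_model(cfg, object$task)
  if (object$model == "rl") {
    z <- colMeans(with_seed(1L,
      rl_criterion_mc(df, object$task, p$alpha,
                      if (object$task == "covert") p$sigma_v else cfg$sigma_v,
                      object$config, n_mc = 1000)))
    out <- data.frame(trial = seq_len(nrow(df)), pi_hat = NA_real_,
                      criterion = z)
  } else {
    pi_hat <- probability_traj(object$model, p, df$category, object$config)
    out <- data.frame(trial = seq_len(nrow(df)), pi_hat = pi_hat,
                      criterion = criterion_from_logodds(stats::qlogis(pi_hat),
                                                         cm))
  }
  if (object$task == "covert")
    out$p_respond_A <- covert_choice_prob(df$stimulus_deg, out$criterion,
                                          cfg$sigma_v,
                                          object$config$lapse_covert)
  out
}

#' Simulate responses from a fitted observer
#'
#' @param object an `"observer_fit"`.
#' @param nsim number of simulated sessions.
#' @param seed RNG seed.
#' @param ... unused.
#' @return list of `"cl_session"` objects simulated at the fitted parameters
#'   on the fitted session's stimuli.
#' @export
simulate.observer_fit <- function(object, nsim = 1, seed = NULL, ...) {
  p <- as.list(coef(object))
  if (object$model == "wilson") {
    p$l2 <- 1 + p$delta1
    p$l3 <- p$l2 + p$delta2
  }
  base_trials <- object$trials
  base_trials$response <- NULL
  with_seed(seed, lapply(seq_len(nsim), function(i)
    simulate_session(object$config, object$model, p, object$task,
                     trials = base_trials)))
}

#' @export
residuals.observer_fit <- function(object, ...) {
  pr <- predict(object)
  if (object$task == "covert")
    as_label01(object$trials$response) - pr$p_respond_A
  else
    as.numeric(object$trials$response) - pr$criterion
}

#' Plot a fitted observer against the session data
#'
#' Covert task: the "excess A responses" trajectory (cumulative A count
#' minus t/2) of the data and of the model's expected responses at the
#' fitted parameters. Overt task: reported criteria (5-trial running
#' average) against the model criterion. The true probability path is shown
#' in a lower panel when available.
#'
#' @param x an `"observer_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.observer_fit <- function(x, ...) {
  df <- x$trials
  pr <- predict(x)
  n <- nrow(df)
  op <- graphics::par(mfrow = c(2, 1), mar = c(3.5, 4, 2, 1))
  on.exit(graphics::par(op))
  if (x$task == "covert") {
    obs <- cumsum(as_label01(df$response)) - seq_len(n) / 2
    mod <- cumsum(pr$p_respond_A) - seq_len(n) / 2
    graphics::plot(obs, type = "l", col = "grey40", xlab = "trial",
                   ylab = "excess A responses",
                   main = sprintf("'%s' fit, covert task", x$model), ...)
    graphics::lines(mod, col = "firebrick")
  } else {
    run5 <- stats::filter(as.numeric(df$response), rep(1 / 5, 5), sides = 2)
    graphics::plot(as.numeric(df$response), pch = 16, cex = 0.3,
                   col = "grey70", xlab = "trial", ylab = "criterion (deg)",
                   main = sprintf("'%s' fit, overt task", x$model), ...)
    graphics::lines(run5, col = "grey40")
    graphics::lines(pr$criterion, col = "firebrick")
  }
  if (!is.null(df$pi_t))
    graphics::plot(df$pi_t, type = "s", ylim = c(0, 1), xlab = "trial",
                   ylab = expression(pi[A]))
  invisible(x)
}
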