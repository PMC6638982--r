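#' Configuration of the probability-tracking categorization task
#'
#' Defines the generative world: a category-A probability that follows a
#' sample-and-hold path over a discrete state set, Gaussian stimulus
#' categories separated to reach a target discriminability, Gaussian sensory
#' noise on the measurement, and (for the overt task) Gaussian
#' criterion-adjustment noise on the reported criterion. Orientations are in
#' degrees relative to the neutral criterion; with the default symmetric
#' placement the neutral criterion is at 0 and category A lies clockwise
#' (negative orientations).
#'
#' @param n_trials number of trials per session.
#' @param state_set ordered set of category-A probability states.
#' @param run_min,run_max bounds of the discrete-uniform segment-length
#'   distribution (trials between change points).
#' @param sigma_s category SD in degrees (both categories share it).
#' @param sigma_v sensory (visual) noise SD in degrees.
#' @param sigma_a criterion-adjustment noise SD in degrees (overt task only).
#' @param target_dprime discriminability the category separation is set to
#'   achieve on the noisy measurement distribution.
#' @param delta_theta category-mean separation in degrees; if `NULL`
#'   (default) it is computed from `target_dprime` via
#'   [category_separation_for_dprime()].
#' @param mu_A mean orientation of category A; default `-delta_theta/2` so
#'   that the neutral criterion is at 0.
#' @param lapse_covert,lapse_overt fixed lapse rates of the two tasks.
#' @param overt_decision_variance `"category"` (default) places the overt
#'   optimal criterion using the category variance \eqn{\sigma_s^2};
#'   `"measurement"` uses \eqn{\sigma_s^2 + \sigma_v^2}.
#' @return an object of class `"task_config"`.
#' @examples
#' cfg <- task_config()
#' cfg$delta_theta            # 1.5 * sqrt(200) ~ 21.2 degrees
#' @export
task_config <- function(n_trials = 800,
                        state_set = c(0.2, 0.35, 0.5, 0.65, 0.8),
                        run_min = 80, run_max = 120,
                        sigma_s = 10, sigma_v = 10, sigma_a = 15,
                        target_dprime = 1.5,
                        delta_theta = NULL, mu_A = NULL,
                        lapse_covert = 1e-4, lapse_overt = 5e-5,
                        overt_decision_variance = c("category", "measurement")) {
  overt_decision_variance <- match.arg(overt_decision_variance)
  stop_if_not(length(state_set) >= 2 && !is.unsorted(state_set, strictly = TRUE),
              "state_set must be sorted with at least 2 distinct values")
  stop_if_not(all(state_set > 0 & state_set < 1), "state_set values must lie in (0,1)")
  stop_if_not(run_min >= 1, "invalid config: run_min must be >= 1")
  stop_if_not(run_min <= run_max, "invalid config: run_min must be <= run_max")
  stop_if_not(all(c(sigma_s, sigma_v, sigma_a) > 0), "all SDs must be > 0")
  stop_if_not(n_trials >= 1, "n_trials must be >= 1")
  if (is.null(delta_theta))
    delta_theta <- category_separation_for_dprime(sigma_s, sigma_v, target_dprime)
  if (is.null(mu_A)) mu_A <- -delta_theta / 2
  structure(list(
    n_trials = n_trials, state_set = state_set,
    run_min = run_min, run_max = run_max,
    mu_A = mu_A, mu_B = mu_A + delta_theta, delta_theta = delta_theta,
    sigma_s = sigma_s, sigma_v = sigma_v, sigma_a = sigma_a,
    target_dprime = target_dprime,
    lapse_covert = lapse_covert, lapse_overt = lapse_overt,
    overt_decision_variance = overt_decision_variance
  ), class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Probability-tracking task configuration\n")
  cat(sprintf("  trials: %d, states: {%s}, run length ~ Unif[%d, %d]\n",
              x$n_trials, paste(x$state_set, collapse = ", "),
              x$run_min, x$run_max))
  cat(sprintf("  categories: mu_A = %.2f, mu_B = %.2f deg (delta = %.2f), sigma_s = %.1f\n",
              x$mu_A, x$mu_B, x$delta_theta, x$sigma_s))
  cat(sprintf("  noise: sigma_v = %.1f, sigma_a = %.1f deg; target d' = %.2f\n",
              x$sigma_v, x$sigma_a, x$target_dprime))
  invisible(x)
}

#' Category separation achieving a target discriminability
#'
#' Returns the category-mean separation \eqn{\Delta\theta} such that the
#' noisy measurement distributions \eqn{x \mid C \sim N(\mu_C,\,\sigma_s^2 +
#' \sigma_v^2)} are separated by the requested d-prime:
#' \eqn{\Delta\theta = d' \sqrt{\sigma_s^2 + \sigma_v^2}}.
#'
#' @param sigma_s category SD in degrees (> 0).
#' @param sigma_v sensory noise SD in degrees (>= 0).
#' @param target_dprime target discriminability (> 0).
#' @return separation in degrees.
#' @examples
#' category_separation_for_dprime(10, 10, 1.5)  # 1.5 * sqrt(200)
#' @export
category_separation_for_dprime <- function(sigma_s, sigma_v, target_dprime = 1.5) {
  stop_if_not(sigma_s > 0 && sigma_v >= 0 && target_dprime > 0,
              "sigma_s and target_dprime must be positive; sigma_v non-negative")
  target_dprime * sqrt(sigma_s^2 + sigma_v^2)
}

#' Sample a piecewise-constant category-probability path
#'
#' Draws segment lengths i.i.d. from the discrete uniform distribution on
#' `run_min:run_max` (the last segment is truncated at `n_trials`). The first
#' state is uniform over the state set; at each change point the new state is
#' uniform over the state set excluding the current one. `change[t] = TRUE`
#' marks a change point occurring after trial `t`.
#'
#' @param config a [task_config()].
#' @param seed integer RNG seed (optional; the path is deterministic given it).
#' @return list with numeric vector `pi` and logical vector `change`, both of
#'   length `n_trials`.
#' @export
sample_probability_path <- function(config, seed = NULL) {
  stop_if_not(config$run_min >= 1, "invalid config: run_min must be >= 1")
  with_seed(seed, {
    n <- config$n_trials
    states <- config$state_set
    pi_t <- numeric(n)
    change <- logical(n)
    cur <- sample1(states)
    t0 <- 0
    while (t0 < n) {
      len <- sample1(config$run_min:config$run_max)
      idx <- (t0 + 1):min(t0 + len, n)
      pi_t[idx] <- cur
      t0 <- t0 + len
      if (t0 < n) {
        change[t0] <- TRUE
        cur <- sample1(setdiff(states, cur))
      }
    }
    list(pi = pi_t, change = change)
  })
}

#' Generate the trial-level stimuli of a session
#'
#' Given a probability path, draws a category per trial
#' (\eqn{P(A) = \pi_t}), a stimulus from the category's Gaussian orientation
#' distribution, and a noisy measurement of the stimulus.
#'
#' @param config a [task_config()].
#' @param seed integer RNG seed.
#' @param path optional probability path as returned by
#'   [sample_probability_path()]; drawn fresh when `NULL`. Supplying a
#'   constant path (e.g. all 0.5) yields an equal-probability session.
#' @return data.frame with columns `trial`, `pi_t`, `change`, `category`
#'   ("A"/"B"), `stimulus_deg`, `measurement_deg`.
#' @export
simulate_trials <- function(config, seed = NULL, path = NULL) {
  with_seed(seed, {
    if (is.null(path)) path <- sample_probability_path(config)
    n <- length(path$pi)
    cat01 <- stats::rbinom(n, 1, path$pi)  # 1 = category A
    mu <- ifelse(cat01 == 1, config$mu_A, config$mu_B)
    s <- stats::rnorm(n, mu, config$sigma_s)
    x <- stats::rnorm(n, s, config$sigma_v)
    data.frame(trial = seq_len(n), pi_t = path$pi,
               change = as.integer(path$change %||% logical(n)),
               category = ifelse(cat01 == 1, "A", "B"),
               stimulus_deg = s, measurement_deg = x,
               stringsAsFactors = FALSE)
  })
}

#' Simulate an observer's responses in a full session
#'
#' Generates a session from the task's generative model (or uses supplied
#' trials) and runs an observer model forward with trial-by-trial category
#' feedback. In the covert task the observer classifies its noisy measurement
#' against the model criterion (with lapses uniform over the two categories);
#' in the overt task the model criterion is reported with Gaussian adjustment
#' noise (lapses uniform over the 180-degree circle).
#'
#' @param config a [task_config()].
#' @param model observer model id; see [observer_models()].
#' @param params named list/vector of model parameters (e.g. `alpha`, `w`,
#'   `r`, `pi_min`, `beta`, `l2`, `l3`, `nu_p`). Trajectory parameters only;
#'   noise comes from `config` unless overridden here via `sigma_v`/`sigma_a`.
#' @param task `"covert"` or `"overt"`.
#' @param seed integer RNG seed.
#' @param trials optional pre-generated trial data.frame from
#'   [simulate_trials()].
#' @return an object of class `"cl_session"`: list with `$trials` (the trial
#'   data.frame including a `response` column), `$model`, `$params`, `$task`,
#'   `$config`, `$seed`. Covert responses are "A"/"B" labels; overt responses
#'   are criterion orientations in degrees.
#' @export
simulate_session <- function(config, model = "bayes_ideal", params = list(),
                             task = c("covert", "overt"), seed = NULL,
                             trials = NULL) {
  task <- match.arg(task)
  check_model_id(model)
  with_seed(seed, {
    if (is.null(trials)) trials <- simulate_trials(config)
    n <- nrow(trials)
    cat01 <- as.integer(trials$category == "A")
    cm <- category_model(config, task)
    sigma_v <- params$sigma_v %||% config$sigma_v
    sigma_a <- params$sigma_a %||% config$sigma_a
    lapse <- if (task == "covert") config$lapse_covert else config$lapse_overt

    if (model == "rl") {
      alpha <- params$alpha %||% stop("rl model needs an 'alpha' parameter")
      z <- cm$z_neutral
      resp <- if (task == "covert") character(n) else numeric(n)
      for (t in seq_len(n)) {
        x <- trials$stimulus_deg[t] + stats::rnorm(1, 0, sigma_v)
        if (task == "covert") {
          choice_A <- if (stats::runif(1) < lapse) stats::runif(1) < 0.5 else x < z
          resp[t] <- if (choice_A) "A" else "B"
          correct <- choice_A == (cat01[t] == 1)
        } else {
          resp[t] <- if (stats::runif(1) < lapse) stats::runif(1, -90, 90)
                     else z + stats::rnorm(1, 0, sigma_a)
          correct <- (trials$stimulus_deg[t] < z) == (cat01[t] == 1)
        }
        if (!correct) z <- z + alpha * (x - z)
      }
    } else {
      pi_hat <- probability_traj(model, params, cat01, config)
      z <- criterion_from_logodds(stats::qlogis(pi_hat), cm)
      if (task == "covert") {
        x <- trials$stimulus_deg + stats::rnorm(n, 0, sigma_v)
        choice_A <- x < z
        lap <- stats::runif(n) < lapse
        choice_A[lap] <- stats::runif(sum(lap)) < 0.5
        resp <- ifelse(choice_A, "A", "B")
      } else {
        resp <- z + stats::rnorm(n, 0, sigma_a)
        lap <- stats::runif(n) < lapse
        resp[lap] <- stats::runif(sum(lap), -90, 90)
      }
    }
    trials$response <- resp
    structure(list(trials = trials, model = model, params = params,
                   task = task, config = config, seed = seed),
              class = "cl_session")
  })
}

#' @export
print.cl_session <- function(x, ...) {
  cat(sprintf("Simulated %s-criterion session: %d trials, observer '%s'\n",
              x$task, nrow(x$trials), x$model))
  if (length(x$params))
    cat("  parameters:",
        paste(names(x$params), signif(unlist(x$params), 4),
              sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
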