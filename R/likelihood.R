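# Trial-level likelihoods for covert choices and overt criterion reports.

# Extract and validate a trial table (with response column) from a session
# object or data.frame.
as_trials <- function(data, need_response = TRUE) {
  if (inherits(data, "cl_session")) data <- data$trials
  stop_if_not(is.data.frame(data), "trials must be a data.frame or cl_session")
  need <- c("category", "stimulus_deg")
  if (need_response) need <- c(need, "response")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cn in intersect(c("pi_t", "stimulus_deg", "measurement_deg"), names(data)))
    if (anyNA(data[[cn]]))
      stop("trial table column '", cn, "' contains missing values", call. = FALSE)
  data
}

# Simulated criterion trajectories of the RL observer: n_mc Monte-Carlo
# measurement vectors with common random numbers. Returns an n_mc x T matrix
# of the internal criterion in force on each trial.
rl_criterion_mc <- function(trials, task, alpha, sigma_v, config,
                            n_mc = 5000, noise = NULL) {
  s <- trials$stimulus_deg
  cat01 <- as_label01(trials$category)
  n <- length(s)
  cm <- category_model(config, task)
  if (is.null(noise)) noise <- matrix(stats::rnorm(n_mc * n), n_mc, n)
  z <- matrix(NA_real_, n_mc, n)
  zc <- rep(cm$z_neutral, n_mc)
  for (t in seq_len(n)) {
    z[, t] <- zc
    x <- s[t] + sigma_v * noise[, t]
    correct <- if (task == "covert") (x < zc) == (cat01[t] == 1L)
               else (s[t] < zc) == (cat01[t] == 1L)
    zc <- ifelse(correct, zc, zc + alpha * (x - zc))
  }
  z
}

#' Log likelihood of a response sequence under an observer model
#'
#' Runs the observer forward on the category feedback stream and sums
#' per-trial log response probabilities: in the covert task the lapse-mixed
#' probability of each choice given the stimulus and the model criterion; in
#' the overt task the lapse-mixed Gaussian density of each reported
#' criterion around the model criterion. For the RL model the criterion
#' depends on the latent measurement sequence, so per-trial probabilities
#' are approximated by Monte Carlo over `n_mc` simulated measurement vectors
#' (covert: fraction of simulated A choices; overt: mixture of Gaussians
#' centered on the simulated criteria), with a fixed seed so the likelihood
#' surface is smooth in the parameters.
#'
#' @param trials a [simulate_session()] object, or a trial data.frame with a
#'   `response` column (covert: "A"/"B"; overt: degrees).
#' @param model observer model id.
#' @param params named list of parameters, including the task's noise
#'   parameter (`sigma_v` covert, `sigma_a` overt).
#' @param task `"covert"` or `"overt"` (taken from the session if omitted).
#' @param config a [task_config()] (taken from the session if omitted).
#' @param n_mc Monte-Carlo sample size for the RL model (default 5000).
#' @param mc_seed seed for the RL Monte-Carlo draws.
#' @return scalar log likelihood.
#' @export
sequence_log_likelihood <- function(trials, model, params, task = NULL,
                                    config = NULL, n_mc = 5000, mc_seed = 1L) {
  if (inherits(trials, "cl_session")) {
    task <- task %||% trials$task
    config <- config %||% trials$config
  }
  stop_if_not(!is.null(task) && !is.null(config),
              "task and config are required when trials is a plain data.frame")
  check_model_id(model)
  df <- as_trials(trials)
  p <- as.list(params)
  lapse <- if (task == "covert") config$lapse_covert else config$lapse_overt
  resp <- df$response
  if (task == "covert") {
    respA <- as_label01(resp) == 1L
    sigma_v <- p$sigma_v %||% config$sigma_v
  } else {
    resp <- as.numeric(resp)
    if (anyNA(resp)) stop("overt responses must be numeric criteria", call. = FALSE)
    sigma_v <- config$sigma_v   # fixed to the known value in the overt task
    sigma_a <- p$sigma_a %||% config$sigma_a
  }

  if (model == "rl") {
    if (task == "covert") {
      # common random numbers: the same measurement draws drive the criterion
      # trajectory and the simulated choices
      noise <- with_seed(mc_seed, matrix(stats::rnorm(n_mc * nrow(df)), n_mc))
      z <- rl_criterion_mc(df, task, p$alpha, sigma_v, config,
                           n_mc = n_mc, noise = noise)
      x <- sweep(sigma_v * noise, 2, df$stimulus_deg, "+")
      pA <- colMeans(x < z)
      pr <- (1 - lapse) * pA + lapse / 2
      return(sum(log(ifelse(respA, pr, 1 - pr))))
    } else {
      z <- with_seed(mc_seed,
        rl_criterion_mc(df, task, p$alpha, sigma_v, config, n_mc = n_mc))
      g <- vapply(seq_len(nrow(df)), function(t)
        mean(stats::dnorm(resp[t], z[, t], sigma_a)), numeric(1))
      return(sum(log((1 - lapse) * g + lapse / 180)))
    }
  }

  cfg <- config
  if (task == "covert") cfg$sigma_v <- sigma_v
  cm <- category_model(cfg, task)
  pi_hat <- probability_traj(model, p, df$category, config)
  z <- criterion_from_logodds(stats::qlogis(pi_hat), cm)
  if (task == "covert") {
    pr <- covert_choice_prob(df$stimulus_deg, z, sigma_v, lapse)
    sum(log(ifelse(respA, pr, 1 - pr)))
  } else {
    sum(overt_report_logdensity(resp, z, sigma_a, lapse))
  }
}
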