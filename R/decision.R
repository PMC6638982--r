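#' Category model geometry for an orientation-categorization task
#'
#' Collects the stimulus-space quantities shared by all observer models: the
#' category means, the common category standard deviation, the sensory and
#' criterion-adjustment noise, and the neutral criterion
#' \eqn{z_\mathrm{neutral} = (\mu_A + \mu_B)/2}. All orientations are in
#' degrees; by package convention stimuli are expressed relative to the
#' neutral criterion, with category A clockwise (lower orientation) of
#' category B.
#'
#' @param config a [task_config()] object.
#' @param task `"covert"` or `"overt"`.
#' @return A list of class `"category_model"` with elements `mu_A`, `mu_B`,
#'   `sigma_s`, `sigma_v`, `sigma_a`, `z_neutral` and `sigma2_dec`, the
#'   decision variance used to place the optimal criterion for this task.
#'
#' @details The decision variance differs between tasks. In the covert task
#'   the observer classifies the noisy internal measurement \eqn{x}, whose
#'   category-conditional variance is \eqn{\sigma_s^2 + \sigma_v^2}. In the
#'   overt task feedback scores the true stimulus orientation against the
#'   reported criterion line, so the default decision variance is
#'   \eqn{\sigma_s^2}; set `config$overt_decision_variance = "measurement"`
#'   to use \eqn{\sigma_s^2 + \sigma_v^2} there as well.
#' @export
category_model <- function(config, task = c("covert", "overt")) {
  task <- match.arg(task)
  s2 <- config$sigma_s^2
  v2 <- config$sigma_v^2
  sigma2_dec <- if (task == "covert") {
    s2 + v2
  } else if (identical(config$overt_decision_variance, "measurement")) {
    s2 + v2
  } else s2
  structure(list(
    mu_A = config$mu_A, mu_B = config$mu_B,
    sigma_s = config$sigma_s, sigma_v = config$sigma_v,
    sigma_a = config$sigma_a,
    z_neutral = (config$mu_A + config$mu_B) / 2,
    sigma2_dec = sigma2_dec, task = task
  ), class = "category_model")
}

#' Optimal decision criterion for a category-A probability
#'
#' Returns the orientation at which the category posteriors are equal for two
#' Gaussian categories with common decision variance: the observer should
#' respond "A" for measurements clockwise (below) this criterion. With equal
#' category probability the criterion sits at the neutral orientation; as
#' \eqn{\pi_A} grows the criterion moves toward the B mean, enlarging the
#' respond-A region.
#'
#' @param pi_A probability of category A, in (0, 1); vectorized.
#' @param cat a [category_model()].
#' @return criterion orientation(s) in degrees,
#'   \eqn{z = z_\mathrm{neutral} + \sigma^2_\mathrm{dec}/(\mu_B-\mu_A)\,
#'   \log(\pi_A/\pi_B)}.
#' @export
optimal_criterion <- function(pi_A, cat) {
  if (any(pi_A <= 0 | pi_A >= 1, na.rm = TRUE))
    stop("pi_A must lie strictly inside (0, 1): the optimal criterion is infinite at 0 or 1",
         call. = FALSE)
  cat$z_neutral + cat$sigma2_dec / (cat$mu_B - cat$mu_A) * log(pi_A / (1 - pi_A))
}

# Criterion from a log-odds trajectory; tolerates +/-Inf log odds (degenerate
# probability estimates), which propagate to an infinite criterion and hence
# to lapse-floored choice probabilities.
criterion_from_logodds <- function(logodds, cat) {
  cat$z_neutral + cat$sigma2_dec / (cat$mu_B - cat$mu_A) * logodds
}

#' Probability of a covert "A" response
#'
#' For an observer with a deterministic trial criterion \eqn{z_t}, the
#' probability that the noisy measurement of stimulus \eqn{s_t} falls
#' clockwise of the criterion is \eqn{\Phi((z_t - s_t)/\sigma_v)}. A fixed
#' lapse rate mixes in a uniformly random choice.
#'
#' @param stimulus stimulus orientation(s) in degrees.
#' @param criterion criterion orientation(s) in degrees (may be infinite).
#' @param sigma_v sensory noise SD in degrees.
#' @param lapse lapse probability (default `1e-4`, the fixed covert value).
#' @return probability of responding "A", in `[lapse/2, 1 - lapse/2]`.
#' @export
covert_choice_prob <- function(stimulus, criterion, sigma_v, lapse = 1e-4) {
  p <- stats::pnorm((criterion - stimulus) / sigma_v)
  (1 - lapse) * p + lapse / 2
}

#' Log density of an overt criterion report
#'
#' The reported criterion is the model criterion perturbed by Gaussian
#' adjustment noise, mixed with a lapse component uniform over the 180-degree
#' orientation circle. The density is per degree.
#'
#' @param reported reported criterion orientation(s) in degrees.
#' @param criterion model criterion orientation(s) in degrees.
#' @param sigma_a adjustment noise SD in degrees (> 0).
#' @param lapse lapse probability (default `5e-5`, the fixed overt value).
#' @return log density value(s).
#' @export
overt_report_logdensity <- function(reported, criterion, sigma_a, lapse = 5e-5) {
  stop_if_not(all(sigma_a > 0), "sigma_a must be positive")
  g <- stats::dnorm(reported, mean = criterion, sd = sigma_a)
  g[!is.finite(criterion)] <- 0  # infinitely displaced criterion: lapse only
  log((1 - lapse) * g + lapse / 180)
}
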