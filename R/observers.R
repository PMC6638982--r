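#' Observer model identifiers
#'
#' The trial-level observer models available for simulation and fitting:
#' \describe{
#'   \item{`fixed`}{assumes equal category probability throughout; the
#'     criterion stays at the neutral orientation.}
#'   \item{`exp`}{exponential averaging of experienced labels with smoothing
#'     factor `alpha` (a delta rule on the probability estimate).}
#'   \item{`exp_bias`}{`exp`, with the estimate shrunk toward 0.5 by weight
#'     `w` (conservatism).}
#'   \item{`wilson`}{three-node mixture of delta rules approximating the
#'     run-length posterior (parameters `l2`, `l3`, `nu_p`; hazard fixed at
#'     0.01, node 1 fixed at run length 1).}
#'   \item{`rl`}{reinforcement learning of the criterion itself: after
#'     errors the criterion moves toward the measurement by `alpha`.}
#'   \item{`behrens`, `behrens_bias`}{grid-based Bayesian learner tracking
#'     probability, volatility and volatility drift; the `_bias` variant
#'     shrinks the estimate toward 0.5 by `w`.}
#'   \item{`bayes_ideal`, `bayes_r`, `bayes_pi`, `bayes_beta`, `bayes_rpb`}{
#'     change-point detection observers; see [belief_spec_for_model()].}
#' }
#' @return character vector of model ids.
#' @export
observer_models <- function() {
  c("fixed", "exp", "exp_bias", "wilson", "rl", "behrens", "behrens_bias",
    "bayes_ideal", "bayes_r", "bayes_pi", "bayes_beta", "bayes_rpb")
}

check_model_id <- function(model) {
  if (!is.character(model) || length(model) != 1 || !(model %in% observer_models()))
    stop("unknown observer model id: ", paste(model, collapse = ", "),
         " (see observer_models())", call. = FALSE)
  invisible(model)
}

as_label01 <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    l <- as.character(labels)
    stop_if_not(all(l %in% c("A", "B")), "category labels must be 'A' or 'B'")
    as.integer(l == "A")
  } else {
    stop_if_not(all(labels %in% c(0, 1)), "numeric labels must be 0/1")
    as.integer(labels)
  }
}

#' Exponential-averaging update of a probability estimate
#'
#' One delta-rule step: \eqn{\hat\pi \leftarrow \alpha\,[C = A] +
#' (1-\alpha)\hat\pi}, giving recent labels more weight. The memory time
#' constant is \eqn{\tau = -1/\log(1-\alpha)} trials.
#'
#' @param state list with `estimate` (current probability) and `alpha`
#'   (smoothing factor in (0, 1]); create with `exp_state(alpha)`.
#' @param label `"A"`/`"B"` or 1/0.
#' @return updated state.
#' @export
exp_update <- function(state, label) {
  c01 <- as_label01(label)
  state$estimate <- state$alpha * c01 + (1 - state$alpha) * state$estimate
  state
}

#' @rdname exp_update
#' @param alpha smoothing factor.
#' @param estimate initial estimate (default 0.5).
#' @export
exp_state <- function(alpha, estimate = 0.5) {
  list(estimate = estimate, alpha = alpha)
}

#' Conservative shrinkage of a probability estimate
#'
#' Averages an estimate with the equal-probability prior:
#' \eqn{\tilde\pi = w\hat\pi + (1-w)/2}. `w = 1` leaves the estimate
#' untouched; `w = 0` pins it at 0.5.
#'
#' @param estimate probability estimate(s) in `[0, 1]`.
#' @param w weight on the estimate, in `[0, 1]`.
#' @return blended probability(ies).
#' @export
bias_blend <- function(estimate, w) {
  stop_if_not(all(estimate >= 0 & estimate <= 1) && all(w >= 0 & w <= 1),
              "estimate and w must lie in [0, 1]")
  w * estimate + (1 - w) / 2
}

#' Mixture-of-delta-rules (three-node) probability learner
#'
#' Approximates the run-length posterior with a small set of nodes at run
#' lengths `l_1 < l_2 < ...`; each node runs a delta rule with learning rate
#' \eqn{1/(l_i + \nu_p)}, where `nu_p` acts as pseudocounts of a Beta prior
#' toward equal probability. Node weights are updated by likelihood-weighting
#' each node's prediction of the label, routing hazard-`h` mass to the first
#' node, and spreading the remaining mass so the represented mean run length
#' advances by one per trial (mass moves from node i to i+1 with fraction
#' `1/(l_{i+1} - l_i)`; the top node maps to itself). The overall estimate is
#' the weight-averaged node estimate.
#'
#' @param nodes increasing vector of node run lengths (first node normally 1).
#' @param nu_p prior-strength parameter (>= 0).
#' @param h hazard rate (default 0.01, one change per 100 trials).
#' @param rates optional explicit per-node learning rates overriding
#'   `1/(nodes + nu_p)`.
#' @param weights initial node weights (default: all weight on the first
#'   node, i.e. a change is assumed at t = 1).
#' @return list state with `nodes`, `rates`, `estimates`, `weights`, `h` and
#'   the growth matrix `G`.
#' @export
wilson_state <- function(nodes, nu_p = 2, h = 0.01, rates = NULL, weights = NULL) {
  stop_if_not(!is.unsorted(nodes, strictly = TRUE) && all(nodes >= 1),
              "nodes must be increasing run lengths >= 1")
  m <- length(nodes)
  if (is.null(rates)) rates <- 1 / (nodes + nu_p)
  if (is.null(weights)) weights <- c(1, rep(0, m - 1))
  G <- diag(m)
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      f <- min(1, 1 / (nodes[i + 1] - nodes[i]))
      G[i, i] <- 1 - f
      G[i, i + 1] <- f
    }
  }
  list(nodes = nodes, nu_p = nu_p, h = h, rates = rates,
       estimates = rep(0.5, m), weights = weights, G = G)
}

#' @rdname wilson_state
#' @param state a `wilson_state()`.
#' @param label `"A"`/`"B"` or 1/0.
#' @export
wilson_update <- function(state, label) {
  c01 <- as_label01(label)
  w <- state$weights
  if (any(w < -1e-9) || abs(sum(w) - 1) > 1e-6)
    stop("internal error: Wilson node weights are not a simplex", call. = FALSE)
  lik <- ifelse(c01 == 1L, state$estimates, 1 - state$estimates)
  wl <- w * lik
  s <- sum(wl)
  wn <- (1 - state$h) * drop(crossprod(state$G, wl))
  wn[1] <- wn[1] + state$h * s
  state$weights <- wn / sum(wn)
  est <- state$estimates + state$rates * (c01 - state$estimates)
  # keep node estimates off the exact 0/1 boundary: with nu_p pseudocounts a
  # node's predictive never saturates, and exact saturation would zero every
  # likelihood weight on the next contradicting label
  state$estimates <- pmin(pmax(est, 1e-12), 1 - 1e-12)
  state
}

#' @rdname wilson_state
#' @export
wilson_estimate <- function(state) {
  sum(state$weights * state$estimates)
}

#' Reinforcement-learning criterion update
#'
#' The criterion itself (not a probability estimate) is adjusted after
#' errors: \eqn{z \leftarrow z + \alpha_{RL}(x_t - z)} when the feedback was
#' "incorrect", unchanged when "correct".
#'
#' @param state list with `z` (criterion, degrees) and `alpha`; create with
#'   `rl_state(alpha, z)`.
#' @param measurement noisy measurement \eqn{x_t} in degrees.
#' @param feedback_correct logical; was the trial's response correct?
#' @return updated state.
#' @export
rl_update <- function(state, measurement, feedback_correct) {
  if (!feedback_correct)
    state$z <- state$z + state$alpha * (measurement - state$z)
  state
}

#' @rdname rl_update
#' @param alpha learning rate in `[0, 1]`.
#' @param z initial criterion (degrees; the neutral criterion).
#' @export
rl_state <- function(alpha, z = 0) {
  list(z = z, alpha = alpha)
}

# ---- Volatility-tracking Bayesian learner (Behrens-style grid filter) ----

#' Grid state of the volatility-tracking probability learner
#'
#' Maintains a joint density over (probability `pi`, log-volatility `v`,
#' log volatility-diffusion `k`) on a 3-D grid. Per trial the density is
#' propagated through a Gaussian random walk on `v` (variance `exp(k)`) and a
#' Beta transition on `pi` (mean `pi_t`, concentration `exp(v_{t+1})`),
#' multiplied by the Bernoulli likelihood of the observed label, and
#' renormalized. The probability estimate is the mean of the `pi` marginal.
#'
#' Grid ranges are configuration: `pi` linear on `pi_range`; `exp(v)`
#' (concentration) and `exp(k)` (diffusion variance) log-spaced on
#' `conc_range` and `diff_range`.
#'
#' @param n_bins grid resolution per axis (default 30).
#' @param pi_range range of the probability axis.
#' @param conc_range range of the Beta concentration `exp(v)`.
#' @param diff_range range of the volatility diffusion variance `exp(k)`.
#' @return list state of class `"behrens_grid"` with the density array `$p`
#'   and precomputed transition kernels.
#' @export
behrens_grid <- function(n_bins = 30, pi_range = c(0.01, 0.99),
                         conc_range = c(2, 1e4), diff_range = c(1e-4, 10)) {
  pi_g <- seq(pi_range[1], pi_range[2], length.out = n_bins)
  v_g <- seq(log(conc_range[1]), log(conc_range[2]), length.out = n_bins)
  k_g <- seq(log(diff_range[1]), log(diff_range[2]), length.out = n_bins)
  # v random walk kernels, one per k (columns: v_old -> rows: v_new)
  Tv <- lapply(k_g, function(k) {
    M <- outer(v_g, v_g, function(vn, vo) stats::dnorm(vn, vo, sqrt(exp(k))))
    sweep(M, 2, colSums(M), "/")
  })
  # pi Beta kernels, one per v_new (columns: pi_old -> rows: pi_new)
  Tpi <- lapply(v_g, function(v) {
    conc <- exp(v)
    M <- vapply(pi_g, function(po) {
      lg <- stats::dbeta(pi_g, po * conc, (1 - po) * conc, log = TRUE)
      w <- exp(lg - max(lg))
      w / sum(w)
    }, numeric(n_bins))
    M
  })
  p <- array(1 / n_bins^3, dim = rep(n_bins, 3))
  structure(list(p = p, pi_grid = pi_g, v_grid = v_g, k_grid = k_g,
                 Tv = Tv, Tpi = Tpi, n_bins = n_bins),
            class = "behrens_grid")
}

behrens_propagate <- function(grid) {
  p <- grid$p
  nb <- grid$n_bins
  for (ki in seq_len(nb)) p[, , ki] <- p[, , ki] %*% t(grid$Tv[[ki]])
  for (vi in seq_len(nb)) p[, vi, ] <- grid$Tpi[[vi]] %*% p[, vi, ]
  p
}

#' @rdname behrens_grid
#' @param grid a `"behrens_grid"`.
#' @param label `"A"`/`"B"` or 1/0.
#' @param propagate apply the volatility and probability transitions before
#'   the likelihood (skipped for the first observation, whose prior is the
#'   initial grid itself).
#' @export
behrens_update <- function(grid, label, propagate = TRUE) {
  c01 <- as_label01(label)
  p <- if (propagate) behrens_propagate(grid) else grid$p
  lik <- if (c01 == 1L) grid$pi_grid else 1 - grid$pi_grid
  p <- p * lik  # pi is the fastest-varying dimension: recycling is aligned
  s <- sum(p)
  if (!is.finite(s) || s <= 1e-300) {
    lp <- log(p)
    p <- exp(lp - max(lp))
    s <- sum(p)
  }
  grid$p <- p / s
  grid
}

#' @rdname behrens_grid
#' @export
behrens_estimate <- function(grid) {
  sum(grid$p * grid$pi_grid)
}

behrens_traj <- function(labels01, n_bins = 30, ...) {
  grid <- behrens_grid(n_bins = n_bins, ...)
  n <- length(labels01)
  out <- numeric(n)
  for (t in seq_len(n)) {
    if (t > 1) grid$p <- behrens_propagate(grid)
    out[t] <- behrens_estimate(grid)
    grid <- behrens_update(grid, labels01[t], propagate = FALSE)
  }
  out
}

# ---- per-trial probability estimate trajectories ----

exp_traj <- function(labels01, alpha) {
  n <- length(labels01)
  out <- numeric(n)
  est <- 0.5
  for (t in seq_len(n)) {
    out[t] <- est
    est <- alpha * labels01[t] + (1 - alpha) * est
  }
  out
}

wilson_traj <- function(labels01, nodes, nu_p, h = 0.01, rates = NULL) {
  st <- wilson_state(nodes, nu_p, h, rates)
  n <- length(labels01)
  out <- numeric(n)
  for (t in seq_len(n)) {
    out[t] <- wilson_estimate(st)
    st <- wilson_update(st, labels01[t])
  }
  out
}

#' Per-trial probability estimates of an observer model
#'
#' Runs a (non-RL) observer model forward over the category feedback stream
#' and returns the category-A probability estimate in force at the start of
#' each trial — the quantity its decision criterion is computed from. The RL
#' model has no probability estimate and is rejected here.
#'
#' @param model observer model id (see [observer_models()]).
#' @param params named list of trajectory parameters.
#' @param labels category labels, `"A"`/`"B"` or 1/0.
#' @param config a [task_config()] (true generative values, used by the
#'   Bayesian variants' default beliefs).
#' @return numeric vector of probability estimates, one per trial.
#' @export
probability_traj <- function(model, params, labels, config) {
  check_model_id(model)
  p <- as.list(params)
  c01 <- as_label01(labels)
  n <- length(c01)
  switch(model,
    fixed = rep(0.5, n),
    exp = exp_traj(c01, p$alpha),
    exp_bias = bias_blend(exp_traj(c01, p$alpha), p$w),
    wilson = {
      nodes <- if (!is.null(p$nodes)) p$nodes else c(1, p$l2, p$l3)
      wilson_traj(c01, nodes, p$nu_p %||% 2, p$h %||% 0.01, p$rates)
    },
    behrens = behrens_traj(c01, n_bins = p$n_bins %||% 30),
    behrens_bias = bias_blend(behrens_traj(c01, n_bins = p$n_bins %||% 30), p$w),
    rl = stop("the RL model updates a criterion, not a probability estimate; ",
              "use rl_criterion_mc() or simulate_session()", call. = FALSE),
    run_bayes_sequence(c01, belief_spec_for_model(model, p, config))
  )
}
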