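#' Belief specification for the change-point detection observer
#'
#' The Bayesian change-point observer tracks a joint posterior over the
#' current run length (trials since the last change point) and the
#' probability state that governed the run before that change. Its beliefs
#' about the generative model are captured by: a discrete set of candidate
#' category-A probability states, a discrete-uniform run-length distribution
#' on `[L_min, L_max]`, and a Beta(beta, beta) hyperprior re-weighting the
#' state set after every change point (beta = 1 is uniform; large beta biases
#' beliefs toward equal probability).
#'
#' @param states sorted vector of believed probability states in (0, 1).
#' @param L_min,L_max believed run-length support (integers, `1 <= L_min <=
#'   L_max`).
#' @param beta Beta hyperprior parameter (> 0).
#' @return object of class `"changepoint_spec"` with precomputed hazard
#'   vector and per-previous-state priors.
#' @seealso [belief_spec_for_model()] for the named observer variants.
#' @export
changepoint_spec <- function(states, L_min, L_max, beta = 1) {
  stop_if_not(all(states > 0 & states < 1), "believed states must lie in (0,1)")
  stop_if_not(!is.unsorted(states, strictly = TRUE), "states must be sorted and distinct")
  stop_if_not(L_min >= 1 && L_min <= L_max, "need 1 <= L_min <= L_max")
  stop_if_not(beta > 0, "beta must be > 0")
  K <- length(states)
  # Beta(beta,beta) density evaluated at the discrete states
  bw <- stats::dbeta(states, beta, beta)
  if (!any(bw > 0)) bw <- as.numeric(states == states[which.min(abs(states - 0.5))])
  # P0[k, j]: prior over new state k given previous state j; j = 1 is the
  # sentinel "no previous state" (first segment), j = 1 + i excludes state i
  P0 <- matrix(0, K, K + 1)
  P0[, 1] <- bw / sum(bw)
  for (i in seq_len(K)) {
    p <- bw
    p[i] <- 0
    P0[, 1 + i] <- p / sum(p)
  }
  lens <- seq_len(L_max)
  h <- ifelse(lens < L_min, 0, 1 / (L_max - lens + 1))
  structure(list(states = states, K = K, L_min = L_min, L_max = L_max,
                 beta = beta, P0 = P0, h = h,
                 log_s = log(states), log_1ms = log1p(-states)),
            class = "changepoint_spec")
}

#' Believed-model specification for a named Bayesian observer variant
#'
#' Maps an observer model id and its free parameters to a
#' [changepoint_spec()]:
#' \describe{
#'   \item{`bayes_ideal`}{the true generative values: the task's state set,
#'     run length uniform on `[run_min, run_max]`, `beta = 1`.}
#'   \item{`bayes_r`}{run length believed uniform on `[floor(2r/3), r]`
#'     (parameter `r`; `r = 120` reproduces the ideal observer).}
#'   \item{`bayes_pi`}{five states evenly spaced from `pi_min` to
#'     `1 - pi_min` (parameter `pi_min`).}
#'   \item{`bayes_beta`}{Beta(beta, beta) hyperprior applied after each
#'     change point (parameter `beta`).}
#'   \item{`bayes_rpb`}{run length uniform on `[r, r + delta_r]`, five states
#'     from `pi_min` to `pi_max`, and free `beta`.}
#' }
#'
#' @param model one of `"bayes_ideal"`, `"bayes_r"`, `"bayes_pi"`,
#'   `"bayes_beta"`, `"bayes_rpb"`.
#' @param params named list of the variant's free parameters.
#' @param config a [task_config()] supplying the true values.
#' @return a [changepoint_spec()].
#' @export
belief_spec_for_model <- function(model, params, config) {
  p <- as.list(params)
  switch(model,
    bayes_ideal = changepoint_spec(config$state_set, config$run_min, config$run_max, 1),
    bayes_r = {
      r <- round(p$r %||% stop("bayes_r needs parameter 'r'"))
      changepoint_spec(config$state_set, max(1, floor(2 * r / 3)), max(1, r), 1)
    },
    bayes_pi = {
      pm <- p$pi_min %||% stop("bayes_pi needs parameter 'pi_min'")
      changepoint_spec(seq(pm, 1 - pm, length.out = 5),
                       config$run_min, config$run_max, 1)
    },
    bayes_beta = changepoint_spec(config$state_set, config$run_min, config$run_max,
                                  p$beta %||% stop("bayes_beta needs parameter 'beta'")),
    bayes_rpb = {
      r <- round(p$r); dr <- round(p$delta_r)
      changepoint_spec(seq(p$pi_min, p$pi_max, length.out = 5),
                       max(1, r), max(1, r) + max(0, dr), p$beta)
    },
    stop("unknown Bayesian variant: ", model)
  )
}

#' Hazard of a run ending at a given length
#'
#' Under a believed discrete-uniform run-length distribution on
#' `[L_min, L_max]`, the probability that a run ends at length `r` given it
#' has lasted `r` trials is 0 below `L_min`, `1/(L_max - r + 1)` inside the
#' support, and 1 at (or clamped above) `L_max`.
#'
#' @param run_length non-negative integer run length(s).
#' @param spec a [changepoint_spec()].
#' @return hazard probability(ies).
#' @export
hazard <- function(run_length, spec) {
  stop_if_not(all(run_length >= 0), "run_length must be >= 0")
  ifelse(run_length < spec$L_min, 0,
         ifelse(run_length >= spec$L_max, 1, 1 / (spec$L_max - run_length + 1)))
}

#' Posterior over the current probability state within a run
#'
#' Given the category counts of the current run and the state `xi` in force
#' before the last change point, the posterior over the believed state set is
#' proportional to the after-change prior (Beta-weighted, excluding `xi`)
#' times the Bernoulli likelihood of the run's labels:
#' \eqn{P(\pi \mid r, \xi, C) \propto p(\pi \mid \xi, \beta)\,
#'   \pi^{n_A}(1-\pi)^{n_B}}.
#'
#' @param run_counts integer vector `c(n_A, n_B)` of category counts in the
#'   current run.
#' @param xi previous state (must be in `spec$states`), or `NA` for the
#'   sentinel "no previous state" of the first segment.
#' @param spec a [changepoint_spec()].
#' @return named probability vector over `spec$states`.
#' @export
conditional_state_posterior <- function(run_counts, xi, spec) {
  stop_if_not(length(run_counts) == 2 && all(run_counts >= 0),
              "run_counts must be c(n_A, n_B) with non-negative entries")
  j <- if (is.na(xi)) 1L else {
    m <- match(TRUE, abs(spec$states - xi) < 1e-12)
    if (is.na(m)) stop("xi is not in the believed state set", call. = FALSE)
    1L + m
  }
  lw <- log(spec$P0[, j]) + run_counts[1] * spec$log_s + run_counts[2] * spec$log_1ms
  w <- exp(lw - max(lw[is.finite(lw)]))
  w[!is.finite(w)] <- 0
  stats::setNames(w / sum(w), format(spec$states))
}

# Likelihood matrix of run labels: rows len = 0..R, cols believed states.
# Row-normalized by its max (all downstream uses are within-row ratios).
# Rows for lengths longer than the label history are padded with ones.
run_likelihood_matrix <- function(cums, t, spec) {
  R <- spec$L_max
  L <- matrix(1, R + 1, spec$K)
  vmax <- min(t, R)
  if (vmax >= 1) {
    lens <- seq_len(vmax)
    nA <- cums[t + 1] - cums[t + 1 - lens]
    nB <- lens - nA
    lw <- outer(nA, spec$log_s) + outer(nB, spec$log_1ms)
    lw <- lw - apply(lw, 1, max)
    L[lens + 1, ] <- exp(lw)
  }
  L
}

# Predictive P(C = A | r, xi) for every node, given the run-likelihood matrix
node_predictive <- function(Lmat, spec) {
  num <- Lmat %*% (spec$states * spec$P0)
  den <- Lmat %*% spec$P0
  num / den
}

#' Fresh joint belief over run length and pre-change state
#'
#' Initializes the change-point observer: all weight on run length 0 with the
#' sentinel "no previous state", i.e. the first segment's state is a fresh
#' draw from the (Beta-weighted) full state set.
#'
#' @param spec a [changepoint_spec()].
#' @return object of class `"joint_belief"` holding the weight table `$w`
#'   (rows: run lengths `0:L_max`; columns: sentinel then previous states),
#'   the observed label history, and cached predictive quantities.
#' @export
new_joint_belief <- function(spec) {
  w <- matrix(0, spec$L_max + 1, spec$K + 1)
  w[1, 1] <- 1
  Lmat <- run_likelihood_matrix(0, 0, spec)
  structure(list(spec = spec, w = w, t = 0L, cums = 0L,
                 Lmat = Lmat, PA = node_predictive(Lmat, spec)),
            class = "joint_belief")
}

#' One filtering step of the change-point observer
#'
#' Absorbs a category label into the joint posterior over (run length,
#' pre-change state): every node's weight is multiplied by its predictive
#' probability of the label and its run grows by one; hazard mass
#' `h(r)` then flows to run length 0, with the new pre-change state drawn
#' from the posterior of the ending run (including the just-absorbed label);
#' the table is renormalized. Run counts are read from the stored label
#' history, so nodes with equal run length share sufficient statistics.
#'
#' @param belief a `"joint_belief"` from [new_joint_belief()].
#' @param new_label `"A"`/`"B"` (or 1/0).
#' @return the updated `"joint_belief"`.
#' @export
update_joint_belief <- function(belief, new_label) {
  spec <- belief$spec
  c01 <- if (is.character(new_label) || is.factor(new_label))
    as.integer(as.character(new_label) == "A") else as.integer(new_label)
  stop_if_not(c01 %in% c(0L, 1L), "labels must be 'A'/'B' (or 1/0)")
  R <- spec$L_max
  obs <- if (c01 == 1L) belief$PA else 1 - belief$PA
  w1 <- matrix(0, R + 1, spec$K + 1)
  w1[2:(R + 1), ] <- belief$w[1:R, ] * obs[1:R, ]
  tot <- sum(w1)
  if (!is.finite(tot) || tot <= 1e-300)
    stop("numerical underflow in change-point filter: all joint weights vanished",
         call. = FALSE)
  t_new <- belief$t + 1L
  cums <- c(belief$cums, belief$cums[length(belief$cums)] + c01)
  Lmat2 <- run_likelihood_matrix(cums, t_new, spec)
  hcol <- c(0, spec$h)                      # hazard by run length 1..R
  cm <- w1 * hcol
  stay <- w1 * (1 - hcol)
  den <- Lmat2 %*% spec$P0                  # ending-run normalizers
  U <- crossprod(Lmat2, cm / den)           # K x (K+1)
  new0 <- rowSums(spec$P0 * U)              # mass entering (r = 0, xi = state k)
  stay[1, 2:(spec$K + 1)] <- stay[1, 2:(spec$K + 1)] + new0
  w2 <- stay / sum(stay)
  structure(list(spec = spec, w = w2, t = t_new, cums = cums,
                 Lmat = Lmat2, PA = node_predictive(Lmat2, spec)),
            class = "joint_belief")
}

#' Predictive probability of category A under the current belief
#'
#' Marginalizes the per-node state posteriors over the joint (run length,
#' pre-change state) weights: \eqn{P(C_{t+1} = A \mid C_{1:t}) = E[\pi_t]}.
#' Always bounded by the smallest and largest believed states.
#'
#' @param belief a `"joint_belief"`.
#' @return probability of category A on the next trial.
#' @export
predictive_category_prob <- function(belief) {
  sum(belief$w * belief$PA)
}

#' Run the change-point observer over a label sequence
#'
#' Forward-filters a category label stream and returns, for every trial, the
#' predictive category-A probability the observer held *before* seeing that
#' trial's label — the estimate that drives its decision criterion.
#'
#' @param labels vector of `"A"`/`"B"` labels (or 1/0).
#' @param spec a [changepoint_spec()].
#' @return numeric vector of predictive probabilities, same length as
#'   `labels`; empty input gives an empty output.
#' @export
run_bayes_sequence <- function(labels, spec) {
  c01 <- if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "A") else as.integer(labels)
  n <- length(c01)
  if (!n) return(numeric(0))
  stop_if_not(all(c01 %in% c(0L, 1L)), "labels must be 'A'/'B' (or 1/0)")
  out <- numeric(n)
  belief <- new_joint_belief(spec)
  for (t in seq_len(n)) {
    out[t] <- predictive_category_prob(belief)
    belief <- update_joint_belief(belief, c01[t])
  }
  out
}
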