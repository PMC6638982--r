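---
title: "Observer models of criterion learning under changing category probability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observer models of criterion learning under changing category probability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critlearn)
```

## The scientific problem

In a perceptual categorization task, the optimal placement of the decision
criterion depends on the prior probability of each category. When that
probability changes at hidden change points, an observer must track it from
trial-by-trial feedback alone. `critlearn` implements the full modelling
pipeline for this problem: a generative task, a family of trial-level
observer models that differ in *how* they estimate category probability, the
response likelihoods that connect an estimate to observable behavior in two
task variants, Bayesian model fitting on parameter grids, and group-level
model comparison.

### The generative task

Category A probability $\pi_t$ follows a *sample-and-hold* path: it is held
constant and then, every 80–120 trials (discrete uniform), jumps to a new
state drawn from the set $S_\pi = \{0.2, 0.35, 0.5, 0.65, 0.8\}$ excluding
the current one. On each trial a category $C_t$ is drawn
($P(A) = \pi_t$), a stimulus orientation $s_t \sim N(\mu_C, \sigma_s^2)$
with $\sigma_s = 10°$, and a noisy internal measurement
$x_t \sim N(s_t, \sigma_v^2)$. The category separation is set to
$\Delta\theta = d'\sqrt{\sigma_s^2 + \sigma_v^2}$ so that the task has a
target discriminability $d' = 1.5$ *on the measurement distribution*; with
$\sigma_v = 10°$ this gives $\Delta\theta \approx 21.2°$ and an
equal-priors ideal accuracy of $\Phi(d'/2) \approx 0.77$, which is why we
define $d'$ on the measurement rather than the stimulus distribution.

Two response modes share this generative world:

* **covert-criterion task** — the observer classifies the stimulus
  ("A"/"B"); the criterion is implicit in the choice;
* **overt-criterion task** — the observer explicitly reports the criterion
  orientation before the stimulus appears; the report is corrupted by
  Gaussian adjustment noise $\sigma_a$.

All orientations are in degrees relative to the neutral criterion
$z_\mathrm{neutral} = (\mu_A + \mu_B)/2$, with category A clockwise (lower).
Gaussians live on the real line — all spreads are far below the 180°
orientation period — and only the overt lapse density (uniform, $1/180$ per
degree) treats orientation as circular.

```{r}
cfg <- task_config()
cfg
```

## Observer models

Every model (except RL) produces a per-trial estimate
$\hat\pi_{A,t}$ from the feedback labels $C_{1:t-1}$ and places its
criterion at the optimal point for that estimate,
$z_t = z_\mathrm{neutral} + \frac{\sigma^2_\mathrm{dec}}{\mu_B - \mu_A}
\ln\frac{\hat\pi_{A,t}}{1 - \hat\pi_{A,t}}$.

### Change-point detection observers

The Bayesian family filters a joint posterior over the current *run length*
$r_t$ (trials since the last change) and the *pre-change state* $\xi_t$.
Given $(r_t, \xi_t)$ and the run's labels, the posterior over the current
state is conjugate-discrete:
$P(\pi \mid r, \xi, C) \propto p(\pi \mid \xi, \beta)\,\pi^{n_A}(1-\pi)^{n_B}$,
where the after-change prior $p(\pi \mid \xi, \beta)$ re-weights the state
set by a Beta$(\beta,\beta)$ density and excludes $\xi$. The predictive
category probability is the posterior mean of $\pi$, marginalized over
$(r, \xi)$.

The filtering step absorbs each label first (the run grows $r \to r+1$ and
each node is re-weighted by its predictive probability of the label) and
then applies the hazard $h(r) = P(L = r \mid L \ge r)$ of the believed
discrete-uniform run-length distribution, routing change mass to $r = 0$
with $\xi'$ drawn from the ending run's state posterior. This ordering makes
$r_t = 0$ mean "a change occurred after trial $t$, the new run is empty",
which is the convention the run-count bookkeeping relies on. Two numerical
choices matter:

* run lengths are truncated at the believed maximum $L_\mathrm{max}$, where
  the hazard is exactly 1, so the weight table is finite without
  approximation;
* the per-run label-likelihood matrix is computed in log space and
  normalized row-wise by its maximum — every downstream use is a
  within-row ratio, so this is exact and prevents underflow for runs of
  hundreds of trials.

The filter is validated against a brute-force enumeration over *all*
change-point segmentations (tiny problems, tolerance $10^{-10}$), which pins
the recursion independently of its algebra.

The initial belief uses a sentinel "no previous state" whose exclusion set
is empty: the first segment's state is a fresh Beta-weighted draw from the
full state set, exactly as in the generative model.

Variants differ only in believed parameters: `bayes_ideal` uses the truth;
`bayes_r` believes $L \sim \mathrm{Unif}[\lfloor 2r/3\rfloor, r]$;
`bayes_pi` believes five states spanning $[\pi_\min, 1-\pi_\min]$;
`bayes_beta` adds the equal-probability hyperprior $\beta$; `bayes_rpb`
frees run length, state range and $\beta$ together. Setting $r = 120$,
$\pi_\min = 0.2$ or $\beta = 1$ each reproduces the ideal observer exactly —
a property the test suite asserts on full-length sessions.

One subtlety of the exclusion rule: under a long streak of A labels the
predictive converges to the top state (0.8) *within* a believed run, but
after each believed change point it must temporarily favor the runner-up
(0.65), because the new state excludes the old one. The predictive therefore
cycles rather than settling at 0.8.

### Heuristic observers

* **fixed** — assumes $\pi = 0.5$ forever; criterion pinned at neutral.
* **exp** — exponential averaging,
  $\hat\pi \leftarrow \alpha C_t + (1-\alpha)\hat\pi$, time constant
  $\tau = -1/\ln(1-\alpha)$ trials.
* **exp_bias** — the same with conservatism: the reported estimate is
  $w\hat\pi + (1-w)/2$.
* **wilson** — a three-node mixture of delta rules approximating the
  run-length posterior. Node $l_i$ learns at rate $1/(l_i + \nu_p)$; node
  weights are likelihood-weighted by each node's prediction, hazard mass
  ($h = 0.01$, one change per 100 trials) is routed to node 1, and growth
  mass moves from node $i$ to $i+1$ with fraction $1/(l_{i+1} - l_i)$ so
  the represented mean run length advances by one per trial (the top node
  maps to itself). All weight starts on node 1 (a change is assumed at
  $t = 1$). With a single node this is *exactly* the exp model, the limit
  that pins the weight machinery. Node estimates are clamped to
  $[10^{-12}, 1-10^{-12}]$: the pseudocount interpretation of $\nu_p$ never
  saturates, and exact floating-point saturation would zero every node
  likelihood at the next contradicting label.
* **rl** — no probability estimate at all; the criterion moves toward the
  measurement after errors, $z \leftarrow z + \alpha_{RL}(x_t - z)$.
* **behrens / behrens_bias** — a grid-based Bayesian learner over
  (probability $\pi$, log-volatility $v$, log volatility-drift $k$). Each
  trial the joint density is pushed through a Gaussian random walk on $v$
  (variance $e^k$) and a Beta transition on $\pi$ with mean $\pi_t$ and
  concentration $e^{v_{t+1}}$ — shape parameters $(\pi c, (1-\pi)c)$, which
  keeps the mean a martingale — then multiplied by the Bernoulli likelihood.
  The five-dimensional transition integral factorizes into two sequential
  1-D kernel convolutions on the 30-bin axes, which is mathematically
  identical and tractable. Grid ranges are configuration, not theory:
  $\pi \in [0.01, 0.99]$ linear, concentration $e^v \in [2, 10^4]$ and
  diffusion variance $e^k \in [10^{-4}, 10]$ log-spaced — wide enough to be
  effectively non-informative for these session lengths.

### Decision rules and likelihoods

The covert decision uses decision variance
$\sigma^2_\mathrm{dec} = \sigma_s^2 + \sigma_v^2$ (the classification is of
the noisy measurement). For the overt task the report is scored against the
true stimulus, which the observer never measures before reporting, so the
default overt decision variance is $\sigma_s^2$; because the convention is
genuinely underdetermined, `task_config(overt_decision_variance =
"measurement")` switches to $\sigma_s^2 + \sigma_v^2$.

Covert response probability: $\Phi((z_t - s_t)/\sigma_v)$, mixed with a
fixed lapse $\lambda = 10^{-4}$ (uniform over the two choices). Overt
response density: $(1-\lambda)N(\hat z_t; z_t, \sigma_a^2) + \lambda/180$
with $\lambda = 5\times10^{-5}$. Lapse behavior in simulation mirrors the
likelihood exactly.

The RL likelihood has no closed form (the criterion depends on the latent
measurements), so it is approximated by Monte Carlo over 5000 simulated
measurement vectors with common random numbers across parameter values —
two independent seeds change an 800-trial log likelihood by well under 0.5
points. Feedback correctness inside the Monte-Carlo rollout uses the
internal (pre-adjustment-noise) criterion in the overt task, keeping the
simulator and the likelihood mutually consistent.

## Fitting and comparison

`fit_observer()` evaluates the log joint
$\log p(\mathrm{data}\mid\theta) + \log p(\theta)$ on a grid spanning the
prior box — 100 points per axis by default, 50 for the Wilson model — and
integrates it by the trapezoidal rule in log space to obtain the log
marginal likelihood. Priors are uniform in a transformed space where
stated: $\sqrt\beta \in (0,10]$, $\sqrt{\delta_1} \in [1.01,5]$,
$\sqrt{\delta_2} \in [1.01,14]$ (node spacings $l_2 = 1+\delta_1$,
$l_3 = l_2+\delta_2$), $\ln\nu_p \in [0,5]$ (read as natural log, so
$\nu_p \in [1, e^5]$ — the log base is not determined by theory and is
exposed through the prior registry). Axes include the prior endpoints;
open supports are evaluated on slightly inset closed boxes
($\pi_\min \in [0.005, 0.495]$, $\sqrt\beta \in [0.05, 10]$) so every grid
node is a valid model, and the prior is the proper uniform on those
effective bounds. Noise parameters are task-specific: $\sigma_v$ is free
only in covert fits; overt fits fix $\sigma_v$ at its known value and free
$\sigma_a$, keeping model complexity equal across tasks.

In the covert task the criterion scale $(\sigma_s^2+\sigma_v^2)/\Delta\mu$
depends on $\sigma_v$, but the estimate trajectory does not, so the grid
evaluator computes each trajectory once and sweeps the noise axis
vectorized; the conservatism weight $w$ is likewise factored out of the
base trajectory. These exact factorizations are what make grid fitting
cheap; the test suite cross-checks grid cells against the scalar
likelihood API.

The `bayes_rpb` model (six parameters) exceeds what grid integration can
bear and is fitted by bounded multi-start maximum likelihood (L-BFGS-B, 20
restarts by default) with AIC/BIC for comparison — the same role the
original fitting protocol assigned to its high-dimensional model.

Group-level comparison: `delta_scores_bootstrap()` (percentile bootstrap
over subjects, 10,000 replicates, 2.5/97.5 percentiles) and
`bms_protected_exceedance()` — the variational Dirichlet-multinomial scheme
with $\alpha_0 = 1$, exceedance probabilities by $10^6$ seeded Dirichlet
draws (argmax with random tie-breaking, a measure-zero event), and the
protected version $\phi_k = EP_k(1 - BOR) + BOR/K$ with the Bayes omnibus
risk from the free-energy comparison against the equal-frequency null.
Evidence is invariant to per-subject constants and model order, and
$\phi \to 1/K$ as evidence differences vanish — all asserted as tests.

## Validation machinery

* `posterior_predictive()` draws parameters from the grid posterior
  (default 1000 draws) and simulates behavior on the fitted stimuli,
  averaging 10,000 response draws per trial in the covert task. The band is
  the pointwise mean ± SD across draws. Because each simulated trajectory
  averages away single-session response noise, the band describes *model*
  uncertainty and is deliberately narrower than a raw cumulative-response
  realization; the calibration test therefore checks that fresh single-draw
  predictive trajectories fall inside the band at the nominal 68% rate
  (±15 percentage points), not that the raw data do.
* `parameter_recovery()` simulates sessions at known parameters, refits,
  and reports bias, RMSE and true-vs-recovered correlation. Adjustment
  noise $\sigma_a$ in the overt task is known to recover with a positive
  bias; that is reported, not failed.
* `model_recovery()` fits every candidate to data simulated from every
  generator (parameters drawn from plausible regimes — smoothing factors
  0.1–0.3, conservatism weights 0.5–0.9, sensory noise 8–12°) and tallies a
  confusion matrix of best-evidence models.

### Problem sizes

The test suite runs recovery at desk scale by the package's own choice:
25-point grid axes, 20 sessions of 800 trials for parameter recovery, 10
datasets per model of 400 trials on a 3-model set for model recovery.
Paper-scale resolutions (100-point axes, $10^4$ bootstrap and $10^6$
Dirichlet draws) remain the function defaults.

## What the generator does and does not emulate

The synthetic task reproduces the generative statistics the models assume:
sample-and-hold probability with uniform 80–120 segment lengths, the
five-state set, Gaussian categories at $d' = 1.5$, Gaussian sensory and
adjustment noise, and the fixed lapse rates. It does not emulate
properties of real observers that lie outside every model here: drifting
category-mean beliefs, sequential choice dependencies beyond the modelled
feedback loop, reaction times, or motivational effects of the points score.
Passing recovery tests therefore show that the *pipeline* is consistent —
that the models are discriminable and their parameters estimable from data
that obey the assumed generative model — not that real observers obey it.

## Known limitations

* The overt decision-variance convention is a documented switch, not a
  resolved question.
* Grid fitting of the Wilson model at its full default resolution
  ($50^3$ trajectory combinations) is expensive in plain R; reduced grids
  are recommended for exploration.
* The RL likelihood inherits Monte-Carlo jitter; common random numbers make
  it smooth enough for bounded optimization but gradients remain noisy near
  parameter values where simulated choices flip.
* Exceedance probabilities are Monte-Carlo estimates; at $10^6$ draws their
  SE is about $5\times10^{-4}$.

## A minimal session

```{r, fig.width = 6, fig.height = 5}
cfg <- task_config(n_trials = 300)
ses <- simulate_session(cfg, "exp_bias", list(alpha = 0.17, w = 0.58),
                        task = "covert", seed = 1)
fit <- fit_observer(ses, "exp_bias", n = 20)
summary(fit)
plot(fit)
```
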