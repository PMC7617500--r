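---
title: "Modelling vaginal community state type dynamics with hierarchical continuous-time Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vaginal community state type dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cstmc)
```

## The problem

Vaginal microbiota compositions are conventionally summarised per sample as
community state types (CSTs): I, II and V are dominated by *Lactobacillus
crispatus*, *L. gasseri* and *L. jensenii* and are considered optimal for
health; CST III (*L. iners*-dominated) is sub-optimal; CST IV (a diverse
anaerobic assemblage, with sub-types IV-A/B/C) is non-optimal and is the
microbial context of bacterial vaginosis.  In longitudinal cohorts, each
woman contributes a sequence of CST labels at irregular sampling times.
The questions this package addresses are: how stable is each community
state; which participant-level covariates (alcohol consumption, smoking,
contraception, antibiotic treatment, ...) shift the transition rates; and
how much do women differ beyond what the measured covariates explain.

Because rare CSTs (II, V, and the IV sub-types) provide too few transitions
to estimate rates of their own, the state space is pooled to three
health-graded states: 1 = Optimal (I, II, V), 2 = Suboptimal (III),
3 = Nonoptimal (IV-A/B/C).

## The model

Between observations, each participant's state evolves as a continuous-time
Markov chain on the three pooled states.  For participant $p$, the
instantaneous intensity of moving from state $i$ to $j$ is

$$q_{p,i,j} = \exp(\mu_{p,i,j} + \beta_{i,j} X_p),$$

a proportional-hazards form: $X_p$ is the participant's transformed
covariate vector and $\beta_{i,j}$ a log hazard ratio.  Covariate effects
are constrained symmetric within each unordered state pair,
$\beta_{j,i} = -\beta_{i,j}$: a covariate's pull toward one member of a
pair is exactly the mirror of its pull in the reverse direction.  The six
directed intercepts $\mu_{p,i,j}$ are *not* constrained symmetric — the
chain may, and does, move toward deterioration faster than toward
recovery.  The package stores one coefficient per pair and derives the
directed value by a fixed sign convention: positive $\beta$ favours the
less optimal member of the pair.

Intercepts carry participant-level random effects in a non-centred
parameterisation,

$$\mu_{p,i,j} = (\hat\mu_{i,j} + s_{p,i,j})\,\mu_{sd} + \bar\mu, \qquad
  s_p = \mathrm{diag}(sd_s)\, L_s\, z_p,$$

with $\hat\mu_{i,j} \sim N(0,1)$, $z_p \sim N(0,1)^6$,
$sd_s \sim t_4^+(0,1)$ and $L_s$ the Cholesky factor of a $6\times 6$
correlation matrix with an LKJ(2) prior.  Coefficients take weakly
informative $t_4(0,1)$ priors.  The intensity matrix $Q_p$ has the
off-diagonal rates above and diagonal entries equal to minus the row sums,
and the probability of the state observed after an elapsed time
$\Delta t$ is a row of the matrix exponential $P_p = \exp(\Delta t\, Q_p)$.
Each participant's first observed state is conditioned on; every
subsequent observation contributes a categorical log-probability.  The
observed CST is taken as the true state (no misclassification layer).

Time-varying antibiotic exposure is handled piecewise-constant: recorded
episode start/end dates split an observation interval into segments, the
covariate value in force at the *start* of a segment governs that segment,
and the interval matrix is the ordered product of segment matrix
exponentials.  Antibiotic indicators are coded 0/1 with 0 = untreated so
that the model intercept represents the untreated condition; static
binaries are deviation-coded $\pm 0.5$ instead, which places the intercept
at the theoretical midpoint.

## Units and reporting scales

All rates and times are in **days** internally.  Reporting layers
summarise at a 7-day horizon ("weekly" persistence), 90 days (the
three-month recast) and as sojourn times $-1/q_{i,i}$ in days.
Counterfactual prevalence is a long-run (stationary) summary; a
finite-horizon trajectory mode is available behind a flag (the two can
disagree when covariates act asymmetrically on slow and fast transitions,
so both are exposed and labelled).

## Covariate preprocessing

Binary questionnaire covariates whose modal value exceeds 90% of
non-missing observations are excluded before fitting — such columns carry
almost no contrast.  Continuous covariates are centred and scaled;
right-skewed, zero-inclusive scales (alcohol, BMI, partner count, red-meat
frequency) are log1p-transformed first (log1p rather than log because
zeros are legitimate values on these scales).  The default scaling divisor
is **two** standard deviations, paired with $\pm 0.5$ deviation coding, so
a binary contrast and a 2-SD continuous contrast are on a comparable
"full contrast" scale; single-SD scaling is available via
`build_design(scale = "sd")`.  A guard flag forbids double transformation.
Missing covariate cells (rare in the target design: a single missing
continuous value) are completed by chained-equation regression imputation
with predictive-mean matching (5 donors, 5 sweeps), producing `m = 10`
completed tables fitted separately and pooled; the imputer is intentionally
minimal and pluggable.

## Inference engine

The model density is isolated in `log_posterior()` (likelihood plus the
five prior blocks on their constrained supports).  Sampling runs on an
unconstrained scale — log random-effect scales, and the correlation factor
through a tanh/canonical-partial-correlation transform with its exact
Jacobian — using an adaptive Metropolis-within-Gibbs scheme:

* joint random-walk updates for the blocks (intercepts, coefficients, log
  scales, correlation factor), with step sizes tuned by Robbins–Monro
  toward an acceptance rate of 0.234 and proposal shapes replaced during
  warm-up by the Cholesky factor of the regularised empirical covariance
  of the block history (adaptive Metropolis);
* a compiled per-participant sweep for the latents $z_p$, each touching
  only that participant's likelihood term (the likelihood factorises over
  participants given the global parameters);
* adaptation is frozen after warm-up, so post-warm-up draws target the
  exact posterior.

Initial values are drawn at 0.1 times the prior scale around zero in the
unconstrained space, seeded; chain $c$ of imputation $m$ runs under
`seed + 1000 (m - 1) + c`, making every fit bit-reproducible.  Transition
probabilities are floored at $10^{-300}$ before logs (with a counter and
warning) so that numerically impossible observed transitions keep the
posterior finite rather than crashing a chain.

The matrix exponential is computed three ways that must agree to $10^{-8}$
on test matrices: Padé scaling-and-squaring (`Matrix::expm`, the numerics
core), an eigendecomposition route, and the compiled Armadillo routine
used in the likelihood hot path.

Convergence is assessed with rank-normalised split R-hat (bulk and folded)
and bulk effective sample size with Geyer initial-monotone truncation,
treating every (imputation, chain) run as a chain; the conventional flags
are R-hat < 1.01 and ESS ≥ 1000 at full scale, scaled down in reduced
runs.  Calibration on synthetic data uses the posterior z-score
$(\text{mean} - \text{truth})/\text{SD}$ and the posterior contraction
$1 - \text{posterior var}/\text{prior var}$.

### Scale choices

Test- and desk-scale runs use 4 chains × 500 sampled iterations after 500
warm-up on a 40-participant synthetic cohort; this is the package's own
choice of reduced problem size at which credible-interval coverage and
|z| < 3 calibration are verifiable in minutes on one CPU.  The full-scale
configuration (4 × 10,000 + 1,000 across 10 imputations) is available
through `mcmc_config()` but is not exercised by the test suite.  At
reduced scale the random-walk engine mixes slowly relative to a
gradient-based sampler — effective sample sizes per parameter are in the
tens, not thousands — which widens Monte-Carlo error but does not bias the
posterior; the acceptance checks are therefore phrased as coverage and
calibration statements rather than point reproduction.

## The synthetic cohort generator

`make_fixture()` and the `generator_config()`/`generate_covariates()`/
`generate_trajectories()` stack emulate the cohort design the model
targets: 125 participants; per-participant sample counts
`3 + NegBin(size 2.2, mean 9.5)`, giving median 11 and quartiles 7/16;
sampling intervals drawn from a mixture of point masses at 7 and 28 days
(weights 0.45/0.40, jitter SD 0.5 d) and a uniform(1, 60) component
(0.15), reproducing the bimodal interval distribution of a design with
weekly self-samples and monthly/bimonthly visits; binary covariate
prevalences matching the published cohort summary; one missing cell in
one continuous covariate; and Poisson antibiotic episodes (7-day default
duration).  True intercepts are derived from the reported population
sojourn times (6.9, 4.2, 1.6 days, exits split evenly within a state) on
the scale $\bar\mu = \log(1/7)$, $\mu_{sd} = 1$; $\log(1/7)$ (one
transition per week) is the package's default centring for the intercept
scale, and both hyperparameters are configurable.

Trajectories are generated from the model itself: latents drawn standard
normal, first state from the participant's stationary distribution
(conditioning on a stationary start avoids initialisation transients;
frozen or reducible chains fall back to a uniform start), subsequent
states either from categorical draws of interval matrix exponentials
(default) or from explicit jump-and-hold simulation — the two modes agree
in distribution and are cross-checked by a chi-square test.

What the generator does *not* emulate: menstrual-cycle periodicity,
behaviour drift over follow-up (static covariates are truly static here),
CST misclassification, and within-pool heterogeneity (raw labels inside a
pooled state are redrawn at their observed within-pool shares, carrying no
dynamics).  Passing tests therefore demonstrate that the pipeline recovers
the data-generating process *of this model class*, not that the model is
correct for any real cohort.

## Numerical and design choices

* Stationary distributions solve $\pi Q = 0$, $\sum \pi = 1$ by direct
  linear solve, with a positivity check on $\exp(Q)$ guarding against
  reducible inputs.
* Equal-tailed central 95% quantile intervals everywhere.
* Posterior predictive checks reuse each participant's inferred latents
  (within-cohort comparison); a new-woman mode draws fresh latents.
* The per-pair/per-direction bookkeeping (sign convention, pair indices)
  lives in a single table, `transition_table()`, used by every layer.
* The "representative reference value" for counterfactuals is 0 on the
  transformed scale — the population mean for continuous covariates, the
  midpoint for deviation-coded binaries, untreated for antibiotics.
* One ambiguity in the headline covariate count is left to the user: the
  two dated antibiotic indicators ship as separate time-varying columns
  alongside the 15 retained static covariates; whether one calls the panel
  "16" or "17" covariates depends on whether the antibiotics are counted
  as one.

## Known limitations

* The random-walk engine is the package's only sampler; for paper-scale
  runs a gradient-based backend would be preferable, and the isolated
  `log_posterior()` is the intended integration point.
* R-hat < 1.01 is typically not attained at the reduced test scale; the
  test suite verifies calibration (coverage, z-scores, contraction)
  instead, and flags convergence honestly through `convergence_report()`.
* No hidden-Markov misclassification layer, no model comparison (WAIC /
  LOO), no within-MCMC imputation — imputation is a pre-step.

## A short walk-through

```{r example, eval = FALSE}
fx <- make_fixture("recovery", seed = 1)
fit <- fit_ctmc(fx$cohort, fx$design,
                config = mcmc_config(chains = 4, iter = 500, warmup = 500, seed = 1))
convergence_report(fit, ess_min = 100)
summarise_transitions(fit)            # weekly/90-day persistence, sojourn times
summarise_hazard_ratios(fit)          # exp(beta) with direction probabilities
counterfactual_prevalence(fit, "alcohol", grid = seq(0, 19, by = 1))
individual_variability(fit)           # where women differ most
```
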