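---
title: "Population-level scale-setting for the hierarchical LBA: models, sampler, and validation design"
author: "hlba authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-level scale-setting for the hierarchical LBA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Evidence-accumulation models express choice and response time through
latent quantities — drift rates, boundaries, start points — whose "unit of
evidence" is undefined until one parameter is fixed to set the scale. In
the Linear Ballistic Accumulator (LBA) the conventional choice is to fix
the between-trial drift-rate standard deviation `sv` at 1 *for every
participant*. That convention silently assumes participants (and groups)
do not differ in `sv`. When they do, the misfit leaks into the freely
estimated parameters: two groups that truly differ only in `sv` will
appear to differ in drift rates and boundaries instead, while the true
difference is invisible because it lives in the fixed parameter.

`hlba` implements, alongside the classic constraint, a population-level
alternative for hierarchical Bayesian estimation: fix the *population
mean* of `sv` at (approximately) 1 through a near-degenerate hyper-prior,
while leaving every individual's `sv` free. The unit of evidence is then
"one population-level `sv`", shared by all participants, and individual
and group differences in `sv` remain expressible.

## Model

Each two-choice trial races two linear ballistic accumulators. Accumulator
$i$ starts at a point drawn uniformly on $[0, A]$, accrues evidence at a
rate drawn once per trial from $\mathrm{Normal}(v_i, sv)$, and responds
when it reaches the absolute boundary $b = A + B$ with $B > 0$ the gap
above the start-point range. The observed response time adds a
non-decision time $t_0$ (seconds). The defective density of response
$c$ at time $t$ is the first-passage density of the winning accumulator at
$t - t_0$ times the survivor function of the loser, both in the standard
closed form built from normal CDF/PDF terms.

The participant-level parameter vector is
$(A, B, v_\mathrm{true}, v_\mathrm{false}, sv, t_0)$, with one `sv`
shared by the two accumulators. We parameterise the boundary through the
gap $B$ rather than the absolute $b$: it keeps $b > A$ by construction for
any positive draw or proposal, it is the convention of the
differential-evolution MCMC tooling this literature uses, and it makes a
small lower bound (0.05) on the "boundary" parameter coherent.

Hierarchy: for each free parameter $p$, individual values are
conditionally $\mathrm{Normal}(\mu_p, \sigma_p)$ truncated below at 0.
The truncated-normal link keeps $\sigma_p$ interpretable against the
generating SDs; the family is the convention of the hierarchical-LBA
literature (the studies this package replicates do not state one).

Priors:

* $\mu_p$ for non-`sv` parameters: $\mathrm{Normal}(m_p, 1)$ truncated at
  0, centred at user-supplied prior means $m_p$. The SD of 1 is weakly
  informative at the scale of typical generating values (0.3–3); it is
  exposed as `mu_prior_sd`.
* $\sigma_p$: uniform (a scaled Beta(1,1)) on $[0, 3]$ — effectively
  data-determined.
* Scale setting, `method = "new"`: $\mu_{sv}$ uniform on
  $[0.999, 1.001]$. This is a genuine (sampled) prior, not a hard
  constant: the population mean of `sv` is *de facto* fixed at about 1
  while individual `sv` values vary freely.
* Scale setting, `method = "classic"`: `sv` is fixed at 1 for every
  participant and excluded from the parameter vector.
* $t_0$ is estimated by default, with its $\mu$ prior centred at the
  supplied prior mean; `fix_t0 = TRUE` fixes it (see *Problem sizes*).

## Sampler

Posterior sampling uses blocked differential-evolution MCMC
(`run_mcmc()`), the de-facto standard for hierarchical LBA posteriors,
with the conventional chain count of three times the number of free
parameters (minimum 4). Each sweep:

1. **Participant blocks.** For each participant, all chains propose
   jointly: $x^\ast_k = x_k + \gamma (x_m - x_n) + \mathrm{U}(-\epsilon,
   \epsilon)$, with $m, n$ distinct random other chains,
   $\gamma = 2.38/\sqrt{2d}$ scaled by a per-sweep $\mathrm{U}(0.5, 1)$
   factor, and $\epsilon = 0.001$. Strictly positive parameters
   ($A, B, sv, t_0$) are proposed on the log scale with the Jacobian in
   the acceptance ratio, so domain constraints hold by construction. The
   Metropolis target is the participant's trial log-likelihood plus the
   truncated-normal link density at the chain's current
   $(\mu, \sigma)$.
2. **Hyper blocks.** For each free parameter, the pair
   $(\mu_p, \sigma_p)$ is updated by a 2-D crossover proposal against the
   link density of all individuals plus the hyper-priors. Updating
   hyper-parameters in per-parameter pairs rather than one joint block is
   deliberate: a joint update of all hyper-parameters mixes poorly
   (acceptance collapses as dimension grows) and starves the hierarchy,
   which shows up as inflated individual-level PSRF. The hyper block
   costs no likelihood evaluations either way.
3. **Migration.** During burn-in only, an occasional sweep
   (probability 0.05) replaces crossover with a cyclic swap among a
   random subset of chains, letting outlier chains rejoin; it is disabled
   after burn-in so kept draws come from a fixed kernel.

Initialisation: each participant's chains start at a cheap penalised-MLE
point (Nelder-Mead on the participant's likelihood plus a weak
truncated-normal penalty at the prior means) plus N(0, 0.1) jitter on the
transformed scale; $\mu$ starts at the prior means, $\sigma$ at 0.5.
Starting at a per-participant mode rather than at shared prior means
matters most when the true individual parameters are widely spread (as in
the two-group design below); with shared-mean starts the burn-in has to
carry every chain along a likelihood ridge and short runs fail their
convergence gate.

Numerical guards: z-scores are clipped at ±38 before normal CDF/PDF
evaluation, trial densities are floored at `1e-300`, and the total
log-likelihood is floored at `-1e10` so chains remain movable from
invalid regions. Non-finite initial likelihoods are re-jittered a bounded
number of times, then fail loudly.

Sweep counts follow the published convention: burn-in 1,000, then 12,000
sweeps thinned by 12, read as 1,000 kept draws per chain (the alternative
reading — thin after keeping 12,000 — is available by passing
`n_samples = 144000`). Convergence is assessed with the classic
(non-split) Gelman–Rubin PSRF per participant-parameter on kept draws;
participants whose worst PSRF is $\ge 1.1$ are excluded from recovery
statistics, and the exclusion list is reported.

## Synthetic cohorts

`draw_cohort()` emulates the generating process of the replication
studies: individual parameters drawn from independent normal populations
(SDs 0.6 for $A$ and $B$, 0.8 for the two drift rates, 0.4 for `sv`),
then corrected — floors of 0.05 for $A$, $B$, $v_\mathrm{false}$, 1.3 for
$v_\mathrm{true}$, 0.01 for `sv`, applied first, then the unconditional
replacement $v_\mathrm{false} := v_\mathrm{true} - 0.2$ whenever the
drift gap is below 0.2 (the replacement is not re-checked against the
floor; with the 1.3 floor on $v_\mathrm{true}$ the conflict cannot
arise). $t_0$ is the constant 0.3 s. The 21-configuration grid
(`study1_grid()`) crosses boundary-gap and correct-drift means over
{2.3, 2.5, 2.7} and the incorrect-drift mean over {0.6, 0.8, 1.0} in the
published partial-factorial pattern, with $A$-mean 2 and `sv`-mean 1
throughout. `study2_config()` builds the two-group design: groups of 50
differing only in the `sv` mean (1.5 vs 0.5).

Trial simulation races the two accumulators with independent start
points and drifts; trials where both sampled drifts are non-positive
never terminate and are redrawn. Correspondingly the likelihood is *not*
renormalised by the probability of termination by default (the mass is
negligible at these parameter ranges, about $10^{-3}$); both the
simulator convention and a `renormalize` flag for the likelihood are
exposed, and the package's own validation compares like with like.

Prior means for fitting are perturbed away from the generating truth in
two published styles: additive $\mathrm{Normal}(0, 0.1)$ noise
(`noisy_prior_means_study1()`), or a uniform draw within ±2 standard
errors of the truth (`noisy_prior_means_study2()`), with
$\mathrm{SE} = \mathrm{SD}/\sqrt{n}$ and $n$ the per-group size (the
source is ambiguous about $n$; per-group is the reading implemented, and
$n$ is an explicit argument). The `sv` prior mean is never perturbed —
its prior is the scale constraint itself.

Seeding: one master seed spawns independent L'Ecuyer-CMRG substreams per
participant, for parameter draws and for trials, so enlarging a cohort
never reshuffles existing participants.

## Recovery metrics and method comparison

* **Pearson r** between true and posterior-mean individual parameters
  (relative agreement), via `cor.test()`.
* **ICC(2,1)** — two-way random effects, single measures, absolute
  agreement — computed from the two-way ANOVA decomposition with
  $k = 2$ raters (true, estimated); the F test uses
  $(n-1, (n-1)(k-1))$ df and the confidence interval is the
  Shrout–Fleiss F-based interval. The p-value and CI come from different
  approximations and can disagree near zero; that behaviour is inherited
  from the published procedure.
* **Fisher-Z averaging** of correlations across configurations;
  ranges are reported as min/max over per-configuration values.
* **DIC** per participant, $\bar D + p_D$ with
  $p_D = \bar D - D(\bar\theta)$ at the posterior-mean parameters,
  summed for a dataset-level comparison (lower is better). DIC is known
  to be a blunt instrument for models of this complexity; it is used
  comparatively, as in the source studies.
* **Group comparison**: pooled-variance two-sample t-tests on
  posterior-mean parameters after PSRF filtering
  ($\mathrm{df} = n_1 + n_2 - 2$), $\alpha = 0.05$ two-sided, no
  multiple-testing correction — all matching the published analysis
  choices.

Posterior means pool all chains and kept iterations.

## Problem sizes

Two presets (`scale_preset()`):

* `full` — 100 participants × 1,000 trials, burn-in 1,000, 12,000 sweeps
  thinned by 12, $t_0$ estimated. This matches the published studies and
  takes hours per fit on one CPU.
* `desk` — 20 participants × 300 trials (the two-group design uses
  2 × 15), burn-in 500, 3,000 sweeps thinned by 3, $t_0$ fixed at its
  generating value. These sizes keep the complete
  simulate–fit–score loop in the couple-of-minutes range per fit while
  leaving the model structure untouched. $t_0$ is fixed at desk scale
  because its generating value is constant across participants: the
  population SD of $t_0$ then collapses toward zero and produces a
  funnel-shaped posterior that short chains cannot traverse; full-length
  chains handle it, so the full preset estimates $t_0$.

The package's test-suite and the acceptance script run everything at desk
scale.

## What the validation does and does not show

The synthetic generator reproduces the studies' *stated* conditions:
independent normal individual differences with known truncations, a
constant $t_0$, stationary parameters, and exactly two response
alternatives. Real data differ in ways the generator does not emulate —
contaminant and anticipatory responses, within-trial drift noise,
parameter correlations across people, practice and fatigue drifts.
Passing recovery at desk scale therefore demonstrates the estimator's
internal consistency under the model's own assumptions, not robustness to
model misspecification.

One empirical caveat surfaced by this implementation: how well
$v_\mathrm{false}$ recovers depends strongly on the generating
configuration. At the configuration used for the desk-scale recovery
check (boundary gap 2.5, drifts 2.5/0.8), errors are common enough
(~15–20% of trials) and decision times long enough that the losing
accumulator's survivor term keeps $v_\mathrm{false}$ well identified —
there it is among the *best*-recovered parameters, consistent with the
published two-group study at the same means. The often-cited weakness of
$v_\mathrm{false}$ recovery emerges when averaging over many
configurations, several of which provide far less error information.

## Known limitations

* The hierarchy is defined on the natural scale with truncation; a
  log-scale hierarchy is a different model and out of scope.
* No covariate or condition structure on parameters; one dataset = one
  population (the two-group design is handled at the comparison stage,
  not inside the model).
* DIC is the only fit index, inherited from the replicated procedure;
  WAIC/LOO are deliberately out of scope.
* The sampler is random-walk-based (DE-MCMC); gradient-based samplers
  are out of scope.
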