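# hlba — hierarchical Bayesian LBA with population-level scale-setting

`hlba` fits the Linear Ballistic Accumulator (LBA) model of two-choice
decisions and response times by hierarchical Bayesian estimation, for
researchers who use evidence-accumulation models to compare individuals
and groups.

## The scientific problem

LBA parameters are latent, so one parameter must be fixed to define the
unit of evidence. The classic convention fixes the between-trial
drift-rate SD, `sv = 1`, **for every participant** — which assumes away
individual and group differences in `sv`. If that assumption is wrong,
true `sv` differences masquerade as spurious differences in drift rates
and boundaries, and the real difference is undetectable.

`hlba` implements both that classic constraint and a population-level
alternative: in a hierarchical model with individual parameters
`p_i ~ Normal(Mu_p, Sigma_p)` (truncated at 0), the scale is set by giving
the population mean of `sv` a near-degenerate uniform prior,

```
Mu_sv ~ Uniform(0.999, 1.001),    Sigma_p ~ Uniform(0, 3),
```

which de facto fixes the *population mean* of `sv` at about 1 while every
individual `sv` stays free. Per trial, each accumulator starts at
`U[0, A]`, accumulates at a rate drawn from `Normal(v_i, sv)`, and
responds on reaching the boundary `b = A + B`; the response time adds the
non-decision time `t0`. Estimation is by blocked differential-evolution
MCMC (chains = 3 × free parameters, crossover proposals
`gamma (x_m - x_n)` with log-scale proposals for positive parameters),
with Gelman–Rubin PSRF convergence gating at 1.1, and recovery /
comparison scoring by Pearson r, ICC(2,1) absolute agreement, Fisher-Z
averaging, DIC, and pooled-variance group t-tests.

## Worked example

Simulate a 20-participant cohort (300 trials each) from known parameters,
fit it with the population-level scale policy, and score recovery:

```r
library(hlba)
res <- replicate_study1(config_index = 14, method = "new",
                        scale = "desk", seed = 1)
print(res$fit)
print(res$recovery)
```

```
Hierarchical Bayesian LBA fit (new scale-setting)
20 participants, 15 chains x 1000 kept draws
20 of 20 participants converged (PSRF < 1.1)
Population-level posterior means:
         mu_A          mu_B     mu_v_true    mu_v_false         mu_sv
        2.523         2.889         2.818         0.345         1.000
      sigma_A       sigma_B  sigma_v_true sigma_v_false      sigma_sv
        1.459         0.819         0.870         1.188         0.413

Parameter recovery (20 participants retained)
 parameter pearson_r pearson_p icc21 icc21_p icc21_lo icc21_hi
         A     0.816         0 0.605       0    0.380    0.795
         B     0.732         0 0.497       0    0.271    0.719
    v_true     0.859         0 0.641       0    0.429    0.816
   v_false     0.966         0 0.895       0    0.797    0.953
        sv     0.801         0 0.700       0    0.487    0.855
```

Reading the output: all 20 simulated participants pass the PSRF < 1.1
convergence gate; `mu_sv` sits at 1.000 because its prior confines it to
[0.999, 1.001] — that is the scale constraint at work. The recovery table
correlates each participant's true generating value with their posterior
mean: Pearson r measures relative agreement (ordering of individuals),
ICC(2,1) absolute agreement, so ICC ≤ r whenever estimates are
systematically shifted. Here the drift of the correct response and `sv` —
the parameter the classic method cannot even estimate — recover with
r ≥ 0.8.

The group-comparison pipeline (`replicate_study2()`) simulates two groups
differing **only** in mean `sv` (1.5 vs 0.5), fits the data under both
scale policies and contrasts them: the population-level policy detects
the `sv` difference and nothing else, while the classic policy misses it
and instead reports significant group differences in `A`, `B` and
`v_true` that do not exist; DIC favours the population-level policy.

A command-line wrapper with `simulate` / `fit` / `report` /
`replicate-study1` / `replicate-study2` subcommands is installed at
`inst/cli/hlba.R`.

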