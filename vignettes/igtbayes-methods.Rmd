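---
title: "Methods: Bayesian group comparison for the Iowa Gambling Task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian group comparison for the Iowa Gambling Task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, priors, samplers and numerical choices
behind `igtbayes`, and states plainly what the package's synthetic-data
checks do and do not establish.

## The task and the cognitive model

The Iowa Gambling Task presents four decks; the traditional payoff
structure gives decks A and B a reward of 100 per draw with 1250 lost per
10 cards (five losses for A, one for B) and decks C and D a reward of 50
with 250 lost per 10 cards, so each 10-card block nets −250 on the bad
decks and +250 on the good decks. The scheme object enforces these block
invariants; within-block loss *positions* are not part of the published
table, so the package fixes canonical positions (deck A magnitudes −150
… −350 in ascending order at draws 3, 5, 7, 9, 10) and offers a
seed-controlled within-block shuffle. Per-deck draw counters, not the
global trial index, advance the schedule, because agents sample decks
unevenly.

PVL-Delta describes a player by four parameters:

* `A` in [0, 1] — outcome sensitivity, the curvature of the prospect
  utility `u(x) = x^A` (gains) / `−w·|x|^A` (losses);
* `w` in [0, 5] — loss aversion, the weight on negative net outcomes;
* `a` in [0, 1] — the delta-rule updating rate (`a` near 1 = strong
  recency);
* `c` in [0, 5] — response consistency, mapped to the softmax
  sensitivity `θ = 3^c − 1` (0 at `c = 0`, i.e. uniform random choice, up
  to 242).

Expectancies start at zero, so the first trial is uniform; trial `t`'s
choice probability conditions on the history through `t − 1` only.

### Numerical conventions

* **Outcome scaling.** Net outcomes are divided by 100 before the utility
  (configurable `outcome_scale`; 1 restores raw units). The source
  analyses do not state a scaling; dividing by 100 keeps `θ·Ev` within
  floating-point comfort at `c = 5` and matches published parameter
  magnitudes. The same constant must be used for simulation and fitting;
  every fit records it.
* **Softmax** is computed with max-subtraction, and the log-likelihood in
  log-sum-exp form, so it is finite for all in-range parameters even when
  a choice has vanishing probability.
* **`x = 0` utility** is defined as exactly 0 (covers `0^0` at `A = 0`;
  both branches are continuous there).
* **Probit boundaries.** `to_probit()` clips unit-scale values into
  `[1e-6, 1 − 1e-6]` with a warning, since `Φ⁻¹` diverges at the bounds.

## Hierarchical estimation

Within a group, probit-transformed individual parameters are modeled as
`z'_i ~ N(μ_z', σ_z')` for each of the four parameters (with `w` and `c`
first rescaled to the unit interval by dividing by 5). Priors are
`μ_z' ~ N(0, 1)` and `σ_z' ~ Uniform(0, 1.5)`. Each group is fitted
independently, so group-level SDs may differ between groups at this
stage.

No Hamiltonian Monte Carlo backend is available in the target
environment, so the package implements the posterior contract with an
adaptive Metropolis-within-Gibbs sampler (compiled, Rcpp):

1. each individual probit parameter: random-walk Metropolis against the
   compiled likelihood, proposal scales adapted in batches of 50 during
   burn-in only (target acceptance 0.44);
2. group means: exact conjugate normal draws;
3. group SDs: exact Gibbs draws — under the uniform prior the conditional
   of `σ²` is a truncated inverse-gamma, sampled by inverse CDF;
4. an interweaved non-centered step: holding the standardized residuals
   `ε_i = (z'_i − μ)/σ` fixed, `σ` (and then `μ`) is proposed jointly with
   a rescaling/translation of all individual parameters. This breaks the
   funnel between group SDs and individual parameters that otherwise
   stalls mixing when a parameter (typically `A`) is weakly identified;
   without it, split-chain R-hat for `σ_A` stayed near 1.15–1.4 at
   settings where all parameters now reach < 1.05.

With the likelihood switched off (`likelihood = FALSE`) individual
parameters are drawn by exact Gibbs, so the chain samples the prior; the
test suite uses this for prior calibration.

Convergence is monitored by split-chain Gelman–Rubin R-hat for every
parameter against a threshold of 1.05 (rule-of-thumb bound 1.1);
non-convergence flags the result and warns, never silently passes.
Reference sampler settings: 3 chains, 2000 burn-in, 4000 retained draws
(estimation); tests and the acceptance script use documented reductions
of the retained draws, never of the models.

Point estimates for downstream stages default to posterior means taken on
the probit scale and then transformed to the natural scale (the
alternative, averaging natural-scale draws, is available as an option).

## Product-space model comparison

Sixteen models arise from letting any subset of the four group-level
means differ between groups; group-level SDs are always shared, and all
models have prior probability 1/16 (four independent Bernoulli(1/2)
difference indicators). Under equal prior probabilities the Bayes factor
between two models is their posterior-probability ratio.

The supermodel sampler follows the Carlin–Chib construction with one
structural improvement: the indicator full conditionals are *collapsed* —
the three candidate group-level means per parameter (pooled, group 1,
group 2) are integrated out analytically under their `N(0, 1)` priors, so
the indicator update depends only on the individual parameters and the
shared SD. Two consequences:

* the pseudo-priors for inactive means cancel exactly; they only refresh
  bookkeeping draws that nothing else conditions on. The classical
  moment-matched pseudo-priors (pilot fits of the pooled data and of each
  group) remain available via `pilot = "auto"` but are inert for the
  reported probabilities, which is why the default skips the pilot fits;
* the per-cycle conditional probability of every model is available in
  closed form, so posterior model probabilities are estimated by
  Rao-Blackwellization (averaging the exact conditional joint over the 16
  models) rather than by counting indicator visits. Visit proportions are
  still recorded and reported; the two estimators agree within Monte
  Carlo error, but the marginalized one is what makes the
  7000-versus-5000-draw stability check reproducible at the 0.01 level on
  a single CPU.

Each retained draw runs three full update cycles (individual-parameter
scan, SD, indicators, means) to cut the autocorrelation that feeds the
model probabilities. Indicator mixing is summarized by the per-chain
switch rate; a chain whose indicators never move raises a pseudo-prior
mismatch warning.

### Known limitation: knife-edge Jeffreys categories

The stability check also compares Jeffreys evidence categories (bands
1–3–10–30–100) between the two runs. When a Bayes factor sits essentially
on a band boundary — e.g. BF ≈ 3.00 for one two-parameter model in the
fixed-seed synthetic study used by the acceptance suite (2.99 vs 3.10
across runs) — no finite pair of runs classifies it stably even though
all probabilities agree to < 0.01. The corresponding acceptance assertion
is deliberately left failing rather than reseeded around; the
quantitative stability assertion passes.

### Null-model behavior at small groups

With identical generating parameters, the null model is *usually* the
posterior mode, but with 12 agents per group some single-difference model
edges it out in roughly half of replicates: for weakly identified
parameters the latent-parameter uncertainty erodes the Occam penalty of a
second group mean (verified against a closed-form oracle for the
collapsed indicator conditional). At the reference design of 19 + 19
agents with 100 trials the null tops the posterior in the clear majority
of replicates, and the package's end-to-end null-pipeline check runs at
that design.

## Latent-mixture group membership

All participants are pooled, labels ignored, and membership is modeled as
`z_i ~ Bernoulli(ψ)`, `ψ ~ Uniform(0, 1)`. The informed variant
(the package's primary one) builds priors that approximate the stage-1
posteriors: normal priors on `μ_z'` with the stage-1 posterior mean and
SD, and zero-truncated normal priors on `σ_z'` (no upper truncation is
imposed — only positivity is stated for this stage). The un-informed
variant (stage-1 estimation priors for both components) is available with
`priors = NULL`.

Membership indicators are updated by exact full conditionals and
memberships are reported as Rao-Blackwellized posterior means of `z_i`.
In prior-calibration mode the sampler switches to a blocked update —
`z_i` drawn marginally (its conditional with the individual parameters
integrated out is exactly Bernoulli(ψ)), then the parameters refreshed
from the assigned component — because the single-site update freezes when
the two informed components barely overlap.

Safeguards: a label-switching check verifies each fitted component mean
stays closer (probit-scale Euclidean) to its own prior center than to the
other group's; the result carries a `parameter_inference = FALSE` marker
in the informed case, because the data enter twice (once building the
priors, once fitting) and the fit must not be reused for parameter
estimates. Ties at the 0.5 classification threshold are labeled
`"unclassified"`.

## Post hoc absolute fit

Model adequacy is checked by one-step-ahead *postdictions*: for each
trial, fitted individual parameters plus the observed history up to the
previous trial give the predicted choice probabilities; these are
averaged within 10-trial blocks across participants and placed beside
observed block-wise choice proportions, per deck and aggregated into good
(C + D) versus bad (A + B) decks. Predictions never condition on
model-generated choices, which the tests verify by permuting future
trials. Whether to average probabilities over posterior draws or evaluate
at point estimates is not settled in the source analyses; the default
uses posterior-mean parameters, with draw-averaging available.

## Synthetic data: what the generator emulates — and not

`generate_group_dataset()` draws individual probit parameters from
`N(μ_z', σ_z')`, transforms them, and lets compiled PVL-Delta agents play
the traditional 100-trial scheme; `generate_two_group_study()` assembles
a 19 + 19 default-design study with labels withheld from the pooled data.
One master seed spawns a deterministic stream per participant, so
participant *i* is bit-identical whenever `(seed, i)` match, independent
of group size.

Default truth values for tests sit at mid-scale (probit 0, SD 0.3) —
deliberately *not* copied from published posterior figures, which would
have had to be read off plots. Where an effect is needed, tests shift one
group-level mean by a stated probit amount (1.5–2 units).

The generator emulates exactly the model being fitted. Green recovery and
pipeline tests therefore establish *internal* correctness — the samplers
target the stated posteriors, the comparison machinery detects
differences that exist and favors the null when none do — but say nothing
about how well PVL-Delta describes real decision-makers: human data show
perseveration, deck-position habits and non-stationarity that the model
(and hence the generator) does not produce.

One empirical subtlety found while validating: the posterior SD of a
group-level mean is **not** monotone in trials-per-agent at moderate
sizes. With few trials the group SD is itself underestimated (individual
estimates shrink together), which narrows the group-mean interval below
its long-task width; and `c` saturates through `θ = 3^c − 1`, so very
consistent agents bound `c` only from below. The recovery property test
therefore contrasts 10 versus 100 trials, where the improvement is
unambiguous for all four parameters.

## Sampler settings and other defaults

| Setting | Default | Notes |
|---|---|---|
| estimation chains / burn-in / draws | 3 / 2000 / 4000 | reference analysis settings |
| comparison chains / burn-in / draws | 3 / 1000 / 7000 | stability re-run at 5000 |
| mixture chains / burn-in / draws | 5 / 1000 / 9000 | |
| R-hat threshold | 1.05 | 1.1 rule-of-thumb also reported |
| `outcome_scale` | 100 | part of the model configuration |
| `σ` prior upper bound (estimation) | 1.5 | uniform prior |
| probit clipping `ε` | 1e-6 | warned |
| classification threshold | 0.5 | ties → `"unclassified"` |

Seeds are mandatory everywhere; identical configuration and seed
reproduce results bit for bit, and all CLI outputs embed provenance
(package version, configuration, seed).
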