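---
title: "Estimating emotion-mediated treatment effects with a randomized cooling-off period"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating emotion-mediated treatment effects with a randomized cooling-off period}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coolmediate)
```

## The identification problem

A single treated/control comparison cannot separate a treatment's direct
effect on behavior from the part that runs through a mediator, because the
treatment moves both the mediator and the outcome. When the mediator is a
*short-lived* state — here, the negative emotions triggered by an undercover
animal-farming video — a randomized cooling-off period offers a way out: a
few minutes of unrelated filler questions let the primary emotions fade for
some participants before the outcome (a donation decision) is measured,
while leaving everything else about their experience unchanged.

The design crosses video exposure `D` with the cooling-off indicator `C`,
yielding four arms: Novid-Short, Novid-Long, Vid-Short and Vid-Long, with
equal assignment probabilities. Outcomes are two bounded scores per
participant: the donation score (mean of seven donation amounts in cents,
divided by 100) and the negative-emotion score (five negative-valence
Likert items plus reverse-coded happiness, normalized to [0, 1] by adding 2
and dividing by 36).

## Model and assumptions

Participants are classified by the latent response of their binary emotional
state `M` to the video: always-takers (`M = 1` regardless, share `p_a`),
never-takers (`M = 0` regardless, `p_n`) and compliers (`M` switches from 0
to 1 with exposure, `p_c`). The identification argument needs:

1. **No defiers.** Nobody is calmed by footage of animal abuse.
2. **Exclusion restriction.** The cooling-off period affects donations only
   through the mediator. (The design backs this with a pre-registered
   falsification check: donations in Novid-Short vs Novid-Long.)
3. **Partial mediator manipulation.** A share `q` of exposed compliers
   reverts to the low state during cooling off.
4. **Equal complier effects.** The donation effect of the emotional state is
   the same for reverting and non-reverting compliers.

Under 1–4 the arm means identify the total effect
`Δ_TT = Ȳ_VS − Ȳ_NS`, the compliance share
`q = (M̄_VS − M̄_VL) / (M̄_VS − M̄_NS)` and the mediated effect
`Δ_M = (Ȳ_VS − Ȳ_VL) / q`, which equals the strata-level quantity
`p_c · E[Y(1,1) − Y(1,0) | complier]`. The package computes both forms and
`population_arm_means()` + `true_estimands()` make the equality testable to
numerical precision on an exact synthetic population.

One wording ambiguity was resolved in favor of the published results
tables: the total effect contrasts Vid-Short with Novid-Short (not a pooled
no-video group), matching how the arm means are reported.

## Decision rules

Inference is bootstrap-percentile based with participants resampled with
replacement *within arm* (`B = 1000` by default). Arm sizes are fixed by
design, and the estimands are arm-mean contrasts, so within-arm resampling
is the scheme that reproduces the sampling variation of the design; it also
keeps the `Δ_TT` and `Δ_M` draws paired when both are computed from the same
resamples (`bootstrap_effects()`), which the mediated-share decomposition
requires.

The registered rules, applied literally:

- reject `H1: Δ_TT ≤ 0` iff the 5th percentile of the draws is **strictly**
  greater than 0 (`>`, not `≥`);
- reject `H2: Δ_M ≤ 0` by the same rule;
- if `H1` is rejected and `H2` is not: economically insignificant iff the
  95th percentile of the `Δ_M` draws is strictly below the 3-percentage-point
  threshold (`econ_threshold = 0.03`, tunable), otherwise inconclusive;
- one-sided p-values are reported as the share of draws at or below zero.

**Percentile convention.** Because a percentile is compared with a hard
zero, the convention must be bit-stable: `boot_percentile()` sorts the
draws and returns the order statistic at rank `ceiling(p * B)`. No
interpolation is used.

**Degenerate draws.** A bootstrap draw can make `q̂`'s denominator (or `q̂`
itself) vanish; such draws are recorded as invalid, excluded from the
percentile computation and reported. More than 1% invalid draws raises an
`inference_unstable` error rather than a silent summary. The original data
never hit this case, but a general tool must define it. Tolerance for
degeneracy is `1e-9` on the score scale.

If the falsification check fails jointly (Wilcoxon p < 0.05 *and* a
Novid-Short/Novid-Long gap above 2pp), the main estimator is invalid; the
correction for a cooling-off direct effect is not part of this package, so
`run_pipeline("analyze")` raises a documented `not_implemented` condition
instead of inventing one.

## The synthetic generator

`simulate_experiment()` draws four-arm tables from the exact structural
model the estimator assumes, with known truths:

- **Arms**: exact counts per cell (stratified assignment), not Bernoulli —
  matching equal randomization and removing design noise from simulations.
- **Strata and mediator**: multinomial strata with shares
  `(p_a, p_n, p_c)`; mediator states deterministic except for exposed
  compliers under cooling off, who revert with probability `q`.
- **Donations**: with probability `zero_inflation` (default 0.3, between
  the pilot's zero-donation shares with and without the video) a
  participant gives 0 to every option; otherwise one "generosity" level is
  drawn from a beta distribution (overdispersion `donation_noise`, default
  0.3) and the seven options are binomial on 0..100 around it. The mixing
  makes options correlate within participant — real donation batteries are
  highly reliable — and keeps the unconditional mean *exactly*
  `mu_y(stratum, D, M)`. A truncated-and-rounded continuous kernel was
  rejected because truncation biases the mean, breaking the generator's own
  estimand-consistency guarantee.
- **Emotions**: each item is `1 + beta-binomial(6)` around a state anchor
  (defaults: negatives 6.1 / happiness 1.9 in the high state, 1.8 / 5.6 in
  the low state, chosen so the expected emotion scores are 0.85 and 0.15).
  Beta-binomial draws have exactly the anchor mean and live exactly on
  1..7, so no clipping bias; `likert_noise` (default 0.15) is the
  overdispersion.
- **Seeds**: one master seed with fixed child streams per stage (arms,
  strata, mediators, outcomes, attrition), so each stage is reproducible in
  isolation.

**Calibration.** `default_strata_config()` solves, in closed form, for the
parameters that make the *population* arm means equal the published ones:
donation scores 16.4 / 20.2 / 19.1% and emotion scores 25.7 / 66.0 / 32.2%
for Novid-Short / Vid-Short / Vid-Long (Novid-Long mirrors Novid-Short by
the exclusion restriction). Given the two emotion anchors, the emotion
means pin down `p_a = 0.153`, `p_c = 0.576`, `p_n = 0.271` and
`q = 0.839`; the donation means then pin down the complier cells. The
strata shares and complier-level donation means are **not** reported by the
original study, so the remaining structural choices — never-taker and
always-taker baselines 0.10 and 0.26 and direct video effects 0.02 / 0.03 /
0.026 — are illustrative values of realistic magnitude, not estimates.
`config_with_mediated_effect()` rescales the complier contrast to any
target mediated effect (e.g. 0 or 0.05) for calibration and recovery
studies.

**What the generator does not emulate**: item-level heaping at round
amounts, demographic heterogeneity, arm-specific extensive-margin effects
(zero-inflation is common to all arms, so extensive-margin contrasts are
driven only by the conditional mean), and any real attrition mechanism
(attrition is optional, uniform within arm, and exists to exercise the
gate). Passing recovery tests therefore show that the estimator and its
decision rules behave as designed *under the model's own assumptions* —
they are not evidence about violations of those assumptions in field data.

## Scoring choices

The aggregate emotion score is computed as
`(sum of five negatives − happiness + 2) / 36`: of the two readings the
verbal description admits (sum vs average), only the sum-based one yields
the stated [0, 1] bounds exactly, so it is adopted. For Cronbach's alpha
the happiness item is instead reversed as `8 − rating` so all items share a
direction; alpha uses population (n-denominator) variances in both
numerator and denominator — only the ratio matters, and consistency avoids
small-n asymmetry. Records failing the exclusion rules are dropped before
scoring; nothing is imputed.

## Power planning

`simulate_power()` mirrors the registered sampling plan: resample a
pilot-like table within arm to the candidate size `n`, compute the
bootstrap SE of `Δ_M` (`B` inner draws, SE = SD of valid draws), and reject
when the assumed effect (default 0.05) exceeds `z_(1−α) · SE` — the normal
approximation the plan itself invokes, not the percentile rule. The
equivalent formulation `SE < effect / z_(1−α)` gives the critical SE
`critical_se(0.05) ≈ 0.030`, and the minimum detectable effect is
`(z_(1−α) + z_(power)) · SE ≈ 3.29 · SE` at the defaults. The original
power figures (100% at 800/arm, 3.4pp MDE at N = 3200) depend on
unpublished pilot variance components; the package reproduces the
qualitative shape (power non-decreasing in `n`, SE shrinking) and the
arithmetic identities, not those exact numbers.

## Numerical and testing notes

- The Wilcoxon rank-sum test uses midranks, tie-corrected variance and
  continuity correction (via `stats::wilcox.test(exact = FALSE)`). Against
  an exact permutation-enumeration oracle the approximation agrees within
  0.02 for tie-free samples of 5–8 per group (the worst case over all
  rank-sum values is 0.017); below 5 per group or under heavy ties the
  mid-distribution error can reach ~0.04–0.09, a known property of the
  approximation documented here rather than hidden.
- The mediated-share decomposition floors negative mediated draws at 0,
  winsorizes ratios at 1, and excludes (but counts) draws with a
  non-positive total effect — the original data had none, so the exclusion
  convention is this package's.
- Forecast aggregation uses the median of within-forecaster ratios, not the
  ratio of medians; the two disagree on asymmetric data, and a regression
  test encodes the distinction.
- Simulation sizes in the test suite: recovery and null-calibration use 500
  replicates at 800 per arm (the registered design), with `B = 1000` for
  the null-calibration rejection rule; the power-curve checks use
  `S = 100`, `B = 200` over per-arm sizes 100–800. These sizes give
  Monte-Carlo standard errors well below the margins being tested while
  keeping the default suite quick to run.

## Limitations

- The alternative estimator for a cooling-off direct effect on donations is
  intentionally absent; the pipeline only detects when it would be needed.
- No covariate adjustment, no delta-method standard errors, no sensitivity
  analysis for defiers or for unequal complier effects.
- The generator's strata shares and complier donation levels are
  illustrative defaults; conclusions that depend on them (e.g. absolute
  power numbers) should be re-derived from a user's own pilot data.
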