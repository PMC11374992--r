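# coolmediate

Causal mediation analysis for randomized experiments that manipulate a
**short-lived mediator with a randomized cooling-off period**. The motivating
setting is an online experiment on the effect of an undercover animal-farming
video on charitable donations: does the video move donations *through* the
viewer's immediate negative emotions, or independently of them? Because the
emotional reaction fades within minutes, randomizing a ~5-minute filler
questionnaire ("cooling off") between the video and the donation decision
creates exogenous variation in the mediator that a single treated/control
contrast cannot provide.

The package is aimed at experimental economists, social psychologists and
applied statisticians who run (or plan) four-arm designs of this type:
video yes/no crossed with cooling-off yes/no, giving the arms Novid-Short,
Novid-Long, Vid-Short and Vid-Long.

## The estimator

Let `Y` be the donation score (mean of seven donations in cents / 100, in
[0, 1]) and `M` the binary latent emotional state measured by the
negative-emotion score. Participants belong to principal strata defined by
the mediator's response to the video: always-takers (share `p_a`),
never-takers (`p_n`) and compliers (`p_c`); defiers — people *relaxed* by
footage of animal abuse — are assumed absent. A share `q` of exposed
compliers reverts to the low emotional state during the cooling-off period.

Under random assignment, the exclusion restriction (cooling off affects
donations only via emotions) and equal complier effects, the arm means
identify:

- total effect: `Δ_TT = Ȳ_VS − Ȳ_NS`
- compliance share: `q̂ = (M̄_VS − M̄_VL) / (M̄_VS − M̄_NS)`
- mediated effect: `Δ_M = δ / q` with `δ = Ȳ_VS − Ȳ_VL`,
  equal to `p_c · E[Y(1,1) − Y(1,0) | complier]` at the population level.

Inference follows pre-registered bootstrap percentile rules (participants
resampled within arm, `B = 1000`): reject `H1: Δ_TT ≤ 0` iff the 5th
percentile of the `Δ_TT` draws is strictly positive, likewise `H2: Δ_M ≤ 0`;
if `H1` is rejected but `H2` is not, the mediated effect is declared
economically insignificant iff the 95th percentile of `Δ_M` is below 3
percentage points, and inconclusive otherwise.

The package also provides the outcome-neutral validity gates (Cronbach's
alpha ≥ 0.6 for both scales, ≥ 20pp emotion drop under cooling off, ≤ 10pp
attrition shift per arm, a Wilcoxon filler-effect check), a
simulation-based power planner, exploratory decompositions (mediated share
of the total effect, per-emotion and per-option contrasts, extensive
margin), forecast aggregation by median-of-ratios, and a synthetic
four-arm generator with closed-form true estimands for recovery testing.

## Worked example

```r
library(coolmediate)

cfg    <- default_strata_config(n_per_arm = 800, seed = 42)
scored <- score_participants(simulate_experiment(cfg))
summarize_arms(scored)
#>           arm   n mean_donation_score mean_neg_emotion_score
#> 1 Novid-Short 800           0.1740304              0.2706597
#> 2  Novid-Long 800           0.1737964              0.2557986
#> 3   Vid-Short 800           0.2038643              0.6371528
#> 4    Vid-Long 800           0.1903071              0.3333681

estimate_mediated_effect(summarize_arms(scored))
#> Plug-in estimates (donation-score units):
#>   total effect      delta_TT = +0.0298
#>   video-arm contrast   delta = +0.0136
#>   compliance share     q_hat = 0.8289
#>   mediated effect    delta_M = +0.0164

eff <- bootstrap_effects(scored, B = 1000, seed = 42)
decide_hypotheses(eff$tt, eff$m)
#> Registered decision report:
#>   H1 (total effect <= 0): rejected (5th pct +0.0100, p = 0.006)
#>   H2 (mediated effect <= 0): not rejected (5th pct -0.0089, p = 0.145)
#>   mediation verdict: inconclusive (95th pct +0.0404 vs threshold 0.03)
```

Reading the output: the video raises mean donations by about 3 percentage
points of the endowment (`delta_TT`), and the cooling-off period removes
about 83% of the emotion spike (`q_hat`). Dividing the video-arm donation
contrast `delta` by `q_hat` attributes about 1.6pp of the total effect to
the emotion channel — positive, but small enough that the bootstrap cannot
rule out zero, so the registered rules reject `H1`, fail to reject `H2`
and return an inconclusive mediation verdict. The generator's defaults are
calibrated so its population arm means equal the published donation scores
(16.4 / 20.2 / 19.1%) and emotion scores (25.7 / 66.0 / 32.2%).

The same workflow runs file-to-file via `run_pipeline("simulate" | "score" |
"validate" | "analyze" | "power" | "explore" | "report", ...)`, each stage
writing its artifacts plus a deterministic manifest.

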