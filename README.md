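# wswcat

Social categorization analysis for **Who-Said-What (WSW) memory-confusion
experiments**, for behavioral researchers who measure spontaneous grouping
from recall errors.

In a WSW study, participants view faces paired with spoken statements and
later attribute each statement to a face. Misattributions are informative:
if a statement by one speaker is credited to another face that shares a
social attribute (sex, race, a facial scar), the attribute evidently
organized memory. `wswcat` implements the complete analysis chain around
this idea, plus a generative simulator so every stage is testable with
known ground truth.

## The statistics at the core

For each participant and each binary cue *c*, errors are split into
within-category errors (chosen face shares cue *c* with the true speaker)
and between-category errors, and summarized as the **proportional
categorization score**

```
score_c = (within_c − between_c) / total errors
```

Scores lie in [−1, 1]; cues are scored independently (an error can be
"within" for several cues at once). Under uniform random guessing in a
balanced 2×2×2 face set the expectation is not 0 but **−1/7** (3 of the 7
error alternatives share any given cue), and the chance that an error
shares *at least one* cue with the true speaker is **6/7**; both baselines
are computed exactly by the package (`expected_random_score()`,
`feature_overlap_probability()`).

Cue interdependence is assessed by OLS on uncentered scores,

```
scar_score ~ b0 + b1·race_score + b2·sex_score + b3·race_score·sex_score
```

with simple slopes `b1 + b3·v` at moderator levels `v` (mean ± 1 SD) and
delta-method standard errors (`simple_slopes()`, `slope_contrast()`).

Because all cue scores are carved from one finite error pool, they trade
off mechanically even under pure guessing. The **constrained resampling
null** (`run_null_simulation()`) isolates this artifact: each replicate
keeps every participant's error count and the task structure fixed,
redraws each error's chosen face uniformly over the 7 incorrect
alternatives, re-scores, and refits the regression through the identical
code path. Observed statistics are then located in the null with
type-7 empirical quantiles and add-one-corrected tail probabilities,
`p = (1 + #extreme) / (1 + R)`.

The simulator (`simulate_wsw_cohort()`) draws per-participant accuracy
from a Beta distribution and latent cue weights from a multivariate
normal; error choices follow a cue-match softmax,
`P(f) ∝ exp(Σ_c w_c · match_c(f, true))`, which nests uniform guessing at
`w = 0`.

## Worked example

```r
library(wswcat)

cohort <- simulate_wsw_cohort(wsw_config(n_participants = 300, seed = 42))
scores <- categorization_scores(cohort$trials, cohort$design)
cue_summary(scores)
#>   cue       n   mean    sd statistic    df  p.value cohens_d chance_score
#> 1 sex     299  0.315 0.547      9.96   298 2.38e-20    0.576       -0.143
#> 2 race    299 -0.116 0.557     -3.61   298 3.64e- 4   -0.209       -0.143
#> 3 scar    299 -0.300 0.512    -10.1    298 7.07e-21   -0.585       -0.143
```

One simulated participant had zero errors, so 299 of 300 are scored. With
the default generator (weight means 1.0 / 0.15 / −0.15) the cohort shows
the canonical WSW pattern: strong sex-based categorization, weak race, and
a scar score *below* its −0.143 chance level (a contrast rather than a
grouping pattern).

```r
overlap_statistics(cohort$trials, cohort$design)
#> participant-mean overlap: 0.925 (SD 0.118), t(298) = 9.97, p = 2.14e-20, d = 0.58
#> pooled: 2652 of 2870 errors (92.4%) share a cue; exact binomial p = 9.73e-29 (greater)
```

Errors share at least one cue with the true speaker more often than the
6/7 ≈ 85.7% chance baseline — responding is not indiscriminate guessing.

```r
fit <- fit_interaction_model(scores, outcome = "scar", predictors = c("race", "sex"))
glance(fit)[, c("r.squared", "statistic", "df", "df.residual", "nobs")]
#>   r.squared statistic    df df.residual  nobs
#> 1     0.250      32.8     3         295   299

simple_slopes(fit)
#>   level        moderator_value estimate std.error statistic  p.value
#> 1 -1 SD (Low)           -0.232   -0.278    0.0617     -4.51 9.40e- 6
#> 2 Mean                   0.315   -0.381    0.0469     -8.11 1.37e-14
#> 3 +1 SD (High)           0.862   -0.483    0.0645     -7.49 8.08e-13
```

Scar-based categorization declines as race-based categorization rises, and
the decline steepens with stronger sex-based categorization — the cue
hierarchy suppresses anomaly-based grouping.

```r
ns <- run_null_simulation(cohort$trials, cohort$design, n_replicates = 1000, seed = 43)
glance(ns)
#>   n_replicates n_failed observed_r2 null_r2_q999     p_r2 p_interaction
#> 1         1000        0       0.250        0.221 0.000999         0.593
autoplot(ns)   # histogram of the null R² with the observed value marked
```

The observed R² = 0.250 exceeds every one of 1000 constrained-null
replicates (99.9% quantile 0.221), so the fitted structure reflects
genuine cue-based encoding, not the shared-error-pool artifact — while the
interaction coefficient alone stays inside its null here (p = 0.593).

`run_wsw_pipeline(out_dir)` chains all stages and writes every artifact
(trials/scores/model/replicates CSV + JSON summaries) with recorded seeds.

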