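---
title: "Measuring social categorization from memory confusions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring social categorization from memory confusions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wswcat)
```

This vignette is the package's account of its statistical machinery: the
measurement model behind the Who-Said-What (WSW) paradigm, the generative
model used for simulation, the inferential procedures, the numerical
conventions, and the choices we made where more than one defensible
convention exists.

## 1. The measurement model

A WSW experiment presents `2^k` faces in a balanced factorial design over
`k` binary social cues — here sex (female/male), race (Black/White), and a
facial scar (absent/present), so 8 faces — each paired with several
first-person statements (3 per face, 24 pairings). After a distractor, a
surprise recall task asks which face made each statement. Correct
responses confound memory, category information and guessing, so only the
errors are analysed.

For cue `c`, an error is *within-category* when the chosen face shares
cue `c` with the true speaker, and *between-category* otherwise. Each
participant's proportional categorization score is

$$\mathrm{score}_c = \frac{\mathrm{within}_c - \mathrm{between}_c}{\mathrm{total\ errors}} \in [-1, 1].$$

Cues are scored on the same error pool and are not mutually exclusive.
Two exact combinatorial baselines anchor interpretation
(`expected_random_score()`, `feature_overlap_probability()`; both return
exact rationals and agree with exhaustive pair enumeration by
construction):

* Under uniform guessing over the `2^k - 1` alternatives,
  `E[score_c] = (s - d)/(2^k - 1)` with `s = 2^{k-1} - 1` same-cue and
  `d = 2^{k-1}` different-cue alternatives: **−1/7 ≈ −0.143** for `k = 3`,
  identical for every cue. Scores are *not* base-rate corrected; the
  baseline is carried alongside (`chance_score`) instead, so the raw score
  remains in its conventional metric.
* The probability that a uniformly chosen error shares at least one cue
  with the true speaker is `1 - 1/(2^k - 1)` = **6/7** for `k = 3` (the
  only overlap-free alternative is the full complement face).

Participants with zero errors have no defined score. They are flagged and
excluded from aggregates and model fits, never imputed as zero — which
also reproduces the familiar pattern that the analysed `n` falls slightly
below the recruited `n`.

## 2. The generative model (what the simulator does and does not emulate)

`simulate_wsw_cohort()` gives every participant a latent accuracy
`a_i ~ Beta(α, β)` and a latent weight vector `w_i ~ N(μ_w, Σ_w)`, one
weight per cue. Each of the 24 statements is recalled correctly with
probability `a_i`; otherwise the error face is drawn from the cue-match
softmax

$$P(\mathrm{choose}\ f) \propto \exp\Big(\sum_c w_{ic}\, \mathbb{1}[\mathrm{match}_c(f, \mathrm{true})]\Big), \qquad f \neq \mathrm{true}.$$

This is the minimal exponential-family choice model that nests uniform
guessing (`w = 0`) and produces graded within-category confusion; `w_c`
is the log-odds bonus per shared cue. Useful exact consequences, all
tested: `w = 0` gives 1/7 per alternative; `w_sex = ln 2` gives 0.2 for
each same-sex and 0.1 for each different-sex alternative; as
`w_sex → ∞` errors confine to the 3 same-sex faces, forcing race and scar
scores to −1/3 — the conditional-tradeoff signature that motivates the
null simulation.

Defaults (all overridable in `wsw_config()`): `n = 500` participants ×
24 trials; accuracy `Beta(6, 4)` (mean 0.6, ≈ 10 errors of 24, the error
volume typical of online WSW cohorts); weight means `(1.0, 0.15, −0.15)`
for sex/race/scar with unit variances and zero covariances. These
defaults are chosen to *qualitatively* mirror the canonical ordering —
strong sex-based, weak race-based, weakly contrastive scar-based
categorization — not to reproduce any particular dataset's values.

What the generator does **not** emulate: encoding-time attention and
fatigue, statement semantics and stereotype congruence, face-specific
idiosyncrasies (each design cell is one face in the classic paradigm),
response-time structure, and any accuracy–weight correlation (available
only through `Σ_w` configuration; accuracy and weights are independent by
default because the literature gives no joint model). Passing simulation
tests therefore certifies the *pipeline arithmetic and its statistical
behaviour under the stated model*, not the psychology of any real cohort.

Generation is serial on a single RNG stream seeded from
`config$seed`; identical seeds give bit-identical cohorts. Cohorts of the
sizes used here generate in seconds, so no per-participant substream
scheme is needed for parallelism.

## 3. Inference

**Overlap analysis.** Two complementary tests ask whether errors exceed
the 6/7 overlap baseline: a two-sided one-sample t-test of per-participant
overlap proportions (reported with Cohen's `d = (m - p_0)/s`), and an
exact binomial test of the pooled trial-level count. The binomial test is
one-sided (greater) by default because the scientific question is
elevation above chance; a two-sided flag exists. The participant-level
mean is unweighted over participants with ≥ 1 error.

**Interaction regression.** `fit_interaction_model()` fits OLS of one
cue's score on two others and their product, on **uncentered** scores.
Uncentered fitting is deliberate: conventional WSW reports present simple
slopes at raw moderator values whose mean matches the moderator's
descriptive mean, which is only coherent when the coefficients are on the
raw scale. Simple slopes are `b1 + b3·v` with delta-method standard
errors from the coefficient covariance,
`SE(v) = √(Var b1 + v² Var b3 + 2v Cov(b1, b3))`, and t-tests on the
residual df. Slope contrasts are `b3(v_b − v_a)` with
`SE = |v_b − v_a|·SE(b3)`; their t statistic equals the interaction's t in
magnitude for *every* level pair — an algebraic identity the tests check
to machine precision, and a useful internal consistency check on any
reported slope table. Nested models are compared with
`ΔF = (ΔR²/q) / ((1 − R²_full)/df_full)`, verified against the RSS-based
`anova()` decomposition. Covariates join by participant id, dummy-coded
with the modal category as reference (no convention is standard in this
literature, and the modal reference keeps contrasts interpretable in
unbalanced samples), with listwise deletion and logged counts.

**Two-sided p-values** are used for all coefficient and slope tests.

## 4. The constrained resampling null

Because every cue score is computed from the same finite error pool,
scores trade off mechanically: an error that is within-category for sex
has its race/scar categories fixed by the face design. Regressing one
score on others therefore yields nonzero R² even under uniform guessing.
`run_null_simulation()` quantifies exactly this artifact: each replicate
keeps the set of correct trials and each participant's error count fixed
(a conservation property tested bit-for-bit), redraws every error's
chosen face uniformly over the 7 alternatives, then reruns
`categorization_scores()` and `fit_interaction_model()` — the same
functions as the primary analysis, so there is no observed/null
implementation drift. Replicates that fail to fit are dropped and
counted (`n_failed`).

Conventions, stated in the output metadata:

* **Quantiles**: type-7 order statistics (linear interpolation between
  closest ranks).
* **Tail probabilities**: add-one corrected,
  `p = (1 + #extreme)/(1 + R)`, so a finite Monte Carlo never reports 0;
  the raw proportion is available by flag.
* **Tail modes**: R² uses the upper tail; coefficients default to
  magnitude (`|x| ≥ |obs|`), with signed tails available.
* Error *positions* are fixed and only error *choices* are resampled:
  the null conditions on each participant's realized error count rather
  than re-randomizing which trials were errors, because the error count
  is an ability nuisance parameter, not part of the categorization signal
  being tested.

Two calibration facts are worth knowing (both tested). First, on cohorts
generated under uniform guessing the observed R² behaves like one more
draw from its own null, so it falls inside the central 95% of the null
about 95% of the time. Second, the null R² location rises as error pools
shrink, but only slightly (a few thousandths of R² between 20 and 5
errors per participant): the proportional score's correlation structure
is largely invariant to pool size because signal and noise moments scale
together. The mechanical artifact is therefore mostly a *correlation*
phenomenon (null replicates show systematically negative cue-score
correlations), not a small-sample one.

## 5. Numerical and edge-case conventions

* Face ids are 0-based integers in binary-counting order of the cue
  codes (first cue = most significant bit); level-to-code mappings are
  explicit configuration and travel in faces CSV header comments.
* Exact rationals back the combinatorial baselines; closed forms are
  cross-checked against enumeration for `k ≤ 4` as exact integer
  identities, not float comparisons.
* Softmax utilities are max-shifted before exponentiation, so extreme
  weights (e.g. `w = 50`) cannot overflow.
* Degenerate inputs fail loudly with classed errors: non-binary or
  duplicated cues, unbalanced face tables on file read, unknown face ids
  (with row numbers), `correct` flags contradicting the ids, constant
  outcomes in t-tests, rank-deficient design matrices, zero-length
  replicate vectors, `level_a = level_b` contrasts.
* A constant covariate is dropped (with a message) rather than breaking
  the fit, so the covariate model degrades gracefully to the core model.

## 6. Problem sizes used by the test suite

The suite exercises each stochastic property at sizes chosen for
Monte-Carlo resolution against its tolerance: calibration of generator
means pools eight 500-participant cohorts (standard error ≈ 0.005 against
a ±0.02 band); parameter recovery uses one 20,000-participant cohort so
the rank correlation is estimated to ±0.007; null-coverage calibration
uses 100 cohorts of 120 participants × 500 replicates; the error-regime
comparison uses 300-participant cohorts × 400 replicates because the
trend it checks is only a few thousandths of R². All randomized tests run
under seeds fixed in the test files.

## 7. Known limitations

* The parameter-recovery rank correlation between planted weights and
  observed scores sits near 0.80 under the reference conditions
  (accuracy ~ Beta(5,5), unit-variance weights, 24 trials); with ~12
  errors per participant the score simply cannot be a much sharper
  estimate of the latent weight. Designs wanting tighter recovery need
  more trials, not more participants.
* The regression operates on participant-level indices; it does not model
  conditional cue competition within single error choices. A trial-level
  discrete-choice treatment (e.g. conditional logit over the 8
  alternatives) is out of scope here.
* The simulator's softmax is a modeling convenience, not a claim about
  mechanism; other confusion models with matching first moments would
  yield the same scores.
* Scores from very small error pools are coarse (an `e`-error participant
  has score resolution `2/e`), which inflates participant-level variance;
  the package reports `n_errors` so users can weight or filter
  deliberately rather than silently.
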