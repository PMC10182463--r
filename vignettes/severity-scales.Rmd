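---
title: "Semantic severity scales: models, choices, and what the synthetic studies show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic severity scales: models, choices, and what the synthetic studies show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`semscale` measures how well the severity of violent events survives being
communicated through language, comparing human readers against a
computational model trained on the language itself. This vignette is the
package's own account of the underlying models, the tunable parameters and
why their defaults are what they are, what the synthetic study generator
does and does not emulate, and the numerical decisions a maintainer would
want written down.

## 1. The measurement problem

Two groups rate the same events on a 0–10 severity instrument. Phase-1
(P1) participants experienced the events and described each with five
keywords; phase-2 (P2) participants only read the descriptions. Two
discrepancies are of interest:

* **Calibration bias**: `mean(P2) − mean(P1)` for a condition
  (psychological or physical violence). The sign convention is fixed so
  that negative means readers under-rate; the reported t statistics carry
  the same sign (`calibration_test()`).
* **Accuracy bias**: for each P2 rater, the Pearson correlation between
  their ratings and the P1 ratings of the same events
  (`accuracy_by_rater()`); low correlation means the rater cannot
  reproduce the experiencers' ranking. Model accuracy is the same
  statistic with the model's predictions substituted for the rater's
  numbers, so human and model are scored on identical event sets.

The package's question is whether a regression model reading only the
keywords shows smaller biases than the human readers.

## 2. The semantic space

`count_cooccurrences()` counts, for every ordered pair of distinct
positions at distance ≤ `window` inside a single n-gram, one co-occurrence
of the two words, weighted by the n-gram's corpus count. Both directions
are counted: the matrix then supports symmetric word–word similarity,
which is what an additive text embedding needs. Counts are not weighted by
distance within the window; a repeated word at two positions contributes
to the matrix diagonal. Row and column vocabularies are the most frequent
corpus words (frequency ties broken lexicographically, for determinism),
`log(count + 1)` attenuates raw frequency artifacts (natural log by
default; `log_base = "base10"` is available), and a truncated SVD keeps
the `n_dims` leading dimensions — the ones carrying the most information.

Numerical choices in `build_space()`:

* Embeddings are the left singular vectors scaled by their singular values
  (`U·S`). Because every word vector is then renormalized to unit length,
  the scaling convention only affects intermediate values; it is
  documented here rather than exposed as an option.
* SVD signs are indeterminate per dimension; the largest-magnitude loading
  of each dimension is forced positive so spaces are identical across
  platforms and repeated runs.
* Requesting more dimensions than the numerical rank is an error that
  names the achievable rank. Words whose vectors collapse to zero norm
  (possible for degenerate corpora) are dropped with a warning rather than
  silently carried as zero vectors.
* Words are lowercased and whitespace-tokenized; there is no stemming.

The default `space_config()` mirrors full-corpus scale (±4 window in
5-grams, 120,000 row words, 50,000 column words, 512 dimensions). The
synthetic pipeline default is 64 dimensions over a vocabulary of a few
hundred words — comfortably above the ~23 clusters the generator plants,
and small enough that a complete run takes seconds.

## 3. Text embeddings and semantic scales

A keyword response is embedded as the normalized sum of its word vectors
(`embed_keywords()`): order-free, with duplicated words contributing
multiply (the summation is literal). Out-of-vocabulary words are skipped
with a warning; a fully out-of-vocabulary response is an explicit error,
never a silent zero vector, and exact cancellation (a zero-norm sum) is
likewise an error.

`train_scale()` is deliberately plain: ordinary least squares with an
intercept on the first `k` embedding dimensions, or a maximum-likelihood
logit for binary outcomes. No regularization is used anywhere. The
intercept is included as standard regression practice even though the
scale is often written `y = c·x`; without it the model would be forced
through the origin of an arbitrary embedding basis. Rank deficiency and
logistic non-convergence are errors that name the offending dimensions or
the iteration count; perfect separation is detected and flagged.

Cross-validation (`cross_validated_fit()`) uses one fixed grouped
partition: all ratings of one source text share a fold (10 folds by
default), so no text ever appears on both sides. Within each training
partition, `select_dimensions()` picks `k` from a geometric-style grid
{2, 4, 8, 16, 32, 64, 96, 128, 192, 256, 384, 512} clipped to the data.
"Highest fit" is scored by inner 5-fold grouped cross-validation by
default: scoring the plain training fit instead would always favour the
largest `k` whenever noise is present, which is exactly the overfitting
the outer loop is supposed to guard against. A `method = "train-fit"`
switch preserves the simpler reading for comparison. Ties are broken
toward the smallest `k` (scores compared with a 1e-10 tolerance so exact
fits at several `k` resolve to the most parsimonious).

## 4. The bias report

`build_bias_report()` fills one row per condition (combined,
psychological, physical): rating counts, the correlations r(P1, P2),
r(P1, MP1), r(P1, MP2), means and SDs, and the two biases. MP2 are the
out-of-fold predictions for P2 responses ("all data points evaluated
once"); MP1 come from a final model fit on all P2 data and applied to the
P1 responses — the model is trained purely on P2 so it never sees a P1
rating.

Aggregation for the calibration tests is an inference the package makes
explicit and keeps switchable: the human test compares per-event P1
ratings against per-rater P2 means (for 68 events and 20 raters per
condition this gives the pooled df of 86 familiar from such designs), and
the model test compares per-event P1 ratings against per-event mean MP2
predictions (df 134). The accuracy test is a two-sample t on the
per-rater r values, human vs model (df 38 at 20 raters per condition),
on raw r by default — a `fisher_z` option applies `atanh` first for the
variance-stabilized version. p values are reported unadjusted; no
multiple-testing correction is applied.

One statistical caveat is worth stating plainly. Within a single study
the two phases rate the *same events*, so P1 and P2 summaries are
positively dependent and any two-independent-sample t between them is
conservative. The type-I-error simulation in the acceptance suite
therefore evaluates `calibration_test()` on independent draws (P1 events
from one generated study, P2 rater means from another, both with the
planted shift at zero), in the variance-robust Welch mode, since per-event
ratings and per-rater means have unequal variances by construction; that
is the setting in which a 5% test should reject 5% of the time. The
pooled mode remains the default for reporting because it reproduces the
conventional df arithmetic.

## 5. Word scores

For the word-cloud outputs, three scales are trained on the full P2 data:
severity (linear), physical-vs-psychological (logistic; physical coded 1),
and per-record calibration bias (linear, P2 rating minus the event's P1
rating). Full-data rather than cross-validated models are used for word
scoring: the scores are descriptive, not accuracy claims. Every distinct
in-vocabulary word occurring in the responses is scored through its own
unit word vector, and scores are standardized over exactly that set of
distinct words — the dataset vocabulary is the only reference population
available to a renderer, and standardizing over it makes z values
invariant to any positive affine transform of the raw scale. If all
scores coincide the z values are defined as 0 (with a warning); fewer
than two distinct scorable words is an error, since an SD would be
undefined.

## 6. The synthetic study generator

The original study's text data are not deposited, so `generate_study()`
draws a study with the same shape and the statistical structure the
analysis assumes:

* latent event severity `s_e ~ Normal(mu_c, sigma_c)` per condition;
* P1 rating `round(clip(s_e + Normal(0, sigma_p1)))`;
* P2 rating `round(clip(mu_c + delta_c + sensitivity_c·(s_e − mu_c) +
  gamma_r + Normal(0, sigma_p2_c)))` with per-rater offsets
  `gamma_r ~ Normal(0, rater_sd)`;
* keywords drawn from the severity bin of a *perceived* severity
  `s_e + Normal(0, channel noise)` in disjoint condition-specific bin
  vocabularies, with a `filler_prob` chance per slot of a shared filler
  word; the matching n-gram corpus (`generate_corpus()`) makes same-bin
  words co-occur preferentially so the learned space clusters them.

Defaults are the study conditions: 68 events per condition, 40 raters
split evenly, 5 keywords, latent means/SDs 6.46 (1.69) psychological and
6.59 (1.81) physical, planted shifts −0.61 and +0.95 — all anchored to
`reference_summary()`.

The `sensitivity` term deserves its derivation. Readers in this regime
reproduce experiencers' rankings only weakly (per-rater r² around 0.06
psychological, 0.2 physical). A purely additive reader model
(`sensitivity = 1`) cannot reach correlations that low without rating
noise so large (SD ≳ 6 on an 11-point scale) that clipping to [0, 10]
dominates the distribution and corrupts the planted mean shifts. Instead
the generator lets communicated severity regress toward the scale mean
with slope `sensitivity_c` — a standard account of judgment under an
impoverished channel — and uses moderate rating noise. With per-rater
correlation approximately
`b·sigma_c² / sqrt((sigma_c² + sigma_p1²)·(b²·sigma_c² + sigma_p2²))`,
the defaults b = 0.32, sigma_p2 = 2.2 (psychological) and b = 0.50,
sigma_p2 = 1.6 (physical) place human accuracy near r² = 0.05 and 0.22
while keeping clipping distortion of the planted shifts under about 0.1
rating units. `sensitivity = c(1, 1)` restores the purely additive model.
These constants live in the config, not in code, and were fixed once from
this calculation.

Two deliberate distortions of the rating instrument are kept: ratings are
clipped to [0, 10] *before* rounding to integers, which slightly shrinks
the observed shift for conditions whose means sit near the scale ends
(physical, mean 7.54: the shrinkage is a few hundredths to ~0.1). The
recovery tolerance of ±0.15 rating units accounts for this.

`signal_variance_fraction()` computes, from the retained generating
truth, the share of P2 rating variance explained by the true (condition,
perceived bin) cell — the ceiling available to *any* predictor working
from the keywords, since keywords are conditionally independent of the
rating given that cell. The acceptance suite checks that the
cross-validated r² lands within ±0.1 of this ceiling, averaged over 20
seeds.

What the generator does **not** emulate: real English words and their
polysemy, free-text narratives (explicitly out of scope throughout),
rater-specific scale use beyond an additive offset, correlations between
a rater's keyword choice and their own rating error, and corpus
statistics of a terabyte n-gram collection. Passing tests therefore
demonstrate that the machinery recovers what it is designed to recover
under its own assumptions — not that the same r² values would appear on
real IPV narratives.

## 7. Problem sizes and determinism

Simulation-based checks run at the full study design (68 events per
condition, 40 raters, 2720 P2 ratings) with a desk-scale language side:
~4000 synthetic 5-grams, a ~216-word vocabulary, 64 retained dimensions,
and the dimension grid clipped to {2, …, 64}. Twenty seeds for the
recovery and ordering checks and 1000 replicates for the test-size check
keep the whole suite in the tens of seconds while leaving Monte-Carlo
error well inside the stated tolerances. Every random draw flows through
a seed argument (`with_seed` semantics: the caller's RNG state is
restored), stage seeds in `run_pipeline()` derive deterministically from
the master seed, and output files carry no timestamps, so identical
config + seed reproduces every artifact byte for byte. The run manifest
records config, seed, and the per-fold dimension trace; stages are
regenerated rather than content-hash cached, since at these sizes a rerun
costs seconds and cache invalidation would be the only hard part.

## 8. Known limitations

* The bias report's aggregation conventions (rater means vs event means)
  are inferred from the df arithmetic of the study design, not stated by
  it; both are exposed as ordinary function arguments so either side can
  be re-aggregated.
* Keyword counts are configurable per response but default to 5 for both
  conditions; protocols that elicit a different count per condition are
  supported by generating and validating with a different
  `keywords_per_response`.
* The number of P2 raters defaults to 40 (20 per condition). The
  validation layer treats a rater spanning conditions as a warning, not
  an error, to admit messier real tables.
* Raw r values (not Fisher-z) are compared by default in the accuracy
  test; with 20 raters per side and r far from ±1 the difference is
  minor, but the option exists because the raw-r test is not exact.
* Logistic scales refuse single-class outcomes and flag separation rather
  than regularizing; with planted, fully separable vocabularies the
  coefficients under separation are direction-stable but scale-unstable.
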