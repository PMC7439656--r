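---
title: "User-informed fuzzy encodings for ordinal severity scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{User-informed fuzzy encodings for ordinal severity scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordifuzz)
```

## The problem

Clinical questionnaires and patient-reported outcome measures (PROMs) record
symptom severity on ordered verbal scales such as the five-level HL7 set
*Absent < Mild < Moderate < Severe < Extreme*. Downstream models usually
replace these labels with the integers 0..4, which silently asserts that the
perceived distance between *Absent* and *Mild* equals the distance between
*Severe* and *Extreme*. People do not perceive the scale that way, and the
spacing they do perceive can be elicited: ask raters to mark, on a 0--100
visual-analogue continuum, the interval of values each label covers, plus a
single most-representative point (RP).

`ordifuzz` turns such elicitations into *fuzzy sets* -- discrete weight
functions $\mu_v$ over the integer grid $0..100$, one per label $v$ -- and
from them derives numeric feature encodings, compares how different rater
strata (clinicians vs laypeople) understand the same words, and benchmarks
the encodings against the classical rank/one-hot baselines in a nested
cross-validated regression harness.

## From intervals to fuzzy sets

Three fuzzification routes are exposed; all produce a `fuzzy_set` holding a
non-negative raw weight per grid value together with two normalizations:
*membership* $\mu_v(x) = w_v(x) / \max_y w_v(y)$ (the modal value has
membership 1) and *probability* $p_v(x) = w_v(x) / \sum_y w_v(y)$.

* **Representative points** (`fuzzify_from_points`): $w_v(x)$ counts how
  many respondents named $x$ as the RP of level $v$.
* **Interval centers** (`fuzzify_from_interval_centers`): each interval
  $[l_i, u_i]$ is reduced to its midpoint (for a single interval the
  centroid and the median coincide there), rounded half-up, and counted as
  a point.
* **Whole intervals** (`fuzzify_from_whole_intervals`): every grid value
  covered by $[l_i, u_i]$ receives weight $w_i = 1/(u_i - l_i + 1)$, so
  each interval deposits exactly one unit of evidence, spread thinly when
  the rater was vague. A degenerate interval $[x,x]$ is a unit point mass.

The resulting sets are deliberately *not* constrained to be fuzzy numbers:
no convexity, unimodality, or parametric shape is imposed, because elicited
opinion is frequently multimodal. The whole-interval route can be noisy on
the raw grid; `bin_fuzzy_set` coarsens it into consecutive bins of a chosen
width (bins are anchored at the smallest grid value, a bin is represented
by the arithmetic mean of its member values, and total mass is preserved;
the mean is unbiased for full bins and remains well defined for a short
last bin).

The max-normalization of membership is a deliberate choice the source
counts do not force: it guarantees that a level's own component in the
membership encoding below is exactly 1, which in turn makes the encoding
collapse *bit-exactly* to one-hot when supports are disjoint.

## From fuzzy sets to feature encodings

Let $V = \{v_1 < \dots < v_k\}$ be the scale and $\mu_v$ the fuzzy set of
level $v$.

**Centroid (CoIED).** Center-of-gravity defuzzification,
$$\mathrm{CoIED}(v) = \frac{\sum_{x} x\,\mu_v(x)}{\sum_{x} \mu_v(x)},$$
a scalar on the 0--100 scale. It is invariant to rescaling the weights, so
raw weights, membership, and probability give the same value.
`build_coied_map` also reports whether the map preserves the scale order;
an order-preserving map can stretch or shrink perceived distances but never
reverses the labels. CoIED values are intentionally *not* rescaled to
$[0,1]$: any standardization is a model-pipeline concern and is applied
per training fold inside the benchmark.

**Weighted sampling.** Each label occurrence is replaced by a draw from
$p_v$. Two granularities exist because elicited-semantics sampling can be
read either way: `per_cell` (the default) draws independently for every
occurrence, `per_label` draws once per level and reuses the value. The
default is `per_cell` because only independent draws can produce the
caveat this encoding is known for: when supports overlap, a single row can
receive values that reverse the label order even though the centroids are
ordered. Both modes are pure functions of `(column, sets, seed, mode)`.

**Membership vector.** The level's most representative value
$x_v = \arg\max_x \mu_v(x)$ (ties broken toward the smallest grid value --
the scale's "less severe" end -- purely for determinism) is mapped to
$\langle \mu_{v_1}(x_v), \dots, \mu_{v_k}(x_v) \rangle$. With pairwise
disjoint supports this is exactly the one-hot vector of $v$; with
overlapping supports the off-components quantify how much neighboring
labels also claim $x_v$.

**Baselines.** `baseline_encode` provides the integer rank ($v_i \mapsto
i-1$), one-hot, and rank-hot (staircase) encodings.

## Comparing rater strata

`compare_all_levels` runs, per level, a two-sided two-sample
Kolmogorov--Smirnov test (shape) and Mann--Whitney U test (mean rank)
between two strata, on one of three sample sources: pooled interval
extremes (each respondent contributes both endpoints), per-respondent
interval midpoints, or RPs. Raw p-values are reported without multiplicity
correction, matching how such per-level scans are conventionally read. The
Mann--Whitney p-value is exact for two untied samples of at most 8 values
and uses the tie-corrected normal approximation otherwise; with
integer-valued data ties are unavoidable, and the KS p-value is the
(conservative) asymptotic one.

A calibration subtlety worth knowing: the pooled-extremes source is *not*
an iid sample. Each respondent contributes the antithetic pair
$(c - h,\ c + h)$, whose half-width noise cancels within the pair, so
under the null the rank statistic is under-dispersed relative to the
exchangeability assumption and the test becomes conservative (in our null
simulations the fraction of p < 0.05 drops to about 0.01). On
per-respondent summaries (midpoints, RPs) the test is well calibrated
(observed fraction ≈ 0.05). Conservatism never invalidates reported
significances, but power comparisons across sources should keep this in
mind.

`qualitative_bin_summary` summarizes the inverse mapping (respondents name
the label best matching a number drawn from 1--99): values are binned at a
configurable width (the default width 3 partitions 1--99 into exactly 33
bins, anchored at 1), and each bin's label counts are classified by an
escalating prevalence scheme -- *superiority* (modal label, ties broken
toward the lower rank), *majority* (mode share > 0.5), *statistical
majority* (additionally, a 1-df $\chi^2$ goodness-of-fit of the top two
counts against equal expectation has p < 0.05). When a bin holds a single
label the second count is taken as 0; no continuity correction is applied.
These two choices are documented prominently because reasonable variants
exist; the classification is monotone by construction.

## The synthetic generators

Nothing in the package requires survey or patient data; three seeded
generators emulate the study designs the pipeline targets.

**Interval surveys** (`gen_interval_survey`). Per respondent and level:
center $\sim N(\text{level center}, \sigma_c)$, half-width $\sim
|N(m_h, \sigma_h)|$, interval = center ± half-width clipped to $[0,100]$
and rounded; the RP adds $N(0, \sigma_{rp})$ jitter to the center. The
shipped default profiles (`default_profiles()`, versioned in
`inst/extdata/default_profiles.yaml`) place doctor centers at
(9, 26, 47, 67, 88) and patient centers at (14, 26.5, 41, 58, 71) with
$\sigma_c = 5$, $m_h = 8$, $\sigma_h = 3$, $\sigma_{rp} = 4$: clinicians
anchor *Absent* lower and the severe end higher than laypeople, interval
half-widths sit near 8--10 grid units, and adjacent levels overlap. These
are an *emulation* of published stratum contrasts, not estimates of any
deposited dataset.

Clipping has a visible consequence: for a level center within one typical
half-width of a boundary, midpoints are biased away from the boundary
(analytically about 0.9 grid units for a center at 9 with mean half-width
8). Centroid recovery of the generating centers to within one grid unit
therefore holds for interior centers and is checked there; near-boundary
centers are recovered with a small inward bias that is a property of the
censored design, not of the estimator.

**Qualitative surveys** (`gen_qualitative_survey`). Values are uniform
integers on 1--99; the chosen label is sampled with probability
proportional to $\exp(-(x - c_v)^2 / 2\sigma_c^2)$, which degenerates to
the nearest-center label as $\sigma_c \to 0$.

**Outcome dataset** (`gen_outcome_dataset`). A 336-row, 15-feature
PROM-style prognostic table: gender, age, intervention type, 3 continuous
scores, and 9 ordinal items. Each ordinal item observes a latent severity
$z \sim N(50, 20)$ clipped to $[0,100]$ and records the label of the
cutpoint interval containing $z$; the continuous target is a linear
function of the *latent* severities (not the ranks) plus the other
features and $N(0, 1)$ noise. The default cutpoints (5, 15, 30, 80) are
strongly non-uniform -- a wide *Severe* band, as is plausible for items
administered to surgical candidates -- chosen so that the per-level
conditional means $E[z \mid \text{label}]$ are far from affine in the
rank. That is the regime the benchmark exists to probe: with uniform
cutpoints the rank encoding is essentially correct and no encoding can
beat it; early drafts with milder cutpoints produced conditional means
correlating > 0.99 with the ranks, which defeats the generator's purpose.
The coefficients (0.05 per latent unit, noise SD 1.0) make the ordinal
items carry the dominant share of explainable variance, since the
benchmark isolates ordinal-encoding effects.

What the generators deliberately do **not** emulate: respondent-level
"random filling" artifacts, item non-response, per-item idiosyncratic
semantics, or any distributional fingerprint of real deposited survey
data. Passing tests on this synthetic world show the machinery is correct
and the effects have the claimed directions under the stated model; they
do not certify effect sizes on real clinical data.

## The benchmark harness

`nested_cv_evaluate` scores one (model, encoding) pair: 5 outer folds give
unbiased MAE and $R^2$ (computed against each test fold's own mean); an
inner loop (default 3 folds) tunes hyperparameters by MAE. Models are
random forest (300 trees, default mtry, no inner tuning), k-nearest
neighbours ($k \in \{3,5,7,11\}$), LASSO ($\lambda$ on a log grid
$10^{-3}..10$), and RBF-kernel SVR ($C \in \{1,4,16\}$, $\gamma \in
\{2^{-7}, 2^{-5}, 2^{-3}\}$). Continuous and encoded features are
standardized inside each training fold for the distance- and penalty-based
models; the forest sees raw values. Confidence intervals are 95%
t-intervals over the outer-fold scores -- the simplest defensible reading
of "CIs from 5-fold nested cross-validation"; the fold-score vectors are
returned so a percentile bootstrap can be substituted. The stochastic
weighted-sampling encoding is re-encoded and re-evaluated 10 times
(distinct derived seeds, re-encoding *before* each repeat's CV run) and
fold scores are pooled. A constant training target degenerates every model
to the mean predictor; a constant *test* fold leaves $R^2$ undefined and
that fold is excluded from the $R^2$ interval with a warning.

**Order invariance of forests.** Regression trees threshold features, so
they see only the ordering of a feature's values. `rf_order_invariance_check`
verifies the consequence: a strictly increasing CoIED map grows the same
trees as the rank encoding (same seed, same folds) and the out-of-fold
predictions coincide, making the MAE difference exactly zero. One caveat
found while validating this: tree implementations place numeric thresholds
at *midpoints* of adjacent observed values, so when a level is locally
absent at a split, its navigation can differ between two maps unless the
map is affine in rank (integer-affine maps are also exact in floating
point). The check is therefore exact for rank-affine CoIED maps -- which
the pipeline produces under uniform perception -- and near-exact otherwise
(a handful of rows out of hundreds may route differently, moving MAE by
well under 1%). Non-monotone maps void the premise; the check declines to
run and returns `NA`.

## Numerical and interface choices

* Grid values are integers 0--100; non-integer inputs are rounded half-up
  (`floor(x + 0.5)`), the convention that keeps midpoints of
  integer-endpoint intervals deterministic.
* A representative point outside its own interval is kept (intervals and
  RPs are separate elicitations) but counted in the cleaning report.
  Cleaning is strictly mechanical -- every dropped row carries a named
  reason code, and no attempt is made to replicate judgmental
  "random-looking answer" removal, so the accounting is auditable.
  Duplicate (respondent, level) rows keep the first occurrence. Rows are
  kept regardless of whether the respondent completed every item.
* Fuzzy sets serialize to JSON as `(level, grid, raw_weight)` only;
  normalizations are recomputed on load so the two representations can
  never drift apart.
* All stochastic steps take explicit integer seeds and restore the
  caller's RNG state; the CV harness derives fold and fit seeds from the
  run seed so results are reproducible end to end.
* Simulation sizes used by the package's own checks (chosen to estimate
  each quantity to well within its assertion tolerance): 200 null and 100
  shifted replicates at 100--200 respondents per stratum for test
  calibration; 10 seeds at 1,000 respondents for center recovery; 10
  seeds of the 336-row outcome table for the encoding benchmark.

## Known limitations

* The benchmark addresses regression targets only; ordinal-target models
  (e.g. rank-ordered logit) and group-penalized handling of the
  vector-valued encodings are out of scope.
* Fuzzy sets are discrete by design; no parametric (triangular or
  trapezoidal) fitting is offered.
* The $\chi^2$ statistical-majority call in sparse bins rests on expected
  counts below 5; read it as a flag, not an inference.
* Centroid recovery near the 0/100 boundaries carries the censoring bias
  described above.
* The pooled-extremes comparison is conservative under the null (see
  above); per-respondent sources are the calibrated choice when false
  positive control at nominal level matters.
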