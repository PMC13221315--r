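---
title: "Methods: AHP and SWING priority weighting with synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AHP and SWING priority weighting with synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(washpriority)
```

# The model

`washpriority` implements a two-stage participatory weighting model for a
two-level decision hierarchy: top-level *domains* of service management
and, within each domain, operational *indicators*. The bundled default is
the school-sanitation O&M hierarchy of 6 domains and 33 indicators
(`default_hierarchy()`), but every function accepts an arbitrary
`hierarchy_spec`.

## Domain weights: the AHP eigenproblem

Each participant supplies a positive reciprocal matrix $A$ of pairwise
domain comparisons on Saaty's 1–9 scale. The weight vector is the
principal eigenvector $\omega$ of

$$ (A - \lambda_{max} I)\,\omega = 0, \qquad \sum_i \omega_i = 1 . $$

We solve this by **power iteration** with L1 renormalization: by
Perron–Frobenius the dominant eigenvalue of a positive matrix is simple
with a strictly positive eigenvector, so the iteration converges
geometrically at rate $|\lambda_2|/\lambda_1$; for an exactly consistent
matrix ($a_{ij} = w_i/w_j$, rank one) a single multiplication is exact.
Convergence is declared when successive iterates differ by less than
$10^{-12}$ in the max norm (cap: 10,000 iterations), and the returned pair
is additionally required to satisfy the residual bound
$\lVert A\omega - \lambda_{max}\omega\rVert / \lVert\omega\rVert \le 10^{-9}$;
otherwise an error reports the residual. A dense LAPACK eigen-decomposition
serves as an independent oracle in the test suite, never as the
implementation — the two routes agree to $10^{-8}$ across thousands of
random reciprocal matrices.

**Consistency.** $CI = (\lambda_{max} - n)/(n-1)$ (clamped at zero within
$10^{-9}$ of exact consistency) and $CR = CI / RI(n)$, with $RI$ the Saaty
random-index table for orders 1–15 hardcoded in `random_index()` and
overridable through the `ri` argument — alternative RI calibrations exist
in the literature, and none of the package's logic depends on the specific
table. $CR$ is defined as 0 for $n \le 2$, where reciprocal matrices are
always consistent. Screening retains judgments with $CR \le 0.1$
(`screen_judgments()`), the conventional acceptability threshold.

**Aggregation.** Retained matrices are combined by the element-wise
geometric mean (aggregation of individual judgments, AIJ), computed in log
space on the upper triangle and mirrored, so the aggregate is exactly
reciprocal by construction; the geometric mean is the only averaging rule
with that property. We aggregate *matrices first* and eigen-solve once —
not the mean of individual eigenvectors — because the judgment, not the
derived weight, is the elicited datum. Overall weights pool all retained
participants directly by default; `pooling = "groups"` instead aggregates
the per-group aggregates. The two coincide exactly when group sizes are
equal and no participant is rejected; we expose both because either
reading of "overall weights across all participants" is defensible.

## Local weights: SWING normalization

Within a domain of $k$ indicators, a participant assigns the most valued
improvement (the anchor swing) 100 points and scores the rest relative to
it. Local weights are

$$ \alpha_i = \frac{S_i}{\sum_{j=1}^{k} S_j}. $$

Across participants we **average the raw scores first and then
normalize** (`local_weights_all()`, the default), the stated procedure of
SWING practice; the alternative order (normalize each participant, then
average the weight vectors) is available via `order = "normalize_first"`.
The orders differ whenever participants spread different point totals: the
default implicitly weights participants by their total spread, the
alternative weights participants equally. Averaged scores are deliberately
*not* re-anchored to 100 — the mean of anchors need not be 100 and the
normalization is anchor-free.

SWING tables are **not** filtered by the AHP consistency status of the
same participant: CR is a property of pairwise matrices and has no SWING
analogue. Passing `couple_swing_to_cr = TRUE` to
`run_priority_analysis()` couples the two filters for sensitivity
analysis.

## Global composition, ranking, quartiles

Global weights are the products $g = d \times \alpha$, which sum to one
over the whole hierarchy because both factors are probability vectors.
Ranking (`rank_indicators()`) sorts by *unrounded* global weight with
exact ties broken by hierarchy position (a stable sort) — the bundled
reference model contains such a tie (W1.1 and W1.3, both 0.067) and the
positional rule reproduces its printed order deterministically. Quartiles
(`quartile_flags()`) are rank-based: ascending tie-broken rank $r$ of $m$
rows maps to quartile $\lceil 4r/m \rceil$, quartile 1 being the
least-weighted quarter. A value-based quartile would be ambiguous under
ties; the rank-based rule is the simplest deterministic definition.

Reporting rounds **half-up to 3 decimals** (`round_half_up()`), matching
how elicitation results are conventionally printed; base R's half-even
rounding would flip several third decimals. Rounding is display-only —
composition, ranking and quartiles always use unrounded values. On the
bundled reference model, recomposing rounded domain × rounded local
weights reproduces the published rounded global on 31 of 33 rows; the two
exceptions (W4.8, W5.2) differ by exactly 0.001 because the original
composition used unrounded intermediates. The test suite asserts exact
agreement on the 31 self-consistent rows and |difference| ≤ 0.001
everywhere.

## Uncertainty

**Bootstrap** (`bootstrap_domain_weights()`): participants are resampled
with replacement, the whole AIJ-plus-eigenvector computation is rerun per
replicate, and percentile intervals are read from the replicate
distribution. Defaults: $B = 10{,}000$, level 0.95. Resampling is
**stratified by stakeholder group** (7 draws per group under the default
design), preserving the elicitation design; `stratified = FALSE` pools.
The resampling unit is the *participant* — an entire comparison matrix —
never individual matrix entries, since judgments within a person are
dependent. Percentile rather than BCa intervals: the minimal-assumption
choice, adequate for the near-symmetric replicate distributions the AIJ
aggregate produces. Participants are internally sorted by (group, id), so
results are input-order invariant at a fixed seed; all randomness flows
from one seeded generator whose seed is recorded in the output.

**Group comparison** (`compare_groups()`): for each domain, the
Kruskal–Wallis rank test (tie-corrected $H$, $\chi^2$ approximation with
$df = \text{groups} - 1$) on *participant-level* eigenvector weights
grouped by stakeholder category. Individual weights rather than group
aggregates keep each group at its full sample size ($n = 7$ per group
under the default design — small, but a usable rank-test sample, whereas
group means would leave $n = 1$). When every pooled value is identical the
tie-correction denominator vanishes; $H$ is then 0 by definition (no rank
variation) and $p = 1$. Computation is delegated to
`stats::kruskal.test()`; an independent first-principles rank oracle
verifies it in the tests.

# The synthetic-elicitation generator

`generate_cohort()` simulates a stakeholder workshop with known ground
truth so that the full pipeline is testable end to end:

* **Pairwise matrices** — multiplicative log-normal noise around the
  consistent matrix of the true weights: for $i<j$,
  $a_{ij} = (w_i/w_j)\,e^{\varepsilon}$,
  $\varepsilon \sim N(0, \sigma_{ahp}^2)$, lower triangle mirrored. This
  is the standard AHP error model and respects reciprocity by
  construction. Optional snapping to the nearest Saaty value emulates a
  paper elicitation form; snapping is **off by default** because it biases
  ratios and would confound recovery analyses.
* **SWING tables** — noiseless scores invert the normalization,
  $S_i = 100\,\alpha_i/\max_j \alpha_j$; additive $N(0,\sigma_{swing}^2)$
  noise is applied, scores are clipped to stay in $(0, 100]$ (floored at
  1 point — SWING scores are elicited in whole points, and a vanishing
  score would be an elicitation artefact), and the table is rescaled so
  its maximum is exactly 100, the anchor every valid table carries.

**Default study conditions.** Five stakeholder groups (Regulators,
Researchers, Practitioners, Head Teachers, Sanitation Teachers) of 7
participants each; ground truth equal to the bundled reference model's
domain and local weights; $\sigma_{ahp} = 0.15$ and $\sigma_{swing} = 10$
points. The AHP noise level was chosen once as the moderate-disagreement
regime in which essentially every simulated judge still meets
$CR \le 0.1$ on a 6×6 matrix — matching a workshop in which all
participants passed screening (facilitated elicitation re-checks
inconsistent responses on the spot) while leaving visible between-judge
variation; 10 points is a plausible per-indicator scoring dispersion on a
0–100 scale. Per-group ground-truth overrides
(`group_truth_overrides`) allow simulating systematic between-group
divergence for power studies.

**What the generator does not emulate:** correlated biases within a
stakeholder group (beyond a shared truth override), order or fatigue
effects in elicitation, heaping on favourite scale values (unless
snapping is on), and missing responses. Passing tests on synthetic
cohorts therefore demonstrates the *computational* correctness and
statistical calibration of the pipeline under a clean error model, not
the behavioural realism of any workshop.

# Validation results computed by the suite

The test suite (and only it) establishes, at fixed seeds:

* zero-noise cohorts pass screening with zero rejections and the pipeline
  returns the configured truth — domain, local and global weights — to
  $10^{-9}$ end to end;
* at $\sigma_{ahp} = 0.15$, the median mean-absolute-error of recovered
  domain weights over 100 replicate cohorts is below 0.02, and the median
  MAE is non-decreasing in $\sigma \in \{0, 0.1, 0.3\}$;
* nominal 95% bootstrap intervals achieve empirical coverage inside
  (0.90, 0.99) over 200 simulated cohorts at $B = 500$, and degenerate
  identical-participant cohorts give zero-width intervals;
* the Kruskal–Wallis test holds its nominal size: null rejection rate at
  $\alpha = 0.05$ within (0.02, 0.08) over 2,000 simulations of 5 groups
  of 7.

Problem sizes in the suite (replicate counts, $B$, cohort counts) are the
smallest at which these checks are stable, chosen so the whole suite runs
in about a minute on one core.

# Numerical and degenerate-input conventions

* Reciprocity is validated at relative tolerance $10^{-9}$; the Saaty
  scale check admits relative tolerance $10^{-6}$ so decimal renderings
  of 1/3, 1/7, 1/9 in text files validate.
* Judgment files store the upper triangle authoritatively; lower-triangle
  records are accepted but must agree with the reciprocal of their mirror.
  Values are written with 15 significant digits (12 guaranteed).
* Weight vectors must sum to 1 within $10^{-9}$; aggregated matrices are
  exempt from the Saaty scale restriction (their entries are geometric
  means).
* Empty inputs: screening an empty cohort returns empty sets; an empty
  judgment file reads as an empty list; a group losing all members in
  screening is dropped from per-group outputs with a warning naming it;
  an all-rejected cohort aborts the pipeline with a clear message.
* `cohort_config(seed = s)` makes cohorts bit-reproducible; the bootstrap
  and the pipeline take independent seeds and restore the caller's RNG
  state.

# Known limitations

* The bundled random-index table stops at order 15; larger hierarchies
  need a user-supplied RI vector.
* No inconsistency repair or judgment-revision suggestions; re-elicitation
  is a human process.
* No fuzzy-AHP, ANP, interval-judgment or missing-data extensions; SWING
  scores cannot be imputed.
* The published confidence intervals of the reference study depend on its
  raw workshop judgments and unstated resampling scheme; the package makes
  no attempt to reproduce them bit-for-bit, and its bootstrap is validated
  by coverage simulation instead.
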