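---
title: "Methods: correspondence-analysis association mapping of fecal acid profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correspondence-analysis association mapping of fecal acid profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdscfa)
```

## The problem and the model

Small IBD cohorts mix a handful of continuous laboratory measurements
(fecal organic-acid concentrations in µg/g dry mass, age, BMI) with many
categorical covariates (diagnosis group, diet type, food-frequency
categories, medication flags). `ibdscfa` analyses such tables by reducing
everything to categories and ordinating the resulting indicator matrix by
correspondence analysis (CA). The association structure is then read off
the plane of the first two dimensions.

**Encoding.** Each continuous parameter is dichotomized at its cohort
median (`median_split()`): a subject is `above` only if strictly above,
so ties go `under` (configurable). Each categorical parameter contributes
one 0/1 column per observed level; unobserved levels are dropped and
recorded in the scheme. A subject missing a parameter keeps all-zero
cells there rather than being imputed — its row simply carries less mass.
The result is a subjects × levels indicator matrix, the multiple-CA
variant of the method; `burt_table()` exposes the levels × levels
cross-tabulation, whose CA has identical standard coordinates with
squared singular values (asserted in the test suite).

**Correspondence analysis.** `fit_ca()` follows the textbook algebra:
with correspondence matrix $P$, masses $r, c$, the standardized residuals
$S_{ij} = (P_{ij} - r_i c_j)/\sqrt{r_i c_j}$ are decomposed by SVD;
principal inertias are $\lambda_k = \sigma_k^2$ with
$\sum_k \lambda_k = \chi^2/n$, and column principal coordinates are
$c_j^{-1/2} v_{jk} \sigma_k$. The quality of representation of a level in
a subset of dimensions (its $\cos^2$) is the share of its squared
chi-distance to the centroid captured by those dimensions.

## Numerical choices

* Dimensions are retained down to a relative singular-value tolerance of
  `max(dim) * .Machine$double.eps`; algebraic identities (inertia vs
  $\chi^2/n$, reconstruction of $P$) are tested at `1e-10`, transition
  formulas at `1e-8`.
* Sign convention: each singular-vector pair is flipped so that the
  largest-magnitude column loading is positive, making coordinates
  reproducible across BLAS implementations.
* Exact independence (zero total inertia) yields a model with no usable
  dimensions; the explained-inertia share is defined as 1 there.
* A level coinciding with the centroid has undefined $\cos^2$; it is
  reported as 0 with an `at_centroid` flag.
* Zero-mass rows or columns are an error in `fit_ca()`; the encoder never
  produces them (empty levels are dropped at encoding time).

## The inertia-share convention for the stopping rule

The discard loop (`select_model()`) refits the CA repeatedly, each time
removing the parameter whose levels are worst represented in the first
two dimensions, and stops when that plane explains at least half of the
total inertia. "Share of total inertia" has three established dialects
for indicator input, and the choice matters a great deal:

* **`indicator`** — raw shares $\sum_{k\le 2}\lambda_k / \sum_k\lambda_k$.
  For $Q$ encoded parameters the total inertia is fixed at $(J-Q)/Q$
  regardless of the association structure, so raw two-dimensional shares
  rarely exceed ~0.2 for $Q$ beyond a handful: the loop must prune almost
  everything before the criterion can be met.
* **`burt`** — shares of $\lambda_k^2$, what a CA of the Burt table
  reports.
* **`benzecri`** (default) — Benzécri-adjusted shares
  $\big((Q/(Q-1))(\lambda_k - 1/Q)\big)^2$ over dimensions with
  $\lambda_k > 1/Q$. Dimensions at the $1/Q$ "chance" floor carry no
  adjusted inertia; this is the convention in which classic MCA software
  prints its percentages, and the only one under which a model retaining
  ~17 parameters (≈38 levels) can legitimately report its first plane
  above 50% — which is the regime in which published analyses of this
  kind, plotting all retained levels on one numbered map, operate.

The adjusted convention is therefore the default for the stopping rule;
`inertia_explained()` itself defaults to the raw share, and both
alternatives are one argument away. Parameter-level quality is aggregated
from level-wise $\cos^2$ as the column-mass-weighted mean (mass-weighting
matches the CA geometry, where inertia contributions are mass ×
squared distance); a max-of-levels aggregate is available. Ties discard
the later parameter in encoding order; one parameter is removed per
iteration; the loop stops, flagged, at `min_params = 4`, below which a
two-dimensional map is degenerate.

## Association weights

Levels qualify for pairing when either of their first two principal
coordinates exceeds 0.3 in absolute value (strict, per-dimension — not
the vector norm). For two qualifying points the signed weight is
$w = \lVert p_A\rVert\,\lVert p_B\rVert\cos\theta$, the planar dot
product. This reading — rather than any $\cos^2$ variant — is the one
that can be negative, matching the inverse relationships such a weight
must express, and on principal coordinates of binary levels its
magnitude lands on the 0.8–1.4 scale typical of reported tables. A
per-dimension variant (coordinate products each multiplied by
$\cos\theta$) sits behind `method = "per_dimension"`. Pairs of levels of
the same parameter are excluded: complementary levels oppose each other
by construction. Coordinates are taken from dimensions 1–2 only,
matching the plotted plane. No significance is attached to a weight; it
is a descriptive effect-size on the ordination.

## Contingency statistics

Odds ratios use the cross-product with the Haldane–Anscombe +0.5
correction applied (and flagged) only when a zero cell is present.
Confidence intervals are Woolf (log-normal): this method exactly
reproduces both fully recoverable published interval pairs at three
decimals, which conditional-exact intervals do not. P-values are Fisher
exact with the minimum-likelihood two-sided rule (the convention of the
common 2×2 web calculators; `stats::fisher.test` is the independent
cross-check in the tests), with the Woolf z-test p reported alongside.
`recover_table()` scans all integer tables on given row margins for
those reproducing a printed OR and CI at three decimals — two published
contrasts are uniquely recoverable this way; the two FFQ-based ones admit
no consistent table on full margins (consistent with item non-response)
and are reported as non-recoverable.

## The synthetic cohort generator

`generate_cohort()` emulates the study's structure: groups of 43/18/16
(ulcerative colitis, Crohn disease, controls); per-group truncated
log-normal BMI with medians 21.6/20.2/21.6 kg/m² and log-SDs
0.18/0.16/0.15 chosen to match the published per-group ranges
(13.8–37.1 kg/m² overall); ages with medians 32/30/23.5 years; sex,
medication and diet-type marginals taken from the published group
characteristics (e.g. standard diet in 16/43 UC and 11/16 control
subjects); and log-normal acid concentrations whose medians default to
the reported cohort medians (acetic 1135.3, propionic 381.2, butyric
215.0, isobutyric 43.0, valeric 5.52, isovaleric 46.3, phosphoric
837.6 µg/g). The shared acid log-SD of 0.6 reflects the 2–3-fold
interquartile spread typical of fecal SCFA measurements.

Planted effects are multiplicative on the acid draws by BMI category;
the default plant halves butyric, propionic and isovaleric in
underweight subjects and doubles isobutyric in excessive-weight
subjects. Because the analysis is median-split-based, medians — not
means — are held fixed: the baseline median of a planted acid is
adjusted analytically (`uniroot` on the mixture CDF over the
analytically computed BMI-category probabilities) so the cohort-wide
median still equals the configured value. Optional dependencies can tie
medication probabilities to BMI category (e.g. more steroid use among
underweight subjects); they are off by default so the all-factors-one
configuration is an exact independence null.

What the generator does **not** emulate: the real joint distribution of
diet, medication and disease activity (only marginals plus optional
one-way tweaks); measurement censoring at the quantification limit
(values are drawn uncensored; `censor_concentration()` applies LOQ/LOD
flags, with half-LOD substitution below the detection limit, as a
separate explicit step); and any group→acid effects beyond the
BMI-category plants. Passing recovery tests on these cohorts therefore
demonstrates that the pipeline detects the planted kind of structure at
realistic noise — not that every association it reports on real data is
causal or even stable: with ~38 levels on the plane, rare levels (a
few subjects) sit far from the centroid and can produce large chance
weights. The weight's rank among all pairs, not its mere presence above
the coordinate cutoff, is the robust readout; the test suite asserts
exactly that rank property on cohorts with a planted binary pair.

## Problem sizes in the tests

The suite exercises the CA algebra on ~1000 random count tables of 3–7
rows/columns, the discard loop on 100 simulated 12-parameter cohorts of
77 subjects, the end-to-end association recovery on 2 × 200 simulated
cohorts (default plant and null), and the weight algebra on 10⁴ random
point pairs; generator calibration checks use cohorts of ~1000–2000
subjects. These sizes make the whole suite run in a few minutes while
keeping Monte-Carlo standard errors on the measured rates near 2–3
percentage points.

## Known limitations

* At 77 subjects with ~20%-prevalence BMI categories, a twofold
  multiplicative plant on a log-normal acid (≈1.15 log-SD) yields
  per-pair detection rates in the 70–90% range — single-cohort
  association maps of this kind are reconnaissance, not confirmation.
* The stopping rule's inertia convention changes how much is pruned;
  results should be reported together with the convention used (the
  selection trace records it).
* Median splits discard within-half information by design; no ordinal
  scale beyond two categories is offered for continuous parameters.
* Fisher's exact two-sided p has several conventions; both
  minimum-likelihood and tail-doubling are implemented, defaulting to
  the former.
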