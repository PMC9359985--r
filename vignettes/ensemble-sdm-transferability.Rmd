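---
title: "Ensemble distribution models and spatial transferability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble distribution models and spatial transferability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`sdmtransfer` implements a presence–background species distribution
modeling (SDM) workflow built around three questions: how suitable is each
cell of a landscape for a species, how much does an ensemble of dissimilar
algorithms improve over any single one, and how far do models calibrated in
one geographic region transfer to neighboring regions they have never seen.
Because the survey data that motivate this class of analysis are typically
access-restricted, the package ships a virtual-species generator with a
known truth surface, so every claim the workflow makes can be checked
against ground truth rather than taken on faith.

## The modeling problem

The data are presence-only: coordinates where the species was recorded,
with no usable absences. The standard device is to contrast presences with
*background* (pseudo-absence) points drawn uniformly from the study domain
— by default 10,000 of them — and to give the two classes equal total
weight (prevalence 0.5): presences weigh 1 each and background rows weigh
`n_presence / n_background` each. With equal class totals, a model with no
information predicts 0.5 everywhere, which makes scores comparable across
designs of different sizes.

Before modeling, occurrences are thinned to at most one point per 1-km
grid cell (the covariate resolution), reducing spatial pseudo-replication
from clustered survey effort. A stricter minimum-distance filter (one
point per 5 km, greedy and seeded) is available; the pipeline can fit both
data sets and report the Pearson correlation between the two resulting
suitability maps, which is the practical test of whether residual spatial
autocorrelation changes the answer.

## Base algorithms

Four algorithms are implemented natively, chosen to span the main model
families used in ensemble SDM platforms:

* **GLM** — weighted-likelihood logistic regression fit by iteratively
  reweighted least squares, with linear plus quadratic terms per covariate
  by default. Quadratic terms let suitability peak at intermediate covariate
  values (snowfall is the canonical case). Step-halving guards the IRLS
  iterations, and quasi-separation is flagged when the linear predictor
  exceeds ±25.
* **SRE** (surface range envelope / BIOCLIM) — a site is suitable iff every
  covariate lies within the central `[alpha, 1 - alpha]` quantile interval
  of the presence values; `alpha = 0.025` by default. Quantiles use the
  linear-interpolation rule (R type 7), fixed so envelopes are reproducible.
* **CTA** — a classification tree grown by exact weighted-Gini
  minimization. Every (variable, midpoint) split is scanned; ties go to the
  lowest variable index, then the lowest split value, so fits are
  deterministic without randomness. Defaults: depth 5, minimum leaf weight 1.
* **GBM** — stagewise gradient boosting of depth-2 regression trees on the
  Bernoulli deviance gradient, with Newton leaf steps shrunk by a 0.1
  learning rate, 500 stages, no early stopping. Small, deterministic, and
  adequate for landscapes at this scale; the per-stage training deviance is
  recorded and is non-increasing.

Further algorithms (random forest, GAM, MaxEnt, FDA, ...) join through
`sdm_adapter()`, a two-function contract (`fit`, `predict` into [0, 1]);
their internals are deliberately out of scope.

## Evaluation and the ensemble

Internal skill is estimated by three repeated stratified random 80/20
splits. Three *repeated splits* — not a 3-fold partition — because an 80/20
ratio is incompatible with a partition into three folds; this matches the
`NbRunEval` semantics of the biomod2 platform this workflow follows.

Discrimination is measured by AUC (computed from midranks, which equals the
pairwise probability definition with ties counted ½ exactly), and by
sensitivity, specificity and TSS at the threshold that maximizes
sensitivity + specificity over the set of unique observed scores.
Presences are classified at `score >= tau` (inclusive), so a threshold
equal to the maximum presence score still classifies that presence
correctly; threshold ties resolve to the smallest candidate.

Every (algorithm × CV run) fit is an ensemble member. Member weights are
proportional to evaluation-set skill above the no-skill floor —
`max(ROC - 0.5, 0)` by default (TSS above 0 as the alternative) — so
near-random members get near-zero weight rather than half weight. The
ensemble's own threshold is re-optimized on the ensemble's scores over the
full design, not averaged from member thresholds. The committee map
binarizes each member at its own threshold and stores the fraction of
members voting "present": an uncertainty surface whose extremes mean
unanimity. Internal ensemble skill is reported as the mean over runs of the
run-level ensemble's evaluation-set metrics; this keeps evaluation data out
of the weights being evaluated within each run.

Variable importance is permutation-based: a covariate's column is permuted
(5 repetitions by default) and importance is the mean of
`1 - cor(original, permuted predictions)`, clamped at zero — a model that
ignores a covariate scores exactly 0. Values are reported raw (not
normalized per model). Response curves vary one covariate over its observed
range with the others held at their calibration medians — the median rather
than the mean because the distance covariates are strongly right-skewed.

## Variable screening

Ecological covariate sets are collinear. The screening step computes the
Pearson correlation matrix over jointly valid cells, enumerates every
variable subset containing no pair with `|r| >= 0.7` (the common SDM
convention; the threshold is configurable since no universal cutoff
exists), and ranks the admissible sets by cross-validated ROC of a logistic
screening model, ties broken by sensitivity and then by smaller set size.
Screening with the GLM only, rather than the full ensemble, keeps the
all-subsets scan affordable; full-ensemble screening of each subset is a
deliberate non-default because its cost grows as
(algorithms × runs × subsets).

## Transferability schemes

The domain is partitioned into regions (three vertical bands in the
synthetic landscape, emulating a three-state study area). Regions are first
balanced by downsampling every region's presences to the smallest region's
count, so no region dominates by sample size alone. Two schemes are then run
for every focal region:

* **cross-validation**: presences from the focal region, background from
  the whole domain;
* **extrapolation**: presences *and* background restricted to the focal
  region, after which the fitted model predicts the entire domain.

Each run is validated against the other regions' presences. Validation
needs absences too; the package draws one fresh domain-wide background
sample, shared across all runs, so validation ROCs are comparable between
runs (what served as validation absences is an open choice in this class of
study; sharing one sample is the least-variance option and is
configurable). Validation sensitivity uses each run's own optimized
threshold, since it is a property of that run's calibration.

Maps are compared to the regional model with Spearman rank correlation over
all jointly valid cells (no subsampling — grids at this scale make that
cheap) and with the niche-overlap indices Schoener's D
(`1 - 0.5 * sum |p1 - p2|`) and Hellinger-based I
(`1 - 0.5 * sum (sqrt(p1) - sqrt(p2))^2`), both computed after normalizing
each map to sum to 1 over the joint support; both run from 0 (no overlap)
to 1 (identical distributions) and are invariant to positive rescaling of
either map. No ordering between D and I is assumed or asserted — neither
dominates the other in general.

## The virtual landscape

`generate_landscape()` builds a 240 × 360 grid of 1-km cells (desk-scale,
the same order as a three-state region at 1-km resolution after
downscaling). Covariate fields are separable moving-average smoothings of
seeded uniform noise (half-width 10 cells, giving ~20-km patches) plus
deterministic north–south gradients: spatial autocorrelation without
heavyweight geostatistics. Crops occupy the 30% of cells with the lowest
latent natural-cover values (so crops and natural cover are negatively
associated by construction), developed land the top 7% of an independent
field — fractions chosen to echo a heavily cultivated, lightly developed
region. The distance covariates are exact Euclidean distance transforms of
those masks, computed with the two-pass separable parabola algorithm and
tested cell-for-cell against a brute-force scan.

True suitability is exactly
`plogis(b0 + b1*natural + b2*log1p(dist_crops) + b3*road + b4*snow + b5*snow^2)`
with defaults `(-4, 3.5, 1.0, -0.6, 1.0, -0.2)`. The log1p transform makes
the crops response saturate within a few km; the quadratic snow term peaks
at 2.5 m; `dist_developed` is generated but carries no effect, serving as a
built-in nuisance covariate. The coefficient magnitudes were set so the two
dominant covariates are natural cover and distance to crops — the structure
the workflow is meant to recover — with road and snow as secondary effects.
Presences are 500 cells drawn without replacement with probability
proportional to truth, one jittered point per cell (finer-than-cell
structure would be erased by the 1-km thinning anyway).

Three presets define the study conditions: `homogeneous` (same process
everywhere, overlapping covariate ranges across regions),
`range_truncated` (region 1 additionally receives crops on a 4-cell
lattice, so its distance-to-crops range is truncated — models calibrated
there never see large distances and must extrapolate beyond their
calibration range), and `null` (all slopes zero, for verifying that
fitted skill stays at chance).

What the generator does **not** emulate: survey-effort heterogeneity
(beyond an optional bias mask), detection error, territoriality or any
movement process, temporal structure, and real covariate cross-correlation
patterns. Passing tests on this landscape therefore demonstrate that the
machinery recovers a known smooth logistic truth under clean sampling — not
that any particular field data set satisfies those assumptions.

## Numerical choices and degenerate inputs

* Point-to-cell assignment uses half-open intervals from the lower-left
  origin; files store rows north-first and are converted on read.
* Aggregation drops trailing partial blocks (undersized blocks would bias
  proportions); the origin shifts north accordingly.
* Zero-variance covariates: excluded from the GLM (no coefficient);
  flagged `NA` in correlation matrices (never silently 0); constant maps
  make map correlations `NA` with a warning.
* All-zero suitability maps make the overlap indices error rather than
  return a value.
* The background sampler draws cells with replacement by default (plain
  "n random points" semantics); a no-duplicate-cell policy is a flag and
  errors when `n` exceeds the available cells. Whether background may fall
  on presence cells is likewise left permissive by default.
* Every stochastic step takes an explicit seed; pipeline stage seeds are
  derived from one master seed, and the run manifest records the seeds and
  an MD5 hash of every artifact, making reruns byte-comparable.

## Problem sizes

The shipped analyses and checks use the generator's study conditions: the
240 × 360 landscape, 500 presences, 10,000 background points, 3-run 80/20
cross-validation, 500-stage GBM. The test suite exercises the same code on
smaller landscapes (60 × 90, ~1,500 background) where an identity is being
checked rather than a simulation property, and at the full sizes where the
property is about recovery or transfer (suitability recovery, scheme
overlap, range-truncation direction over five replicate landscapes).

## Known limitations

* The four native algorithms are deliberately compact reference
  implementations; they are not tuned competitors to mature libraries, and
  the ensemble reaches the full eight-algorithm roster only through
  adapters.
* Extrapolation behavior of the quadratic GLM outside the calibration range
  is polynomial and can be aggressive; the SRE member clamps to {0, 1}.
  This heterogeneity is intentional — it is what the transferability
  assessment measures — but it means single-member maps should not be
  interpreted in isolation.
* Maps are in-memory matrices; the package targets desk-scale rasters
  (millions of cells), not tiled continental products.
* ASCII grids are the only raster interchange format; they are exact and
  text-based but bulky for very large grids.
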