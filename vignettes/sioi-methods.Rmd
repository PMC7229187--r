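---
title: "Methods: spatial immune profiling and the SIOI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial immune profiling and the SIOI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
procedures it implements, the assumptions behind them, the tunable
parameters and their defaults, what the synthetic-cohort generator does
and does not emulate, and the numerical and design choices made where the
underlying protocol left the choice open.

## The profiling model

Cells enter the pipeline as centroids in micrometres (image convention:
origin top-left, y increasing downward; all statistics are Euclidean
distances and areas, so the convention is inert) with per-compartment dye
intensities on two serial slides. Slide 1 carries CD3 (FITC), CD8 (Cy5)
and pancytokeratin (PCK, Cy3); slide 2 carries CD68 (FITC), CD163 (Cy5)
and PCK.

**Phenotyping.** A channel is called positive from its nucleus /
cytoplasm / membrane exceedances of fixed thresholds — lymphocyte slide
nucleus FITC 0.15, Cy5 0.132; macrophage slide nucleus FITC 0.200, Cy5
0.132; cytoplasm 0.5 (FITC) and 0.075 (Cy5); membrane 0.5 and 0.075.
The source protocol lists the three compartment thresholds but not how
they combine into a channel call (that logic lives inside the commercial
image-analysis software), so the combination rule is a configurable
parameter (`positivity_rule`): the default `"any"` (any compartment
strictly exceeds its threshold) is the most permissive documented choice,
with `"nucleus"` and `"cyto_and_membrane"` as alternatives. This default
is a documented package decision, not a claim about the original
software's rule. All comparisons are strict, so a value exactly at a
threshold is negative — a deterministic tie rule whose probability-zero
boundary makes it harmless. Colocalization (both channels positive)
defines CD3⁺CD8⁺ and CD68⁺CD163⁺ cells; double positives count toward
both single-marker reporting totals, and CD68⁺CD163⁻ is its own
reporting class. Tumor cells are PCK⁺ cells (per-cell CY3 threshold 0.1,
pipeline plumbing: the original workflow segments tumor at the pixel
level, which is out of scope here). The slide-level mean PCK intensity is
dichotomized at 2.16 × 10⁻² and logged; in the original workflow the
category selects between two pixel classifiers, so here it is reported
but drives nothing.

**Regions.** The invasive margin (IM) is the symmetric band within
500 μm of the invasive-front polyline ("in and out" of the front),
clipped to the tissue extent; the tumor core (CT) is the tumor polygon
minus the IM; IMCT is their union; and the TBROI is the tumor ∩
1000-μm-buffer of the front — intersecting with the tumor polygon
enforces "inward" without needing an oriented polyline. Whether the outer
IM band should be clipped to tissue or to the scanned area is not
specified by the protocol; the clipping extent is a parameter
(`extent_bbox`), defaulting to the tumor bounding box expanded by the
band width. No polygon-boolean geometry library is required: regions are
represented implicitly by membership predicates (boundary-inclusive
ray-casting point-in-polygon plus distance-to-polyline), the tumor area
is the exact shoelace value, and band areas are computed by two-level
grid quadrature — interior 50-μm cells at full weight, boundary cells
refined with 5-μm cell-centre samples. The quadrature error is a fraction
of the fine pitch along the boundary, far below the 0.5% at which the
analytic test cases are checked; regions thinner than the coarse pitch
could in principle slip between corner samples, but the package's bands
are 500–1000 μm wide. CT's area is defined as tumor minus IM-within-
tumor, so the additivity identity area(IM ∩ tumor) + area(CT) =
area(tumor) holds exactly rather than to quadrature error. Boundary
points count as inside every region they bound, keeping density
denominators stable.

**Tumor buds.** Buds are connected clusters of at most four tumor cells.
The clustering rule of the original software is unpublished, so the
package uses the minimal reproducible surrogate: single-linkage
connected components at a fixed link distance, default 15 μm (about one
nucleus diameter plus margin), exposed as `bud_link_um`. Clustering runs
over *all* tumor cells so that cells contiguous with the main tumor mass
join large components and are never miscounted as buds; a component is a
bud iff its size is ≤ 4 *and its centroid* lies in the TBROI (a single
deterministic criterion, rather than requiring every member inside). The
implementation bins cells on a grid of the link distance and unions
neighbouring bins; the test suite proves it identical to dense
single-linkage clustering.

**Coregistration.** Serial 3-μm sections are related by a near-rigid
map, so the model is a similarity transform (scaled rotation plus
translation), estimated in closed form by orthogonal Procrustes with
scale on landmark pairs; a landmark-free ICP refinement on PCK⁺
centroids is available when no fiducials exist. ICP alternates
nearest-neighbour matching with the closed-form re-fit, never accepts a
step that increases the matched-pair RMSE, and reports its final residual
honestly — with a grossly wrong initialisation on sparse clouds it can
converge to a wrong optimum, which the residual exposes. Whether the
original registration was rigid or deformable is unstated; results here
are interpreted under the similarity assumption.

**Features.** The catalog is the closed set implied by the protocol: 6
marker classes × 3 regions densities (cells/mm²), the TB count,
CD68⁺/CD163⁺ ratios in 3 regions, 3 macrophage classes × 3 targets (TB,
CD3⁺, CD8⁺) × 2 radii (0–50, 0–100 μm) proximity means, and 3 lymphocyte
classes within 0–50 μm of TBs — 43 named features. The published count
of 69 image-based features is not enumerated anywhere in the source, so
the realized catalog length is logged rather than forced. Proximity
features are *means per target* (matching "the average number of
lymphocytes within 50 μm of TB"), with the radius boundary inclusive.
Undefined quantities are explicit: a zero-area region yields a missing
density, not 0; a CD68⁺/CD163⁺ ratio with an empty denominator is +∞
(the ratio-high side of any finite cutoff) and 0/0 is missing.

**Zero-bud policy.** A patient with no detected buds has no bud-proximity
features. The protocol never defines this case. The default policy
(`zero_bud_policy = "favorable"`) assigns such patients the favorable
flag at binarization, because absent budding is the prognostically good
state; `"missing"` (exclude) and `"zero"` are alternatives, and the
choice is logged prominently in every report.

## The selection chain and the index

Features are z-scored before the LASSO (penalty fairness across scales)
while cutpoints are computed on the raw scale (so cutoffs keep physical
units, e.g. cells/mm²). The chain is:

1. **LASSO Cox** (`glmnet`), λ by 10-fold cross-validated partial-
   likelihood deviance at the minimum; the one-standard-error rule is
   selectable (`lambda_rule`), as the original choice is unstated.
   Constant columns are dropped with a warning; non-finite values are
   median-imputed, and both actions are recorded in the trace.
2. **Random forest** (500 trees) classifying the binary disease-specific
   death label, features ranked by mean decrease Gini; the out-of-bag
   error is recorded. A classification forest is used because the
   published importance table is classification-style mean decrease
   Gini, which a survival forest would not produce; how censoring was
   encoded in the label is unstated, so the label is death over the full
   follow-up by default, with the censoring horizon configurable.
3. **Gini filter** at strictly > 3.
4. **Correlation pruning**: greedy in decreasing Gini order, keeping a
   feature iff its |Spearman r| with every kept feature is below
   `correlation_prune_threshold`. The "highly correlated" threshold is
   unstated in the source; the package default is 0.8, and the tests
   prove the greedy walk equals the rule's defining fixed point.
5. **Cutpoints** by the maximally selected standardized log-rank
   statistic over midpoints of sorted distinct values, both groups
   ≥ `cutpoint_min_group_prop` (default 0.1, the survminer convention) of
   the cohort; ties in |z| go to the smallest cutoff; the favorable side
   is the one with fewer deaths than expected. The scan uses the
   package's own O(n log n) hypergeometric log-rank statistic and is
   tested for exact equality against an exhaustive `survdiff` scan.
6. **Iterative refinement**: "removal until it negatively affects the
   model's prognostic value" is operationalized as — fit a univariate Cox
   model to the ordinal favorable count; tentatively remove the
   component with the largest own univariate Cox p; commit iff the
   index's Wald p does not increase (likelihood-ratio χ² selectable via
   `refine_criterion`). The criterion was never defined by the source;
   both the choice and the full step-by-step trace are exposed.

Binarization is strict ("above"/"below" the cutoff; equality, including
values within 1e-9 relative of the cutoff to absorb floating-point
round-off in derived ratios, is unfavorable). With k components (k = 3
in the published index), all-favorable patients form the low-risk
"+/+/+" tier, exactly one unfavorable "+/+/−", and the rest
"+/−/− or −/−/−"; the 2-tier split is low-risk iff all favorable. Cox
models use Efron tie handling (the standard default of the era's survival
software); monotone likelihood (e.g. a tier with no deaths) is flagged
rather than reported as a huge finite hazard ratio.

In batch use, `run_pipeline()` applies two logged fallbacks so a
low-event draw cannot kill a run: an empty LASSO selection passes the
full catalog to the forest, and a Gini filter that leaves fewer than
`min_components` (default 3) candidates keeps the top-k by Gini. The
operations themselves (`lasso_cox_select()`, `gini_filter()`) return the
strict results.

## The synthetic-cohort generator

The generator emulates the structures the pipeline consumes, with
defaults fixed once as the package's reference study conditions:

- 1.5 × 1.5 mm tissue, sinusoidal invasive front (amplitude 100 μm,
  period 750 μm, depth 400 μm); tumor occupies the deep side.
- Immune classes as homogeneous Poisson processes over the whole tissue
  (both sides of the front), with disjoint-class rates (cells/mm²):
  CD3⁺CD8⁻ 220, CD3⁻CD8⁺ 90, CD3⁺CD8⁺ 150, CD68⁺CD163⁻ 80, CD163⁺CD68⁻
  90, CD68⁺CD163⁺ 50 — chosen so the reporting-class medians sit near
  the published cutoffs (median CD3⁺ IMCT density ≈ 400 cells/mm² vs the
  389.6 cutoff; CD68⁺/CD163⁺ CT ratio median ≈ 0.95 vs 1.096).
- The tumor mass as dense uniform nests (8 nests/mm², radius 60 μm,
  overall 1200 tumor cells/mm²): within-nest density is high enough that
  nests are internally connected at the 15-μm link distance, so small
  components away from nests are genuine planted buds, not sampling
  artefacts of a loose cluster process.
- Planted buds: Poisson count (mean 12) of clusters of 1–4 cells
  (probabilities 0.35/0.30/0.20/0.15) in a 6-μm-radius disc, placed in
  the TBROI with ≥ 60 μm clearance from all other tumor cells — so
  internal spacing is below, and separation above, the link distance,
  making exact bud recovery a testable invariant.
- Lymphocyte–bud attraction: per bud, Poisson extras of each lymphocyte
  class uniform in the 50-μm disc (means 1.0 / 0.5 / 2.5 for
  CD3⁺CD8⁻ / CD3⁻CD8⁺ / CD3⁺CD8⁺, putting the CD3⁺CD8⁺-near-TB mean
  ≈ 3.5 against the 4.1 cutoff); with the attraction at 0 the mean count
  within 50 μm of buds equals the CSR expectation λπr²/10⁶, which the
  tests check.
- Slide 2 holds the macrophages plus the tumor pattern jittered by
  1.5 μm (serial-section decorrelation), mapped through a random
  similarity transform (rotation SD 2°, translation SD 150 μm, scale SD
  1%); the transform and four corner fiducials are recorded so
  coregistration is testable against ground truth.
- Intensities are drawn a margin (0.1) above the thresholds for carried
  markers and below for absent ones, plus truncated Gaussian noise
  (SD 0.02): at zero noise classification inverts exactly; the
  recovery error is non-decreasing in the noise.
- Survival is exponential: h(t) = h0·exp(βᵀz + β_pT·pT4) with h0 =
  0.0012/month over an 11.8-year horizon (≈ 15% disease-specific deaths,
  matching the reported training-cohort event rate), z the cohort-
  standardized true features (so β is a log-HR per SD regardless of
  density scales), planted β = (−0.65, −0.60, +0.55) on CD3⁺ IMCT
  density, CD3⁺CD8⁺ near TB, and the CD68⁺/CD163⁺ CT ratio — protective,
  protective, hazardous — plus a pT4 effect (prevalence 0.23, log-HR
  0.6) and 15% independent uniform censoring. Per-patient log-normal
  multipliers (SD 0.5 on lymphocyte rates, 0.45 on the CD68/CD163 tilt,
  0.8 on attraction) carry the between-patient heterogeneity the index
  must detect.

A feature-level generator (`generate_feature_cohort()`) draws the three
index features and independent noise features directly with realistic
marginals and the same exponential survival model. The selection-chain
and index-recovery test batteries use it because their conditions are
feature-level (planted log-HRs per SD among noise features) and the
spatial machinery is already tested on its own; the baseline hazard
there (0.004/month over 120 months, ≈ 35–40% events) is chosen to give
the selection stages adequate event counts, as a screening study would
require.

What the generator does **not** emulate: raw pixel images and
segmentation error, intensity spillover/autofluorescence between
channels, spatially correlated immune infiltration gradients beyond
bud attraction, correlated clinicopathological covariates, and
non-proportional hazards. Passing tests therefore demonstrate that the
pipeline's computations are correct and that the chain recovers planted
structure under the stated model — not that the index generalizes to any
particular real cohort.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty point sets give zero
counts (not errors), zero-area regions give missing densities, constant
features are rejected by the cutpoint scan and dropped by the LASSO with
a warning, and duplicate patient ids abort. All randomness flows from
explicit seeds; a fixed seed reproduces the full report byte for byte,
which the suite asserts by serializing two runs.

The test batteries run at sizes that keep the default suite within a few
minutes on one CPU while leaving the statistical checks well-powered:
proximity oracles at 500 × 200 points × 100 seeds, bud oracles at 2000
cells × 20 seeds, Cox coverage at n = 1000 × 200 replicates, cutpoint
oracles at n = 60 × 50 datasets, selection-chain recovery at n = 300 × 50
replicates (3 planted features, |log-HR| = 0.7/SD, 20 noise features),
and end-to-end index recovery at n = 300 × 50 replicate pairs with
planted per-SD log-hazards (1.4 / 1.4 / 0.9) mirroring the published
univariate component hazard ratios. End-to-end spatial runs use cohorts
of 12–20 patients in the tests and the full 113 + 117 in
`scripts/acceptance.R` and the `analysis/` drivers.

## Known limitations

- The bud link distance, channel-combination rule, correlation-pruning
  threshold, refinement criterion and zero-bud policy are surrogates for
  unpublished details of the original toolchain; all are exposed as
  configuration and echoed in every report, but results can shift under
  different choices.
- The IM quadrature treats a coarse cell as interior when all four
  corners are inside; pathological regions thinner than 50 μm would be
  misweighted (not a regime the package's bands enter).
- Ratio features with empty denominators use an ∞ sentinel that
  binarizes correctly but must be imputed (column median, logged) before
  the LASSO/forest stages.
- With very few events the selection stages degrade gracefully (logged
  fallbacks) but the resulting index can be a single component; the
  report makes that visible rather than padding the index.
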