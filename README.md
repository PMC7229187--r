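# sioi — spatial immune profiling and the Spatial Immuno-Oncology Index

`sioi` is an R package for region-resolved spatial analysis of the
colorectal tumor microenvironment from multiplex-immunofluorescence cell
data, and for building and validating the **Spatial Immuno-Oncology Index
(SIOI)** — a combinatorial prognostic category for stage II colorectal
cancer built from three image-based features: lymphocytic infiltration,
bud-proximal lymphocytes, and the macrophage subpopulation balance.

It is written for computational-pathology and spatial-biology researchers
who have per-cell exports (centroids in μm plus compartment dye
intensities, or precomputed phenotype flags) from two coregistered serial
slides — one stained for CD3/CD8/pancytokeratin, one for
CD68/CD163/pancytokeratin — together with the tumor polygon and the
invasive-front polyline, and disease-specific survival follow-up.

## What it computes

**Profiling.** Cells are phenotyped by fixed dye-intensity thresholds
(lymphocyte slide: nucleus FITC 0.15 / Cy5 0.132; macrophage slide:
nucleus FITC 0.200 / Cy5 0.132; cytoplasm 0.5 / 0.075 and membrane
0.5 / 0.075 on both), with CD3⁺CD8⁺ and CD68⁺CD163⁺ colocalization
classes. The tumor geometry defines the invasive margin (IM; a 500-μm
band either side of the invasive front), the tumor core (CT; the
remaining tumor), their union (IMCT), and the tumor-budding region of
interest (TBROI; the 1000-μm band inward from the front). Tumor buds are
connected clusters of ≤ 4 tumor cells (single linkage at a configurable
link distance, default 15 μm) whose centroid lies in the TBROI. The
macrophage slide is mapped into the lymphocyte-slide frame by a
closed-form Procrustes similarity fit on landmarks (optionally refined by
ICP on PCK⁺ centroids). The per-patient feature table holds 43 features:
densities (cells/mm²) of CD3⁺, CD8⁺, CD3⁺CD8⁺, CD68⁺, CD163⁺ and
CD68⁺CD163⁻ cells in IM/CT/IMCT, the TB count, CD68⁺/CD163⁺ ratios per
region, mean counts of each macrophage class within 0–50 and 0–100 μm of
TBs, CD3⁺ and CD8⁺ cells, and mean lymphocyte counts within 0–50 μm
of TBs.

**Model construction.** Features are screened by a Cox proportional-
hazards model with the LASSO penalty (10-fold cross-validated λ), ranked
by a 500-tree random forest's mean decrease Gini on the disease-specific
death label, filtered at Gini > 3, pruned so that of any highly
correlated pair only the higher-Gini feature survives, dichotomized at
maximally selected log-rank cutpoints, and refined by iteratively
removing the least significant component while the combined index's Cox
p-value improves. Patients with all three favorable features form the
“+/+/+” (low-risk) tier, two favorable features “+/+/−”, and one or none
“+/−/− or −/−/−”; Kaplan–Meier and univariate/forward-stepwise Cox
analyses evaluate the index at full follow-up and at censoring horizons.

**Synthetic cohorts.** Because the underlying patient data are not
deposited, `generate_cohort()` builds fully synthetic cohorts with known
ground truth — tissue geometry, marker-typed point patterns, planted
buds, intensities consistent with the thresholds, a known inter-slide
transform, and exponential proportional-hazards survival driven by the
planted spatial features — so every stage, and the end-to-end recovery of
the index, is testable.

## Worked example

```r
library(sioi)

cohort <- generate_cohort(synth_config(n_patients = 113, seed = 1))
report <- run_pipeline(cohort, pipeline_config(seed = 1))

length(report$feature_catalog)        # 43 image-based features
report$selection_trace$components     # the learned index components
report$evaluation[[1]]$cox$hr         # HR per tier, full follow-up
```

On the seed-1 synthetic training cohort (113 patients, 29
disease-specific deaths) this prints a three-component index and

```
training SIOI HR/tier = 6.26 (p = 6.8e-06)
low-risk 5-year survival = 96.7%
high-risk share of deaths = 96.6%
```

i.e. the per-tier hazard ratio of the learned index, the Kaplan–Meier
survival of the “+/+/+” tier at 60 months, and the fraction of all deaths
captured by the high-risk tier. Scoring an independent synthetic
validation cohort (117 patients, censored at 8.6 years) with the training
cutpoints applied unmodified gives HR/tier = 3.01 (p = 0.007) and 100%
5-year survival in the low-risk tier.

The numbered drivers under `analysis/` run the same study as separate
narrative steps (simulate → profile → select → evaluate), writing their
tables under `results/`.

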