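#!/usr/bin/env Rscript
# Profile both cohorts from their raw on-disk form: classify phenotypes
# from dye intensities, estimate the slide-2 -> slide-1 transform from the
# fiducial landmarks, build the IM/CT/IMCT/TBROI regions, detect tumor
# buds, and compute the 43-feature table plus its Spearman matrix.
# Run analysis/01_simulate.R first.

suppressMessages(library(sioi))
cfg <- pipeline_config(seed = 2024L)

profile_cohort <- function(dir, label) {
  cohort <- read_cohort(dir)
  cat(sprintf("profiling %s (%d patients) ...\n", label,
              length(cohort$cases)))
  feats <- lapply(cohort$cases, function(cs) {
    s1 <- cs$slide1
    s2 <- cs$slide2
    ph1 <- classify_lymphocyte(s1, cfg$thresholds, cfg$positivity_rule)
    ph1[classify_tumor(s1, cfg$thresholds) & ph1 == "negative"] <- "TUMOR"
    s1$phenotype <- ph1
    ph2 <- classify_macrophage(s2, cfg$thresholds, cfg$positivity_rule)
    ph2[classify_tumor(s2, cfg$thresholds) & ph2 == "negative"] <- "TUMOR"
    s2$phenotype <- ph2
    tf <- estimate_transform(cs$landmarks$moving, cs$landmarks$fixed)
    s2 <- apply_transform(s2, tf)
    rg <- build_regions(cs$tumor, cs$front,
                        im_half_width_um = cfg$im_half_width_um,
                        tbroi_width_um = cfg$tbroi_width_um)
    buds <- detect_buds(s1[s1$phenotype == "TUMOR", c("x_um", "y_um")],
                        rg, cfg$bud_link_um)
    compute_case_features(s1, s2, rg, buds,
                          radii_um = cfg$proximity_radii_um,
                          zero_bud_policy = cfg$zero_bud_policy)
  })
  tab <- build_feature_table(feats)
  write_feature_table(tab, sprintf("results/%s_features.csv", label))
  sm <- spearman_matrix(tab[, feature_catalog()])
  utils::write.csv(round(sm, 4), sprintf("results/%s_spearman.csv", label))
  cat(sprintf("  %d features/patient; %d zero-bud patient(s)\n",
              length(feature_catalog()), sum(tab$zero_bud)))
  cat(sprintf("  TB count vs CD3+ IMCT density: Spearman r = %.2f\n",
              sm["tb_count", "den_CD3_IMCT"]))
  tab
}

invisible(profile_cohort("results/cohorts/training", "training"))
invisible(profile_cohort("results/cohorts/validation", "validation"))
cat("feature tables and Spearman matrices written under results/\n")
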