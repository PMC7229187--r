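#!/usr/bin/env Rscript
# Feature selection on the training cohort: LASSO-penalized Cox (10-fold
# CV), random-forest mean-decrease-Gini ranking (500 trees), the Gini > 3
# filter, correlation pruning, maximally selected survival cutpoints, and
# iterative removal of the least significant component. Writes the full
# selection trace and the final component rules.
# Run analysis/01_simulate.R and analysis/02_profile.R first.

suppressMessages(library(sioi))
cfg <- pipeline_config(seed = 2024L)

features <- read_feature_table("results/training_features.csv")
survival <- read_survival_table("results/cohorts/training/survival.csv")
stopifnot(identical(features$patient_id, survival$patient_id))
X <- as.matrix(features[, feature_catalog()])

lasso <- suppressWarnings(
  lasso_cox_select(X, survival, folds = cfg$lasso_folds, seed = cfg$seed))
cat(sprintf("LASSO (lambda = %.4g) kept %d of %d features:\n",
            lasso$lambda, length(lasso$selected), ncol(X)))
print(round(lasso$coefficients, 5))

rf_in <- if (length(lasso$selected)) lasso$selected else colnames(X)
ranking <- rf_gini_rank(X[, rf_in, drop = FALSE], survival$event,
                        n_trees = cfg$rf_trees, seed = cfg$seed)
cat(sprintf("random forest OOB error: %.3f; Gini ranking:\n",
            attr(ranking, "oob_error")))
print(ranking)

filtered <- gini_filter(ranking, cfg$gini_threshold)
if (nrow(filtered) < cfg$min_components) {
  cat(sprintf("only %d feature(s) above Gini %.1f; keeping top %d\n",
              nrow(filtered), cfg$gini_threshold, cfg$min_components))
  filtered <- head(ranking, cfg$min_components)
}
sm <- spearman_matrix(features[, feature_catalog()])
pruned <- prune_correlated(filtered, sm, cfg$correlation_prune_threshold)
cat("after correlation pruning:", paste(pruned$feature, collapse = ", "), "\n")

rules <- lapply(setNames(nm = pruned$feature), function(f)
  optimal_cutpoint(features[[f]], survival,
                   min_group_prop = cfg$cutpoint_min_group_prop, feature = f))
flags <- sapply(pruned$feature, function(f)
  binarize(features[[f]], rules[[f]],
           zero_bud = if (grepl("_TB_", f)) features$zero_bud else NULL,
           zero_bud_policy = cfg$zero_bud_policy))
refined <- iterative_refine(flags, survival, criterion = cfg$refine_criterion)
rules <- rules[refined$kept]
cat("final SIOI components:\n")
for (f in names(rules)) {
  cat(sprintf("  %-28s cutoff %.4g, favorable %s\n", f,
              rules[[f]]$cutoff, rules[[f]]$favorable_direction))
}

dir.create("results", showWarnings = FALSE)
trace <- list(lasso = lasso[c("selected", "coefficients", "lambda")],
              gini = ranking, filtered = filtered$feature,
              pruned = pruned$feature, refinement = refined$trace,
              components = refined$kept,
              rules = lapply(rules, unclass))
writeLines(jsonlite::toJSON(trace, auto_unbox = TRUE, digits = NA,
                            force = TRUE, na = "null"),
           "results/selection_trace.json")
writeLines(jsonlite::toJSON(lapply(rules, unclass), auto_unbox = TRUE,
                            digits = NA), "results/sioi_rules.json")
cat("selection trace and rules written under results/\n")
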