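# End-to-end orchestration: classification -> coregistration -> regions ->
# buds -> features -> Spearman -> LASSO Cox -> RF Gini -> Gini filter ->
# correlation pruning -> cutpoints -> iterative refinement -> SIOI ->
# Cox/KM evaluation (full follow-up and configured horizons). The report
# records every threshold used and the full selection trace, and is
# byte-reproducible for a fixed seed.

# Profile one case: phenotypes, frame alignment, regions, buds, features.
profile_case <- function(cs, config) {
  s1 <- cs$slide1
  s2 <- cs$slide2
  have_intens <- all(c("nucleus_FITC", "nucleus_Cy5") %in% names(s1))
  if (have_intens) {
    ph1 <- classify_lymphocyte(s1, config$thresholds, config$positivity_rule)
    tum <- classify_tumor(s1, config$thresholds)
    ph1[tum & ph1 == "negative"] <- "TUMOR"
    s1$phenotype <- ph1
    ph2 <- classify_macrophage(s2, config$thresholds, config$positivity_rule)
    tum2 <- classify_tumor(s2, config$thresholds)
    ph2[tum2 & ph2 == "negative"] <- "TUMOR"
    s2$phenotype <- ph2
  } else if (!"phenotype" %in% names(s1)) {
    stop("cells carry neither intensities nor phenotype flags")
  }
  tf <- if (!is.null(cs$landmarks)) {
    estimate_transform(cs$landmarks$moving, cs$landmarks$fixed,
                       kind = "similarity")
  } else {
    refine_icp(s2[s2$phenotype == "TUMOR", c("x_um", "y_um")],
               s1[s1$phenotype == "TUMOR", c("x_um", "y_um")])
  }
  s2_aligned <- apply_transform(s2, tf)
  regions <- cs$regions %||% build_regions(
    cs$tumor, cs$front, extent_bbox = cs$extent_bbox,
    im_half_width_um = config$im_half_width_um,
    tbroi_width_um = config$tbroi_width_um,
    coarse_um = config$area_coarse_um, fine_um = config$area_fine_um)
  tumor_pts <- s1[s1$phenotype == "TUMOR", c("x_um", "y_um"), drop = FALSE]
  buds <- detect_buds(tumor_pts, regions, config$bud_link_um)
  feats <- compute_case_features(s1, s2_aligned, regions, buds,
                                 radii_um = config$proximity_radii_um,
                                 zero_bud_policy = config$zero_bud_policy)
  pck_cat <- if ("cytoplasm_CY3_PCK" %in% names(s1)) {
    dichotomize_pck(mean(s1$cytoplasm_CY3_PCK),
                    config$thresholds$pck_slide_threshold)
  } else NA_character_
  list(features = feats, regions = regions, buds = buds,
       transform = tf, pck_category = pck_cat)
}

# Learn cutpoint rules and component flags for a set of candidate features.
learn_cutpoints <- function(feature_table, candidates, survival, config) {
  rules <- list()
  flags <- matrix(NA, nrow(feature_table), length(candidates),
                  dimnames = list(feature_table$patient_id, candidates))
  for (f in candidates) {
    rules[[f]] <- optimal_cutpoint(feature_table[[f]], survival,
                                   min_group_prop = config$cutpoint_min_group_prop,
                                   feature = f)
    zb <- if (grepl("_TB_", f)) feature_table$zero_bud else NULL
    flags[, f] <- binarize(feature_table[[f]], rules[[f]],
                           zero_bud = zb,
                           zero_bud_policy = config$zero_bud_policy)
  }
  list(rules = rules, flags = flags)
}

#' Score a cohort against fixed SIOI component rules
#'
#' Applies previously learned cutpoint rules unmodified (as in external
#' validation) and assigns the combinatorial category.
#'
#' @param feature_table Feature table (with `patient_id` and `zero_bud`).
#' @param rules Named list of [optimal_cutpoint()] rules (the components).
#' @param zero_bud_policy Policy for TB-proximity features of zero-bud
#'   cases.
#' @return Data frame: `patient_id`, one flag column per component,
#'   `n_favorable`, `tier3`, `tier2`.
#' @export
sioi_score <- function(feature_table, rules,
                       zero_bud_policy = "favorable") {
  comp <- names(rules)
  flags <- matrix(NA, nrow(feature_table), length(comp),
                  dimnames = list(NULL, comp))
  for (f in comp) {
    zb <- if (grepl("_TB_", f)) feature_table$zero_bud else NULL
    flags[, f] <- binarize(feature_table[[f]], rules[[f]], zero_bud = zb,
                           zero_bud_policy = zero_bud_policy)
  }
  assign <- sioi_assign(flags)
  cbind(data.frame(patient_id = feature_table$patient_id,
                   stringsAsFactors = FALSE),
        as.data.frame(flags), assign)
}

# Cox + KM summary of a SIOI assignment at one follow-up horizon.
evaluate_sioi <- function(sioi, survival, horizon_months = NULL) {
  surv <- survival
  label <- "full"
  if (!is.null(horizon_months)) {
    surv <- censor_at(surv, horizon_months)
    label <- paste0(horizon_months, "m")
  }
  ok <- !is.na(sioi$tier3)
  # ordinal risk: 0 = low-risk tier, increasing toward the high-risk tier
  idx <- as.numeric(sioi$tier3[ok]) - 1
  s_ok <- surv[ok, , drop = FALSE]
  cox <- tryCatch(cox_univariate(idx, s_ok), error = function(e) NULL)
  km <- tryCatch(km_curves(sioi$tier3[ok], s_ok), error = function(e) NULL)
  surv_at <- tryCatch(
    km_survival_at(sioi$tier3[ok], s_ok,
                   if (is.null(horizon_months)) max(s_ok$time_months)
                   else horizon_months),
    error = function(e) NULL)
  deaths_by_tier2 <- tapply(s_ok$event, sioi$tier2[ok], sum)
  list(horizon = label,
       cox = if (is.null(cox)) NULL else cox[c("coef", "hr", "ci_lower",
                                               "ci_upper", "p", "n_events")],
       logrank_p = if (is.null(km)) NA_real_ else km$logrank_p,
       km_survival = as.list(surv_at),
       deaths_low_risk = unname(deaths_by_tier2["low-risk"]),
       deaths_high_risk = unname(deaths_by_tier2["high-risk"]),
       n_by_tier3 = as.list(table(sioi$tier3[ok])))
}

#' Run the full profiling + SIOI pipeline on a cohort
#'
#' @param cohort A [generate_cohort()] result, or a directory written by
#'   [write_cohort()].
#' @param config A [pipeline_config()].
#' @return A `sioi_report` list: configuration echo (all thresholds),
#'   feature catalog and table, Spearman matrix, the full selection trace
#'   (LASSO set and lambda, Gini ranking, filtered / pruned subsets,
#'   cutpoints, refinement steps), per-patient SIOI assignments, and
#'   Cox/KM evaluation at full follow-up and each configured horizon.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  survival <- cohort$survival
  if (anyDuplicated(survival$patient_id)) {
    stop("validation error: duplicated patient_id in survival table")
  }
  log <- list()
  profiled <- lapply(cohort$cases, profile_case, config = config)
  feats <- lapply(profiled, `[[`, "features")
  ftab <- build_feature_table(feats)
  ftab <- ftab[match(survival$patient_id, ftab$patient_id), , drop = FALSE]
  catalog <- feature_catalog()
  log$n_features <- length(catalog)
  log$zero_bud_patients <- ftab$patient_id[ftab$zero_bud]
  log$pck_categories <- vapply(profiled, `[[`, "", "pck_category")

  smat <- spearman_matrix(ftab[, catalog, drop = FALSE])

  X <- as.matrix(ftab[, catalog, drop = FALSE])
  lasso <- tryCatch(
    suppressWarnings(lasso_cox_select(X, survival,
                                      folds = config$lasso_folds,
                                      seed = config$seed,
                                      lambda_rule = config$lambda_rule)),
    error = function(e) list(selected = character(0), coefficients = numeric(0),
                             lambda = NA_real_, dropped_constant = character(0),
                             imputed = character(0), cv = NULL,
                             error = conditionMessage(e)))
  rf_input <- lasso$selected
  if (!length(rf_input)) {
    log$lasso_fallback <- paste(
      "LASSO selected no feature; full catalog passed to the forest",
      lasso$error %||% "")
    sds <- apply(X, 2, function(v) stats::sd(v[is.finite(v)]))
    rf_input <- catalog[is.finite(sds) & sds > 0]
  }
  ranking <- rf_gini_rank(X[, rf_input, drop = FALSE], survival$event,
                          n_trees = config$rf_trees, seed = config$seed)
  filtered <- gini_filter(ranking, config$gini_threshold)
  if (nrow(filtered) < config$min_components) {
    log$gini_fallback <- sprintf(
      "only %d feature(s) exceeded Gini %.2f; keeping the top %d by Gini",
      nrow(filtered), config$gini_threshold, config$min_components)
    filtered <- utils::head(ranking, config$min_components)
  }
  pruned <- prune_correlated(filtered, smat,
                             config$correlation_prune_threshold)
  cp <- learn_cutpoints(ftab, pruned$feature, survival, config)
  refine <- iterative_refine(cp$flags, survival,
                             criterion = config$refine_criterion)
  rules <- cp$rules[refine$kept]
  sioi <- sioi_score(ftab, rules, zero_bud_policy = config$zero_bud_policy)
  evals <- c(list(evaluate_sioi(sioi, survival)),
             lapply(config$censor_horizons_months, function(h)
               evaluate_sioi(sioi, survival, h)))
  report <- list(
    config = config_echo(config),
    n_patients = nrow(survival),
    n_events = sum(survival$event),
    feature_catalog = catalog,
    log = log,
    selection_trace = list(
      lasso = list(selected = lasso$selected,
                   coefficients = as.list(lasso$coefficients),
                   lambda = lasso$lambda,
                   dropped_constant = lasso$dropped_constant,
                   imputed = lasso$imputed),
      gini_ranking = ranking,
      gini_filtered = filtered$feature,
      oob_error = attr(ranking, "oob_error"),
      pruned = pruned$feature,
      pruned_pairs = attr(pruned, "pruned_pairs"),
      cutpoints = lapply(cp$rules, unclass),
      refinement = refine$trace,
      components = refine$kept
    ),
    rules = lapply(rules, unclass),
    sioi = sioi,
    evaluation = evals,
    features = ftab,
    spearman = round(smat, 6)
  )
  class(report) <- "sioi_report"
  report
}

# Flat echo of every tunable so a run's thresholds are auditable.
config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$thresholds <- unclass(cfg$thresholds)
  cfg
}

#' Write a pipeline report as JSON
#' @param report A [run_pipeline()] result.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                              digits = NA, na = "null", null = "null",
                              dataframe = "columns", force = TRUE),
             path)
  invisible(path)
}

#' Write / read a cohort as flat files
#'
#' One directory per cohort: `survival.csv`, and per patient
#' `<id>_slide1.csv`, `<id>_slide2.csv`, `<id>_geometry.geojson`,
#' `<id>_landmarks.csv`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Cohort directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_survival_table(cohort$survival, file.path(dir, "survival.csv"))
  for (id in names(cohort$cases)) {
    cs <- cohort$cases[[id]]
    write_cell_table(cs$slide1, file.path(dir, paste0(id, "_slide1.csv")))
    write_cell_table(cs$slide2, file.path(dir, paste0(id, "_slide2.csv")))
    write_geometry(cs$tumor, cs$front,
                   file.path(dir, paste0(id, "_geometry.geojson")))
    lm <- data.frame(moving_x = cs$landmarks$moving[, 1],
                     moving_y = cs$landmarks$moving[, 2],
                     fixed_x = cs$landmarks$fixed[, 1],
                     fixed_y = cs$landmarks$fixed[, 2])
    utils::write.csv(lm, file.path(dir, paste0(id, "_landmarks.csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  survival <- read_survival_table(file.path(dir, "survival.csv"))
  ids <- survival$patient_id
  cases <- lapply(ids, function(id) {
    geo <- read_geometry(file.path(dir, paste0(id, "_geometry.geojson")))
    lm <- utils::read.csv(file.path(dir, paste0(id, "_landmarks.csv")))
    list(slide1 = read_cell_table(file.path(dir, paste0(id, "_slide1.csv"))),
         slide2 = read_cell_table(file.path(dir, paste0(id, "_slide2.csv"))),
         tumor = geo$tumor, front = geo$front, extent_bbox = NULL,
         landmarks = list(moving = as.matrix(lm[, c("moving_x", "moving_y")]),
                          fixed = as.matrix(lm[, c("fixed_x", "fixed_y")])))
  })
  names(cases) <- ids
  list(cases = cases, survival = survival)
}
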