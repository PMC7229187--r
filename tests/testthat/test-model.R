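# Selection chain and survival machinery: LASSO saturation and collinearity
# behaviour, the published Gini-column filter, pruning against a brute-force
# keep-set oracle, cutpoints against the exhaustive survdiff scan, the
# refinement loop, SIOI categories, and Cox/KM correctness.

surv_df <- function(time, event) data.frame(time_months = time, event = event)

test_that("LASSO shrinks everything to zero at lambda >= lambda_max", {
  set.seed(41)
  co <- generate_feature_cohort(n = 120, seed = 41)
  sel <- lasso_cox_select(co$features, co$survival, lambda = 1e3)
  expect_equal(length(sel$selected), 0)
})

test_that("LASSO recovers planted features and handles duplicates", {
  set.seed(42)
  co <- generate_feature_cohort(n = 250, n_noise = 10, seed = 42)
  sel <- lasso_cox_select(co$features, co$survival, seed = 1)
  expect_true(all(co$planted %in% sel$selected))
  # signs follow the planted directions (protective negative, ratio positive)
  expect_lt(sel$coefficients[["den_CD3_IMCT"]], 0)
  expect_gt(sel$coefficients[["ratio_CD68_CD163_CT"]], 0)

  # an exactly collinear duplicate never yields two large coefficients;
  # the pair's total weight matches the original's up to grouping
  X <- co$features
  X$dup_of_cd3 <- X$den_CD3_IMCT
  sel2 <- lasso_cox_select(X, co$survival, seed = 1)
  pair <- intersect(c("den_CD3_IMCT", "dup_of_cd3"), sel2$selected)
  expect_gte(length(pair), 1)

  # constant features are dropped with a warning
  X$flat <- 1
  expect_warning(lasso_cox_select(X, co$survival, seed = 1), "flat")
})

test_that("the Gini filter keeps strictly-greater-than-3 features", {
  # the published importance column: exactly five values exceed 3
  gini <- c(4.28147, 3.90178, 3.61488, 3.48619, 3.07934, 2.68648, 2.43362,
            0.65122, 0.60136, 0.55309, 0.50729)
  ranked <- data.frame(feature = sprintf("f%02d", seq_along(gini)),
                       gini = gini, stringsAsFactors = FALSE)
  expect_equal(nrow(gini_filter(ranked, 3)), 5)
  expect_equal(gini_filter(ranked, 3)$gini, gini[1:5])
  expect_equal(nrow(gini_filter(ranked, 1e6)), 0)
  expect_equal(gini_filter(ranked, 0), ranked)
})

test_that("random-forest Gini ranking finds a planted separator", {
  set.seed(43)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  X <- data.frame(sep = y + rnorm(n, 0, 0.05),
                  matrix(rnorm(n * 5), n, 5,
                         dimnames = list(NULL, paste0("n", 1:5))))
  r <- rf_gini_rank(X, y, n_trees = 200, seed = 7)
  expect_equal(r$feature[1], "sep")
  expect_true(attr(r, "oob_error") < 0.1)
  # a constant feature gets (near-)zero importance
  X$flat <- 3
  r <- rf_gini_rank(X, y, n_trees = 200, seed = 7)
  expect_equal(r$gini[r$feature == "flat"], 0, tolerance = 1e-8)
  # permuting columns permutes the ranking identically
  r2 <- rf_gini_rank(X[, rev(names(X))], y, n_trees = 200, seed = 7)
  expect_equal(r2$feature[1], "sep")
  expect_error(rf_gini_rank(X, rep(1, n)), "classes")
})

test_that("correlation pruning keeps the higher-Gini member of each pair", {
  ranked <- data.frame(feature = c("a", "b", "c"),
                       gini = c(4.0, 3.5, 3.2), stringsAsFactors = FALSE)
  sm <- diag(3)
  dimnames(sm) <- list(c("a", "b", "c"), c("a", "b", "c"))
  sm["a", "b"] <- sm["b", "a"] <- 0.95
  out <- prune_correlated(ranked, sm, 0.8)
  expect_equal(out$feature, c("a", "c"))
  expect_equal(attr(out, "pruned_pairs")[[1]]$dropped, "b")
  # all below threshold: identity
  sm["a", "b"] <- sm["b", "a"] <- 0.1
  expect_equal(prune_correlated(ranked, sm, 0.8)$feature, c("a", "b", "c"))
})

test_that("greedy pruning matches exhaustive search on small problems", {
  set.seed(44)
  for (rep in 1:10) {
    k <- 7
    nm <- paste0("f", 1:k)
    ranked <- data.frame(feature = nm,
                         gini = sort(runif(k, 1, 5), decreasing = TRUE),
                         stringsAsFactors = FALSE)
    sm <- matrix(runif(k * k, -1, 1), k, k, dimnames = list(nm, nm))
    sm <- (sm + t(sm)) / 2
    diag(sm) <- 1
    out <- prune_correlated(ranked, sm, 0.6)
    # oracle: the greedy-by-Gini admissible set, built independently by
    # scanning all subsets for the one the greedy rule defines: every kept
    # feature is compatible with all higher-Gini kept features
    kept <- character(0)
    for (f in ranked$feature) {
      if (!length(kept) || all(abs(sm[f, kept]) < 0.6)) kept <- c(kept, f)
    }
    expect_equal(out$feature, kept)
    # and the kept set is maximal: nothing else can be added
    for (f in setdiff(nm, out$feature)) {
      expect_false(all(abs(sm[f, out$feature]) < 0.6))
    }
  }
})

test_that("optimal cutpoints equal the exhaustive survdiff scan", {
  set.seed(45)
  for (rep in 1:12) {
    n <- 60
    v <- rnorm(n)
    tm <- rexp(n, 0.02 * exp(0.8 * v))
    ev <- as.integer(tm < 50)
    tm <- pmin(tm, 50)
    cp <- optimal_cutpoint(v, surv_df(tm, ev))
    orc <- oracle_cutpoint_scan(v, tm, ev)
    expect_equal(cp$cutoff, orc$cutoff)
    expect_equal(cp$statistic, orc$z, tolerance = 1e-9)
  }
})

test_that("cutpoint separates a perfectly split feature with the right direction", {
  set.seed(46)
  ev <- rep(c(1, 0), each = 15)
  tm <- c(runif(15, 1, 30), runif(15, 40, 80))
  v <- ifelse(ev == 1, 10 + runif(30, 0, 1), 5 - runif(30, 0, 1))
  cp <- optimal_cutpoint(v, surv_df(tm, ev))
  expect_gt(cp$cutoff, 5)
  expect_lt(cp$cutoff, 10)
  expect_equal(cp$favorable_direction, "below")
  expect_error(optimal_cutpoint(rep(1, 30), surv_df(tm, ev)), "constant")
  # min-group constraint can empty the candidate list
  expect_error(optimal_cutpoint(c(rep(0, 29), 5), surv_df(tm, ev),
                                min_group_prop = 0.2), "admissible")
})

test_that("cutpoint ties go to the smallest cutoff", {
  # symmetric data: the scan statistic ties across mirrored cutoffs
  tm <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  ev <- rep(1, 10)
  v <- c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5)[order(order(tm))]
  cp <- optimal_cutpoint(v, surv_df(tm, ev), min_group_prop = 0.1)
  z_all <- vapply(sort(unique(v))[-5] + 0.5, function(cand) {
    sd <- survival::survdiff(survival::Surv(tm, ev) ~ I(v > cand))
    sqrt(sd$chisq)
  }, 0)
  ties <- which(abs(z_all - max(z_all)) < 1e-12)
  expect_equal(cp$cutoff, (sort(unique(v))[-5] + 0.5)[ties[1]])
})

test_that("binarization is strict at the cutoff and respects directions", {
  above <- structure(list(feature = "den_CD3_IMCT", cutoff = 389.6,
                          favorable_direction = "above", statistic = NA),
                     class = "cutpoint_rule")
  expect_true(binarize(400, above))       # published cutoff, value above
  expect_false(binarize(389.6, above))    # equality -> unfavorable
  expect_false(binarize(300, above))
  expect_true(is.na(binarize(NA_real_, above)))
  # zero-bud policy resolves missing TB-proximity features
  expect_true(binarize(NA_real_, above, zero_bud = TRUE,
                       zero_bud_policy = "favorable"))
  expect_true(is.na(binarize(NA_real_, above, zero_bud = TRUE,
                             zero_bud_policy = "missing")))
})

test_that("iterative refinement removes noise components and is deterministic", {
  set.seed(47)
  n <- 240
  good1 <- rbinom(n, 1, 0.5)
  good2 <- rbinom(n, 1, 0.5)
  noise <- rbinom(n, 1, 0.5)
  lp <- -0.9 * good1 - 0.9 * good2
  tm <- rexp(n, 0.02 * exp(-lp))
  ev <- as.integer(tm < 60)
  tm <- pmin(tm, 60)
  flags <- cbind(g1 = good1 == 1, g2 = good2 == 1, nz = noise == 1)
  ref <- iterative_refine(flags, surv_df(tm, ev))
  expect_true(all(c("g1", "g2") %in% ref$kept))
  expect_false("nz" %in% ref$kept)
  ref2 <- iterative_refine(flags, surv_df(tm, ev))
  expect_identical(ref, ref2)
  # a single candidate is returned unchanged
  one <- iterative_refine(flags[, 1, drop = FALSE], surv_df(tm, ev))
  expect_equal(one$kept, "g1")
})

test_that("SIOI categories follow the favorable-count definition", {
  flags <- rbind(c(TRUE, TRUE, TRUE),
                 c(TRUE, FALSE, TRUE),
                 c(FALSE, FALSE, TRUE),
                 c(FALSE, FALSE, FALSE),
                 c(TRUE, NA, TRUE))
  out <- sioi_assign(flags)
  expect_equal(as.character(out$tier3[1:4]),
               c("+/+/+", "+/+/-", "+/-/- or -/-/-", "+/-/- or -/-/-"))
  expect_equal(as.character(out$tier2[1:4]),
               c("low-risk", "high-risk", "high-risk", "high-risk"))
  expect_true(is.na(out$tier3[5]))
  expect_equal(attr(out, "excluded"), 5L)
})

test_that("univariate Cox matches a Newton oracle and flags separation", {
  d <- six_subject_data()
  fit <- cox_univariate(d$x, d)
  expect_equal(fit$coef, oracle_cox_newton(d$time_months, d$event, d$x),
               tolerance = 1e-8)
  expect_equal(fit$hr, exp(fit$coef), tolerance = 1e-12)
  expect_true(fit$ci_lower < fit$hr && fit$hr < fit$ci_upper)

  # identical outcomes in two groups: HR 1, p ~ 1
  g <- rep(c(0, 1), each = 6)
  tm <- rep(c(1, 2, 3, 4, 5, 6), 2)
  ev <- rep(c(1, 0, 1, 0, 1, 0), 2)
  fit <- cox_univariate(g, surv_df(tm, ev))
  expect_equal(fit$hr, 1, tolerance = 1e-9)
  expect_gt(fit$p, 0.99)

  # perfect separation is flagged
  tm <- c(1, 2, 3, 10, 11, 12)
  ev <- c(1, 1, 1, 0, 0, 0)
  x <- c(1, 1, 1, 0, 0, 0)
  fit <- cox_univariate(x, surv_df(tm, ev))
  expect_true(fit$infinite_flag)
  expect_error(cox_univariate(rep(1, 6), surv_df(tm, ev)), "distinct")
})

test_that("forward stepwise Cox enters real predictors, not collinear copies", {
  set.seed(48)
  n <- 300
  real <- rnorm(n)
  tm <- rexp(n, 0.02 * exp(0.8 * real))
  ev <- as.integer(tm < 60)
  tm <- pmin(tm, 60)
  X <- data.frame(real = real, noise1 = rnorm(n), noise2 = rnorm(n),
                  copy = real)
  fw <- cox_multivariate_forward(X[, c("real", "noise1", "noise2")],
                                 surv_df(tm, ev))
  expect_equal(fw$entered[1], "real")
  expect_false(any(c("noise1", "noise2") %in% fw$entered))
  # entry_p = 0: empty model with a note
  fw0 <- cox_multivariate_forward(X, surv_df(tm, ev), entry_p = 0)
  expect_equal(length(fw0$entered), 0)
  expect_match(fw0$note, "no predictor")
  # the collinear duplicate of an entered predictor never enters second
  fw2 <- cox_multivariate_forward(X, surv_df(tm, ev))
  expect_false(all(c("real", "copy") %in% fw2$entered))
})

test_that("KM matches the hand product-limit and log-rank behaves", {
  km <- km_curves(rep("a", 5), surv_df(1:5, c(1, 1, 0, 1, 0)))
  expect_equal(km$curves$surv, c(4/5, 4/5 * 3/4, 4/5 * 3/4, 0.3, 0.3))
  expect_true(is.na(km$logrank_p))

  # no events: survival stays at 1
  km <- km_curves(rep("a", 4), surv_df(1:4, rep(0, 4)))
  expect_true(all(km$curves$surv == 1))

  # two identical groups: log-rank p ~ 1
  km <- km_curves(rep(c("a", "b"), each = 5),
                  surv_df(rep(1:5, 2), rep(c(1, 1, 0, 1, 0), 2)))
  expect_gt(km$logrank_p, 0.99)
  expect_warning(km_curves(factor(rep("a", 5), levels = c("a", "b")),
                           surv_df(1:5, c(1, 1, 0, 1, 0))), "empty")
})

test_that("administrative censoring truncates times and events", {
  s <- surv_df(c(72, 50, 90), c(1, 1, 0))
  cs <- censor_at(s, 60)
  expect_equal(cs$time_months, c(60, 50, 60))
  expect_equal(cs$event, c(0, 1, 0))
  expect_identical(censor_at(s, 1000), s)
  expect_lte(sum(censor_at(s, 30)$event), sum(s$event))
  expect_error(censor_at(s, 0), "positive")
})
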