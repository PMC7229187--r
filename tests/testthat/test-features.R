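# Spatial features: density arithmetic and Poisson consistency, inclusive
# proximity radii against a brute-force oracle, bud-proximal lymphocyte
# means with the zero-bud policy, macrophage ratios, the feature catalog,
# and the Spearman matrix.

test_that("density is count over area, with undefined areas propagated", {
  pts <- cbind(runif(100, 0, 100), runif(100, 0, 100))
  expect_equal(cell_density(pts, NULL, 2.0), 50)
  expect_equal(cell_density(matrix(numeric(0), ncol = 2), NULL, 2.0), 0)
  expect_true(is.na(cell_density(pts, NULL, 0)))
})

test_that("a homogeneous Poisson density is estimated within Poisson error", {
  # lambda = 389.6 cells/mm^2 (the published CD3-IMCT cutoff reused as a
  # realistic rate) on 10 mm^2: s.e. = sqrt(lambda / A)
  set.seed(31)
  lambda <- 389.6
  area <- 10
  n <- rpois(1, lambda * area)
  est <- n / area
  expect_lt(abs(est - lambda), 3 * sqrt(lambda / area))
})

test_that("proximity counts use an inclusive radius and match brute force", {
  tgt <- rbind(c(0, 0))
  src <- rbind(c(30, 0), c(49.9, 0), c(50, 0), c(60, 0))
  pc <- proximity_count(src, tgt, 50)
  expect_equal(pc$counts, 3L)
  expect_equal(pc$mean, 3)

  expect_equal(proximity_count(matrix(numeric(0), ncol = 2), tgt, 50)$counts, 0L)
  expect_true(is.na(proximity_count(src, matrix(numeric(0), ncol = 2), 50)$mean))
  expect_error(proximity_count(src, tgt, 0), "positive")

  set.seed(32)
  for (rep in 1:10) {
    src <- cbind(runif(300, 0, 800), runif(300, 0, 800))
    tgt <- cbind(runif(120, 0, 800), runif(120, 0, 800))
    for (r in c(50, 100)) {
      expect_identical(proximity_count(src, tgt, r)$counts,
                       oracle_count_within(src, tgt, r))
    }
  }
})

test_that("counts are monotone nondecreasing in the radius", {
  set.seed(34)
  src <- cbind(runif(200, 0, 500), runif(200, 0, 500))
  tgt <- cbind(runif(50, 0, 500), runif(50, 0, 500))
  prev <- rep(0L, 50)
  for (r in c(10, 25, 50, 100, 200)) {
    cur <- proximity_count(src, tgt, r)$counts
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("bud-proximal lymphocyte means average over buds", {
  buds <- rbind(c(0, 0), c(1000, 0))
  lymph <- rbind(matrix(rep(c(30, 0), 4), ncol = 2, byrow = TRUE),
                 matrix(rep(c(1000, 40), 6), ncol = 2, byrow = TRUE))
  expect_equal(mean_lymphocytes_near_buds(lymph, buds), 5)
  one <- mean_lymphocytes_near_buds(rbind(c(40, 0)), rbind(c(0, 0)))
  expect_equal(one, 1)
  # zero buds: the policy decides
  none <- matrix(numeric(0), ncol = 2)
  f <- mean_lymphocytes_near_buds(lymph, none, zero_bud_policy = "favorable")
  expect_true(is.na(f))
  expect_equal(attr(f, "zero_bud"), "favorable")
  expect_equal(as.numeric(mean_lymphocytes_near_buds(lymph, none,
                                                     zero_bud_policy = "zero")), 0)
})

test_that("macrophage ratio handles zero denominators as documented", {
  expect_equal(macrophage_ratio(219.2, 200), 1.096)
  expect_equal(macrophage_ratio(0, 100), 0)
  expect_equal(macrophage_ratio(100, 0), Inf)
  expect_true(is.na(macrophage_ratio(0, 0)))
  expect_error(macrophage_ratio(-1, 10), "negative")
  # at exactly the published cutoff with direction "below", the flag is
  # unfavorable (strict inequality)
  rule <- structure(list(feature = "ratio_CD68_CD163_CT", cutoff = 1.096,
                         favorable_direction = "below", statistic = NA),
                    class = "cutpoint_rule")
  expect_false(binarize(macrophage_ratio(219.2, 200), rule))
  expect_false(binarize(Inf, rule))
  expect_true(binarize(0.5, rule))
})

test_that("the feature catalog is fixed and the table is idempotent", {
  cat43 <- feature_catalog()
  expect_equal(length(cat43), 43)
  expect_equal(sum(grepl("^den_", cat43)), 18)
  expect_equal(sum(grepl("^ratio_", cat43)), 3)
  expect_equal(sum(grepl("^prox_", cat43)), 21)
  expect_true("tb_count" %in% cat43)

  cfg <- small_synth(seed = 5L)
  cs1 <- generate_case(cfg, seed = 51)
  cs2 <- generate_case(cfg, seed = 52)
  fv <- function(cs) {
    tumor_pts <- cs$slide1[cs$slide1$phenotype == "TUMOR", c("x_um", "y_um")]
    buds <- detect_buds(tumor_pts, cs$regions)
    compute_case_features(cs$slide1,
                          apply_transform(cs$slide2, cs$transform),
                          cs$regions, buds)
  }
  f1 <- fv(cs1)
  tab <- build_feature_table(list(P1 = f1, P2 = fv(cs2)))
  expect_equal(nrow(tab), 2)
  expect_equal(names(tab), c("patient_id", cat43, "zero_bud"))
  # recomputation reproduces the row exactly
  expect_equal(unlist(tab[1, cat43]), fv(cs1)[cat43])
  expect_error(build_feature_table(list(P1 = f1, P1 = f1)), "unique")
})

test_that("cross-slide features are identical under an identity transform", {
  cfg <- small_synth(transform_rot_sd_deg = 0, transform_trans_sd_um = 0,
                     transform_scale_sd = 0, seed = 6L)
  cs <- generate_case(cfg, seed = 61)
  tumor_pts <- cs$slide1[cs$slide1$phenotype == "TUMOR", c("x_um", "y_um")]
  buds <- detect_buds(tumor_pts, cs$regions)
  aligned <- apply_transform(cs$slide2, cs$transform)
  ident <- compute_case_features(cs$slide1, cs$slide2, cs$regions, buds)
  mapped <- compute_case_features(cs$slide1, aligned, cs$regions, buds)
  expect_equal(ident, mapped, tolerance = 1e-12)
})

test_that("Spearman matrix is monotone-invariant and matches rank-Pearson", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 10)
  tab <- data.frame(a = x, b = exp(x), c = -x)
  r <- spearman_matrix(tab)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 3))

  set.seed(36)
  tab <- as.data.frame(matrix(sample(1:5, 50, replace = TRUE), 10, 5))
  r <- spearman_matrix(tab)
  oracle <- stats::cor(apply(tab, 2, rank), method = "pearson")
  expect_equal(unclass(r)[1:5, 1:5], oracle, tolerance = 1e-12,
               ignore_attr = TRUE)

  tab$const <- 1
  r <- spearman_matrix(tab)
  expect_true(all(is.na(r["const", colnames(r) != "const"])))
  expect_equal(attr(r, "undefined_columns"), "const")
})
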