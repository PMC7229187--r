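# The generator's planted structure is recoverable: Poisson counts at the
# configured rates, read-back of planted buds, intensity inversion through
# the classifier, CSR proximity with attraction off, linear scaling in the
# rate, exponential survival with beta = 0, and seed reproducibility.

test_that("zero rates give empty patterns and all-zero truth", {
  cfg <- small_synth(lambda_mm2 = c(CD3only = 0, CD8only = 0, CD3CD8 = 0,
                                    CD68only = 0, CD163only = 0,
                                    CD68CD163 = 0, TUMOR = 0),
                     bud_mean_count = 0)
  cs <- generate_case(cfg, seed = 1)
  expect_equal(nrow(cs$slide1), 0)
  expect_equal(nrow(cs$slide2), 0)
  expect_equal(cs$truth$n_buds, 0)
})

test_that("uniform counts follow the Poisson mean", {
  # lambda = 1000 cells/mm^2 on 2x2 mm: expect 4000 +- 4 sd
  cfg <- synth_config(extent_um = c(2000, 2000), front_depth_um = 500,
                      lambda_mm2 = c(CD3only = 1000, CD8only = 0, CD3CD8 = 0,
                                     CD68only = 0, CD163only = 0,
                                     CD68CD163 = 0, TUMOR = 0),
                      bud_mean_count = 0, bud_attraction = c(CD3only = 0))
  counts <- vapply(1:5, function(s) nrow(generate_case(cfg, seed = s)$slide1), 0)
  expect_true(all(abs(counts - 4000) < 4 * sqrt(4000)))
  # expected counts scale linearly with the rate
  cfg2 <- utils::modifyList(cfg, list(lambda_mm2 = c(
    CD3only = 250, CD8only = 0, CD3CD8 = 0, CD68only = 0, CD163only = 0,
    CD68CD163 = 0, TUMOR = 0)))
  class(cfg2) <- "synth_config"
  counts2 <- vapply(1:5, function(s) nrow(generate_case(cfg2, seed = s)$slide1), 0)
  expect_equal(mean(counts2) / mean(counts), 0.25, tolerance = 0.1)
})

test_that("planted buds read back with their sizes and tight dispersion", {
  cfg <- small_synth(bud_mean_count = 10, bud_size_probs = c(0, 0, 1, 0))
  cs <- generate_case(cfg, seed = 3)
  expect_gt(cs$truth$n_buds, 0)
  expect_true(all(cs$truth$buds$n_cells == 3))
  tumor_pts <- cs$slide1[cs$slide1$phenotype == "TUMOR", c("x_um", "y_um")]
  # member cells of each planted bud lie within twice the spread radius
  for (b in seq_len(cs$truth$n_buds)) {
    d <- sqrt((tumor_pts$x_um - cs$truth$buds$x_um[b])^2 +
                (tumor_pts$y_um - cs$truth$buds$y_um[b])^2)
    expect_equal(sum(d <= 2 * cfg$bud_spread_um), 3)
  }
})

test_that("same seed gives a bit-identical case and cohort", {
  cfg <- small_synth(n_patients = 3L, seed = 9L)
  a <- generate_case(cfg, seed = 77)
  b <- generate_case(cfg, seed = 77)
  expect_identical(a$slide1, b$slide1)
  expect_identical(a$truth$buds, b$truth$buds)
  ca <- generate_cohort(cfg)
  cb <- generate_cohort(cfg)
  expect_identical(ca$survival, cb$survival)
  expect_identical(ca$features, cb$features)
})

test_that("noiseless intensities invert exactly through the classifier", {
  cfg <- small_synth(seed = 10L)
  cs <- generate_case(cfg, seed = 5)
  s1 <- generate_intensities(cs$slide1, "lymphocyte", noise_sd = 0)
  got <- classify_lymphocyte(s1)
  want <- ifelse(s1$phenotype %in% c("CD3only", "CD8only", "CD3CD8"),
                 s1$phenotype, "negative")
  expect_identical(got, want)
  expect_identical(classify_tumor(s1), s1$phenotype == "TUMOR")
  # a cell with no markers stays below every threshold
  neg <- s1[got == "negative", ]
  th <- threshold_set()$lymphocyte
  expect_true(all(neg$nucleus_FITC < th$nucleus[["FITC"]]))
  expect_true(all(neg$nucleus_Cy5 < th$nucleus[["Cy5"]]))
  expect_error(generate_intensities(cs$slide1, "lymphocyte", noise_sd = -1),
               "nonnegative")
})

test_that("phenotype recovery error is monotone in the intensity noise", {
  cfg <- small_synth(seed = 11L)
  cs <- generate_case(cfg, seed = 6)
  errs <- vapply(c(0, 0.05, 0.15, 0.4), function(sd) {
    set.seed(99)
    s1 <- generate_intensities(cs$slide1, "lymphocyte", noise_sd = sd)
    got <- classify_lymphocyte(s1)
    want <- ifelse(s1$phenotype %in% c("CD3only", "CD8only", "CD3CD8"),
                   s1$phenotype, "negative")
    mean(got != want)
  }, 0)
  expect_equal(errs[1], 0)
  expect_true(all(diff(errs) >= 0))
  expect_gt(errs[4], 0)
})

test_that("without attraction, bud-proximal lymphocytes match CSR", {
  # E[count within r of a point] = lambda * pi * r^2 / 1e6 under CSR
  lambda <- 600
  cfg <- synth_config(extent_um = c(1500, 1500), front_depth_um = 300,
                      lambda_mm2 = c(CD3only = lambda, CD8only = 0,
                                     CD3CD8 = 0, CD68only = 0, CD163only = 0,
                                     CD68CD163 = 0, TUMOR = 0),
                      bud_mean_count = 10,
                      bud_attraction = c(CD3only = 0, CD8only = 0, CD3CD8 = 0))
  means <- vapply(1:10, function(s) {
    cs <- generate_case(cfg, seed = 100 + s)
    if (cs$truth$n_buds == 0) return(NA_real_)
    lymph <- cs$slide1[cs$slide1$phenotype == "CD3only", c("x_um", "y_um")]
    mean_lymphocytes_near_buds(lymph, cs$truth$buds[, c("x_um", "y_um")], 50)
  }, 0)
  expected <- lambda * pi * 50^2 / 1e6
  expect_equal(mean(means, na.rm = TRUE), expected, tolerance = 0.15)
  # with attraction on, the mean exceeds CSR
  cfg2 <- utils::modifyList(cfg, list(bud_attraction = c(CD3only = 4)))
  class(cfg2) <- "synth_config"
  cs <- generate_case(cfg2, seed = 100)
  lymph <- cs$slide1[cs$slide1$phenotype == "CD3only", c("x_um", "y_um")]
  expect_gt(mean_lymphocytes_near_buds(lymph, cs$truth$buds[, c("x_um", "y_um")], 50),
            expected)
})

test_that("with beta = 0 survival is exponential at the baseline hazard", {
  # at n = 2000 the MLE of an exponential rate (events / total exposure
  # before the horizon) recovers h0 within 10%
  co <- generate_feature_cohort(n = 2000, beta = c(den_CD3_IMCT = 0),
                                h0 = 0.004, horizon_months = 120, seed = 13)
  rate_hat <- sum(co$survival$event) / sum(co$survival$time_months)
  expect_equal(rate_hat, 0.004, tolerance = 0.1)
})

test_that("a strong planted effect is recovered by univariate Cox", {
  hits <- 0
  for (s in 1:20) {
    co <- generate_feature_cohort(n = 300, beta = c(den_CD3_IMCT = -0.7),
                                  n_noise = 0, seed = 600 + s)
    z <- scale(co$features$den_CD3_IMCT)[, 1]
    fit <- cox_univariate(z, co$survival)
    if (fit$ci_lower <= exp(-0.7) && exp(-0.7) <= fit$ci_upper) hits <- hits + 1
  }
  expect_gte(hits, 17)  # ~95% nominal coverage over 20 replicates
})

test_that("a tiny horizon censors every record", {
  co <- generate_feature_cohort(n = 50, horizon_months = 0.001, seed = 14)
  expect_equal(sum(co$survival$event), 0)
})

test_that("unknown feature names in beta are rejected with the known list", {
  cfg <- small_synth(beta = c(not_a_feature = 1))
  expect_error(generate_cohort(cfg), "feature_catalog")
})
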