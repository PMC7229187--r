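# Synthetic cohort generator. Emulates the structures the pipeline
# consumes: a rectangular tissue with a straight or sinusoidal invasive
# front separating stroma (above) from tumor (below, in image-space y),
# marker-typed cell point patterns (homogeneous Poisson for immune classes,
# a Thomas cluster process for the tumor mass), planted tumor buds of 1-4
# cells inside the TBROI with an enforced clearance from all other tumor
# cells (so bud recovery is exactly testable), an optional excess of
# lymphocytes within the attraction radius of buds, compartment dye
# intensities consistent with the classification thresholds, a known
# similarity transform between the two serial-slide frames, and
# disease-specific survival drawn from an exponential proportional-hazards
# model whose log-hazard depends on planted spatial features.

#' Synthetic cohort configuration
#'
#' Defaults define the package's reference study conditions (rationale in
#' the methods vignette): 1.5 x 1.5 mm tissue, sinusoidal front, disjoint
#' phenotype intensities chosen so the reporting-class medians sit near the
#' published cutoffs, exponential baseline hazard 0.0012/month over an
#' 11.8-year horizon (~15% disease-specific deaths), and per-patient
#' log-normal density multipliers that carry the planted prognostic
#' structure.
#'
#' @param ... Overrides of the defaults (unknown names are an error).
#' @return A `synth_config` list.
#' @export
synth_config <- function(...) {
  cfg <- list(
    n_patients = 113L,
    extent_um = c(1500, 1500),
    front_depth_um = 400,
    front_shape = "sinusoidal",      # or "straight"
    front_amplitude_um = 100,
    front_period_um = 750,
    # cells/mm^2 for the DISJOINT phenotype classes
    lambda_mm2 = c(CD3only = 220, CD8only = 90, CD3CD8 = 150,
                   CD68only = 80, CD163only = 90, CD68CD163 = 50,
                   TUMOR = 1200),
    tumor_process = "nests",         # dense uniform nests, or "uniform"
    tumor_nest_mm2 = 8,              # tumor nests (glands) per mm^2
    tumor_nest_radius_um = 60,
    bud_mean_count = 12,
    bud_size_probs = c(0.35, 0.30, 0.20, 0.15),
    bud_spread_um = 6,
    bud_clearance_um = 60,
    bud_attraction = c(CD3only = 1.0, CD8only = 0.5, CD3CD8 = 2.5),
    attraction_radius_um = 50,
    patient_sd = 0.5,                # log-sd of per-patient multipliers
    ratio_sd = 0.45,                 # log-sd of the CD68 vs CD163 tilt
    slide_jitter_um = 1.5,
    transform_rot_sd_deg = 2,
    transform_trans_sd_um = 150,
    transform_scale_sd = 0.01,
    intensity_margin = 0.1,
    intensity_noise_sd = 0.02,
    h0_per_month = 0.0012,
    beta = c(den_CD3_IMCT = -0.65, prox_CD3CD8_TB_50 = -0.60,
             ratio_CD68_CD163_CT = 0.55),
    beta_pt = 0.6,
    pt4_prob = 0.23,
    horizon_months = 141.6,
    uniform_censor_frac = 0.15,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown synth_config fields: ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, over)
  if (any(cfg$extent_um <= 0)) stop("config error: nonpositive tissue extent")
  if (any(cfg$lambda_mm2 < 0) || cfg$bud_mean_count < 0) {
    stop("config error: rates must be nonnegative")
  }
  if (cfg$horizon_months <= 0) stop("config error: horizon must be positive")
  class(cfg) <- "synth_config"
  cfg
}

# Invasive-front polyline and tumor polygon for the configured shape.
synth_geometry <- function(cfg) {
  W <- cfg$extent_um[1]
  H <- cfg$extent_um[2]
  if (cfg$front_shape == "straight") {
    front <- cbind(c(0, W), c(cfg$front_depth_um, cfg$front_depth_um))
  } else {
    x <- seq(0, W, length.out = max(41L, ceiling(W / 25)))
    y <- cfg$front_depth_um +
      cfg$front_amplitude_um * sin(2 * pi * x / cfg$front_period_um)
    front <- cbind(x, y)
  }
  # tumor occupies the deep side of the front (larger y, image convention)
  tumor <- rbind(front, c(W, H), c(0, H))
  list(front = front, tumor = tumor, extent_bbox = c(0, W, 0, H))
}

# Homogeneous Poisson points at lambda (cells/mm^2) on the extent rectangle.
rpoints_uniform <- function(lambda_mm2, extent_um) {
  area_mm2 <- prod(extent_um) / 1e6
  n <- stats::rpois(1, lambda_mm2 * area_mm2)
  cbind(stats::runif(n, 0, extent_um[1]), stats::runif(n, 0, extent_um[2]))
}

# Tumor mass as dense uniform nests (gland-like clusters) restricted to
# the tumor polygon: Poisson nest centres inside the tumor, each nest a
# uniform disc whose within-nest density is high enough that the nest is
# internally connected at the bud link distance (so small components away
# from nests are genuine buds, not sampling artefacts).
rpoints_nests_tumor <- function(lambda_mm2, nest_mm2, radius_um,
                                extent_um, tumor) {
  area_mm2 <- prod(extent_um) / 1e6
  n_nest <- stats::rpois(1, nest_mm2 * area_mm2)
  if (n_nest == 0 || lambda_mm2 == 0) return(matrix(numeric(0), ncol = 2))
  px <- stats::runif(n_nest, 0, extent_um[1])
  py <- stats::runif(n_nest, 0, extent_um[2])
  keep <- point_in_polygon(px, py, tumor)
  px <- px[keep]; py <- py[keep]
  if (!length(px)) return(matrix(numeric(0), ncol = 2))
  mu <- lambda_mm2 / nest_mm2            # mean cells per nest
  n_off <- stats::rpois(length(px), mu)
  tot <- sum(n_off)
  if (tot == 0) return(matrix(numeric(0), ncol = 2))
  cx <- rep(px, n_off)
  cy <- rep(py, n_off)
  ang <- stats::runif(tot, 0, 2 * pi)
  rad <- radius_um * sqrt(stats::runif(tot))
  x <- cx + rad * cos(ang)
  y <- cy + rad * sin(ang)
  keep <- x >= 0 & x <= extent_um[1] & y >= 0 & y <= extent_um[2] &
    point_in_polygon(x, y, tumor)
  cbind(x[keep], y[keep])
}

# Draw a random similarity transform (slide1 frame -> slide2 frame).
random_similarity <- function(cfg) {
  th <- stats::rnorm(1, 0, cfg$transform_rot_sd_deg * pi / 180)
  s <- exp(stats::rnorm(1, 0, cfg$transform_scale_sd))
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  transform2d(s * R, stats::rnorm(2, 0, cfg$transform_trans_sd_um),
              kind = "similarity")
}

#' Generate one synthetic case (tissue, two slides, planted truth)
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed for this case.
#' @param multipliers Optional named per-patient density multipliers
#'   (`lymph`, `macro`, `tilt`, `attract`, `bud`); default all 1 (used by
#'   [generate_cohort()] to plant prognostic heterogeneity).
#' @return List: `front`, `tumor`, `extent_bbox`, `slide1` / `slide2` cell
#'   data frames (slide2 in its own frame), `transform` (slide2 -> slide1),
#'   `landmarks` (paired fiducials), and `truth` (planted buds, per-class
#'   region counts, the transform, the multipliers).
#' @export
generate_case <- function(cfg = synth_config(), seed = 1L,
                          multipliers = NULL) {
  set.seed(seed)
  mult <- utils::modifyList(
    list(lymph = 1, macro = 1, tilt = 1, attract = 1, bud = 1),
    as.list(multipliers %||% list()))
  geo <- synth_geometry(cfg)
  lam <- cfg$lambda_mm2
  lam[c("CD3only", "CD8only", "CD3CD8")] <-
    lam[c("CD3only", "CD8only", "CD3CD8")] * mult$lymph
  lam[c("CD68only", "CD68CD163")] <-
    lam[c("CD68only", "CD68CD163")] * mult$macro * c(mult$tilt, 1)
  lam["CD163only"] <- lam["CD163only"] * mult$macro / mult$tilt

  # tumor mass
  tumor_xy <- if (lam["TUMOR"] == 0) {
    matrix(numeric(0), ncol = 2)
  } else if (cfg$tumor_process == "nests") {
    rpoints_nests_tumor(lam["TUMOR"], cfg$tumor_nest_mm2,
                        cfg$tumor_nest_radius_um,
                        cfg$extent_um, geo$tumor)
  } else {
    p <- rpoints_uniform(lam["TUMOR"], cfg$extent_um)
    p[point_in_polygon(p[, 1], p[, 2], geo$tumor), , drop = FALSE]
  }

  # planted buds inside the TBROI, clear of the mass and of each other
  front_d <- function(x, y) dist_to_polyline(x, y, geo$front)
  in_tbroi <- function(x, y) {
    point_in_polygon(x, y, geo$tumor) & front_d(x, y) <= cfg$tbroi_width_um %||% 1000
  }
  n_buds <- stats::rpois(1, cfg$bud_mean_count * mult$bud)
  bud_cells <- matrix(numeric(0), ncol = 2)
  truth_buds <- data.frame(x_um = numeric(0), y_um = numeric(0),
                           n_cells = integer(0))
  if (n_buds > 0) {
    centers <- matrix(numeric(0), ncol = 2)
    placed_sizes <- integer(0)
    tries <- 0L
    while (nrow(centers) < n_buds && tries < 400L * n_buds) {
      tries <- tries + 1L
      cx <- stats::runif(1, 0, cfg$extent_um[1])
      cy <- stats::runif(1, 0, cfg$extent_um[2])
      if (!in_tbroi(cx, cy)) next
      clear <- TRUE
      if (nrow(tumor_xy)) {
        clear <- min((tumor_xy[, 1] - cx)^2 + (tumor_xy[, 2] - cy)^2) >
          cfg$bud_clearance_um^2
      }
      if (clear && nrow(centers)) {
        clear <- min((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
          (2 * cfg$bud_clearance_um)^2
      }
      if (!clear) next
      centers <- rbind(centers, c(cx, cy))
      placed_sizes <- c(placed_sizes,
                        sample.int(4L, 1, prob = cfg$bud_size_probs))
    }
    if (nrow(centers)) {
      cell_list <- vector("list", nrow(centers))
      for (b in seq_len(nrow(centers))) {
        k <- placed_sizes[b]
        ang <- stats::runif(k, 0, 2 * pi)
        rad <- cfg$bud_spread_um * sqrt(stats::runif(k))
        cell_list[[b]] <- cbind(centers[b, 1] + rad * cos(ang),
                                centers[b, 2] + rad * sin(ang))
      }
      bud_cells <- do.call(rbind, cell_list)
      truth_buds <- data.frame(
        x_um = vapply(cell_list, function(m) mean(m[, 1]), 0),
        y_um = vapply(cell_list, function(m) mean(m[, 2]), 0),
        n_cells = placed_sizes)
    }
  }
  all_tumor <- rbind(tumor_xy, bud_cells)

  # immune classes: homogeneous Poisson over the whole tissue (both sides
  # of the front), plus bud-attracted lymphocytes within the attraction
  # radius of each planted bud
  immune <- list()
  for (cl in c("CD3only", "CD8only", "CD3CD8", "CD68only", "CD163only",
               "CD68CD163")) {
    immune[[cl]] <- rpoints_uniform(lam[[cl]], cfg$extent_um)
  }
  if (nrow(truth_buds) && any(cfg$bud_attraction > 0)) {
    for (cl in names(cfg$bud_attraction)) {
      rate <- cfg$bud_attraction[[cl]] * mult$attract
      if (rate <= 0) next
      n_extra <- stats::rpois(nrow(truth_buds), rate)
      tot <- sum(n_extra)
      if (tot == 0) next
      bx <- rep(truth_buds$x_um, n_extra)
      by <- rep(truth_buds$y_um, n_extra)
      ang <- stats::runif(tot, 0, 2 * pi)
      rad <- cfg$attraction_radius_um * sqrt(stats::runif(tot))
      immune[[cl]] <- rbind(immune[[cl]],
                            cbind(bx + rad * cos(ang), by + rad * sin(ang)))
    }
  }

  mk_cells <- function(classes, prefix) {
    parts <- lapply(classes, function(cl) {
      m <- immune[[cl]]
      if (is.null(m) || nrow(m) == 0) return(NULL)
      data.frame(x_um = m[, 1], y_um = m[, 2], phenotype = cl,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, c(parts, list(NULL)))
    if (is.null(df)) df <- data.frame(x_um = numeric(0), y_um = numeric(0),
                                      phenotype = character(0))
    df
  }
  slide1 <- mk_cells(c("CD3only", "CD8only", "CD3CD8"))
  if (nrow(all_tumor)) {
    slide1 <- rbind(slide1, data.frame(x_um = all_tumor[, 1],
                                       y_um = all_tumor[, 2],
                                       phenotype = "TUMOR"))
  }
  slide1$cell_id <- sprintf("s1_%05d", seq_len(max(1, nrow(slide1)))[seq_len(nrow(slide1))])

  # slide 2 carries the macrophages and (serial-section) tumor cells: the
  # same tumor pattern jittered by a couple of microns, then mapped through
  # the unknown-to-the-pipeline frame transform
  slide2_frame1 <- mk_cells(c("CD68only", "CD163only", "CD68CD163"))
  if (nrow(all_tumor)) {
    jit <- matrix(stats::rnorm(2 * nrow(all_tumor), 0, cfg$slide_jitter_um),
                  ncol = 2)
    slide2_frame1 <- rbind(slide2_frame1,
                           data.frame(x_um = all_tumor[, 1] + jit[, 1],
                                      y_um = all_tumor[, 2] + jit[, 2],
                                      phenotype = "TUMOR"))
  }
  to_slide2 <- random_similarity(cfg)
  slide2 <- apply_transform(slide2_frame1, to_slide2)
  slide2$cell_id <- sprintf("s2_%05d", seq_len(max(1, nrow(slide2)))[seq_len(nrow(slide2))])
  transform_to_frame1 <- invert_transform(to_slide2)

  W <- cfg$extent_um[1]; H <- cfg$extent_um[2]
  fixed_landmarks <- rbind(c(0, 0), c(W, 0), c(W, H), c(0, H))
  moving_landmarks <- apply_transform(fixed_landmarks, to_slide2)

  regions <- build_regions(geo$tumor, geo$front, extent_bbox = geo$extent_bbox)
  count_by_region <- function(df) {
    if (!nrow(df)) return(NULL)
    m <- assign_region(df, regions)
    rowsum(m + 0L, df$phenotype)
  }
  truth <- list(
    buds = truth_buds,
    n_buds = nrow(truth_buds),
    transform_to_frame1 = transform_to_frame1,
    multipliers = mult,
    counts_slide1 = count_by_region(slide1),
    counts_slide2 = count_by_region(slide2_frame1)
  )
  list(front = geo$front, tumor = geo$tumor, extent_bbox = geo$extent_bbox,
       slide1 = slide1, slide2 = slide2,
       landmarks = list(moving = moving_landmarks, fixed = fixed_landmarks),
       transform = transform_to_frame1, regions = regions, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Add compartment intensities consistent with the thresholds
#'
#' For each marker a cell carries, the designated channel's compartment
#' intensities are drawn `margin` above the classification threshold (plus
#' truncated Gaussian noise); channels the cell lacks are drawn below.
#' With `noise_sd = 0` the classification stage recovers the phenotypes
#' with zero errors; increasing noise produces a non-decreasing error rate.
#'
#' @param cells Cell data frame with a `phenotype` column.
#' @param slide `"lymphocyte"` or `"macrophage"`.
#' @param thresholds A [threshold_set()].
#' @param margin Offset from each threshold (default 0.1).
#' @param noise_sd Gaussian noise SD (>= 0), truncated so intensities stay
#'   nonnegative.
#' @return The cell table with the seven intensity columns filled in.
#' @export
generate_intensities <- function(cells, slide = c("lymphocyte", "macrophage"),
                                 thresholds = threshold_set(), margin = 0.1,
                                 noise_sd = 0.02) {
  slide <- match.arg(slide)
  if (noise_sd < 0) stop("config error: noise_sd must be nonnegative")
  n <- nrow(cells)
  th <- thresholds[[slide]]
  pos_fitc <- cells$phenotype %in% if (slide == "lymphocyte")
    c("CD3only", "CD3CD8") else c("CD68only", "CD68CD163")
  pos_cy5 <- cells$phenotype %in% if (slide == "lymphocyte")
    c("CD8only", "CD3CD8") else c("CD163only", "CD68CD163")
  draw <- function(base) pmax(0, base + stats::rnorm(n, 0, noise_sd))
  for (comp in c("nucleus", "cytoplasm", "membrane")) {
    for (ch in c("FITC", "Cy5")) {
      pos <- if (ch == "FITC") pos_fitc else pos_cy5
      t0 <- th[[comp]][[ch]]
      base <- ifelse(pos, t0 + margin, pmax(0, t0 - margin) * 0.5)
      cells[[paste0(comp, "_", ch)]] <- draw(base)
    }
  }
  pck_pos <- cells$phenotype == "TUMOR"
  t0 <- thresholds$pck_cell_threshold
  cells$cytoplasm_CY3_PCK <- draw(ifelse(pck_pos, t0 + margin,
                                         pmax(0, t0 - margin) * 0.5))
  cells
}

#' Generate a synthetic cohort with planted prognostic structure
#'
#' Per patient, log-normal multipliers perturb the lymphocyte densities,
#' the macrophage CD68/CD163 tilt, the bud-attraction strength and the bud
#' rate; the true feature vector is computed from the planted geometry
#' with the package's own spatial statistics; features named in `beta` are
#' z-scored across the cohort and survival times are drawn from
#' `h(t) = h0 * exp(beta' z + beta_pt * pT4)` (exponential baseline), with
#' administrative censoring at the horizon plus independent uniform
#' censoring.
#'
#' @param cfg A [synth_config()].
#' @param with_intensities Also draw dye intensities (default TRUE), so the
#'   classification stage is exercised downstream.
#' @return List: `cases` (named by patient id), `survival` (data frame,
#'   includes `pt_stage`), `features` (true feature table), `truth`
#'   (multipliers, beta, linear predictors).
#' @export
generate_cohort <- function(cfg = synth_config(), with_intensities = TRUE) {
  unknown <- setdiff(names(cfg$beta), feature_catalog())
  if (length(unknown)) {
    stop("config error: unknown feature name(s) in beta: ",
         paste(unknown, collapse = ", "),
         " (known features: see feature_catalog())")
  }
  set.seed(cfg$seed)
  n <- cfg$n_patients
  mults <- data.frame(
    lymph = exp(stats::rnorm(n, 0, cfg$patient_sd)),
    macro = exp(stats::rnorm(n, 0, cfg$patient_sd / 2)),
    tilt = exp(stats::rnorm(n, 0, cfg$ratio_sd)),
    attract = exp(stats::rnorm(n, 0, cfg$patient_sd * 1.6)),
    bud = exp(stats::rnorm(n, 0, cfg$patient_sd / 2))
  )
  pt4 <- stats::rbinom(n, 1, cfg$pt4_prob)
  case_seeds <- sample.int(2^31 - 1, n)
  surv_seed <- sample.int(2^31 - 1, 1)
  ids <- sprintf("P%03d", seq_len(n))
  cases <- vector("list", n)
  names(cases) <- ids
  feats <- vector("list", n)
  names(feats) <- ids
  for (i in seq_len(n)) {
    cs <- generate_case(cfg, seed = case_seeds[i],
                        multipliers = as.list(mults[i, ]))
    tumor_pts <- cs$slide1[cs$slide1$phenotype == "TUMOR",
                           c("x_um", "y_um"), drop = FALSE]
    buds <- detect_buds(tumor_pts, cs$regions)
    feats[[i]] <- compute_case_features(
      cs$slide1,
      apply_transform(cs$slide2, cs$transform),
      cs$regions, buds)
    if (with_intensities) {
      cs$slide1 <- generate_intensities(cs$slide1, "lymphocyte",
                                        noise_sd = cfg$intensity_noise_sd,
                                        margin = cfg$intensity_margin)
      cs$slide2 <- generate_intensities(cs$slide2, "macrophage",
                                        noise_sd = cfg$intensity_noise_sd,
                                        margin = cfg$intensity_margin)
    }
    cs$regions <- NULL   # the pipeline rebuilds regions from the geometry
    cases[[i]] <- cs
  }
  ftab <- build_feature_table(feats)
  set.seed(surv_seed)
  Z <- as.matrix(ftab[, names(cfg$beta), drop = FALSE])
  for (j in seq_len(ncol(Z))) {
    z <- Z[, j]
    z[!is.finite(z)] <- stats::median(z[is.finite(z)])
    Z[, j] <- (z - mean(z)) / stats::sd(z)
  }
  lp <- as.numeric(Z %*% cfg$beta) + cfg$beta_pt * pt4
  t_event <- stats::rexp(n, rate = cfg$h0_per_month * exp(lp))
  c_admin <- rep(cfg$horizon_months, n)
  c_unif <- ifelse(stats::runif(n) < cfg$uniform_censor_frac,
                   stats::runif(n, 0, cfg$horizon_months), Inf)
  cens <- pmin(c_admin, c_unif)
  time <- pmin(t_event, cens)
  event <- as.integer(t_event <= cens)
  time <- pmax(time, 1e-3)
  survival <- data.frame(patient_id = ids, time_months = time, event = event,
                         pt_stage = ifelse(pt4 == 1, "pT4", "pT3"),
                         stringsAsFactors = FALSE)
  list(cases = cases, survival = survival, features = ftab,
       truth = list(multipliers = mults, beta = cfg$beta, lp = lp,
                    pt4 = pt4))
}

#' Generate a feature-level cohort for selection-chain batteries
#'
#' Draws patient feature vectors directly — the three SIOI-structure
#' features with realistic marginals (log-normal CD3 density around the
#' published cutoff scale, gamma bud-proximal lymphocyte counts, log-normal
#' macrophage ratio) plus independent log-normal noise features — and
#' exponential proportional-hazards survival from the standardized planted
#' features. Used for the planted-recovery and end-to-end index batteries,
#' where the spatial point patterns themselves are not under test.
#'
#' @param n Patients.
#' @param beta Named log-HR (per SD) over the planted features; names must
#'   be among the generated columns.
#' @param n_noise Number of noise features (default 20).
#' @param h0 Baseline hazard per month (default 0.004).
#' @param horizon_months Administrative censoring horizon (default 120).
#' @param seed Seed.
#' @return List: `features` (data frame), `survival`, `planted` (names).
#' @export
generate_feature_cohort <- function(n = 300,
                                    beta = c(den_CD3_IMCT = -0.7,
                                             prox_CD3CD8_TB_50 = -0.7,
                                             ratio_CD68_CD163_CT = 0.7),
                                    n_noise = 20, h0 = 0.004,
                                    horizon_months = 120, seed = 1L) {
  set.seed(seed)
  X <- data.frame(
    den_CD3_IMCT = stats::rlnorm(n, log(390), 0.5),
    prox_CD3CD8_TB_50 = stats::rgamma(n, shape = 2, scale = 2),
    ratio_CD68_CD163_CT = stats::rlnorm(n, log(1.0), 0.4)
  )
  if (n_noise > 0) {
    for (j in seq_len(n_noise)) {
      X[[sprintf("noise_%02d", j)]] <- stats::rlnorm(n, log(100), 0.5)
    }
  }
  miss <- setdiff(names(beta), names(X))
  if (length(miss)) stop("beta names not generated: ", paste(miss, collapse = ", "))
  Z <- scale(as.matrix(X[, names(beta), drop = FALSE]))
  lp <- as.numeric(Z %*% beta)
  t_event <- stats::rexp(n, rate = h0 * exp(lp))
  time <- pmin(t_event, horizon_months)
  event <- as.integer(t_event <= horizon_months)
  survival <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                         time_months = pmax(time, 1e-3), event = event,
                         stringsAsFactors = FALSE)
  list(features = X, survival = survival, planted = names(beta))
}
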