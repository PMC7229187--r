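# Region-resolved densities, macrophage ratios, proximity features and the
# Spearman matrix. Reporting marker classes are unions of the disjoint
# phenotype labels: CD3+ = CD3only + CD3CD8, CD8+ = CD8only + CD3CD8,
# CD68+ = CD68only + CD68CD163, CD163+ = CD163only + CD68CD163, and
# CD68+CD163- = CD68only. Distances are Euclidean and the radius boundary
# is inclusive ("within 0-50 um" counts a source exactly at 50 um).

REPORTING_CLASSES <- list(
  CD3 = c("CD3only", "CD3CD8"),
  CD8 = c("CD8only", "CD3CD8"),
  CD3CD8 = "CD3CD8",
  CD68 = c("CD68only", "CD68CD163"),
  CD163 = c("CD163only", "CD68CD163"),
  CD68_CD163neg = "CD68only"
)

DENSITY_CLASSES <- c("CD3", "CD8", "CD3CD8", "CD68", "CD163", "CD68_CD163neg")
MACRO_CLASSES <- c("CD68", "CD163", "CD68_CD163neg")
LYMPH_CLASSES <- c("CD3", "CD8", "CD3CD8")
REGIONS <- c("IM", "CT", "IMCT")

#' The fixed feature catalog
#'
#' Densities for six marker classes in IM/CT/IMCT (18), the tumor-bud
#' count (1), the CD68+/CD163+ ratio per region (3), mean counts of each
#' macrophage class within 50 and 100 um of TBs, CD3+ and CD8+ cells (18),
#' and mean counts of CD3+, CD8+ and CD3+CD8+ lymphocytes within 50 um of
#' TBs (3): 43 named image-based features in a fixed order.
#'
#' @return Character vector of feature names.
#' @export
feature_catalog <- function() {
  dens <- paste0("den_", rep(DENSITY_CLASSES, each = 3), "_", REGIONS)
  ratios <- paste0("ratio_CD68_CD163_", REGIONS)
  prox <- as.vector(outer(
    paste0("prox_", rep(MACRO_CLASSES, each = 3), "_", c("TB", "CD3", "CD8")),
    c(50, 100), paste, sep = "_"))
  lymph_tb <- paste0("prox_", LYMPH_CLASSES, "_TB_50")
  c(dens, "tb_count", ratios, prox, lymph_tb)
}

#' Density of points inside a region
#'
#' @param points Point coordinates of one phenotype class.
#' @param region_contains Membership function `f(x, y)` (e.g. a
#'   `region_set` predicate), or NULL to count all points.
#' @param area_mm2 Region area in mm^2; a zero/invalid area yields `NA`
#'   (an undefined density is a missing feature, never 0).
#' @return Density in cells/mm^2.
#' @export
cell_density <- function(points, region_contains, area_mm2) {
  if (!is.finite(area_mm2) || area_mm2 <= 0) return(NA_real_)
  xy <- as_xy_matrix(points)
  n <- if (is.null(region_contains)) nrow(xy) else {
    if (nrow(xy) == 0) 0L else sum(region_contains(xy[, 1], xy[, 2]))
  }
  n / area_mm2
}

#' Per-target proximity counts
#'
#' For each target, the number of sources at Euclidean distance <= radius
#' (inclusive boundary), plus the mean over targets.
#'
#' @param sources,targets Point matrices / data frames.
#' @param radius_um Radius (> 0).
#' @return List with `counts` (integer per target) and `mean` (0 when
#'   there are targets but no sources; `NA` when there are no targets).
#' @export
proximity_count <- function(sources, targets, radius_um) {
  if (radius_um <= 0) stop("radius_um must be positive")
  counts <- count_within_radius(sources, targets, radius_um)
  list(counts = counts,
       mean = if (length(counts)) mean(counts) else NA_real_)
}

# Chunked pairwise counting: for each target row, the number of source
# rows within r (inclusive).
count_within_radius <- function(sources, targets, r) {
  src <- as_xy_matrix(sources)
  tgt <- as_xy_matrix(targets)
  nt <- nrow(tgt)
  if (nt == 0) return(integer(0))
  if (nrow(src) == 0) return(integer(nt))
  r2 <- r^2
  out <- integer(nt)
  s2 <- rowSums(src^2)
  i <- 1L
  chunk <- max(1L, floor(4e6 / nrow(src)))
  while (i <= nt) {
    j <- min(nt, i + chunk - 1L)
    Tq <- tgt[i:j, , drop = FALSE]
    d2 <- outer(rowSums(Tq^2), s2, "+") - 2 * Tq %*% t(src)
    out[i:j] <- as.integer(rowSums(d2 <= r2 + 1e-9))
    i <- j + 1L
  }
  out
}

#' Mean lymphocyte count within a radius of tumor buds
#'
#' @param lymphocytes Lymphocyte coordinates (one class).
#' @param buds Bud centroid coordinates (data frame from [detect_buds()]
#'   or a matrix).
#' @param radius_um Radius (default 50).
#' @param zero_bud_policy What to return when there are no buds:
#'   `"favorable"` (default) and `"missing"` return `NA` tagged with the
#'   policy (resolved at binarization: absent budding is the prognostically
#'   favorable state); `"zero"` returns 0.
#' @return Mean count per bud, with attribute `zero_bud` when no buds.
#' @export
mean_lymphocytes_near_buds <- function(lymphocytes, buds, radius_um = 50,
                                       zero_bud_policy = "favorable") {
  bud_xy <- if (is.data.frame(buds)) as_xy_matrix(buds) else as_xy_matrix(buds)
  if (nrow(bud_xy) == 0) {
    out <- if (zero_bud_policy == "zero") 0 else NA_real_
    attr(out, "zero_bud") <- zero_bud_policy
    return(out)
  }
  proximity_count(lymphocytes, bud_xy, radius_um)$mean
}

#' CD68+/CD163+ ratio
#'
#' @param cd68_density,cd163_density Nonnegative densities (cells/mm^2).
#' @return `cd68/cd163`; `Inf` when CD163 is absent but CD68 present (the
#'   ratio-high side of any finite cutoff); `NA` when both are 0.
#' @export
macrophage_ratio <- function(cd68_density, cd163_density) {
  if (any(c(cd68_density, cd163_density) < 0, na.rm = TRUE)) {
    stop("input error: negative density")
  }
  ifelse(is.na(cd68_density) | is.na(cd163_density), NA_real_,
         ifelse(cd163_density == 0,
                ifelse(cd68_density == 0, NA_real_, Inf),
                cd68_density / cd163_density))
}

# Coordinates of the cells in a reporting class.
class_points <- function(cells, class) {
  cells[cells$phenotype %in% REPORTING_CLASSES[[class]], c("x_um", "y_um"),
        drop = FALSE]
}

#' Compute the full feature vector for one profiled case
#'
#' @param slide1 Lymphocyte-slide cells (data frame with coordinates and a
#'   `phenotype` column over the disjoint labels).
#' @param slide2 Macrophage-slide cells, already mapped into the slide-1
#'   frame.
#' @param regions A [build_regions()] result.
#' @param buds A [detect_buds()] result.
#' @param radii_um Proximity radii (default c(50, 100)).
#' @param zero_bud_policy Policy for TB-proximity features when the case
#'   has no buds (see [mean_lymphocytes_near_buds()]).
#' @return Named numeric vector over [feature_catalog()], with attribute
#'   `zero_bud` (TRUE/FALSE).
#' @export
compute_case_features <- function(slide1, slide2, regions, buds,
                                  radii_um = c(50, 100),
                                  zero_bud_policy = "favorable") {
  feats <- stats::setNames(rep(NA_real_, length(feature_catalog())),
                           feature_catalog())
  pts <- c(lapply(stats::setNames(nm = LYMPH_CLASSES), class_points,
                  cells = slide1),
           lapply(stats::setNames(nm = MACRO_CLASSES), class_points,
                  cells = slide2))
  memb <- lapply(pts, assign_region, regions = regions)
  for (cl in DENSITY_CLASSES) {
    for (rg in REGIONS) {
      a <- regions$areas_mm2[[rg]]
      feats[paste0("den_", cl, "_", rg)] <-
        if (!is.finite(a) || a <= 0) NA_real_ else sum(memb[[cl]][, rg]) / a
    }
  }
  feats["tb_count"] <- buds$n_buds
  for (rg in REGIONS) {
    feats[paste0("ratio_CD68_CD163_", rg)] <- macrophage_ratio(
      feats[paste0("den_CD68_", rg)], feats[paste0("den_CD163_", rg)])
  }
  bud_xy <- as_xy_matrix(buds$buds)
  zero_bud <- nrow(bud_xy) == 0
  targets <- list(TB = bud_xy,
                  CD3 = as_xy_matrix(pts$CD3),
                  CD8 = as_xy_matrix(pts$CD8))
  for (src in MACRO_CLASSES) {
    for (tg in names(targets)) {
      for (r in radii_um) {
        nm <- paste0("prox_", src, "_", tg, "_", r)
        if (!nm %in% names(feats)) next
        if (tg == "TB" && zero_bud) {
          feats[nm] <- if (zero_bud_policy == "zero") 0 else NA_real_
        } else {
          feats[nm] <- proximity_count(pts[[src]], targets[[tg]], r)$mean
        }
      }
    }
  }
  for (src in LYMPH_CLASSES) {
    nm <- paste0("prox_", src, "_TB_50")
    if (zero_bud) {
      feats[nm] <- if (zero_bud_policy == "zero") 0 else NA_real_
    } else {
      feats[nm] <- proximity_count(pts[[src]], bud_xy, 50)$mean
    }
  }
  attr(feats, "zero_bud") <- zero_bud
  feats
}

#' Assemble the patient-by-feature table
#'
#' @param case_features Named list (patient id -> feature vector from
#'   [compute_case_features()]).
#' @return Data frame with `patient_id`, one column per catalog feature, a
#'   logical `zero_bud` column, and the catalog as attribute `catalog`.
#' @export
build_feature_table <- function(case_features) {
  ids <- names(case_features)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("case_features must be a named list with unique patient ids")
  }
  mat <- do.call(rbind, lapply(case_features, function(f) f[feature_catalog()]))
  out <- data.frame(patient_id = ids, mat, check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$zero_bud <- vapply(case_features, function(f)
    isTRUE(attr(f, "zero_bud")), logical(1))
  attr(out, "catalog") <- feature_catalog()
  out
}

#' Spearman correlation matrix of a feature table
#'
#' Spearman r with average ranks for ties; pairs involving a constant
#' column are flagged (returned as `NA` and listed in the
#' `undefined_columns` attribute) rather than silently propagated.
#'
#' @param table Feature table (data frame) or numeric matrix.
#' @param columns Columns to use (default: all numeric feature columns).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(table, columns = NULL) {
  if (is.data.frame(table)) {
    num <- vapply(table, is.numeric, logical(1))
    X <- as.matrix(table[, num, drop = FALSE])
  } else {
    X <- as.matrix(table)
  }
  if (!is.null(columns)) {
    miss <- setdiff(columns, colnames(X))
    if (length(miss)) stop("unknown columns: ", paste(miss, collapse = ", "))
    X <- X[, columns, drop = FALSE]
  }
  if (nrow(X) < 3) stop("spearman_matrix needs at least 3 rows")
  const <- apply(X, 2, function(v) {
    v <- v[is.finite(v)]
    length(v) == 0 || max(v) == min(v)
  })
  r <- suppressWarnings(stats::cor(X, method = "spearman",
                                   use = "pairwise.complete.obs"))
  r[const, ] <- NA_real_
  r[, const] <- NA_real_
  diag(r) <- 1
  attr(r, "undefined_columns") <- colnames(X)[const]
  r
}
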