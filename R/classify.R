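# Phenotype assignment from compartment dye intensities. Classification is
# threshold-based: a channel (FITC or Cy5) is called positive when the
# configured combination of its nucleus / cytoplasm / membrane exceedances
# holds. The published protocol lists the three compartment thresholds but
# not the combination rule, so the rule is configurable; the default calls
# a channel positive when ANY compartment strictly exceeds its threshold.
# All comparisons are strict: a value exactly at a threshold is negative.

#' Marker intensity thresholds
#'
#' Defaults are the published fixed thresholds: lymphocyte slide nucleus
#' FITC 0.15 / Cy5 0.132; macrophage slide nucleus FITC 0.200 / Cy5 0.132;
#' cytoplasm 0.5 (FITC) / 0.075 (Cy5) and membrane 0.5 / 0.075 on both
#' slides; slide-level PCK dichotomization threshold 2.16e-2. The per-cell
#' PCK positivity threshold used to identify tumor cells from the CY3
#' channel is pipeline plumbing (the published workflow segments tumor at
#' the pixel level) and defaults to 0.1.
#'
#' @param lymphocyte,macrophage Per-slide lists with `nucleus`, `cytoplasm`,
#'   `membrane`, each a named vector with `FITC` and `Cy5` entries.
#' @param pck_slide_threshold Mean-slide-intensity threshold for the
#'   low/high PCK dichotomization.
#' @param pck_cell_threshold Per-cell CY3_PCK positivity threshold.
#' @return A `threshold_set` list.
#' @export
threshold_set <- function(
    lymphocyte = list(nucleus   = c(FITC = 0.15, Cy5 = 0.132),
                      cytoplasm = c(FITC = 0.5,  Cy5 = 0.075),
                      membrane  = c(FITC = 0.5,  Cy5 = 0.075)),
    macrophage = list(nucleus   = c(FITC = 0.200, Cy5 = 0.132),
                      cytoplasm = c(FITC = 0.500, Cy5 = 0.075),
                      membrane  = c(FITC = 0.500, Cy5 = 0.075)),
    pck_slide_threshold = 2.16e-2,
    pck_cell_threshold = 0.1) {
  t <- list(lymphocyte = lymphocyte, macrophage = macrophage,
            pck_slide_threshold = pck_slide_threshold,
            pck_cell_threshold = pck_cell_threshold)
  vals <- unlist(t)
  if (any(vals < 0)) stop("all thresholds must be nonnegative")
  class(t) <- "threshold_set"
  t
}

# TRUE where the channel is positive under `rule`.
channel_positive <- function(cells, channel, slide_thresholds, rule) {
  comp <- c("nucleus", "cytoplasm", "membrane")
  cols <- paste0(comp, "_", channel)
  miss <- setdiff(cols, names(cells))
  if (length(miss)) {
    stop(sprintf("input error: missing compartment intensity column '%s'",
                 miss[1]))
  }
  ex <- vapply(comp, function(cp) {
    v <- cells[[paste0(cp, "_", channel)]]
    if (anyNA(v)) {
      bad <- cells$cell_id[which(is.na(v))[1]]
      stop(sprintf("input error: missing %s %s intensity for cell '%s'",
                   cp, channel, bad))
    }
    v > slide_thresholds[[cp]][[channel]]
  }, logical(nrow(cells)))
  ex <- matrix(ex, nrow = nrow(cells))
  switch(rule,
         any = ex[, 1] | ex[, 2] | ex[, 3],
         nucleus = ex[, 1],
         cyto_and_membrane = ex[, 2] & ex[, 3],
         stop("unknown positivity rule: ", rule))
}

#' Classify lymphocyte-slide cells
#'
#' FITC carries CD3 and Cy5 carries CD8; colocalization (both channels
#' positive) is the CD3+CD8+ class.
#'
#' @param cells Cell data frame with the six compartment intensity columns.
#' @param thresholds A [threshold_set()].
#' @param rule Channel positivity rule: `"any"` (default), `"nucleus"`, or
#'   `"cyto_and_membrane"`.
#' @return Character vector over `{"CD3only", "CD8only", "CD3CD8",
#'   "negative"}` — i.e. CD3+CD8-, CD3-CD8+, CD3+CD8+, double-negative.
#' @export
classify_lymphocyte <- function(cells, thresholds = threshold_set(),
                                rule = "any") {
  cd3 <- channel_positive(cells, "FITC", thresholds$lymphocyte, rule)
  cd8 <- channel_positive(cells, "Cy5", thresholds$lymphocyte, rule)
  out <- rep("negative", nrow(cells))
  out[cd3 & !cd8] <- "CD3only"
  out[!cd3 & cd8] <- "CD8only"
  out[cd3 & cd8] <- "CD3CD8"
  out
}

#' Classify macrophage-slide cells
#'
#' FITC carries CD68 and Cy5 carries CD163 (nucleus FITC threshold 0.200 on
#' this slide). Double positives count toward both the CD68+ and CD163+
#' reporting totals; CD68+CD163- is its own reporting class.
#'
#' @inheritParams classify_lymphocyte
#' @return Character vector over `{"CD68only", "CD163only", "CD68CD163",
#'   "negative"}`.
#' @export
classify_macrophage <- function(cells, thresholds = threshold_set(),
                                rule = "any") {
  cd68 <- channel_positive(cells, "FITC", thresholds$macrophage, rule)
  cd163 <- channel_positive(cells, "Cy5", thresholds$macrophage, rule)
  out <- rep("negative", nrow(cells))
  out[cd68 & !cd163] <- "CD68only"
  out[!cd68 & cd163] <- "CD163only"
  out[cd68 & cd163] <- "CD68CD163"
  out
}

#' Classify tumor (PCK+) cells from the CY3 channel
#'
#' @param cells Cell data frame with a `cytoplasm_CY3_PCK` column.
#' @param thresholds A [threshold_set()].
#' @return Logical vector (TRUE = PCK-positive tumor cell).
#' @export
classify_tumor <- function(cells, thresholds = threshold_set()) {
  if (!"cytoplasm_CY3_PCK" %in% names(cells)) {
    stop("input error: missing compartment intensity column 'cytoplasm_CY3_PCK'")
  }
  cells$cytoplasm_CY3_PCK > thresholds$pck_cell_threshold
}

#' Dichotomize a slide by its mean PCK intensity
#'
#' @param mean_slide_pck_intensity Mean CY3_PCK intensity over the slide.
#' @param threshold Dichotomization threshold (default 2.16e-2).
#' @return `"high"` iff the intensity strictly exceeds the threshold, else
#'   `"low"` (the boundary value is assigned to `"low"`).
#' @export
dichotomize_pck <- function(mean_slide_pck_intensity, threshold = 2.16e-2) {
  if (any(mean_slide_pck_intensity < 0)) {
    stop("input error: negative PCK intensity")
  }
  ifelse(mean_slide_pck_intensity > threshold, "high", "low")
}

#' Tumor mask from a supplied polygon or PCK+ centroids
#'
#' The published workflow segments tumor from stroma with pixel-level
#' classifiers; here the tumor mask is either a user-supplied polygon
#' (preferred, passed through unchanged) or the union of discs of radius
#' `buffer_um` around PCK+ cell centroids.
#'
#' @param polygon Optional tumor polygon (vertex matrix); returned as-is.
#' @param pck_centroids Optional matrix / data frame of PCK+ cell centroids.
#' @param buffer_um Disc radius for centroid mode (default 20).
#' @return A `tumor_mask` with `$contains(x, y)` membership and
#'   `$area_um2(coarse_um, fine_um)` for centroid-mode masks; polygon mode
#'   wraps the polygon.
#' @export
tumor_mask_from_pck <- function(polygon = NULL, pck_centroids = NULL,
                                buffer_um = 20) {
  if (!is.null(polygon)) {
    poly <- as_xy_matrix(polygon)
    return(structure(list(
      kind = "polygon", polygon = poly,
      contains = function(x, y) point_in_polygon(x, y, poly),
      area_um2 = function(...) polygon_area(poly)
    ), class = "tumor_mask"))
  }
  if (is.null(pck_centroids)) {
    stop("tumor_mask_from_pck: supply a polygon or PCK+ centroids")
  }
  ctr <- as_xy_matrix(pck_centroids)
  contains <- function(x, y) {
    if (nrow(ctr) == 0) return(rep(FALSE, length(x)))
    ok <- rep(FALSE, length(x))
    for (i in seq_len(nrow(ctr))) {
      ok <- ok | ((x - ctr[i, 1])^2 + (y - ctr[i, 2])^2 <= buffer_um^2)
    }
    ok
  }
  area_um2 <- function(coarse_um = buffer_um / 2, fine_um = buffer_um / 25) {
    if (nrow(ctr) == 0) return(0)
    bbox <- c(min(ctr[, 1]) - buffer_um, max(ctr[, 1]) + buffer_um,
              min(ctr[, 2]) - buffer_um, max(ctr[, 2]) + buffer_um)
    quad_area(contains, bbox, coarse_um = coarse_um, fine_um = fine_um)
  }
  structure(list(kind = "disc_union", centroids = ctr, buffer_um = buffer_um,
                 contains = contains, area_um2 = area_um2),
            class = "tumor_mask")
}
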