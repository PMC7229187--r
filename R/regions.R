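# Tumor-region construction. The invasive margin (IM) is a symmetric
# 500-micron band on either side of the invasive-front polyline, clipped to
# the tissue extent; the tumor core (CT) is the remaining tumor area; IMCT
# is their union; the tumor-budding region of interest (TBROI) is the
# 1000-micron band inward from the front, i.e. tumor intersect
# buffer(front, 1000) — the tumor intersection enforces "inward" without
# an oriented polyline. Regions are represented implicitly by membership
# predicates (distance-to-front + point-in-polygon, boundary inclusive);
# areas come from the shoelace formula (tumor) and adaptive quadrature
# (bands), with CT defined as tumor minus IM-inside-tumor so that
# area(IM within tumor) + area(CT) = area(tumor) holds exactly.

#' Build the IM / CT / IMCT / TBROI region set
#'
#' @param tumor_polygon Tumor polygon vertex matrix (open ring), or `NULL`
#'   / zero-area for an empty tumor (all tumor-side regions empty).
#' @param front_polyline Invasive-front polyline vertex matrix (>= 2
#'   vertices, positive length).
#' @param extent_bbox Tissue extent `c(xmin, xmax, ymin, ymax)` to which
#'   the outer half of the IM band is clipped. Defaults to the bounding box
#'   of the tumor polygon expanded by `im_half_width_um`.
#' @param im_half_width_um Half-width of the invasive margin (default 500).
#' @param tbroi_width_um Inward width of the TBROI (default 1000).
#' @param coarse_um,fine_um Quadrature resolution for band areas.
#' @return A `region_set` with `$contains(x, y, region)` predicates and
#'   `$areas_mm2` (named: IM, CT, IMCT, TBROI, tumor).
#' @export
build_regions <- function(tumor_polygon, front_polyline, extent_bbox = NULL,
                          im_half_width_um = 500, tbroi_width_um = 1000,
                          coarse_um = 50, fine_um = 5) {
  front <- as_xy_matrix(front_polyline)
  if (nrow(front) < 2 || polyline_length(front) <= 0) {
    stop("invasive front must be a polyline of positive length")
  }
  tumor <- as_xy_matrix(tumor_polygon)
  tumor_area_um2 <- polygon_area(tumor)
  has_tumor <- tumor_area_um2 > 0
  if (is.null(extent_bbox)) {
    base <- if (has_tumor) tumor else front
    extent_bbox <- c(min(base[, 1]) - im_half_width_um,
                     max(base[, 1]) + im_half_width_um,
                     min(base[, 2]) - im_half_width_um,
                     max(base[, 2]) + im_half_width_um)
  }
  if (has_tumor) {
    fr <- range(front[, 1])
    tr <- range(tumor[, 1])
    fy <- range(front[, 2])
    ty <- range(tumor[, 2])
    if (fr[1] > tr[2] || fr[2] < tr[1] || fy[1] > ty[2] || fy[2] < ty[1]) {
      warning("invasive front lies entirely outside the tumor bounding box")
    }
  }

  in_extent <- function(x, y) {
    x >= extent_bbox[1] & x <= extent_bbox[2] &
      y >= extent_bbox[3] & y <= extent_bbox[4]
  }
  in_tumor <- function(x, y) {
    if (!has_tumor) return(rep(FALSE, length(x)))
    point_in_polygon(x, y, tumor)
  }
  front_dist <- function(x, y) dist_to_polyline(x, y, front)

  pred <- list(
    IM = function(x, y) front_dist(x, y) <= im_half_width_um & in_extent(x, y),
    CT = function(x, y) in_tumor(x, y) & front_dist(x, y) > im_half_width_um,
    IMCT = NULL,  # filled below
    TBROI = function(x, y) in_tumor(x, y) & front_dist(x, y) <= tbroi_width_um
  )
  pred$IMCT <- function(x, y) pred$IM(x, y) | pred$CT(x, y)
  im_in_tumor <- function(x, y) pred$IM(x, y) & in_tumor(x, y)

  qa <- function(p, bbox) quad_area(p, bbox, coarse_um = coarse_um,
                                    fine_um = fine_um)
  band_bbox <- c(
    max(extent_bbox[1], min(front[, 1]) - tbroi_width_um),
    min(extent_bbox[2], max(front[, 1]) + tbroi_width_um),
    max(extent_bbox[3], min(front[, 2]) - tbroi_width_um),
    min(extent_bbox[4], max(front[, 2]) + tbroi_width_um)
  )
  im_bbox <- c(
    max(extent_bbox[1], min(front[, 1]) - im_half_width_um),
    min(extent_bbox[2], max(front[, 1]) + im_half_width_um),
    max(extent_bbox[3], min(front[, 2]) - im_half_width_um),
    min(extent_bbox[4], max(front[, 2]) + im_half_width_um)
  )
  area_im <- qa(pred$IM, im_bbox)
  area_im_tumor <- if (has_tumor) qa(im_in_tumor, im_bbox) else 0
  if (has_tumor && area_im_tumor == 0) {
    stop("geometry error: invasive margin does not intersect the tumor polygon")
  }
  area_ct <- if (has_tumor) tumor_area_um2 - area_im_tumor else 0
  area_tbroi <- if (has_tumor) qa(pred$TBROI, band_bbox) else 0
  # IM and CT are disjoint by construction, so area(IMCT) is their sum
  area_imct <- area_im + area_ct

  areas_mm2 <- round(c(IM = area_im, CT = area_ct, IMCT = area_imct,
                       TBROI = area_tbroi, tumor = tumor_area_um2) / 1e6, 6)
  structure(list(
    tumor = tumor, front = front, extent_bbox = extent_bbox,
    im_half_width_um = im_half_width_um, tbroi_width_um = tbroi_width_um,
    predicates = pred, areas_mm2 = areas_mm2
  ), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set> areas (mm^2):\n")
  print(x$areas_mm2)
  invisible(x)
}

#' Assign points to regions
#'
#' Multi-label membership by boundary-inclusive point-in-region tests; a
#' point gets the IMCT label iff it has the IM or the CT label. Points
#' outside all regions get an all-FALSE row.
#'
#' @param points Two-column matrix or data frame with `x_um`/`y_um`.
#' @param regions A [build_regions()] result.
#' @return Logical matrix with columns `IM`, `CT`, `IMCT`, `TBROI`.
#' @export
assign_region <- function(points, regions) {
  xy <- as_xy_matrix(points)
  out <- vapply(c("IM", "CT", "IMCT", "TBROI"),
                function(r) regions$predicates[[r]](xy[, 1], xy[, 2]),
                logical(nrow(xy)))
  if (nrow(xy) == 1L) out <- matrix(out, nrow = 1,
                                    dimnames = list(NULL, c("IM", "CT", "IMCT", "TBROI")))
  out
}
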