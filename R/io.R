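# Cohort data model and file formats. Cells, survival records and feature
# tables travel as CSV; tumor geometry as GeoJSON (coordinates in
# micrometres); reports and selection traces as JSON. Cell tables carry one
# row per cell with coordinates in micrometres, optional compartment
# intensity columns and an optional disjoint phenotype label.

# Recognised compartment x channel intensity columns. FITC carries CD3
# (lymphocyte slide) or CD68 (macrophage slide); Cy5 carries CD8 or CD163;
# CY3_PCK is the pancytokeratin (tumor cell) channel.
INTENSITY_COLUMNS <- c(
  "nucleus_FITC", "cytoplasm_FITC", "membrane_FITC",
  "nucleus_Cy5", "cytoplasm_Cy5", "membrane_Cy5",
  "cytoplasm_CY3_PCK"
)

# Disjoint phenotype labels used throughout the package. Reporting classes
# (e.g. "all CD3-positive cells") are unions of these.
PHENOTYPE_LEVELS <- c("CD3only", "CD8only", "CD3CD8",
                      "CD68only", "CD163only", "CD68CD163",
                      "TUMOR", "negative")

#' Read a per-cell table
#'
#' @param path CSV file with a header. Must contain the coordinate columns
#'   named in `schema`; unknown columns are dropped.
#' @param schema Named list mapping the standard fields `cell_id`, `x`, `y`
#'   to column names in the file. Defaults to `cell_id`, `x_um`, `y_um`.
#' @return A data frame (one row per cell, input order preserved) with
#'   columns `cell_id`, `x_um`, `y_um`, any recognised intensity columns,
#'   and `phenotype` if present.
#' @export
read_cell_table <- function(path, schema = list()) {
  schema <- utils::modifyList(
    list(cell_id = "cell_id", x = "x_um", y = "y_um"), schema)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (f in c("x", "y")) {
    if (!schema[[f]] %in% names(raw)) {
      stop(sprintf("cell table schema error: missing coordinate column '%s'",
                   schema[[f]]))
    }
  }
  out <- data.frame(row.names = NULL)
  n <- nrow(raw)
  out <- data.frame(
    cell_id = if (schema$cell_id %in% names(raw))
      as.character(raw[[schema$cell_id]]) else sprintf("cell_%d", seq_len(n)),
    stringsAsFactors = FALSE
  )
  for (f in c("x", "y")) {
    v <- raw[[schema[[f]]]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "")
    if (length(bad)) {
      stop(sprintf("cell table parse error: non-numeric %s coordinate at row %d",
                   f, bad[1]))
    }
    out[[paste0(f, "_um")]] <- num
  }
  for (col in INTENSITY_COLUMNS) {
    if (col %in% names(raw)) {
      out[[col]] <- as.numeric(raw[[col]])
      if (any(out[[col]] < 0, na.rm = TRUE)) {
        stop(sprintf("negative intensity in column '%s'", col))
      }
    }
  }
  if ("phenotype" %in% names(raw)) {
    out$phenotype <- as.character(raw$phenotype)
  }
  out
}

#' Write a per-cell table
#' @param cells Data frame from [read_cell_table()] or the generator.
#' @param path Output CSV path.
#' @export
write_cell_table <- function(cells, path) {
  keep <- intersect(c("cell_id", "x_um", "y_um", INTENSITY_COLUMNS, "phenotype"),
                    names(cells))
  utils::write.csv(cells[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read tumor geometry from GeoJSON
#'
#' Expects a FeatureCollection with a Polygon feature whose
#' `properties.role` is `"tumor"` and a LineString with role
#' `"invasive_front"`, coordinates in micrometres.
#'
#' @param path GeoJSON file path.
#' @return List with `tumor` (vertex matrix, open ring) and `front`
#'   (polyline vertex matrix).
#' @export
read_geometry <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("geometry format error: not a FeatureCollection")
  tumor <- NULL
  front <- NULL
  for (f in gj$features) {
    role <- f$properties$role
    coords <- f$geometry$coordinates
    if (identical(role, "tumor")) {
      ring <- coords[[1]]
      tumor <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    } else if (identical(role, "invasive_front")) {
      front <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    }
  }
  if (is.null(tumor) || is.null(front)) {
    stop("geometry format error: features must be role-tagged 'tumor' and 'invasive_front'")
  }
  # drop the closing vertex and any consecutive duplicates
  if (nrow(tumor) >= 2 && all(tumor[1, ] == tumor[nrow(tumor), ])) {
    tumor <- tumor[-nrow(tumor), , drop = FALSE]
  }
  dup <- c(FALSE, rowSums(abs(diff(tumor))) == 0)
  tumor <- tumor[!dup, , drop = FALSE]
  if (polygon_area(tumor) <= 0) {
    stop("geometry validation error: degenerate tumor polygon (area 0)")
  }
  if (nrow(front) < 2) {
    stop("geometry validation error: invasive front needs >= 2 vertices")
  }
  list(tumor = tumor, front = front)
}

#' Write tumor geometry to GeoJSON
#' @param tumor Polygon vertex matrix (open ring).
#' @param front Polyline vertex matrix.
#' @param path Output path.
#' @export
write_geometry <- function(tumor, front, path) {
  tumor <- as_xy_matrix(tumor)
  front <- as_xy_matrix(front)
  ring <- rbind(tumor, tumor[1, ])
  fc <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature",
           properties = list(role = "tumor", units = "um"),
           geometry = list(type = "Polygon",
                           coordinates = list(lapply(seq_len(nrow(ring)),
                                                     function(i) as.numeric(ring[i, ]))))),
      list(type = "Feature",
           properties = list(role = "invasive_front", units = "um"),
           geometry = list(type = "LineString",
                           coordinates = lapply(seq_len(nrow(front)),
                                                function(i) as.numeric(front[i, ]))))
    )
  )
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a cohort survival table
#'
#' @param path CSV with columns `patient_id`, `time_months`, `event` and
#'   any clinicopathological covariates (kept as-is).
#' @return Data frame of disease-specific survival records.
#' @export
read_survival_table <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "time_months", "event")
  miss <- setdiff(req, names(s))
  if (length(miss)) stop("survival table missing columns: ",
                         paste(miss, collapse = ", "))
  s$patient_id <- as.character(s$patient_id)
  if (anyDuplicated(s$patient_id)) {
    stop("survival validation error: duplicated patient_id '",
         s$patient_id[duplicated(s$patient_id)][1], "'")
  }
  if (any(!is.finite(s$time_months)) || any(s$time_months <= 0)) {
    stop("survival validation error: time_months must be positive")
  }
  if (!all(s$event %in% c(0, 1))) {
    stop("survival validation error: event must be 0/1")
  }
  s
}

#' Write a survival table
#' @param survival Data frame with `patient_id`, `time_months`, `event`.
#' @param path Output CSV path.
#' @export
write_survival_table <- function(survival, path) {
  utils::write.csv(survival, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a patient-by-feature table
#' @param table Data frame with `patient_id` and numeric feature columns.
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(t$patient_id)) stop("duplicated patient_id in feature table")
  t
}

#' Pipeline configuration
#'
#' Every tunable of the pipeline is a named default here, so a run's report
#' can echo the complete set of thresholds used. Defaults follow the
#' published protocol where one exists (marker intensity thresholds, 500-um
#' invasive margin, 1000-um TBROI, 50/100-um radii, 10-fold LASSO CV,
#' 500-tree forest, Gini > 3); surrogate defaults (bud link distance,
#' correlation-pruning threshold, zero-bud policy) are documented in the
#' methods vignette.
#'
#' @param ... Overrides of the defaults (unknown names are an error).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    thresholds = threshold_set(),
    positivity_rule = "any",
    im_half_width_um = 500,
    tbroi_width_um = 1000,
    proximity_radii_um = c(50, 100),
    bud_link_um = 15,
    pck_buffer_um = 20,
    area_coarse_um = 50,
    area_fine_um = 5,
    lasso_folds = 10,
    lambda_rule = "min",
    rf_trees = 500,
    gini_threshold = 3.0,
    min_components = 3,
    correlation_prune_threshold = 0.8,
    cutpoint_min_group_prop = 0.1,
    forward_entry_p = 0.05,
    zero_bud_policy = "favorable",
    refine_criterion = "wald",
    censor_horizons_months = 60,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, over)
  stopifnot(
    cfg$im_half_width_um > 0, cfg$tbroi_width_um > 0,
    all(cfg$proximity_radii_um > 0),
    !is.unsorted(cfg$proximity_radii_um),
    cfg$bud_link_um > 0,
    cfg$cutpoint_min_group_prop > 0, cfg$cutpoint_min_group_prop < 0.5,
    cfg$lasso_folds >= 2, cfg$rf_trees >= 1
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys are `pipeline_config()` fields.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$thresholds)) {
    vals$thresholds <- do.call(threshold_set, vals$thresholds)
  }
  do.call(pipeline_config, vals)
}
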