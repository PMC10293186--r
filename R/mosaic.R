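# Compositing per-unit suitability surfaces into categorical vegetation
# maps and summarizing them through time.

#' Composite per-unit suitability surfaces into one vegetation map
#'
#' Cell-by-cell analysis of the suitability maps: each cell takes the label
#' of the unit with highest suitability, provided that maximum reaches
#' `threshold`; otherwise it is assigned the no-analog class (no unit's
#' modeled probability makes the cell climatically plausible). Exact ties
#' go to the unit listed first in `order` (default: the input list order),
#' recorded in the map's provenance.
#'
#' @param surfaces named list of `suitability_surface`s, one per unit,
#'   sharing geometry and age.
#' @param threshold no-analog probability threshold (default 0.1).
#' @param order unit tie-break / priority order (default `names(surfaces)`).
#' @return A [vegetation_map()].
#' @export
composite_vegetation <- function(surfaces, threshold = 0.1, order = NULL) {
  if (length(surfaces) == 0) stopf("`surfaces` must be non-empty")
  ids <- vapply(surfaces, `[[`, character(1), "vu_id")
  if (is.null(names(surfaces))) names(surfaces) <- ids
  order <- order %||% names(surfaces)
  surfaces <- surfaces[order]
  ids <- vapply(surfaces, `[[`, character(1), "vu_id")
  geom <- surfaces[[1]]$geom
  age <- surfaces[[1]]$age_ka
  for (s in surfaces) {
    if (!same_geometry(geom, s$geom)) stopf("surface geometries differ")
    if (!isTRUE(all.equal(age, s$age_ka))) stopf("surface ages differ")
  }
  vals <- vapply(surfaces, function(s) as.vector(s$values),
                 numeric(geom$n_rows * geom$n_cols))
  vals <- matrix(vals, ncol = length(surfaces))
  best <- max.col(vals, ties.method = "first")
  lab <- ids[best]
  lab[vals[cbind(seq_len(nrow(vals)), best)] < threshold] <- no_analog_label()
  vegetation_map(matrix(lab, geom$n_rows, geom$n_cols), geom, age_ka = age,
                 threshold = threshold,
                 provenance = sprintf("%s@%g%s", ids, age,
                                      ifelse(vapply(surfaces, `[[`, logical(1),
                                                    "corrected"), ":corr", "")))
}

#' Area covered by each unit on a vegetation map
#'
#' @param vumap a [vegetation_map()].
#' @param cell_area_km2 area of one cell, km^2 (default: cell size squared).
#' @param units labels to tabulate (default: all labels on the map plus the
#'   no-analog class); absent labels report zero area.
#' @return data.frame `age_ka`, `unit`, `n_cells`, `area_km2`; unit areas
#'   plus no-analog sum to the total grid area.
#' @export
area_by_vu <- function(vumap, cell_area_km2 = vumap$geom$cell_size_km^2,
                       units = NULL) {
  if (cell_area_km2 <= 0) stopf("`cell_area_km2` must be > 0")
  units <- units %||% map_units(vumap, include_no_analog = TRUE)
  units <- union(units, no_analog_label())
  counts <- table(factor(as.vector(vumap$labels), levels = units))
  data.frame(age_ka = vumap$age_ka, unit = units,
             n_cells = as.integer(counts),
             area_km2 = as.numeric(counts) * cell_area_km2,
             stringsAsFactors = FALSE)
}

#' Elevation limits of each unit on a vegetation map
#'
#' Lower and upper limits as percentiles (default 2nd/98th, robust to
#' single-cell outliers) of the elevations of the unit's cells; `NA` for
#' units absent from the map.
#'
#' @param vumap a [vegetation_map()].
#' @param dem elevation matrix (m) on the same geometry (e.g.
#'   `stack$elevation`).
#' @param lower_pct,upper_pct percentiles in `[0, 100]`,
#'   `lower_pct < upper_pct`.
#' @param units labels to report (default: units present).
#' @return data.frame `age_ka`, `unit`, `lower_m`, `upper_m`, `lower_pct`,
#'   `upper_pct`.
#' @export
elevation_limits <- function(vumap, dem, lower_pct = 2, upper_pct = 98,
                             units = NULL) {
  if (!is.matrix(dem) || !all(dim(dem) == dim(vumap$labels))) {
    stopf("`dem` must match the map geometry")
  }
  if (lower_pct < 0 || upper_pct > 100 || lower_pct >= upper_pct) {
    stopf("need 0 <= lower_pct < upper_pct <= 100")
  }
  units <- units %||% map_units(vumap)
  lab <- as.vector(vumap$labels)
  elev <- as.vector(dem)
  lims <- t(vapply(units, function(u) {
    e <- elev[lab == u]
    if (length(e) == 0) return(c(NA_real_, NA_real_))
    stats::quantile(e, c(lower_pct, upper_pct) / 100, names = FALSE, type = 7)
  }, numeric(2)))
  data.frame(age_ka = vumap$age_ka, unit = units,
             lower_m = lims[, 1], upper_m = lims[, 2],
             lower_pct = lower_pct, upper_pct = upper_pct,
             stringsAsFactors = FALSE)
}

#' Tidy summary of areas and elevation limits across time slices
#'
#' @param areas list of [area_by_vu()] rows (one element per age).
#' @param limits optional list of [elevation_limits()] rows, same ages.
#' @return data.frame `age_ka`, `unit`, `n_cells`, `area_km2`, `lower_m`,
#'   `upper_m`, sorted oldest to youngest, complete over ages x labels.
#' @export
timeseries_summary <- function(areas, limits = NULL) {
  if (length(areas) == 0) stopf("need at least one age")
  a <- do.call(rbind, areas)
  if (!is.null(limits)) {
    l <- do.call(rbind, limits)[, c("age_ka", "unit", "lower_m", "upper_m")]
    a <- merge(a, l, by = c("age_ka", "unit"), all.x = TRUE)
  } else {
    a$lower_m <- NA_real_
    a$upper_m <- NA_real_
  }
  a <- a[order(-a$age_ka, match(a$unit, unique(a$unit))), ]
  rownames(a) <- NULL
  a
}
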