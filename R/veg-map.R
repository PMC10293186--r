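#' Label used for cells suitable for no vegetation unit
#' @return character scalar `"no_analog"`.
#' @export
no_analog_label <- function() "no_analog"

#' Categorical per-cell vegetation-unit map
#'
#' Every cell carries exactly one label: a vegetation-unit id or the
#' no-analog code for cells where all modeled suitabilities fall below the
#' threshold.
#'
#' @param labels character matrix (n_rows x n_cols) of unit labels.
#' @param geom a [grid_geometry()].
#' @param age_ka slice age (ka BP).
#' @param threshold the no-analog probability threshold used (NA if not
#'   applicable, e.g. ground-truth maps use the same rule on true suitability).
#' @param provenance character vector of input surface ids.
#' @return A `vegetation_map` object.
#' @export
vegetation_map <- function(labels, geom, age_ka = 0, threshold = NA_real_,
                           provenance = character()) {
  if (!inherits(geom, "grid_geometry")) stopf("`geom` must be a grid_geometry")
  if (!is.matrix(labels) || !is.character(labels) ||
      !all(dim(labels) == c(geom$n_rows, geom$n_cols))) {
    stopf("`labels` must be a character matrix matching the geometry")
  }
  if (anyNA(labels)) stopf("every cell must carry a label (use no_analog_label())")
  structure(list(geom = geom, age_ka = age_ka, labels = labels,
                 threshold = threshold, provenance = provenance),
            class = "vegetation_map")
}

#' @export
print.vegetation_map <- function(x, ...) {
  tab <- sort(table(x$labels), decreasing = TRUE)
  cat(sprintf("<vegetation_map> %d x %d cells, age %g ka\n",
              x$geom$n_rows, x$geom$n_cols, x$age_ka))
  print(tab)
  invisible(x)
}

#' Unit labels present on a vegetation map
#'
#' @param vumap a [vegetation_map()].
#' @param include_no_analog include the no-analog class?
#' @return character vector of labels.
#' @export
map_units <- function(vumap, include_no_analog = FALSE) {
  u <- sort(unique(as.vector(vumap$labels)))
  if (!include_no_analog) u <- setdiff(u, no_analog_label())
  u
}
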