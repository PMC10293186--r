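#' Grid geometry for raster-like objects
#'
#' All gridded objects in the package (climate stacks, suitability surfaces,
#' vegetation maps) share a simple regular-grid geometry: `n_rows` x `n_cols`
#' square cells of edge `cell_size_km`, with the grid origin (lower-left
#' corner) at `(xmin, ymin)` in km. Registration is cell-center: the center of
#' cell (row r, col c) sits at `xmin + (c - 0.5) * cell_size_km`,
#' `ymin + (r - 0.5) * cell_size_km`, with row 1 the southernmost row.
#'
#' @param n_rows,n_cols grid dimensions in cells.
#' @param cell_size_km cell edge length (km).
#' @param xmin,ymin coordinates of the grid's lower-left corner (km).
#' @return A `grid_geometry` list.
#' @export
grid_geometry <- function(n_rows, n_cols, cell_size_km, xmin = 0, ymin = 0) {
  assert_scalar_number(n_rows, "n_rows", positive = TRUE)
  assert_scalar_number(n_cols, "n_cols", positive = TRUE)
  assert_scalar_number(cell_size_km, "cell_size_km", positive = TRUE)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size_km = cell_size_km, xmin = xmin, ymin = ymin),
    class = "grid_geometry"
  )
}

same_geometry <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size_km - b$cell_size_km) < tol &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol
}

#' Cell-center coordinates of every grid cell
#'
#' Cells are indexed column-major (index = (col - 1) * n_rows + row), matching
#' the layout of the layer matrices.
#'
#' @param geom a [grid_geometry()].
#' @return data.frame with columns `cell`, `row`, `col`, `x`, `y` (km).
#' @export
cell_centers <- function(geom) {
  row <- rep(seq_len(geom$n_rows), times = geom$n_cols)
  col <- rep(seq_len(geom$n_cols), each = geom$n_rows)
  data.frame(
    cell = seq_len(geom$n_rows * geom$n_cols), row = row, col = col,
    x = geom$xmin + (col - 0.5) * geom$cell_size_km,
    y = geom$ymin + (row - 0.5) * geom$cell_size_km
  )
}

#' Locate points on the grid
#'
#' @param geom a [grid_geometry()].
#' @param x,y point coordinates (km).
#' @return data.frame with `row`, `col`, `cell`; NA for points off the grid.
#' @export
cells_at <- function(geom, x, y) {
  col <- floor((x - geom$xmin) / geom$cell_size_km) + 1
  row <- floor((y - geom$ymin) / geom$cell_size_km) + 1
  # points exactly on the top/right edge belong to the last cell
  col[x == geom$xmin + geom$n_cols * geom$cell_size_km] <- geom$n_cols
  row[y == geom$ymin + geom$n_rows * geom$cell_size_km] <- geom$n_rows
  off <- col < 1 | col > geom$n_cols | row < 1 | row > geom$n_rows
  row[off] <- NA_integer_; col[off] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = as.integer((col - 1) * geom$n_rows + row))
}

#' Bioclimatic variable catalogue
#'
#' The standard 19 bioclim summaries, identified by their conventional codes.
#' `kind` distinguishes temperature layers (degrees C), precipitation layers
#' (mm) and dimensionless indices; validity checks (non-negative
#' precipitation, warmest-month >= coldest-month temperature) key off it.
#'
#' @return data.frame with columns `code`, `name`, `kind`.
#' @export
bioclim_variables <- function() {
  data.frame(
    code = paste0("bio", 1:19),
    name = c(
      "mean annual temperature", "mean diurnal range", "isothermality",
      "temperature seasonality", "max temperature of warmest month",
      "min temperature of coldest month", "temperature annual range",
      "mean temperature of wettest quarter", "mean temperature of driest quarter",
      "mean temperature of warmest quarter", "mean temperature of coldest quarter",
      "mean annual precipitation", "precipitation of wettest month",
      "precipitation of driest month", "precipitation seasonality",
      "precipitation of wettest quarter", "precipitation of driest quarter",
      "precipitation of warmest quarter", "precipitation of coldest quarter"
    ),
    kind = c("temperature", "temperature", "index", "index", "temperature",
             "temperature", "temperature", "temperature", "temperature",
             "temperature", "temperature", "precipitation", "precipitation",
             "precipitation", "index", "precipitation", "precipitation",
             "precipitation", "precipitation"),
    stringsAsFactors = FALSE
  )
}

#' The nine default predictor variables
#'
#' The predictor set used for niche modelling by default: mean annual
#' temperature, max temperature of warmest month, min temperature of coldest
#' month, mean temperature of wettest and driest quarters, mean annual
#' precipitation, precipitation of wettest and driest months, and
#' precipitation of warmest quarter.
#'
#' @return character vector of bioclim codes.
#' @export
default_predictors <- function() {
  c("bio1", "bio5", "bio6", "bio8", "bio9", "bio12", "bio13", "bio14", "bio18")
}

#' Multi-variable bioclimatic raster stack for one time slice
#'
#' @param layers named list of numeric matrices (n_rows x n_cols), one per
#'   bioclim variable, plus optional extras.
#' @param elevation elevation matrix (m), same dimensions.
#' @param geom a [grid_geometry()].
#' @param age_ka slice age in thousand years before present (0 = present).
#' @return A `climate_stack` object.
#' @export
climate_stack <- function(layers, elevation, geom, age_ka = 0) {
  if (!inherits(geom, "grid_geometry")) stopf("`geom` must be a grid_geometry")
  if (length(layers) == 0 || is.null(names(layers)) || any(names(layers) == "")) {
    stopf("`layers` must be a non-empty named list of matrices")
  }
  dims <- c(geom$n_rows, geom$n_cols)
  for (nm in names(layers)) {
    if (!is.matrix(layers[[nm]]) || !all(dim(layers[[nm]]) == dims)) {
      stopf("layer '%s' does not match the grid geometry (%d x %d)",
            nm, dims[1], dims[2])
    }
  }
  if (!is.matrix(elevation) || !all(dim(elevation) == dims)) {
    stopf("`elevation` does not match the grid geometry")
  }
  cat_kind <- bioclim_variables()
  precip <- intersect(names(layers), cat_kind$code[cat_kind$kind == "precipitation"])
  for (nm in precip) {
    if (any(layers[[nm]] < 0, na.rm = TRUE)) {
      stopf("precipitation layer '%s' has negative values", nm)
    }
  }
  if (all(c("bio5", "bio6") %in% names(layers)) &&
      any(layers$bio5 < layers$bio6, na.rm = TRUE)) {
    stopf("bio5 (max temp warmest month) < bio6 (min temp coldest month) in some cells")
  }
  structure(list(geom = geom, age_ka = age_ka, layers = layers,
                 elevation = elevation),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("<climate_stack> %d x %d cells @ %g km, age %g ka\n",
              x$geom$n_rows, x$geom$n_cols, x$geom$cell_size_km, x$age_ka))
  cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Extract layer values as a cells-by-variables matrix
#'
#' @param stack a [climate_stack()].
#' @param variables layer names; default all layers.
#' @param cells optional integer cell indices (column-major); default all.
#' @return numeric matrix, one column per variable.
#' @export
stack_values <- function(stack, variables = names(stack$layers), cells = NULL) {
  missing_vars <- setdiff(variables, names(stack$layers))
  if (length(missing_vars)) {
    stopf("stack is missing variable(s): %s", paste(missing_vars, collapse = ", "))
  }
  n <- stack$geom$n_rows * stack$geom$n_cols
  idx <- cells %||% seq_len(n)
  out <- vapply(variables, function(v) as.vector(stack$layers[[v]])[idx],
                numeric(length(idx)))
  out <- matrix(out, nrow = length(idx),
                dimnames = list(NULL, variables))
  out
}

#' Climate values at point coordinates
#'
#' @param stack a [climate_stack()].
#' @param x,y coordinates (km).
#' @param variables layer names.
#' @return matrix of values (rows = points); error if any point is off-grid.
#' @export
stack_values_at <- function(stack, x, y, variables = names(stack$layers)) {
  loc <- cells_at(stack$geom, x, y)
  if (anyNA(loc$cell)) stopf("%d point(s) fall outside the grid", sum(is.na(loc$cell)))
  stack_values(stack, variables, cells = loc$cell)
}
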