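# Small in-code fixtures shared across test files.

# compact landscape for fast end-to-end tests
small_spec <- function(seed = 7L) {
  landscape_spec(n_rows = 60, n_cols = 60, seed = seed)
}

# hand-built climate stack from named layer matrices (vectors recycled)
manual_stack <- function(layers, n_rows, n_cols, elevation = NULL,
                         age_ka = 0, cell_size_km = 1) {
  geom <- grid_geometry(n_rows, n_cols, cell_size_km)
  lay <- lapply(layers, function(v) matrix(v, n_rows, n_cols))
  elev <- if (is.null(elevation)) matrix(0, n_rows, n_cols)
          else matrix(elevation, n_rows, n_cols)
  climate_stack(lay, elev, geom, age_ka = age_ka)
}

# vegetation map from a character vector/matrix of labels
manual_vumap <- function(labels, n_rows, n_cols, age_ka = 0,
                         cell_size_km = 1) {
  vegetation_map(matrix(labels, n_rows, n_cols),
                 grid_geometry(n_rows, n_cols, cell_size_km),
                 age_ka = age_ka)
}

# bare suitability surface for compositing tests
manual_surface <- function(values, vu_id, n_rows, n_cols, age_ka = 0,
                           corrected = FALSE) {
  geom <- grid_geometry(n_rows, n_cols, 1)
  structure(
    list(vu_id = vu_id, age_ka = age_ka, geom = geom,
         values = matrix(values, n_rows, n_cols), output = "cloglog",
         corrected = corrected,
         clamp_mask = matrix(FALSE, n_rows, n_cols)),
    class = "suitability_surface"
  )
}

# direct (independent) Spearman via the classic rank formula, no ties
spearman_by_hand <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
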