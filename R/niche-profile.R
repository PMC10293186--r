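# Climatic characterization of vegetation units and predictor screening.

# Even-odd point-in-polygon test for cell centers. `poly` is a data.frame or
# list of data.frames (rings) with columns x, y; a point inside an odd number
# of rings is inside the polygon (holes supported implicitly).
point_in_polygon <- function(px, py, poly) {
  rings <- if (is.data.frame(poly)) list(poly) else poly
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    xs <- ring$x; ys <- ring$y
    n <- length(xs)
    j <- n
    hit <- rep(FALSE, length(px))
    for (i in seq_len(n)) {
      crosses <- ((ys[i] > py) != (ys[j] > py)) &
        (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
      hit <- xor(hit, crosses)
      j <- i
    }
    inside <- xor(inside, hit)
  }
  inside
}

#' Extract per-cell climate values within a unit's extent
#'
#' Collects the value of every grid cell whose center falls inside the
#' extent: either the cells labelled `vu_id` on a categorical
#' [vegetation_map()], or the cells whose centers lie inside a polygon
#' (data.frame with columns `x`, `y`, or a list of such rings; even-odd
#' rule). Cells with a missing value in any variable are dropped from all
#' variables jointly.
#'
#' @param stack a [climate_stack()].
#' @param extent a [vegetation_map()] or polygon ring(s).
#' @param vu_id unit label (used with a vegetation-map extent; recorded
#'   either way).
#' @param variables layer names to extract (default: all).
#' @return A `climate_sample`: list with `vu_id`, `n_cells`, `values`
#'   (data.frame, one column per variable).
#' @export
extract_climate_values <- function(stack, extent, vu_id,
                                   variables = names(stack$layers)) {
  geom <- stack$geom
  if (inherits(extent, "vegetation_map")) {
    if (!same_geometry(geom, extent$geom)) {
      stopf("vegetation map and stack geometries differ")
    }
    cells <- which(as.vector(extent$labels) == vu_id)
  } else {
    cc <- cell_centers(geom)
    cells <- cc$cell[point_in_polygon(cc$x, cc$y, extent)]
  }
  if (length(cells) == 0) {
    stopf("extent for '%s' overlaps no grid cells", vu_id)
  }
  vals <- stack_values(stack, variables, cells = cells)
  keep <- stats::complete.cases(vals)
  vals <- as.data.frame(vals[keep, , drop = FALSE])
  structure(list(vu_id = vu_id, n_cells = nrow(vals), values = vals),
            class = "climate_sample")
}

#' Frequency profile of one climatic variable within a unit
#'
#' Histogram with `n_bins` equal-width bins spanning exactly the sample's
#' `[min, max]`; the usual summary of the prevalent climatic conditions of a
#' vegetation unit.
#'
#' @param sample a `climate_sample` from [extract_climate_values()].
#' @param variable variable name.
#' @param n_bins number of bins (>= 1).
#' @return list with `breaks` (length `n_bins + 1`) and `counts`
#'   (length `n_bins`, summing to the sample size).
#' @export
climate_frequency_profile <- function(sample, variable, n_bins = 20) {
  if (!variable %in% names(sample$values)) {
    stopf("variable '%s' not present in the sample", variable)
  }
  if (n_bins < 1) stopf("`n_bins` must be >= 1")
  v <- sample$values[[variable]]
  rng <- range(v)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(v, breaks = breaks, include.lowest = TRUE,
                      right = TRUE, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts)
}

#' Pairwise Spearman correlation between stack layers
#'
#' Rank correlation (average ranks for ties) over the cells where both
#' layers are valid. Constant layers have undefined correlations; these are
#' reported as `NA` with a warning, except the unit diagonal.
#'
#' @param stack a [climate_stack()].
#' @param variables layer names (>= 2).
#' @return A `correlation_matrix`: symmetric numeric matrix of Spearman rho
#'   with unit diagonal.
#' @export
spearman_matrix <- function(stack, variables = names(stack$layers)) {
  if (length(variables) < 2) stopf("need at least two variables")
  x <- stack_values(stack, variables)
  ok <- stats::complete.cases(x)
  if (sum(ok) < 3) stopf("fewer than 3 jointly valid cells")
  x <- x[ok, , drop = FALSE]
  sds <- apply(x, 2L, stats::sd)
  constant <- names(which(sds == 0))
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  if (length(constant)) {
    warnf("constant layer(s) with undefined correlations: %s",
          paste(constant, collapse = ", "))
    rho[constant, ] <- NA_real_
    rho[, constant] <- NA_real_
  }
  diag(rho) <- 1
  class(rho) <- c("correlation_matrix", class(rho))
  rho
}

#' Greedy collinearity screening of predictor variables
#'
#' Repeatedly drops the non-override variable with the most above-threshold
#' partners (`|rho| > threshold`) until no pair involving a droppable
#' variable exceeds the threshold. Ties are broken by dropping the variable
#' later in the input column order, so the result is deterministic.
#' `keep_overrides` are never dropped (pairs among them may stay above the
#' threshold, mirroring correlated variables retained for their
#' complementary information); `drop_overrides` are removed up front.
#' Undefined (`NA`) correlations never count as above threshold.
#'
#' @param corr a [spearman_matrix()] result (or any symmetric matrix with
#'   dimnames).
#' @param threshold absolute-correlation cut (default 0.85).
#' @param keep_overrides,drop_overrides variable names forced in/out.
#' @return A `predictor_set`: list with `retained`, `discarded`, and a
#'   `rationale` data.frame (variable, status, reason).
#' @export
select_predictors <- function(corr, threshold = 0.85,
                              keep_overrides = character(),
                              drop_overrides = character()) {
  vars <- colnames(corr)
  if (is.null(vars)) stopf("`corr` must have variable dimnames")
  bad <- setdiff(c(keep_overrides, drop_overrides), vars)
  if (length(bad)) stopf("unknown override variable(s): %s", paste(bad, collapse = ", "))
  both <- intersect(keep_overrides, drop_overrides)
  if (length(both)) {
    stopf("variable(s) in both keep and drop overrides: %s",
          paste(both, collapse = ", "))
  }
  current <- setdiff(vars, drop_overrides)
  dropped <- drop_overrides
  reason <- stats::setNames(rep("", length(vars)), vars)
  reason[drop_overrides] <- "drop-override"
  repeat {
    sub <- abs(corr[current, current, drop = FALSE])
    diag(sub) <- 0
    sub[is.na(sub)] <- 0
    exceed <- sub > threshold
    droppable <- setdiff(current, keep_overrides)
    # only pairs with at least one droppable member need resolving
    relevant <- exceed
    keep_idx <- current %in% keep_overrides
    relevant[keep_idx, keep_idx] <- FALSE
    if (!any(relevant)) break
    counts <- rowSums(exceed)[droppable]
    counts <- counts[counts > 0]
    if (length(counts) == 0) break   # only keep-keep conflicts remain
    worst <- max(counts)
    candidates <- names(counts)[counts == worst]
    victim <- candidates[which.max(match(candidates, vars))]
    current <- setdiff(current, victim)
    dropped <- c(dropped, victim)
    reason[victim] <- sprintf("collinear (|rho| > %.2f with %d partner(s))",
                              threshold, worst)
  }
  if (length(current) == 0) stopf("screening discarded every variable")
  reason[current] <- ifelse(current %in% keep_overrides,
                            "kept-override", "below-threshold")
  rationale <- data.frame(
    variable = vars,
    status = ifelse(vars %in% current, "retained", "discarded"),
    reason = reason[vars],
    stringsAsFactors = FALSE
  )
  structure(list(retained = vars[vars %in% current],
                 discarded = vars[!vars %in% current],
                 rationale = rationale),
            class = "predictor_set")
}

#' Default screening configuration
#'
#' Threshold `|rho| = 0.85` with the nine standard predictors
#' ([default_predictors()]) as keep-overrides. On the full 19-variable
#' synthetic stack this reproduces the conventional nine-predictor outcome
#' while remaining fully configurable.
#'
#' @return list with `threshold`, `keep_overrides`, `drop_overrides`.
#' @export
default_screening <- function() {
  list(threshold = 0.85, keep_overrides = default_predictors(),
       drop_overrides = character())
}
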