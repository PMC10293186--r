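# Fossil-pollen validation: taxa grouping, percentage series, habitat
# distances, and model-proxy concordance.

excluded_assignments <- function() {
  c("excluded-wetland", "excluded-ambiguous", "excluded-multigroup")
}

#' Validate a taxa-to-unit grouping table
#'
#' Each taxon must carry exactly one assignment: a vegetation-unit label or
#' one of the exclusion classes (`excluded-wetland`, `excluded-ambiguous`,
#' `excluded-multigroup` - local wetland taxa, taxa of unclear ecological
#' significance, and taxa characteristic of more than one unit).
#'
#' @param df data.frame with columns `taxon`, `assignment`.
#' @param units known unit labels (default: the seven default units).
#' @return A `taxa_grouping` data.frame; a message summarizes assigned vs
#'   excluded counts.
#' @export
taxa_grouping <- function(df, units = names(default_niches())) {
  if (!all(c("taxon", "assignment") %in% names(df))) {
    stopf("grouping table needs columns `taxon` and `assignment`")
  }
  if (nrow(df) == 0) stopf("grouping table is empty")
  dup <- df$taxon[duplicated(df$taxon)]
  if (length(dup)) stopf("duplicate taxon row(s): %s",
                         paste(unique(dup), collapse = ", "))
  known <- c(units, excluded_assignments())
  bad <- which(!df$assignment %in% known)
  if (length(bad)) {
    stopf("unknown unit label '%s' for taxon '%s' (row %d)",
          df$assignment[bad[1]], df$taxon[bad[1]], bad[1])
  }
  n_assigned <- sum(df$assignment %in% units)
  message(sprintf("taxa grouping: %d assigned to units, %d excluded",
                  n_assigned, nrow(df) - n_assigned))
  df <- df[, c("taxon", "assignment")]
  class(df) <- c("taxa_grouping", "data.frame")
  df
}

as_taxa_grouping <- function(x, units = NULL) {
  if (inherits(x, "taxa_grouping")) return(x)
  u <- units %||% unique(x$assignment[!x$assignment %in% excluded_assignments()])
  suppressMessages(taxa_grouping(x, units = u))
}

#' Load a taxa grouping table from CSV
#'
#' @param file CSV path with columns `taxon`, `assignment`.
#' @param units known unit labels.
#' @return A [taxa_grouping()].
#' @export
load_taxa_grouping <- function(file, units = names(default_niches())) {
  taxa_grouping(utils::read.csv(file, stringsAsFactors = FALSE), units = units)
}

#' Unit-group pollen percentages per sample
#'
#' The pollen sum of a sample is the total grains of taxa assigned to a
#' unit (excluded taxa sit outside both numerator and denominator), and a
#' group's percentage is 100 x its grains / pollen sum. Samples whose
#' pollen sum is zero are reported missing with a warning. Taxa counted but
#' absent from the grouping are treated as excluded-ambiguous with a
#' warning.
#'
#' @param record a `pollen_record` (see [generate_pollen_record()] or
#'   [read_pollen_record()]).
#' @param grouping a [taxa_grouping()].
#' @return A `grouped_pollen_series`: long data.frame `sample_id`, `age_ka`,
#'   `unit`, `percentage`, `pollen_sum`, `excluded_grains`.
#' @export
group_percentages <- function(record, grouping) {
  counts <- record$counts
  if (any(counts < 0)) stopf("negative pollen counts")
  grouping <- as_taxa_grouping(grouping)
  unlisted <- setdiff(colnames(counts), grouping$taxon)
  if (length(unlisted)) {
    warnf("%d counted taxa missing from the grouping treated as excluded-ambiguous: %s",
          length(unlisted), paste(utils::head(unlisted, 5), collapse = ", "))
    grouping <- rbind(grouping,
                      data.frame(taxon = unlisted,
                                 assignment = "excluded-ambiguous"))
  }
  assign <- stats::setNames(grouping$assignment, grouping$taxon)[colnames(counts)]
  units <- sort(unique(assign[!assign %in% excluded_assignments()]))
  if (length(units) == 0) stopf("no counted taxon is assigned to any unit")
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    cnt <- counts[i, ]
    by_unit <- vapply(units, function(u) sum(cnt[assign == u]), numeric(1))
    psum <- sum(by_unit)
    excl <- sum(cnt) - psum
    pct <- if (psum > 0) 100 * by_unit / psum else rep(NA_real_, length(units))
    if (psum == 0) warnf("sample '%s': all grains excluded; percentages missing",
                         record$samples$sample_id[i])
    rows[[i]] <- data.frame(sample_id = record$samples$sample_id[i],
                            age_ka = record$samples$age_ka[i],
                            unit = units, percentage = pct,
                            pollen_sum = psum, excluded_grains = excl,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("grouped_pollen_series", "data.frame")
  out
}

#' Distance from a site to the nearest mapped habitat of a unit
#'
#' Euclidean distance (km) from the site to the nearest cell center
#' labelled `vu_id`; 0 when the site's own cell is so labelled, `Inf` when
#' the unit is absent from the map.
#'
#' @param vumap a [vegetation_map()].
#' @param site length-2 numeric `(x, y)` in km.
#' @param vu_id unit label.
#' @return distance in km.
#' @export
habitat_distance <- function(vumap, site, vu_id) {
  geom <- vumap$geom
  loc <- cells_at(geom, site[1], site[2])
  if (anyNA(loc$cell)) stopf("site (%g, %g) lies outside the grid",
                             site[1], site[2])
  idx <- which(as.vector(vumap$labels) == vu_id)
  if (length(idx) == 0) return(Inf)
  if (vumap$labels[loc$row, loc$col] == vu_id) return(0)
  row <- (idx - 1L) %% geom$n_rows + 1L
  col <- (idx - 1L) %/% geom$n_rows + 1L
  cx <- geom$xmin + (col - 0.5) * geom$cell_size_km
  cy <- geom$ymin + (row - 0.5) * geom$cell_size_km
  sqrt(min((cx - site[1])^2 + (cy - site[2])^2))
}

#' Rank concordance between pollen abundance and habitat proximity
#'
#' Spearman correlation between a unit group's pollen percentages and the
#' negative of the modeled habitat distance across ages: positive rho means
#' the taxon group is more abundant when the hindcast places its habitat
#' nearer the site. (The underlying model-proxy comparison is classically
#' visual; this statistic is the package's monotone, distribution-free
#' operationalization of it.)
#'
#' @param series a [group_percentages()] result.
#' @param distances data.frame `age_ka`, `distance_km` for one unit
#'   (infinite distances are dropped).
#' @param vu_id the unit whose percentages to use.
#' @param tol_ka max |age difference| when matching samples to slices
#'   (nearest neighbor, default 0.5 ka).
#' @return one-row data.frame `vu_id`, `rho`, `n_ages`; `rho` is `NA` when
#'   either series is constant (undefined ranks).
#' @export
concordance <- function(series, distances, vu_id, tol_ka = 0.5) {
  s <- series[series$unit == vu_id & !is.na(series$percentage), ]
  d <- distances[is.finite(distances$distance_km), ]
  if (nrow(s) == 0 || nrow(d) == 0) stopf("no usable data for unit '%s'", vu_id)
  nearest <- vapply(s$age_ka, function(a) {
    i <- which.min(abs(d$age_ka - a))
    if (abs(d$age_ka[i] - a) <= tol_ka) i else NA_integer_
  }, integer(1))
  ok <- !is.na(nearest)
  if (sum(ok) < 3) stopf("fewer than 3 paired ages for unit '%s'", vu_id)
  pct <- s$percentage[ok]
  dist <- d$distance_km[nearest[ok]]
  if (stats::sd(pct) == 0 || stats::sd(dist) == 0) {
    message(sprintf("unit '%s': constant series; concordance undefined", vu_id))
    rho <- NA_real_
  } else {
    rho <- stats::cor(pct, -dist, method = "spearman")
  }
  data.frame(vu_id = vu_id, rho = rho, n_ages = sum(ok),
             stringsAsFactors = FALSE)
}
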