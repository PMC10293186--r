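# End-to-end synthetic hindcast: landscape -> truth -> models -> past
# projections -> composites -> summaries.

#' Run the full hindcasting pipeline on a synthetic landscape
#'
#' Generates a present-day climate stack and ground-truth vegetation map,
#' samples presences for every unit, fits one maximum-entropy model per
#' unit and evaluates it on a holdout, then (optionally) projects all
#' models onto every past slice, applies the CO2 correction, composites
#' per-slice vegetation maps, and summarizes areas and elevation limits
#' through time.
#'
#' @param spec a [landscape_spec()].
#' @param ages past slice ages, ka BP (default 22:1, one per millennium
#'   since the glacial maximum).
#' @param niches list of [niche_definition()]s (default [default_niches()]).
#' @param n_presences presences sampled per unit.
#' @param n_background background cells shared by all models.
#' @param test_fraction holdout fraction (default 0.25).
#' @param beta,n_hinge_knots model settings, see [fit_maxent()].
#' @param correction apply the CO2 correction to past surfaces?
#' @param corr_table a [correction_table()] (default synthetic factors).
#' @param threshold no-analog compositing threshold (default 0.1).
#' @param project if FALSE stop after model fitting and evaluation.
#' @param seed master integer seed; all sampling seeds derive from it.
#' @return list with `present_stack`, `truth`, `background`, `occurrences`,
#'   `models`, `evaluations` (AUC per unit), and when `project`:
#'   `hindcast` (all per-unit surfaces), `composites` (per past age),
#'   `present_composite`, `areas`, `limits`, `summary`, `co2`.
#' @export
run_synthetic_hindcast <- function(spec = landscape_spec(), ages = 22:1,
                                   niches = default_niches(),
                                   n_presences = 1000, n_background = 10000,
                                   test_fraction = 0.25, beta = 1,
                                   n_hinge_knots = 31, correction = TRUE,
                                   corr_table = default_correction_table(),
                                   threshold = 0.1, project = TRUE,
                                   seed = 1L) {
  seed <- as.integer(seed)
  present <- generate_climate_stack(spec, age_ka = 0)
  truth <- generate_true_vegetation(present, niches, threshold = threshold)
  units <- vapply(niches, `[[`, character(1), "vu_id")
  background <- sample_background(present, n_background,
                                  predictors = default_predictors(),
                                  seed = seed + 101L)
  occurrences <- list(); models <- list(); evaluations <- list()
  for (k in seq_along(units)) {
    vu <- units[k]
    occ <- sample_presences(truth, vu, n = n_presences, seed = seed + 17L * k)
    sp <- split_occurrences(occ, test_fraction, seed = seed + 29L * k)
    mod <- fit_maxent(sp$train, background, present, beta = beta,
                      n_hinge_knots = n_hinge_knots)
    occurrences[[vu]] <- occ
    models[[vu]] <- mod
    evaluations[[vu]] <- evaluate_auc(mod, sp$test, background, present)
  }
  out <- list(spec = spec, present_stack = present, truth = truth,
              background = background, occurrences = occurrences,
              models = models, evaluations = evaluations,
              aucs = vapply(evaluations, `[[`, numeric(1), "auc"))
  if (!project) return(out)

  co2 <- generate_co2_series(sort(unique(c(ages, 0)), decreasing = TRUE))
  stacks <- lapply(ages, function(a) generate_climate_stack(spec, age_ka = a))
  hind <- run_hindcast(models, stacks, co2 = co2, table = corr_table,
                       ages = ages, correction_on = correction)
  use <- if (correction) hind$corrected else hind$uncorrected
  composites <- list()
  areas <- list(); limits <- list()
  for (a in ages) {
    keys <- sprintf("%s@%g", units, a)
    cm <- composite_vegetation(use[keys], threshold = threshold, order = keys)
    composites[[as.character(a)]] <- cm
    areas[[as.character(a)]] <- area_by_vu(cm, units = units)
    limits[[as.character(a)]] <- elevation_limits(cm, present$elevation,
                                                  units = units)
  }
  present_surfaces <- lapply(models, predict_suitability, stack = present)
  present_composite <- composite_vegetation(present_surfaces,
                                            threshold = threshold)
  list2 <- c(out, list(
    hindcast = hind, composites = composites,
    present_composite = present_composite,
    present_areas = area_by_vu(present_composite, units = units),
    present_limits = elevation_limits(present_composite, present$elevation,
                                      units = units),
    areas = areas, limits = limits,
    summary = timeseries_summary(areas, limits),
    co2 = co2
  ))
  list2
}
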