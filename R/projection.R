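# Hindcast projection of fitted niche models and the CO2 physiological
# correction.

#' Per-unit CO2 correction table
#'
#' Each vegetation unit carries a base factor `f_lgm`: the ratio of its
#' fraction cover under glacial CO2 to its cover under present CO2 (from
#' dynamical vegetation model experiments; < 1 for forests whose growth low
#' CO2 suppresses, > 1 for open C4-dominated units it favors). The factor at
#' an arbitrary concentration follows the assumed linear relation between
#' CO2 and the intensity of the physiological effect, anchored at
#' `c_lgm` (full effect) and `c_ref` (no effect).
#'
#' @param df data.frame with columns `vu_id`, `f_lgm` and optionally
#'   `c_lgm`, `c_ref`.
#' @param c_lgm glacial reference concentration, ppm (default 185).
#' @param c_ref no-effect reference concentration, ppm (default 280,
#'   pre-industrial).
#' @return A `correction_table` data.frame.
#' @export
correction_table <- function(df, c_lgm = 185, c_ref = 280) {
  if (!all(c("vu_id", "f_lgm") %in% names(df))) {
    stopf("`df` needs columns `vu_id` and `f_lgm`")
  }
  if (is.null(df$c_lgm)) df$c_lgm <- c_lgm
  if (is.null(df$c_ref)) df$c_ref <- c_ref
  if (any(df$f_lgm <= 0)) stopf("`f_lgm` must be > 0")
  if (any(df$c_lgm >= df$c_ref)) stopf("`c_lgm` must be < `c_ref`")
  if (anyDuplicated(df$vu_id)) stopf("duplicate unit in correction table")
  df <- df[, c("vu_id", "f_lgm", "c_lgm", "c_ref")]
  class(df) <- c("correction_table", "data.frame")
  df
}

#' Default synthetic correction table
#'
#' Synthetic base factors for the seven default units: growth suppression
#' under glacial CO2 for the forest belts (DAF, MAF at 0.7, EB at 0.85), no
#' net effect for the afroalpine belt, and enhancement of the open woodland
#' and scrub units (ACB, CTW at 1.3, DSS at 1.1). Endpoints 185 ppm
#' (glacial) and 280 ppm (pre-industrial).
#'
#' @return A [correction_table()].
#' @export
default_correction_table <- function() {
  correction_table(data.frame(
    vu_id = c("AA", "EB", "DAF", "MAF", "ACB", "CTW", "DSS"),
    f_lgm = c(1.0, 0.85, 0.7, 0.7, 1.3, 1.3, 1.1)
  ))
}

#' CO2 correction factor at a given concentration
#'
#' Linear in concentration on `[c_lgm, c_ref]`:
#' `factor(c) = 1 + (f_lgm - 1) * (c_ref - c) / (c_ref - c_lgm)`, equal to
#' `f_lgm` at the glacial endpoint and exactly 1 at and above `c_ref`
#' (no physiological effect near pre-industrial levels). Below `c_lgm` the
#' line is extrapolated but floored at 0.
#'
#' @param table a [correction_table()].
#' @param vu_id unit label.
#' @param c CO2 concentration(s), ppm (> 0).
#' @return numeric factor(s), dimensionless.
#' @export
correction_factor <- function(table, vu_id, c) {
  if (any(c <= 0)) stopf("concentration must be > 0")
  row <- table[table$vu_id == vu_id, ]
  if (nrow(row) != 1) stopf("unknown unit '%s' in correction table", vu_id)
  f <- 1 + (row$f_lgm - 1) * (row$c_ref - c) / (row$c_ref - row$c_lgm)
  f[c >= row$c_ref] <- 1
  pmax(f, 0)
}

#' Apply a CO2 correction factor to a suitability surface
#'
#' Per-cell probability becomes `min(1, factor * value)`; the surface is
#' flagged corrected and a second application errors.
#'
#' @param surface a `suitability_surface`.
#' @param factor non-negative scalar factor.
#' @return the corrected surface.
#' @export
apply_correction <- function(surface, factor) {
  if (factor < 0) stopf("`factor` must be >= 0")
  if (isTRUE(surface$corrected)) stopf("surface is already CO2-corrected")
  surface$values <- pmin(factor * surface$values, 1)
  surface$corrected <- TRUE
  surface
}

#' Project a fitted model onto a (past) climate stack
#'
#' Cloglog suitability using the training-time feature scaling. With
#' `clamp = TRUE` (default), predictor values outside the training min/max
#' are clamped to the range boundary and flagged in the clamping mask - the
#' standard safeguard against extrapolating features beyond their fitted
#' support. Projecting onto the training stack reproduces the training-time
#' prediction exactly.
#'
#' @param model a [fit_maxent()] model.
#' @param past_stack a [climate_stack()] with all model variables.
#' @param clamp clamp out-of-range predictors?
#' @return A `suitability_surface` at the stack's age.
#' @export
project_model <- function(model, past_stack, clamp = TRUE) {
  predict_suitability(model, past_stack, output = "cloglog", clamp = clamp)
}

#' Interpolate a CO2 series at arbitrary ages
#'
#' @param co2 a [generate_co2_series()]-style data.frame (`age_ka`,
#'   `co2_ppm`).
#' @param age_ka ages to resolve (linear interpolation, endpoints extended).
#' @return concentrations, ppm.
#' @export
co2_at <- function(co2, age_ka) {
  stats::approx(co2$age_ka, co2$co2_ppm, xout = age_ka, rule = 2)$y
}

#' Project all models onto all past slices, with optional CO2 correction
#'
#' Runs every model over every requested age (e.g. 7 units x 22 millennial
#' slices = 154 projections). When `correction_on`, also emits a corrected
#' copy of every surface, scaling each unit's probability by its
#' [correction_factor()] at the slice's interpolated CO2 concentration, and
#' logs the per-age factors.
#'
#' @param models named list of [fit_maxent()] models.
#' @param stacks list of [climate_stack()]s, one per requested age.
#' @param co2 CO2 series data.frame (`age_ka`, `co2_ppm`); required when
#'   `correction_on`.
#' @param table a [correction_table()]; required when `correction_on`.
#' @param ages ages to project (default: the stacks' ages).
#' @param correction_on apply the CO2 correction?
#' @param clamp passed to [project_model()].
#' @return A `hindcast` list: `uncorrected` and (optionally) `corrected`
#'   surface lists indexed `"<vu>@<age>"`, plus a `factors` data.frame
#'   (age_ka, vu_id, co2_ppm, factor).
#' @export
run_hindcast <- function(models, stacks, co2 = NULL, table = NULL,
                         ages = NULL, correction_on = FALSE, clamp = TRUE) {
  stack_ages <- vapply(stacks, `[[`, numeric(1), "age_ka")
  ages <- ages %||% sort(unique(stack_ages), decreasing = TRUE)
  missing_ages <- setdiff(ages, stack_ages)
  if (length(missing_ages)) {
    stopf("no climate stack for age(s): %s ka",
          paste(missing_ages, collapse = ", "))
  }
  if (correction_on && (is.null(co2) || is.null(table))) {
    stopf("CO2 series and correction table are required when correction_on")
  }
  uncorrected <- list()
  corrected <- if (correction_on) list() else NULL
  factors <- list()
  for (age in ages) {
    stk <- stacks[[which(stack_ages == age)[1]]]
    ppm <- if (correction_on) co2_at(co2, age) else NA_real_
    for (vu in names(models)) {
      key <- sprintf("%s@%g", vu, age)
      surf <- project_model(models[[vu]], stk, clamp = clamp)
      uncorrected[[key]] <- surf
      if (correction_on) {
        f <- correction_factor(table, vu, ppm)
        corrected[[key]] <- apply_correction(surf, f)
        factors[[key]] <- data.frame(age_ka = age, vu_id = vu,
                                     co2_ppm = ppm, factor = f)
      }
    }
  }
  structure(list(uncorrected = uncorrected, corrected = corrected,
                 factors = if (length(factors)) do.call(rbind, factors) else NULL,
                 ages = ages),
            class = "hindcast")
}
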