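# Presence-background maximum-entropy niche models: training-data
# preparation, fitting, prediction, and holdout evaluation.

#' Split occurrences into training and test sets
#'
#' Holds out `floor(test_fraction * n)` points, sampled without replacement.
#'
#' @param occ an occurrence set (data.frame with `vu_id`, `x`, `y`).
#' @param test_fraction fraction held out, in (0, 1); default 0.25.
#' @param seed integer seed.
#' @return list with `train` and `test` occurrence sets (disjoint, union =
#'   input).
#' @export
split_occurrences <- function(occ, test_fraction = 0.25, seed = 1L) {
  n <- nrow(occ)
  if (n < 2) stopf("need at least 2 occurrences to split")
  if (test_fraction <= 0 || test_fraction >= 1) {
    stopf("`test_fraction` must lie strictly between 0 and 1")
  }
  n_test <- floor(test_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_test))
  list(train = occ[setdiff(seq_len(n), idx), , drop = FALSE],
       test = occ[idx, , drop = FALSE])
}

#' Sample background cells from a climate stack
#'
#' Uniform sample of valid cells (finite in every predictor) without
#' replacement; if the grid has fewer valid cells than requested, all of
#' them are used with a warning.
#'
#' @param stack a [climate_stack()].
#' @param n_background number of background cells (>= 100 by convention).
#' @param predictors variables that must be valid (default: all layers).
#' @param seed integer seed.
#' @return A `background_sample`: data.frame with `cell`, `x`, `y` and one
#'   column per predictor.
#' @export
sample_background <- function(stack, n_background = 10000,
                              predictors = names(stack$layers), seed = 1L) {
  vals <- stack_values(stack, predictors)
  valid <- which(stats::complete.cases(vals) & is.finite(rowSums(vals)))
  if (length(valid) == 0) stopf("no valid background cells")
  if (n_background >= length(valid)) {
    if (n_background > length(valid)) {
      warnf("requested %d background cells but only %d valid cells exist; using all",
            n_background, length(valid))
    }
    take <- valid
  } else {
    take <- valid[with_seed(seed, sample.int(length(valid), n_background))]
  }
  cc <- cell_centers(stack$geom)
  out <- cbind(cc[take, c("cell", "x", "y")],
               as.data.frame(vals[take, , drop = FALSE]))
  rownames(out) <- NULL
  class(out) <- c("background_sample", "data.frame")
  out
}

#' Fit a presence-background maximum-entropy niche model
#'
#' Finds feature weights maximizing the penalized log-likelihood
#' `mean_presence(lambda . f) - log Z - beta * sum_j s_j |lambda_j|`, where
#' `Z = sum_background exp(lambda . f)` and `s_j` is the feature's presence
#' standard error (`sd / sqrt(n_presence)`, floored at 1e-3). The training
#' presences are added to the background for `Z` (the usual
#' presence-background convention, which also keeps the objective bounded
#' when a feature separates presences from background). The objective
#' is convex; the solver (monotone accelerated proximal gradient) runs until
#' the KKT residual of the L1 subdifferential falls below `tol`. The fitted
#' background distribution `q(x) = exp(lambda . f(x)) / Z` and its entropy
#' `H` (nats) are stored for the cloglog output transform.
#'
#' @param train training occurrence set.
#' @param background a [sample_background()] result.
#' @param stack the training [climate_stack()] (presence climate values are
#'   extracted from it).
#' @param predictors predictor variable names (default: the background's
#'   predictor columns).
#' @param classes,n_hinge_knots feature classes and hinge-knot count, see
#'   [feature_expansion()].
#' @param beta regularization multiplier (dimensionless, default 1).
#' @param tol KKT residual tolerance (default 1e-6).
#' @param max_iter solver iteration cap.
#' @return A `niche_model`: feature expansion, weights `lambda`, `log_z`,
#'   entropy `H`, `beta`, per-feature penalty scales, objective path and
#'   training metadata.
#' @export
fit_maxent <- function(train, background, stack,
                       predictors = setdiff(names(background),
                                            c("cell", "x", "y")),
                       classes = c("linear", "quadratic", "product", "hinge"),
                       n_hinge_knots = 31, beta = 1, tol = 1e-6,
                       max_iter = 200000L) {
  if (nrow(train) < 10) stopf("need >= 10 training presences")
  if (nrow(background) < 100) stopf("need >= 100 background cells")
  if (beta < 0) stopf("`beta` must be >= 0")
  pres_x <- stack_values_at(stack, train$x, train$y, predictors)
  bg_x <- as.matrix(background[, predictors, drop = FALSE])
  all_x <- rbind(pres_x, bg_x)
  fe <- feature_expansion(
    list(min = apply(all_x, 2L, min), max = apply(all_x, 2L, max)),
    classes = classes, n_hinge_knots = n_hinge_knots
  )
  Fp <- feature_matrix(fe, pres_x, clamp = FALSE)$F
  Fb <- feature_matrix(fe, bg_x, clamp = FALSE)$F
  pbar <- colMeans(Fp)
  s <- pmax(apply(Fp, 2L, stats::sd), 1e-3) / sqrt(nrow(Fp))
  w <- beta * s

  # training presences join the background for the normalizer Z (the
  # standard presence-background convention); otherwise a feature whose
  # presence mean exceeds its background maximum separates the classes and
  # the penalized likelihood is unbounded
  Fz <- rbind(Fb, Fp)
  fit <- maxent_solve_cpp(Fz, pbar, w, tol, as.integer(max_iter), 25L)
  if (!fit$converged) {
    cond <- structure(
      class = c("paleoveg_convergence_error", "error", "condition"),
      list(message = sprintf(
        "maxent solver did not reach tol %.1e in %d iterations (KKT residual %.3e)",
        tol, fit$iterations, fit$kkt_residual),
        call = sys.call(),
        diagnostics = fit[c("kkt_residual", "iterations", "objective")])
    )
    stop(cond)
  }
  lambda <- as.numeric(fit$lambda)
  scores <- as.numeric(Fz %*% lambda)
  mx <- max(scores)
  log_z <- mx + log(sum(exp(scores - mx)))
  q <- exp(scores - log_z)
  H <- -sum(ifelse(q > 0, q * log(q), 0))

  structure(
    list(vu_id = unique(train$vu_id)[1] %||% NA_character_,
         features = fe, lambda = lambda, log_z = log_z, entropy = H,
         beta = beta, penalty_scale = s,
         objective_path = as.numeric(fit$objective_path),
         kkt_residual = fit$kkt_residual,
         meta = list(n_presence = nrow(train), n_background = nrow(background),
                     n_z = nrow(Fz), predictors = predictors,
                     iterations = fit$iterations)),
    class = "niche_model"
  )
}

#' @export
print.niche_model <- function(x, ...) {
  cat(sprintf(
    "<niche_model> unit %s: %d features (%d nonzero), H = %.3f nats, beta = %g\n",
    x$vu_id, length(x$lambda), sum(x$lambda != 0), x$entropy, x$beta))
  invisible(x)
}

# linear scores for arbitrary raw predictor rows (chunked for big grids)
model_scores <- function(model, x, clamp = TRUE, chunk = 20000L) {
  n <- nrow(x)
  scores <- numeric(n)
  clamped <- logical(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    fm <- feature_matrix(model$features, x[idx, , drop = FALSE], clamp = clamp)
    scores[idx] <- as.numeric(fm$F %*% model$lambda)
    clamped[idx] <- fm$clamped
  }
  list(scores = scores, clamped = clamped)
}

#' Predict per-cell suitability on a climate stack
#'
#' `raw` output is the relative occurrence rate
#' `q(x) = exp(lambda . f(x)) / Z` normalized over the model's training
#' background (it sums to 1 when evaluated on those cells). `cloglog`
#' output is `1 - exp(-exp(H) * q(x))`, clipped to `[0, 1]`, interpretable
#' as probability of occurrence. Predictor values outside the training range
#' are clamped to the range boundary and flagged in the clamping mask.
#'
#' @param model a [fit_maxent()] model.
#' @param stack a [climate_stack()] providing all model variables.
#' @param output `"cloglog"` (default) or `"raw"`.
#' @param clamp clamp out-of-range predictors (default TRUE)?
#' @return A `suitability_surface`: list with `vu_id`, `age_ka`, `geom`,
#'   `values` matrix, `output`, `corrected` flag and logical `clamp_mask`.
#' @export
predict_suitability <- function(model, stack, output = c("cloglog", "raw"),
                                clamp = TRUE) {
  output <- match.arg(output)
  miss <- setdiff(model$meta$predictors, names(stack$layers))
  if (length(miss)) stopf("stack is missing model variable(s): %s",
                          paste(miss, collapse = ", "))
  x <- stack_values(stack, model$meta$predictors)
  sc <- model_scores(model, x, clamp = clamp)
  q <- exp(sc$scores - model$log_z)
  v <- if (output == "raw") q else pmin(1, pmax(0, 1 - exp(-exp(model$entropy) * q)))
  geom <- stack$geom
  structure(
    list(vu_id = model$vu_id, age_ka = stack$age_ka, geom = geom,
         values = matrix(v, geom$n_rows, geom$n_cols),
         output = output, corrected = FALSE,
         clamp_mask = matrix(sc$clamped, geom$n_rows, geom$n_cols)),
    class = "suitability_surface"
  )
}

#' @export
print.suitability_surface <- function(x, ...) {
  cat(sprintf(
    "<suitability_surface> unit %s, age %g ka, %s output%s; range [%.3f, %.3f]\n",
    x$vu_id, x$age_ka, x$output, if (x$corrected) " (CO2-corrected)" else "",
    min(x$values), max(x$values)))
  invisible(x)
}

#' Evaluate a model with AUC on held-out presences vs background
#'
#' The exact rank statistic: the probability that a random test presence
#' scores above a random background cell, counting ties as 1/2. Because AUC
#' is rank-based it is identical for raw and cloglog outputs.
#'
#' @param model a [fit_maxent()] model.
#' @param test held-out occurrence set.
#' @param background a [sample_background()] result.
#' @param stack the [climate_stack()] to score on.
#' @return An `evaluation_result`: list with `vu_id`, `auc`, `n_test`,
#'   `n_background`.
#' @export
evaluate_auc <- function(model, test, background, stack) {
  if (nrow(test) < 1 || nrow(background) < 1) {
    stopf("need at least one test point and one background cell")
  }
  s_test <- model_scores(model, stack_values_at(stack, test$x, test$y,
                                                model$meta$predictors))$scores
  s_bg <- model_scores(model,
                       as.matrix(background[, model$meta$predictors,
                                            drop = FALSE]))$scores
  structure(list(vu_id = model$vu_id, auc = auc_exact(s_test, s_bg),
                 n_test = length(s_test), n_background = length(s_bg)),
            class = "evaluation_result")
}

#' Exact AUC from positive and negative scores
#'
#' `P(score_pos > score_neg) + 0.5 P(tie)` over all pairs, computed by the
#' rank (Mann-Whitney) identity - exact, not trapezoidal.
#'
#' @param pos,neg numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_exact <- function(pos, neg) {
  if (length(pos) < 1 || length(neg) < 1) stopf("need scores in both groups")
  r <- rank(c(pos, neg), ties.method = "average")
  nt <- length(pos)
  (sum(r[seq_len(nt)]) - nt * (nt + 1) / 2) / (nt * length(neg))
}
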