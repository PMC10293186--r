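# Feature expansion for maximum-entropy niche models. Variables are first
# rescaled to [0,1] by their training min/max; every derived feature then
# also maps in-range inputs to [0,1], which keeps the L1 penalty comparable
# across feature classes.

#' Build a maximum-entropy feature expansion
#'
#' Defines the feature classes applied to scaled predictors:
#' * `linear` - the scaled variable itself;
#' * `quadratic` - its square;
#' * `product` - pairwise products of scaled variables;
#' * `hinge` - forward `max(0, z - k) / (1 - k)` and reverse
#'   `max(0, k - z) / k` ramps at `n_hinge_knots` evenly spaced interior
#'   knots per variable.
#'
#' @param ranges data.frame or list with per-variable `min` and `max`
#'   (named), taken from the training data.
#' @param classes subset of `c("linear", "quadratic", "product", "hinge")`.
#' @param n_hinge_knots interior hinge knots per variable (default 31, both
#'   directions at each knot).
#' @return A `feature_expansion` object.
#' @export
feature_expansion <- function(ranges,
                              classes = c("linear", "quadratic", "product", "hinge"),
                              n_hinge_knots = 31) {
  classes <- match.arg(classes, several.ok = TRUE)
  vars <- names(ranges$min)
  if (is.null(vars) || !identical(vars, names(ranges$max))) {
    stopf("`ranges` must carry identically named `min` and `max` vectors")
  }
  if (any(ranges$max <= ranges$min)) {
    stopf("degenerate training range (max <= min) for: %s",
          paste(vars[ranges$max <= ranges$min], collapse = ", "))
  }
  knots <- if ("hinge" %in% classes && n_hinge_knots > 0) {
    seq_len(n_hinge_knots) / (n_hinge_knots + 1)
  } else numeric()
  labels <- character()
  if ("linear" %in% classes) labels <- c(labels, paste0("lin:", vars))
  if ("quadratic" %in% classes) labels <- c(labels, paste0("quad:", vars))
  if ("product" %in% classes && length(vars) > 1) {
    pairs <- utils::combn(vars, 2)
    labels <- c(labels, paste0("prod:", pairs[1, ], "*", pairs[2, ]))
  }
  if (length(knots)) {
    for (v in vars) {
      labels <- c(labels, paste0("hingeF:", v, "@", signif(knots, 4)),
                  paste0("hingeR:", v, "@", signif(knots, 4)))
    }
  }
  structure(list(variables = vars,
                 min = ranges$min, max = ranges$max,
                 classes = classes, knots = knots, labels = labels),
            class = "feature_expansion")
}

#' Scale raw predictor values to the training [0,1] range
#'
#' @param fe a [feature_expansion()].
#' @param x matrix of raw values (columns named by variable).
#' @param clamp clamp out-of-range values to the range boundary?
#' @return list with `z` (scaled matrix) and `clamped` (logical vector,
#'   TRUE where any variable was clamped).
#' @export
scale_predictors <- function(fe, x, clamp = TRUE) {
  x <- x[, fe$variables, drop = FALSE]
  z <- sweep(x, 2L, fe$min, `-`)
  z <- sweep(z, 2L, fe$max - fe$min, `/`)
  clamped <- rep(FALSE, nrow(z))
  if (clamp) {
    out <- z < 0 | z > 1
    clamped <- rowSums(out) > 0
    z[z < 0] <- 0
    z[z > 1] <- 1
  }
  list(z = z, clamped = clamped)
}

#' Evaluate the feature matrix
#'
#' @param fe a [feature_expansion()].
#' @param x matrix of raw predictor values (columns named by variable).
#' @param clamp passed to [scale_predictors()].
#' @return list with `F` (rows x features matrix) and `clamped`.
#' @export
feature_matrix <- function(fe, x, clamp = TRUE) {
  sc <- scale_predictors(fe, x, clamp = clamp)
  z <- sc$z
  n <- nrow(z)
  v <- length(fe$variables)
  blocks <- list()
  if ("linear" %in% fe$classes) blocks$linear <- z
  if ("quadratic" %in% fe$classes) blocks$quadratic <- z^2
  if ("product" %in% fe$classes && v > 1) {
    pairs <- utils::combn(v, 2)
    blocks$product <- z[, pairs[1, ], drop = FALSE] * z[, pairs[2, ], drop = FALSE]
  }
  if (length(fe$knots)) {
    k <- fe$knots
    hm <- matrix(0, n, 2 * length(k) * v)
    col0 <- 0L
    for (j in seq_len(v)) {
      zj <- z[, j]
      for (i in seq_along(k)) {
        hm[, col0 + i] <- pmax(0, zj - k[i]) / (1 - k[i])
      }
      for (i in seq_along(k)) {
        hm[, col0 + length(k) + i] <- pmax(0, k[i] - zj) / k[i]
      }
      col0 <- col0 + 2L * length(k)
    }
    blocks$hinge <- hm
  }
  fm <- do.call(cbind, blocks)
  colnames(fm) <- fe$labels
  list(F = fm, clamped = sc$clamped)
}
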