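#' Specification of a synthetic landscape
#'
#' Describes the synthetic study region: grid dimensions, the temperature
#' lapse rate tying climate to a generated elevation field, a west-east /
#' south-north precipitation trend, and the smoothness of the terrain. All
#' downstream climate layers are deterministic functions of this spec and its
#' seed.
#'
#' @param n_rows,n_cols grid dimensions in cells (>= 8).
#' @param cell_size_km cell edge length, km.
#' @param lapse_rate temperature decrease per 100 m of elevation, degrees C.
#'   Tropical-highland lapse rates fall in 0.5-0.7; values outside that band
#'   trigger a warning.
#' @param sea_level_temp mean annual temperature at 0 m, degrees C.
#' @param precip_gradient length-2 vector: precipitation trend in mm per cell
#'   along x (eastward) and y (northward).
#' @param precip_base mean annual precipitation at the grid center, mm.
#' @param precip_noise_sd s.d. of the smoothed random precipitation
#'   component, mm (0 for a purely deterministic gradient).
#' @param roughness terrain roughness (dimensionless, > 0): larger values
#'   give shorter-wavelength relief.
#' @param seasonal_contrast scales the spatial modulation of seasonal
#'   temperature range and precipitation seasonality by local dryness; 0
#'   makes every seasonal offset spatially constant (the "no-noise"
#'   configuration in which temperature layers are exact affine functions of
#'   elevation).
#' @param max_elevation_m top of the rescaled elevation field, m.
#' @param seed integer random seed.
#' @return A `landscape_spec` object.
#' @export
landscape_spec <- function(n_rows = 200, n_cols = 200, cell_size_km = 1,
                           lapse_rate = 0.6, sea_level_temp = 28,
                           precip_gradient = c(-5, 0), precip_base = 1100,
                           precip_noise_sd = 150, roughness = 0.5,
                           seasonal_contrast = 1, max_elevation_m = 4500,
                           seed = 1L) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) || n_rows < 8 || n_cols < 8) {
    stopf("grid dimensions must be numeric and >= 8 cells")
  }
  assert_scalar_number(cell_size_km, "cell_size_km", positive = TRUE)
  assert_scalar_number(lapse_rate, "lapse_rate", positive = TRUE)
  if (lapse_rate < 0.5 || lapse_rate > 0.7) {
    warnf("lapse_rate %.2f is outside the regional 0.5-0.7 degC/100 m band", lapse_rate)
  }
  assert_scalar_number(roughness, "roughness", positive = TRUE)
  if (length(precip_gradient) != 2L || !is.numeric(precip_gradient)) {
    stopf("`precip_gradient` must be a numeric length-2 vector (mm/cell in x, y)")
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size_km = cell_size_km, lapse_rate = lapse_rate,
         sea_level_temp = sea_level_temp, precip_gradient = precip_gradient,
         precip_base = precip_base, precip_noise_sd = precip_noise_sd,
         roughness = roughness, seasonal_contrast = seasonal_contrast,
         max_elevation_m = max_elevation_m, seed = as.integer(seed)),
    class = "landscape_spec"
  )
}

#' Default glacial-interglacial climate anomaly for a slice age
#'
#' Temperature offset linear in age (-6 degrees C at 22 ka to 0 at present)
#' and precipitation scale factor 0.8 at 22 ka rising to 1.0 at present,
#' emulating cold and dry glacial conditions relaxing into the Holocene.
#'
#' @param age_ka slice age, ka BP.
#' @return list with `temp_offset` (degrees C) and `precip_scale`.
#' @export
default_anomaly <- function(age_ka) {
  a <- max(0, age_ka)
  list(temp_offset = -6 * a / 22, precip_scale = 1 - 0.2 * a / 22)
}

# Elevation field: spectrally smoothed Gaussian noise plus one deterministic
# NE-SW ridge, rescaled to [0, max_elevation_m]. Mildly right-skewed so
# highlands occupy a minority of the landscape, as on real tropical massifs.
synth_elevation <- function(spec) {
  nr <- spec$n_rows; nc <- spec$n_cols
  sigma <- max(2, min(nr, nc) * 0.06 / max(spec$roughness, 0.05))
  z <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
  z <- (z - min(z)) / (max(z) - min(z))
  col_frac <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  row_frac <- matrix(rep((seq_len(nr) - 0.5) / nr, times = nc), nr, nc)
  ridge_axis <- 0.55 * col_frac + 0.45 * row_frac
  ridge <- exp(-((ridge_axis - 0.5) / 0.06)^2)
  e <- z + 0.6 * ridge
  e <- (e - min(e)) / (max(e) - min(e))
  spec$max_elevation_m * e^3
}

# Smoothed random precipitation component (mm); structural (age-invariant).
synth_precip_noise <- function(spec) {
  if (spec$precip_noise_sd <= 0) return(matrix(0, spec$n_rows, spec$n_cols))
  nr <- spec$n_rows; nc <- spec$n_cols
  sigma <- max(2, min(nr, nc) * 0.05)
  z <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
  z <- z / stats::sd(z)
  spec$precip_noise_sd * z
}

#' Generate a synthetic bioclimatic stack for one time slice
#'
#' Builds an elevation field (smoothed random surface plus a deterministic
#' ridge), then derives bioclim layers from it: every temperature layer is
#' `sea_level_temp - lapse_rate * elevation / 100` plus a layer-specific
#' seasonal offset and the slice temperature anomaly; precipitation layers
#' are the base spatial gradient times the slice precipitation scale factor,
#' floored at zero. Seasonal range and precipitation seasonality increase
#' with local dryness (scaled by `seasonal_contrast`), which gives the
#' derived 19-variable set a realistic collinearity structure. Output is
#' bit-identical for identical `(spec, age, anomaly)`.
#'
#' @param spec a [landscape_spec()].
#' @param age_ka slice age, ka BP.
#' @param anomaly list with `temp_offset` (degrees C, additive to all
#'   temperature layers) and `precip_scale` (> 0, multiplies all
#'   precipitation amounts); defaults to [default_anomaly()] at `age_ka`.
#' @param full_bioclim if TRUE generate all 19 bioclim layers; otherwise the
#'   nine default predictors only.
#' @return A [climate_stack()].
#' @export
generate_climate_stack <- function(spec, age_ka = 0,
                                   anomaly = default_anomaly(age_ka),
                                   full_bioclim = FALSE) {
  if (!inherits(spec, "landscape_spec")) stopf("`spec` must be a landscape_spec")
  if (!is.numeric(anomaly$precip_scale) || anomaly$precip_scale <= 0) {
    stopf("precipitation scale factor must be > 0")
  }
  dT <- anomaly$temp_offset
  ps <- anomaly$precip_scale
  nr <- spec$n_rows; nc <- spec$n_cols
  geom <- grid_geometry(nr, nc, spec$cell_size_km)

  fields <- with_seed(spec$seed, {
    list(elev = synth_elevation(spec), pnoise = synth_precip_noise(spec))
  })
  elev <- fields$elev

  cc <- cell_centers(geom)
  xk <- matrix(cc$x, nr, nc); yk <- matrix(cc$y, nr, nc)
  x_mid <- geom$xmin + nc * spec$cell_size_km / 2
  y_mid <- geom$ymin + nr * spec$cell_size_km / 2
  p_base <- spec$precip_base +
    spec$precip_gradient[1] * (xk - x_mid) / spec$cell_size_km +
    spec$precip_gradient[2] * (yk - y_mid) / spec$cell_size_km +
    fields$pnoise
  bio12 <- pmax(ps * p_base, 0)

  # dryness in [0,1] drives seasonal contrast (drier = more seasonal climate)
  rng <- range(bio12)
  dry <- if (diff(rng) > 0) (rng[2] - bio12) / diff(rng) else matrix(0, nr, nc)
  sc <- spec$seasonal_contrast
  A <- 3 + 5 * dry * sc          # annual temperature half-range, degC
  D <- 8 + 6 * dry * sc          # mean diurnal range, degC
  S <- 0.25 + 0.55 * dry * sc    # precipitation seasonality index in (0,1)

  t_base <- spec$sea_level_temp - spec$lapse_rate * elev / 100 + dT
  layers <- list(
    bio1  = t_base,
    bio5  = t_base + A + D / 2,
    bio6  = t_base - A - D / 2,
    bio8  = t_base + 0.3 * A,
    bio9  = t_base - 0.3 * A,
    bio12 = bio12,
    bio13 = bio12 * (1 + 2 * S) / 12,
    bio14 = bio12 * (1 - S) * 0.5 / 12,
    bio18 = bio12 * (0.30 + 0.20 * S)
  )
  if (full_bioclim) {
    layers <- c(layers, list(
      bio2  = D,
      bio3  = 100 * D / (2 * A + D),
      bio4  = 100 * A / sqrt(2),
      bio7  = 2 * A + D,
      bio10 = t_base + 0.7 * A,
      bio11 = t_base - 0.7 * A,
      bio15 = 100 * S,
      bio16 = bio12 * (1 + 2 * S) * 2.7 / 12,
      bio17 = bio12 * (1 - S) * 0.5 * 3.3 / 12,
      bio19 = bio12 * (1 - S) * 0.5 * 2.5 / 12
    ))
    layers <- layers[paste0("bio", 1:19)]
  }
  climate_stack(layers, elev, geom, age_ka = age_ka)
}

#' Gaussian climatic envelope defining a synthetic vegetation unit
#'
#' Ground truth for recovery tests: a unit's suitability at a cell is the
#' product over variables of Gaussian densities (rescaled to peak at 1),
#' `prod_v exp(-0.5 ((x_v - optimum_v) / tolerance_v)^2)`.
#'
#' @param vu_id unit label (e.g. "AA", "EB", "DAF", "MAF", "ACB", "CTW", "DSS").
#' @param optima named numeric vector of per-variable optima (variable units).
#' @param tolerances named numeric vector of per-variable s.d. tolerances
#'   (> 0), same names as `optima`.
#' @return A `niche_definition` object.
#' @export
niche_definition <- function(vu_id, optima, tolerances) {
  if (!identical(sort(names(optima)), sort(names(tolerances)))) {
    stopf("optima and tolerances must share variable names")
  }
  if (any(tolerances <= 0)) stopf("tolerances must be > 0")
  structure(list(vu_id = vu_id, optima = optima,
                 tolerances = tolerances[names(optima)]),
            class = "niche_definition")
}

#' Default synthetic vegetation units arranged in altitudinal belts
#'
#' Seven units echoing the Ethiopian potential-vegetation classes: an
#' afroalpine belt (AA) and ericaceous belt (EB) at cold high elevations, dry
#' and moist Afromontane forests (DAF, MAF) at mid elevations separated by
#' annual rainfall, Acacia-Commiphora (ACB) and Combretum-Terminalia (CTW)
#' woodlands in warm lowlands separated by rainfall, and desert/semi-desert
#' scrub (DSS) on the hottest driest floor. With the default landscape
#' ([landscape_spec()]), lapse rate 0.6 degC/100 m and sea-level temperature
#' 28 degC, the envelope crossovers place AA above ~3200 m, EB ~2900-3200 m,
#' the forests ~1800-2900 m, the woodlands ~600-1800 m and DSS below.
#'
#' @return named list of [niche_definition()]s in the canonical unit order
#'   AA, EB, DAF, MAF, ACB, CTW, DSS (also the compositing tie-break order).
#' @export
default_niches <- function() {
  defs <- list(
    niche_definition("AA",  c(bio1 = 6),                  c(bio1 = 2)),
    niche_definition("EB",  c(bio1 = 9.5),                c(bio1 = 0.9)),
    niche_definition("DAF", c(bio1 = 14,   bio12 = 950),  c(bio1 = 2.2, bio12 = 350)),
    niche_definition("MAF", c(bio1 = 14.5, bio12 = 1650), c(bio1 = 2.2, bio12 = 250)),
    niche_definition("ACB", c(bio1 = 21.5, bio12 = 800),  c(bio1 = 2.6, bio12 = 300)),
    niche_definition("CTW", c(bio1 = 21.5, bio12 = 1400), c(bio1 = 2.6, bio12 = 300)),
    niche_definition("DSS", c(bio1 = 26.5, bio12 = 400),  c(bio1 = 1.8, bio12 = 400))
  )
  stats::setNames(defs, vapply(defs, `[[`, character(1), "vu_id"))
}

# Product-Gaussian suitability of one niche over all cells; returns a vector.
niche_suitability <- function(stack, niche) {
  vars <- names(niche$optima)
  x <- stack_values(stack, vars)
  z2 <- sweep(x, 2L, niche$optima, `-`)
  z2 <- sweep(z2, 2L, niche$tolerances, `/`)^2
  exp(-0.5 * rowSums(z2))
}

#' Ground-truth vegetation map from climatic envelopes
#'
#' Assigns each cell to the niche with maximal product-Gaussian suitability;
#' cells where every suitability falls below `threshold` get the no-analog
#' label.
#'
#' @param stack a [climate_stack()].
#' @param niches list of [niche_definition()]s.
#' @param threshold no-analog suitability threshold (default 0.1).
#' @return A [vegetation_map()].
#' @export
generate_true_vegetation <- function(stack, niches, threshold = 0.1) {
  if (length(niches) == 0) stopf("`niches` must be a non-empty list")
  for (n in niches) {
    miss <- setdiff(names(n$optima), names(stack$layers))
    if (length(miss)) stopf("niche '%s' references missing variable(s): %s",
                            n$vu_id, paste(miss, collapse = ", "))
  }
  suit <- vapply(niches, function(n) niche_suitability(stack, n),
                 numeric(stack$geom$n_rows * stack$geom$n_cols))
  suit <- matrix(suit, ncol = length(niches))
  ids <- vapply(niches, `[[`, character(1), "vu_id")
  best <- max.col(suit, ties.method = "first")
  lab <- ids[best]
  lab[suit[cbind(seq_len(nrow(suit)), best)] < threshold] <- no_analog_label()
  vegetation_map(matrix(lab, stack$geom$n_rows, stack$geom$n_cols),
                 stack$geom, age_ka = stack$age_ka, threshold = threshold,
                 provenance = paste0("true:", ids))
}

#' Sample presence locations within a unit's mapped extent
#'
#' Draws `n` coordinates uniformly over the cells labelled `vu_id` (cells
#' with replacement, then a uniform jitter within each chosen cell, so no
#' two points coincide almost surely).
#'
#' @param vumap a [vegetation_map()].
#' @param vu_id unit label to sample from.
#' @param n number of presence points (>= 1).
#' @param seed integer seed.
#' @return An `occurrence_set`: data.frame with columns `vu_id`, `x`, `y`
#'   and attribute `provenance = "synthetic"`.
#' @export
sample_presences <- function(vumap, vu_id, n = 1000, seed = 1L) {
  if (n < 1) stopf("`n` must be >= 1")
  idx <- which(vumap$labels == vu_id)
  if (length(idx) == 0) stopf("unit '%s' occupies no cells on this map", vu_id)
  geom <- vumap$geom
  with_seed(seed, {
    pick <- idx[sample.int(length(idx), n, replace = TRUE)]
    row <- (pick - 1L) %% geom$n_rows + 1L
    col <- (pick - 1L) %/% geom$n_rows + 1L
    cs <- geom$cell_size_km
    occ <- data.frame(
      vu_id = unname(vu_id),
      x = geom$xmin + (col - 1L) * cs + stats::runif(n) * cs,
      y = geom$ymin + (row - 1L) * cs + stats::runif(n) * cs
    )
    attr(occ, "provenance") <- "synthetic"
    class(occ) <- c("occurrence_set", "data.frame")
    occ
  })
}

#' Synthetic atmospheric CO2 concentration series
#'
#' Piecewise-linear ramp through anchor points rising monotonically from
#' 185 ppm at 22 ka (glacial low) to 280 ppm at present (pre-industrial),
#' evaluated at the requested ages.
#'
#' @param ages slice ages, ka BP (any order; deduplicated).
#' @return A `co2_series`: data.frame `age_ka`, `co2_ppm`, sorted oldest
#'   first.
#' @export
generate_co2_series <- function(ages = 22:0) {
  if (length(ages) == 0) stopf("`ages` must be non-empty")
  anchors_age <- c(22, 18, 15, 11, 7, 0)
  anchors_ppm <- c(185, 190, 210, 250, 265, 280)
  ages <- sort(unique(ages), decreasing = TRUE)
  ppm <- stats::approx(anchors_age, anchors_ppm, xout = pmin(pmax(ages, 0), 22),
                       rule = 2)$y
  out <- data.frame(age_ka = ages, co2_ppm = ppm)
  class(out) <- c("co2_series", "data.frame")
  out
}

#' Synthetic taxa-to-unit grouping table
#'
#' Emulates a regional pollen-taxonomy table: `n_assigned` taxa assigned to
#' vegetation units (round-robin over `units`), the remainder split between
#' wetland, ambiguous, and multigroup exclusions.
#'
#' @param units unit labels to assign taxa to.
#' @param n_taxa total number of taxa (default 361).
#' @param n_assigned taxa with clear ecological significance (default 240).
#' @param seed integer seed (shuffles assignments).
#' @return data.frame `taxon`, `assignment` suitable for [taxa_grouping()].
#' @export
generate_taxa_grouping <- function(units = names(default_niches()),
                                   n_taxa = 361, n_assigned = 240, seed = 1L) {
  if (n_assigned > n_taxa) stopf("`n_assigned` cannot exceed `n_taxa`")
  n_excl <- n_taxa - n_assigned
  with_seed(seed, {
    assigned <- rep(units, length.out = n_assigned)
    excl_pool <- c("excluded-wetland", "excluded-ambiguous", "excluded-multigroup")
    excluded <- rep(excl_pool, length.out = n_excl)
    assignment <- sample(c(assigned, excluded))
    data.frame(
      taxon = sprintf("taxon_%03d", seq_len(n_taxa)),
      assignment = assignment,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic fossil pollen record at a site
#'
#' One sample per time slice. Unit-group proportions are proportional to
#' `exp(-d_g / delta_km)`, where `d_g` is the distance from the site to the
#' nearest cell mapped as group `g`'s unit on that slice (0 when the site
#' sits inside the unit, weight 0 when the unit is absent). The assignable
#' mass (1 - wetland_prop - ambiguous_prop) is split among unit groups by
#' those weights, evenly among each group's taxa; wetland and
#' ambiguous/multigroup taxa receive fixed background proportions. Counts
#' are drawn multinomially.
#'
#' @param site length-2 numeric `(x, y)` in km.
#' @param vumaps time-ordered list of [vegetation_map()]s (shared geometry).
#' @param taxa_grouping a [taxa_grouping()] or the data.frame accepted by it.
#' @param counts_per_sample grains counted per sample (>= 1).
#' @param delta_km distance-decay scale of pollen transport (default 20 km).
#' @param wetland_prop,ambiguous_prop fixed background proportions for
#'   excluded taxa.
#' @param seed integer seed.
#' @return A `pollen_record`: list with `site` (x, y, elevation NA),
#'   `samples` (data.frame `sample_id`, `age_ka`) and integer `counts`
#'   matrix (samples x taxa).
#' @export
generate_pollen_record <- function(site, vumaps, taxa_grouping,
                                   counts_per_sample = 300, delta_km = 20,
                                   wetland_prop = 0.12, ambiguous_prop = 0.08,
                                   seed = 1L) {
  if (counts_per_sample < 1) stopf("`counts_per_sample` must be >= 1")
  grouping <- as_taxa_grouping(taxa_grouping)
  geom <- vumaps[[1]]$geom
  for (vm in vumaps) {
    if (!same_geometry(geom, vm$geom)) stopf("all vegetation maps must share geometry")
  }
  if (anyNA(cells_at(geom, site[1], site[2])$cell)) {
    stopf("site (%g, %g) lies outside the grid", site[1], site[2])
  }
  units <- unique(grouping$assignment[!startsWith(grouping$assignment, "excluded-")])
  taxa <- grouping$taxon
  wet_taxa <- taxa[grouping$assignment == "excluded-wetland"]
  amb_taxa <- taxa[grouping$assignment %in%
                     c("excluded-ambiguous", "excluded-multigroup")]
  assignable <- 1 - wetland_prop * (length(wet_taxa) > 0) -
    ambiguous_prop * (length(amb_taxa) > 0)

  ages <- vapply(vumaps, `[[`, numeric(1), "age_ka")
  counts <- matrix(0L, nrow = length(vumaps), ncol = length(taxa),
                   dimnames = list(sprintf("s%02d", seq_along(vumaps)), taxa))
  with_seed(seed, {
    for (i in seq_along(vumaps)) {
      d <- vapply(units, function(u) habitat_distance(vumaps[[i]], site, u),
                  numeric(1))
      w <- ifelse(is.finite(d), exp(-d / delta_km), 0)
      prob <- stats::setNames(numeric(length(taxa)), taxa)
      if (sum(w) > 0) {
        gshare <- assignable * w / sum(w)
        for (g in seq_along(units)) {
          gt <- taxa[grouping$assignment == units[g]]
          if (length(gt)) prob[gt] <- gshare[g] / length(gt)
        }
      }
      if (length(wet_taxa)) prob[wet_taxa] <- wetland_prop / length(wet_taxa)
      if (length(amb_taxa)) prob[amb_taxa] <- ambiguous_prop / length(amb_taxa)
      if (sum(prob) == 0) stopf("no taxon has positive expected proportion")
      counts[i, ] <- as.integer(stats::rmultinom(1, counts_per_sample,
                                                 prob / sum(prob)))
    }
  })
  structure(
    list(site = list(x = site[1], y = site[2], elevation = NA_real_),
         samples = data.frame(sample_id = rownames(counts), age_ka = ages),
         counts = counts),
    class = "pollen_record"
  )
}
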