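# Synthetic landscape generator: lapse-rate climate, ground-truth belts,
# presence sampling, CO2 ramp, pollen assemblages.

test_that("temperature follows the lapse rate exactly and anomalies are additive", {
  spec <- small_spec()
  st <- generate_climate_stack(spec, age_ka = 0)
  # mean annual temperature is an exact affine function of elevation:
  # 28 degC at sea level minus 0.6 degC per 100 m (a 1000 m cell reads 22.0)
  expect_equal(st$layers$bio1,
               spec$sea_level_temp - spec$lapse_rate * st$elevation / 100,
               tolerance = 1e-12)
  cold <- generate_climate_stack(spec, age_ka = 0,
                                 anomaly = list(temp_offset = -4,
                                                precip_scale = 1))
  for (v in c("bio1", "bio5", "bio6", "bio8", "bio9")) {
    expect_equal(cold$layers[[v]], st$layers[[v]] - 4, tolerance = 1e-12)
  }
  expect_equal(cold$layers$bio12, st$layers$bio12)
  dry <- generate_climate_stack(spec, age_ka = 0,
                                anomaly = list(temp_offset = 0,
                                               precip_scale = 0.8))
  expect_true(all(dry$layers$bio12 >= 0))
  expect_equal(dry$layers$bio12[st$layers$bio12 > 0],
               pmax(0.8 * st$layers$bio12, 0)[st$layers$bio12 > 0])
})

test_that("stacks are deterministic in (spec, seed) and validate inputs", {
  spec <- small_spec()
  a <- generate_climate_stack(spec, age_ka = 5)
  b <- generate_climate_stack(spec, age_ka = 5)
  expect_identical(a, b)
  expect_error(landscape_spec(n_rows = 4), "dimensions")
  expect_error(generate_climate_stack(spec,
                                      anomaly = list(temp_offset = 0,
                                                     precip_scale = 0)),
               "scale factor")
  expect_warning(landscape_spec(lapse_rate = 0.9), "0.5-0.7")
})

test_that("regressing any temperature layer on elevation recovers the lapse rate", {
  spec <- landscape_spec(n_rows = 60, n_cols = 60, seasonal_contrast = 0,
                         seed = 3L)
  st <- generate_climate_stack(spec)
  for (v in c("bio1", "bio5", "bio6", "bio8", "bio9")) {
    slope <- stats::coef(stats::lm(as.vector(st$layers[[v]]) ~
                                     as.vector(st$elevation)))[2]
    expect_equal(unname(slope), -spec$lapse_rate / 100, tolerance = 1e-6)
  }
})

test_that("ground-truth assignment matches brute-force suitability evaluation", {
  st <- generate_climate_stack(small_spec())
  lo <- niche_definition("LOW", c(bio1 = 26), c(bio1 = 6))
  hi <- niche_definition("HIGH", c(bio1 = 8), c(bio1 = 6))
  tv <- generate_true_vegetation(st, list(lo, hi), threshold = 0.1)
  # brute force every cell with the raw Gaussian formula
  t1 <- as.vector(st$layers$bio1)
  s_lo <- exp(-0.5 * ((t1 - 26) / 6)^2)
  s_hi <- exp(-0.5 * ((t1 - 8) / 6)^2)
  want <- ifelse(pmax(s_lo, s_hi) < 0.1, no_analog_label(),
                 ifelse(s_lo >= s_hi, "LOW", "HIGH"))
  expect_identical(as.vector(tv$labels), want)
  # the boundary is an elevation contour: every LOW cell sits below every
  # HIGH cell (ties impossible on continuous elevations)
  el <- as.vector(st$elevation)
  expect_lt(max(el[tv$labels == "LOW"]), min(el[tv$labels == "HIGH"]))
})

test_that("single broad niche claims all cells; hopeless niche yields no-analog", {
  st <- generate_climate_stack(small_spec())
  broad <- niche_definition("ALL", c(bio1 = 15), c(bio1 = 100))
  tv <- generate_true_vegetation(st, list(broad))
  expect_true(all(tv$labels == "ALL"))
  far <- niche_definition("FAR", c(bio1 = 500), c(bio1 = 1))
  tv2 <- generate_true_vegetation(st, list(far))
  expect_true(all(tv2$labels == no_analog_label()))
  expect_error(generate_true_vegetation(st, list()), "non-empty")
})

test_that("default units form ordered altitudinal belts", {
  st <- generate_climate_stack(landscape_spec(seed = 11L))
  tv <- generate_true_vegetation(st, default_niches())
  el <- as.vector(st$elevation)
  lab <- as.vector(tv$labels)
  m <- vapply(c("AA", "EB", "DAF"), function(u) mean(el[lab == u]), numeric(1))
  expect_true(m["AA"] > m["EB"])
  expect_true(m["EB"] > m["DAF"])
})

test_that("presence sampling stays inside the unit and is reproducible", {
  st <- generate_climate_stack(small_spec())
  tv <- generate_true_vegetation(st, default_niches())
  occ <- sample_presences(tv, "CTW", n = 1000, seed = 5)
  expect_equal(nrow(occ), 1000)
  loc <- cells_at(tv$geom, occ$x, occ$y)
  expect_true(all(tv$labels[cbind(loc$row, loc$col)] == "CTW"))
  occ2 <- sample_presences(tv, "CTW", n = 1000, seed = 5)
  expect_identical(occ, occ2)
  expect_error(sample_presences(tv, "NOPE"), "no cells")
  # single-cell unit: the one point lies within that cell
  one <- manual_vumap(c("Z", rep("Q", 99)), 10, 10)
  p <- sample_presences(one, "Z", n = 1, seed = 2)
  expect_true(p$x >= 0 && p$x <= 1 && p$y >= 0 && p$y <= 1)
})

test_that("CO2 ramp is monotone from 185 ppm at 22 ka to 280 ppm at present", {
  s <- generate_co2_series(22:0)
  expect_equal(s$co2_ppm[s$age_ka == 22], 185)
  expect_equal(s$co2_ppm[s$age_ka == 0], 280)
  mid <- s$co2_ppm[s$age_ka == 11]
  expect_gt(mid, 185)
  expect_lt(mid, 280)
  # ages sorted oldest first, concentrations non-decreasing toward present
  expect_true(all(diff(s$age_ka) < 0))
  expect_true(all(diff(s$co2_ppm) >= 0))
  expect_error(generate_co2_series(numeric()), "non-empty")
})

test_that("pollen generator concentrates assignable mass on the local unit", {
  vm <- manual_vumap("A", 20, 20)
  tg <- generate_taxa_grouping(units = c("A", "B"), n_taxa = 30,
                               n_assigned = 20, seed = 1)
  rec <- generate_pollen_record(c(10, 10), list(vm), tg,
                                counts_per_sample = 2000, seed = 3)
  assign <- setNames(tg$assignment, tg$taxon)[colnames(rec$counts)]
  # unit B is absent from the map: its taxa receive nothing
  expect_equal(sum(rec$counts[1, assign == "B"]), 0)
  expect_gt(sum(rec$counts[1, assign == "A"]), 0)
  expect_error(generate_pollen_record(c(10, 10), list(vm), tg,
                                      counts_per_sample = 0), ">= 1")
  expect_error(generate_pollen_record(c(999, 10), list(vm), tg), "outside")
})

test_that("empirical pollen proportions match the distance-decay model", {
  # unit A on the west edge, unit B on the south edge; site distances are
  # then known exactly and expected group shares follow exp(-d/delta)
  lab <- matrix("bg", 40, 40)
  lab[, 1] <- "A"
  lab[1, ] <- "B"
  vm <- vegetation_map(lab, grid_geometry(40, 40, 1))
  tg <- data.frame(taxon = c("a1", "a2", "b1", "wet1", "amb1"),
                   assignment = c("A", "A", "B", "excluded-wetland",
                                  "excluded-ambiguous"))
  site <- c(10.5, 20.5)
  d_A <- 10.5 - 0.5
  d_B <- 20.5 - 0.5
  # groups come from the taxa table, so the unlabelled "bg" matrix carries
  # no pollen group; assignable mass splits between A and B only
  w <- exp(-c(d_A, d_B) / 20)
  share <- 0.8 * w / sum(w)
  rec <- generate_pollen_record(site, list(vm), tg,
                                counts_per_sample = 10000, seed = 9)
  p <- rec$counts[1, ] / 10000
  expect_lt(abs(p[["a1"]] + p[["a2"]] - share[1]), 0.02)
  expect_lt(abs(p[["b1"]] - share[2]), 0.02)
  expect_lt(abs(p[["wet1"]] - 0.12), 0.02)
  expect_lt(abs(p[["amb1"]] - 0.08), 0.02)
})

test_that("group share decreases with distance to habitat, others fixed", {
  lab <- matrix("bg", 40, 40)
  lab[, 1] <- "A"
  lab[1, ] <- "B"
  vm <- vegetation_map(lab, grid_geometry(40, 40, 1))
  tg <- data.frame(taxon = c("a1", "b1"), assignment = c("A", "B"))
  share_A <- function(x) {
    rec <- generate_pollen_record(c(x, 20.5), list(vm), tg,
                                  counts_per_sample = 20000, seed = 4)
    rec$counts[1, "a1"] / sum(rec$counts[1, ])
  }
  near <- share_A(5.5)   # d_A = 5, d_B = 20 in both cases
  far <- share_A(15.5)   # d_A = 15
  expect_gt(near, far)
})

test_that("synthetic taxa table reproduces the assigned/excluded split", {
  tg <- generate_taxa_grouping()
  expect_equal(nrow(tg), 361)
  units <- names(default_niches())
  expect_equal(sum(tg$assignment %in% units), 240)
  expect_equal(sum(startsWith(tg$assignment, "excluded-")), 121)
})
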