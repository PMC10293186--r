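# Pollen grouping, percentage series, habitat distance, concordance.

test_that("taxa grouping validates structure and reports the split", {
  tg_df <- generate_taxa_grouping()
  expect_message(tg <- taxa_grouping(tg_df), "240 assigned.*121 excluded")
  dup <- rbind(tg_df, tg_df[1, ])
  expect_error(suppressMessages(taxa_grouping(dup)), "duplicate")
  expect_error(suppressMessages(taxa_grouping(tg_df[0, ])), "empty")
  bad <- tg_df
  bad$assignment[5] <- "XYZ"
  expect_error(suppressMessages(taxa_grouping(bad)), "XYZ")
})

test_that("group percentages use the assigned-taxa pollen sum only", {
  counts <- matrix(c(30, 50, 20), 1, dimnames = list("s1", c("tA", "tB", "tW")))
  rec <- list(site = list(x = 0, y = 0),
              samples = data.frame(sample_id = "s1", age_ka = 4),
              counts = counts)
  tg <- data.frame(taxon = c("tA", "tB", "tW"),
                   assignment = c("A", "B", "excluded-wetland"))
  gp <- group_percentages(rec, tg)
  expect_equal(gp$percentage[gp$unit == "A"], 37.5)
  expect_equal(gp$percentage[gp$unit == "B"], 62.5)
  expect_equal(unique(gp$pollen_sum), 80)
  expect_equal(unique(gp$excluded_grains), 20)
  expect_equal(sum(gp$percentage), 100, tolerance = 1e-9)
  # adding grains to an excluded taxon changes no group percentage
  rec2 <- rec
  rec2$counts[1, "tW"] <- 500
  gp2 <- group_percentages(rec2, tg)
  expect_equal(gp2$percentage, gp$percentage)
  # all grains excluded -> missing with warning
  rec3 <- rec
  rec3$counts[1, ] <- c(0, 0, 12)
  expect_warning(gp3 <- group_percentages(rec3, tg), "excluded")
  expect_true(all(is.na(gp3$percentage)))
  rec4 <- rec
  rec4$counts[1, 1] <- -1
  expect_error(group_percentages(rec4, tg), "negative")
  # unlisted taxa fall into the ambiguous class with a warning
  tg_short <- tg[1:2, ]
  expect_warning(gp5 <- group_percentages(rec, tg_short), "missing from")
  expect_equal(gp5$percentage[gp5$unit == "A"], 37.5)
})

test_that("synthetic records round-trip to the generator's proportions", {
  vm <- manual_vumap("A", 20, 20)
  lab <- vm$labels
  lab[, 20] <- "B"
  vm <- vegetation_map(lab, vm$geom)
  tg <- data.frame(taxon = c("a1", "a2", "b1", "w1"),
                   assignment = c("A", "A", "B", "excluded-wetland"))
  rec <- generate_pollen_record(c(2.5, 10.5), list(vm), tg,
                                counts_per_sample = 20000, seed = 6)
  gp <- group_percentages(rec, tg)
  w <- exp(-c(0, 19.5 - 2.5) / 20)     # site sits in A; B is 17 km east
  want <- 100 * w / sum(w)
  expect_equal(gp$percentage[gp$unit == "A"], want[1], tolerance = 1.5)
  expect_equal(gp$percentage[gp$unit == "B"], want[2], tolerance = 1.5)
})

test_that("habitat distance matches an exhaustive all-cell scan", {
  lab <- matrix("x", 12, 12)
  lab[4, 9] <- "U"      # cell center (8.5, 3.5)
  vm <- vegetation_map(lab, grid_geometry(12, 12, 1))
  expect_equal(habitat_distance(vm, c(5.5, 3.5), "U"), 3)
  expect_equal(habitat_distance(vm, c(8.6, 3.4), "U"), 0)
  expect_identical(habitat_distance(vm, c(1, 1), "absent"), Inf)
  expect_error(habitat_distance(vm, c(50, 1), "U"), "outside")
  set.seed(41)
  rl <- sample(c("U", "V"), 144, replace = TRUE, prob = c(0.1, 0.9))
  rvm <- vegetation_map(matrix(rl, 12, 12), grid_geometry(12, 12, 1))
  site <- c(7.3, 2.9)
  got <- habitat_distance(rvm, site, "U")
  # oracle: zero when the site's own cell is labelled, else the nearest
  # labelled cell-center distance, scanned exhaustively
  if (rvm$labels[floor(site[2]) + 1, floor(site[1]) + 1] == "U") {
    best <- 0
  } else {
    best <- Inf
    for (r in 1:12) for (c in 1:12) {
      if (rvm$labels[r, c] == "U") {
        d <- sqrt((c - 0.5 - site[1])^2 + (r - 0.5 - site[2])^2)
        best <- min(best, d)
      }
    }
  }
  expect_equal(got, best)
})

test_that("concordance is the Spearman rank agreement with proximity", {
  series <- data.frame(sample_id = paste0("s", 1:4), age_ka = c(12, 7, 4, 1),
                       unit = "A", percentage = c(10, 20, 15, 5),
                       pollen_sum = 100, excluded_grains = 0)
  # strictly decreasing percentage with strictly increasing distance
  d_perfect <- data.frame(age_ka = c(12, 7, 4, 1),
                          distance_km = c(1, 2, 3, 4) * 2)
  s_perfect <- series
  s_perfect$percentage <- c(40, 30, 20, 10)
  expect_equal(concordance(s_perfect, d_perfect, "A")$rho, 1)
  # hand-computed 4-point case: rho = 1 - 6*8/60 = 0.2
  d <- data.frame(age_ka = c(12, 7, 4, 1), distance_km = c(8, 2, 12, 4))
  got <- concordance(series, d, "A")
  expect_equal(got$rho, 0.2)
  expect_equal(got$rho, spearman_by_hand(series$percentage, -d$distance_km))
  expect_equal(got$n_ages, 4)
  # constant distances -> undefined, reported missing
  flat <- data.frame(age_ka = c(12, 7, 4, 1), distance_km = rep(3, 4))
  expect_message(cf <- concordance(series, flat, "A"), "undefined")
  expect_true(is.na(cf$rho))
  expect_error(concordance(series[1:2, ], d, "A"), "fewer than 3")
})

test_that("hindcast vegetation shifts leave a concordant pollen signal", {
  # three synthetic slices with the montane belt descending into the past;
  # records generated from those same maps must track habitat proximity
  spec <- small_spec(seed = 12L)
  niches <- default_niches()
  maps <- lapply(c(22, 11, 0), function(a) {
    generate_true_vegetation(generate_climate_stack(spec, age_ka = a), niches)
  })
  tg_df <- generate_taxa_grouping(seed = 2)
  tg <- suppressMessages(taxa_grouping(tg_df))
  dem <- generate_climate_stack(spec)$elevation
  mid <- which(dem > 1500 & dem < 2500, arr.ind = TRUE)[1, ]
  site <- c(mid[2] - 0.5, mid[1] - 0.5)
  rec <- generate_pollen_record(site, maps, tg, counts_per_sample = 2000,
                                seed = 3)
  gp <- group_percentages(rec, tg)
  rhos <- c()
  for (u in c("DAF", "ACB", "AA")) {
    d <- data.frame(age_ka = c(22, 11, 0),
                    distance_km = vapply(maps, habitat_distance, numeric(1),
                                         site = site, vu_id = u))
    if (all(is.finite(d$distance_km)) && sd(d$distance_km) > 0) {
      rhos <- c(rhos, concordance(gp, d, u)$rho)
    }
  }
  expect_gt(mean(rhos, na.rm = TRUE), 0)
})
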