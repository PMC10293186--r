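# Presence-background maximum-entropy models: splitting, background,
# solver correctness, prediction transforms, AUC.

test_that("holdout split uses the floor rule and reproduces exactly", {
  occ <- data.frame(vu_id = "U", x = runif(1000), y = runif(1000))
  sp <- split_occurrences(occ, 0.25, seed = 3)
  expect_equal(nrow(sp$test), 250)
  expect_equal(nrow(sp$train), 750)
  expect_equal(nrow(merge(sp$test, sp$train)), 0)
  both <- rbind(sp$train, sp$test)
  expect_setequal(both$x, occ$x)
  sp4 <- split_occurrences(occ[1:4, ], 0.25, seed = 1)
  expect_equal(nrow(sp4$test), 1)
  expect_identical(split_occurrences(occ, 0.25, seed = 3), sp)
  expect_error(split_occurrences(occ[1, , drop = FALSE]), "at least 2")
  expect_error(split_occurrences(occ, 1.2), "between 0 and 1")
})

test_that("background sampling is valid, capped, and uniform", {
  st <- manual_stack(list(bio1 = rnorm(50), bio12 = runif(50, 0, 100)), 10, 5)
  expect_warning(bg <- sample_background(st, 10000, seed = 1), "using all")
  expect_equal(nrow(bg), 50)
  expect_true(all(is.finite(as.matrix(bg[, c("bio1", "bio12")]))))
  # empirical selection frequency uniform within binomial error
  hits <- integer(50)
  for (r in 1:300) {
    b <- sample_background(st, 10, seed = 1000 + r)
    hits[b$cell] <- hits[b$cell] + 1
  }
  p <- 10 / 50
  expect_true(all(abs(hits - 300 * p) < 5 * sqrt(300 * p * (1 - p))))
})

test_that("fitted weight matches a 1-D brute-force objective scan", {
  # one binary feature over a 20-cell background
  B <- matrix(c(rep(1, 6), rep(0, 14)), ncol = 1)
  pbar <- 0.7
  w <- 0.05
  fit <- paleoveg:::maxent_solve_cpp(B, pbar, w, 1e-9, 100000L, 25L)
  grid <- seq(-10, 10, by = 1e-4)
  obj <- vapply(grid, function(l) {
    log(sum(exp(B * l))) - pbar * l + w * abs(l)
  }, numeric(1))
  expect_lt(abs(fit$lambda - grid[which.min(obj)]), 1e-3)
  expect_true(fit$converged)
})

test_that("uninformative or crushed features leave the background uniform", {
  B <- matrix(1, 20, 1)                   # constant feature
  fit <- paleoveg:::maxent_solve_cpp(B, 1, 0.1, 1e-9, 1000L, 5L)
  expect_equal(as.numeric(fit$lambda), 0)
  # a dominating penalty forces all weights to zero -> uniform q
  st <- generate_climate_stack(small_spec())
  tv <- generate_true_vegetation(st, default_niches())
  occ <- sample_presences(tv, "CTW", 200, seed = 1)
  bg <- sample_background(st, 500, predictors = default_predictors(), seed = 2)
  m <- fit_maxent(occ, bg, st, beta = 1e6, n_hinge_knots = 5)
  expect_true(all(m$lambda == 0))
  raw <- predict_suitability(m, st, output = "raw")
  expect_equal(max(raw$values), min(raw$values))
  clog <- predict_suitability(m, st)
  expect_equal(unique(as.vector(clog$values)), 1 - exp(-1), tolerance = 1e-12)
})

test_that("solver objective is non-increasing and KKT conditions hold", {
  st <- generate_climate_stack(small_spec())
  tv <- generate_true_vegetation(st, default_niches())
  occ <- sample_presences(tv, "DAF", 300, seed = 5)
  bg <- sample_background(st, 1000, predictors = default_predictors(), seed = 6)
  m <- fit_maxent(occ, bg, st, n_hinge_knots = 11)
  expect_true(all(diff(m$objective_path) <= 1e-9))
  # independent KKT recomputation: |presence mean - E_q f| <= beta*s + tol
  pres_x <- stack_values_at(st, occ$x, occ$y, m$meta$predictors)
  bg_x <- as.matrix(bg[, m$meta$predictors])
  Fp <- feature_matrix(m$features, pres_x, clamp = FALSE)$F
  Fz <- feature_matrix(m$features, rbind(bg_x, pres_x), clamp = FALSE)$F
  q <- exp(as.numeric(Fz %*% m$lambda) - m$log_z)
  expect_equal(sum(q), 1, tolerance = 1e-9)
  resid <- abs(colMeans(Fp) - as.numeric(t(Fz) %*% q))
  expect_true(all(resid <= m$beta * m$penalty_scale + 1e-4))
})

test_that("raw output normalizes over the training set; cloglog is monotone", {
  st <- generate_climate_stack(small_spec())
  tv <- generate_true_vegetation(st, default_niches())
  occ <- sample_presences(tv, "EB", 200, seed = 8)
  bg <- sample_background(st, 800, predictors = default_predictors(), seed = 9)
  m <- fit_maxent(occ, bg, st, n_hinge_knots = 11)
  pres_x <- stack_values_at(st, occ$x, occ$y, m$meta$predictors)
  train_x <- rbind(as.matrix(bg[, m$meta$predictors]), pres_x)
  Fz <- feature_matrix(m$features, train_x, clamp = FALSE)$F
  raw_train <- exp(as.numeric(Fz %*% m$lambda) - m$log_z)
  expect_equal(sum(raw_train), 1, tolerance = 1e-9)
  raw <- predict_suitability(m, st, output = "raw")
  clog <- predict_suitability(m, st, output = "cloglog")
  o <- order(as.vector(raw$values))
  expect_true(all(diff(as.vector(clog$values)[o]) >= -1e-12))
  expect_true(all(clog$values >= 0 & clog$values <= 1))
})

test_that("AUC is exact pair counting and rank-invariant", {
  expect_equal(auc_exact(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_equal(auc_exact(c(1, 1), c(1, 1, 1)), 0.5)
  expect_equal(auc_exact(c(5, 6), c(1, 2)), 1)
  # exhaustive pair-counting oracle on random instances
  set.seed(11)
  for (r in 1:20) {
    pos <- sample(1:8, 7, replace = TRUE)
    neg <- sample(1:8, 9, replace = TRUE)
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc_exact(pos, neg), mean(pairs))
  }
  # monotone transform of scores leaves model AUC unchanged (raw vs cloglog
  # are monotone transforms of each other, so this is the same invariance)
  st <- generate_climate_stack(small_spec())
  tv <- generate_true_vegetation(st, default_niches())
  occ <- sample_presences(tv, "AA", 200, seed = 13)
  sp <- split_occurrences(occ, 0.25, seed = 14)
  bg <- sample_background(st, 600, predictors = default_predictors(), seed = 15)
  m <- fit_maxent(sp$train, bg, st, n_hinge_knots = 11)
  a1 <- evaluate_auc(m, sp$test, bg, st)$auc
  s_test <- paleoveg:::model_scores(
    m, stack_values_at(st, sp$test$x, sp$test$y, m$meta$predictors))$scores
  s_bg <- paleoveg:::model_scores(m, as.matrix(bg[, m$meta$predictors]))$scores
  expect_equal(auc_exact(exp(s_test), exp(s_bg)), a1, tolerance = 1e-12)
})

test_that("top decile of modeled suitability recovers the true extent", {
  st <- generate_climate_stack(landscape_spec())
  tv <- generate_true_vegetation(st, default_niches())
  occ <- sample_presences(tv, "DAF", 1000, seed = 22)
  sp <- split_occurrences(occ, 0.25, seed = 23)
  bg <- sample_background(st, 10000, predictors = default_predictors(),
                          seed = 24)
  m <- fit_maxent(sp$train, bg, st)
  s <- predict_suitability(m, st)
  top <- as.vector(s$values) >= stats::quantile(s$values, 0.9)
  truth <- as.vector(tv$labels) == "DAF"
  jaccard <- sum(top & truth) / sum(top | truth)
  expect_gte(jaccard, 0.3)
})
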