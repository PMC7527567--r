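test_that("generation is fully deterministic under a fixed seed", {
  cfg <- test_config(seed = 11)
  expect_identical(generate_landscape(cfg)$values,
                   generate_landscape(cfg)$values)
  expect_identical(generate_dem(cfg)$values, generate_dem(cfg)$values)
  z1 <- generate_zones(cfg); z2 <- generate_zones(cfg)
  expect_identical(z1$raster$values, z2$raster$values)
  expect_identical(z1$levels, z2$levels)
  cfg2 <- test_config(seed = 12)
  expect_false(identical(generate_landscape(cfg)$values,
                         generate_landscape(cfg2)$values))
})

test_that("realized class proportions track the requested ones", {
  cfg <- synthetic_config(nrow = 64, ncol = 64, n_seeds = 16, seed = 2)
  r <- generate_landscape(cfg)
  at <- area_table(r)
  realized <- at$cells / sum(at$cells)
  expect_true(all(abs(realized - cfg$proportions) <= 0.05))
})

test_that("cohesion 0 degenerates to independent per-cell draws", {
  p <- c("1" = 0.6, "2" = 0.4)
  cfg <- synthetic_config(nrow = 64, ncol = 64, proportions = p,
                          cohesion = 0, scheme = eco_binary_scheme(),
                          seed = 8)
  r <- generate_landscape(cfg)
  n <- length(r$values)
  frac1 <- mean(r$values == 1)
  # binomial oracle: 4-sigma band around 0.6
  expect_lt(abs(frac1 - 0.6), 4 * sqrt(0.6 * 0.4 / n))
  # independent draws fragment the landscape far more than cohesive growth
  frag <- generate_landscape(synthetic_config(nrow = 64, ncol = 64,
                                              cohesion = 0, seed = 13))
  coh <- generate_landscape(synthetic_config(nrow = 64, ncol = 64,
                                             cohesion = 1, seed = 13))
  expect_gt(nrow(label_patches(frag)), 5 * nrow(label_patches(coh)))
})

test_that("cohesion 1 yields few compact patches", {
  p <- c("1" = 0.5, "2" = 0.5)
  cfg <- synthetic_config(nrow = 64, ncol = 64, proportions = p,
                          cohesion = 1, n_seeds = 6,
                          scheme = eco_binary_scheme(), seed = 9)
  r <- generate_landscape(cfg)
  expect_lt(nrow(label_patches(r)), 0.05 * length(r$values))
})

test_that("the DEM is nonnegative, seeded, smooth, and flat with 0 bumps", {
  cfg <- test_config(seed = 5)
  d <- generate_dem(cfg)
  expect_true(all(d$values >= 0))
  flat <- generate_dem(synthetic_config(nrow = 16, ncol = 16, n_bumps = 0))
  expect_true(all(flat$values == 0))
  # smoothness: mean |cell-to-cell difference| well below bump amplitude
  dif <- abs(diff(d$values))
  expect_lt(mean(dif), cfg$bump_amplitude / 5)
  # single bump peaks near its center: maximum is on the bump, and the
  # surface decreases away from the maximum along rows
  one <- generate_dem(synthetic_config(nrow = 32, ncol = 32, n_bumps = 1,
                                       seed = 3))
  peak <- which(one$values == max(one$values), arr.ind = TRUE)[1, ]
  expect_true(all(one$values <= one$values[peak[1], peak[2]]))
})

test_that("conversion frequency matches the generating probability", {
  # all slopes/covariate effects zero: conversion is pure Bernoulli(p)
  p_true <- 0.3
  cfg <- synthetic_config(
    nrow = 64, ncol = 64, n_bumps = 0, seed = 21,
    true_coef = c(intercept = qlogis(p_true), slope = 0, elevation = 0,
                  distance = 0, level4 = 0, level5 = 0))
  land0 <- generate_landscape(cfg)
  dem <- generate_dem(cfg)
  zones <- generate_zones(cfg)
  land1 <- simulate_change(land0, dem, zones, cfg)
  eco0 <- land0$values %in% eco_codes(cfg$scheme)
  eco1 <- land1$values %in% eco_codes(cfg$scheme)
  n <- sum(eco0)
  frac <- sum(eco0 & !eco1) / n
  expect_lt(abs(frac - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
  # non-ecological cells never change
  expect_identical(land1$values[!eco0], land0$values[!eco0])
})

test_that("probability-zero conversion leaves the landscape unchanged", {
  cfg <- synthetic_config(
    nrow = 32, ncol = 32, seed = 22,
    true_coef = c(intercept = -50, slope = 0, elevation = 0,
                  distance = 0, level4 = 0, level5 = 0))
  land0 <- generate_landscape(cfg)
  land1 <- simulate_change(land0, generate_dem(cfg), generate_zones(cfg),
                           cfg)
  expect_identical(land1$values, land0$values)
})

test_that("strongly negative distance effect targets near-built-up cells", {
  cfg <- synthetic_config(
    nrow = 64, ncol = 64, n_bumps = 0, seed = 23,
    true_coef = c(intercept = 1, slope = 0, elevation = 0,
                  distance = -8, level4 = 0, level5 = 0))
  land0 <- generate_landscape(cfg)
  dist <- distance_to_builtup(land0)
  land1 <- simulate_change(land0, generate_dem(cfg), generate_zones(cfg),
                           cfg)
  eco0 <- land0$values %in% eco_codes(cfg$scheme)
  conv <- eco0 & !(land1$values %in% eco_codes(cfg$scheme))
  near <- eco0 & dist$values <= stats::median(dist$values[eco0])
  p_near <- sum(conv & near) / sum(near)
  p_far <- sum(conv & !near) / sum(eco0 & !near)
  expect_gt(p_near, p_far)
})

test_that("scenarios are co-registered, seeded bundles over all dates", {
  cfg <- test_config(seed = 31)
  sc <- generate_scenario(cfg)
  expect_length(sc$land, 4)
  expect_identical(names(sc$land), as.character(cfg$dates))
  for (r in sc$land) expect_true(is_coregistered(sc$land[[1]], r))
  expect_true(is_coregistered(sc$land[[1]], sc$dem))
  sc2 <- generate_scenario(test_config(seed = 32))
  expect_identical(dim(sc2$land[[1]]$values), dim(sc$land[[1]]$values))
  expect_false(identical(sc2$land[[1]]$values, sc$land[[1]]$values))
  # eco land can only shrink with gains disabled
  eco_areas <- vapply(sc$land, function(r) class_area(to_binary_eco(r), 1),
                      numeric(1))
  expect_true(all(diff(eco_areas) <= 0))
})

test_that("scenario transition frequencies match the generating model", {
  cfg <- synthetic_config(nrow = 64, ncol = 64, seed = 33,
                          dates = c(2000L, 2010L))
  sc <- generate_scenario(cfg)
  land0 <- sc$land[[1]]; land1 <- sc$land[[2]]
  stack <- covariate_stack(land0, sc$dem, sc$zones,
                           levels = sc$zones$levels)
  eco <- which(land0$values %in% eco_codes(cfg$scheme))
  lev <- stack$level$values[eco]
  cf <- cfg$true_coef
  p <- plogis(cf[["intercept"]] + cf[["slope"]] * stack$slope$values[eco] +
                cf[["elevation"]] * stack$elevation$values[eco] +
                cf[["distance"]] * stack$distance$values[eco] +
                cf[["level4"]] * (lev == 4) + cf[["level5"]] * (lev == 5))
  conv <- !(land1$values[eco] %in% eco_codes(cfg$scheme))
  # binomial oracle on the heterogeneous conversion count
  mu <- sum(p); sdv <- sqrt(sum(p * (1 - p)))
  expect_lt(abs(sum(conv) - mu), 4 * sdv)
})

test_that("written scenarios round-trip through the manifest directory", {
  cfg <- synthetic_config(nrow = 16, ncol = 16, seed = 41)
  sc <- generate_scenario(cfg)
  dir <- file.path(tempdir(), "scen41")
  write_scenario(sc, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  r <- read_raster(file.path(dir, "land_1991.asc"), "categorical",
                   scheme = cfg$scheme)
  expect_identical(r$values, sc$land[[1]]$values)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 41)
})
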