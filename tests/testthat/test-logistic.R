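test_that("Horn slope matches closed forms on flat and planar DEMs", {
  flat <- continuous_raster(matrix(100, 8, 8), 30)
  expect_true(all(compute_slope(flat)$values == 0))

  # plane rising 0.1 m per m eastward: slope = atan(0.1) on every interior
  # cell (edge-replicated borders see half the gradient across them)
  cs <- 30
  plane <- continuous_raster(
    outer(rep(1, 8), (1:8) * 0.1 * cs), cs)
  s <- compute_slope(plane)
  expect_equal(s$values[, 2:7], matrix(atan(0.1) * 180 / pi, 8, 6),
               tolerance = 1e-12)
  expect_equal(round(s$values[4, 4], 2), 5.71)

  # rotating the plane 90 degrees leaves the slope magnitude unchanged
  plane_t <- continuous_raster(t(plane$values), cs)
  expect_equal(compute_slope(plane_t)$values, t(s$values))
  expect_error(compute_slope(continuous_raster(matrix(1, 1, 5), 30)),
               "at least 2")
})

test_that("distance from built-up land is exact Euclidean in km", {
  v <- matrix(1, 7, 7); v[4, 4] <- 9
  r <- categorical_raster(v, 30, scheme = default_scheme())
  d <- distance_to_builtup(r)
  expect_equal(d$values[4, 4], 0)
  expect_equal(d$values[4, 5], 0.03)
  expect_equal(d$values[3, 3], 0.03 * sqrt(2))
  expect_equal(round(d$values[3, 3], 4), 0.0424)
  expect_error(distance_to_builtup(
    categorical_raster(matrix(1, 3, 3), 30, scheme = default_scheme())),
    "no built-up")
})

test_that("distance transform equals the brute-force oracle", {
  for (s in 1:10) {
    r <- rand_cat_raster(12, 12, c(1, 9), seed = 700 + s,
                         scheme = default_scheme())
    if (!any(r$values == 9)) next
    d <- distance_to_builtup(r)
    oracle <- brute_edt(r$values == 9) * 30 / 1000
    expect_equal(d$values, oracle, tolerance = 1e-9)
  }
})

test_that("growth rates use geometric annualization and the 5-level bins", {
  zones <- generate_zones(synthetic_config(nrow = 16, ncol = 16,
                                           n_zones = 3, seed = 1))
  # doubling over 27 years: about 2.60% per year, level 1
  gl <- growth_rate_levels(c(10, 10, 10), c(20, 10, 10), 27, zones)
  expect_equal(gl$rates_pct[1], 100 * (2^(1 / 27) - 1))
  expect_equal(round(gl$rates_pct[1], 2), 2.60)
  expect_equal(gl$levels, c(1L, 1L, 1L))
  # bin lookups: 12% -> 3, 40% -> 5; boundaries are right-closed
  r12 <- growth_rate_levels(c(1, 1, 1), (1 + c(0.12, 0.40, 0.05)), 1, zones)
  expect_equal(r12$levels, c(3L, 5L, 1L))
  r_edge <- growth_rate_levels(rep(1, 3), 1 + c(0.05, 0.10, 0.35), 1, zones)
  expect_equal(r_edge$levels, c(1L, 2L, 4L))
  expect_error(growth_rate_levels(c(0, 1, 1), c(1, 1, 1), 10, zones),
               "undefined")
  # arithmetic option
  ga <- growth_rate_levels(c(10, 10, 10), c(20, 10, 10), 27, zones,
                           method = "arithmetic")
  expect_equal(ga$rates_pct[1], 100 / 27)
  # levels broadcast to every zone cell
  expect_true(all(gl$raster$values == 1))
})

test_that("sample draws are seeded, exhaustive when n = all, and unbiased", {
  cfg <- synthetic_config(nrow = 64, ncol = 64, seed = 81,
                          dates = c(1991L, 2018L))
  sc <- generate_scenario(cfg)
  stack <- covariate_stack(sc$land[[1]], sc$dem, sc$zones,
                           levels = sc$zones$levels)
  eco_n <- sum(sc$land[[1]]$values %in% eco_codes(cfg$scheme))
  s1 <- draw_samples(sc$land[[1]], sc$land[[2]], stack, 500, seed = 5)
  s2 <- draw_samples(sc$land[[1]], sc$land[[2]], stack, 500, seed = 5)
  expect_identical(s1, s2)
  expect_error(draw_samples(sc$land[[1]], sc$land[[2]], stack, eco_n + 1),
               "only")
  all_s <- draw_samples(sc$land[[1]], sc$land[[2]], stack, eco_n)
  expect_equal(nrow(all_s), eco_n)
  # sample prevalence near the map-wide persistence fraction
  p_map <- mean(all_s$y)
  p_smp <- mean(s1$y)
  expect_lt(abs(p_smp - p_map), 3 * sqrt(p_map * (1 - p_map) / 500))
  # exactly one growth-level dummy active per record (level 1 = reference)
  expect_true(all(rowSums(all_s[, c("level2", "level3", "level4",
                                    "level5")]) <= 1))
})

test_that("an intercept-only fit on a balanced outcome gives alpha = 0", {
  d <- data.frame(x = rnorm(100), y = rep(c(0, 1), 50))
  fit <- fit_logistic(d, stepwise = FALSE, vars = "x")
  # x is noise; the intercept stays at logit(0.5) = 0 within its SE
  int <- fit$coefficients[fit$coefficients$term == "(Intercept)", ]
  expect_lt(abs(int$estimate), 3 * int$se)
  fit0 <- stats::glm(y ~ 1, binomial, d)
  expect_equal(unname(coef(fit0)[1]), 0, tolerance = 1e-10)
})

test_that("the reported -2LL equals the hand-written likelihood", {
  set.seed(42)
  n <- 500
  d <- data.frame(slope = runif(n, 0, 20), distance = runif(n, 0, 3))
  p <- plogis(0.5 - 0.1 * d$slope + 0.6 * d$distance)
  d$y <- rbinom(n, 1, p)
  fit <- fit_logistic(d, stepwise = FALSE)
  phat <- predict(fit, d)
  expect_equal(fit$minus2LL, -2 * loglik_oracle(d$y, phat),
               tolerance = 1e-8)
  expect_lte(fit$minus2LL, fit$null_minus2LL)
  expect_equal(fit$lr_chisq, fit$null_minus2LL - fit$minus2LL)
})

test_that("IRLS and a direct likelihood maximizer agree on coefficients", {
  set.seed(43)
  n <- 400
  d <- data.frame(a = rnorm(n), b = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-0.3 + 0.8 * d$a - 0.5 * d$b))
  fit <- fit_logistic(d, stepwise = FALSE)
  X <- cbind(1, d$a, d$b)
  nll <- function(beta) -loglik_oracle(d$y, plogis(drop(X %*% beta)))
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(fit$coefficients$estimate), opt$par,
               tolerance = 1e-5)
})

test_that("forward stepwise keeps informative terms and drops noise", {
  set.seed(44)
  n <- 4000
  d <- data.frame(slope = runif(n, 0, 25), elevation = runif(n, 0, 200),
                  noise1 = rnorm(n), noise2 = rnorm(n))
  d$y <- rbinom(n, 1, plogis(1 - 0.08 * d$slope - 0.02 * d$elevation))
  fit <- fit_logistic(d, stepwise = TRUE)
  expect_true(all(c("slope", "elevation") %in% fit$included))
  expect_equal(fit$lr_df, length(fit$included))
})

test_that("degenerate outcomes and separation raise errors", {
  d <- data.frame(x = rnorm(20), y = rep(1, 20))
  expect_error(fit_logistic(d, stepwise = FALSE), "single class")
  sep <- data.frame(x = c(-(10:1), 1:10), y = rep(c(0, 1), each = 10))
  expect_error(suppressWarnings(fit_logistic(sep, stepwise = FALSE)),
               "separation")
})

test_that("the transformation probability equals one minus the logistic", {
  expect_equal(round(evaluate_transform_probability(0, 0, 0, 0, 0), 4),
               0.7012)
  expect_equal(round(evaluate_transform_probability(10, 100, 1, 1, 0), 4),
               0.0737)
  # identity P = 1 - sigma(z) = sigma(-z) to machine precision
  cf <- default_transform_coefficients()
  for (s in 1:50) {
    set.seed(900 + s)
    A <- runif(1, 0, 45); B <- runif(1, 0, 500); C <- runif(1, 0, 10)
    D <- rbinom(1, 1, 0.5); E <- if (D == 1) 0 else rbinom(1, 1, 0.5)
    z <- cf[["intercept"]] + cf[["slope"]] * A + cf[["elevation"]] * B +
      cf[["distance"]] * C + cf[["level4"]] * D + cf[["level5"]] * E
    p <- evaluate_transform_probability(A, B, C, D, E)
    expect_lt(abs(p - (1 - plogis(z))), 1e-12)  # absolute machine agreement
    expect_identical(p, plogis(-z))
  }
  # strictly decreasing in the distance covariate
  ps <- evaluate_transform_probability(5, 50, seq(0, 5, 0.5), 0, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("confusion statistics are exact rationals of the counts", {
  perfect <- confusion_stats(diag(c(40, 60)))
  expect_equal(perfect$overall_accuracy_pct, 100)
  expect_equal(perfect$kappa, 1)
  chance <- confusion_stats(matrix(25, 2, 2))
  expect_equal(chance$kappa, 0)
  expect_error(confusion_stats(matrix(0, 2, 2)), "empty")
})

test_that("probability maps partition ecological cells into 5 levels", {
  cfg <- test_config(seed = 91)
  sc <- generate_scenario(cfg)
  stack <- covariate_stack(sc$land[[1]], sc$dem, sc$zones,
                           levels = sc$zones$levels)
  pm <- predict_probability_map(stack, sc$land[[1]])
  eco <- sc$land[[1]]$values %in% eco_codes(cfg$scheme)
  expect_true(all(is.na(pm$prob$values[!eco])))
  expect_true(all(!is.na(pm$levels$values[eco])))
  expect_true(all(pm$levels$values[eco] %in% 1:5))
  pv <- pm$prob$values[eco]
  expect_true(all(pv > 0 & pv < 1))
  expect_equal(pm$mean_probability, mean(pv))
  # fixed cuts: 0.05 low, 0.30 relatively low, 0.46 relatively high
  lv <- function(p) 1 + (p > 0.1) + (p > 0.3) + (p > 0.45) + (p > 0.65)
  expect_equal(lv(0.05), 1); expect_equal(lv(0.30), 2)
  expect_equal(lv(0.46), 4)
  expect_error(predict_probability_map(list(slope = stack$slope),
                                       sc$land[[1]]), "missing layer")
})

test_that("uniform covariates give a constant probability map", {
  sc <- default_scheme()
  land <- categorical_raster(matrix(c(1, 9), 8, 8), 30, scheme = sc)
  dem <- continuous_raster(matrix(50, 8, 8), 30)
  stack <- list(slope = compute_slope(dem), elevation = dem,
                distance = distance_to_builtup(land),
                level = continuous_raster(matrix(1, 8, 8), 30,
                                          units = "level"))
  # flatten distance too so every covariate is uniform
  stack$distance$values[] <- 0.5
  pm <- predict_probability_map(stack, land)
  expected <- evaluate_transform_probability(0, 50, 0.5, 0, 0)
  eco_vals <- pm$prob$values[land$values == 1]
  expect_true(all(abs(eco_vals - expected) < 1e-12))
})
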