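#' Slope from a DEM (Horn's method)
#'
#' 3x3 finite-difference gradient with Horn weighting: for each cell the
#' east-west and north-south rates of change are weighted sums of the three
#' neighboring columns/rows (weights 1-2-1) divided by `8 * cell_size`, and
#' slope = `atan(sqrt(p^2 + q^2))` in degrees. Border cells use edge
#' replication.
#'
#' @param dem a `continuous_raster` in meters with square cells.
#' @return a `continuous_raster` of slope in degrees.
#' @export
compute_slope <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 2 || nc < 2)
    stop("DEM must have at least 2 rows and 2 columns")
  cs <- dem$cell_size
  zp <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, nc, drop = FALSE])
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  w <- zp[i, j - 1]; e <- zp[i, j + 1]
  n <- zp[i - 1, j]; s <- zp[i + 1, j]
  nw <- zp[i - 1, j - 1]; ne <- zp[i - 1, j + 1]
  sw <- zp[i + 1, j - 1]; se <- zp[i + 1, j + 1]
  p <- ((ne + 2 * e + se) - (nw + 2 * w + sw)) / (8 * cs)
  q <- ((sw + 2 * s + se) - (nw + 2 * n + ne)) / (8 * cs)
  continuous_raster(atan(sqrt(p^2 + q^2)) * 180 / pi, cs, dem$origin,
                    dem$year, units = "degrees")
}

#' Euclidean distance from built-up land
#'
#' Exact per-cell Euclidean distance (between cell centers) to the nearest
#' built-up cell, in kilometers; built-up cells get 0. Nodata cells do not
#' block distance propagation but stay masked in the output.
#'
#' @param land a `categorical_raster`.
#' @param code the built-up class code (default: the scheme's built-up
#'   class).
#' @return a `continuous_raster` in km.
#' @export
distance_to_builtup <- function(land, code = builtup_code(land$scheme)) {
  built <- !is.na(land$values) & land$values == code
  if (!any(built))
    stop("no built-up cells present; distance surface undefined")
  m <- matrix(1, nrow(land$values), ncol(land$values))
  m[built] <- 0
  d <- EBImage::imageData(EBImage::distmap(m, metric = "euclidean"))
  d <- d * land$cell_size / 1000
  d[is.na(land$values)] <- NA_real_
  continuous_raster(matrix(d, nrow(land$values)), land$cell_size,
                    land$origin, land$year, units = "km")
}

#' Built-up growth-rate levels per zone
#'
#' Computes each zone's average annual built-up growth rate
#' `r = (A_t1 / A_t0)^(1/years) - 1` (geometric; an arithmetic option
#' `r = (A_t1/A_t0 - 1)/years` is available) and bins it into five levels:
#' 0-5% = 1, 5-10% = 2, 10-20% = 3, 20-35% = 4, above 35% = 5 (bins
#' left-open, right-closed; rates at or below zero fall in level 1). The
#' level is broadcast to every cell of its zone.
#'
#' @param area_t0,area_t1 per-zone built-up areas (same length, zone id =
#'   position); all `area_t0` must be positive.
#' @param years length of the period in years.
#' @param zones a zone set from [generate_zones()], or a zone-id raster.
#' @param method `"geometric"` (default) or `"arithmetic"`.
#' @return list with `levels` (integer per zone), `rates_pct` (annual rate,
#'   percent) and `raster` (per-cell level, `continuous_raster`).
#' @export
growth_rate_levels <- function(area_t0, area_t1, years, zones,
                               method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  if (length(area_t0) != length(area_t1))
    stop("per-zone area vectors differ in length")
  if (any(area_t0 <= 0))
    stop("zone(s) ", paste(which(area_t0 <= 0), collapse = ", "),
         " have no built-up area at t0; growth rate undefined")
  if (years <= 0) stop("years must be positive")
  r <- if (method == "geometric") (area_t1 / area_t0)^(1 / years) - 1
       else (area_t1 / area_t0 - 1) / years
  pct <- 100 * r
  eps <- 1e-9   # keep rates computed as exactly 5/10/20/35% in the lower bin
  lev <- 1L + (pct > 5 + eps) + (pct > 10 + eps) + (pct > 20 + eps) +
    (pct > 35 + eps)
  zr <- if (is.list(zones) && !inherits(zones, "eco_raster")) zones$raster
        else zones
  v <- matrix(lev[zr$values], nrow(zr$values))
  list(levels = as.integer(lev), rates_pct = pct,
       raster = continuous_raster(v, zr$cell_size, zr$origin, zr$year,
                                  units = "level"))
}

#' Per-zone built-up areas
#'
#' @param land a `categorical_raster`.
#' @param zones a zone set or zone-id raster.
#' @param code built-up class code.
#' @return numeric vector of built-up km² per zone id.
#' @export
zone_builtup_areas <- function(land, zones,
                               code = builtup_code(land$scheme)) {
  zr <- if (is.list(zones) && !inherits(zones, "eco_raster")) zones$raster
        else zones
  check_coregistered(land, zr, "land use and zones")
  ids <- sort(unique(zr$values[!is.na(zr$values)]))
  a <- vapply(ids, function(z)
    sum(land$values == code & zr$values == z, na.rm = TRUE), numeric(1))
  a * land$cell_size^2 / 1e6
}

#' Assemble the model covariate stack
#'
#' Builds the co-registered covariate layers of the conversion model: slope
#' (degrees, from the DEM), elevation (the DEM itself), distance from
#' built-up land (km, from the land-use raster), and the growth-level raster
#' with its level-2..5 indicator layers. Growth levels are taken from
#' `levels` when supplied (e.g. a synthetic scenario's true zone levels) and
#' otherwise computed from the observed built-up change between `land` and
#' `land_t1` over `years`.
#'
#' @param land a `categorical_raster` (period start).
#' @param dem co-registered DEM (m).
#' @param zones zone set from [generate_zones()] (or list with `raster`).
#' @param levels optional integer vector of growth levels per zone id.
#' @param land_t1,years required when `levels` is `NULL`.
#' @return list of class `covariate_stack`: `slope`, `elevation`,
#'   `distance`, `level` rasters plus `level_values` per zone.
#' @export
covariate_stack <- function(land, dem, zones, levels = NULL,
                            land_t1 = NULL, years = NULL) {
  if (is.null(dem)) stop("covariate stack requires a DEM layer")
  if (is.null(zones)) stop("covariate stack requires a zone layer")
  check_coregistered(land, dem, "land use and DEM")
  zr <- if (is.list(zones) && !inherits(zones, "eco_raster")) zones$raster
        else zones
  check_coregistered(land, zr, "land use and zones")
  if (is.null(levels)) {
    if (is.null(land_t1) || is.null(years))
      stop("either zone growth levels or (land_t1, years) must be supplied")
    a0 <- zone_builtup_areas(land, zr)
    a1 <- zone_builtup_areas(land_t1, zr)
    levels <- growth_rate_levels(a0, a1, years, zr)$levels
  }
  lv <- matrix(levels[zr$values], nrow(zr$values))
  structure(list(
    slope = compute_slope(dem),
    elevation = dem,
    distance = distance_to_builtup(land),
    level = continuous_raster(lv, land$cell_size, land$origin, land$year,
                              units = "level"),
    level_values = as.integer(levels)),
    class = "covariate_stack")
}

#' Draw a training or validation sample of ecological cells
#'
#' Samples `n` cells uniformly without replacement from the cells that are
#' ecological land at the period start, reads their covariates, and codes
#' the outcome. With `outcome = "remain"` (the default convention),
#' `y = 1` means the cell is still ecological at the period end; with
#' `outcome = "transform"`, `y = 1` means it converted.
#'
#' @param land_t0,land_t1 co-registered `categorical_raster`s.
#' @param stack a [covariate_stack()] built at the period start.
#' @param n sample size (at most the number of ecological cells at t0).
#' @param seed integer seed; the draw is deterministic given it.
#' @param outcome `"remain"` or `"transform"`.
#' @return data frame with columns `slope`, `elevation`, `distance`,
#'   `level2`..`level5`, `y`; attributes `cells` (sampled cell indices),
#'   `outcome`, `years`.
#' @export
draw_samples <- function(land_t0, land_t1, stack, n, seed = 1L,
                         outcome = c("remain", "transform")) {
  outcome <- match.arg(outcome)
  check_same_mask(land_t0, land_t1, "sampling rasters")
  eco <- which(!is.na(land_t0$values) &
                 land_t0$values %in% eco_codes(land_t0$scheme))
  if (n > length(eco))
    stop("requested ", n, " samples but only ", length(eco),
         " ecological cells at t0")
  cells <- with_seed(as.integer(seed), sort(sample(eco, n)))
  still <- land_t1$values[cells] %in% eco_codes(land_t1$scheme)
  y <- if (outcome == "remain") as.integer(still) else as.integer(!still)
  lev <- stack$level$values[cells]
  out <- data.frame(
    slope = stack$slope$values[cells],
    elevation = stack$elevation$values[cells],
    distance = stack$distance$values[cells],
    level2 = as.integer(lev == 2), level3 = as.integer(lev == 3),
    level4 = as.integer(lev == 4), level5 = as.integer(lev == 5),
    y = y)
  attr(out, "cells") <- cells
  attr(out, "outcome") <- outcome
  attr(out, "years") <- c(land_t0$year, land_t1$year)
  out
}

#' Fit the conversion model by maximum likelihood
#'
#' Binomial logistic regression fitted by iteratively reweighted least
#' squares. With `stepwise = TRUE` covariates enter one at a time by the
#' largest significant likelihood-ratio improvement until no candidate's
#' entry test has p below `entry_p` (forward stepwise selection); otherwise
#' all candidate covariates are fitted at once.
#'
#' @param samples a data frame from [draw_samples()] (outcome column `y`).
#' @param stepwise logical.
#' @param entry_p entry threshold for the stepwise LRT (default 0.05).
#' @param vars candidate covariate columns (default: every non-`y` column).
#' @return An `eco_logit_fit`: list with `coefficients` (data frame of
#'   estimates, standard errors, z and p values), `included`, `minus2LL`,
#'   `lr_chisq`, `lr_df`, `null_minus2LL`, `converged`, and the underlying
#'   `glm` object.
#' @export
fit_logistic <- function(samples, stepwise = TRUE, entry_p = 0.05,
                         vars = NULL) {
  if (is.null(vars)) vars <- setdiff(names(samples), "y")
  if (length(unique(samples$y)) < 2)
    stop("outcome has a single class; logistic fit undefined")
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  if (stepwise) {
    fit <- stats::glm(y ~ 1, family = stats::binomial(), data = samples,
                      control = ctrl)
    included <- character()
    candidates <- vars
    while (length(candidates)) {
      scope <- stats::as.formula(paste("~ . +",
                                       paste(candidates, collapse = " + ")))
      tab <- stats::add1(fit, scope = scope, test = "LRT")
      tab <- tab[-1, , drop = FALSE]
      p <- tab[["Pr(>Chi)"]]
      best <- which.min(p)
      if (!length(best) || is.na(p[best]) || p[best] >= entry_p) break
      newvar <- rownames(tab)[best]
      included <- c(included, newvar)
      fit <- stats::glm(
        stats::reformulate(included, "y"),
        family = stats::binomial(), data = samples, control = ctrl)
      candidates <- setdiff(candidates, newvar)
    }
  } else {
    included <- vars
    fit <- stats::glm(stats::reformulate(vars, "y"),
                      family = stats::binomial(), data = samples,
                      control = ctrl)
  }
  cf <- summary(fit)$coefficients
  big <- abs(cf[, "Estimate"]) > 15 | cf[, "Std. Error"] > 100
  if (any(big))
    stop("fit did not stabilize (possible complete separation) in: ",
         paste(rownames(cf)[big], collapse = ", "))
  structure(list(
    coefficients = data.frame(term = rownames(cf),
                              estimate = cf[, "Estimate"],
                              se = cf[, "Std. Error"],
                              z = cf[, "z value"],
                              p = cf[, "Pr(>|z|)"],
                              row.names = NULL),
    included = included,
    minus2LL = fit$deviance,
    null_minus2LL = fit$null.deviance,
    lr_chisq = fit$null.deviance - fit$deviance,
    lr_df = fit$df.null - fit$df.residual,
    converged = fit$converged,
    outcome = attr(samples, "outcome") %||% "remain",
    glm = fit), class = "eco_logit_fit")
}

#' @export
print.eco_logit_fit <- function(x, ...) {
  cat("<eco_logit_fit> -2LL = ", round(x$minus2LL, 1),
      ", LR chi2(", x$lr_df, ") = ", round(x$lr_chisq, 1), "\n", sep = "")
  print(transform(x$coefficients, estimate = round(estimate, 4),
                  se = round(se, 4), z = round(z, 2),
                  p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
predict.eco_logit_fit <- function(object, newdata, ...) {
  stats::predict(object$glm, newdata = newdata, type = "response")
}

#' Reference transformation-model coefficients
#'
#' The published driving-factor coefficients for ecological-to-built-up
#' conversion in a rapidly urbanizing coastal city, expressed on the
#' persistence side of the logit: with
#' `z = 0.069*A + 0.033*B + 0.473*C - 1.079*D - 0.963*E - 0.853`
#' (A slope in degrees, B elevation in m, C distance from built-up land in
#' km, D and E the growth-level-4/5 indicators), the transformation
#' probability is `P = 1 - 1/(1 + exp(-z))`.
#'
#' @return named numeric vector
#'   `c(intercept, slope, elevation, distance, level4, level5)`.
#' @export
default_transform_coefficients <- function() {
  c(intercept = -0.853, slope = 0.069, elevation = 0.033,
    distance = 0.473, level4 = -1.079, level5 = -0.963)
}

#' Evaluate the transformation probability
#'
#' `P = 1 - plogis(z)` with `z` the persistence-side linear predictor
#' `intercept + slope*A + elevation*B + distance*C + level4*D + level5*E`;
#' equivalently `plogis(-z)`. Total function of its real arguments,
#' vectorized.
#'
#' @param A slope, degrees. @param B elevation, m.
#' @param C distance from built-up land, km.
#' @param D,E growth-level-4 and level-5 indicators (0/1).
#' @param coef named coefficient vector as in
#'   [default_transform_coefficients()].
#' @return transformation probability in (0, 1).
#' @examples
#' evaluate_transform_probability(0, 0, 0, 0, 0)  # ~0.701
#' @export
evaluate_transform_probability <- function(A, B, C, D, E,
    coef = default_transform_coefficients()) {
  z <- coef[["intercept"]] + coef[["slope"]] * A +
    coef[["elevation"]] * B + coef[["distance"]] * C +
    coef[["level4"]] * D + coef[["level5"]] * E
  stats::plogis(-z)   # = 1 - plogis(z), stable when plogis(z) is near 1
}

#' Confusion-matrix accuracy statistics
#'
#' Overall accuracy (diagonal total over grand total), per-observed-row
#' accuracies, and Cohen's kappa — all exact rationals of the cell counts.
#'
#' @param m square confusion matrix, rows = observed, columns = predicted.
#' @return list: `matrix`, `n`, `diagonal_total`, `row_accuracy_pct`,
#'   `overall_accuracy_pct`, `kappa`.
#' @examples
#' confusion_stats(matrix(c(5230, 963, 1184, 2623), 2))
#' @export
confusion_stats <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("confusion matrix must be square")
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  list(matrix = m, n = n, diagonal_total = sum(diag(m)),
       row_accuracy_pct = 100 * diag(m) / rowSums(m),
       overall_accuracy_pct = 100 * po,
       kappa = if (pe < 1) (po - pe) / (1 - pe) else 1)
}

#' Validate a fitted conversion model on a holdout sample
#'
#' Classifies each holdout cell as changed when its predicted
#' transformation probability exceeds `threshold`, crosses prediction with
#' observation (rows: observed unchanged / changed) and reports
#' [confusion_stats()].
#'
#' @param fit an `eco_logit_fit` (fitted on either outcome convention) or a
#'   numeric vector of transformation probabilities per holdout record.
#' @param holdout a [draw_samples()] data frame (any outcome coding; it is
#'   read from its `outcome` attribute).
#' @param threshold classification cut on the transformation probability.
#' @return [confusion_stats()] list with labeled matrix.
#' @export
validate_model <- function(fit, holdout, threshold = 0.5) {
  if (!nrow(holdout)) stop("empty holdout sample")
  p_change <- if (is.numeric(fit)) fit
  else {
    p <- predict(fit, holdout)
    # translate the model's fitted probability to a change probability
    # according to the outcome convention it was trained under
    if (identical(fit$outcome, "transform")) p else 1 - p
  }
  obs_changed <- if (identical(attr(holdout, "outcome"), "transform"))
    holdout$y == 1 else holdout$y == 0
  pred_changed <- p_change > threshold
  m <- matrix(c(sum(!obs_changed & !pred_changed),
                sum(obs_changed & !pred_changed),
                sum(!obs_changed & pred_changed),
                sum(obs_changed & pred_changed)), 2,
              dimnames = list(observed = c("unchanged", "changed"),
                              predicted = c("unchanged", "changed")))
  confusion_stats(m)
}

#' Transformation-probability map and 5-level classification
#'
#' Evaluates the transformation probability on every ecological cell from
#' the covariate stack, classifies it into the five fixed probability levels
#' (at most 0.1 = low; 0.1-0.3 = relatively low; 0.3-0.45 = medium;
#' 0.45-0.65 = relatively high; above 0.65 = high), masks non-ecological
#' cells, and reports the mean probability per ecological land class.
#'
#' @param stack a [covariate_stack()].
#' @param land the `categorical_raster` supplying ecological status and
#'   classes.
#' @param coef coefficient vector as in
#'   [default_transform_coefficients()].
#' @return list: `prob` (`continuous_raster`, probability), `levels`
#'   (`categorical_raster` coded 1-5), `class_means` (data frame),
#'   `mean_probability` (over all ecological cells).
#' @export
predict_probability_map <- function(stack, land,
    coef = default_transform_coefficients()) {
  for (nm in c("slope", "elevation", "distance", "level"))
    if (is.null(stack[[nm]])) stop("covariate stack is missing layer: ", nm)
  lev <- stack$level$values
  p <- evaluate_transform_probability(
    stack$slope$values, stack$elevation$values, stack$distance$values,
    (lev == 4) * 1, (lev == 5) * 1, coef)
  eco <- !is.na(land$values) & land$values %in% eco_codes(land$scheme)
  p[!eco] <- NA_real_
  pm <- matrix(p, nrow(land$values))
  lv <- 1 + (pm > 0.1) + (pm > 0.3) + (pm > 0.45) + (pm > 0.65)
  level_scheme <- land_scheme(
    1:5, c("low", "relatively low", "medium", "relatively high", "high"),
    rep(FALSE, 5))
  cls <- intersect(eco_codes(land$scheme),
                   unique(land$values[!is.na(land$values)]))
  class_means <- data.frame(
    code = cls,
    name = land$scheme$name[match(cls, land$scheme$code)],
    mean_probability = vapply(cls, function(k)
      mean(pm[!is.na(land$values) & land$values == k], na.rm = TRUE),
      numeric(1)))
  list(prob = continuous_raster(pm, land$cell_size, land$origin, land$year,
                                units = "probability"),
       levels = categorical_raster(lv, land$cell_size, land$origin,
                                   land$year, level_scheme),
       class_means = class_means,
       mean_probability = mean(pm[eco]))
}
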