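#' Configuration for synthetic landscape scenarios
#'
#' Bundles every knob of the synthetic-data generator: grid geometry, class
#' proportions, patch cohesion, DEM roughness, growth-zone count, the true
#' conversion-model coefficients, the scenario dates, and the RNG seed.
#' Defaults describe the study conditions the package is tested under: a
#' 224 x 224 grid of 30 m cells, ten classes of which five ecological classes
#' cover about 54% of the landscape, 13 growth zones, four dates spanning
#' 1991-2018, and true coefficients equal to the published transformation
#' equation for an urbanizing coastal city (expressed on the conversion side
#' of the logit, see Details).
#'
#' @details The generator converts ecological cells to built-up land with
#' probability `plogis(a + b_slope*A + b_elev*B + b_dist*C + b_l4*D + b_l5*E)`
#' where `A` = slope (degrees), `B` = elevation (m), `C` = distance from
#' built-up land (km) and `D`, `E` indicate growth-rate levels 4 and 5.
#' `true_coef` holds `(a, b_slope, b_elev, b_dist, b_l4, b_l5)` on this
#' conversion scale; [default_transform_coefficients()] is the same model
#' written on the
#' persistence scale, so the default is its negation.
#'
#' @param nrow,ncol grid shape (>= 8 each).
#' @param cell_size cell side, meters.
#' @param proportions named numeric vector of target class proportions
#'   (names = class codes); must sum to 1.
#' @param cohesion patch cohesion in `[0, 1]`: 0 = independent per-cell draws,
#'   1 = pure multi-seed region growing.
#' @param n_seeds total number of region-growing seeds across classes.
#' @param n_bumps,bump_amplitude DEM: number of Gaussian hills and their
#'   maximum amplitude (m).
#' @param n_zones number of built-up growth zones (Voronoi cells).
#' @param dates integer years, ascending.
#' @param true_coef named numeric vector
#'   `c(intercept, slope, elevation, distance, level4, level5)` on the
#'   conversion scale.
#' @param allow_gains logical; if `TRUE`, a small non-ecological to ecological
#'   backflow is simulated (off by default: the fitted model concerns losses).
#' @param gain_prob per-cell per-period gain probability when
#'   `allow_gains = TRUE`.
#' @param scheme a [land_scheme].
#' @param seed integer RNG seed; fixing it makes every generated object
#'   reproducible.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(nrow = 224, ncol = 224, cell_size = 30,
                             proportions = c("1" = 0.25, "2" = 0.04,
                                             "3" = 0.06, "4" = 0.08,
                                             "5" = 0.06, "6" = 0.05,
                                             "7" = 0.04, "8" = 0.16,
                                             "9" = 0.22, "10" = 0.04),
                             cohesion = 0.85, n_seeds = 40,
                             n_bumps = 6, bump_amplitude = 120,
                             n_zones = 13,
                             dates = c(1991L, 2000L, 2010L, 2018L),
                             true_coef = c(intercept = 0.853,
                                           slope = -0.069,
                                           elevation = -0.033,
                                           distance = -0.473,
                                           level4 = 1.079,
                                           level5 = 0.963),
                             allow_gains = FALSE, gain_prob = 0.01,
                             scheme = default_scheme(), seed = 1L) {
  if (nrow < 8 || ncol < 8) stop("grid must be at least 8 x 8")
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("class proportions must sum to 1 (got ", sum(proportions), ")")
  if (is.null(names(proportions)) ||
      !all(as.integer(names(proportions)) %in% scheme$code))
    stop("proportions must be named by scheme class codes")
  if (cohesion < 0 || cohesion > 1) stop("cohesion must be in [0, 1]")
  need <- c("intercept", "slope", "elevation", "distance", "level4", "level5")
  if (!all(need %in% names(true_coef)))
    stop("true_coef must be named: ", paste(need, collapse = ", "))
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cell_size = cell_size, proportions = proportions,
                 cohesion = cohesion, n_seeds = as.integer(n_seeds),
                 n_bumps = as.integer(n_bumps),
                 bump_amplitude = bump_amplitude,
                 n_zones = as.integer(n_zones),
                 dates = as.integer(sort(dates)),
                 true_coef = true_coef[need],
                 allow_gains = isTRUE(allow_gains), gain_prob = gain_prob,
                 scheme = scheme, seed = as.integer(seed)),
            class = "synthetic_config")
}

# evaluate `code` with a private, restored RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# 4-neighbor binary dilation of a logical matrix
dilate4 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-nr, ]
  out[-nr, ] <- out[-nr, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -nc]
  out[, -nc] <- out[, -nc] | m[, -1]
  out
}

#' Generate a spatially cohesive categorical landscape
#'
#' Multi-seed region growing: each class receives seeds and a cell quota
#' proportional to its target share; classes grow breadth-first from their
#' seeds, claiming unowned neighbor cells until quotas are filled, which
#' yields compact patches whose realized proportions track the targets.
#' A fraction `1 - cohesion` of cells is then redrawn independently from the
#' target proportions, so `cohesion = 0` degenerates to an independent
#' per-cell draw and `cohesion = 1` keeps the grown patches intact.
#'
#' @param config a [synthetic_config].
#' @return a `categorical_raster` stamped with the first scenario date.
#' @export
generate_landscape <- function(config) {
  with_seed(config$seed + 1L, {
    nr <- config$nrow; nc <- config$ncol; n <- nr * nc
    codes <- as.integer(names(config$proportions))
    p <- as.numeric(config$proportions)
    v <- matrix(NA_real_, nr, nc)

    if (config$cohesion > 0) {
      # integer quotas by largest remainder
      raw <- p * n
      quota <- floor(raw)
      left <- n - sum(quota)
      if (left > 0) {
        o <- order(raw - quota, decreasing = TRUE)
        quota[o[seq_len(left)]] <- quota[o[seq_len(left)]] + 1
      }
      nseed <- pmax(1L, round(config$n_seeds * p))
      cells <- sample.int(n, sum(nseed))
      cls_of_seed <- rep(codes, nseed)
      v[cells] <- cls_of_seed
      claimed <- tabulate(match(cls_of_seed, codes), length(codes))
      repeat {
        grew <- FALSE
        for (ki in sample(seq_along(codes))) {
          if (claimed[ki] >= quota[ki]) next
          terr <- !is.na(v) & v == codes[ki]
          front <- which(dilate4(terr) & is.na(v))
          if (!length(front)) {
            # class is walled in but under quota: plant a fresh seed so the
            # realized proportions stay on target
            open <- which(is.na(v))
            if (!length(open)) next
            front <- if (length(open) == 1) open else sample(open, 1)
          }
          take <- min(length(front), quota[ki] - claimed[ki])
          if (take < length(front)) front <- sample(front, take)
          v[front] <- codes[ki]
          claimed[ki] <- claimed[ki] + take
          grew <- TRUE
        }
        if (!grew || all(claimed >= quota)) break
      }
      # enclosed leftovers: flood from any claimed territory, quotas ignored
      while (anyNA(v)) {
        grew <- FALSE
        for (ki in sample(seq_along(codes))) {
          terr <- !is.na(v) & v == codes[ki]
          if (!any(terr)) next
          front <- which(dilate4(terr) & is.na(v))
          if (!length(front)) next
          v[front] <- codes[ki]
          grew <- TRUE
        }
        if (!grew) { v[is.na(v)] <- sample(codes, sum(is.na(v)),
                                           replace = TRUE, prob = p); break }
      }
    }

    noise <- if (config$cohesion >= 1) logical(n)
             else stats::runif(n) > config$cohesion
    if (any(noise))
      v[noise] <- sample(codes, sum(noise), replace = TRUE, prob = p)
    categorical_raster(v, config$cell_size, year = config$dates[1],
                       scheme = config$scheme)
  })
}

#' Generate a smooth synthetic DEM
#'
#' A nonnegative elevation surface built as a seeded sum of 2-D Gaussian
#' bumps placed uniformly over the grid; `n_bumps = 0` yields a flat zero
#' DEM. Amplitudes are drawn in `[0.5, 1] * bump_amplitude` and bump widths
#' in 10-25% of the grid extent, giving hill-scale relief that is smooth at
#' the cell scale.
#'
#' @param config a [synthetic_config].
#' @return a `continuous_raster` in meters.
#' @export
generate_dem <- function(config) {
  with_seed(config$seed + 2L, {
    nr <- config$nrow; nc <- config$ncol; cs <- config$cell_size
    x <- matrix((seq_len(nc) - 0.5) * cs, nr, nc, byrow = TRUE)
    y <- matrix((nr - seq_len(nr) + 0.5) * cs, nr, nc)
    v <- matrix(0, nr, nc)
    if (config$n_bumps > 0) {
      ext <- max(nr, nc) * cs
      for (b in seq_len(config$n_bumps)) {
        cx <- stats::runif(1, 0, nc * cs)
        cy <- stats::runif(1, 0, nr * cs)
        amp <- stats::runif(1, 0.5, 1) * config$bump_amplitude
        sd <- stats::runif(1, 0.10, 0.25) * ext
        v <- v + amp * exp(-((x - cx)^2 + (y - cy)^2) / (2 * sd^2))
      }
    }
    continuous_raster(v, cs, year = config$dates[1], units = "m")
  })
}

#' Generate built-up growth zones
#'
#' Partitions the grid into `n_zones` Voronoi cells of random sites — a
#' stand-in for administrative units — and assigns each zone a built-up
#' growth-rate level 1-5. When `n_zones >= 5` the first five zones receive a
#' permutation of all five levels so every level is represented.
#'
#' @param config a [synthetic_config].
#' @return list with `raster` (zone-id `continuous_raster`) and `levels`
#'   (integer vector of growth levels indexed by zone id).
#' @export
generate_zones <- function(config) {
  with_seed(config$seed + 3L, {
    nr <- config$nrow; nc <- config$ncol; k <- config$n_zones
    si <- stats::runif(k, 0.5, nr + 0.5)
    sj <- stats::runif(k, 0.5, nc + 0.5)
    ii <- matrix(seq_len(nr), nr, nc)
    jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    d2 <- array(Inf, dim(ii)); zone <- array(1L, dim(ii))
    for (z in seq_len(k)) {
      dz <- (ii - si[z])^2 + (jj - sj[z])^2
      upd <- dz < d2
      zone[upd] <- z
      d2[upd] <- dz[upd]
    }
    levels <- if (k >= 5) c(sample(1:5), sample(1:5, k - 5, replace = TRUE))
              else sample(1:5, k, replace = TRUE)
    list(raster = continuous_raster(zone + 0, config$cell_size,
                                    year = config$dates[1], units = "zone"),
         levels = as.integer(levels))
  })
}

#' Simulate one period of ecological-land conversion
#'
#' Each ecological cell converts to built-up land with the probability given
#' by the true logistic model on its covariates (slope, elevation, distance
#' from built-up land, growth-level-4/5 indicators); non-ecological cells are
#' left unchanged. With `allow_gains = TRUE`, non-ecological, non-built-up
#' cells may flow back to grassland with probability `gain_prob`.
#'
#' @param land_t0 a `categorical_raster` at the period start.
#' @param dem a co-registered DEM (`continuous_raster`, m).
#' @param zones a zone set from [generate_zones()].
#' @param config a [synthetic_config].
#' @param step integer period index, used to vary the RNG substream.
#' @return a `categorical_raster` at the period end.
#' @export
simulate_change <- function(land_t0, dem, zones, config, step = 1L) {
  if (is.null(dem) || is.null(zones))
    stop("simulate_change requires DEM and zone covariate layers")
  check_coregistered(land_t0, dem, "land use and DEM")
  check_coregistered(land_t0, zones$raster, "land use and zones")
  with_seed(config$seed + 10L + step, {
    sch <- land_t0$scheme
    bu <- builtup_code(sch)
    slope <- compute_slope(dem)
    dist <- distance_to_builtup(land_t0)
    lev <- zones$levels[zones$raster$values]
    cf <- config$true_coef
    lp <- cf[["intercept"]] + cf[["slope"]] * slope$values +
      cf[["elevation"]] * dem$values + cf[["distance"]] * dist$values +
      cf[["level4"]] * (lev == 4) + cf[["level5"]] * (lev == 5)
    p <- stats::plogis(lp)
    v <- land_t0$values
    eco <- !is.na(v) & (v %in% eco_codes(sch))
    conv <- eco & (stats::runif(length(v)) < p)
    v[conv] <- bu
    if (config$allow_gains) {
      cand <- !is.na(v) & !(v %in% eco_codes(sch)) & v != bu
      gain <- cand & (stats::runif(length(v)) < config$gain_prob)
      v[gain] <- sch$code[sch$name == "grassland"]
    }
    categorical_raster(matrix(v, nrow(land_t0$values)), land_t0$cell_size,
                       land_t0$origin, scheme = sch)
  })
}

#' Generate a complete multi-date scenario
#'
#' Chains [generate_landscape()], [generate_dem()], [generate_zones()] and
#' one [simulate_change()] per period into a self-consistent, co-registered,
#' fully seeded bundle.
#'
#' @param config a [synthetic_config].
#' @return list with `land` (named list of `categorical_raster`, one per
#'   date), `dem`, `zones`, and the `config` echo.
#' @export
generate_scenario <- function(config) {
  land0 <- generate_landscape(config)
  dem <- generate_dem(config)
  zones <- generate_zones(config)
  land <- list(land0)
  for (k in seq_along(config$dates)[-1]) {
    nxt <- simulate_change(land[[k - 1]], dem, zones, config, step = k - 1L)
    nxt$year <- config$dates[k]
    land[[k]] <- nxt
  }
  names(land) <- as.character(config$dates)
  list(land = land, dem = dem, zones = zones, config = config)
}

#' Write a scenario bundle to disk
#'
#' Writes one ASCII grid per land-use date plus the DEM and zone rasters, and
#' a JSON manifest echoing the seed and configuration for reproducibility.
#'
#' @param bundle result of [generate_scenario()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (yr in names(bundle$land))
    write_raster(bundle$land[[yr]], file.path(dir, paste0("land_", yr, ".asc")))
  write_raster(bundle$dem, file.path(dir, "dem.asc"))
  write_raster(bundle$zones$raster, file.path(dir, "zones.asc"))
  cfg <- unclass(bundle$config)
  cfg$scheme <- as.data.frame(unclass(cfg$scheme))
  manifest <- list(seed = cfg$seed, dates = cfg$dates,
                   zone_levels = bundle$zones$levels, config = cfg)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
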