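#' Run the full assessment pipeline
#'
#' Executes every stage of the ecological-land assessment route on a
#' multi-date scenario — transition matrices with contribution/probability
#' statistics and gain/loss maps, landscape- and class-level metric reports,
#' the equivalent-area quality series, the gravity-center migration track,
#' one conversion-model fit with holdout validation, and the
#' transformation-probability map — and optionally writes all tabular and
#' raster outputs plus a JSON manifest to a directory.
#'
#' The input is either a synthetic scenario request (a [synthetic_config])
#' or a pre-built bundle of the same shape as [generate_scenario()] output
#' (list with `land`, `dem`, `zones`, `config`). Any stage failure aborts
#' with the stage name and cause.
#'
#' @param config a [synthetic_config], or a scenario bundle.
#' @param out_dir optional output directory; when given, CSV/ASCII-grid/JSON
#'   outputs and a manifest are written there.
#' @param n_train,n_holdout training and validation sample sizes for the
#'   model stage (capped at the available ecological cells).
#' @param threshold classification threshold for validation.
#' @param quiet suppress stage log messages.
#' @return a `pipeline_bundle` list: `scenario`, `transitions` (per period:
#'   `matrix`, `net`, `BC`, `gains_losses`), `metrics` (per date),
#'   `quality`, `gravity`, `model` (`stack`, `fit`, `validation`,
#'   `prediction`), `seed`.
#' @export
run_pipeline <- function(config, out_dir = NULL, n_train = 20000,
                         n_holdout = 10000, threshold = 0.5,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message("[ecoland] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  scenario <- stage("simulate", {
    if (inherits(config, "synthetic_config")) {
      say("generating synthetic scenario (seed ", config$seed, ")")
      generate_scenario(config)
    } else if (is.list(config) && !is.null(config$land)) config
    else stop("config must be a synthetic_config or a scenario bundle")
  })
  land <- scenario$land
  if (length(land) < 2)
    stop("stage 'simulate' failed: need rasters for at least 2 dates")
  yrs <- names(land)

  trans <- stage("transitions", {
    say("transition matrices for ", length(land) - 1, " period(s)")
    lapply(seq_len(length(land) - 1), function(k) {
      tm <- transition_matrix(land[[k]], land[[k + 1]])
      tmb <- transition_matrix(to_binary_eco(land[[k]]),
                               to_binary_eco(land[[k + 1]]))
      list(period = paste(yrs[k], yrs[k + 1], sep = "-"),
           matrix = tm, net = net_change(tm),
           BC = contribution_probability(tmb),
           binary_matrix = tmb,
           gains_losses = gains_losses_map(land[[k]], land[[k + 1]]))
    })
  })

  metrics <- stage("metrics", {
    say("landscape metrics for ", length(land), " date(s)")
    lapply(land, metric_report)
  })

  quality <- stage("quality", quality_series(land))

  gravity <- stage("gravity", gravity_track(land))

  model <- stage("model", {
    if (is.null(scenario$dem)) stop("missing DEM layer")
    if (is.null(scenario$zones)) stop("missing zone layer")
    t0 <- land[[1]]; t1 <- land[[length(land)]]
    years <- as.integer(yrs[length(yrs)]) - as.integer(yrs[1])
    stack <- covariate_stack(t0, scenario$dem, scenario$zones,
                             levels = scenario$zones$levels,
                             land_t1 = t1, years = years)
    n_eco <- sum(!is.na(t0$values) &
                   t0$values %in% eco_codes(t0$scheme))
    seed <- scenario$config$seed %||% 1L
    n_tr <- min(n_train, floor(n_eco / 2))
    n_ho <- min(n_holdout, n_eco - n_tr)
    say("model fit on ", n_tr, " samples, validation on ", n_ho)
    train <- draw_samples(t0, t1, stack, n_tr, seed = seed + 101L)
    holdout <- draw_samples(t0, t1, stack, n_ho, seed = seed + 202L)
    if (length(unique(train$y)) < 2) {
      say("outcome has a single class; model fit skipped")
      list(stack = stack, train_n = n_tr, fit = NULL, validation = NULL,
           prediction = NULL,
           note = "outcome has a single class; model fit skipped")
    } else {
      fit <- fit_logistic(train, stepwise = TRUE)
      val <- validate_model(fit, holdout, threshold = threshold)
      pred <- predict_probability_map(stack, t0,
                                      coef = fitted_coef_vector(fit))
      list(stack = stack, train_n = n_tr, fit = fit, validation = val,
           prediction = pred)
    }
  })

  bundle <- structure(list(scenario = scenario, transitions = trans,
                           metrics = metrics, quality = quality,
                           gravity = gravity, model = model,
                           seed = scenario$config$seed %||% NA_integer_),
                      class = "pipeline_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir, quiet = quiet)
  bundle
}

# map a stepwise fit's terms onto the 6-slot coefficient vector used by
# evaluate_transform_probability (absent terms contribute 0); translated to
# the persistence-side convention expected there
fitted_coef_vector <- function(fit) {
  est <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  sgn <- if (identical(fit$outcome, "transform")) -1 else 1
  pick <- function(nm) {
    v <- unname(est[nm])
    if (is.na(v)) 0 else v
  }
  c(intercept = sgn * pick("(Intercept)"), slope = sgn * pick("slope"),
    elevation = sgn * pick("elevation"), distance = sgn * pick("distance"),
    level4 = sgn * pick("level4"), level5 = sgn * pick("level5"))
}

write_bundle <- function(bundle, out_dir, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                       row.names = FALSE)
  for (tr in bundle$transitions) {
    tag <- tr$period
    utils::write.csv(tr$matrix$area,
                     file.path(out_dir, paste0("transition_", tag, ".csv")))
    w(tr$net, paste0("net_change_", tag, ".csv"))
    utils::write.csv(round(tr$BC$B, 6),
                     file.path(out_dir, paste0("B_", tag, ".csv")))
    utils::write.csv(round(tr$BC$C, 6),
                     file.path(out_dir, paste0("C_", tag, ".csv")))
    write_raster(tr$gains_losses$map,
                 file.path(out_dir, paste0("gains_losses_", tag, ".asc")))
  }
  w(do.call(rbind, bundle$metrics), "metrics.csv")
  w(bundle$quality$series, "quality_series.csv")
  w(bundle$quality$changes, "quality_changes.csv")
  w(bundle$gravity$centers, "gravity_centers.csv")
  w(bundle$gravity$moves, "gravity_moves.csv")
  if (!is.null(bundle$model$fit)) {
    w(bundle$model$fit$coefficients, "model_coefficients.csv")
    w(bundle$model$prediction$class_means, "class_mean_probability.csv")
    write_raster(bundle$model$prediction$prob,
                 file.path(out_dir, "transform_probability.asc"))
    write_raster(bundle$model$prediction$levels,
                 file.path(out_dir, "transform_levels.asc"))
  }
  manifest <- list(seed = bundle$seed,
                   dates = names(bundle$scenario$land),
                   package_version =
                     as.character(utils::packageVersion("ecoland")),
                   model = if (is.null(bundle$model$fit))
                     list(note = bundle$model$note)
                   else
                     list(minus2LL = bundle$model$fit$minus2LL,
                          included = bundle$model$fit$included,
                          overall_accuracy_pct =
                            bundle$model$validation$overall_accuracy_pct))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!quiet) message("[ecoland] outputs written to ", out_dir)
  invisible(out_dir)
}

#' Human-readable summary of a pipeline bundle
#'
#' Deterministic plain-text summary: per-period net ecological change,
#' headline landscape metrics, equivalent-area series with one-decimal
#' percentage reductions, gravity displacements, model fit statistics, and
#' per-class mean transformation probabilities. If the bundle is incomplete
#' the missing sections are listed instead.
#'
#' @param bundle a `pipeline_bundle` from [run_pipeline()].
#' @return character vector of report lines (also printed invisibly via
#'   `cat` when `print = TRUE`).
#' @param print logical; cat the lines to the console.
#' @export
report_summary <- function(bundle, print = FALSE) {
  need <- c("transitions", "metrics", "quality", "gravity", "model")
  missing <- need[vapply(need, function(nm) is.null(bundle[[nm]]),
                         logical(1))]
  if (length(missing))
    return(paste("incomplete bundle; missing sections:",
                 paste(missing, collapse = ", ")))
  ln <- c("== Ecological land assessment summary ==", "")
  ln <- c(ln, "-- Net ecological-land change (km2) --")
  for (tr in bundle$transitions) {
    nb <- net_change(tr$binary_matrix)
    eco <- nb[nb$class == "ecological", ]
    ln <- c(ln, paste0(tr$period, ": ", fmt1(eco$area_start), " -> ",
                       fmt1(eco$area_end), " (net ",
                       fmt1(eco$net_change), "), C(eco->non-eco) = ",
                       fmt1(tr$BC$C["ecological", "non-ecological"]),
                       "%, B = ",
                       fmt1(tr$BC$B["ecological", "non-ecological"]), "%"))
  }
  ln <- c(ln, "", "-- Landscape metrics (landscape level) --")
  for (yr in names(bundle$metrics)) {
    m <- bundle$metrics[[yr]]
    m <- m[m$level == "landscape", ]
    ln <- c(ln, paste0(yr, ": ",
                       paste(m$metric, fmt1(m$value), collapse = ", ")))
  }
  ln <- c(ln, "", "-- Equivalent ecological area --")
  s <- bundle$quality$series
  ln <- c(ln, paste0(s$year, ": ", fmt1(s$equivalent_area_km2),
                     " km2 (Q = ", formatC(s$Q, format = "f", digits = 3),
                     ")"))
  ch <- bundle$quality$changes
  ln <- c(ln, paste0("reductions: ",
                     paste(ch$period, paste0(fmt1(ch$reduction_pct), "%"),
                           collapse = ", ")))
  ln <- c(ln, "", "-- Center-of-gravity migration (ecological land) --")
  mv <- bundle$gravity$moves
  ln <- c(ln, paste0(mv$period, ": ", fmt1(mv$distance_m), " m to the ",
                     mv$direction))
  ln <- c(ln, "", "-- Conversion model --")
  f <- bundle$model$fit
  if (is.null(f)) {
    ln <- c(ln, bundle$model$note)
    if (print) cat(ln, sep = "\n")
    return(ln)
  }
  ln <- c(ln, paste0("included terms: ", paste(f$included, collapse = ", ")),
          paste0("-2LL = ", fmt1(f$minus2LL), ", LR chi2(", f$lr_df,
                 ") = ", fmt1(f$lr_chisq)),
          paste0("holdout overall accuracy = ",
                 fmt1(bundle$model$validation$overall_accuracy_pct),
                 "%, kappa = ",
                 formatC(bundle$model$validation$kappa, format = "f",
                         digits = 3)))
  cm <- bundle$model$prediction$class_means
  ln <- c(ln, paste0("mean transformation probability: ",
                     paste(cm$name,
                           formatC(cm$mean_probability, format = "f",
                                   digits = 3), collapse = ", ")),
          paste0("ecological-land mean = ",
                 formatC(bundle$model$prediction$mean_probability,
                         format = "f", digits = 3)))
  if (print) {
    cat(ln, sep = "\n")
    return(invisible(ln))
  }
  ln
}
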