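#' Normalized ecosystem-service values
#'
#' The default per-class service values are the normalized (0-1) ecosystem
#' service equivalence factors for the 10-class urban legend: woodland is the
#' reference (1.00), rivers and shallow water 0.92, tidal flats 0.72,
#' reservoirs and pit ponds 0.63, grassland 0.47, paddy fields 0.29,
#' aquaculture areas 0.23, rainfed cropland 0.16, unutilized land 0.10 and
#' built-up land 0.08.
#'
#' @param codes integer class codes.
#' @param delta numeric values in `[0, 1]`, one per code.
#' @return A data frame (`service_values`) with columns `code`, `delta`.
#' @export
service_values <- function(codes = 1:10,
                           delta = c(1.00, 0.47, 0.16, 0.29, 0.23,
                                     0.63, 0.72, 0.92, 0.08, 0.10)) {
  if (length(codes) != length(delta))
    stop("codes and delta must have the same length")
  if (any(delta < 0 | delta > 1))
    stop("normalized service values must lie in [0, 1]")
  out <- data.frame(code = as.integer(codes), delta = as.numeric(delta))
  class(out) <- c("service_values", "data.frame")
  out
}

#' @rdname service_values
#' @param path CSV file with columns `code`, `delta`.
#' @export
read_service_values <- function(path) {
  d <- utils::read.csv(path)
  service_values(d$code, d$delta)
}

#' Equivalent ecological area and quality score
#'
#' The equivalent ecological area is `sum_i delta_i * A_i` — each class area
#' weighted by its normalized ecosystem-service value — and the average
#' equivalent area is `Q = sum_i delta_i * A_i / A`, a dimensionless quality
#' score bounded by the smallest and largest `delta` among the included
#' classes. By default the computation runs over the ecological classes only
#' (the headline quality series); `subset = "all"` scores the whole
#' landscape.
#'
#' @param r a `categorical_raster`.
#' @param values a [service_values] table covering every included class.
#' @param subset `"ecological"` (default) or `"all"`.
#' @return one-row data frame: `year`, `n_classes`, `area_km2` (total area of
#'   included classes), `equivalent_area_km2`, `Q`.
#' @examples
#' sc <- eco_binary_scheme()
#' r <- categorical_raster(matrix(c(1, 1, 1, 2), 2), 1000, scheme = sc)
#' equivalent_area(r, service_values(1:2, c(1, 0.08)), subset = "all")
#' @export
equivalent_area <- function(r, values = service_values(),
                            subset = c("ecological", "all")) {
  subset <- match.arg(subset)
  codes <- if (subset == "ecological") eco_codes(r$scheme) else r$scheme$code
  present <- intersect(codes, unique(r$values[!is.na(r$values)]))
  missing_delta <- setdiff(present, values$code)
  if (length(missing_delta))
    stop("no service value for class code(s): ",
         paste(missing_delta, collapse = ", "))
  a_i <- vapply(codes, function(k) class_area(r, k), numeric(1))
  d_i <- values$delta[match(codes, values$code)]
  d_i[is.na(d_i) & a_i == 0] <- 0       # absent classes need no delta
  eq <- sum(d_i * a_i)
  a <- sum(a_i)
  data.frame(year = if (is.null(r$year)) NA_integer_ else r$year,
             n_classes = length(present), area_km2 = a,
             equivalent_area_km2 = eq,
             Q = if (a > 0) eq / a else NA_real_)
}

#' Ecological-quality time series
#'
#' Per-year equivalent-area results plus period-over-period percentage
#' reductions `(prev - cur) / prev * 100` of the equivalent area (negative
#' values are gains), reported to one decimal in [report_summary()].
#'
#' @param rasters list of `categorical_raster`s with year stamps.
#' @param values a [service_values] table.
#' @param subset `"ecological"` or `"all"`.
#' @return list with `series` (data frame, one row per year) and `changes`
#'   (data frame: `period`, `reduction_pct`).
#' @export
quality_series <- function(rasters, values = service_values(),
                           subset = c("ecological", "all")) {
  subset <- match.arg(subset)
  if (length(rasters) < 2) stop("need at least two dates")
  yrs <- vapply(rasters, function(r)
    if (is.null(r$year)) NA_integer_ else r$year, integer(1))
  if (anyNA(yrs)) stop("all rasters must carry a year stamp")
  if (is.unsorted(yrs)) {
    warning("rasters were not in year order; sorting")
    rasters <- rasters[order(yrs)]
    yrs <- sort(yrs)
  }
  series <- do.call(rbind, lapply(rasters, equivalent_area,
                                  values = values, subset = subset))
  eq <- series$equivalent_area_km2
  changes <- data.frame(
    period = paste(yrs[-length(yrs)], yrs[-1], sep = "-"),
    reduction_pct = (eq[-length(eq)] - eq[-1]) / eq[-length(eq)] * 100)
  list(series = series, changes = changes)
}

#' Percentage reduction between two values
#'
#' `(a - b) / a * 100`: the period-over-period reduction used throughout the
#' quality and change reporting (negative = increase).
#'
#' @param a start value; @param b end value.
#' @return reduction in percent.
#' @export
pct_reduction <- function(a, b) (a - b) / a * 100
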