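#' In-memory raster grids
#'
#' `eco_raster` is the package's grid container: a numeric matrix of values
#' (`NA` = nodata), a square cell size in meters, the projected coordinate of
#' the grid's lower-left corner, and optional metadata. Row 1 is the top
#' (northernmost) row, matching on-disk raster conventions; the center of the
#' cell in row `i`, column `j` is at
#' `x = xll + (j - 0.5) * cell_size`, `y = yll + (nrow - i + 0.5) * cell_size`.
#'
#' Two rasters are co-registered iff their shape, cell size and origin match
#' exactly; all multi-layer operations in the package require it.
#'
#' @param values numeric matrix; `NA` marks nodata cells.
#' @param cell_size cell side length in meters (> 0).
#' @param origin numeric `c(x, y)`: projected coordinates (m) of the
#'   lower-left corner.
#' @param year optional integer year stamp.
#' @param scheme a [land_scheme]; every unmasked code must belong to it.
#' @param units unit label for continuous rasters
#'   (`"m"`, `"degrees"`, `"km"`, `"probability"`, ...).
#' @return An `eco_raster` (subclass `categorical_raster` or
#'   `continuous_raster`).
#' @examples
#' r <- categorical_raster(matrix(c(1, 1, 2, 2), 2), 30, scheme = eco_binary_scheme())
#' class_area(r, 1)
#' @export
categorical_raster <- function(values, cell_size, origin = c(0, 0),
                               year = NULL, scheme = default_scheme()) {
  r <- new_raster(values, cell_size, origin, year,
                  subclass = "categorical_raster")
  r$scheme <- scheme
  validate_codes(r$values, scheme)
  r
}

#' @rdname categorical_raster
#' @export
continuous_raster <- function(values, cell_size, origin = c(0, 0),
                              year = NULL, units = "m") {
  r <- new_raster(values, cell_size, origin, year,
                  subclass = "continuous_raster")
  r$units <- units
  if (identical(units, "probability")) {
    v <- r$values[!is.na(r$values)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop("probability raster values must lie in [0, 1]")
  }
  r
}

new_raster <- function(values, cell_size, origin, year, subclass) {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number (meters)")
  if (length(origin) != 2L || !is.numeric(origin))
    stop("origin must be c(x, y) in projected meters")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin),
         year = if (is.null(year)) NULL else as.integer(year)),
    class = c(subclass, "eco_raster"))
}

validate_codes <- function(values, scheme) {
  v <- values[!is.na(values)]
  bad <- sort(unique(v[!(v %in% scheme$code)]))
  if (length(bad))
    stop("raster contains codes not in the scheme: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.eco_raster <- function(x, ...) {
  cat("<", class(x)[1], "> ", nrow(x$values), " x ", ncol(x$values),
      " cells of ", x$cell_size, " m", sep = "")
  if (!is.null(x$year)) cat(", year ", x$year, sep = "")
  cat("\n  origin (", x$origin[1], ", ", x$origin[2], "), ",
      sum(is.na(x$values)), " nodata cells\n", sep = "")
  invisible(x)
}

#' Co-registration test
#'
#' @param a,b `eco_raster` objects.
#' @return `TRUE` iff shape, cell size and origin match exactly.
#' @export
is_coregistered <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(a$cell_size == b$cell_size) &&
    isTRUE(all(a$origin == b$origin))
}

check_coregistered <- function(a, b, what = "rasters") {
  if (!identical(dim(a$values), dim(b$values)))
    stop(what, " have mismatched shapes: ",
         paste(dim(a$values), collapse = "x"), " vs ",
         paste(dim(b$values), collapse = "x"))
  if (!is_coregistered(a, b))
    stop(what, " are not co-registered (cell size or origin differ)")
  invisible(TRUE)
}

check_same_mask <- function(a, b, what = "rasters") {
  check_coregistered(a, b, what)
  if (!identical(is.na(a$values), is.na(b$values)))
    stop(what, " have mismatched nodata masks")
  invisible(TRUE)
}

#' Cell-center coordinates
#'
#' @param r an `eco_raster`.
#' @return list with matrices `x` and `y` of cell-center coordinates (m).
#' @export
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cell_size
  x <- matrix(r$origin[1] + (seq_len(nc) - 0.5) * cs, nr, nc, byrow = TRUE)
  y <- matrix(r$origin[2] + (nr - seq_len(nr) + 0.5) * cs, nr, nc)
  list(x = x, y = y)
}

#' Class and total areas
#'
#' Areas are computed by cell counting: `count * cell_size^2 / 1e6` km².
#'
#' @param r a `categorical_raster`.
#' @param code a class code present in the raster's scheme.
#' @return `class_area()`: area in km². `area_table()`: data frame of per-class
#'   areas for every scheme class (zero if absent). `total_area()`: unmasked
#'   area in km².
#' @export
class_area <- function(r, code) {
  if (!(code %in% r$scheme$code))
    stop("code ", code, " is not in the raster's scheme")
  sum(r$values == code, na.rm = TRUE) * r$cell_size^2 / 1e6
}

#' @rdname class_area
#' @export
area_table <- function(r) {
  n <- vapply(r$scheme$code,
              function(k) sum(r$values == k, na.rm = TRUE), integer(1))
  data.frame(code = r$scheme$code, name = r$scheme$name,
             ecological = r$scheme$ecological,
             cells = n, area_km2 = n * r$cell_size^2 / 1e6,
             stringsAsFactors = FALSE)
}

#' @rdname class_area
#' @export
total_area <- function(r) sum(!is.na(r$values)) * r$cell_size^2 / 1e6

#' Collapse a land-use raster to ecological / non-ecological
#'
#' Maps every unmasked cell through the scheme's ecological flag onto the
#' two-class legend of [eco_binary_scheme()] (1 = ecological,
#' 2 = non-ecological). The nodata mask is preserved.
#'
#' @param r a `categorical_raster`.
#' @return a `categorical_raster` with the binary scheme.
#' @export
to_binary_eco <- function(r) {
  eco <- eco_codes(r$scheme)
  v <- ifelse(is.na(r$values), NA_real_,
              ifelse(r$values %in% eco, 1, 2))
  v <- matrix(v, nrow(r$values))
  categorical_raster(v, r$cell_size, r$origin, r$year, eco_binary_scheme())
}
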