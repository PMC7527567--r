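#' Read and write rasters as Esri ASCII grids
#'
#' The on-disk format is the plain-text Esri ASCII grid (`.asc`): a six-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of cell values, north row first. All
#' coordinates must be planar projected meters; files whose cell size is on
#' the degree scale (<= 0.01) are rejected because every analysis in the
#' package measures length and area in meters.
#'
#' @param path file path.
#' @param type `"categorical"` or `"continuous"`.
#' @param scheme a [land_scheme] used to validate categorical codes.
#' @param year optional year stamp attached to the result.
#' @param units unit label for continuous rasters.
#' @return `read_raster()` returns an `eco_raster`; `write_raster()` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".asc")
#' r <- categorical_raster(matrix(c(1, 2, 2, 1), 2), 30, scheme = eco_binary_scheme())
#' write_raster(r, f)
#' r2 <- read_raster(f, "categorical", scheme = eco_binary_scheme())
#' @export
read_raster <- function(path, type = c("categorical", "continuous"),
                        scheme = default_scheme(), year = NULL, units = "m") {
  type <- match.arg(type)
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys))
    stop("not an Esri ASCII grid: missing header keys ",
         paste(setdiff(need, keys), collapse = ", "))
  if (vals[["cellsize"]] <= 0.01)
    stop("cell size ", vals[["cellsize"]], " looks like geographic degrees; ",
         "rasters must be in a projected CRS with meter units")
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  skip <- sum(keys %in% c(need, "nodata_value"))
  v <- scan(path, skip = skip, quiet = TRUE)
  nr <- vals[["nrows"]]; nc <- vals[["ncols"]]
  if (length(v) != nr * nc)
    stop("expected ", nr * nc, " cell values, found ", length(v))
  m <- matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  org <- c(vals[["xllcorner"]], vals[["yllcorner"]])
  if (type == "categorical")
    categorical_raster(m, vals[["cellsize"]], org, year, scheme)
  else
    continuous_raster(m, vals[["cellsize"]], org, year, units)
}

#' @rdname read_raster
#' @param r an `eco_raster` to write.
#' @export
write_raster <- function(r, path) {
  v <- r$values
  v[is.na(v)] <- -9999
  hdr <- c(
    paste("ncols", ncol(r$values)),
    paste("nrows", nrow(r$values)),
    paste("xllcorner", format(r$origin[1], scientific = FALSE)),
    paste("yllcorner", format(r$origin[2], scientific = FALSE)),
    paste("cellsize", format(r$cell_size, scientific = FALSE)),
    "NODATA_value -9999")
  body <- apply(v, 1L, function(row)
    paste(format(row, trim = TRUE, scientific = FALSE, digits = 15),
          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
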