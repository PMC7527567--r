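#' Land-type classification schemes
#'
#' A `land_scheme` describes the categorical legend of a land-use raster:
#' integer class codes, human-readable names, and a flag marking the classes
#' that count as ecological land (land providing natural ecosystem services).
#'
#' @param codes integer vector of unique, positive class codes.
#' @param names character vector of class names, same length as `codes`.
#' @param ecological logical vector flagging ecological classes.
#' @return An object of class `land_scheme`: a data frame with columns
#'   `code`, `name`, `ecological`.
#' @examples
#' sc <- land_scheme(1:2, c("forest", "city"), c(TRUE, FALSE))
#' @export
land_scheme <- function(codes, names, ecological) {
  codes <- as.integer(codes)
  if (length(codes) < 2L) stop("a land scheme needs at least 2 classes")
  if (anyDuplicated(codes)) stop("class codes must be unique")
  if (any(codes <= 0L)) stop("class codes must be positive integers")
  if (length(names) != length(codes) || length(ecological) != length(codes))
    stop("codes, names and ecological must have the same length")
  out <- data.frame(code = codes, name = as.character(names),
                    ecological = as.logical(ecological),
                    stringsAsFactors = FALSE)
  class(out) <- c("land_scheme", "data.frame")
  out
}

#' Default 10-class urban land-use scheme
#'
#' The canonical 10-type urban legend used throughout the package, in the
#' fixed coefficient-table order. Five classes are ecological land:
#' woodland, grassland, reservoirs and pit ponds, tidal flats, and rivers and
#' shallow water. Cropland (rainfed and paddy) and aquaculture areas are
#' production land with fragile ecological function; unutilized land is
#' excluded because its ecological benefit is not sustainable.
#'
#' @return A [land_scheme] with codes 1-10.
#' @export
default_scheme <- function() {
  land_scheme(
    codes = 1:10,
    names = c("woodland", "grassland", "rainfed cropland", "paddy fields",
              "aquaculture areas", "reservoirs and pit ponds", "tidal flats",
              "rivers and shallow water", "built-up land", "unutilized land"),
    ecological = c(TRUE, TRUE, FALSE, FALSE, FALSE,
                   TRUE, TRUE, TRUE, FALSE, FALSE)
  )
}

#' Two-class ecological / non-ecological scheme
#'
#' Legend used by binary ecological-status rasters: code 1 = ecological,
#' code 2 = non-ecological.
#' @return A [land_scheme].
#' @export
eco_binary_scheme <- function() {
  land_scheme(1:2, c("ecological", "non-ecological"), c(TRUE, FALSE))
}

#' @export
print.land_scheme <- function(x, ...) {
  cat("<land_scheme> ", nrow(x), " classes (",
      sum(x$ecological), " ecological)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

eco_codes <- function(scheme) scheme$code[scheme$ecological]

builtup_code <- function(scheme) {
  i <- grep("built", scheme$name, ignore.case = TRUE)
  if (length(i) != 1L)
    stop("scheme must contain exactly one built-up class ",
         "(name matching 'built'); pass `code` explicitly instead")
  scheme$code[i]
}

#' Read or write a land scheme as CSV
#'
#' CSV columns: `code`, `name`, `ecological` (logical or 0/1).
#' @param path file path.
#' @param scheme a [land_scheme].
#' @return `read_scheme()` returns a [land_scheme]; `write_scheme()` returns
#'   `path` invisibly.
#' @export
read_scheme <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("code", "name", "ecological")
  if (!all(need %in% names(d)))
    stop("scheme CSV must have columns: ", paste(need, collapse = ", "))
  land_scheme(d$code, d$name, as.logical(d$ecological))
}

#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  utils::write.csv(as.data.frame(scheme), path, row.names = FALSE)
  invisible(path)
}
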