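#' Identify patches in a categorical raster
#'
#' A patch is a maximal set of same-class cells connected under the chosen
#' connectivity (default 8, the standard raster landscape-metric convention).
#' Per-patch perimeters count exposed cell sides under 4-neighborhood: sides
#' facing another class, a nodata cell, or the landscape boundary. Each
#' patch also carries its contiguity value, computed from the 3x3 weighted
#' template (center 1, orthogonal neighbors 2, diagonal neighbors 1; weight
#' sum 13): the patch-mean template sum minus one, divided by 12, which is 0
#' for a single-cell patch and approaches 1 for large solid blocks.
#'
#' @param r a `categorical_raster`.
#' @param connectivity 8 (default) or 4.
#' @return A data frame (`patch_set`) with one row per patch: `id`, `code`,
#'   `cells`, `area_m2`, `area_ha`, `perimeter_m`, `contig`. The integer
#'   label matrix is attached as attribute `labels`.
#' @export
label_patches <- function(r, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  v <- r$values
  nr <- nrow(v); nc <- ncol(v); n <- nr * nc
  unmasked <- which(!is.na(v))
  if (!length(unmasked)) {
    out <- data.frame(id = integer(), code = numeric(), cells = integer(),
                      area_m2 = numeric(), area_ha = numeric(),
                      perimeter_m = numeric(), contig = numeric())
    attr(out, "labels") <- matrix(NA_integer_, nr, nc)
    class(out) <- c("patch_set", "data.frame")
    return(out)
  }
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  id <- matrix(seq_len(n), nr, nc)
  elist <- vector("list", length(shifts))
  for (s in seq_along(shifts)) {
    di <- shifts[[s]][1]; dj <- shifts[[s]][2]
    i1 <- seq_len(nr - di); i2 <- i1 + di
    if (dj >= 0) { j1 <- seq_len(nc - dj); j2 <- j1 + dj }
    else { j1 <- seq(1L - dj, nc); j2 <- j1 + dj }
    same <- !is.na(v[i1, j1, drop = FALSE]) &
      !is.na(v[i2, j2, drop = FALSE]) &
      v[i1, j1, drop = FALSE] == v[i2, j2, drop = FALSE]
    elist[[s]] <- cbind(id[i1, j1, drop = FALSE][same],
                        id[i2, j2, drop = FALSE][same])
  }
  e <- do.call(rbind, elist)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, t(e))
  memb <- igraph::components(g)$membership
  memb[-unmasked] <- NA_integer_
  # renumber patches consecutively in first-appearance order
  lab <- match(memb, unique(memb[unmasked]))
  labm <- matrix(lab, nr, nc)

  cs <- r$cell_size
  exposed <- exposed_sides(v)
  per_cells <- tabulate(lab[unmasked], nbins = max(lab, na.rm = TRUE))
  per_perim <- as.numeric(tapply(exposed[unmasked], lab[unmasked], sum)) * cs
  codes <- as.numeric(tapply(v[unmasked], lab[unmasked], `[`, 1L))
  tsum <- contig_template_sum(labm)
  per_contig <- (as.numeric(tapply(tsum[unmasked], lab[unmasked], mean)) - 1) / 12
  out <- data.frame(id = seq_along(per_cells), code = codes,
                    cells = per_cells,
                    area_m2 = per_cells * cs^2,
                    area_ha = per_cells * cs^2 / 1e4,
                    perimeter_m = per_perim, contig = per_contig)
  attr(out, "labels") <- labm
  class(out) <- c("patch_set", "data.frame")
  out
}

# per-cell count of exposed sides (4-neighborhood): unlike class, nodata
# neighbor, or grid boundary
exposed_sides <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(0L, nr, nc)
  nb <- function(di, dj) {
    m <- matrix(NA_real_, nr, nc)
    i_to <- seq_len(nr); j_to <- seq_len(nc)
    i_fr <- i_to + di; j_fr <- j_to + dj
    ok_i <- i_fr >= 1 & i_fr <= nr; ok_j <- j_fr >= 1 & j_fr <= nc
    m[i_to[ok_i], j_to[ok_j]] <- v[i_fr[ok_i], j_fr[ok_j]]
    m
  }
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    w <- nb(d[1], d[2])
    out <- out + (is.na(w) | w != v)
  }
  out[is.na(v)] <- 0L
  out
}

# per-cell 3x3 contiguity template sum over same-patch neighbors
contig_template_sum <- function(labm) {
  nr <- nrow(labm); nc <- ncol(labm)
  out <- matrix(1, nr, nc)   # center weight
  wts <- list(c(-1L, 0L, 2), c(1L, 0L, 2), c(0L, -1L, 2), c(0L, 1L, 2),
              c(-1L, -1L, 1), c(-1L, 1L, 1), c(1L, -1L, 1), c(1L, 1L, 1))
  for (w in wts) {
    di <- w[1]; dj <- w[2]
    m <- matrix(NA_integer_, nr, nc)
    i_to <- which(seq_len(nr) + di >= 1 & seq_len(nr) + di <= nr)
    j_to <- which(seq_len(nc) + dj >= 1 & seq_len(nc) + dj <= nc)
    m[i_to, j_to] <- labm[i_to + di, j_to + dj]
    out <- out + w[3] * (!is.na(m) & !is.na(labm) & m == labm)
  }
  out[is.na(labm)] <- NA_real_
  out
}

#' Class adjacency table
#'
#' Counts shared cell sides between classes under 4-neighborhood among
#' unmasked cells, with the double-count convention (each adjacency is
#' tallied from both participating cells), as used by the contagion index.
#'
#' @param r a `categorical_raster`.
#' @return symmetric numeric matrix `g` with one row/column per class present.
#' @export
adjacency_table <- function(r) {
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  present <- sort(unique(v[!is.na(v)]))
  g <- matrix(0, length(present), length(present),
              dimnames = list(present, present))
  tally <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return()
    t2 <- table(factor(a[ok], levels = present),
                factor(b[ok], levels = present))
    g <<- g + unclass(t2) + t(unclass(t2))
  }
  if (nr > 1) tally(v[-nr, , drop = FALSE], v[-1, , drop = FALSE])
  if (nc > 1) tally(v[, -nc, drop = FALSE], v[, -1, drop = FALSE])
  g
}

#' Landscape-level pattern metrics
#'
#' Computes the landscape-level metric set on a categorical raster:
#' \describe{
#'   \item{ED}{edge density, internal unlike-class edge length per area
#'     (m/ha); the landscape boundary is not counted.}
#'   \item{PD}{patch density, patches per 100 ha.}
#'   \item{LSI}{landscape shape index `0.25 * E' / sqrt(A')` with `E'` the
#'     total edge length including the landscape boundary (m) and `A'` the
#'     total area (m²).}
#'   \item{LPI}{largest patch index, percent of total area in the largest
#'     patch.}
#'   \item{CONTAG}{contagion, the adjacency-entropy aggregation measure in
#'     percent; undefined (`NA`) with fewer than two classes.}
#'   \item{SHDI}{Shannon diversity of class-area proportions.}
#'   \item{SHEI}{Shannon evenness, `SHDI / ln(m)` for `m` classes present;
#'     undefined with one class.}
#' }
#' Nodata cells count as landscape boundary: their sides contribute to
#' perimeter and to `E'`, never to unlike-class edge.
#'
#' @param r a `categorical_raster`.
#' @param connectivity patch connectivity, 8 (default) or 4.
#' @return tidy data frame: `level`, `class`, `metric`, `value`, `units`.
#' @export
landscape_metrics <- function(r, connectivity = 8) {
  v <- r$values
  cs <- r$cell_size
  n_cells <- sum(!is.na(v))
  if (n_cells == 0) stop("raster has no unmasked cells")
  a_m2 <- n_cells * cs^2
  a_ha <- a_m2 / 1e4
  patches <- label_patches(r, connectivity)
  g <- adjacency_table(r)
  present <- as.numeric(rownames(g))
  m <- length(present)
  p_i <- vapply(present, function(k) sum(v == k, na.rm = TRUE), numeric(1)) /
    n_cells

  unlike <- (sum(g) / 2 - sum(diag(g)) / 2)  # single-count unlike adjacencies
  edge_internal_m <- unlike * cs
  boundary_m <- boundary_edge_m(v, cs)
  ed <- edge_internal_m / a_ha
  lsi <- 0.25 * (edge_internal_m + boundary_m) / sqrt(a_m2)
  pd <- nrow(patches) / a_ha * 100
  lpi <- 100 * max(patches$area_m2) / a_m2
  shdi <- -sum(p_i * log(p_i))
  shei <- if (m > 1) shdi / log(m) else NA_real_
  contag <- if (m > 1) {
    gi <- rowSums(g)
    q <- sweep(g, 1, ifelse(gi > 0, gi, NA_real_), "/") * p_i
    terms <- q * log(q)
    100 * (1 + sum(terms[is.finite(terms)]) / (2 * log(m)))
  } else NA_real_

  data.frame(
    level = "landscape", class = NA_character_,
    metric = c("ED", "PD", "LSI", "LPI", "CONTAG", "SHDI", "SHEI"),
    value = c(ed, pd, lsi, lpi, contag, shdi, shei),
    units = c("m/ha", "patches/100 ha", "dimensionless", "%", "%",
              "dimensionless", "dimensionless"),
    stringsAsFactors = FALSE)
}

# total length (m) of cell sides facing nodata or the grid boundary
boundary_edge_m <- function(v, cs) {
  nr <- nrow(v); nc <- ncol(v)
  cnt <- 0L
  pad <- function(x, di, dj) {
    m <- matrix(NA_real_, nr, nc)
    ii <- seq_len(nr) + di; jj <- seq_len(nc) + dj
    ok_i <- which(ii >= 1 & ii <= nr); ok_j <- which(jj >= 1 & jj <= nc)
    m[ok_i, ok_j] <- x[ii[ok_i], jj[ok_j]]
    m
  }
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    w <- pad(v, d[1], d[2])
    cnt <- cnt + sum(!is.na(v) & is.na(w))
  }
  cnt * cs
}

#' Class-level pattern metrics
#'
#' PD and LPI use the total landscape area as denominator (the reporting
#' convention for class tables); the class shape index is
#' `0.25 * E_c / sqrt(A_c)` with `E_c` the class's total edge (the summed
#' patch perimeters) and `A_c` the class area; CONTIG_AM is the
#' area-weighted mean of per-patch contiguity with weights
#' patch area / class area.
#'
#' @param r a `categorical_raster`.
#' @param code class code.
#' @param connectivity patch connectivity, 8 (default) or 4.
#' @return tidy data frame as in [landscape_metrics()]. If the class is
#'   absent all values are `NA` (with a warning).
#' @export
class_metrics <- function(r, code, connectivity = 8) {
  patches <- label_patches(r, connectivity)
  cl <- patches[patches$code == code, , drop = FALSE]
  if (!nrow(cl)) {
    warning("class ", code, " absent from raster; metrics undefined")
    vals <- rep(NA_real_, 4)
  } else {
    a_m2 <- sum(!is.na(r$values)) * r$cell_size^2
    a_ha <- a_m2 / 1e4
    ac <- sum(cl$area_m2)
    vals <- c(nrow(cl) / a_ha * 100,
              0.25 * sum(cl$perimeter_m) / sqrt(ac),
              100 * max(cl$area_m2) / a_m2,
              sum(cl$area_m2 / ac * cl$contig))
  }
  data.frame(level = "class", class = as.character(code),
             metric = c("PD", "LSI", "LPI", "CONTIG_AM"),
             value = vals,
             units = c("patches/100 ha", "dimensionless", "%",
                       "dimensionless"),
             stringsAsFactors = FALSE)
}

#' Metric report for one or more dates
#'
#' Convenience wrapper producing the tidy landscape- plus class-level metric
#' table for a raster, optionally restricted to given class codes.
#'
#' @param r a `categorical_raster`.
#' @param codes class codes for class-level metrics (default: all present).
#' @param connectivity patch connectivity.
#' @return tidy data frame with a `year` column prepended.
#' @export
metric_report <- function(r, codes = NULL, connectivity = 8) {
  if (is.null(codes)) codes <- sort(unique(r$values[!is.na(r$values)]))
  out <- rbind(landscape_metrics(r, connectivity),
               do.call(rbind, lapply(codes, function(k)
                 class_metrics(r, k, connectivity))))
  cbind(year = if (is.null(r$year)) NA_integer_ else r$year, out)
}
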