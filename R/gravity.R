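#' Center of gravity of a land class
#'
#' The area-weighted mean coordinate of all cells in a class (or of all
#' ecological land): `X_t = sum(C_i x_i) / sum(C_i)` and likewise for `Y_t`,
#' with `C_i` the contributing area. With equal cell areas this is the
#' arithmetic mean of contributing cell centers; decomposing the class into
#' regions and area-weighting their centroids gives the same point.
#'
#' @param r a `categorical_raster`.
#' @param group either `"ecological"` (all ecological classes pooled) or one
#'   or more class codes.
#' @return A `gravity_center`: list with `x`, `y` (projected m), `group`,
#'   `year`, `area_km2`.
#' @export
center_of_gravity <- function(r, group = "ecological") {
  sel <- if (identical(group, "ecological"))
    !is.na(r$values) & r$values %in% eco_codes(r$scheme)
  else !is.na(r$values) & r$values %in% group
  if (!any(sel))
    stop("no cells in group '", paste(group, collapse = ","),
         "'; center of gravity undefined")
  ctr <- cell_centers(r)
  structure(list(x = mean(ctr$x[sel]), y = mean(ctr$y[sel]),
                 group = group,
                 year = if (is.null(r$year)) NA_integer_ else r$year,
                 area_km2 = sum(sel) * r$cell_size^2 / 1e6),
            class = "gravity_center")
}

#' @export
print.gravity_center <- function(x, ...) {
  cat("<gravity_center> group ", paste(x$group, collapse = ","),
      if (!is.na(x$year)) paste0(", year ", x$year),
      ": (", round(x$x, 1), ", ", round(x$y, 1), ") m, ",
      round(x$area_km2, 2), " km2\n", sep = "")
  invisible(x)
}

#' Displacement between two gravity centers
#'
#' Component-wise difference `b - a` (east and north, m), the Euclidean
#' distance, and a compass octant label from 45-degree sectors around the
#' eight principal directions.
#'
#' @param a,b `gravity_center`s of the same class group.
#' @return data frame: `dx_east_m`, `dy_north_m`, `distance_m`, `direction`.
#' @examples
#' sc <- eco_binary_scheme()
#' r1 <- categorical_raster(matrix(c(1, 2, 2, 2), 2), 30, scheme = sc)
#' r2 <- categorical_raster(matrix(c(2, 2, 1, 2), 2), 30, scheme = sc)
#' displacement(center_of_gravity(r1), center_of_gravity(r2))
#' @export
displacement <- function(a, b) {
  if (!identical(a$group, b$group))
    stop("gravity centers belong to different class groups")
  dx <- b$x - a$x
  dy <- b$y - a$y
  data.frame(dx_east_m = dx, dy_north_m = dy,
             distance_m = sqrt(dx^2 + dy^2),
             direction = compass_octant(dx, dy),
             stringsAsFactors = FALSE)
}

compass_octant <- function(dx, dy) {
  if (dx == 0 && dy == 0) return("none")
  ang <- atan2(dx, dy) * 180 / pi          # bearing: 0 = north, 90 = east
  if (ang < 0) ang <- ang + 360
  labs <- c("north", "northeast", "east", "southeast",
            "south", "southwest", "west", "northwest")
  labs[(floor((ang + 22.5) / 45) %% 8) + 1]
}

#' Gravity-center migration track over a scenario
#'
#' Centers of gravity per date plus displacement vectors between consecutive
#' dates for a class group.
#'
#' @param rasters list of year-stamped `categorical_raster`s.
#' @param group as in [center_of_gravity()].
#' @return list with `centers` (data frame: year, x, y, area_km2) and
#'   `moves` (data frame of period displacements).
#' @export
gravity_track <- function(rasters, group = "ecological") {
  ctrs <- lapply(rasters, center_of_gravity, group = group)
  centers <- data.frame(
    year = vapply(ctrs, `[[`, integer(1), "year"),
    x = vapply(ctrs, `[[`, numeric(1), "x"),
    y = vapply(ctrs, `[[`, numeric(1), "y"),
    area_km2 = vapply(ctrs, `[[`, numeric(1), "area_km2"))
  moves <- do.call(rbind, lapply(seq_len(length(ctrs) - 1), function(k) {
    cbind(period = paste(centers$year[k], centers$year[k + 1], sep = "-"),
          displacement(ctrs[[k]], ctrs[[k + 1]]))
  }))
  list(centers = centers, moves = moves)
}
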