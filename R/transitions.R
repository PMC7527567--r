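#' Land transformation matrix between two dates
#'
#' Cross-tabulates co-registered land-use rasters into the class-by-class
#' area matrix `T` (km², rows = origin class at t0, columns = destination
#' class at t1) and the row-normalized transition probability matrix `P`.
#' Rows of `P` satisfy `0 <= P_ij <= 1` and sum to 1 wherever the origin
#' class has nonzero area at t0; rows for classes absent at t0 are left
#' undefined (`NA`), not zero.
#'
#' @param r0,r1 co-registered `categorical_raster`s sharing a scheme and
#'   nodata mask.
#' @return A `transition_matrix` object: list with `area` (km² matrix),
#'   `prob`, `labels`, `years`, `cell_size`.
#' @examples
#' sc <- eco_binary_scheme()
#' a <- categorical_raster(matrix(c(1, 1, 2, 2), 2), 30, scheme = sc)
#' b <- categorical_raster(matrix(c(1, 2, 2, 2), 2), 30, scheme = sc)
#' transition_matrix(a, b)
#' @export
transition_matrix <- function(r0, r1) {
  check_same_mask(r0, r1, "transition rasters")
  if (!identical(r0$scheme$code, r1$scheme$code))
    stop("rasters use different schemes")
  sch <- r0$scheme
  keep <- !is.na(r0$values)
  tab <- table(factor(r0$values[keep], levels = sch$code),
               factor(r1$values[keep], levels = sch$code))
  a <- unclass(tab) * r0$cell_size^2 / 1e6
  dimnames(a) <- list(from = sch$name, to = sch$name)
  rs <- rowSums(a)
  p <- a / ifelse(rs > 0, rs, NA_real_)
  structure(list(area = a, prob = p, labels = sch$name,
                 years = c(r0$year, r1$year), cell_size = r0$cell_size,
                 scheme = sch),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> ", paste(x$years, collapse = " -> "),
      ", areas in km2\n", sep = "")
  print(round(x$area, 2))
  invisible(x)
}

#' Net area change per class
#'
#' For each class, the start area `A_a` (row sum of the area matrix), end
#' area `A_b` (column sum) and the net change `A = A_b - A_a`. In a closed
#' landscape the signed changes sum to zero.
#'
#' @param tm a [transition_matrix()].
#' @return data frame with columns `class`, `area_start`, `area_end`,
#'   `net_change` (km²).
#' @export
net_change <- function(tm) {
  a_a <- rowSums(tm$area)
  a_b <- colSums(tm$area)
  data.frame(class = tm$labels, area_start = as.numeric(a_a),
             area_end = as.numeric(a_b),
             net_change = as.numeric(a_b - a_a),
             stringsAsFactors = FALSE)
}

#' Contribution (B) and transition-probability (C) percentages
#'
#' `C_ij = 100 * T_ij / sum_j T_ij` is the origin-normalized transition
#' probability (rows sum to 100%); `B_ij = 100 * T_ij / sum_i T_ij` is the
#' destination-normalized contribution — the share of class `j`'s area at t1
#' that originated as class `i` (columns sum to 100%). Entries whose
#' normalizing area is zero are `NA`.
#'
#' @param tm a [transition_matrix()].
#' @return list with percentage matrices `B` and `C`.
#' @export
contribution_probability <- function(tm) {
  rs <- rowSums(tm$area)
  cs <- colSums(tm$area)
  C <- 100 * tm$area / ifelse(rs > 0, rs, NA_real_)
  B <- 100 * sweep(tm$area, 2, ifelse(cs > 0, cs, NA_real_), "/")
  list(B = B, C = C)
}

#' Markov projection of a land-use state vector
#'
#' Propagates a per-class state (areas or probabilities) through `steps`
#' applications of a row-stochastic transition probability matrix:
#' `S_{t+1} = S_t P`. Total mass is conserved at every step.
#'
#' @param P square row-stochastic matrix (rows may be all-`NA` only for
#'   states with zero mass).
#' @param s nonnegative state vector conformable with `P`.
#' @param steps nonnegative integer number of transitions.
#' @return the projected state vector.
#' @examples
#' markov_project(matrix(c(0.9, 0, 0.1, 1), 2), c(1, 0), 1)
#' @export
markov_project <- function(P, s, steps = 1L) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop("P must be a square matrix")
  if (length(s) != nrow(P)) stop("state vector not conformable with P")
  if (any(s < 0)) stop("state vector must be nonnegative")
  Pw <- P
  undef <- apply(Pw, 1, function(r) all(is.na(r)))
  if (any(undef & s > 0))
    stop("P has undefined rows for states with nonzero mass")
  Pw[undef, ] <- 0; diag(Pw)[undef] <- 1   # absorbing placeholder, mass 0
  if (any(is.na(Pw)) || any(Pw < -1e-12) ||
      any(abs(rowSums(Pw) - 1) > 1e-8))
    stop("P is not a row-stochastic matrix")
  out <- as.numeric(s)
  for (k in seq_len(steps)) out <- as.numeric(out %*% Pw)
  stats::setNames(out, colnames(P))
}

#' Ecological gain / loss map between two dates
#'
#' Compares per-cell ecological status and classifies each cell as gain
#' (non-eco to eco), loss (eco to non-eco), stable ecological or stable
#' non-ecological. Summary areas accompany the map.
#'
#' @param r0,r1 co-registered `categorical_raster`s with identical masks.
#' @return list with `map` (a `categorical_raster`; 1 = gain, 2 = loss,
#'   3 = stable ecological, 4 = stable non-ecological) and `summary`
#'   (data frame of areas in km²).
#' @export
gains_losses_map <- function(r0, r1) {
  check_same_mask(r0, r1, "gain/loss rasters")
  e0 <- to_binary_eco(r0)$values == 1
  e1 <- to_binary_eco(r1)$values == 1
  v <- matrix(NA_real_, nrow(r0$values), ncol(r0$values))
  v[!e0 & e1] <- 1; v[e0 & !e1] <- 2
  v[e0 & e1] <- 3; v[!e0 & !e1] <- 4
  legend <- land_scheme(1:4, c("gain", "loss", "stable ecological",
                               "stable non-ecological"),
                        c(TRUE, FALSE, TRUE, FALSE))
  map <- categorical_raster(v, r0$cell_size, r0$origin, r1$year, legend)
  cellkm2 <- r0$cell_size^2 / 1e6
  smry <- data.frame(
    status = legend$name,
    area_km2 = vapply(1:4, function(k) sum(v == k, na.rm = TRUE),
                      integer(1)) * cellkm2)
  list(map = map, summary = smry)
}
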