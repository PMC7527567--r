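# Independent brute-force oracles used to cross-check the implementation.
# Everything here is written with explicit loops and no calls into the
# package's metric/labeling code paths.

# breadth-first-search connected-component labeling
bfs_label_oracle <- function(v, connectivity = 8) {
  nr <- nrow(v); nc <- ncol(v)
  lab <- matrix(NA_integer_, nr, nc)
  nbrs <- if (connectivity == 8)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
          c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  cur <- 0L
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (is.na(v[i0, j0]) || !is.na(lab[i0, j0])) next
    cur <- cur + 1L
    queue <- list(c(i0, j0))
    lab[i0, j0] <- cur
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbrs))) {
        i <- cell[1] + nbrs[k, 1]; j <- cell[2] + nbrs[k, 2]
        if (i < 1 || i > nr || j < 1 || j > nc) next
        if (is.na(v[i, j]) || !is.na(lab[i, j])) next
        if (v[i, j] != v[cell[1], cell[2]]) next
        lab[i, j] <- cur
        queue[[length(queue) + 1]] <- c(i, j)
      }
    }
  }
  lab
}

# explicit-loop landscape-level metrics
brute_landscape_oracle <- function(v, cs, connectivity = 8) {
  nr <- nrow(v); nc <- ncol(v)
  n_cells <- sum(!is.na(v))
  a_m2 <- n_cells * cs^2; a_ha <- a_m2 / 1e4
  lab <- bfs_label_oracle(v, connectivity)
  n_patches <- max(lab, na.rm = TRUE)
  patch_cells <- tabulate(lab[!is.na(lab)], n_patches)

  unlike <- 0L; boundary <- 0L
  present <- sort(unique(v[!is.na(v)]))
  g <- matrix(0, length(present), length(present),
              dimnames = list(present, present))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(v[i, j])) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || is.na(v[ii, jj])) {
        boundary <- boundary + 1L
      } else {
        a <- match(v[i, j], present); b <- match(v[ii, jj], present)
        g[a, b] <- g[a, b] + 1     # double count: visited from both sides
        if (v[i, j] != v[ii, jj]) unlike <- unlike + 1L
      }
    }
  }
  unlike <- unlike / 2             # each unlike side visited twice
  p_i <- sapply(present, function(k) sum(v == k, na.rm = TRUE)) / n_cells
  m <- length(present)
  shdi <- -sum(p_i * log(p_i))
  contag <- if (m > 1) {
    acc <- 0
    for (a in seq_len(m)) for (b in seq_len(m)) {
      q <- p_i[a] * g[a, b] / sum(g[a, ])
      if (is.finite(q) && q > 0) acc <- acc + q * log(q)
    }
    100 * (1 + acc / (2 * log(m)))
  } else NA_real_
  list(ED = unlike * cs / a_ha,
       PD = n_patches / a_ha * 100,
       LSI = 0.25 * (unlike * cs + boundary * cs) / sqrt(a_m2),
       LPI = 100 * max(patch_cells) * cs^2 / a_m2,
       CONTAG = contag,
       SHDI = shdi,
       SHEI = if (m > 1) shdi / log(m) else NA_real_)
}

# brute-force Euclidean distance (cell units) to nearest TRUE cell
brute_edt <- function(built) {
  nr <- nrow(built); nc <- ncol(built)
  idx <- which(built, arr.ind = TRUE)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out[i, j] <- sqrt(min((idx[, 1] - i)^2 + (idx[, 2] - j)^2))
  out
}

# random categorical raster fixture
rand_cat_raster <- function(nr, nc, codes = 1:2, seed = 1, cell_size = 30,
                            scheme = NULL) {
  set.seed(seed)
  if (is.null(scheme)) {
    if (identical(codes, 1:2)) scheme <- eco_binary_scheme()
    else scheme <- default_scheme()
  }
  categorical_raster(matrix(sample(codes, nr * nc, TRUE), nr, nc),
                     cell_size, scheme = scheme)
}

# small fast synthetic config for tests
test_config <- function(seed = 1, ...) {
  synthetic_config(nrow = 48, ncol = 48, n_seeds = 12, seed = seed, ...)
}

# hand-written Bernoulli log-likelihood
loglik_oracle <- function(y, p) sum(y * log(p) + (1 - y) * log(1 - p))
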