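# Independent brute-force oracles, deliberately written with naive loops so
# they share no code path with the package internals.

# difference operator by direct cell-by-cell enumeration (dense)
oracle_difference_matrix <- function(n_rows, n_cols) {
  idx <- function(i, j) (j - 1L) * n_rows + i     # column-major like R
  rows <- list()
  for (i in seq_len(n_rows)) {
    for (j in seq_len(n_cols)) {
      if (j < n_cols) {                            # right neighbor
        r <- numeric(n_rows * n_cols)
        r[idx(i, j)] <- 1; r[idx(i, j + 1L)] <- -1
        rows[[length(rows) + 1L]] <- r
      }
      if (i < n_rows) {                            # down neighbor
        r <- numeric(n_rows * n_cols)
        r[idx(i, j)] <- 1; r[idx(i + 1L, j)] <- -1
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  do.call(rbind, rows)
}

# dense literal evaluation of the smoothing operator
oracle_smoother_matrix <- function(n_rows, n_cols, gamma) {
  Bd <- oracle_difference_matrix(n_rows, n_cols)
  solve(diag(n_rows * n_cols) + gamma * t(Bd) %*% Bd)
}

# all-pairs Matheron estimator with explicit double loops
oracle_semivariogram <- function(z, px, bin_width, max_lag) {
  nr <- nrow(z); nc <- ncol(z)
  ss <- list(); np <- list(); dsum <- list()
  for (a in seq_len(nr * nc - 1L)) {
    ia <- (a - 1L) %% nr + 1L; ja <- (a - 1L) %/% nr + 1L
    for (b in (a + 1L):(nr * nc)) {
      ib <- (b - 1L) %% nr + 1L; jb <- (b - 1L) %/% nr + 1L
      d <- sqrt((ia - ib)^2 + (ja - jb)^2) * px
      if (d > max_lag + bin_width / 2) next
      k <- as.character(round(d / bin_width))
      sq <- (z[ia, ja] - z[ib, jb])^2
      ss[[k]] <- (ss[[k]] %||% 0) + sq
      np[[k]] <- (np[[k]] %||% 0) + 1
      dsum[[k]] <- (dsum[[k]] %||% 0) + d
    }
  }
  bins <- sort(as.integer(names(ss)))
  bins <- bins[bins * bin_width <= max_lag]
  out <- data.frame(
    lag = vapply(as.character(bins), function(k) dsum[[k]] / np[[k]], 0),
    gamma_hat = vapply(as.character(bins),
                       function(k) ss[[k]] / (2 * np[[k]]), 0),
    n_pairs = vapply(as.character(bins), function(k) np[[k]], 0))
  out[order(out$lag), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# closed-form spherical semivariogram values for fit-recovery tests
oracle_spherical <- function(h, c0, c, a) {
  ifelse(h <= a, c0 + c * (1.5 * h / a - 0.5 * (h / a)^3), c0 + c)
}

# small helper: a reproducible random raster
random_grid <- function(nr, nc, seed, px = 4) {
  set.seed(seed)
  raster_grid(matrix(runif(nr * nc), nr, nc), pixel_size = px)
}
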