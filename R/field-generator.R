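#' Specify a field-generation problem
#'
#' A `field_spec` bundles everything needed to generate one random NDVI
#' field by two-dimensional Tikhonov regularization: the grid dimensions,
#' pixel size, the coarse pixel's target mean and variance, the smoothness
#' multiplier gamma, and the bounds of the uniform prior draw.
#'
#' The defaults are the subarctic tundra parameterization used throughout
#' the package examples: a 62 x 62 grid of 4 m pixels (a ~250 m coarse
#' pixel), target mean 0.54 and target population variance 0.009.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers, product >= 4).
#' @param pixel_size Pixel side length in meters (> 0).
#' @param mu_target Target field mean (dimensionless NDVI).
#' @param sigma2_target Target field population variance (> 0).
#' @param gamma Smoothness multiplier, gamma >= 0.  gamma = 0 gives an
#'   uncorrelated rescaled uniform field; large gamma gives a nearly
#'   uniform surface at the mean.
#' @param draw_bounds Length-2 numeric, min < max, bounds of the uniform
#'   prior draw.  Default `c(0, 1)`, the plausible NDVI range of a
#'   terrestrial surface.
#' @param seed Optional integer seed making generation reproducible.
#'
#' @return An object of class `field_spec`.
#' @examples
#' spec <- field_spec(gamma = 10, seed = 1)
#' spec
#' @export
field_spec <- function(n_rows = 62L, n_cols = 62L, pixel_size = 4,
                       mu_target = 0.54, sigma2_target = 0.009,
                       gamma = 10, draw_bounds = c(0, 1), seed = NULL) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    stop("`n_rows` and `n_cols` must be positive integers")
  }
  if (n_rows * n_cols < 4L) stop("grid must have at least 4 cells")
  if (!is.finite(sigma2_target) || sigma2_target <= 0) {
    stop("`sigma2_target` must be > 0")
  }
  if (!is.finite(gamma) || gamma < 0) stop("`gamma` must be finite and >= 0")
  if (length(draw_bounds) != 2L || !all(is.finite(draw_bounds)) ||
      draw_bounds[1] >= draw_bounds[2]) {
    stop("`draw_bounds` must be c(min, max) with min < max")
  }
  if (!is.finite(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be > 0")
  }
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 pixel_size = as.numeric(pixel_size),
                 mu_target = as.numeric(mu_target),
                 sigma2_target = as.numeric(sigma2_target),
                 gamma = as.numeric(gamma),
                 draw_bounds = as.numeric(draw_bounds),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "field_spec")
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf(paste0("<field_spec> %d x %d grid, %.6g m pixels\n",
                     "  target mean %.6g, target variance %.6g, gamma %.6g\n",
                     "  prior draw U(%.3g, %.3g), seed %s\n"),
              x$n_rows, x$n_cols, x$pixel_size, x$mu_target,
              x$sigma2_target, x$gamma, x$draw_bounds[1], x$draw_bounds[2],
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

#' Build the 2D first-difference operator
#'
#' Constructs the sparse matrix `B` whose rows encode all cardinal
#' (horizontal and vertical) neighbor pairs of a non-periodic
#' `n_rows x n_cols` grid: each row has a +1 and a -1 so that `B %*% z`
#' is the vector of first differences of the vectorized field `z`
#' (column-major, R's native layout).  `B` annihilates constant fields.
#'
#' Rows are ordered deterministically: all horizontal (within-row) pairs
#' in row-major scan order first, then all vertical (within-column)
#' pairs, giving `n_rows*(n_cols-1) + n_cols*(n_rows-1)` rows in total.
#'
#' @param n_rows,n_cols Grid dimensions; the grid must have at least one
#'   neighbor pair (so a 1 x 1 grid is an error).
#'
#' @return A `difference_operator`: a `Matrix::sparseMatrix` of dimension
#'   `n_pairs x (n_rows*n_cols)` with `n_rows`/`n_cols` attributes.
#' @examples
#' B <- difference_operator(2, 2)
#' Matrix::crossprod(B)   # graph Laplacian of the 2 x 2 grid
#' @export
difference_operator <- function(n_rows, n_cols) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("grid dimensions must be positive")
  if (n_rows == 1L && n_cols == 1L) {
    stop("a 1 x 1 grid has no cardinal neighbor pairs")
  }
  idx <- function(i, j) (j - 1L) * n_rows + i  # column-major cell index

  rows_h <- n_rows * (n_cols - 1L)  # horizontal pairs (i,j)-(i,j+1)
  rows_v <- n_cols * (n_rows - 1L)  # vertical pairs (i,j)-(i+1,j)

  # horizontal pairs in row-major scan order
  if (rows_h > 0L) {
    i_h <- rep(seq_len(n_rows), each = n_cols - 1L)
    j_h <- rep(seq_len(n_cols - 1L), times = n_rows)
    from_h <- idx(i_h, j_h); to_h <- idx(i_h, j_h + 1L)
  } else from_h <- to_h <- integer(0)
  # vertical pairs in row-major scan order
  if (rows_v > 0L) {
    i_v <- rep(seq_len(n_rows - 1L), each = n_cols)
    j_v <- rep(seq_len(n_cols), times = n_rows - 1L)
    from_v <- idx(i_v, j_v); to_v <- idx(i_v + 1L, j_v)
  } else from_v <- to_v <- integer(0)

  n_pairs <- rows_h + rows_v
  B <- Matrix::sparseMatrix(
    i = rep(seq_len(n_pairs), 2L),
    j = c(from_h, from_v, to_h, to_v),
    x = rep(c(1, -1), each = n_pairs),
    dims = c(n_pairs, n_rows * n_cols))
  attr(B, "n_rows") <- n_rows
  attr(B, "n_cols") <- n_cols
  B
}

#' Build the Tikhonov smoother
#'
#' Forms the smoothing operator `S = (I + gamma * t(B) %*% B)^-1` for a
#' given first-difference operator and smoothness multiplier: gamma
#' weights the squared-first-difference penalty linearly, balancing a
#' purely random field (gamma = 0) against a uniform surface at the mean
#' (gamma large).  `S` is symmetric positive definite, leaves constant
#' fields unchanged (its row sums are 1 because `B` annihilates
#' constants), and reduces to the identity at gamma = 0.  Rather than a
#' dense inverse, the operator is stored as a cached sparse Cholesky
#' factorization of `I + gamma t(B) B`, so that many fields can be
#' generated cheaply from one factorization.
#'
#' @param B A `difference_operator`, or a `field_spec` (in which case the
#'   operator is built for its grid and `gamma` defaults to the spec's).
#' @param gamma Smoothness multiplier, finite and >= 0.
#'
#' @return An object of class `tik_smoother` with elements `factor` (the
#'   Cholesky factorization; `NULL` at gamma = 0), `gamma`, `n_rows`,
#'   `n_cols`.
#' @examples
#' S <- tik_smoother(difference_operator(8, 8), gamma = 10)
#' z <- smooth_field(S, rep(0.54, 64))
#' all.equal(z, rep(0.54, 64))   # constants pass through
#' @export
tik_smoother <- function(B, gamma = NULL) {
  if (inherits(B, "field_spec")) {
    if (is.null(gamma)) gamma <- B$gamma
    B <- difference_operator(B$n_rows, B$n_cols)
  }
  if (is.null(gamma)) stop("`gamma` must be supplied")
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma < 0) {
    stop("`gamma` must be a single finite number >= 0")
  }
  n_rows <- attr(B, "n_rows"); n_cols <- attr(B, "n_cols")
  if (is.null(n_rows) || is.null(n_cols)) {
    stop("`B` must be a difference_operator (see difference_operator())")
  }
  fac <- NULL
  if (gamma > 0) {
    A <- Matrix::Diagonal(ncol(B)) + gamma * Matrix::crossprod(B)
    fac <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  }
  structure(list(factor = fac, gamma = as.numeric(gamma),
                 n_rows = n_rows, n_cols = n_cols),
            class = "tik_smoother")
}

#' @export
print.tik_smoother <- function(x, ...) {
  cat(sprintf("<tik_smoother> %d x %d grid, gamma = %.6g%s\n",
              x$n_rows, x$n_cols, x$gamma,
              if (x$gamma == 0) " (identity)" else ""))
  invisible(x)
}

#' Apply a Tikhonov smoother to a field
#'
#' Computes `S %*% z`, i.e. solves `(I + gamma t(B) B) s = z` using the
#' cached factorization.
#'
#' @param smoother A `tik_smoother`.
#' @param z Numeric vector of length `n_rows*n_cols` (column-major), or a
#'   matrix of matching dimensions.
#' @return Smoothed values in the same shape as `z`.
#' @export
smooth_field <- function(smoother, z) {
  stopifnot(inherits(smoother, "tik_smoother"))
  n <- smoother$n_rows * smoother$n_cols
  was_matrix <- is.matrix(z)
  if (was_matrix) {
    if (!all(dim(z) == c(smoother$n_rows, smoother$n_cols))) {
      stop("field dimensions do not match the smoother's grid")
    }
    z <- as.vector(z)
  }
  if (length(z) != n) stop("field length does not match the smoother's grid")
  s <- if (smoother$gamma == 0) as.numeric(z) else {
    as.numeric(Matrix::solve(smoother$factor, z, system = "A"))
  }
  if (was_matrix) s <- matrix(s, smoother$n_rows, smoother$n_cols)
  s
}

## rescale a smoothed draw to hit the target mean and population variance
## exactly; Psi is the empirical (population) variance of the smoothed draw
normalize_field <- function(s, mu_target, sigma2_target) {
  mu_alpha <- mean(s)
  psi <- pop_var(s)
  scale <- sqrt(sigma2_target / psi)
  if (psi <= 0 || !is.finite(scale)) {
    stop(paste("smoothed draw has zero empirical variance (degenerate draw",
               "or over-smoothing to exact constancy); cannot normalize"))
  }
  list(values = scale * (s - mu_alpha) + mu_target,
       record = list(mu_alpha = mu_alpha, psi = psi, scale = scale))
}

#' Generate a Tikhonov-regularized random NDVI field
#'
#' Draws a uniform random field over the spec's `draw_bounds`, smooths it
#' with `(I + gamma t(B) B)^-1`, and rescales the result to hit the
#' target mean and population variance exactly:
#' `alpha' = sqrt(sigma2 / Psi) * (S alpha - mean(S alpha)) + mu`,
#' where `Psi` is the empirical population variance of the smoothed draw.
#' The output therefore has sample mean `mu_target` and population
#' variance `sigma2_target` to machine precision for every realization.
#'
#' Values are not clipped to the draw bounds by default, since clipping
#' would break the exact mean/variance normalization; set `clip = TRUE`
#' to clamp the output to `draw_bounds` (at the cost of that exactness).
#'
#' @param spec A `field_spec`.
#' @param smoother Optional pre-built `tik_smoother` for the spec's grid
#'   and gamma; built on the fly when omitted.  Passing a cached smoother
#'   is the fast path when generating ensembles.
#' @param n Number of fields to generate.
#' @param clip Clamp output to `draw_bounds`?  Default `FALSE`.
#'
#' @return For `n = 1` a `raster_grid` (units `"NDVI"`) with a
#'   `normalization` attribute (list: `mu_alpha`, `psi`, `scale`); for
#'   `n > 1` a list of such grids.
#' @examples
#' f <- generate_field(field_spec(16, 16, gamma = 5, seed = 42))
#' mean(f)                      # 0.54 to machine precision
#' @export
generate_field <- function(spec, smoother = NULL, n = 1L, clip = FALSE) {
  stopifnot(inherits(spec, "field_spec"))
  if (is.null(smoother)) smoother <- tik_smoother(spec)
  if (smoother$n_rows != spec$n_rows || smoother$n_cols != spec$n_cols) {
    stop("smoother was built for different grid dimensions")
  }
  if (smoother$gamma != spec$gamma) {
    stop("smoother was built for a different gamma")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n_cells <- spec$n_rows * spec$n_cols
  out <- vector("list", n)
  for (k in seq_len(n)) {
    alpha <- stats::runif(n_cells, spec$draw_bounds[1], spec$draw_bounds[2])
    s <- smooth_field(smoother, alpha)
    nf <- normalize_field(s, spec$mu_target, spec$sigma2_target)
    vals <- nf$values
    if (clip) vals <- pmin(pmax(vals, spec$draw_bounds[1]),
                           spec$draw_bounds[2])
    g <- raster_grid(matrix(vals, spec$n_rows, spec$n_cols),
                     pixel_size = spec$pixel_size, units = "NDVI")
    attr(g, "normalization") <- nf$record
    out[[k]] <- g
  }
  if (n == 1L) out[[1L]] else out
}
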