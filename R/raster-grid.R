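#' Create a raster grid
#'
#' A `raster_grid` is the package's basic spatial container: a numeric
#' matrix of pixel values on a regular square lattice, together with the
#' pixel side length in meters and a free-form units tag (e.g. `"NDVI"`,
#' `"LAI"`, `"gC_per_pixel_season"`).
#'
#' @param values Numeric matrix of pixel values; all entries must be finite.
#' @param pixel_size Pixel side length in meters (> 0).
#' @param units Character tag describing what the values are.
#'
#' @return An object of class `raster_grid`: the value matrix with
#'   `pixel_size` and `units` attributes.
#' @examples
#' g <- raster_grid(matrix(runif(16), 4, 4), pixel_size = 4, units = "NDVI")
#' dim(g)
#' @export
raster_grid <- function(values, pixel_size = 4, units = "NDVI") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (!all(is.finite(values))) {
    stop("raster values must all be finite")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (meters)")
  }
  structure(values,
            pixel_size = as.numeric(pixel_size),
            units = as.character(units),
            class = c("raster_grid", "matrix", "array"))
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d pixels, %.6g m pixel size, units: %s\n",
              nrow(x), ncol(x), pixel_size(x), attr(x, "units")))
  v <- as.vector(x)
  cat(sprintf("  mean %.6g, population variance %.6g, range [%.6g, %.6g]\n",
              mean(v), pop_var(v), min(v), max(v)))
  invisible(x)
}

#' @export
plot.raster_grid <- function(x, main = attr(x, "units"), ...) {
  px <- pixel_size(x)
  # image() draws x along rows; transpose and flip so row 1 is at the top
  z <- t(x[nrow(x):1, , drop = FALSE])
  graphics::image(x = seq_len(nrow(z)) * px, y = seq_len(ncol(z)) * px,
                  z = z, xlab = "x (m)", ylab = "y (m)", main = main,
                  useRaster = TRUE, asp = 1, ...)
  invisible(x)
}

#' Pixel size of a raster grid
#' @param x A `raster_grid`.
#' @return Pixel side length in meters.
#' @export
pixel_size <- function(x) {
  ps <- attr(x, "pixel_size")
  if (is.null(ps)) stop("object has no pixel_size attribute")
  ps
}

## population variance (divisor N) -- the convention used throughout
pop_var <- function(x) {
  x <- as.vector(x)
  mean((x - mean(x))^2)
}

as_raster_grid <- function(values, like = NULL, pixel_size = NULL,
                           units = NULL) {
  if (!is.null(like)) {
    if (is.null(pixel_size)) pixel_size <- pixel_size(like)
    if (is.null(units)) units <- attr(like, "units")
  }
  raster_grid(values, pixel_size = pixel_size, units = units)
}
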