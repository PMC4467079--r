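#' Isotropic empirical semivariogram of a raster grid
#'
#' Computes the classical Matheron estimator
#' `gamma_hat(h) = sum((z_i - z_j)^2) / (2 N(h))` over all pixel pairs
#' whose Euclidean separation falls in each lag bin.  All pairs are
#' enumerated exactly by scanning integer lattice offsets, so the result
#' equals a brute-force all-pairs computation.
#'
#' Lag bins have width `bin_width` and nominal centers at integer
#' multiples of `bin_width` (edges at half-multiples); empty bins are
#' dropped.  The reported `lag` of each bin is the count-weighted mean
#' pair separation inside it, which is what the model fit uses.
#'
#' @param grid A `raster_grid` (>= 2 pixels).
#' @param max_lag Largest lag retained, in meters.  Default: half the
#'   longer grid side length.
#' @param bin_width Bin width in meters.  Default: the pixel size.
#'
#' @return A `semivariogram`: a data frame with columns `lag` (m),
#'   `gamma_hat` (semivariance) and `n_pairs`, carrying the field's
#'   population variance and pixel size as attributes.
#' @examples
#' g <- raster_grid(matrix(rnorm(64), 8, 8), pixel_size = 4)
#' empirical_semivariogram(g)
#' @export
empirical_semivariogram <- function(grid, max_lag = NULL, bin_width = NULL) {
  stopifnot(inherits(grid, "raster_grid"))
  nr <- nrow(grid); nc <- ncol(grid)
  if (nr * nc < 2L) stop("grid must have at least 2 pixels")
  px <- pixel_size(grid)
  if (is.null(bin_width)) bin_width <- px
  if (!is.finite(bin_width) || bin_width <= 0) stop("`bin_width` must be > 0")
  if (is.null(max_lag)) max_lag <- max(nr, nc) / 2 * px
  if (!is.finite(max_lag) || max_lag <= 0) stop("`max_lag` must be > 0")

  z <- unclass(grid)
  lag_cut <- max_lag + bin_width / 2       # outer edge of the last bin
  di_max <- min(nr - 1L, floor(lag_cut / px))
  dj_max <- min(nc - 1L, floor(lag_cut / px))

  # half-plane of lattice offsets: dj > 0 (any di), or dj == 0 and di > 0
  offs <- rbind(
    expand.grid(di = seq_len(di_max), dj = 0L),
    expand.grid(di = seq.int(-di_max, di_max), dj = seq_len(max(dj_max, 0L))))
  d <- sqrt(offs$di^2 + offs$dj^2) * px
  keep <- d <= lag_cut & d > 0
  offs <- offs[keep, , drop = FALSE]; d <- d[keep]
  if (nrow(offs) == 0L) stop("no pixel pairs fall within `max_lag`")

  ss <- numeric(nrow(offs)); np <- numeric(nrow(offs))
  for (k in seq_len(nrow(offs))) {
    di <- offs$di[k]; dj <- offs$dj[k]
    ri <- seq_len(nr - abs(di)); cj <- seq_len(nc - dj)
    r1 <- if (di >= 0) ri else ri + abs(di)
    r2 <- if (di >= 0) ri + di else ri
    dz <- z[r1, cj, drop = FALSE] - z[r2, cj + dj, drop = FALSE]
    ss[k] <- sum(dz * dz)
    np[k] <- length(dz)
  }

  bin <- as.integer(round(d / bin_width))
  agg_ss <- tapply(ss, bin, sum)
  agg_np <- tapply(np, bin, sum)
  agg_d  <- tapply(d * np, bin, sum) / agg_np   # count-weighted mean lag
  keep_bin <- agg_np > 0 & as.integer(names(agg_ss)) * bin_width <= max_lag
  if (!any(keep_bin)) stop("all lag bins are empty after filtering")

  out <- data.frame(lag = as.numeric(agg_d[keep_bin]),
                    gamma_hat = as.numeric(agg_ss[keep_bin] /
                                             (2 * agg_np[keep_bin])),
                    n_pairs = as.numeric(agg_np[keep_bin]))
  out <- out[order(out$lag), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, field_var = pop_var(z), pixel_size = px,
            class = c("semivariogram", "data.frame"))
}

#' @export
print.semivariogram <- function(x, ...) {
  cat(sprintf("<semivariogram> %d lag bins, %.6g - %.6g m (field variance %.4g)\n",
              nrow(x), min(x$lag), max(x$lag), attr(x, "field_var")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more bins\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
plot.semivariogram <- function(x, ...) {
  graphics::plot(x$lag, x$gamma_hat, xlab = "lag (m)",
                 ylab = "semivariance", pch = 16, ...)
  invisible(x)
}

## spherical variogram model
spherical_model <- function(h, nugget, partial_sill, range_m) {
  hr <- pmin(h / range_m, 1)
  nugget + partial_sill * (1.5 * hr - 0.5 * hr^3)
}

#' Fit a spherical variogram model
#'
#' Fits `gamma(h) = c0 + c * (1.5 h/a - 0.5 (h/a)^3)` for `h <= a` (and
#' `c0 + c` beyond) to an empirical semivariogram by weighted nonlinear
#' least squares with all three parameters constrained non-negative.
#' The default weights are `n_pairs / lag`: pair counts damped by lag,
#' so that the densely populated long-lag bins do not swamp the
#' near-origin rise that identifies short ranges, while the long-lag
#' plateau still anchors large ranges.  The range may exceed the largest
#' lag — strongly smoothed fields plateau beyond the observable domain —
#' but is bounded at twice it (the domain side length under the default
#' half-side maximum lag), past which neither the range nor the sill is
#' identifiable and both inflate without bound.
#'
#' The optimizer is started from several range guesses (including the
#' first lag reaching 95% of the apparent sill) and the best weighted
#' fit is kept; nugget starts at the first-bin semivariance and the
#' partial sill at the field variance minus that (falling back to the
#' semivariogram maximum when the field variance is unknown).
#'
#' @param sv A `semivariogram` (>= 4 bins), or any data frame with
#'   columns `lag`, `gamma_hat` and optionally `n_pairs`.
#' @param weights Optional numeric vector of fit weights overriding the
#'   default `n_pairs / lag`.
#' @param flat What to do when the semivariogram carries no structure
#'   (all semivariances equal, e.g. a constant field): `"error"` stops;
#'   `"flag"` returns an unconverged fit marked `flagged = TRUE`.
#'
#' @return A `spherical_fit`: list with `nugget`, `partial_sill`,
#'   `range_m`, `converged`, `flagged`, and the underlying `nls` fit.
#' @examples
#' h <- seq(4, 124, by = 4)
#' sv <- data.frame(lag = h,
#'                  gamma_hat = 0.002 + 0.007 * (pmin(h / 48, 1) * 1.5 -
#'                                               pmin(h / 48, 1)^3 * 0.5),
#'                  n_pairs = rep(100, length(h)))
#' coef(fit_spherical(sv))
#' @export
fit_spherical <- function(sv, weights = NULL, flat = c("error", "flag")) {
  flat <- match.arg(flat)
  if (!all(c("lag", "gamma_hat") %in% names(sv))) {
    stop("`sv` needs columns `lag` and `gamma_hat`")
  }
  fv <- attr(sv, "field_var")
  sv <- as.data.frame(sv)
  if (nrow(sv) < 4L) stop("need at least 4 semivariogram bins to fit")
  w <- if (!is.null(weights)) weights else if ("n_pairs" %in% names(sv)) {
    sv$n_pairs / sv$lag
  } else 1 / sv$lag

  if (max(sv$gamma_hat) - min(sv$gamma_hat) <= 1e-15 * max(1, max(sv$gamma_hat))) {
    if (flat == "error") {
      stop("flat semivariogram: range is unidentifiable (constant field?)")
    }
    return(structure(list(nugget = sv$gamma_hat[1], partial_sill = 0,
                          range_m = max(sv$lag), converged = FALSE,
                          flagged = TRUE, fit = NULL),
                     class = "spherical_fit"))
  }

  c0_0 <- max(sv$gamma_hat[1], 0)
  sill_tot <- if (!is.null(fv) && is.finite(fv) && fv > 0) fv else
    max(sv$gamma_hat)
  c_0 <- max(sill_tot - c0_0, 0.25 * sill_tot)
  reach <- which(sv$gamma_hat >= 0.95 * sill_tot)
  a_0 <- if (length(reach)) sv$lag[reach[1]] else max(sv$lag)
  h1 <- min(sv$lag); hmax <- max(sv$lag)
  a_max <- 2 * hmax

  fits <- list()
  for (a_try in unique(pmin(c(a_0, 2 * h1, 5 * h1, hmax / 2, 2 * hmax),
                            a_max))) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        gamma_hat ~ spherical_model(lag, c0, c, a),
        data = sv, weights = w,
        start = list(c0 = c0_0, c = c_0, a = a_try),
        lower = c(0, 0, 1e-6), upper = c(Inf, Inf, a_max),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits)) {
    if (flat == "error") stop("spherical variogram fit failed to converge")
    return(structure(list(nugget = NA_real_, partial_sill = NA_real_,
                          range_m = NA_real_, converged = FALSE,
                          flagged = TRUE, fit = NULL),
                     class = "spherical_fit"))
  }
  dev <- vapply(fits, stats::deviance, numeric(1))
  best <- fits[[which.min(dev)]]
  cf <- stats::coef(best)
  # a range pinned at its upper bound is not an interior estimate: the
  # semivariogram never approached a plateau and the fit is unidentifiable
  at_bound <- cf["a"] >= 0.999 * a_max
  structure(list(nugget = unname(cf["c0"]), partial_sill = unname(cf["c"]),
                 range_m = unname(cf["a"]),
                 converged = isTRUE(best$convInfo$isConv) ||
                   best$convInfo$stopCode %in% 1:3,
                 flagged = unname(at_bound), fit = best),
            class = "spherical_fit")
}

#' @export
print.spherical_fit <- function(x, ...) {
  cat(sprintf(paste0("<spherical_fit> nugget %.4g, partial sill %.4g,",
                     " range %.4g m%s%s\n"),
              x$nugget, x$partial_sill, x$range_m,
              if (isTRUE(x$converged)) "" else " [not converged]",
              if (isTRUE(x$flagged)) " [flagged: unidentifiable]" else ""))
  invisible(x)
}

#' @export
coef.spherical_fit <- function(object, ...) {
  c(nugget = object$nugget, partial_sill = object$partial_sill,
    range_m = object$range_m)
}

#' @export
predict.spherical_fit <- function(object, lag, ...) {
  spherical_model(lag, object$nugget, object$partial_sill, object$range_m)
}

#' Radially averaged power spectrum of a raster grid
#'
#' Removes the field mean, applies the 2D discrete Fourier transform, and
#' accumulates squared spectral magnitude within annular frequency bins
#' one fundamental frequency wide.  Power is normalized so that the total
#' over all nonzero-frequency bins equals the field's population variance
#' (a discrete Parseval convention), and frequencies are reported in
#' cycles per meter using the grid's pixel size.
#'
#' @param grid A `raster_grid`, at least 4 x 4.
#'
#' @return A `radial_spectrum`: data frame with columns `frequency`
#'   (cycles per m, zero excluded), `wavelength` (m) and `power`.
#' @examples
#' g <- raster_grid(matrix(cos(2 * pi * (1:64) / 32), 64, 64,
#'                         byrow = TRUE), pixel_size = 4)
#' sp <- radial_power_spectrum(g)
#' sp$wavelength[which.max(sp$power)]   # 128 m = 32 pixels * 4 m
#' @export
radial_power_spectrum <- function(grid) {
  stopifnot(inherits(grid, "raster_grid"))
  nr <- nrow(grid); nc <- ncol(grid)
  if (nr < 4L || nc < 4L) stop("grid must be at least 4 x 4")
  px <- pixel_size(grid)

  z <- unclass(grid) - mean(grid)
  P <- Mod(stats::fft(z))^2

  fi <- ifelse(seq_len(nr) - 1L <= nr / 2, seq_len(nr) - 1L,
               seq_len(nr) - 1L - nr) / (nr * px)
  fj <- ifelse(seq_len(nc) - 1L <= nc / 2, seq_len(nc) - 1L,
               seq_len(nc) - 1L - nc) / (nc * px)
  fr <- sqrt(outer(fi^2, fj^2, `+`))

  f0 <- 1 / (max(nr, nc) * px)              # fundamental frequency
  bin <- as.integer(round(fr / f0))
  nz <- bin > 0L
  tot <- sum(P[nz])
  v <- pop_var(z)
  pw <- if (tot > 0) tapply(P[nz], bin[nz], sum) * (v / tot) else
    tapply(P[nz], bin[nz], sum)            # constant field: all-zero power

  out <- data.frame(frequency = as.integer(names(pw)) * f0,
                    power = as.numeric(pw))
  out <- out[order(out$frequency), , drop = FALSE]
  out$wavelength <- 1 / out$frequency
  rownames(out) <- NULL
  structure(out[, c("frequency", "wavelength", "power")],
            pixel_size = px, field_var = v,
            class = c("radial_spectrum", "data.frame"))
}

#' @export
plot.radial_spectrum <- function(x, log = "xy", ...) {
  ok <- x$power > 0
  graphics::plot(x$wavelength[ok], x$power[ok], log = log, type = "b",
                 pch = 16, xlab = "wavelength (m)", ylab = "power", ...)
  invisible(x)
}

## 5-parameter Richards (generalized logistic) curve and its inverse
richards <- function(x, A, K, g, m, nu) {
  A + (K - A) / (1 + exp(-g * (x - m)))^(1 / nu)
}
richards_inverse <- function(y, A, K, g, m, nu) {
  m - log(((K - A) / (y - A))^nu - 1) / g
}

#' Build a gamma-to-range calibration curve
#'
#' For each value on a grid of `log10(gamma)`, generates an ensemble of
#' Tikhonov-regularized fields from the template spec, fits a spherical
#' variogram model to each, and records the mean and standard deviation
#' of the fitted range.  A generalized logistic (Richards) curve
#' `R(x) = A + (K - A) / (1 + exp(-g (x - m)))^(1/nu)` is then fit to the
#' mean ranges as a function of `x = log10(gamma)` by nonlinear least
#' squares; if the 5-parameter fit is ill-conditioned the shape exponent
#' `nu` is fixed at 1.
#'
#' Unidentifiable (flagged or unconverged) variogram fits at a grid point
#' are dropped; losing more than half of an ensemble triggers a warning.
#'
#' @param template A `field_spec`; its `gamma` is overridden by the grid.
#'   Its `seed` (if set) makes the whole curve reproducible.
#' @param log10_gamma Numeric grid of log10(gamma) values (>= 4 points).
#' @param n_iter Fields per grid point (>= 2).
#'
#' @return A `calibration_curve`: list with `points` (data frame:
#'   `log10_gamma`, `mean_range`, `sd_range`, `n_ok`, `n_dropped`),
#'   `logistic` (named vector A, K, g, m, nu) and `logistic_fit`.
#' @examples
#' \donttest{
#' tpl <- field_spec(31, 31, seed = 1)
#' cc <- build_calibration_curve(tpl, log10_gamma = c(-1, 0, 0.5, 1, 1.5, 2),
#'                               n_iter = 20)
#' calibrate_gamma(cc, target_range = 40)
#' }
#' @export
build_calibration_curve <- function(template, log10_gamma = seq(-1, 2, 0.5),
                                    n_iter = 100L) {
  stopifnot(inherits(template, "field_spec"))
  if (length(log10_gamma) < 4L) stop("need at least 4 gamma grid points")
  if (n_iter < 2L) stop("`n_iter` must be >= 2")
  log10_gamma <- sort(as.numeric(log10_gamma))

  B <- difference_operator(template$n_rows, template$n_cols)
  pts <- lapply(log10_gamma, function(lg) {
    spec <- template
    spec$gamma <- 10^lg
    sm <- tik_smoother(B, spec$gamma)
    fields <- generate_field(spec, smoother = sm, n = n_iter)
    ranges <- vapply(fields, function(f) {
      ft <- fit_spherical(empirical_semivariogram(f), flat = "flag")
      if (isTRUE(ft$flagged) || !isTRUE(ft$converged)) NA_real_ else ft$range_m
    }, numeric(1))
    n_ok <- sum(!is.na(ranges))
    if (n_ok < n_iter / 2) {
      warning(sprintf(
        "log10(gamma) = %.3g: %d of %d variogram fits unusable",
        lg, n_iter - n_ok, n_iter))
    }
    data.frame(log10_gamma = lg,
               mean_range = mean(ranges, na.rm = TRUE),
               sd_range = stats::sd(ranges, na.rm = TRUE),
               n_ok = n_ok, n_dropped = n_iter - n_ok)
  })
  pts <- do.call(rbind, pts)

  x <- pts$log10_gamma; y <- pts$mean_range
  start5 <- list(A = max(min(y) * 0.9, 1e-3), K = max(y) * 1.1,
                 g = 2, m = stats::median(x), nu = 1)
  lower5 <- c(0, 0, 1e-3, min(x) - 5, 1e-2)
  upper5 <- c(max(y), 10 * max(y), 50, max(x) + 5, 100)
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ richards(x, A, K, g, m, nu), data = dat,
                      start = start5, lower = lower5, upper = upper5,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(stats::coef(fit)))) {
    fit <- minpack.lm::nlsLM(
      y ~ richards(x, A, K, g, m, 1), data = dat,
      start = start5[c("A", "K", "g", "m")],
      lower = lower5[1:4], upper = upper5[1:4],
      control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- c(stats::coef(fit), nu = 1)
  } else {
    cf <- stats::coef(fit)
  }
  cf <- cf[c("A", "K", "g", "m", "nu")]
  structure(list(points = pts, logistic = cf, logistic_fit = fit,
                 template = template, n_iter = as.integer(n_iter)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %d gamma grid points, %d fields each\n",
              nrow(x$points), x$n_iter))
  print.data.frame(x$points, digits = 4)
  cat(sprintf("  logistic: A = %.4g, K = %.4g, g = %.4g, m = %.4g, nu = %.4g\n",
              x$logistic["A"], x$logistic["K"], x$logistic["g"],
              x$logistic["m"], x$logistic["nu"]))
  invisible(x)
}

#' @export
predict.calibration_curve <- function(object, log10_gamma, ...) {
  cf <- object$logistic
  richards(log10_gamma, cf["A"], cf["K"], cf["g"], cf["m"], cf["nu"])
}

#' @export
plot.calibration_curve <- function(x, ...) {
  p <- x$points
  graphics::plot(p$log10_gamma, p$mean_range, pch = 16,
                 xlab = expression(log[10](gamma)),
                 ylab = "mean fitted range (m)", ...)
  graphics::arrows(p$log10_gamma, p$mean_range - p$sd_range,
                   p$log10_gamma, p$mean_range + p$sd_range,
                   angle = 90, code = 3, length = 0.03)
  xx <- seq(min(p$log10_gamma), max(p$log10_gamma), length.out = 200)
  graphics::lines(xx, predict(x, xx))
  invisible(x)
}

#' Calibrate gamma to a target semivariogram range
#'
#' Inverts the fitted generalized logistic curve analytically to find the
#' smoothness multiplier whose ensemble mean range equals the target.
#'
#' @param curve A `calibration_curve`.
#' @param target_range Target semivariogram range in meters; must lie
#'   strictly between the logistic's lower and upper asymptotes.
#'
#' @return The calibrated gamma (on the natural scale, i.e. `10^x`).
#' @export
calibrate_gamma <- function(curve, target_range) {
  stopifnot(inherits(curve, "calibration_curve"))
  cf <- curve$logistic
  A <- unname(cf["A"]); K <- unname(cf["K"])
  if (!is.finite(target_range) || target_range <= A || target_range >= K) {
    stop(sprintf(
      "target range %.4g m is outside the achievable interval (%.4g, %.4g) m",
      target_range, A, K))
  }
  x <- richards_inverse(target_range, A, K, unname(cf["g"]),
                        unname(cf["m"]), unname(cf["nu"]))
  10^x
}
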