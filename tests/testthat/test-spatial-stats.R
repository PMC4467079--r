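test_that("semivariogram of tiny grids matches hand computation", {
  g <- raster_grid(matrix(c(0, 1), 1, 2), pixel_size = 4)
  sv <- empirical_semivariogram(g, max_lag = 4)
  expect_equal(sv$lag, 4)
  expect_equal(sv$gamma_hat, 0.5)      # (1-0)^2 / (2*1)
  expect_equal(sv$n_pairs, 1)

  const <- raster_grid(matrix(0.54, 5, 5), pixel_size = 4)
  sv <- empirical_semivariogram(const)
  expect_true(all(sv$gamma_hat == 0))
})

test_that("Matheron estimator equals all-pairs brute force on small grids", {
  for (dims in list(c(4, 5), c(6, 6), c(3, 6))) {
    g <- random_grid(dims[1], dims[2], seed = dims[1] * 10 + dims[2])
    ml <- max(dims) / 2 * 4
    sv <- empirical_semivariogram(g, max_lag = ml)
    ref <- oracle_semivariogram(unclass(g), 4, 4, ml)
    expect_equal(sv$lag, ref$lag, tolerance = 1e-12)
    expect_equal(sv$gamma_hat, ref$gamma_hat, tolerance = 1e-12)
    expect_equal(sv$n_pairs, ref$n_pairs)
  }
})

test_that("white noise has flat semivariance at its variance", {
  set.seed(11)
  v <- 0.25
  g <- raster_grid(matrix(rnorm(40 * 40, sd = sqrt(v)), 40, 40),
                   pixel_size = 4)
  sv <- empirical_semivariogram(g)
  expect_true(all(abs(sv$gamma_hat - v) / v < 0.15))
  expect_lt(abs(mean(sv$gamma_hat) - v) / v, 0.05)
})

test_that("spherical fit recovers noise-free model parameters exactly", {
  h <- seq(4, 124, by = 4)
  sv <- data.frame(lag = h, gamma_hat = oracle_spherical(h, 0.002, 0.007, 48),
                   n_pairs = rep(500, length(h)))
  fit <- fit_spherical(sv)
  expect_equal(fit$nugget, 0.002, tolerance = 1e-6)
  expect_equal(fit$partial_sill, 0.007, tolerance = 1e-6)
  expect_equal(fit$range_m, 48, tolerance = 1e-6)
  expect_lt(stats::deviance(fit$fit), 1e-8)
  expect_true(fit$converged)
})

test_that("flat semivariograms are unidentifiable", {
  sv <- data.frame(lag = c(4, 8, 12, 16), gamma_hat = rep(0.009, 4),
                   n_pairs = rep(10, 4))
  expect_error(fit_spherical(sv), "unidentifiable")
  flagged <- fit_spherical(sv, flat = "flag")
  expect_true(flagged$flagged)
  expect_false(flagged$converged)
})

test_that("radial spectrum isolates a pure cosine and conserves variance", {
  px <- 4
  # cosine along columns with wavelength 32 pixels on a 64x64 grid
  z <- matrix(cos(2 * pi * (0:63) / 32), 64, 64, byrow = TRUE)
  sp <- radial_power_spectrum(raster_grid(z, pixel_size = px))
  expect_equal(sp$frequency[which.max(sp$power)], 1 / (32 * px),
               tolerance = 1e-10)
  expect_gt(max(sp$power) / sum(sp$power), 0.999)

  g <- random_grid(16, 16, seed = 2)
  sp <- radial_power_spectrum(g)
  expect_equal(sum(sp$power), mean((g - mean(g))^2), tolerance = 1e-10)
  expect_true(all(diff(sp$frequency) > 0))
  expect_true(all(sp$power >= 0))

  const <- raster_grid(matrix(1, 8, 8), pixel_size = px)
  expect_true(all(radial_power_spectrum(const)$power == 0))
})

test_that("variance is partitioned into nugget plus sill across gamma", {
  for (g in c(0.1, 1, 10, 100)) {
    spec <- field_spec(gamma = g, seed = 31)
    fields <- generate_field(spec, tik_smoother(spec), n = 12)
    tot <- vapply(fields, function(f) {
      ft <- fit_spherical(empirical_semivariogram(f), flat = "flag")
      if (ft$flagged || !ft$converged) NA_real_ else ft$nugget + ft$partial_sill
    }, numeric(1))
    expect_lt(abs(mean(tot, na.rm = TRUE) - 0.009) / 0.009, 0.15)
  }
})

test_that("smoother strength drives the fitted range monotonically", {
  mean_range <- vapply(c(0.1, 1, 10, 100), function(g) {
    spec <- field_spec(gamma = g, seed = 13)
    fields <- generate_field(spec, tik_smoother(spec), n = 15)
    r <- vapply(fields, function(f) {
      ft <- fit_spherical(empirical_semivariogram(f), flat = "flag")
      if (ft$flagged || !ft$converged) NA_real_ else ft$range_m
    }, numeric(1))
    mean(r, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_range) > 0))
})

test_that("calibration curve is self-consistent and invertible", {
  tpl <- field_spec(seed = 17)
  cc <- build_calibration_curve(tpl, log10_gamma = c(-1, 0, 0.5, 1, 1.5, 2),
                                n_iter = 15)
  # fitted curve tracks the recorded mean ranges
  pred <- predict(cc, cc$points$log10_gamma)
  expect_lt(max(abs(pred - cc$points$mean_range) / cc$points$mean_range),
            0.35)
  # monotone in the target
  g40 <- calibrate_gamma(cc, 40)
  g80 <- calibrate_gamma(cc, 80)
  expect_gt(g80, g40)
  # targets outside the asymptotes are refused with the interval reported
  expect_error(calibrate_gamma(cc, 1e6), "achievable")
})

test_that("calibration round trip recovers a known gamma", {
  gamma_true <- 5
  spec <- field_spec(gamma = gamma_true, seed = 23)
  fields <- generate_field(spec, tik_smoother(spec), n = 20)
  r <- vapply(fields, function(f) {
    ft <- fit_spherical(empirical_semivariogram(f), flat = "flag")
    if (ft$flagged || !ft$converged) NA_real_ else ft$range_m
  }, numeric(1))
  target <- mean(r, na.rm = TRUE)

  cc <- build_calibration_curve(field_spec(seed = 29),
                                log10_gamma = c(-1, 0, 0.5, 1, 1.5, 2),
                                n_iter = 15)
  gamma_hat <- calibrate_gamma(cc, target)
  expect_lt(abs(gamma_hat - gamma_true) / gamma_true, 0.25)
})
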