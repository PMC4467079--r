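test_that("quota methods select exactly floor(f * N) pixels", {
  g <- random_grid(10, 10, seed = 6)
  for (m in 1:3) {
    mask <- classify_edges(g, m)
    expect_equal(sum(mask), 30L)                  # floor(0.3 * 100)
    expect_equal(attr(mask, "fraction"), 0.3)
  }
  expect_equal(sum(classify_edges(g, 1, target_fraction = 0.25)), 25L)
  expect_equal(sum(classify_edges(random_grid(7, 9, seed = 8), 2)),
               floor(0.3 * 63))
})

test_that("method 4 marks both sides of the rounded class boundary", {
  z <- cbind(matrix(0.2, 4, 2), matrix(0.8, 4, 2))
  mask <- classify_edges(raster_grid(z, pixel_size = 4), 4)
  expected <- cbind(matrix(FALSE, 4, 1), matrix(TRUE, 4, 2),
                    matrix(FALSE, 4, 1))
  expect_equal(unclass(mask)[, ], expected, ignore_attr = TRUE)
  expect_equal(attr(mask, "fraction"), 0.5)

  # a uniform class has no boundary at all
  mask <- classify_edges(raster_grid(matrix(0.9, 4, 4), pixel_size = 4), 4)
  expect_equal(sum(mask), 0L)

  # 0.5 rounds up: a 0.5 pixel joins the vegetated class
  z <- matrix(c(0.5, 0.4, 0.5, 0.4), 2, 2)
  mask <- classify_edges(raster_grid(z, pixel_size = 4), 4)
  expect_true(all(mask))
})

test_that("edge classification is deterministic, even under ties", {
  z <- matrix(rep(c(0.2, 0.5, 0.8), length.out = 25), 5, 5)
  g <- raster_grid(z, pixel_size = 4)
  for (m in c(1, 4)) {
    m1 <- classify_edges(g, m)
    m2 <- classify_edges(g, m)
    expect_identical(unclass(m1)[, ], unclass(m2)[, ])
  }
  gr <- random_grid(8, 8, seed = 14)
  expect_identical(unclass(classify_edges(gr, 3))[, ],
                   unclass(classify_edges(gr, 3))[, ])
})

test_that("degenerate inputs for edge classification error out", {
  flat <- raster_grid(matrix(1, 5, 5), pixel_size = 4)
  expect_error(classify_edges(flat, 2), "constant")
  expect_error(classify_edges(flat, 3), "constant")
  expect_error(classify_edges(random_grid(5, 5, 1), 7), "method")
  expect_error(classify_edges(random_grid(2, 5, 1), 2), "3 x 3")
  expect_error(classify_edges(random_grid(5, 5, 1), 1,
                              target_fraction = 1.2), "between 0 and 1")
})

make_uniform_gpp <- function(nr = 10, nc = 10, value = 2) {
  per_pixel <- raster_grid(matrix(value, nr, nc), pixel_size = 4,
                           units = "gC_per_pixel_season")
  trscape:::new_gpp_map(per_pixel, pixel_area = 16)
}

test_that("edge reduction scales masked pixels and recomputes totals", {
  gpp <- make_uniform_gpp()
  # exactly 30% of uniform pixels at factor 0.7: exactly 9% off the total
  mask <- matrix(FALSE, 10, 10); mask[1:30] <- TRUE
  red <- apply_edge_reduction(gpp, mask, factor = 0.7)
  expect_equal(1 - red$landscape_total / gpp$landscape_total, 0.09,
               tolerance = 1e-12)
  # factor 1 and empty masks change nothing
  expect_equal(apply_edge_reduction(gpp, mask, factor = 1)$landscape_total,
               gpp$landscape_total)
  none <- matrix(FALSE, 10, 10)
  expect_equal(apply_edge_reduction(gpp, none)$landscape_total,
               gpp$landscape_total)
  expect_error(apply_edge_reduction(gpp, matrix(FALSE, 9, 10)), "dimensions")
  expect_error(apply_edge_reduction(gpp, mask, factor = 0), "factor")
})

test_that("the relative reduction equals the edge share times (1 - factor)", {
  set.seed(21)
  forcing <- synthesize_ppfd(n_days = 2)
  ndvi <- generate_field(field_spec(20, 20, gamma = 5, seed = 21))
  gpp <- integrate_gpp(ndvi, forcing)
  for (m in 1:4) {
    mask <- classify_edges(ndvi, m)
    red <- apply_edge_reduction(gpp, mask, factor = 0.7)
    loss <- 1 - red$landscape_total / gpp$landscape_total
    edge_share <- sum(gpp$per_pixel_totals[mask]) / sum(gpp$per_pixel_totals)
    expect_equal(loss, 0.3 * edge_share, tolerance = 1e-10)
    expect_lte(loss, 0.3)
    expect_gte(loss, 0)
  }
})

test_that("gradient methods concentrate losses on productive pixels", {
  spec <- field_spec(gamma = 10^0.85, seed = 33)
  fields <- generate_field(spec, tik_smoother(spec), n = 8)
  forcing <- synthesize_ppfd(n_days = 1)
  loss <- sapply(fields, function(f) {
    gpp <- integrate_gpp(f, forcing)
    vapply(1:3, function(m) {
      red <- apply_edge_reduction(gpp, classify_edges(f, m))
      1 - red$landscape_total / gpp$landscape_total
    }, numeric(1))
  })
  expect_gt(mean(loss[2, ]), mean(loss[1, ]))
  expect_gt(mean(loss[3, ]), mean(loss[1, ]))
})
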