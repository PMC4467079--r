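test_that("difference operator encodes all cardinal neighbor pairs", {
  B <- difference_operator(2, 2)
  expect_equal(dim(B), c(4L, 4L))
  # t(B) B is the graph Laplacian of the 2x2 grid 4-cycle
  L <- as.matrix(Matrix::crossprod(B))
  adj <- matrix(c(0, 1, 1, 0,
                  1, 0, 0, 1,
                  1, 0, 0, 1,
                  0, 1, 1, 0), 4, 4)   # cells in column-major order
  expect_equal(unname(L), 2 * diag(4) - adj)
  expect_equal(unname(diag(L)), rep(2, 4))

  for (dims in list(c(1, 2), c(3, 1), c(3, 4), c(5, 5))) {
    B <- difference_operator(dims[1], dims[2])
    n_pairs <- dims[1] * (dims[2] - 1) + dims[2] * (dims[1] - 1)
    expect_equal(nrow(B), n_pairs)
    # each row holds exactly a +1 and a -1
    Bm <- as.matrix(B)
    expect_true(all(apply(Bm, 1, function(r) {
      sum(r == 1) == 1 && sum(r == -1) == 1 && sum(r != 0) == 2
    })))
    # constants are annihilated
    expect_equal(as.numeric(B %*% rep(0.54, ncol(B))),
                 rep(0, n_pairs))
  }

  expect_equal(as.matrix(difference_operator(1, 2)),
               matrix(c(1, -1), 1, 2), ignore_attr = TRUE)
  expect_error(difference_operator(1, 1), "neighbor")
})

test_that("smoother matches hand algebra and dense evaluation", {
  # gamma = 0 is the identity
  S0 <- tik_smoother(difference_operator(3, 3), gamma = 0)
  z <- rnorm(9)
  expect_identical(smooth_field(S0, z), z)

  # 1x2 grid at gamma 1: hand-inverted (I + B'B) = [[2,-1],[-1,2]]
  S <- tik_smoother(difference_operator(1, 2), gamma = 1)
  expect_equal(smooth_field(S, c(1, 0)), c(2 / 3, 1 / 3))
  expect_equal(smooth_field(S, c(0, 1)), c(1 / 3, 2 / 3))

  # constants pass through unchanged for any gamma (row sums are 1)
  for (g in c(0.1, 1, 10, 250)) {
    S <- tik_smoother(difference_operator(6, 4), gamma = g)
    expect_equal(smooth_field(S, rep(0.54, 24)), rep(0.54, 24),
                 tolerance = 1e-12)
  }

  # dense-oracle equivalence and symmetry/PD on small grids
  for (dims in list(c(4, 4), c(5, 7), c(8, 8))) {
    for (g in c(0.5, 10)) {
      So <- oracle_smoother_matrix(dims[1], dims[2], g)
      expect_equal(unname(So), unname(t(So)), tolerance = 1e-10)
      expect_true(all(eigen(So, symmetric = TRUE,
                            only.values = TRUE)$values > 0))
      S <- tik_smoother(difference_operator(dims[1], dims[2]), gamma = g)
      set.seed(1)
      z <- runif(prod(dims))
      expect_equal(smooth_field(S, z), as.numeric(So %*% z),
                   tolerance = 1e-8)
    }
  }

  expect_error(tik_smoother(difference_operator(2, 2), gamma = NA_real_))
  expect_error(tik_smoother(difference_operator(2, 2), gamma = -1))
})

test_that("generated fields hit the target mean and variance exactly", {
  for (g in c(0, 0.1, 10, 100)) {
    spec <- field_spec(12, 17, mu_target = 0.54, sigma2_target = 0.009,
                       gamma = g, seed = 42)
    f <- generate_field(spec)
    expect_lt(abs(mean(f) - 0.54), 1e-10)
    expect_lt(abs(mean((f - mean(f))^2) - 0.009), 1e-10)
  }
  # and for a different parameterization
  spec <- field_spec(9, 9, mu_target = 0.2, sigma2_target = 0.03,
                     gamma = 3, seed = 7)
  f <- generate_field(spec)
  expect_lt(abs(mean(f) - 0.2), 1e-10)
  expect_lt(abs(mean((f - mean(f))^2) - 0.03), 1e-10)
})

test_that("generation is seed-deterministic and matches the dense oracle", {
  spec <- field_spec(8, 8, gamma = 5, seed = 123)
  f1 <- generate_field(spec)
  f2 <- generate_field(spec)
  expect_identical(unclass(f1)[, ], unclass(f2)[, ])

  # literal replay: same draw through the dense operator, same normalization
  So <- oracle_smoother_matrix(8, 8, 5)
  set.seed(123)
  alpha <- runif(64, 0, 1)
  s <- as.numeric(So %*% alpha)
  expected <- sqrt(0.009 / mean((s - mean(s))^2)) * (s - mean(s)) + 0.54
  expect_equal(as.vector(unclass(f1)), expected, tolerance = 1e-8)
})

test_that("gamma = 0 yields an affine rescaling of the raw draw", {
  spec <- field_spec(10, 10, gamma = 0, seed = 5)
  f <- generate_field(spec)
  set.seed(5)
  alpha <- runif(100, 0, 1)
  expect_gt(cor(as.vector(unclass(f)), alpha), 1 - 1e-12)
})

test_that("degenerate smoothed draws are rejected by name", {
  expect_error(trscape:::normalize_field(rep(0.5, 16), 0.54, 0.009),
               "zero empirical variance")
})

test_that("clipping keeps values inside the draw bounds", {
  spec <- field_spec(10, 10, sigma2_target = 0.2, gamma = 0, seed = 3)
  f <- generate_field(spec, clip = TRUE)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("mismatched smoother and spec are refused", {
  spec <- field_spec(6, 6, gamma = 2, seed = 1)
  expect_error(generate_field(spec, tik_smoother(difference_operator(5, 6),
                                                 gamma = 2)), "dimensions")
  expect_error(generate_field(spec, tik_smoother(difference_operator(6, 6),
                                                 gamma = 3)), "gamma")
})
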