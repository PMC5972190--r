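const_vol <- function(c0, n = 6) intensity_volume(array(c0, rep(n, 3)))

test_that("all smoothing filters are identities on constant volumes", {
  v <- const_vol(0.37)
  expect_equal(guided_filter(v, 1, 1)$data, v$data, tolerance = 1e-12)
  expect_equal(bilateral_filter(v)$data, v$data, tolerance = 1e-12)
  expect_equal(sharpen(v)$data, v$data, tolerance = 1e-12)
})

test_that("guided filter matches the per-window brute-force oracle", {
  for (seed in c(1, 2, 3)) {
    x <- rand_vol(8, seed)
    for (eps in c(1, 0.01)) {
      got <- guided_filter(intensity_volume(x), r = 1, eps = eps)$data
      expect_lt(max(abs(got - oracle_guided(x, 1, eps))), 1e-8)
    }
  }
  # larger radius too
  x <- rand_vol(9, 4)
  got <- guided_filter(intensity_volume(x), r = 2, eps = 0.1)$data
  expect_lt(max(abs(got - oracle_guided(x, 2, 0.1))), 1e-8)
})

test_that("guided filter damps noise and stays within the input range", {
  set.seed(10)
  x <- array(pmin(pmax(0.4 + rnorm(20^3, 0, 0.05), 0), 1), rep(20, 3))
  q <- guided_filter(intensity_volume(x), 1, 1)$data
  expect_lt(sd(q), sd(x))          # eps = 1 forces a_k <= 0.2 on noise
  expect_gte(min(q), min(x) - 1e-12)
  expect_lte(max(q), max(x) + 1e-12)
})

test_that("bilateral filter matches the direct triple-loop oracle", {
  for (seed in c(5, 6)) {
    x <- rand_vol(6, seed)
    got <- bilateral_filter(intensity_volume(x), sigma = 1,
                            mu = 0.00017)$data
    expect_lt(max(abs(got - oracle_bilateral(x, 1, 0.00017, 2))), 1e-10)
  }
})

test_that("bilateral filter converges to a Gaussian blur for huge mu", {
  x <- rand_vol(6, 7)
  got <- bilateral_filter(intensity_volume(x), sigma = 1, mu = 1e6)$data
  expect_lt(max(abs(got - oracle_gauss_cube(x, 1, 2))), 1e-6)
})

test_that("bilateral output stays inside the neighborhood value hull", {
  x <- rand_vol(10, 8)
  q <- bilateral_filter(intensity_volume(x))$data
  expect_gte(min(q), min(x) - 1e-12)
  expect_lte(max(q), max(x) + 1e-12)
})

test_that("smoothing parameter validation rejects bad values", {
  v <- const_vol(0.5)
  expect_error(guided_filter(v, 0, 1), "r must")
  expect_error(guided_filter(v, 1, 0), "eps")
  expect_error(bilateral_filter(v, sigma = 0), "sigma")
  expect_error(bilateral_filter(v, mu = 0), "mu")
  expect_error(bilateral_filter(v, support_radius = 1), "support_radius")
  expect_error(sharpen(v, amount = -1), "amount")
})

test_that("sharpening overshoots at a step edge and is identity at 0", {
  x <- array(0.2, c(5, 5, 20))
  x[, , 11:20] <- 0.8
  v <- intensity_volume(x)
  s <- sharpen(v, amount = 1, blur_sigma = 1)$data
  # undershoot on the dark side, overshoot capped by clipping on the bright
  expect_lt(s[3, 3, 10], 0.8 - 1e-6)
  expect_lt(min(s[3, 3, 8:10]), 0.2 + 1e-9)  # never brightens the dark side
  expect_lt(s[3, 3, 10], x[3, 3, 10])
  expect_gt(s[3, 3, 11], x[3, 3, 11] - 1e-12)
  expect_equal(sharpen(v, amount = 0)$data, x)
  # far from the edge the profile is untouched
  expect_equal(s[3, 3, 1:4], x[3, 3, 1:4], tolerance = 1e-6)
})

test_that("histogram matching leaves a volume of identical slices alone", {
  set.seed(9)
  sl <- matrix(runif(64), 8, 8)
  x <- array(0, c(5, 8, 8))
  for (k in 1:5) x[k, , ] <- sl
  out <- histogram_match_slices(intensity_volume(x))$data
  expect_lt(max(abs(out - x)), 1e-6)
})

test_that("histogram matching reproduces the sort-assign map on two slices", {
  x <- array(0, c(2, 2, 2))
  x[1, , ] <- c(0.2, 0.4, 0.6, 0.8)   # reference
  x[2, , ] <- c(0.1, 0.2, 0.3, 0.4)
  out <- histogram_match_slices(intensity_volume(x), reference_slice = 1,
                                n_quantiles = 4)$data
  expect_equal(sort(as.vector(out[2, , ])), c(0.2, 0.4, 0.6, 0.8),
               tolerance = 1e-12)
  # order preserved
  expect_identical(order(out[2, , ]), order(x[2, , ]))
})

test_that("histogram matching equalizes empirical CDFs across slices", {
  set.seed(12)
  nz <- 6
  x <- array(0, c(nz, 104, 104))
  for (k in 1:nz) x[k, , ] <- runif(104^2, 0.1 + 0.05 * k, 0.6 + 0.05 * k)
  out <- histogram_match_slices(intensity_volume(x), reference_slice = 3)$data
  for (k in setdiff(1:nz, 3))
    expect_lt(ks_sup_distance(as.vector(out[k, , ]),
                              as.vector(out[3, , ])), 0.01)
})

test_that("histogram matching rejects degenerate references", {
  x <- rand_vol(6, 13)
  expect_error(histogram_match_slices(intensity_volume(x), 0), "reference")
  expect_error(histogram_match_slices(intensity_volume(x), 7), "reference")
  x[2, , ] <- 0.5
  expect_error(histogram_match_slices(intensity_volume(x), 2), "degenerate")
})

test_that("histogram matching is independent of slice processing order", {
  # each non-reference slice is mapped through the reference only, so
  # permuting slices permutes outputs identically
  x <- rand_vol(6, 14)
  out <- histogram_match_slices(intensity_volume(x), 1)$data
  perm <- c(1, 4, 3, 2, 6, 5)
  xp <- x[perm, , ]
  outp <- histogram_match_slices(intensity_volume(xp), 1)$data
  expect_equal(outp, out[perm, , ], tolerance = 1e-12)
})
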