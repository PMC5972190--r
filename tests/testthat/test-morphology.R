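test_that("structuring elements enumerate the expected offset sets", {
  expect_equal(nrow(oracle_se_offsets("cross", 1)), 7)    # center + 6 faces
  expect_equal(nrow(oracle_se_offsets("cross", 3)), 19)
  expect_equal(nrow(oracle_se_offsets("box", 1)), 27)
  expect_equal(nrow(oracle_se_offsets("cross", 0)), 1)
  expect_error(structuring_element("cross", -1), "non-negative")
})

test_that("cross erosion/dilation via line decomposition is bit-identical to enumeration", {
  for (case in list(list(n = 16, r = 1, seed = 21),
                    list(n = 24, r = 2, seed = 22),
                    list(n = 32, r = 3, seed = 23),
                    list(n = 16, r = 64, seed = 24))) {
    x <- rand_vol(case$n, case$seed)
    se <- structuring_element("cross", case$r)
    offs <- oracle_se_offsets("cross", case$r)
    got_e <- suppressWarnings(erode(x, se))     # r = 64 exceeds small axes
    got_d <- suppressWarnings(dilate(x, se))
    expect_identical(got_e, oracle_morph(x, offs, TRUE, "replicate"),
                     label = sprintf("erode cross r=%d n=%d", case$r, case$n))
    expect_identical(got_d, oracle_morph(x, offs, FALSE, "replicate"),
                     label = sprintf("dilate cross r=%d n=%d", case$r, case$n))
  }
})

test_that("box and ball morphology match direct enumeration", {
  x <- rand_vol(12, 25)
  for (shape in c("box", "ball")) {
    se <- structuring_element(shape, 2)
    offs <- oracle_se_offsets(shape, 2)
    expect_equal(erode(x, se), oracle_morph(x, offs, TRUE, "replicate"))
    expect_equal(dilate(x, se), oracle_morph(x, offs, FALSE, "replicate"))
  }
})

test_that("binary morphology pads with background", {
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  bm <- binary_mask(m)
  se1 <- structuring_element("cross", 1)
  # single interior voxel dilated by cross r=1 -> exactly 7 voxels
  expect_equal(sum(dilate(bm, se1)$data), 7)
  # single voxel eroded by cross r=1 -> empty
  expect_equal(sum(erode(bm, se1)$data), 0)
  # a face-touching solid is eroded from the face side under 0-padding
  full <- binary_mask(array(TRUE, c(5, 5, 5)))
  er <- erode(full, se1)
  expect_false(er$data[1, 3, 3])
  expect_true(er$data[3, 3, 3])
})

test_that("erosion/dilation duality holds for binary inputs", {
  set.seed(26)
  x <- array(runif(14^3) > 0.6, rep(14, 3))
  # keep the complement's border behavior out of scope: compare interiors
  for (shape in c("cross", "box")) {
    se <- structuring_element(shape, 2)
    a <- erode(binary_mask(x), se)$data
    b <- !dilate(binary_mask(!x), se)$data
    core <- 3:12
    expect_identical(a[core, core, core], b[core, core, core])
  }
})

test_that("opening/closing ordering and idempotence", {
  set.seed(27)
  x <- rand_vol(16, 27)
  se <- structuring_element("box", 2)
  op <- opening(x, se); cl <- closing(x, se)
  expect_true(all(op <= x + 1e-12))
  expect_true(all(cl >= x - 1e-12))
  expect_equal(opening(op, se), op, tolerance = 1e-12)
  expect_equal(closing(cl, se), cl, tolerance = 1e-12)

  # closing of random binary masks is idempotent too
  m <- array(runif(20^3) > 0.7, rep(20, 3))
  c1 <- closing(binary_mask(m), se)
  expect_identical(closing(c1, se)$data, c1$data)

  # opening of a solid box by a box SE that fits returns it unchanged
  solid <- array(FALSE, c(12, 12, 12))
  solid[4:8, 4:8, 4:8] <- TRUE
  expect_identical(opening(binary_mask(solid),
                           structuring_element("box", 2))$data, solid)
})

test_that("white top-hat extracts narrow bright structures", {
  expect_equal(white_tophat(array(0.4, c(8, 8, 8)),
                            structuring_element("cross", 2)),
               array(0, c(8, 8, 8)))
  x <- array(0.1, c(9, 9, 9))
  x[5, 5, 5] <- 0.8
  th <- white_tophat(x, structuring_element("cross", 3))
  expect_equal(th[5, 5, 5], 0.7)
  expect_true(all(th >= 0))
  # a single bright voxel cannot host a radius-64 cross either
  th64 <- suppressWarnings(white_tophat(x, structuring_element("cross", 64)))
  expect_equal(th64[5, 5, 5], 0.7)
  # tophat of an opening is zero
  set.seed(28)
  y <- rand_vol(12, 28)
  se <- structuring_element("box", 1)
  expect_equal(white_tophat(opening(y, se), se), array(0, dim(y)),
               tolerance = 1e-12)
})

test_that("a bright slab wider than the cross arms is suppressed", {
  # slab thick in every axis direction of the cross: opening reproduces it
  x <- array(0.05, c(20, 20, 20))
  x[3:18, 3:18, 3:18] <- 0.6
  th <- white_tophat(x, structuring_element("cross", 5))
  expect_lt(max(th[9:12, 9:12, 9:12]), 1e-12)
})

test_that("binarize thresholds with ties as foreground", {
  v <- intensity_volume(array(c(0.034, 0.035, 0.036, rep(0, 5)), c(2, 2, 2)))
  m <- binarize(v, 0.035)
  expect_identical(as.vector(m$data)[1:3], c(FALSE, TRUE, TRUE))
  expect_equal(sum(binarize(intensity_volume(array(0, c(3, 3, 3))),
                            0.035)$data), 0)
  expect_error(binarize(v, 0), "strictly")
  expect_error(binarize(v, 1), "strictly")
  # foreground count is non-increasing in the threshold
  set.seed(29)
  x <- intensity_volume(array(runif(10^3), rep(10, 3)))
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                   function(t) sum(binarize(x, t)$data), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("connected components respect the connectivity model", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE    # diagonal touch
  expect_equal(length(connected_components(m, 26)$sizes), 1)
  expect_equal(length(connected_components(m, 6)$sizes), 2)
  expect_equal(length(connected_components(array(FALSE, c(3, 3, 3)))$sizes),
               0)
  set.seed(30)
  r <- array(runif(15^3) > 0.5, rep(15, 3))
  cc <- connected_components(r, 26)
  expect_equal(sum(cc$sizes), sum(r))
  expect_equal(sort(unique(as.vector(cc$labels))),
               0:length(cc$sizes))
})

test_that("geodesic opening keeps whole surviving components only", {
  m <- array(FALSE, c(60, 60, 60))
  m[5:39, 5:39, 5:39] <- TRUE       # 35^3: contains a 31^3 box
  m[50:54, 50:54, 50:54] <- TRUE    # 5^3: cannot survive size-15 erosion
  out <- geodesic_opening(binary_mask(m), 15)$data
  expect_identical(out[5:39, 5:39, 5:39], m[5:39, 5:39, 5:39])
  expect_equal(sum(out[50:54, 50:54, 50:54]), 0)
  expect_equal(sum(out), 35^3)
  # output is a union of original components, and a subset of the input
  expect_true(all(out <= m))
  # empty in, empty out
  expect_equal(sum(geodesic_opening(binary_mask(array(FALSE, c(8, 8, 8))),
                                    3)$data), 0)
})

test_that("geodesic opening is idempotent on random blob masks", {
  for (seed in 31:40) {
    m <- binary_mask(random_blob_mask(28, 6, c(1.5, 6), seed))
    g1 <- geodesic_opening(m, 3)
    g2 <- geodesic_opening(g1, 3)
    expect_identical(g2$data, g1$data)
    expect_true(all(g1$data <= m$data))
  }
})

test_that("apply_mask multiplies exactly and validates shapes", {
  set.seed(41)
  x <- rand_vol(8, 41)
  m <- array(runif(8^3) > 0.5, rep(8, 3))
  out <- apply_mask(intensity_volume(x), binary_mask(m))
  expect_identical(out$data, x * m)
  expect_identical(apply_mask(x, array(TRUE, dim(x))), x)
  expect_identical(apply_mask(x, array(FALSE, dim(x))), x * 0)
  expect_error(apply_mask(x, array(TRUE, c(4, 4, 4))), "dimension")
})

test_that("line min/max runtime is radius-independent (van Herk contract)", {
  x <- rand_vol(132, 42)   # both windows (17 and 129 voxels) fit the axes
  se8 <- structuring_element("cross", 8)
  se64 <- structuring_element("cross", 64)
  t8 <- vapply(1:3, function(i) system.time(erode(x, se8))[["elapsed"]],
               numeric(1))
  t64 <- vapply(1:3, function(i) system.time(erode(x, se64))[["elapsed"]],
                numeric(1))
  expect_lt(median(t64), 2 * median(t8) + 0.05)
})

test_that("an oversized structuring element warns and degenerates", {
  x <- rand_vol(6, 43)
  expect_warning(er <- erode(x, structuring_element("box", 6)), "exceeds")
  expect_equal(max(er) - min(er), 0)
  expect_equal(min(er), min(x))
})
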