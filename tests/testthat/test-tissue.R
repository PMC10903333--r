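test_that("a bright cuboid on dark background is segmented exactly", {
  vol <- array(0, c(8, 20, 20))
  vol[3:6, 5:14, 6:15] <- 100
  m <- segment_tissue(vol, threshold = 50, closing_um = 4,
                      voxel_size = c(2, 1, 1))
  want <- array(FALSE, c(8, 20, 20))
  want[3:6, 5:14, 6:15] <- TRUE
  expect_identical(m$mask, want)
})

test_that("only the largest connected component is kept", {
  vol <- array(0, c(12, 20, 20))
  vol[2:11, 2:11, 2:11] <- 100 # 1000 voxels
  vol[2:4, 15:17, 15:17] <- 100 # 27 voxels
  m <- segment_tissue(vol, threshold = 50, closing_um = 0,
                      voxel_size = c(1, 1, 1))
  expect_equal(sum(m$mask), 1000)
  expect_false(any(m$mask[, 15:17, 15:17]))
})

test_that("slice-wise hole filling closes interior holes only", {
  vol <- array(0, c(3, 15, 15))
  vol[, 3:12, 3:12] <- 100
  vol[2, 7:8, 7:8] <- 0 # interior dark hole in one slice
  m <- segment_tissue(vol, threshold = 50, closing_um = 0,
                      voxel_size = c(5, 2, 2))
  expect_true(all(m$mask[2, 7:8, 7:8]))
})

test_that("empty foreground raises an actionable error", {
  vol <- array(1, c(4, 5, 5))
  vol[1] <- 2
  expect_error(segment_tissue(vol, threshold = 3), "outside the channel")
})

test_that("cube measurements match analytic values and voxel scaling", {
  mask <- array(FALSE, c(14, 14, 14))
  mask[3:12, 3:12, 3:12] <- TRUE
  m1 <- measure_tissue(mask, voxel_size = c(1, 1, 1))
  expect_equal(m1$volume_um3, 1000)
  expect_equal(m1$area_um2, 600)
  expect_equal(m1$radius_um, sqrt(3) * 9 / 2, tolerance = 1e-9)
  m2 <- measure_tissue(mask, voxel_size = c(2, 1, 1))
  expect_equal(m2$volume_um3, 2000)
  expect_error(measure_tissue(array(FALSE, c(2, 2, 2))), "empty mask")
})

test_that("a digital sphere's volume is within 5% of the analytic value", {
  r <- 20
  n <- c(23, 45, 45)
  vs <- c(2, 1, 1)
  zc <- voxel_centers(n[1], vs[1]) - 23
  yc <- voxel_centers(n[2], vs[2]) - 22.5
  xc <- voxel_centers(n[3], vs[3]) - 22.5
  D <- sqrt(outer(outer(zc^2, yc^2, `+`), xc^2, `+`))
  mask <- D <= r
  m <- measure_tissue(mask, voxel_size = vs)
  expect_lt(abs(m$volume_um3 - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.05)
})

test_that("volume is invariant under axis permutation with matching voxel sizes", {
  set.seed(4)
  mask <- array(runif(6 * 8 * 10) > 0.6, c(6, 8, 10))
  if (!any(mask)) mask[1] <- TRUE
  v1 <- measure_tissue(mask, voxel_size = c(3, 2, 1))$volume_um3
  v2 <- measure_tissue(aperm(mask, c(3, 1, 2)), voxel_size = c(1, 3, 2))$volume_um3
  expect_equal(v1, v2)
})

test_that("relative change maps the baseline to zero", {
  expect_equal(relative_change(c(100, 50)), c(0, -0.5))
  expect_equal(relative_change(rep(7, 5)), rep(0, 5))
  expect_error(relative_change(numeric(0)), "empty")
  expect_error(relative_change(c(0, 1)), "baseline")
})
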