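gaussian_blob_volume <- function(centers_um, dims, vs, sigma = 3) {
  zc <- voxel_centers(dims[1], vs[1])
  yc <- voxel_centers(dims[2], vs[2])
  xc <- voxel_centers(dims[3], vs[3])
  vol <- array(0, dims)
  for (i in seq_len(nrow(centers_um))) {
    D2 <- outer(outer((zc - centers_um[i, 3])^2, (yc - centers_um[i, 2])^2, `+`),
                (xc - centers_um[i, 1])^2, `+`)
    vol <- vol + exp(-D2 / (2 * sigma^2))
  }
  vol
}

test_that("a blank image yields no spots", {
  sp <- detect_nuclei(array(0, c(6, 20, 20)), voxel_size = c(5, 2, 2))
  expect_equal(nrow(sp), 0L)
})

test_that("two well-separated blobs are found within a voxel of truth", {
  dims <- c(10, 40, 40)
  vs <- c(5, 2, 2)
  ctr <- rbind(c(20, 40, 25), c(60, 40, 25)) # (x, y, z) um, 40 um apart
  vol <- 100 * gaussian_blob_volume(ctr, dims, vs)
  sp <- detect_nuclei(vol, voxel_size = vs, diameter_range_um = c(6, 12))
  expect_equal(nrow(sp), 2L)
  sp <- sp[order(sp$x_um), ]
  for (i in 1:2) {
    expect_lt(abs(sp$x_um[i] - ctr[i, 1]), vs[3])
    expect_lt(abs(sp$y_um[i] - ctr[i, 2]), vs[2])
    expect_lt(abs(sp$z_um[i] - ctr[i, 3]), vs[1])
  }
})

test_that("blobs closer than the minimum separation are suppressed to one", {
  dims <- c(10, 40, 40)
  vs <- c(5, 2, 2)
  ctr <- rbind(c(38, 40, 25), c(41, 40, 25)) # 3 um apart < 0.7 * 6
  vol <- 100 * gaussian_blob_volume(ctr, dims, vs)
  sp <- detect_nuclei(vol, voxel_size = vs, diameter_range_um = c(6, 12))
  expect_equal(nrow(sp), 1L)
})

test_that("watershed splits two compartments at the bright plane", {
  dims <- c(6, 20, 40)
  vs <- c(5, 2, 2)
  mem <- array(0, dims)
  mem[, , 20:21] <- 100 # bright wall normal to x
  mask <- array(TRUE, dims)
  seeds <- data.frame(x_um = c(20, 60), y_um = c(20, 20), z_um = c(15, 15))
  lab <- segment_cells(mem, seeds, mask, voxel_size = vs, merge_um = 10,
                       sigma_um = 2)
  expect_equal(sort(unique(as.integer(lab))), c(1L, 2L))
  ## every mask voxel assigned (partition), boundary within one voxel of wall
  expect_true(all(lab > 0))
  x1 <- max(which(apply(lab == 1L, 3, any)))
  x2 <- min(which(apply(lab == 2L, 3, any)))
  expect_gte(x1 + 1L, x2 - 1L) # labels meet
  expect_true(x1 >= 19 && x1 <= 22)
  expect_true(x2 >= 19 && x2 <= 22)
})

test_that("a single seed floods the whole mask; close seeds merge", {
  dims <- c(4, 10, 10)
  mask <- array(TRUE, dims)
  mem <- array(0, dims)
  lab1 <- segment_cells(mem, data.frame(x_um = 5, y_um = 5, z_um = 5),
                        mask, voxel_size = c(2, 2, 2))
  expect_true(all(lab1 == 1L))
  lab2 <- segment_cells(mem, data.frame(x_um = c(5, 10), y_um = c(5, 5),
                                        z_um = c(5, 5)),
                        mask, voxel_size = c(2, 2, 2), merge_um = 14.4)
  expect_equal(max(lab2), 1L) # two seeds 5 um apart under a 14.4 um merge
  expect_error(segment_cells(mem, data.frame(x_um = 1, y_um = 1, z_um = 1),
                             array(FALSE, dims), voxel_size = c(2, 2, 2),
                             snap_um = 0),
               "no seeds fall inside")
})

test_that("size filter honors the strict 'less than' semantics", {
  dims <- c(30, 40, 40)
  lab <- array(0L, dims)
  lab[1:10, 1:40, 1:25] <- 1L # 10000 voxels
  lab[15:24, 1:40, 26:50 - 25] <- 2L
  lab[24, 40, 1] <- 0L # object 2: 9999 voxels
  expect_equal(sum(lab == 1L), 10000)
  expect_equal(sum(lab == 2L), 9999)
  f <- size_filter(lab)
  expect_equal(sum(f == 1L), 10000) # exactly 10,000 voxels retained
  expect_equal(sum(f == 2L), 0) # 9,999 voxels removed
  expect_identical(size_filter(f), f) # idempotent
  expect_identical(size_filter(lab, min_voxels = 0), lab)
  ## physical-unit cutoff converts through the voxel volume
  expect_equal(sum(size_filter(lab, min_um3 = 10000 * 8,
                               voxel_size = c(2, 2, 2)) == 2L), 0)
})

test_that("relabeling makes the label set contiguous", {
  lab <- array(c(0L, 5L, 9L, 5L), c(1, 2, 2))
  out <- relabel_sequential(lab)
  expect_equal(sort(unique(as.integer(out))), 0:2)
  expect_equal(sum(out > 0), 3)
})

test_that("cell measurements are exact for cubes and symmetric objects", {
  lab <- array(0L, c(14, 14, 14))
  lab[3:12, 3:12, 3:12] <- 1L
  tab <- measure_cells(lab, voxel_size = c(1, 1, 1))
  expect_equal(tab$volume_um3, 1000)
  expect_equal(tab$area_um2, 600)
  expect_equal(c(tab$z_um, tab$y_um, tab$x_um), rep(7, 3))
  expect_equal(tab$voxels, 1000L)
  expect_equal(tab$volume_um3, tab$voxels * 1) # volume = count x voxel volume

  ## centroid of a centrally symmetric object is its center of symmetry
  lab2 <- array(0L, c(9, 9, 9))
  ctr <- c(5, 5, 5)
  for (off in list(c(2, 0, 0), c(0, 3, 1), c(1, 1, 2))) {
    lab2[ctr[1] + off[1], ctr[2] + off[2], ctr[3] + off[3]] <- 1L
    lab2[ctr[1] - off[1], ctr[2] - off[2], ctr[3] - off[3]] <- 1L
  }
  t2 <- measure_cells(lab2, voxel_size = c(1, 1, 1))
  expect_equal(c(t2$z_um, t2$y_um, t2$x_um), ctr - 0.5)
})

test_that("a digital sphere's measured cell volume is within 5% of analytic", {
  r <- 12
  vs <- c(3, 1.5, 1.5)
  n <- c(11, 21, 21)
  zc <- voxel_centers(n[1], vs[1]) - 16.5
  yc <- voxel_centers(n[2], vs[2]) - 15.75
  xc <- voxel_centers(n[3], vs[3]) - 15.75
  D <- sqrt(outer(outer(zc^2, yc^2, `+`), xc^2, `+`))
  lab <- array(as.integer(D <= r), dim = n)
  tab <- measure_cells(lab, voxel_size = vs)
  expect_lt(abs(tab$volume_um3 - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.05)
})

test_that("watershed output partitions the mask with merged-seed label count", {
  set.seed(8)
  dims <- c(8, 24, 24)
  vs <- c(5, 2, 2)
  mem <- array(runif(prod(dims)), dims)
  mask <- array(TRUE, dims)
  mask[, 1:2, ] <- FALSE
  seeds <- data.frame(x_um = runif(12, 5, 43), y_um = runif(12, 10, 43),
                      z_um = runif(12, 5, 35))
  lab <- segment_cells(mem, seeds, mask, voxel_size = vs, merge_um = 8)
  expect_true(all(lab[mask] > 0)) # no unassigned foreground
  expect_true(all(lab[!mask] == 0))
  grp <- cluster_points(as.matrix(seeds), 8)
  expect_equal(length(unique(as.integer(lab[lab > 0]))), length(unique(grp)))
})
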