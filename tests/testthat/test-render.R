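## minimal single-cell scene rendered without strain
single_cell_scene <- function(cfg, noise = TRUE, psf = c(0, 0, 0)) {
  geo <- structure(list(
    cells = data.frame(cell_id = 1L, x_um = 64, y_um = 64, z_um = 60,
                       radius_um = 12, n_nuclei = 1L),
    nuclei = data.frame(nucleus_id = 1L, cell_id = 1L, x_um = 64, y_um = 64,
                        z_um = 60),
    domain = tissue_domain(cfg), achieved_packing = 0.01, config = cfg),
    class = "tissue_geometry")
  ft <- c(0, 15)
  ones <- matrix(1, 2, 1)
  pos <- list(x = matrix(64, 2, 1), y = matrix(64, 2, 1), z = matrix(60, 2, 1))
  render_stack(geo, cfg, ones, pos, pos, warp = NULL, frame_times = ft,
               psf_sigma_um = psf, noise = noise)
}

test_that("the membrane channel peaks on the shell without noise", {
  cfg <- tiny_config(read_noise_sd = 0)
  r <- single_cell_scene(cfg, noise = FALSE)
  mem <- stack_volume(r$stack, 1, "membrane")
  idx <- arrayInd(which.max(mem), dim(mem))
  p <- c((idx[1] - 0.5) * cfg$dz, (idx[2] - 0.5) * cfg$dy, (idx[3] - 0.5) * cfg$dx)
  d <- sqrt((p[1] - 60)^2 + (p[2] - 64)^2 + (p[3] - 64)^2)
  expect_lt(abs(d - 12), 1 + 1e-9) # on the shell (half-thickness + rounding)
  ## cytoplasm interior is brightest at the configured photon scale
  cyto <- stack_volume(r$stack, 1, "cytoplasm")
  expect_equal(max(cyto), cfg$photon_scale)
  expect_true(all(r$stack$data >= 0))
})

test_that("rendering is bit-identical for a fixed seed", {
  cfg <- tiny_config(seed = 9)
  a <- single_cell_scene(cfg)
  b <- single_cell_scene(cfg)
  expect_identical(a$stack$data, b$stack$data)
  cfg2 <- tiny_config(seed = 10)
  c2 <- single_cell_scene(cfg2)
  expect_false(identical(a$stack$data, c2$stack$data))
})

test_that("shot noise variance matches the Poisson model in bright voxels", {
  ## tiny scene re-rendered many times; per-voxel variance tracks the mean
  cfg <- sim_config(nz = 4L, ny = 12L, nx = 12L, dz = 10, dy = 4, dx = 4,
                    slab_um = 40, read_noise_sd = 0, photon_scale = 30,
                    seed = 1L)
  geo <- structure(list(
    cells = data.frame(cell_id = 1L, x_um = 24, y_um = 24, z_um = 20,
                       radius_um = 10, n_nuclei = 1L),
    nuclei = data.frame(nucleus_id = 1L, cell_id = 1L, x_um = 24, y_um = 24,
                        z_um = 20),
    domain = tissue_domain(cfg), achieved_packing = 0.1, config = cfg),
    class = "tissue_geometry")
  ones <- matrix(1, 1, 1)
  pos <- list(x = matrix(24, 1, 1), y = matrix(24, 1, 1), z = matrix(20, 1, 1))
  reps <- 500
  acc <- matrix(0, reps, 4 * 12 * 12)
  for (i in seq_len(reps)) {
    cfg$seed <- i
    r <- render_stack(geo, cfg, ones, pos, pos, warp = NULL, frame_times = 0,
                      psf_sigma_um = c(0, 0, 0), noise = TRUE)
    acc[i, ] <- as.numeric(r$stack$data[1, 2, , , ])
  }
  mu <- colMeans(acc)
  vv <- apply(acc, 2, var)
  bright <- mu > 0.5 * cfg$photon_scale
  expect_gt(sum(bright), 10)
  ## pooled variance-to-mean ratio of Poisson counts is 1
  expect_lt(abs(sum(vv[bright]) / sum(mu[bright]) - 1), 0.1)
})

test_that("cells scaled beyond the grid are counted as clipped", {
  cfg <- tiny_config()
  geo <- structure(list(
    cells = data.frame(cell_id = 1L, x_um = 5, y_um = 64, z_um = 60,
                       radius_um = 12, n_nuclei = 1L),
    nuclei = data.frame(nucleus_id = 1L, cell_id = 1L, x_um = 5, y_um = 64,
                        z_um = 60),
    domain = tissue_domain(cfg), achieved_packing = 0.01, config = cfg),
    class = "tissue_geometry")
  pos <- list(x = matrix(5, 1, 1), y = matrix(64, 1, 1), z = matrix(60, 1, 1))
  r <- render_stack(geo, cfg, matrix(1, 1, 1), pos, pos, warp = NULL,
                    frame_times = 0, noise = FALSE)
  expect_gte(r$clipped_cells, 1L)
})
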