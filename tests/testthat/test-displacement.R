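## build a vfield with a prescribed lambda(z) profile, uniform laterally
make_vfield <- function(lambda_of_z, cfg = tiny_config()) {
  grid <- field_grid(cfg)
  dims <- grid$dims
  lam <- lambda_of_z(grid$z)
  v <- array(rep(lam^3, prod(dims[2:3])), dims)
  structure(list(times = c(0, 15), grid = grid,
                 v = array(rep(v, each = 2), c(2, dims))),
            class = "vfield")
}

test_that("no osmotic change means zero displacement", {
  vf <- make_vfield(function(z) rep(1, length(z)))
  pts <- data.frame(x_um = c(30, 64), y_um = c(40, 64), z_um = c(10, 100))
  d <- compute_nuclear_displacement(vf, pts)
  expect_equal(d$z[2, ], pts$z_um, tolerance = 1e-9)
  expect_equal(d$x[2, ], pts$x_um, tolerance = 1e-9)
  expect_equal(d$y[2, ], pts$y_um, tolerance = 1e-9)
})

test_that("uniform swelling moves a nucleus in proportion to its height", {
  vf <- make_vfield(function(z) rep(1.1, length(z)))
  pts <- data.frame(x_um = 64, y_um = 64, z_um = 100)
  d <- compute_nuclear_displacement(vf, pts)
  expect_equal(d$z[2, 1], 110, tolerance = 1e-6)
  ## axial displacement increases with initial height under uniform swelling
  pts2 <- data.frame(x_um = rep(64, 3), y_um = rep(64, 3), z_um = c(20, 60, 100))
  d2 <- compute_nuclear_displacement(vf, pts2)
  expect_true(all(diff(d2$z[2, ] - pts2$z_um) > 0))
})

test_that("depth-varying strain matches a fine trapezoid quadrature", {
  cfg <- tiny_config()
  L <- cfg$slab_um
  lam_fun <- function(z) 1 + 0.1 * z / L
  vf <- make_vfield(lam_fun, cfg)
  z0 <- c(15, 55, 95, 115)
  pts <- data.frame(x_um = rep(64, 4), y_um = rep(64, 4), z_um = z0)
  d <- compute_nuclear_displacement(vf, pts)
  ## oracle: trapezoid rule at 10x the field grid resolution over the
  ## piecewise-linear lambda profile the solver actually sees
  grid_z <- vf$grid$z
  lam_grid <- lam_fun(grid_z)
  interp_lambda <- function(z) approx(c(0, grid_z, L),
                                      c(lam_grid[1], lam_grid, lam_grid[length(lam_grid)]),
                                      xout = z, rule = 2)$y
  oracle <- vapply(z0, function(z) {
    zz <- seq(0, z, length.out = 10 * length(grid_z))
    sum(diff(zz) * (interp_lambda(zz)[-1] + interp_lambda(zz)[-length(zz)]) / 2)
  }, numeric(1))
  expect_lt(max(abs(d$z[2, ] - oracle)), 0.5)
})

test_that("points outside the slab are rejected", {
  vf <- make_vfield(function(z) rep(1, length(z)))
  expect_error(compute_nuclear_displacement(
    vf, data.frame(x_um = 64, y_um = 64, z_um = 200)), "inside the slab")
  expect_error(compute_nuclear_displacement(
    vf, data.frame(x_um = 300, y_um = 64, z_um = 50)), "lateral")
})

test_that("tissue warp volume tracks uniform volume change exactly", {
  vf <- make_vfield(function(z) rep(0.9^(1 / 3), length(z)))
  w <- tissue_warp(vf)
  dom <- vf$grid$domain
  expect_equal(w$volume_um3[2] / (dom$Lx * dom$Ly * dom$slab_um), 0.9,
               tolerance = 1e-6)
  expect_true(all(abs(w$s_lat[2, , ] - 0.9^(1 / 3)) < 1e-9))
})
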