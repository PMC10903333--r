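test_that("an unchanged bath leaves the field constant in space and time", {
  cfg <- tiny_config()
  p <- solution_protocol(M0 = 300, Me = 300, duration = 120)
  f <- simulate_osmolality_field(p, field_grid(cfg), D_eff = 1000)
  expect_true(all(abs(f$Me - 300) < 1e-9))
  expect_true(all(abs(f$Se) < 1e-9))
})

test_that("the field converges to the bath value at long times", {
  cfg <- tiny_config()
  L <- cfg$slab_um
  D <- 1000
  tlong <- 50 * L^2 / D
  p <- solution_protocol(M0 = 300, Me = c(300, 80), switch_times = 0,
                         duration = tlong, frame_interval = tlong / 4)
  f <- simulate_osmolality_field(p, field_grid(cfg), D, dt = tlong / 500)
  final <- f$Me[length(f$times), , , ]
  expect_lt(max(abs(final - 80) / 80), 0.01)
})

test_that("1-D penetration matches the analytic slab series within 2%", {
  cfg <- sim_config(nz = 60L, ny = 2L, nx = 2L, dz = 5, dy = 5, dx = 5,
                    slab_um = 300)
  L <- 300
  D <- 1000
  tq <- L^2 / (4 * D)
  p <- solution_protocol(M0 = 300, Me = c(300, 80), switch_times = 0,
                         duration = tq, frame_interval = tq)
  grid <- field_grid(cfg, lateral_um = 5, nz = 60L)
  f <- simulate_osmolality_field(p, grid, D, dt = 0.02, lateral_bc = "neumann",
                                 times = c(0, tq))
  num <- f$Me[2, , 1, 1]
  ## solver's Dirichlet face is the top (z = L); series has it at x = L
  exact <- slab_series_solution(grid$z, tq, L, D, u0 = 300, ub = 80)
  expect_lt(max(abs(num - exact) / exact), 0.02)
})

test_that("the discrete maximum principle holds for random protocols", {
  cfg <- tiny_config()
  set.seed(11)
  for (rep in 1:5) {
    M0 <- runif(1, 200, 400)
    Me <- c(M0, runif(2, 50, 1500))
    st <- sort(runif(2, 10, 100))
    p <- solution_protocol(M0 = M0, Me = Me, switch_times = st,
                           duration = 120, frame_interval = 10)
    f <- simulate_osmolality_field(p, field_grid(cfg), D_eff = 500, dt = 2)
    lo <- min(M0, Me)
    hi <- max(M0, Me)
    expect_true(all(f$Me >= lo - 1e-8 & f$Me <= hi + 1e-8))
  }
})

test_that("field interpolation at points is exact for linear fields", {
  cfg <- tiny_config()
  grid <- field_grid(cfg)
  dims <- grid$dims
  ## build a field linear in z on the grid; trilinear interp must reproduce it
  fz <- array(rep(grid$z, prod(dims[2:3])), dims)
  fld <- list(times = c(0, 1), grid = grid,
              Me = array(rep(fz, each = 2), c(2, dims)))
  pts <- data.frame(x_um = c(30, 70), y_um = c(40, 90),
                    z_um = c(20, 77))
  got <- field_at_points(fld, pts, "Me")
  expect_equal(as.numeric(got[1, ]), pts$z_um, tolerance = 1e-9)
})

test_that("an invalid step size is rejected with a clear message", {
  cfg <- tiny_config()
  p <- solution_protocol(duration = 60)
  expect_error(simulate_osmolality_field(p, field_grid(cfg), 1000, dt = 0),
               "dt must be > 0")
})
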