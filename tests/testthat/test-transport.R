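test_that("Boyle-van't Hoff equilibrium is recovered without solute or regulation", {
  p <- transport_params(k_w = 0.02, k_s = 0, b = 0, k_r = 0, k_rvi = 0)
  tr <- simulate_cell_volume(p, Me = 600, M0 = 300, times = seq(0, 5000, 100),
                             dt = 0.25)
  expect_equal(tail(tr$v[, 1], 1), 0.5, tolerance = 1e-6)

  ## closed form across a grid of osmolalities and inactive fractions
  for (b in c(0, 0.3, 0.6)) {
    for (Me in c(150, 450, 900)) {
      pb <- transport_params(k_w = 0.02, k_s = 0, b = b, k_r = 0, k_rvi = 0)
      trb <- simulate_cell_volume(pb, Me = Me, M0 = 300,
                                  times = seq(0, 8000, 200), dt = 0.25)
      expect_equal(tail(trb$v[, 1], 1), boyle_vant_hoff(Me, 300, b),
                   tolerance = 1e-6)
    }
  }
})

test_that("isosmotic input leaves the volume identically at baseline", {
  tr <- simulate_cell_volume(transport_params(), Me = 300, M0 = 300,
                             times = seq(0, 480, 15))
  expect_true(all(tr$v == 1))
  expect_true(all(tr$n == 1))
})

test_that("a permeating-solute step produces shrink-swell matching a stiff-ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- transport_params(k_w = 0.02, k_s = 0.004, b = 0.3, k_r = 0, k_rvi = 0)
  M0 <- 300
  times <- seq(0, 2000, 5)
  tr <- simulate_cell_volume(p, Me = M0, Se = 1000, M0 = M0, times = times,
                             dt = 0.5)
  v <- tr$v[, 1]
  expect_lt(min(v), 1)
  expect_gt(tail(v, 1), min(v))
  expect_lt(abs(tail(v, 1) - 1), 0.1)

  oracle <- deSolve::lsoda(
    y = c(w = 1, n = 1, s = 0), times = times,
    func = function(t, y, parms) {
      Mi <- M0 * (y["n"] + y["s"]) / y["w"]
      list(c(p$k_w * (Mi - M0 - 1000) / M0,
             -p$k_r * (p$b + (1 - p$b) * y["w"] - 1),
             p$k_s * (1000 - M0 * y["s"] / y["w"]) / M0))
    }, rtol = 1e-10, atol = 1e-12)
  v_o <- p$b + (1 - p$b) * oracle[, "w"]
  expect_lt(abs(min(v) - min(v_o)) / min(v_o), 0.01)
  expect_lt(abs(times[which.min(v)] - times[which.min(v_o)]) /
              max(times[which.min(v_o)], 1), 0.01)
  expect_lt(max(abs(v - v_o)), 0.005)
})

test_that("larger osmotic challenges give larger equilibrium excursions", {
  Mes <- c(150, 200, 250, 350, 450, 600)
  dev <- vapply(Mes, function(Me) {
    p <- transport_params(k_w = 0.02, k_s = 0, b = 0.3, k_r = 0, k_rvi = 0)
    tr <- simulate_cell_volume(p, Me = Me, M0 = 300, times = seq(0, 6000, 200),
                               dt = 0.5)
    abs(tail(tr$v[, 1], 1) - 1)
  }, numeric(1))
  expect_true(all(diff(dev[1:3]) < 0)) # approaching isosmotic from below
  expect_true(all(diff(dev[4:6]) > 0)) # moving away above
})

test_that("shrink-swell non-monotonicity holds whenever solute lags water", {
  set.seed(5)
  for (rep in 1:5) {
    kw <- runif(1, 0.005, 0.03)
    ks <- kw * runif(1, 0.05, 0.8)
    Se <- runif(1, 300, 1500)
    p <- transport_params(k_w = kw, k_s = ks, b = 0.3, k_r = 0, k_rvi = 0)
    tr <- simulate_cell_volume(p, Me = 300, Se = Se, M0 = 300,
                               times = seq(0, 3000, 10))
    v <- tr$v[, 1]
    expect_lt(min(v), 1)
    expect_gt(tail(v, 1), min(v))
  }
})

test_that("volume trajectories stay above the osmotically inactive fraction", {
  p <- transport_params(k_w = 0.02, k_s = 0.004, b = 0.3, k_r = 0.001)
  tr <- simulate_cell_volume(p, Me = 1215, M0 = 300, times = seq(0, 2000, 10))
  expect_true(all(tr$v > p$b))
})

test_that("matrix forcings reproduce per-cell scalar runs", {
  p <- transport_params(k_w = 0.01, k_s = 0.002, b = 0.3, k_r = 0.001)
  ft <- seq(0, 300, 10)
  Me <- cbind(rep(80, length(ft)), rep(1215, length(ft)))
  tr <- simulate_cell_volume(p, Me, Se = 0 * Me, M0 = 300,
                             times = seq(0, 300, 15), forcing_times = ft)
  tr1 <- simulate_cell_volume(p, Me = 80, M0 = 300, times = seq(0, 300, 15))
  tr2 <- simulate_cell_volume(p, Me = 1215, M0 = 300, times = seq(0, 300, 15))
  expect_equal(tr$v[, 1], tr1$v[, 1], tolerance = 1e-10)
  expect_equal(tr$v[, 2], tr2$v[, 1], tolerance = 1e-10)
})
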