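mkframe <- function(x, y, z) data.frame(x_um = x, y_um = y, z_um = z)

test_that("stationary spots link to themselves with zero displacement", {
  f <- mkframe(c(10, 30, 50), c(10, 10, 10), c(5, 5, 5))
  tr <- link_tracks(list(f, f, f), gate_um = 15, frame_interval = 15)
  expect_equal(length(unique(tr$track_id)), 3L)
  expect_true(all(table(tr$track_id) == 3))
  per <- displacement_summary(tr)$per_track
  expect_true(all(per$net_um == 0))
  expect_true(all(per$path_um == 0))
})

test_that("gated assignment equals exhaustive enumeration on random instances", {
  set.seed(12)
  for (rep in 1:60) {
    n1 <- sample(1:6, 1)
    n2 <- sample(1:6, 1)
    P <- cbind(runif(n1, 0, 60), runif(n1, 0, 60), runif(n1, 0, 30))
    Q <- cbind(runif(n2, 0, 60), runif(n2, 0, 60), runif(n2, 0, 30))
    gate <- runif(1, 10, 40)
    got <- match_points(P, Q, gate)
    want <- brute_force_match(P, Q, gate)
    expect_equal(nrow(got), nrow(want))
    cost <- function(m) sum((P[m[, 1], , drop = FALSE] - Q[m[, 2], , drop = FALSE])^2)
    expect_equal(cost(got), cost(want), tolerance = 1e-9)
  }
})

test_that("drifting spots below half-gate link perfectly", {
  set.seed(3)
  base <- cbind(runif(6, 10, 50), runif(6, 10, 50), runif(6, 5, 25))
  frames <- lapply(0:3, function(k) {
    p <- base + k * 2 + matrix(rnorm(18, 0, 0.3), ncol = 3)
    mkframe(p[, 1], p[, 2], p[, 3])
  })
  tr <- link_tracks(frames, gate_um = 20)
  expect_equal(length(unique(tr$track_id)), 6L)
  expect_true(all(table(tr$track_id) == 4))
})

test_that("a vanishing spot's track simply ends", {
  f1 <- mkframe(c(10, 40), c(10, 10), c(5, 5))
  f2 <- mkframe(10, 10, 5)
  f3 <- mkframe(10, 10, 5)
  tr <- link_tracks(list(f1, f2, f3), gate_um = 10)
  lens <- table(tr$track_id)
  expect_equal(sort(as.integer(lens)), c(1L, 3L))
})

test_that("kinematics are exact for linear and quadratic motion", {
  t <- seq(0, 60, 15)
  tr <- data.frame(track_id = 1L, frame_index = seq_along(t), time_s = t,
                   x_um = 2 * t, y_um = 0, z_um = 0,
                   volume_um3 = NA_real_, detection = seq_along(t))
  k <- compute_kinematics(tr, 15)
  expect_equal(k$vx_um_s, rep(2, 5))
  expect_equal(k$speed_um_s, rep(2, 5))
  expect_equal(k$accel_um_s2[2:4], rep(0, 3))

  tr$x_um <- t^2
  k2 <- compute_kinematics(tr, 15)
  expect_equal(k2$accel_um_s2[2:4], rep(2, 3)) # exact for second differences

  tr$x_um <- rep(5, 5)
  k3 <- compute_kinematics(tr, 15)
  expect_true(all(k3$speed_um_s == 0))
  expect_true(all(k3$accel_um_s2[2:4] == 0))
})

test_that("periphery/core stratification follows the edge distance", {
  mask <- array(TRUE, c(10, 50, 50)) # 500x500x100 um at 10x10x10 um voxels
  vs <- c(10, 10, 10)
  pos <- data.frame(x_um = c(5, 250, 250), y_um = c(250, 250, 250),
                    z_um = c(50, 50, 95))
  r <- stratify_periphery_core(pos, mask, cutoff_um = 50, voxel_size = vs)
  expect_equal(as.character(r), c("periphery", "core", "periphery"))
  ## cutoff beyond the half-width makes everything periphery
  r2 <- stratify_periphery_core(pos, mask, cutoff_um = 400, voxel_size = vs)
  expect_true(all(r2 == "periphery"))
  ## the bottom face is not an exposed boundary
  deep <- data.frame(x_um = 250, y_um = 250, z_um = 5)
  r3 <- stratify_periphery_core(deep, mask, cutoff_um = 50, voxel_size = vs)
  expect_equal(as.character(r3), "core")
  expect_error(stratify_periphery_core(pos, mask, cutoff_um = 0), "cutoff")
})

test_that("displacement summaries report means, signs and upward fractions", {
  t <- c(0, 15)
  mk <- function(id, dz) data.frame(track_id = id, frame_index = 1:2, time_s = t,
                                    x_um = 0, y_um = 0, z_um = c(10, 10 + dz),
                                    volume_um3 = NA_real_, detection = 1:2)
  up <- do.call(rbind, lapply(1:4, mk, dz = 5))
  s <- displacement_summary(up)
  expect_equal(s$overall$mean_axial_um, 5)
  expect_equal(s$overall$upward_fraction, 1)
  mixed <- rbind(do.call(rbind, lapply(1:2, mk, dz = 7)),
                 do.call(rbind, lapply(3:4, mk, dz = -7)))
  s2 <- displacement_summary(mixed)
  expect_equal(s2$overall$mean_axial_um, 0)
  expect_equal(s2$overall$upward_fraction, 0.5)
})

test_that("sparse and dense assignment solvers agree on crowded scenes", {
  dense_match <- function(P, Q, gate) {
    nP <- nrow(P); nQ <- nrow(Q)
    D2 <- pmax(outer(rowSums(P^2), rowSums(Q^2), `+`) - 2 * P %*% t(Q), 0)
    g2 <- gate^2
    B <- g2 * (min(nP, nQ) + 1) + 1
    n <- nP + nQ
    C <- matrix(4 * B, n, n)
    Csub <- D2
    Csub[D2 > g2] <- 4 * B
    C[seq_len(nP), seq_len(nQ)] <- Csub
    C[cbind(seq_len(nP), nQ + seq_len(nP))] <- B
    C[cbind(nP + seq_len(nQ), seq_len(nQ))] <- B
    C[nP + seq_len(nQ), nQ + seq_len(nP)] <- 0
    asg <- pcls4d:::cpp_hungarian(C)
    out <- NULL
    for (r in seq_len(nP))
      if (asg[r] <= nQ && Csub[r, asg[r]] <= g2) out <- rbind(out, c(r, asg[r]))
    if (is.null(out)) matrix(integer(0), 0, 2) else out
  }
  set.seed(41)
  for (rep in 1:40) {
    n1 <- sample(10:60, 1)
    n2 <- sample(10:60, 1)
    P <- cbind(runif(n1, 0, 60), runif(n1, 0, 60), runif(n1, 0, 60))
    Q <- cbind(runif(n2, 0, 60), runif(n2, 0, 60), runif(n2, 0, 60))
    gate <- runif(1, 15, 45)
    a <- match_points(P, Q, gate)
    b <- dense_match(P, Q, gate)
    cost <- function(m) sum((P[m[, 1], , drop = FALSE] - Q[m[, 2], , drop = FALSE])^2)
    expect_equal(nrow(a), nrow(b))
    expect_equal(cost(a), cost(b), tolerance = 1e-9)
  }
})
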