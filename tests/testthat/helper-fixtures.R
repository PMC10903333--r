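## Shared fixtures and independent oracles for the test suite. Everything is
## generated in code; nothing is read from disk.

## internal helpers exercised directly in tests
voxel_centers <- pcls4d:::voxel_centers
cluster_points <- pcls4d:::cluster_points
match_points <- pcls4d:::match_points

## small, fast generator configuration (few cells, coarse grid)
tiny_config <- function(seed = 1L, ...) {
  args <- list(nz = 12L, ny = 32L, nx = 32L, dz = 10, dy = 4, dx = 4,
               slab_um = 120, tissue_margin_um = 12,
               cell_diam_um = 24, cell_diam_sd_um = 3,
               photon_scale = 50, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

## analytic series solution for diffusion in a slab with one Dirichlet face
## (x = L, value ub) and one Neumann face (x = 0), uniform initial value u0:
## u(x,t) = ub + (u0-ub) * sum_n (4(-1)^n / ((2n+1)pi)) cos((2n+1)pi x / 2L)
##          exp(-D ((2n+1)pi/2L)^2 t)
slab_series_solution <- function(x, t, L, D, u0, ub, nterms = 60) {
  s <- 0
  for (n in 0:(nterms - 1)) {
    k <- (2 * n + 1) * pi / (2 * L)
    s <- s + 4 * (-1)^n / ((2 * n + 1) * pi) * cos(k * x) * exp(-D * k^2 * t)
  }
  ub + (u0 - ub) * s
}

## exhaustive optimal gated assignment for small point sets: maximize the
## number of in-gate links, then minimize total squared displacement
brute_force_match <- function(P, Q, gate) {
  nP <- nrow(P); nQ <- nrow(Q)
  D2 <- outer(rowSums(P^2), rowSums(Q^2), `+`) - 2 * P %*% t(Q)
  best <- NULL
  best_key <- c(-1, Inf)
  assign_rec <- function(i, used, links, cost) {
    if (i > nP) {
      key <- c(length(links) / 2, cost)
      if (key[1] > best_key[1] ||
            (key[1] == best_key[1] && key[2] < best_key[2] - 1e-12)) {
        best_key <<- key
        best <<- if (length(links)) matrix(links, ncol = 2, byrow = TRUE)
                 else matrix(integer(0), 0, 2)
      }
      return(invisible())
    }
    assign_rec(i + 1, used, links, cost) # leave i unmatched
    for (j in seq_len(nQ)) {
      if (!used[j] && D2[i, j] <= gate^2) {
        used[j] <- TRUE
        assign_rec(i + 1, used, c(links, i, j), cost + D2[i, j])
        used[j] <- FALSE
      }
    }
  }
  assign_rec(1L, rep(FALSE, nQ), integer(0), 0)
  best[order(best[, 1]), , drop = FALSE]
}

## exhaustive suffix-scan oracle for the equilibration time
suffix_scan_teq <- function(times, values, epsilon = 0.05,
                            perturbation_time = 0, plateau_frac = 0.1) {
  post <- times >= perturbation_time
  times <- times[post]; values <- values[post]
  n <- length(values)
  k <- max(1L, ceiling(plateau_frac * n))
  plateau <- mean(values[(n - k + 1):n])
  for (i in seq_len(n)) {
    if (all(abs(values[i:n] - plateau) <= epsilon * abs(plateau)))
      return(if (i == 1) perturbation_time else times[i])
  }
  NA_real_
}

## cached full-scale benchmark runs shared by the acceptance tests
.bench_cache <- new.env(parent = emptyenv())
acceptance_run <- function(condition, seed = 1L) {
  key <- paste(condition, seed)
  if (!is.null(.bench_cache[[key]])) return(.bench_cache[[key]])
  sim <- simulate_benchmark(condition, seed = seed)
  analysis <- run_analysis(sim$stack, switch_time = 0, gate_um = 20)
  score <- score_benchmark(sim, analysis)
  out <- list(sim = sim, analysis = analysis, score = score)
  .bench_cache[[key]] <- out
  out
}

## reduced-size benchmark for the per-seed direction suite
direction_run <- function(condition, seed) {
  cfg <- benchmark_config(seed = seed, ny = 112L, nx = 112L)
  prot <- benchmark_protocol(condition)
  prot$duration <- 180
  sim <- simulate_benchmark(prot, seed = seed, config = cfg)
  analysis <- run_analysis(sim$stack, switch_time = 0, gate_um = 20,
                           stages = c("tissue", "nuclei"))
  list(sim = sim, analysis = analysis,
       score = score_benchmark(sim, analysis))
}
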