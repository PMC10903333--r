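#' Grid for the extracellular osmolality field
#'
#' The solute field is solved on its own (usually coarser) grid spanning the
#' same physical domain as the image: the slab thickness axially and the full
#' lateral field of view. Osmolality varies over tens of micrometres, so an
#' 8 µm lateral pitch loses nothing while keeping the solve cheap.
#'
#' @param config a [sim_config()]
#' @param lateral_um target lateral grid pitch (µm)
#' @param nz number of axial grid cells (defaults to the image z size)
#' @return list with voxel-center coordinates `z, y, x` (µm), `spacing`
#'   `(dz, dy, dx)`, `dims` `(nz, ny, nx)` and the physical `domain`
#' @export
field_grid <- function(config, lateral_um = 8, nz = NULL) {
  dom <- tissue_domain(config)
  Lx <- dom$Lx
  Ly <- dom$Ly
  L <- dom$slab_um
  ny <- max(2L, round(Ly / lateral_um))
  nx <- max(2L, round(Lx / lateral_um))
  nz <- max(2L, as.integer(nz %||% round(L / config$dz)))
  list(z = voxel_centers(nz, L / nz),
       y = dom$y0 + voxel_centers(ny, Ly / ny),
       x = dom$x0 + voxel_centers(nx, Lx / nx),
       spacing = c(L / nz, Ly / ny, Lx / nx),
       dims = c(nz, ny, nx),
       domain = dom)
}

## One implicit (backward Euler) diffusion sweep along `axis` (1=z, 2=y, 3=x).
## bc: length-2 character ("neumann"/"dirichlet") for the (low, high) faces;
## Dirichlet means the *face* is held at `bath` (ghost-cell formulation,
## second order). Backward Euler gives an M-matrix, so each sweep obeys the
## discrete maximum principle unconditionally.
diffusion_sweep <- function(U, axis, alpha, bc, bath) {
  dims <- dim(U)
  n <- dims[axis]
  if (n == 1L) return(U)
  perm <- c(axis, setdiff(1:3, axis))
  M <- matrix(aperm(U, perm), nrow = n)

  dg <- rep(1 + 2 * alpha, n)
  lo <- rep(-alpha, n) # sub-diagonal entries (row i couples to i-1)
  up <- rep(-alpha, n) # super-diagonal
  add_low <- 0; add_high <- 0
  if (bc[1] == "neumann") dg[1] <- 1 + alpha else { dg[1] <- 1 + 3 * alpha; add_low <- 2 * alpha * bath }
  if (bc[2] == "neumann") dg[n] <- 1 + alpha else { dg[n] <- 1 + 3 * alpha; add_high <- 2 * alpha * bath }
  if (add_low != 0) M[1, ] <- M[1, ] + add_low
  if (add_high != 0) M[n, ] <- M[n, ] + add_high

  ## Thomas algorithm; coefficients are per-row scalars, RHS is a matrix
  cp <- numeric(n)
  cp[1] <- up[1] / dg[1]
  M[1, ] <- M[1, ] / dg[1]
  for (i in 2:n) {
    denom <- dg[i] - lo[i] * cp[i - 1]
    cp[i] <- up[i] / denom
    M[i, ] <- (M[i, ] - lo[i] * M[i - 1, ]) / denom
  }
  for (i in (n - 1):1) M[i, ] <- M[i, ] - cp[i] * M[i + 1, ]

  A <- array(M, dims[perm])
  aperm(A, order(perm))
}

## advance one solute component from t0 to t1 with constant bath value
diffuse_interval <- function(U, grid, D, dt, t0, t1, bath, lateral_bc) {
  if (t1 <= t0 || D == 0) return(U)
  nstep <- max(1L, ceiling((t1 - t0) / dt))
  h <- grid$spacing
  sub <- (t1 - t0) / nstep
  a <- D * sub / h^2
  for (s in seq_len(nstep)) {
    U <- diffusion_sweep(U, 1L, a[1], c("neumann", "dirichlet"), bath)
    U <- diffusion_sweep(U, 2L, a[2], c(lateral_bc, lateral_bc), bath)
    U <- diffusion_sweep(U, 3L, a[3], c(lateral_bc, lateral_bc), bath)
  }
  U
}

#' Simulate solute penetration into the tissue slab
#'
#' Solves the diffusion equation for the non-permeating and permeating bath
#' components on the slab grid. The top face and (by default) the lateral
#' faces are Dirichlet boundaries held at the current bath value — the slab
#' sits in a large well-mixed bath — while the bottom face (chamber glass) is
#' zero-flux. Time stepping is operator-split backward Euler, which is
#' unconditionally stable and obeys the discrete maximum principle, so field
#' values always stay within the bounds set by the initial state and the bath.
#'
#' @param protocol a [solution_protocol()]
#' @param grid a [field_grid()]
#' @param D_eff effective interstitial diffusivity (µm²/s)
#' @param dt time-step size (s); accuracy control only, stability is
#'   unconditional
#' @param lateral_bc `"dirichlet"` (default, bath contact) or `"neumann"`
#'   (sealed sides; turns the solve into the 1-D slab problem)
#' @param times output times (s); defaults to the protocol frame times
#' @return an object of class `osmo_field`: list with `times`, `grid`, and
#'   arrays `Me`, `Se` of dim `(n_times, nz, ny, nx)` in mOsm/kg, plus the
#'   bath values `bath_Me`, `bath_Se` at the output times
#' @export
simulate_osmolality_field <- function(protocol, grid, D_eff, dt = 0.5,
                                      lateral_bc = c("dirichlet", "neumann"),
                                      times = NULL) {
  lateral_bc <- match.arg(lateral_bc)
  if (dt <= 0) stopf("dt must be > 0; the scheme is unconditionally stable but dt sets accuracy")
  times <- sort(unique(times %||% protocol_frame_times(protocol)))
  if (any(times < 0)) stopf("output times must be >= 0")
  dims <- grid$dims

  ## epoch boundaries: 0, switch times, output times, end
  knots <- sort(unique(c(0, protocol$switch_times, times, max(times))))
  bath0 <- protocol_bath(protocol, 0)
  ## initial interior state: baseline M0 and the pre-switch permeating value
  Me_pre <- if (length(protocol$switch_times)) protocol$Se[1] else protocol$Se[1]
  Ue <- array(protocol$M0, dims)
  Us <- array(protocol$Se[1], dims)

  nt <- length(times)
  out_Me <- array(NA_real_, c(nt, dims))
  out_Se <- array(NA_real_, c(nt, dims))
  record <- function(k) {
    out_Me[k, , , ] <<- Ue
    out_Se[k, , , ] <<- Us
  }
  tcur <- 0
  for (k in which(times <= 0)) record(k)
  for (i in seq_len(length(knots) - 1)) {
    t0 <- knots[i]; t1 <- knots[i + 1]
    if (t1 <= tcur) next
    bath <- protocol_bath(protocol, t0)
    Ue <- diffuse_interval(Ue, grid, D_eff, dt, t0, t1, bath$Me, lateral_bc)
    Us <- diffuse_interval(Us, grid, D_eff, dt, t0, t1, bath$Se, lateral_bc)
    tcur <- t1
    for (k in which(abs(times - t1) < 1e-9)) record(k)
  }
  bt <- protocol_bath(protocol, times)
  structure(list(times = times, grid = grid, Me = out_Me, Se = out_Se,
                 bath_Me = bt$Me, bath_Se = bt$Se, protocol = protocol,
                 D_eff = D_eff),
            class = "osmo_field")
}

#' Interpolate a field component at physical points
#'
#' Trilinear interpolation (clamped at the grid margins) of one field
#' component at fixed points for every stored time.
#'
#' @param field an `osmo_field` (or any list with `times`, `grid` and the
#'   named component array)
#' @param points matrix/data frame with columns `x_um, y_um, z_um`
#' @param component `"Me"`, `"Se"`, or another array component of `field`
#' @return matrix `(n_times, n_points)`
#' @export
field_at_points <- function(field, points, component = "Me") {
  pts <- as.matrix(points[, c("x_um", "y_um", "z_um")])
  arr <- field[[component]]
  grid <- field$grid
  nt <- length(field$times)
  dims <- grid$dims
  Fm <- matrix(arr, nrow = nt)

  axinfo <- function(coords, p) {
    n <- length(coords)
    h <- coords[2] - coords[1]
    f <- (p - coords[1]) / h
    i0 <- pmin(pmax(floor(f), 0), n - 1)
    w <- pmin(pmax(f - i0, 0), 1)
    i1 <- pmin(i0 + 1, n - 1)
    list(i0 = i0 + 1, i1 = i1 + 1, w = w)
  }
  az <- axinfo(grid$z, pts[, 3])
  ay <- axinfo(grid$y, pts[, 2])
  ax <- axinfo(grid$x, pts[, 1])
  nz <- dims[1]; ny <- dims[2]
  res <- matrix(0, nt, nrow(pts))
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    iz <- if (bz == 0) az$i0 else az$i1
    iy <- if (by == 0) ay$i0 else ay$i1
    ix <- if (bx == 0) ax$i0 else ax$i1
    w <- (if (bz == 0) 1 - az$w else az$w) *
      (if (by == 0) 1 - ay$w else ay$w) *
      (if (bx == 0) 1 - ax$w else ax$w)
    lin <- iz + nz * (iy - 1) + nz * ny * (ix - 1)
    res <- res + sweep(Fm[, lin, drop = FALSE], 2, w, `*`)
  }
  res
}
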