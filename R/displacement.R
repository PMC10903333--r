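#' Local volume-ratio field on the solute grid
#'
#' Runs the membrane transport model at every field grid voxel, driven by the
#' local extracellular osmolalities, giving the local normalized volume
#' `v(x, t)` of the parenchyma. This is the strain source for tissue
#' deformation and nuclear drift.
#'
#' @param field an `osmo_field` from [simulate_osmolality_field()]
#' @param params a [transport_params()]
#' @param times output times (s); defaults to the field times
#' @param dt integration step (s)
#' @return object of class `vfield`: list with `times`, `grid` and array `v`
#'   of dim `(n_times, nz, ny, nx)`
#' @export
compute_volume_field <- function(field, params, times = NULL, dt = 1) {
  times <- times %||% field$times
  dims <- field$grid$dims
  npts <- prod(dims)
  Me <- matrix(field$Me, nrow = length(field$times))
  Se <- matrix(field$Se, nrow = length(field$times))
  traj <- simulate_cell_volume(params, Me, Se, M0 = field$protocol$M0,
                               times = times, forcing_times = field$times, dt = dt)
  structure(list(times = times, grid = field$grid,
                 v = array(traj$v, c(length(times), dims))),
            class = "vfield")
}

## lambda profiles (nz x npts) at the lateral locations of `pts` for time
## index k, by bilinear lateral interpolation of v^(1/3)
lambda_profiles <- function(vfield, pts, k) {
  grid <- vfield$grid
  dims <- grid$dims
  nz <- dims[1]; ny <- dims[2]
  lam <- array(vfield$v[k, , , ], dims)^(1 / 3)
  lamM <- matrix(lam, nrow = nz)

  axinfo <- function(coords, p) {
    n <- length(coords)
    h <- coords[2] - coords[1]
    f <- (p - coords[1]) / h
    i0 <- pmin(pmax(floor(f), 0), n - 1)
    w <- pmin(pmax(f - i0, 0), 1)
    list(i0 = i0 + 1, i1 = pmin(i0 + 2, n), w = w)
  }
  ay <- axinfo(grid$y, pts[, 2])
  ax <- axinfo(grid$x, pts[, 1])
  col <- function(iy, ix) lamM[, iy + ny * (ix - 1), drop = FALSE]
  t00 <- col(ay$i0, ax$i0); t10 <- col(ay$i1, ax$i0)
  t01 <- col(ay$i0, ax$i1); t11 <- col(ay$i1, ax$i1)
  wy <- matrix(ay$w, nz, nrow(pts), byrow = TRUE)
  wx <- matrix(ax$w, nz, nrow(pts), byrow = TRUE)
  (1 - wy) * (1 - wx) * t00 + wy * (1 - wx) * t10 +
    (1 - wy) * wx * t01 + wy * wx * t11
}

#' Displace material points by the tissue strain field
#'
#' Maps initial positions of material points (nuclei, cell centers) through
#' the local linear strain `lambda(x, t) = v(x, t)^(1/3)`. The axial position
#' integrates the strain of the column below the point, anchored at the
#' chamber glass: `z(t) = integral_0^z0 lambda(z', t) dz'`; swelling below a
#' nucleus pushes it up, shrinkage pulls it down, which is what makes nuclei a
#' probe of local osmotic stress. The lateral position scales the distance
#' from the slab's lateral centroid by the mean lateral strain along the
#' column.
#'
#' @param vfield a `vfield` from [compute_volume_field()]
#' @param points matrix/data frame with columns `x_um, y_um, z_um` (initial
#'   positions, inside the slab)
#' @return list with `times` and matrices `x, y, z` of dim
#'   `(n_times, n_points)` (µm)
#' @export
compute_nuclear_displacement <- function(vfield, points) {
  pts <- as.matrix(as.data.frame(points)[, c("x_um", "y_um", "z_um")])
  grid <- vfield$grid
  L <- grid$domain$slab_um
  dom <- grid$domain
  if (any(pts[, 3] < 0 | pts[, 3] > L))
    stopf("initial axial positions must lie inside the slab [0, %g] um", L)
  if (any(pts[, 1] < dom$x0 | pts[, 1] > dom$x0 + dom$Lx |
            pts[, 2] < dom$y0 | pts[, 2] > dom$y0 + dom$Ly))
    stopf("initial lateral positions must lie inside the slab domain")
  nt <- length(vfield$times)
  np <- nrow(pts)
  cx <- dom$x0 + dom$Lx / 2
  cy <- dom$y0 + dom$Ly / 2
  zc <- grid$z
  nz <- length(zc)
  ## node positions for the axial quadrature: 0, voxel centers, L
  znode <- c(0, zc, L)
  X <- Y <- Z <- matrix(NA_real_, nt, np)
  for (k in seq_len(nt)) {
    lam <- lambda_profiles(vfield, pts, k) # nz x np
    lamn <- rbind(lam[1, ], lam, lam[nz, ]) # constant extrapolation at faces
    ## cumulative trapezoid along znode, per point
    dzseg <- diff(znode)
    seg <- (lamn[-1, , drop = FALSE] + lamn[-(nz + 2), , drop = FALSE]) / 2 *
      matrix(dzseg, nz + 1, np)
    cum <- apply(seg, 2, cumsum) # (nz+1) x np at znode[-1]
    cum <- rbind(0, cum)
    ## interpolate cumulative integral at each point's own z0
    i <- findInterval(pts[, 3], znode, rightmost.closed = TRUE)
    i <- pmin(i, nz + 1)
    a <- (pts[, 3] - znode[i]) / dzseg[i]
    idx <- cbind(i, seq_len(np))
    idx2 <- cbind(i + 1, seq_len(np))
    lam_lo <- lamn[idx]
    lam_hi <- lamn[idx2]
    ## integrate the linear lambda over the partial segment
    partial <- dzseg[i] * a * (lam_lo + (lam_lo + a * (lam_hi - lam_lo))) / 2
    Z[k, ] <- cum[idx] + partial
    s_lat <- cum[nz + 2, ] / L # mean lateral strain over the full column
    X[k, ] <- cx + (pts[, 1] - cx) * s_lat
    Y[k, ] <- cy + (pts[, 2] - cy) * s_lat
  }
  list(times = vfield$times, x = X, y = Y, z = Z)
}

#' Tissue warp summary fields
#'
#' Per output time, the deformed top-surface height `z_top(y, x)` and the
#' lateral scale factor `s_lat(y, x)` on the field grid's lateral nodes.
#' Used to draw the deformed slab outline and as ground truth for the
#' whole-tissue volume.
#'
#' @param vfield a `vfield`
#' @return list with `times`, lateral grids `y`, `x`, arrays `z_top` and
#'   `s_lat` of dim `(n_times, ny, nx)`, and `volume_um3` (deformed slab
#'   volume per time)
#' @export
tissue_warp <- function(vfield) {
  grid <- vfield$grid
  dims <- grid$dims
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  L <- grid$domain$slab_um
  nt <- length(vfield$times)
  ztop <- slat <- array(NA_real_, c(nt, ny, nx))
  vol <- numeric(nt)
  dz <- grid$spacing[1]
  cell_lat_area <- grid$spacing[2] * grid$spacing[3]
  for (k in seq_len(nt)) {
    lam <- array(vfield$v[k, , , ], dims)^(1 / 3)
    colsum <- apply(lam, c(2, 3), sum) * dz # integral of lambda over the column
    ztop[k, , ] <- colsum
    slat[k, , ] <- colsum / L
    vol[k] <- sum(colsum * slat[k, , ]^2) * cell_lat_area
  }
  list(times = vfield$times, y = grid$y, x = grid$x,
       z_top = ztop, s_lat = slat, volume_um3 = vol)
}
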