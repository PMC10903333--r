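#' Construct a 4D stack object
#'
#' Container for multichannel time-lapse voxel data with physical metadata.
#' Axis order is always `(t, c, z, y, x)`; singleton axes are kept.
#'
#' @param data 5-D numeric array `(t, c, z, y, x)`
#' @param voxel_size `(dz, dy, dx)` in µm
#' @param frame_interval frame interval in s
#' @param channels channel names (length = dim 2)
#' @param times frame times (s); defaults to `0, dt, 2 dt, ...`
#' @return an object of class `stack4d`
#' @export
stack4d <- function(data, voxel_size, frame_interval = 1,
                    channels = NULL, times = NULL) {
  d <- dim(data)
  if (length(d) != 5L) stopf("stack data must have 5 axes (t, c, z, y, x); got %d", length(d))
  if (any(voxel_size <= 0)) stopf("voxel sizes must be > 0")
  channels <- channels %||% paste0("ch", seq_len(d[2]))
  if (length(channels) != d[2]) stopf("need one channel name per channel axis entry")
  times <- times %||% ((seq_len(d[1]) - 1) * frame_interval)
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 frame_interval = frame_interval,
                 channels = channels, times = times),
            class = "stack4d")
}

#' @export
print.stack4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<stack4d> %d frames x %d channels x %dx%dx%d (z,y,x) at %gx%gx%g um, dt=%g s\n",
              d[1], d[2], d[3], d[4], d[5],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$frame_interval))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one frame/channel volume from a stack
#' @param stack a [stack4d()]
#' @param frame frame index (1-based)
#' @param channel channel index or name
#' @return 3-D array `(z, y, x)`
#' @export
stack_volume <- function(stack, frame = 1L, channel = 1L) {
  if (is.character(channel)) channel <- match(channel, stack$channels)
  if (is.na(channel)) stopf("unknown channel")
  d <- dim(stack$data)
  array(stack$data[frame, channel, , , ], d[3:5])
}

## bilinear interpolation of a 2D field sampled at (ycoords, xcoords)
## onto arbitrary (Y, X) matrices (clamped)
interp2 <- function(fld, ycoords, xcoords, Y, X) {
  ai <- function(coords, p) {
    n <- length(coords)
    h <- coords[2] - coords[1]
    f <- (p - coords[1]) / h
    i0 <- pmin(pmax(floor(f), 0), n - 1)
    list(i0 = i0 + 1, i1 = pmin(i0 + 2, n), w = pmin(pmax(f - i0, 0), 1))
  }
  ay <- ai(ycoords, Y); ax <- ai(xcoords, X)
  ny <- length(ycoords)
  g <- function(iy, ix) fld[cbind(as.vector(iy), as.vector(ix))]
  v <- (1 - ay$w) * (1 - ax$w) * g(ay$i0, ax$i0) +
    ay$w * (1 - ax$w) * g(ay$i1, ax$i0) +
    (1 - ay$w) * ax$w * g(ay$i0, ax$i1) +
    ay$w * ax$w * g(ay$i1, ax$i1)
  matrix(v, nrow(Y), ncol(Y))
}

#' Render the synthetic 4D stack
#'
#' Draws, per frame, three channels on the image grid: a thin membrane shell
#' at each volume-scaled cell boundary, the cell interiors plus a weak
#' interstitial background inside the deformed slab (cytoplasm channel), and
#' Gaussian blobs at the nucleus positions. Each channel is blurred with an
#' anisotropic Gaussian PSF, scaled to photon counts, and corrupted with
#' Poisson shot noise plus Gaussian read noise. Output is bit-identical for a
#' fixed configuration seed.
#'
#' @param geometry a [build_tissue_geometry()] result
#' @param config the [sim_config()] used for the geometry
#' @param v_cells matrix `(n_frames, n_cells)` of normalized cell volumes
#' @param cell_pos list of matrices `x, y, z` `(n_frames, n_cells)`: displaced
#'   cell centers (µm)
#' @param nuc_pos same structure for nuclei
#' @param warp a [tissue_warp()] (deformed slab outline), or `NULL` to skip
#'   the interstitial background
#' @param frame_times frame times (s)
#' @param psf_sigma_um PSF sigma `(z, y, x)` in µm
#' @param shell_um membrane shell half-thickness (µm)
#' @param background interstitial background intensity (cytoplasm channel)
#' @param noise add Poisson/read noise? If `FALSE` the noiseless photon-scaled
#'   image is returned
#' @return list with `stack` (a [stack4d()], channels
#'   `membrane, cytoplasm, nuclei`), `labels` (list of ground-truth integer
#'   label volumes per frame, label = cell id), and `clipped_cells` (count of
#'   cell-frames clipped at the grid boundary)
#' @export
render_stack <- function(geometry, config, v_cells, cell_pos, nuc_pos,
                         warp = NULL, frame_times,
                         psf_sigma_um = c(3, 1, 1), shell_um = 1,
                         background = 0.3, noise = TRUE) {
  nz <- config$nz; ny <- config$ny; nx <- config$nx
  dz <- config$dz; dy <- config$dy; dx <- config$dx
  nt <- length(frame_times)
  ncell <- nrow(geometry$cells)
  if (ncell > 0 && (nrow(v_cells) != nt || ncol(v_cells) != ncell))
    stopf("v_cells must be (n_frames x n_cells); trajectories must cover all frame times")
  zc <- voxel_centers(nz, dz)
  yc <- voxel_centers(ny, dy)
  xc <- voxel_centers(nx, dx)
  dimv <- c(nz, ny, nx)
  dat <- array(0, c(nt, 3, nz, ny, nx))
  labels <- vector("list", nt)
  clipped <- 0L
  sig_vox <- psf_sigma_um / c(dz, dy, dx)
  rn <- config$nucleus_diam_um / 2
  sigma_n <- config$nucleus_diam_um / 2

  latY <- matrix(yc, ny, nx)
  latX <- matrix(xc, ny, nx, byrow = TRUE)
  dom <- geometry$domain
  ctrx <- dom$x0 + dom$Lx / 2
  ctry <- dom$y0 + dom$Ly / 2

  set.seed(config$seed + 7919L)
  for (k in seq_len(nt)) {
    mem <- array(0, dimv)
    cyto <- array(0, dimv)
    nucch <- array(0, dimv)
    lab <- array(0L, dimv)
    best <- array(Inf, dimv)

    if (!is.null(warp)) {
      ## deformed slab occupancy: z below the warped top surface and lateral
      ## preimage inside the undeformed slab footprint
      s_lat <- interp2(matrix(warp$s_lat[k, , ], length(warp$y)), warp$y, warp$x, latY, latX)
      z_top <- interp2(matrix(warp$z_top[k, , ], length(warp$y)), warp$y, warp$x, latY, latX)
      preX <- ctrx + (latX - ctrx) / s_lat
      preY <- ctry + (latY - ctry) / s_lat
      inside <- preX >= dom$x0 & preX <= dom$x0 + dom$Lx &
        preY >= dom$y0 & preY <= dom$y0 + dom$Ly
      for (iz in seq_len(nz)) {
        m <- inside & (zc[iz] <= z_top)
        cyto[iz, , ][m] <- background
      }
    }

    for (i in seq_len(ncell)) {
      r <- geometry$cells$radius_um[i] * v_cells[k, i]^(1 / 3)
      cx <- cell_pos$x[k, i]; cy <- cell_pos$y[k, i]; cz <- cell_pos$z[k, i]
      ext <- r + shell_um
      iz <- which(abs(zc - cz) <= ext + dz)
      iy <- which(abs(yc - cy) <= ext + dy)
      ix <- which(abs(xc - cx) <= ext + dx)
      ## a cell is clipped when its interior would leave the imaged volume
      ## (the shell may dip below the glass without losing interior voxels)
      full_z <- (cz - r >= -dz) && (cz + r <= nz * dz)
      full_y <- (cy - r >= 0) && (cy + r <= ny * dy)
      full_x <- (cx - r >= 0) && (cx + r <= nx * dx)
      if (!(full_z && full_y && full_x)) clipped <- clipped + 1L
      if (!length(iz) || !length(iy) || !length(ix)) next
      dz2 <- (zc[iz] - cz)^2
      dy2 <- (yc[iy] - cy)^2
      dx2 <- (xc[ix] - cx)^2
      D <- sqrt(outer(outer(dz2, dy2, `+`), dx2, `+`))
      interior <- D <= r
      shell <- abs(D - r) <= shell_um
      sub <- function(A) A[iz, iy, ix, drop = FALSE]
      cy3 <- sub(cyto); cy3[interior] <- 1
      cyto[iz, iy, ix] <- cy3
      mm <- sub(mem); mm[shell] <- 1
      mem[iz, iy, ix] <- mm
      bb <- sub(best); ll <- sub(lab)
      ratio <- D / r
      take <- interior & (ratio < bb)
      ll[take] <- geometry$cells$cell_id[i]
      bb[take] <- ratio[take]
      lab[iz, iy, ix] <- ll
      best[iz, iy, ix] <- bb
    }

    if (!is.null(nuc_pos) && nrow(geometry$nuclei) > 0) {
      ext <- 3 * sigma_n
      for (j in seq_len(nrow(geometry$nuclei))) {
        cx <- nuc_pos$x[k, j]; cy <- nuc_pos$y[k, j]; cz <- nuc_pos$z[k, j]
        iz <- which(abs(zc - cz) <= ext)
        iy <- which(abs(yc - cy) <= ext)
        ix <- which(abs(xc - cx) <= ext)
        if (!length(iz) || !length(iy) || !length(ix)) next
        D2 <- outer(outer((zc[iz] - cz)^2, (yc[iy] - cy)^2, `+`), (xc[ix] - cx)^2, `+`)
        cur <- nucch[iz, iy, ix, drop = FALSE]
        nucch[iz, iy, ix] <- cur + exp(-D2 / (2 * sigma_n^2))
      }
    }

    for (ch in 1:3) {
      img <- switch(ch, mem, cyto, nucch)
      if (any(sig_vox > 0))
        img <- cpp_gaussian_blur3d(img, dimv, sig_vox[1], sig_vox[2], sig_vox[3])
      img <- img * config$photon_scale
      if (noise) {
        img <- rpois(length(img), pmax(img, 0)) +
          rnorm(length(img), 0, config$read_noise_sd)
        img <- pmax(img, 0)
      }
      dat[k, ch, , , ] <- img
    }
    labels[[k]] <- lab
  }

  stk <- stack4d(dat, c(dz, dy, dx),
                 frame_interval = if (nt > 1) frame_times[2] - frame_times[1] else 1,
                 channels = c("membrane", "cytoplasm", "nuclei"),
                 times = frame_times)
  list(stack = stk, labels = labels, clipped_cells = clipped)
}
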