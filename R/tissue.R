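#' Segment the whole-tissue surface
#'
#' Absolute-intensity threshold segmentation of the whole slice, the 3D
#' analogue of an Imaris-style "surfaces" stage: voxels at or above the
#' threshold are foreground, a 3D morphological closing with an
#' anisotropy-aware Euclidean ball bridges dark sinusoid-scale gaps, only the
#' largest 26-connected component is kept, and holes are filled slice-wise in
#' 2D so real lumina running through the slab are not erased.
#'
#' @param volume 3-D array `(z, y, x)` or a [stack4d()]
#' @param channel channel (index or name) when a stack is given
#' @param frame frame index when a stack is given
#' @param threshold absolute intensity threshold; `NULL` uses the lower cut
#'   of a two-threshold Otsu as a starting point (tissue images are trimodal:
#'   dark bath, dim interstitium, bright cells; the whole-tissue surface must
#'   include the interstitium). The acquisition-specific absolute value is
#'   always overridable.
#' @param closing_um closing ball radius (µm)
#' @param voxel_size `(dz, dy, dx)` µm when a bare array is given
#' @return object of class `tissue_mask`: list with logical `mask`,
#'   `voxel_size`, `threshold` and `frame`
#' @export
segment_tissue <- function(volume, channel = "cytoplasm", frame = 1L,
                           threshold = NULL, closing_um = 10,
                           voxel_size = c(1, 1, 1)) {
  if (inherits(volume, "stack4d")) {
    voxel_size <- volume$voxel_size
    volume <- stack_volume(volume, frame, channel)
  }
  dims <- dim(volume)
  rng <- range(volume)
  threshold <- threshold %||% otsu2_thresholds(as.numeric(volume))[1]
  if (threshold < rng[1] || threshold > rng[2])
    stopf("threshold %g is outside the channel intensity range [%g, %g]",
          threshold, rng[1], rng[2])
  fg <- volume >= threshold
  if (!any(fg))
    stopf("empty foreground at threshold %g; try a value near %g",
          threshold, otsu_threshold(as.numeric(volume)))
  if (closing_um > 0) {
    ## exact Euclidean closing via two distance transforms: dilate (distance
    ## to foreground <= r), then erode (distance to the dilated background
    ## > r). The erosion runs on a one-voxel background pad so that regions
    ## the dilation pushed against the array boundary erode back correctly.
    dil <- cpp_edt3d(!fg, dims, voxel_size) <= closing_um
    pd <- dims + 2L
    padded <- array(FALSE, pd)
    padded[2:(dims[1] + 1L), 2:(dims[2] + 1L), 2:(dims[3] + 1L)] <- dil
    ero <- cpp_edt3d(padded, pd, voxel_size) > closing_um
    fg <- array(ero, pd)[2:(dims[1] + 1L), 2:(dims[2] + 1L), 2:(dims[3] + 1L)]
  }
  lab <- cpp_label3d(fg, dims, 26L)
  if (max(lab) > 1L) {
    counts <- tabulate(lab[lab > 0L])
    fg <- array(lab == which.max(counts), dims)
  }
  ## slice-wise hole fill: background components not touching the slice border
  for (z in seq_len(dims[1])) {
    sl <- matrix(fg[z, , ], dims[2], dims[3])
    bg <- cpp_label3d(!sl, c(1L, dims[2], dims[3]), 6L)
    bg <- matrix(bg, dims[2], dims[3])
    border <- unique(c(bg[1, ], bg[dims[2], ], bg[, 1], bg[, dims[3]]))
    holes <- bg > 0 & !(bg %in% border)
    sl[holes] <- TRUE
    fg[z, , ] <- sl
  }
  structure(list(mask = fg, voxel_size = voxel_size,
                 threshold = threshold, frame = frame),
            class = "tissue_mask")
}

#' Measure a tissue mask
#'
#' Volume as foreground voxel count times voxel volume; surface area by
#' exposed-face counting with face areas from the voxel sizes; radius as half
#' the longest diameter, i.e. half the maximum pairwise distance between
#' extreme surface voxels (extremes taken along a deterministic set of
#' spherical directions, exact for convex shapes such as cuboids).
#'
#' @param mask a `tissue_mask`, or a logical array with `voxel_size` attr
#' @param voxel_size `(dz, dy, dx)` µm when a bare array is given
#' @return list with `volume_um3`, `area_um2`, `radius_um`, `voxels`
#' @export
measure_tissue <- function(mask, voxel_size = NULL) {
  if (inherits(mask, "tissue_mask")) {
    voxel_size <- mask$voxel_size
    mask <- mask$mask
  }
  voxel_size <- voxel_size %||% attr(mask, "voxel_size") %||% c(1, 1, 1)
  if (!any(mask)) stopf("empty mask")
  dims <- dim(mask)
  dz <- voxel_size[1]; dy <- voxel_size[2]; dx <- voxel_size[3]
  vol <- sum(mask) * dz * dy * dx
  area <- exposed_face_area(array(as.integer(mask), dims), voxel_size)

  surf <- surface_voxels(mask)
  idx <- which(surf, arr.ind = TRUE)
  pts <- cbind((idx[, 3] - 0.5) * dx, (idx[, 2] - 0.5) * dy, (idx[, 1] - 0.5) * dz)
  radius <- max_pairwise_distance(pts) / 2
  list(volume_um3 = vol, area_um2 = area, radius_um = radius, voxels = sum(mask))
}

## voxels of a mask adjacent (6-connectivity) to background or the array edge
surface_voxels <- function(mask) {
  dims <- dim(mask)
  surf <- array(FALSE, dims)
  pad <- function(axis, dir) {
    shifted <- array(FALSE, dims)
    n <- dims[axis]
    src <- lapply(dims, seq_len)
    dst <- src
    if (dir > 0) { dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
    else { dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1) }
    if (n > 1) shifted[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
    shifted
  }
  for (axis in 1:3) for (dir in c(-1, 1)) surf <- surf | (mask & !pad(axis, dir))
  surf
}

## total exposed-face area of every labeled object (label != neighbor counts)
exposed_face_area <- function(lab, voxel_size, per_label = FALSE) {
  dims <- dim(lab)
  dz <- voxel_size[1]; dy <- voxel_size[2]; dx <- voxel_size[3]
  face <- c(dy * dx, dz * dx, dz * dy) # areas for faces normal to z, y, x
  nlab <- max(lab)
  acc <- if (per_label) numeric(nlab) else 0
  count_faces <- function(a, b, axis_area, labs_a) {
    diffm <- a > 0 & a != b
    if (per_label) {
      t <- tabulate(labs_a[diffm], nlab)
      acc <<- acc + t * axis_area
    } else acc <<- acc + sum(diffm) * axis_area
  }
  for (axis in 1:3) {
    n <- dims[axis]
    idx <- lapply(dims, seq_len)
    lo <- idx; hi <- idx
    if (n > 1) {
      lo[[axis]] <- 1:(n - 1); hi[[axis]] <- 2:n
      a <- lab[lo[[1]], lo[[2]], lo[[3]]]
      b <- lab[hi[[1]], hi[[2]], hi[[3]]]
      count_faces(a, b, face[axis], a)
      count_faces(b, a, face[axis], b)
    }
    ## array boundary faces are exposed
    for (end in c(1L, n)) {
      sel <- idx
      sel[[axis]] <- end
      a <- lab[sel[[1]], sel[[2]], sel[[3]]]
      count_faces(a, 0L, face[axis], a)
    }
  }
  acc
}

## deterministic direction fan (Fibonacci sphere + axis/corner directions);
## diameter of a voxel point cloud via extreme points along each direction
max_pairwise_distance <- function(pts) {
  if (nrow(pts) == 1L) return(0)
  golden <- (1 + sqrt(5)) / 2
  i <- seq_len(128) - 0.5
  theta <- acos(1 - 2 * i / 128)
  phi <- 2 * pi * i / golden
  dirs <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
  axes <- rbind(diag(3), -diag(3))
  dirs <- rbind(dirs, corners, axes)
  proj <- pts %*% t(dirs)
  cand <- unique(c(apply(proj, 2, which.max), apply(proj, 2, which.min)))
  sub <- pts[cand, , drop = FALSE]
  max(stats::dist(sub))
}

#' Relative volume change series
#'
#' @param volumes numeric vector of volumes per timepoint (first is baseline)
#' @return dimensionless `(V - V0) / V0`, first element 0
#' @export
relative_change <- function(volumes) {
  if (!length(volumes)) stopf("empty volume series")
  if (volumes[1] <= 0) stopf("baseline volume must be > 0")
  (volumes - volumes[1]) / volumes[1]
}
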