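#' Detect nuclei as multiscale blob maxima
#'
#' Multiscale difference-of-Gaussian (scale-normalized Laplacian surrogate)
#' blob detection on anisotropy-rescaled data: blurs use per-axis sigmas in
#' voxel units so a spherical nucleus stays spherical in physical space.
#' Local maxima of the response above the threshold are collected across
#' scales and reduced by non-maximum suppression at a minimum physical
#' separation of `0.7 * min(diameter_range)`. Sub-voxel positions come from a
#' per-axis quadratic fit, which matters for coarse z-sampling. Deterministic.
#'
#' @param volume 3-D array `(z, y, x)` (nuclei channel) or a [stack4d()]
#' @param voxel_size `(dz, dy, dx)` µm when a bare array is given
#' @param frame,channel frame/channel selection for a stack
#' @param diameter_range_um candidate nucleus diameter range (µm)
#' @param n_scales number of log-spaced scales across the range
#' @param threshold absolute response threshold, or `"auto"` for 30% of the
#'   maximum response (blank images yield no spots either way)
#' @param time_s acquisition time recorded in the output
#' @return data frame (`spot_table` schema): `frame, time_s, x_um, y_um,
#'   z_um, diameter_um, response, volume_um3`; zero rows when nothing is
#'   detected
#' @export
detect_nuclei <- function(volume, voxel_size = c(1, 1, 1), frame = 1L,
                          channel = "nuclei", diameter_range_um = c(6, 12),
                          n_scales = 3L, threshold = "auto", time_s = NA_real_) {
  if (inherits(volume, "stack4d")) {
    voxel_size <- volume$voxel_size
    time_s <- volume$times[frame]
    volume <- stack_volume(volume, frame, channel)
  }
  if (any(diameter_range_um <= 0)) stopf("diameter range must be positive")
  dims <- dim(volume)
  ## blob scale sigma = d / (2*sqrt(3)) peaks the 3-D response at diameter d
  diams <- exp(seq(log(diameter_range_um[1]), log(diameter_range_um[2]),
                   length.out = n_scales))
  empty <- data.frame(frame = integer(0), time_s = numeric(0),
                      x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      diameter_um = numeric(0), response = numeric(0),
                      volume_um3 = numeric(0))

  responses <- vector("list", length(diams))
  for (si in seq_along(diams)) {
    sg <- diams[si] / (2 * sqrt(3))
    b1 <- cpp_gaussian_blur3d(volume, dims, sg / voxel_size[1], sg / voxel_size[2],
                              sg / voxel_size[3])
    b2 <- cpp_gaussian_blur3d(volume, dims, 1.6 * sg / voxel_size[1],
                              1.6 * sg / voxel_size[2], 1.6 * sg / voxel_size[3])
    responses[[si]] <- array(b1 - b2, dims)
  }
  maxresp <- max(vapply(responses, max, numeric(1)))
  if (maxresp <= 0) return(empty)
  cand <- list()
  floor_thr <- if (identical(threshold, "auto")) 0.02 * maxresp else threshold
  for (si in seq_along(diams)) {
    idx <- cpp_local_maxima3d(responses[[si]], dims, floor_thr)
    if (!length(idx)) next
    sub <- arrayInd(idx, dims)
    cand[[si]] <- data.frame(z = sub[, 1], y = sub[, 2], x = sub[, 3],
                             si = si, resp = responses[[si]][idx])
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || !nrow(cand)) return(empty)
  if (identical(threshold, "auto")) {
    ## blob peaks separate cleanly from noise maxima: Otsu on the peak
    ## response distribution picks the valley between the two populations.
    ## Applied only when the distribution is actually bimodal (a clean image
    ## has blob maxima only, which must all be kept).
    thr <- otsu_threshold(cand$resp)
    above <- cand$resp > thr
    if (nrow(cand) >= 10L && any(above) && any(!above) &&
          mean(cand$resp[above]) > 3 * mean(cand$resp[!above])) {
      cand <- cand[above, , drop = FALSE]
    }
  }

  ## greedy non-maximum suppression by response, physical distance
  min_sep <- 0.7 * min(diameter_range_um)
  ord <- order(-cand$resp, cand$z, cand$y, cand$x)
  cand <- cand[ord, ]
  pz <- (cand$z - 0.5) * voxel_size[1]
  py <- (cand$y - 0.5) * voxel_size[2]
  px <- (cand$x - 0.5) * voxel_size[3]
  keep <- logical(nrow(cand))
  kz <- ky <- kx <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(kz)) {
      d2 <- (kz - pz[i])^2 + (ky - py[i])^2 + (kx - px[i])^2
      if (any(d2 < min_sep^2)) next
    }
    keep[i] <- TRUE
    kz <- c(kz, pz[i]); ky <- c(ky, py[i]); kx <- c(kx, px[i])
  }
  cand <- cand[keep, , drop = FALSE]

  ## sub-voxel quadratic refinement along each axis at the winning scale
  refine <- function(rarr, z, y, x, axis, n) {
    i <- c(z, y, x)[axis]
    if (i <= 1 || i >= n) return(0)
    at <- function(off) {
      j <- c(z, y, x)
      j[axis] <- j[axis] + off
      rarr[j[1], j[2], j[3]]
    }
    denom <- at(-1) - 2 * at(0) + at(1)
    if (denom >= 0) return(0)
    max(-0.5, min(0.5, 0.5 * (at(-1) - at(1)) / denom))
  }
  off <- t(vapply(seq_len(nrow(cand)), function(i) {
    rarr <- responses[[cand$si[i]]]
    c(refine(rarr, cand$z[i], cand$y[i], cand$x[i], 1, dims[1]),
      refine(rarr, cand$z[i], cand$y[i], cand$x[i], 2, dims[2]),
      refine(rarr, cand$z[i], cand$y[i], cand$x[i], 3, dims[3]))
  }, numeric(3)))

  d_est <- diams[cand$si]
  out <- data.frame(frame = frame, time_s = time_s,
                    x_um = (cand$x - 0.5 + off[, 3]) * voxel_size[3],
                    y_um = (cand$y - 0.5 + off[, 2]) * voxel_size[2],
                    z_um = (cand$z - 0.5 + off[, 1]) * voxel_size[1],
                    diameter_um = d_est, response = cand$resp,
                    volume_um3 = 4 / 3 * pi * (d_est / 2)^3)
  ## response plateaus on coarse grids can yield voxel maxima farther apart
  ## than min_sep that refine onto the same physical point; suppress again on
  ## the refined coordinates
  keep <- logical(nrow(out))
  kz <- ky <- kx <- numeric(0)
  for (i in order(-out$response)) {
    if (length(kz) &&
          any((kz - out$z_um[i])^2 + (ky - out$y_um[i])^2 +
                (kx - out$x_um[i])^2 < min_sep^2)) next
    keep[i] <- TRUE
    kz <- c(kz, out$z_um[i]); ky <- c(ky, out$y_um[i]); kx <- c(kx, out$x_um[i])
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Seeded-watershed 3D cell segmentation
#'
#' Seeds closer than the merge distance are unioned (single linkage), so the
#' two nuclei of a binucleate cell grow one label. The membrane channel is
#' smoothed with an anisotropy-corrected Gaussian and flooded from the merged
#' seeds (6-connected priority flooding) within the mask; every mask voxel
#' ends up in exactly one label, with boundaries on membrane ridges.
#'
#' @param membrane 3-D array `(z, y, x)` (membrane channel) or a [stack4d()]
#' @param seeds data frame with `x_um, y_um, z_um` (e.g. from
#'   [detect_nuclei()])
#' @param mask logical array restricting the segmentation (e.g. a cell-signal
#'   or tissue mask)
#' @param voxel_size `(dz, dy, dx)` µm when a bare array is given
#' @param frame,channel frame/channel selection for a stack
#' @param merge_um seed merge distance (µm); must union the two nuclei of a
#'   binucleate cell (up to one cell radius apart) while keeping the nuclei of
#'   adjacent cells (rarely closer than half a cell diameter) separate
#' @param snap_um seeds falling just outside the mask are snapped to the
#'   nearest mask voxel within this radius (µm) rather than dropped
#' @param sigma_um lateral relief smoothing sigma (µm), axially corrected by
#'   the voxel anisotropy
#' @return object of class `label_volume`: integer array `(z, y, x)` with
#'   attributes `voxel_size` and `seed_map` (data frame mapping seed row to
#'   label)
#' @export
segment_cells <- function(membrane, seeds, mask, voxel_size = c(1, 1, 1),
                          frame = 1L, channel = "membrane",
                          merge_um = 11, sigma_um = 2.5, snap_um = 5) {
  if (inherits(membrane, "stack4d")) {
    voxel_size <- membrane$voxel_size
    membrane <- stack_volume(membrane, frame, channel)
  }
  dims <- dim(membrane)
  pts <- as.matrix(as.data.frame(seeds)[, c("x_um", "y_um", "z_um")])
  if (!nrow(pts)) stopf("no seeds supplied")
  grp <- cluster_points(pts, merge_um)

  iz <- nearest_voxel(pts[, 3], dims[1], voxel_size[1])
  iy <- nearest_voxel(pts[, 2], dims[2], voxel_size[2])
  ix <- nearest_voxel(pts[, 1], dims[3], voxel_size[3])
  lin <- cbind(iz, iy, ix)
  inmask <- mask[lin]
  ## a seed just off the mask (detection jitter, axial quantization) is
  ## snapped to the nearest mask voxel within snap_um rather than dropped
  if (snap_um > 0 && any(!inmask)) {
    rad <- ceiling(snap_um / voxel_size)
    for (s in which(!inmask)) {
      zr <- max(1, iz[s] - rad[1]):min(dims[1], iz[s] + rad[1])
      yr <- max(1, iy[s] - rad[2]):min(dims[2], iy[s] + rad[2])
      xr <- max(1, ix[s] - rad[3]):min(dims[3], ix[s] + rad[3])
      subm <- mask[zr, yr, xr, drop = FALSE]
      if (!any(subm)) next
      cand <- which(subm, arr.ind = TRUE)
      dd <- ((zr[cand[, 1]] - 0.5) * voxel_size[1] - pts[s, 3])^2 +
        ((yr[cand[, 2]] - 0.5) * voxel_size[2] - pts[s, 2])^2 +
        ((xr[cand[, 3]] - 0.5) * voxel_size[3] - pts[s, 1])^2
      if (min(dd) <= snap_um^2) {
        b <- which.min(dd)
        lin[s, ] <- c(zr[cand[b, 1]], yr[cand[b, 2]], xr[cand[b, 3]])
        inmask[s] <- TRUE
      }
    }
  }
  if (!any(inmask)) stopf("no seeds fall inside the mask")

  seed_arr <- array(0L, dims)
  seed_arr[lin[inmask, , drop = FALSE]] <- grp[inmask]
  relief <- cpp_gaussian_blur3d(membrane, dims, sigma_um / voxel_size[1],
                                sigma_um / voxel_size[2], sigma_um / voxel_size[3])
  lab <- cpp_watershed3d(relief, seed_arr, mask, dims, voxel_size)
  attr(lab, "voxel_size") <- voxel_size
  attr(lab, "seed_map") <- data.frame(seed = seq_len(nrow(pts)), label = grp,
                                      in_mask = inmask)
  class(lab) <- c("label_volume", class(lab))
  lab
}

#' Remove small labeled objects
#'
#' Objects with a voxel count strictly below `min_voxels` are erased (set to
#' background); all other labels are untouched. The 10,000-voxel default
#' follows common practice for removing sub-cellular debris from 3D cell
#' masks, and is tied to the voxel geometry it was defined for — use
#' `min_um3` to state the cutoff in physical units instead.
#'
#' @param labels integer label array
#' @param min_voxels minimum voxel count to survive (objects with fewer are
#'   removed; an object with exactly `min_voxels` is retained)
#' @param min_um3 alternative physical cutoff (µm³); converted via the voxel
#'   volume of `voxel_size`
#' @param voxel_size `(dz, dy, dx)` µm, needed for `min_um3`
#' @return the filtered label array (idempotent)
#' @export
size_filter <- function(labels, min_voxels = 10000L, min_um3 = NULL,
                        voxel_size = attr(labels, "voxel_size")) {
  if (!is.null(min_um3)) {
    if (is.null(voxel_size)) stopf("min_um3 needs a voxel_size")
    min_voxels <- ceiling(min_um3 / prod(voxel_size))
  }
  if (min_voxels < 0) stopf("min_voxels must be >= 0")
  if (min_voxels == 0 || !any(labels > 0L)) return(labels)
  counts <- tabulate(labels[labels > 0L])
  drop <- which(counts < min_voxels)
  if (length(drop)) labels[labels %in% drop] <- 0L
  labels
}

#' Relabel a label volume to consecutive integers
#' @param labels integer label array
#' @return relabeled array; label set is `1..n` in order of first appearance
#'   of the sorted original ids
#' @export
relabel_sequential <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) return(labels)
  lut <- integer(max(ids))
  lut[ids] <- seq_along(ids)
  out <- labels
  out[labels > 0L] <- lut[labels[labels > 0L]]
  out
}

#' Per-cell morphometrics of a label volume
#'
#' One record per label: voxel count, volume (count x voxel volume), surface
#' area by exposed-face counting, and the geometric (intensity-free) centroid
#' of voxel centers.
#'
#' @param labels integer label array `(z, y, x)`
#' @param voxel_size `(dz, dy, dx)` µm
#' @param frame,time_s recorded in the output
#' @return data frame (`cell_table` schema without `track_id`): `label,
#'   frame, time_s, voxels, volume_um3, area_um2, x_um, y_um, z_um`
#' @export
measure_cells <- function(labels, voxel_size = attr(labels, "voxel_size"),
                          frame = 1L, time_s = NA_real_) {
  voxel_size <- voxel_size %||% c(1, 1, 1)
  dims <- dim(labels)
  labs <- as.integer(labels)
  pos <- which(labs > 0L)
  if (!length(pos))
    return(data.frame(label = integer(0), frame = integer(0), time_s = numeric(0),
                      voxels = integer(0), volume_um3 = numeric(0),
                      area_um2 = numeric(0), x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0)))
  l <- labs[pos]
  nlab <- max(l)
  counts <- tabulate(l, nlab)
  ids <- which(counts > 0L)
  sub <- arrayInd(pos, dims)
  zs <- (sub[, 1] - 0.5) * voxel_size[1]
  ys <- (sub[, 2] - 0.5) * voxel_size[2]
  xs <- (sub[, 3] - 0.5) * voxel_size[3]
  area <- exposed_face_area(array(labs, dims), voxel_size, per_label = TRUE)
  agg_ids <- sort(unique(l))
  data.frame(label = agg_ids,
             frame = frame, time_s = time_s,
             voxels = counts[agg_ids],
             volume_um3 = counts[agg_ids] * prod(voxel_size),
             area_um2 = area[agg_ids],
             x_um = as.numeric(rowsum(xs, l)) / counts[agg_ids],
             y_um = as.numeric(rowsum(ys, l)) / counts[agg_ids],
             z_um = as.numeric(rowsum(zs, l)) / counts[agg_ids])
}

#' Assign time-stable TrackIDs to segmented cells
#'
#' Links per-frame cell centroids with the same gated optimal assignment used
#' for nuclei ([link_tracks()]); a TrackID is constant over the frames a cell
#' is followed and ends when the cell is not matched (no gap closing).
#'
#' @param cell_tables list of per-frame [measure_cells()] data frames
#' @param gate_um maximum centroid displacement per frame (µm)
#' @return one combined data frame with a `track_id` column
#' @export
assign_cell_track_ids <- function(cell_tables, gate_um = 20) {
  if (length(cell_tables) < 2L) stopf("need at least two timepoints")
  linked <- link_tracks(cell_tables, gate_um = gate_um)
  out <- do.call(rbind, lapply(seq_along(cell_tables), function(k) {
    tab <- cell_tables[[k]]
    if (!nrow(tab)) return(cbind(tab, track_id = integer(0)))
    key <- paste(k, seq_len(nrow(tab)))
    lk <- linked[linked$frame_index == k, ]
    tab$track_id <- lk$track_id[match(seq_len(nrow(tab)), lk$detection)]
    tab
  }))
  rownames(out) <- NULL
  out
}
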