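## Gated optimal assignment between two point sets. Returns a two-column
## matrix (i, j) of matched row indices. Candidate pairs are those within the
## gate; the minimum-cost maximum-cardinality matching over squared distances
## is computed exactly by a sparse successive-shortest-augmenting-path solver.
## Because every admissible pair is cheaper than leaving both endpoints
## unmatched, maximizing the number of links takes priority over cost.
match_points <- function(P, Q, gate) {
  nP <- nrow(P); nQ <- nrow(Q)
  if (!nP || !nQ) return(matrix(integer(0), 0, 2))
  D2 <- outer(rowSums(P^2), rowSums(Q^2), `+`) - 2 * P %*% t(Q)
  D2 <- pmax(D2, 0)
  pairs <- which(D2 <= gate^2, arr.ind = TRUE)
  if (!nrow(pairs)) return(matrix(integer(0), 0, 2))
  ml <- cpp_sparse_match(pairs[, 1], pairs[, 2], D2[pairs], nP, nQ)
  i <- which(ml > 0)
  cbind(i, ml[i], deparse.level = 0)
}

#' Link per-frame detections into tracks
#'
#' Frame-to-frame optimal bipartite assignment minimizing total squared
#' displacement among candidate pairs within the gate. Unmatched detections
#' start new tracks; unmatched track heads terminate; there is no gap
#' closing, merging or splitting (nuclei neither divide nor vanish at these
#' timescales, and the simple model keeps exhaustive verification possible).
#' Deterministic.
#'
#' @param detections list (one element per frame, at least two) of data
#'   frames with columns `x_um, y_um, z_um` and optionally `time_s`,
#'   `volume_um3`
#' @param gate_um maximum displacement per frame (µm); either a scalar or a
#'   vector with one gate per frame pair (motion-adaptive gating)
#' @param frame_interval frame interval (s), used when detections carry no
#'   `time_s`
#' @return `TrackTable` data frame: `track_id, frame_index, time_s, x_um,
#'   y_um, z_um, volume_um3, detection` with `(track_id, frame_index)` unique
#'   and times non-decreasing within a track
#' @export
link_tracks <- function(detections, gate_um = 15, frame_interval = 1) {
  nf <- length(detections)
  if (nf < 2L) stopf("need at least two frames to link")
  gate_um <- rep_len(gate_um, nf - 1L)
  getpts <- function(df) as.matrix(as.data.frame(df)[, c("x_um", "y_um", "z_um")])
  rows <- list()
  next_id <- 0L
  prev_ids <- integer(0)

  emit <- function(frame, df, ids) {
    if (!nrow(df)) return()
    t_s <- if ("time_s" %in% names(df) && !all(is.na(df$time_s))) df$time_s
           else rep((frame - 1) * frame_interval, nrow(df))
    vol <- if ("volume_um3" %in% names(df)) df$volume_um3 else rep(NA_real_, nrow(df))
    rows[[length(rows) + 1L]] <<- data.frame(
      track_id = ids, frame_index = frame, time_s = t_s,
      x_um = df$x_um, y_um = df$y_um, z_um = df$z_um,
      volume_um3 = vol, detection = seq_len(nrow(df)))
  }

  df1 <- as.data.frame(detections[[1]])
  prev_ids <- if (nrow(df1)) next_id + seq_len(nrow(df1)) else integer(0)
  next_id <- next_id + nrow(df1)
  emit(1L, df1, prev_ids)
  prev_pts <- getpts(df1)

  for (k in 2:nf) {
    dfk <- as.data.frame(detections[[k]])
    cur_pts <- getpts(dfk)
    ids <- rep(NA_integer_, nrow(dfk))
    if (nrow(dfk) && length(prev_ids)) {
      m <- match_points(prev_pts, cur_pts, gate_um[k - 1L])
      if (nrow(m)) ids[m[, 2]] <- prev_ids[m[, 1]]
    }
    new <- which(is.na(ids))
    if (length(new)) {
      ids[new] <- next_id + seq_along(new)
      next_id <- next_id + length(new)
    }
    emit(k, dfk, ids)
    prev_ids <- ids
    prev_pts <- cur_pts
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$track_id, out$frame_index), ]
}

#' Per-track kinematics
#'
#' Velocity by central differences (one-sided at the ends), acceleration by
#' second differences (`NA` at the ends), both per axis; adds speed and
#' acceleration magnitudes and is exact for linear and quadratic motion
#' respectively.
#'
#' @param tracks a `TrackTable` from [link_tracks()]
#' @param frame_interval frame interval (s) used when `time_s` is missing
#' @return `tracks` with columns `vx_um_s, vy_um_s, vz_um_s, speed_um_s,
#'   accel_um_s2` appended
#' @export
compute_kinematics <- function(tracks, frame_interval = 1) {
  tracks <- tracks[order(tracks$track_id, tracks$frame_index), ]
  n <- nrow(tracks)
  vx <- vy <- vz <- acc <- rep(NA_real_, n)
  for (id in unique(tracks$track_id)) {
    sel <- which(tracks$track_id == id)
    if (length(sel) < 2L) next
    t <- tracks$time_s[sel]
    if (all(is.na(t))) t <- (tracks$frame_index[sel] - 1) * frame_interval
    diffq <- function(p) {
      np <- length(p)
      v <- numeric(np)
      v[1] <- (p[2] - p[1]) / (t[2] - t[1])
      v[np] <- (p[np] - p[np - 1]) / (t[np] - t[np - 1])
      if (np > 2) {
        i <- 2:(np - 1)
        v[i] <- (p[i + 1] - p[i - 1]) / (t[i + 1] - t[i - 1])
      }
      v
    }
    px <- tracks$x_um[sel]; py <- tracks$y_um[sel]; pz <- tracks$z_um[sel]
    vx[sel] <- diffq(px); vy[sel] <- diffq(py); vz[sel] <- diffq(pz)
    if (length(sel) > 2L) {
      i <- 2:(length(sel) - 1)
      h <- diff(t)
      a_axis <- function(p) (p[i + 1] - 2 * p[i] + p[i - 1]) / (h[i - 1] * h[i])
      ax <- a_axis(px); ay <- a_axis(py); az <- a_axis(pz)
      acc[sel[i]] <- sqrt(ax^2 + ay^2 + az^2)
    }
  }
  tracks$vx_um_s <- vx
  tracks$vy_um_s <- vy
  tracks$vz_um_s <- vz
  tracks$speed_um_s <- sqrt(vx^2 + vy^2 + vz^2)
  tracks$accel_um_s2 <- acc
  tracks
}

#' Stratify positions into tissue periphery vs. core
#'
#' Anisotropy-aware Euclidean distance of each position to the nearest
#' solute-exposed boundary of the tissue mask: background inside the mask
#' bounds, the lateral faces and the top face of the grid all count as
#' boundary; the bottom face (chamber glass) does not. Positions closer than
#' the cutoff are `"periphery"`, the rest `"core"`; positions falling outside
#' the mask are labeled periphery with a warning.
#'
#' @param positions data frame with `x_um, y_um, z_um`
#' @param mask a `tissue_mask` (or logical array plus `voxel_size`)
#' @param cutoff_um edge-distance cutoff (µm)
#' @param voxel_size `(dz, dy, dx)` µm for a bare array
#' @return factor of `"periphery"`/`"core"` with attribute `edge_dist_um`
#' @export
stratify_periphery_core <- function(positions, mask, cutoff_um = 50,
                                    voxel_size = NULL) {
  if (cutoff_um <= 0) stopf("cutoff must be > 0")
  if (inherits(mask, "tissue_mask")) {
    voxel_size <- mask$voxel_size
    mask <- mask$mask
  }
  voxel_size <- voxel_size %||% attr(mask, "voxel_size") %||% c(1, 1, 1)
  dims <- dim(mask)
  ## pad by one voxel: background above the top face and beyond the lateral
  ## faces, tissue below the bottom face so the glass is not a boundary
  pd <- c(dims[1] + 2L, dims[2] + 2L, dims[3] + 2L)
  padded <- array(FALSE, pd)
  padded[1, , ] <- TRUE # below the chamber glass: never boundary
  padded[2:(dims[1] + 1L), 2:(dims[2] + 1L), 2:(dims[3] + 1L)] <- mask
  dist <- cpp_edt3d(padded, pd, voxel_size)
  iz <- nearest_voxel(positions$z_um, dims[1], voxel_size[1]) + 1L
  iy <- nearest_voxel(positions$y_um, dims[2], voxel_size[2]) + 1L
  ix <- nearest_voxel(positions$x_um, dims[3], voxel_size[3]) + 1L
  d <- array(dist, pd)[cbind(iz, iy, ix)]
  inside <- array(padded, pd)[cbind(iz, iy, ix)]
  if (any(!inside)) {
    warnf("%d position(s) fall outside the tissue mask; labeled periphery", sum(!inside))
    d[!inside] <- 0
  }
  out <- factor(ifelse(d < cutoff_um, "periphery", "core"),
                levels = c("periphery", "core"))
  attr(out, "edge_dist_um") <- d
  out
}

#' Summarize directional nuclear displacement
#'
#' Net displacement per track (positive axial = toward the exposed top face),
#' the fraction of nuclei moving upward, and per-region drift statistics
#' (both net displacement and path length, since the two answer different
#' questions about "drift").
#'
#' @param tracks a `TrackTable`, optionally with a `region` column
#' @param complete_only use only tracks spanning the full frame range?
#' @return list with `per_track` (one row per track: net displacements, path
#'   length, region), `overall` (mean axial net displacement, upward
#'   fraction, mean drift magnitude), and `by_region` when regions are
#'   present
#' @export
displacement_summary <- function(tracks, complete_only = TRUE) {
  if (!nrow(tracks)) stopf("no tracks to summarize")
  frames <- range(tracks$frame_index)
  per <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame_index), ]
    if (nrow(tr) < 2L) return(NULL)
    if (complete_only &&
          !(tr$frame_index[1] == frames[1] && tr$frame_index[nrow(tr)] == frames[2]))
      return(NULL)
    steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2 + diff(tr$z_um)^2)
    data.frame(track_id = tr$track_id[1],
               n_frames = nrow(tr),
               dx_um = tr$x_um[nrow(tr)] - tr$x_um[1],
               dy_um = tr$y_um[nrow(tr)] - tr$y_um[1],
               dz_um = tr$z_um[nrow(tr)] - tr$z_um[1],
               path_um = sum(steps),
               region = if ("region" %in% names(tr)) as.character(tr$region[1])
                        else NA_character_)
  })
  per <- do.call(rbind, per)
  if (is.null(per) || !nrow(per)) stopf("no complete tracks with >= 2 points")
  per$net_um <- sqrt(per$dx_um^2 + per$dy_um^2 + per$dz_um^2)
  overall <- data.frame(
    n_tracks = nrow(per),
    mean_axial_um = mean(per$dz_um),
    upward_fraction = mean(per$dz_um > 0),
    mean_net_um = mean(per$net_um),
    mean_path_um = mean(per$path_um))
  res <- list(per_track = per, overall = overall)
  if (any(!is.na(per$region))) {
    sp <- split(per, per$region)
    res$by_region <- do.call(rbind, lapply(names(sp), function(r) {
      data.frame(region = r, n_tracks = nrow(sp[[r]]),
                 mean_axial_um = mean(sp[[r]]$dz_um),
                 mean_net_um = mean(sp[[r]]$net_um),
                 mean_path_um = mean(sp[[r]]$path_um))
    }))
  }
  res
}
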