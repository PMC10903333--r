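#' Run the full analysis pipeline on a 4D stack
#'
#' Orchestrates the analysis stages on any `(t, c, z, y, x)` stack:
#' whole-tissue surface volume per frame (`tissue`), nuclei detection,
#' linking, kinematics and periphery/core stratification (`nuclei`),
#' seeded-watershed cell segmentation with per-cell morphometrics and
#' TrackIDs (`cells`), and aggregate volume kinetics (`kinetics`). Stage
#' outputs land in one list (and, with `outdir`, as CSV/JSON files plus a
#' checksum manifest). The analysis contains no randomness: reruns on the
#' same stack reproduce every output byte.
#'
#' @param stack a [stack4d()]
#' @param switch_time bath switch time (s); frames at or before it are the
#'   baseline
#' @param outdir output directory, or `NULL` for in-memory results only
#' @param stages subset of `c("tissue", "nuclei", "cells", "kinetics")`
#' @param tissue_channel,membrane_channel,nuclei_channel channel names
#' @param tissue_threshold absolute threshold for the tissue surface
#'   (`NULL` = Otsu on the first frame, reused for all frames)
#' @param closing_um tissue closing radius (µm)
#' @param diameter_range_um nucleus diameter range for spot detection (µm)
#' @param spot_threshold spot response threshold (see [detect_nuclei()])
#' @param gate_um linking gate (µm/frame)
#' @param edge_cutoff_um periphery/core edge-distance cutoff (µm)
#' @param merge_um binucleate seed merge distance (µm)
#' @param min_um3 minimum cell volume retained by the size filter (µm³)
#' @param seed_propagation carry a seed forward from the previous frame's
#'   centroid for cells whose nucleus is not re-detected (coarse axial
#'   sampling can hide vertically stacked nuclei in compressed tissue);
#'   propagated seeds are advected by the displacement of nearby linked
#'   nuclei
#' @param z_upsample integer axial resampling factor applied before the
#'   watershed, or `"auto"` to resample near-isotropically (target about
#'   3.5 µm); boundary localization between coarse z-slices uses the blurred
#'   intensity profile
#' @param qc_max_step kinetics quality filter: maximum tolerated
#'   frame-to-frame relative volume step (see [filter_volume_series()])
#' @param span loess span for kinetics smoothing
#' @param epsilon equilibration tolerance (fraction of plateau)
#' @return list with elements `tissue` (per-frame measurements), `spots`,
#'   `tracks`, `displacement`, `cells`, `kinetics`, `params`
#' @export
run_analysis <- function(stack, switch_time = 0, outdir = NULL,
                         stages = c("tissue", "nuclei", "cells", "kinetics"),
                         tissue_channel = "cytoplasm",
                         membrane_channel = "membrane",
                         nuclei_channel = "nuclei",
                         tissue_threshold = NULL, closing_um = 10,
                         diameter_range_um = c(6, 12), spot_threshold = "auto",
                         gate_um = 15, edge_cutoff_um = 50,
                         merge_um = 11, min_um3 = 500,
                         seed_propagation = TRUE, z_upsample = 1L,
                         qc_max_step = 0.8,
                         span = 0.5, epsilon = 0.05) {
  stopifnot(inherits(stack, "stack4d"))
  stages <- match.arg(stages, several.ok = TRUE)
  if ("cells" %in% stages && !"nuclei" %in% stages)
    stopf("the 'cells' stage consumes nuclei seeds; enable the 'nuclei' stage")
  if ("kinetics" %in% stages && !"cells" %in% stages)
    stopf("the 'kinetics' stage consumes cell tracks; enable the 'cells' stage")
  need <- c(tissue = tissue_channel,
            nuclei = if (any(c("nuclei", "cells") %in% stages)) nuclei_channel,
            membrane = if ("cells" %in% stages) membrane_channel)
  missing_ch <- setdiff(need, stack$channels)
  if (length(missing_ch))
    stopf("stack lacks required channel(s): %s", paste(missing_ch, collapse = ", "))

  nt <- dim(stack$data)[1]
  vs <- stack$voxel_size
  res <- list(params = list(switch_time = switch_time, stages = stages,
                            tissue_threshold = tissue_threshold,
                            closing_um = closing_um,
                            diameter_range_um = diameter_range_um,
                            gate_um = gate_um, edge_cutoff_um = edge_cutoff_um,
                            merge_um = merge_um, min_um3 = min_um3,
                            span = span, epsilon = epsilon))

  masks <- NULL
  if ("tissue" %in% stages) {
    thr <- tissue_threshold %||%
      otsu2_thresholds(as.numeric(stack_volume(stack, 1L, tissue_channel)))[1]
    res$params$tissue_threshold <- thr
    masks <- vector("list", nt)
    tis <- vector("list", nt)
    for (k in seq_len(nt)) {
      masks[[k]] <- segment_tissue(stack, channel = tissue_channel, frame = k,
                                   threshold = thr, closing_um = closing_um)
      m <- measure_tissue(masks[[k]])
      tis[[k]] <- data.frame(frame = k, time_s = stack$times[k],
                             volume_um3 = m$volume_um3, area_um2 = m$area_um2,
                             radius_um = m$radius_um)
    }
    tis <- do.call(rbind, tis)
    tis$dv_v0 <- relative_change(tis$volume_um3)
    res$tissue <- tis
  }

  if (any(c("nuclei", "cells") %in% stages)) {
    spots <- lapply(seq_len(nt), function(k)
      detect_nuclei(stack, frame = k, channel = nuclei_channel,
                    diameter_range_um = diameter_range_um,
                    threshold = spot_threshold))
    res$spots <- spots
  }

  ## motion-adaptive per-frame gates: the gate needs to exceed the fastest
  ## strain-driven motion, which the whole-tissue volume series bounds; once
  ## the tissue is quiescent a narrow gate avoids spurious long links (and
  ## keeps the assignment problems small in dense, compressed tissue)
  gates <- rep_len(gate_um, max(1L, nt - 1L))
  if (!is.null(res$tissue) && nt > 1L) {
    sc_t <- (1 + res$tissue$dv_v0)^(1 / 3)
    H <- dim(stack$data)[3] * vs[1]
    gates <- pmin(gate_um, pmax(8, 3 * abs(diff(sc_t)) * H))
  }
  res$params$gate_um_frames <- gates

  if ("nuclei" %in% stages) {
    tracks <- link_tracks(res$spots, gate_um = gates,
                          frame_interval = stack$frame_interval)
    tracks <- compute_kinematics(tracks, stack$frame_interval)
    if (!is.null(masks)) {
      first <- tracks[!duplicated(tracks$track_id), ]
      reg <- stratify_periphery_core(first, masks[[1]], cutoff_um = edge_cutoff_um)
      tracks$region <- as.character(reg)[match(tracks$track_id, first$track_id)]
      tracks$edge_dist_um <-
        attr(reg, "edge_dist_um")[match(tracks$track_id, first$track_id)]
    }
    res$tracks <- tracks
    res$displacement <- displacement_summary(tracks)
  }

  if ("cells" %in% stages) {
    cell_tabs <- vector("list", nt)
    label_list <- vector("list", nt)
    prev_centroids <- NULL
    prev_lineage <- integer(0) # TrackID carried by each persistent seed
    next_lineage <- 0L
    ## near-isotropic axial resampling before the watershed: the blurred
    ## intensity profile localizes boundaries between coarse z-slices
    zf <- if (identical(z_upsample, "auto")) max(1L, round(vs[1] / 3.5))
          else max(1L, as.integer(z_upsample))
    vs_f <- c(vs[1] / zf, vs[2], vs[3])
    res$params$z_upsample <- zf
    ## per-frame isotropic tissue scale from the tissue stage, used to adapt
    ## the seed merge distance as the tissue shrinks or swells
    scale_k <- if (!is.null(res$tissue)) (1 + res$tissue$dv_v0)^(1 / 3)
               else rep(1, nt)
    for (k in seq_len(nt)) {
      cyto <- upsample_z(stack_volume(stack, k, tissue_channel), zf)
      memb <- upsample_z(stack_volume(stack, k, membrane_channel), zf)
      base_mask <- if (!is.null(masks)) upsample_z(masks[[k]]$mask + 0, zf) >= 0.5
                   else cyto > 0
      cthr <- otsu_threshold(cyto[base_mask])
      cmask <- cyto >= cthr & base_mask
      det <- res$spots[[k]][, c("x_um", "y_um", "z_um")]
      merge_k <- merge_um * scale_k[k]
      if (seed_propagation && !is.null(prev_centroids) && nrow(prev_centroids)) {
        ## persistent cell identity: binucleate partnerships are decided once
        ## at baseline; afterwards each existing cell carries one seed. The
        ## previous centroids are advected by the displacement of nearby
        ## linked nuclei, refreshed to the matching current detection, and a
        ## cell whose nucleus is missed this frame (coarse z-sampling hides
        ## vertically stacked nuclei) keeps its advected seed. Detections far
        ## from every existing cell start new seeds.
        seeds <- as.data.frame(advect_points(prev_centroids, res$tracks,
                                             k - 1L, k))
        lineage <- prev_lineage
        ## refresh within the tracking gate: advection residuals under fast
        ## strain-driven motion exceed the (much smaller) merge distance
        m <- match_points(as.matrix(seeds), as.matrix(det), gate_um)
        if (nrow(m)) seeds[m[, 1], ] <- det[m[, 2], ]
        extra <- setdiff(seq_len(nrow(det)), m[, 2])
        if (length(extra)) {
          d2 <- outer(rowSums(as.matrix(det[extra, , drop = FALSE])^2),
                      rowSums(as.matrix(seeds)^2), `+`) -
            2 * as.matrix(det[extra, , drop = FALSE]) %*% t(as.matrix(seeds))
          far <- which(apply(d2, 1, min) > merge_k^2)
          if (length(far)) {
            seeds <- rbind(seeds, det[extra[far], , drop = FALSE])
            lineage <- c(lineage, next_lineage + seq_along(far))
            next_lineage <- next_lineage + length(far)
          }
        }
        merge_ws <- min(2, merge_k)
      } else {
        seeds <- det
        lineage <- NULL # assigned per merged group below
        merge_ws <- merge_k
      }
      lab <- segment_cells(memb, seeds, cmask, voxel_size = vs_f,
                           merge_um = merge_ws)
      lab <- size_filter(lab, min_um3 = min_um3, voxel_size = vs_f)
      label_list[[k]] <- lab
      tab <- measure_cells(lab, vs_f, frame = k, time_s = stack$times[k])
      ## carry TrackIDs through the seed lineage: the label of each watershed
      ## group inherits the lineage id of its first seed
      sm <- attr(lab, "seed_map")
      if (is.null(lineage)) {
        ngrp <- max(sm$label)
        lineage_of_group <- next_lineage + seq_len(ngrp)
        next_lineage <- next_lineage + ngrp
      } else {
        lineage_of_group <- rep(NA_integer_, max(sm$label))
        first <- !duplicated(sm$label)
        lineage_of_group[sm$label[first]] <- lineage[sm$seed[first]]
      }
      tab$track_id <- lineage_of_group[tab$label]
      cell_tabs[[k]] <- tab
      prev_centroids <- tab[, c("x_um", "y_um", "z_um")]
      prev_lineage <- tab$track_id
    }
    res$cell_labels <- label_list
    res$cells <- do.call(rbind, cell_tabs)
    rownames(res$cells) <- NULL
  }

  if ("kinetics" %in% stages) {
    series <- normalize_volume_series(
      data.frame(track_id = res$cells$track_id, time_s = res$cells$time_s,
                 volume_um3 = res$cells$volume_um3),
      switch_time = switch_time)
    series <- filter_volume_series(despike_volume_series(series), qc_max_step)
    series <- filter_outlier_series(series)
    agg <- aggregate_mean_sem(series)
    sm <- smooth_series(agg$time_s, agg$mean, span = span)
    res$kinetics <- list(
      series = series, aggregate = agg, smoothed = sm,
      equilibration_s = equilibration_time(sm$time_s, sm$fit, epsilon = epsilon,
                                           perturbation_time = switch_time),
      shrink_swell = shrink_swell_metrics(sm$time_s, sm$fit,
                                          switch_time = switch_time))
  }

  if (!is.null(outdir)) write_run_outputs(res, outdir)
  res
}

## advect points from frame k0 to k1 by the mean displacement of the nearest
## linked nuclei (tracks present in both frames); identity if no tracks
advect_points <- function(pts, tracks, k0, k1, knn = 6L) {
  pts <- as.matrix(pts)
  if (is.null(tracks)) return(as.data.frame(pts))
  a <- tracks[tracks$frame_index == k0, c("track_id", "x_um", "y_um", "z_um")]
  b <- tracks[tracks$frame_index == k1, c("track_id", "x_um", "y_um", "z_um")]
  common <- intersect(a$track_id, b$track_id)
  if (!length(common)) return(as.data.frame(pts))
  a <- a[match(common, a$track_id), ]
  b <- b[match(common, b$track_id), ]
  anchors <- as.matrix(a[, c("x_um", "y_um", "z_um")])
  disp <- as.matrix(b[, c("x_um", "y_um", "z_um")]) - anchors
  out <- pts
  for (i in seq_len(nrow(pts))) {
    d2 <- colSums((t(anchors) - pts[i, ])^2)
    nn <- order(d2)[seq_len(min(knn, length(d2)))]
    out[i, ] <- pts[i, ] + colMeans(disp[nn, , drop = FALSE])
  }
  out <- as.data.frame(out)
  names(out) <- c("x_um", "y_um", "z_um")
  out
}

## write stage tables + JSON summary + checksum manifest under one directory
write_run_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(obj, name) {
    p <- file.path(outdir, name)
    if (is.data.frame(obj)) write.csv(obj, p, row.names = FALSE, na = "")
    else jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <<- c(paths, p)
  }
  if (!is.null(res$tissue)) put(res$tissue, "tissue.csv")
  if (!is.null(res$tracks)) put(res$tracks, "tracks.csv")
  if (!is.null(res$displacement)) {
    put(res$displacement$per_track, "displacement_per_track.csv")
    put(res$displacement$overall, "displacement_overall.csv")
    if (!is.null(res$displacement$by_region))
      put(res$displacement$by_region, "displacement_by_region.csv")
  }
  if (!is.null(res$cells)) put(res$cells, "cells.csv")
  if (!is.null(res$kinetics)) {
    put(res$kinetics$aggregate, "kinetics_aggregate.csv")
    put(res$kinetics$smoothed, "kinetics_smoothed.csv")
    put(list(equilibration_s = res$kinetics$equilibration_s,
             shrink_swell = res$kinetics$shrink_swell), "kinetics_summary.json")
  }
  put(res$params, "run_params.json")
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  invisible(outdir)
}

#' Run a named synthetic benchmark end to end
#'
#' Generates the benchmark, runs every analysis stage on the rendered stack,
#' and scores the measurements against the generator's ground truth: median
#' per-cell volume error, fraction of true cells recovered as exactly one
#' label, nuclei link accuracy against the true correspondences, displacement
#' directions, tissue volume direction, and the equilibration time of the
#' aggregate cell-volume curve.
#'
#' @param condition `"hypo80"`, `"hyper1215"` or `"dmso1molal"`
#' @param seed random seed for the generator
#' @param outdir optional output directory for tables and the JSON summary
#' @param config optional [sim_config()] override (default
#'   [benchmark_config()])
#' @param params optional [transport_params()] override
#' @param noise render noise?
#' @param gate_um linking gate (µm/frame); the benchmark default is sized for
#'   the fastest strain-driven inter-frame motion of the calibrated
#'   conditions, about one cell diameter
#' @param ... further arguments to [run_analysis()]
#' @return list with `summary` (scalar metrics), `analysis` (full
#'   [run_analysis()] result) and `sim` (the benchmark with ground truth)
#' @export
run_benchmark <- function(condition = c("hypo80", "hyper1215", "dmso1molal"),
                          seed = 1L, outdir = NULL, config = NULL,
                          params = NULL, noise = TRUE, gate_um = 20, ...) {
  condition <- match.arg(condition)
  sim <- simulate_benchmark(condition, seed = seed, config = config,
                            params = params %||% transport_params(),
                            noise = noise)
  analysis <- run_analysis(sim$stack, switch_time = 0, gate_um = gate_um, ...)
  score <- score_benchmark(sim, analysis)
  summary <- c(list(condition = condition, seed = seed,
                    n_true_cells = nrow(sim$truth$geometry$cells),
                    n_true_nuclei = nrow(sim$truth$geometry$nuclei)),
               score)
  if (!is.null(outdir)) {
    write_run_outputs(analysis, outdir)
    jsonlite::write_json(summary, file.path(outdir, "benchmark_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(summary = summary, analysis = analysis, sim = sim)
}

#' Score pipeline measurements against generator ground truth
#'
#' @param sim a [simulate_benchmark()] result
#' @param analysis the matching [run_analysis()] result
#' @param match_gate_um gate for matching detections/labels to true objects
#' @return list of scalar recovery metrics
#' @export
score_benchmark <- function(sim, analysis, match_gate_um = 12) {
  truth <- sim$truth
  nt <- length(truth$frame_times)
  out <- list()

  if (!is.null(analysis$tissue)) {
    out$tissue_dv_v0_final <- analysis$tissue$dv_v0[nt]
    out$tissue_volume_direction <- sign(out$tissue_dv_v0_final)
  }

  if (!is.null(analysis$cells)) {
    errs <- c()
    recovered <- c()
    v0 <- 4 / 3 * pi * truth$geometry$cells$radius_um^3
    for (k in seq_len(nt)) {
      meas <- analysis$cells[analysis$cells$frame == k, ]
      if (!nrow(meas)) { recovered <- c(recovered, 0); next }
      tp <- cbind(truth$cell_pos$x[k, ], truth$cell_pos$y[k, ], truth$cell_pos$z[k, ])
      mp <- as.matrix(meas[, c("x_um", "y_um", "z_um")])
      m <- match_points(tp, mp, match_gate_um)
      vt <- truth$v_cells[k, m[, 1]] * v0[m[, 1]]
      errs <- c(errs, abs(meas$volume_um3[m[, 2]] - vt) / vt)
      recovered <- c(recovered, nrow(m) / nrow(truth$geometry$cells))
    }
    out$cell_volume_median_rel_error <- median(errs)
    out$cell_recovered_fraction <- mean(recovered)
  }

  if (!is.null(analysis$tracks)) {
    acc <- link_accuracy(analysis$tracks, truth, match_gate_um = 6)
    out$link_accuracy <- acc$accuracy
    out$n_links_scored <- acc$n_scored
    ds <- analysis$displacement$overall
    out$mean_axial_displacement_um <- ds$mean_axial_um
    out$upward_fraction <- ds$upward_fraction
    ## early window: solute penetration time through the slab plus the
    ## initial membrane response lag. The depth contrast in nuclear drift
    ## persists while strain is still propagating, which outlasts the bare
    ## diffusion time because cells respond with a ~1/k_w lag.
    t_early <- truth$geometry$domain$slab_um^2 / (4 * truth$params$D_eff) +
      0.3 / max(truth$params$k_w, 1e-6)
    early <- analysis$tracks[analysis$tracks$time_s <=
                               max(t_early, 2 * truth$protocol$frame_interval), ]
    if (nrow(early) && "region" %in% names(early)) {
      es <- displacement_summary(early, complete_only = TRUE)
      if (!is.null(es$by_region) && nrow(es$by_region) == 2L) {
        per <- es$by_region[es$by_region$region == "periphery", ]
        cor <- es$by_region[es$by_region$region == "core", ]
        out$early_drift_periphery_um <- per$mean_net_um
        out$early_drift_core_um <- cor$mean_net_um
      }
    }
  }

  if (!is.null(analysis$kinetics)) {
    out$equilibration_s <- analysis$kinetics$equilibration_s
    out$v_min <- analysis$kinetics$shrink_swell$v_min
    out$t_min_s <- analysis$kinetics$shrink_swell$t_min
    out$recovery_fraction <- analysis$kinetics$shrink_swell$recovery_fraction
    agg <- analysis$kinetics$aggregate
    out$n_cells_aggregated <- min(agg$n)
    out$v_final <- agg$mean[nrow(agg)]
  }
  out
}

## fraction of measured frame-to-frame links joining detections of the same
## true cell. Detections are identified by the nearest true nucleus within
## the gate; identity is scored at the owning-cell level because a detector
## working at 10 um z-steps legitimately fuses the two nuclei of a binucleate
## cell into one spot, making nucleus-level identity ill-posed.
link_accuracy <- function(tracks, truth, match_gate_um = 6) {
  nt <- length(truth$frame_times)
  cell_of <- truth$geometry$nuclei$cell_id
  ids <- vector("list", nt)
  for (k in seq_len(nt)) {
    det <- tracks[tracks$frame_index == k, ]
    if (!nrow(det)) { ids[[k]] <- integer(0); next }
    tp <- cbind(truth$nuc_pos$x[k, ], truth$nuc_pos$y[k, ], truth$nuc_pos$z[k, ])
    mp <- as.matrix(det[, c("x_um", "y_um", "z_um")])
    m <- match_points(tp, mp, match_gate_um)
    v <- rep(NA_integer_, nrow(det))
    v[m[, 2]] <- cell_of[m[, 1]]
    ids[[k]] <- stats::setNames(v, det$detection)
  }
  correct <- 0L; scored <- 0L
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, ]
    tr <- tr[order(tr$frame_index), ]
    if (nrow(tr) < 2L) next
    for (r in seq_len(nrow(tr) - 1L)) {
      if (tr$frame_index[r + 1L] != tr$frame_index[r] + 1L) next
      a <- ids[[tr$frame_index[r]]][as.character(tr$detection[r])]
      b <- ids[[tr$frame_index[r + 1L]]][as.character(tr$detection[r + 1L])]
      if (is.na(a) || is.na(b)) next
      scored <- scored + 1L
      if (a == b) correct <- correct + 1L
    }
  }
  list(accuracy = if (scored) correct / scored else NA_real_, n_scored = scored)
}
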