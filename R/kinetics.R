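#' Normalize per-cell volume series to the pre-switch baseline
#'
#' `V0` is the volume at the last frame at or before the switch time;
#' series without a positive baseline are dropped.
#'
#' @param cells data frame with `track_id, time_s, volume_um3`
#' @param switch_time bath switch time (s)
#' @return data frame `track_id, time_s, v` with `v = V / V0`
#' @export
normalize_volume_series <- function(cells, switch_time = 0) {
  out <- lapply(split(cells, cells$track_id), function(tr) {
    tr <- tr[order(tr$time_s), ]
    pre <- which(tr$time_s <= switch_time)
    if (!length(pre)) return(NULL)
    v0 <- tr$volume_um3[max(pre)]
    if (!is.finite(v0) || v0 <= 0) return(NULL)
    data.frame(track_id = tr$track_id, time_s = tr$time_s,
               v = tr$volume_um3 / v0)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Quality-filter volume series
#'
#' Removes series with a physiologically implausible frame-to-frame volume
#' step (osmotic water exchange is rate-limited; a near-doubling or halving
#' between consecutive frames indicates a segmentation merge or a broken
#' track, not biology).
#'
#' @param series data frame with `track_id, time_s, v`
#' @param max_step_frac maximum tolerated relative step between consecutive
#'   frames
#' @return the filtered series
#' @export
filter_volume_series <- function(series, max_step_frac = 0.5) {
  bad <- vapply(split(series, series$track_id), function(tr) {
    tr <- tr[order(tr$time_s), ]
    any(abs(diff(tr$v)) / tr$v[-nrow(tr)] > max_step_frac)
  }, logical(1))
  series[!series$track_id %in% names(bad)[bad], ]
}

#' Despike volume series
#'
#' Removes isolated segmentation glitches from per-cell volume traces: points
#' deviating from a running median by more than `max_dev` (relative) are
#' dropped. A single watershed boundary flip of one coarse z-slice changes a
#' cell's voxel count by tens of percent for one frame; such spikes are
#' artifacts, while genuine osmotic volume change is smooth on the frame
#' timescale.
#'
#' @param series data frame with `track_id, time_s, v`
#' @param window running-median window (odd)
#' @param max_dev maximum tolerated relative deviation from the local median
#' @return the series with spike points removed
#' @export
despike_volume_series <- function(series, window = 5L, max_dev = 0.3) {
  out <- lapply(split(series, series$track_id), function(tr) {
    tr <- tr[order(tr$time_s), ]
    n <- nrow(tr)
    if (n < window) return(tr)
    med <- stats::runmed(tr$v, window, endrule = "median")
    tr[abs(tr$v - med) / med <= max_dev, ]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Reject outlier volume series
#'
#' Robust population-level quality filter: a track whose endpoint normalized
#' volume sits many robust standard deviations from the population median is
#' almost surely a segmentation merge (its volume roughly doubles) or a
#' broken track, not an osmotically plausible cell. Deviations are measured
#' on the mean of the final three points against the population median,
#' scaled by the median absolute deviation.
#'
#' @param series data frame with `track_id, time_s, v`
#' @param k_mad rejection threshold in MAD units
#' @return the filtered series
#' @export
filter_outlier_series <- function(series, k_mad = 4) {
  vfin <- vapply(split(series, series$track_id), function(tr) {
    tr <- tr[order(tr$time_s), ]
    mean(tail(tr$v, 3))
  }, numeric(1))
  med <- median(vfin)
  s <- stats::mad(vfin)
  if (s <= 0) return(series)
  drop <- names(vfin)[abs(vfin - med) > k_mad * s]
  series[!series$track_id %in% drop, ]
}

#' Aggregate volume series into mean and SEM per timepoint
#'
#' Cells tracked for less than `min_frac` of the frames are excluded
#' (partial tracks bias the mean). SEM uses the sample sd (n - 1 denominator)
#' over the cells present at each timepoint.
#'
#' @param series data frame with `track_id, time_s, v`
#' @param min_frac minimum fraction of timepoints a track must cover
#' @return data frame `time_s, mean, sd, sem, n`
#' @export
aggregate_mean_sem <- function(series, min_frac = 0.8) {
  nt <- length(unique(series$time_s))
  len <- table(series$track_id)
  keep <- names(len)[len >= min_frac * nt]
  series <- series[series$track_id %in% keep, ]
  sp <- split(series$v, series$time_s)
  if (any(vapply(sp, length, integer(1)) < 2L))
    stopf("need at least two overlapping series per timepoint")
  out <- data.frame(time_s = as.numeric(names(sp)),
                    mean = vapply(sp, mean, numeric(1)),
                    sd = vapply(sp, sd, numeric(1)),
                    n = vapply(sp, length, numeric(1)))
  out$sem <- out$sd / sqrt(out$n)
  rownames(out) <- NULL
  out[order(out$time_s), c("time_s", "mean", "sd", "sem", "n")]
}

#' Local-regression smoothing of a time series
#'
#' Tricube-weighted local linear regression (loess, degree 1) evaluated on a
#' uniform time grid, with a pointwise 95% interval from the normal
#' approximation to the fit standard error.
#'
#' @param times,values the scattered series (at least 5 points)
#' @param span loess span fraction in (0, 1]
#' @param grid_n number of uniform grid points
#' @return data frame `time_s, fit, se, lo, hi`
#' @export
smooth_series <- function(times, values, span = 0.5, grid_n = 201L) {
  if (length(times) < 5L) stopf("need at least 5 points to smooth")
  if (span <= 0 || span > 1) stopf("span must lie in (0, 1]")
  if (span * length(times) < 2)
    stopf("span window holds fewer than 2 points")
  fit <- loess(values ~ times, span = span, degree = 1,
               family = "gaussian", surface = "direct")
  grid <- seq(min(times), max(times), length.out = grid_n)
  pr <- predict(fit, newdata = data.frame(times = grid), se = TRUE)
  data.frame(time_s = grid, fit = pr$fit, se = pr$se.fit,
             lo = pr$fit - 1.96 * pr$se.fit,
             hi = pr$fit + 1.96 * pr$se.fit)
}

#' Equilibration time of a volume response
#'
#' The plateau is the mean of the final 10% of points; the equilibration time
#' is the earliest time after the perturbation from which the series stays
#' within `epsilon * |plateau|` of the plateau. A constant series
#' equilibrates at the perturbation time; a series whose final point is still
#' outside the band has not settled and yields `NA` (reported as
#' not-equilibrated, not an error). Invariant under time translation and
#' positive volume rescaling.
#'
#' @param times,values the (smoothed) series
#' @param epsilon tolerance as a fraction of the plateau, in (0, 0.5)
#' @param perturbation_time bath switch time (s)
#' @param plateau_frac final fraction of points defining the plateau
#' @return time (s), or `NA` if never settled
#' @export
equilibration_time <- function(times, values, epsilon = 0.05,
                               perturbation_time = 0, plateau_frac = 0.1) {
  if (epsilon <= 0 || epsilon >= 0.5) stopf("epsilon must lie in (0, 0.5)")
  ord <- order(times)
  times <- times[ord]; values <- values[ord]
  post <- times >= perturbation_time
  if (!any(post)) stopf("series does not span the perturbation")
  times <- times[post]; values <- values[post]
  n <- length(values)
  k <- max(1L, ceiling(plateau_frac * n))
  plateau <- mean(values[(n - k + 1L):n])
  ok <- abs(values - plateau) <= epsilon * abs(plateau)
  if (!ok[n]) return(NA_real_)
  bad <- which(!ok)
  if (!length(bad)) return(perturbation_time)
  times[max(bad) + 1L]
}

#' Shrink-swell metrics of a volume response
#'
#' Minimum of the post-switch series, its time, and the recovery fraction
#' `(V_end - V_min) / (V0 - V_min)`: 0 for a monotone decay, 1 for a full
#' return to baseline.
#'
#' @param times,values the (smoothed) series
#' @param switch_time bath switch time (s)
#' @param v0 baseline volume; defaults to the value at the last point at or
#'   before the switch (or the first point)
#' @return list with `v_min`, `t_min`, `v_end`, `recovery_fraction`
#' @export
shrink_swell_metrics <- function(times, values, switch_time = 0, v0 = NULL) {
  ord <- order(times)
  times <- times[ord]; values <- values[ord]
  if (is.null(v0)) {
    pre <- which(times <= switch_time)
    v0 <- if (length(pre)) values[max(pre)] else values[1]
  }
  post <- times >= switch_time
  if (!any(post)) stopf("series does not span the perturbation")
  tp <- times[post]; vp <- values[post]
  imin <- which.min(vp)
  v_min <- vp[imin]
  v_end <- vp[length(vp)]
  denom <- v0 - v_min
  rec <- if (abs(denom) < .Machine$double.eps^0.5) 0 else (v_end - v_min) / denom
  list(v_min = v_min, t_min = tp[imin], v_end = v_end,
       recovery_fraction = rec)
}
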