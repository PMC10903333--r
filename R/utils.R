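`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Voxel-center coordinates along one axis
#'
#' Voxel `i` (1-based) is centered at `(i - 0.5) * spacing` micrometres, with
#' the axis origin at the low face of the grid (z index 1 sits just above the
#' chamber glass).
#'
#' @param n number of voxels
#' @param spacing voxel pitch in micrometres
#' @return numeric vector of length `n`
#' @keywords internal
voxel_centers <- function(n, spacing) (seq_len(n) - 0.5) * spacing

#' Convert physical positions to nearest voxel indices
#' @param pos_um numeric vector of positions (µm)
#' @param n number of voxels along the axis
#' @param spacing voxel pitch (µm)
#' @return integer vector clamped to `[1, n]`
#' @keywords internal
nearest_voxel <- function(pos_um, n, spacing) {
  pmin(pmax(as.integer(floor(pos_um / spacing)) + 1L, 1L), n)
}

## trapezoidal cumulative integral, same length as x, starting at 0
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n == 1L) return(0)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

## single-linkage grouping of points with pairwise distance below `cutoff`;
## returns integer group id per point (union-find)
cluster_points <- function(pts, cutoff) {
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  d <- as.matrix(stats::dist(pts))
  pairs <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

## linear upsampling of a (z, y, x) array along z by an integer factor
upsample_z <- function(arr, factor) {
  if (factor <= 1L) return(arr)
  dims <- dim(arr)
  nz <- dims[1]
  nzf <- nz * factor
  out <- array(0, c(nzf, dims[2], dims[3]))
  pos <- (seq_len(nzf) - 0.5) / factor # in old slice-center units
  i_lo <- pmin(pmax(floor(pos + 0.5), 1L), nz)
  i_hi <- pmin(i_lo + 1L, nz)
  w <- pmin(pmax(pos + 0.5 - i_lo, 0), 1)
  for (j in seq_len(nzf)) {
    out[j, , ] <- (1 - w[j]) * arr[i_lo[j], , ] + w[j] * arr[i_hi[j], , ]
  }
  out
}

## two-threshold (3-class) Otsu on a numeric vector; returns c(lo, hi).
## Used for trimodal tissue images: dark outside, dim interstitium, bright
## cells - the lower threshold separates tissue from background.
otsu2_thresholds <- function(x, nbins = 128L) {
  r <- range(x, finite = TRUE)
  if (r[1] == r[2]) return(c(r[1], r[1]))
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  csum <- c(0, cumsum(p))
  cmu <- c(0, cumsum(p * mids))
  wsum <- function(a, b) csum[b + 1] - csum[a] # class prob over bins a..b
  msum <- function(a, b) cmu[b + 1] - cmu[a]
  best <- -Inf
  bt <- c(1L, 2L)
  for (i in 1:(nbins - 2)) {
    for (j in (i + 1):(nbins - 1)) {
      w1 <- wsum(1L, i); w2 <- wsum(i + 1L, j); w3 <- wsum(j + 1L, nbins)
      if (w1 == 0 || w2 == 0 || w3 == 0) next
      m1 <- msum(1L, i) / w1; m2 <- msum(i + 1L, j) / w2
      m3 <- msum(j + 1L, nbins) / w3
      mt <- cmu[nbins + 1]
      v <- w1 * (m1 - mt)^2 + w2 * (m2 - mt)^2 + w3 * (m3 - mt)^2
      if (v > best) { best <- v; bt <- c(i, j) }
    }
  }
  c(mids[bt[1]], mids[bt[2]])
}

## Otsu threshold on a numeric vector (256-bin histogram)
otsu_threshold <- function(x, nbins = 256L) {
  r <- range(x, finite = TRUE)
  if (r[1] == r[2]) return(r[1])
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mut <- mu[nbins]
  sb2 <- (mut * w0 - mu)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}
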