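## Documented table schemas: column names carry the units. Times are seconds,
## lengths µm, volumes µm³ everywhere; CSVs are UTF-8 with '.' decimals and
## non-finite values written as empty fields.
.table_schemas <- list(
  track_table = c("track_id", "frame", "time_s", "x_um", "y_um", "z_um",
                  "volume_um3", "region", "speed_um_s", "accel_um_s2"),
  cell_table = c("label", "frame", "time_s", "voxels", "volume_um3",
                 "area_um2", "x_um", "y_um", "z_um", "track_id"),
  tissue_table = c("frame", "time_s", "volume_um3", "area_um2", "radius_um",
                   "dv_v0"),
  spot_table = c("frame", "time_s", "x_um", "y_um", "z_um", "diameter_um",
                 "response", "volume_um3"),
  cells_truth = c("cell_id", "x_um", "y_um", "z_um", "radius_um", "n_nuclei"),
  nuclei_truth = c("nucleus_id", "cell_id", "frame", "time_s", "x_um",
                   "y_um", "z_um")
)

#' Write a multichannel 4D stack as multi-page TIFF
#'
#' Pages are ordered t-major, then channel, then z (matching per-timepoint
#' z-stack export). Intensities are stored as 32-bit values normalized by a
#' global scale factor; the scale, voxel sizes, frame interval and channel
#' names are recorded in a YAML sidecar file `<path>.meta.yaml` so the reader
#' can restore physical units and axis shape exactly.
#'
#' @param stack a [stack4d()]
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "stack4d"))
  d <- dim(stack$data)
  scale <- max(stack$data, 1e-12)
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 0L
  for (t in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      for (z in seq_len(d[3])) {
        i <- i + 1L
        pages[[i]] <- matrix(stack$data[t, ch, z, , ] / scale, d[4], d[5])
      }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(axes = "tczyx", nt = d[1], nc = d[2], nz = d[3], ny = d[4], nx = d[5],
               dz_um = stack$voxel_size[1], dy_um = stack$voxel_size[2],
               dx_um = stack$voxel_size[3],
               frame_interval_s = stack$frame_interval,
               channels = as.list(stack$channels),
               times_s = as.list(stack$times),
               intensity_scale = scale)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' Restores the `(t, c, z, y, x)` axis order from the YAML sidecar written by
#' [write_stack()]. Without a sidecar the declared layout (`nc`, `nz`) is
#' used; page count must divide evenly into frames, and missing voxel-size
#' metadata falls back to documented defaults (1 µm isotropic, 1 s frames)
#' with a warning.
#'
#' @param path TIFF path
#' @param nc,nz channel and z-slice counts per frame when no sidecar exists
#' @param voxel_size fallback voxel size `(dz, dy, dx)` µm
#' @param frame_interval fallback frame interval (s)
#' @return a [stack4d()]
#' @export
read_stack <- function(path, nc = 1L, nz = 1L, voxel_size = c(1, 1, 1),
                       frame_interval = 1) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mpath <- paste0(path, ".meta.yaml")
  scale <- 1
  channels <- NULL
  times <- NULL
  if (file.exists(mpath)) {
    meta <- yaml::read_yaml(mpath)
    nc <- meta$nc; nz <- meta$nz
    voxel_size <- c(meta$dz_um, meta$dy_um, meta$dx_um)
    frame_interval <- meta$frame_interval_s
    scale <- meta$intensity_scale %||% 1
    channels <- unlist(meta$channels)
    times <- unlist(meta$times_s)
    if (length(pages) != meta$nt * nc * nz)
      stopf("TIFF %s is truncated: %d pages, sidecar declares %d",
            path, length(pages), meta$nt * nc * nz)
  } else {
    warnf("no metadata sidecar for %s; assuming %g um voxels, %g s frames",
          path, voxel_size[1], frame_interval)
  }
  per_frame <- nc * nz
  if (length(pages) %% per_frame != 0)
    stopf("page count %d is not divisible by channels x slices = %d",
          length(pages), per_frame)
  nt <- length(pages) %/% per_frame
  shp <- dim(pages[[1]])
  dat <- array(0, c(nt, nc, nz, shp[1], shp[2]))
  i <- 0L
  for (t in seq_len(nt))
    for (ch in seq_len(nc))
      for (z in seq_len(nz)) {
        i <- i + 1L
        p <- pages[[i]]
        if (!identical(dim(p), shp))
          stopf("inconsistent page shape at page %d of %s", i, path)
        dat[t, ch, z, , ] <- p * scale
      }
  stack4d(dat, voxel_size, frame_interval, channels = channels, times = times)
}

#' Write a label volume as multi-page TIFF (one page per z-slice)
#'
#' Labels are stored as 16-bit integers (up to 65,535 labels) with the voxel
#' size in a YAML sidecar.
#'
#' @param labels integer array `(z, y, x)`
#' @param path output path
#' @param voxel_size `(dz, dy, dx)` µm
#' @return `path`, invisibly
#' @export
write_labels <- function(labels, path, voxel_size = c(1, 1, 1)) {
  if (max(labels) > 65535L) stopf("more than 65,535 labels not supported")
  d <- dim(labels)
  pages <- lapply(seq_len(d[1]), function(z) matrix(labels[z, , ] / 65535, d[2], d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  yaml::write_yaml(list(nz = d[1], ny = d[2], nx = d[3],
                        dz_um = voxel_size[1], dy_um = voxel_size[2],
                        dx_um = voxel_size[3], encoding = "label16"),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a label volume written by [write_labels()]
#' @param path TIFF path
#' @return integer array `(z, y, x)` with attribute `voxel_size`
#' @export
read_labels <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  arr <- array(0L, c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) arr[z, , ] <- as.integer(round(pages[[z]] * 65535))
  attr(arr, "voxel_size") <- c(meta$dz_um, meta$dy_um, meta$dx_um)
  arr
}

#' Write an analysis table as CSV
#'
#' The column set must match one of the documented schemas exactly (units are
#' part of the column names). Non-finite values are written as empty fields
#' and read back as `NA`.
#'
#' @param table data frame
#' @param path output CSV path
#' @param schema one of `track_table`, `cell_table`, `tissue_table`,
#'   `spot_table`, `cells_truth`, `nuclei_truth`, or `NULL` to auto-detect by
#'   column set
#' @return `path`, invisibly
#' @export
write_table <- function(table, path, schema = NULL) {
  if (is.null(schema)) {
    hit <- vapply(.table_schemas, function(s) identical(names(table), s), logical(1))
    if (!any(hit)) {
      known <- unlist(.table_schemas)
      bad <- setdiff(names(table), known)
      stopf("columns do not match any documented schema%s",
            if (length(bad)) paste0("; unknown columns: ", paste(bad, collapse = ", ")) else "")
    }
    schema <- names(.table_schemas)[which(hit)[1]]
  } else {
    if (!schema %in% names(.table_schemas)) stopf("unknown schema '%s'", schema)
    if (!identical(names(table), .table_schemas[[schema]]))
      stopf("columns must be exactly: %s",
            paste(.table_schemas[[schema]], collapse = ", "))
  }
  tab <- table
  for (j in seq_along(tab))
    if (is.numeric(tab[[j]])) tab[[j]][!is.finite(tab[[j]])] <- NA
  write.csv(tab, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an analysis table written by [write_table()]
#' @param path CSV path
#' @return data frame
#' @export
read_table_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read a simulation configuration from a YAML file
#'
#' Unknown keys are rejected; all omitted keys take their documented defaults
#' and the fully materialized configuration is returned (and echoed with
#' `verbose = TRUE`).
#'
#' @param path YAML config path
#' @param verbose print the materialized configuration?
#' @return a [sim_config()]
#' @export
read_config <- function(path, verbose = FALSE) {
  vals <- yaml::read_yaml(path) %||% list()
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stopf("unknown configuration keys: %s", paste(bad, collapse = ", "))
  cfg <- do.call(sim_config, vals)
  if (verbose) print(cfg)
  cfg
}

#' Write a simulation configuration as YAML
#' @param config a [sim_config()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
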