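#' Benchmark exposure protocols
#'
#' The three calibrated study conditions: a hyposmotic non-permeating switch
#' (300 to 80 mOsm/kg), a hyperosmotic non-permeating switch (300 to
#' 1,215 mOsm/kg), and an isotonic carrier with 1 mol/kg DMSO added
#' (permeating, about 1,000 mOsm/kg). The bath switches at t = 0, so the
#' t = 0 frame is the pre-switch baseline; recordings run 480 s at 15 s
#' frames.
#'
#' @param condition one of `"hypo80"`, `"hyper1215"`, `"dmso1molal"`, or
#'   `"isosmotic"` (control)
#' @return a [solution_protocol()]
#' @export
benchmark_protocol <- function(condition = c("hypo80", "hyper1215",
                                             "dmso1molal", "isosmotic")) {
  condition <- match.arg(condition)
  switch(condition,
    hypo80 = solution_protocol(M0 = 300, Me = c(300, 80), switch_times = 0),
    hyper1215 = solution_protocol(M0 = 300, Me = c(300, 1215), switch_times = 0),
    dmso1molal = solution_protocol(M0 = 300, Me = c(300, 300), Se = c(0, 1000),
                                   switch_times = 0),
    isosmotic = solution_protocol(M0 = 300, Me = 300))
}

#' Benchmark imaging configuration
#'
#' A desk-scale imaging geometry for the synthetic benchmarks: the paper-like
#' axial sampling (10 µm z-steps over a 300 µm slab, with 150 µm of axial
#' headroom so swelling tissue stays inside the stack) and a reduced lateral
#' field of view (256 µm at 2 µm pixels) whose central 192 µm holds tissue,
#' leaving a lateral margin for swelling. This yields roughly 700-800 cells
#' and 850-950 nuclei per frame, enough for stable aggregate kinetics while
#' keeping a full simulate-segment-track-quantify cycle to a few minutes.
#'
#' @param seed random seed
#' @param ... overrides passed to [sim_config()]
#' @return a [sim_config()]
#' @export
benchmark_config <- function(seed = 1L, ...) {
  args <- list(nz = 45L, ny = 128L, nx = 128L, dz = 10, dy = 2, dx = 2,
               slab_um = 300, tissue_margin_um = 32, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' Simulate a full synthetic benchmark with ground truth
#'
#' Runs the whole generator: packs the tissue, solves solute penetration into
#' the slab, integrates per-cell volume trajectories driven by the local
#' osmolality, computes strain-driven displacement of cell centers and
#' nuclei, and renders the noisy three-channel stack with per-frame
#' ground-truth label volumes.
#'
#' @param condition benchmark condition, see [benchmark_protocol()]
#' @param seed random seed (overrides `config$seed`)
#' @param config a [sim_config()]; default [benchmark_config()]
#' @param params a [transport_params()]; default calibrated values
#' @param noise render Poisson/read noise?
#' @param forcing_dt sampling interval (s) of the osmolality forcing fields
#' @param lateral_bc lateral boundary condition of the solute field. The
#'   default `"neumann"` (sealed sides) models a field of view interior to a
#'   much wider slice: solute exchanges only through the exposed top face,
#'   which is what makes the tissue response depth-dependent. Use
#'   `"dirichlet"` for a small explant bathed on all sides.
#' @return object of class `pcls_benchmark`: list with `stack`, `labels`
#'   (ground-truth label volumes per frame) and `truth` (list: `geometry`,
#'   `v_cells`, `cell_pos`, `nuc_pos`, `field`, `vfield`, `warp`,
#'   `frame_times`, `protocol`, `params`, `config`, `condition`)
#' @export
simulate_benchmark <- function(condition = "hypo80", seed = NULL,
                               config = NULL, params = transport_params(),
                               noise = TRUE, forcing_dt = 5,
                               lateral_bc = "neumann") {
  config <- config %||% benchmark_config(seed = seed %||% 1L)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  protocol <- if (inherits(condition, "solution_protocol")) condition
              else benchmark_protocol(condition)
  cond_name <- if (is.character(condition)) condition else "custom"

  geometry <- build_tissue_geometry(config)
  frame_times <- protocol_frame_times(protocol)
  grid <- field_grid(config)
  forcing_times <- sort(unique(c(seq(0, protocol$duration, by = forcing_dt),
                                 protocol$duration)))
  field <- simulate_osmolality_field(protocol, grid, params$D_eff,
                                     times = forcing_times,
                                     lateral_bc = lateral_bc)

  ncell <- nrow(geometry$cells)
  Me_c <- field_at_points(field, geometry$cells, "Me")
  Se_c <- field_at_points(field, geometry$cells, "Se")
  traj <- simulate_cell_volume(params, Me_c, Se_c, M0 = protocol$M0,
                               times = frame_times, forcing_times = field$times)
  vfield <- compute_volume_field(field, params, times = frame_times)
  warp <- tissue_warp(vfield)
  cell_pos <- compute_nuclear_displacement(vfield, geometry$cells)
  nuc_pos <- compute_nuclear_displacement(vfield, geometry$nuclei)

  rend <- render_stack(geometry, config, traj$v, cell_pos, nuc_pos,
                       warp = warp, frame_times = frame_times, noise = noise)

  structure(list(
    stack = rend$stack, labels = rend$labels,
    clipped_cells = rend$clipped_cells,
    truth = list(geometry = geometry, v_cells = traj$v, traj = traj,
                 cell_pos = cell_pos, nuc_pos = nuc_pos, field = field,
                 vfield = vfield, warp = warp, frame_times = frame_times,
                 protocol = protocol, params = params, config = config,
                 condition = cond_name)),
    class = "pcls_benchmark")
}

#' @export
print.pcls_benchmark <- function(x, ...) {
  cat(sprintf("<pcls_benchmark> condition '%s', %d frames, %d cells, %d nuclei, seed %d\n",
              x$truth$condition, length(x$truth$frame_times),
              nrow(x$truth$geometry$cells), nrow(x$truth$geometry$nuclei),
              x$truth$config$seed))
  invisible(x)
}
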