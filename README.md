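# pcls4d

Multiscale 4D quantification of osmotic volume change in precision-cut
liver slices (PCLS).

PCLS are 300–500 µm thick live sections of liver imaged as multichannel
confocal time-lapse z-stacks while the bathing medium changes osmolality
(hypo/hyperosmotic salts, or permeating cryoprotectants such as DMSO).
`pcls4d` measures the response at three scales:

- **whole tissue** — absolute-threshold surface segmentation, volume,
  surface area, longest-diameter radius, and relative volume change per
  timepoint;
- **nuclei** — anisotropy-aware multiscale blob detection, exact gated
  frame-to-frame track linking, velocity/acceleration kinematics, and
  stratification into tissue *periphery* vs. *core* by distance to the
  solute-exposed boundary (nuclei are fiducial probes of local tissue
  strain: hyposmotic exposure drives them upward, hyperosmotic/CPA exposure
  downward);
- **single cells** — seeded-watershed 3D instance segmentation from the
  membrane channel with nuclei seeds (binucleate-aware), size filtering,
  per-cell morphometrics, time-stable TrackIDs, and aggregate volume
  kinetics: loess-smoothed mean ± SEM curves, a 5%-of-plateau equilibration
  time, and shrink–swell metrics.

Because no public raw stacks exist for this problem, the package includes a
first-class synthetic 4D generator with complete ground truth. Its core is
a two-parameter membrane transport model with asymmetric regulatory
volume return (RVD faster than RVI),

```
M_i = M0 (n + s) / w
dw/dt = k_w (M_i − M_e − S_e) / M0        # water
ds/dt = k_s (S_e − M0 s / w) / M0         # permeating solute (CPA)
dn/dt = −k_rvd (v−1)+ + k_rvi (1−v)+      # asymmetric RVD/RVI regulation
v     = b + (1 − b) w                     # normalized cell volume
```

driven by a solute field that diffuses into the slab through its exposed
top face, plus strain-driven displacement of cells and nuclei
(`z(t) = ∫0^z0 v(z')^{1/3} dz'`, anchored at the chamber glass), rendered
into three channels with PSF blur, Poisson shot noise and read noise. With
solute flux and regulation off the model reduces to the Boyle–van't Hoff relation
`v∞ = b + (1 − b) M0/M_e`.

## Worked example

```r
library(pcls4d)

## simulate the calibrated hyposmotic benchmark (bath 300 -> 80 mOsm/kg at
## t = 0; 480 s at 15 s frames; ~800 cells) and analyze the rendered stack
bench <- run_benchmark("hypo80", seed = 1)
str(bench$summary, give.head = FALSE)
```

Output from this run (seed 1):

```
condition                    : "hypo80" (bath 300 -> 80 mOsm/kg at t = 0)
n_true_cells / n_true_nuclei : 826 / 991
tissue_dv_v0_final           : +0.44    # whole tissue swells 44%
cell_volume_median_rel_error : 0.100    # vs. generator ground truth
cell_recovered_fraction      : 0.96
link_accuracy                : 1.00
mean_axial_displacement_um   : +16.9    # nuclei move upward
early_drift_periphery_um     : 6.4      # periphery outruns the core
early_drift_core_um          : 5.3      #   while solute penetrates
equilibration_s              : 319      # ~300 s hyposmotic settling
```

The hyposmotic aggregate cell-volume curve rises above 1 and settles (5% of
plateau) near 300 s; the hyperosmotic benchmark (`"hyper1215"`) falls below
1 and settles about twice as fast; `"dmso1molal"` produces the classic
shrink–swell excursion. Individual stages are plain functions
(`segment_tissue()`, `detect_nuclei()`, `link_tracks()`, `segment_cells()`,
`measure_cells()`, `aggregate_mean_sem()`, `equilibration_time()`, ...) and
run on any `(t, c, z, y, x)` stack written by `write_stack()`; a thin
command-line front end lives at `inst/scripts/pcls4d.R`.

See the methods vignette (`vignettes/pcls4d-methods.Rmd`) for the model,
its assumptions, parameter rationale, and known limitations.

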