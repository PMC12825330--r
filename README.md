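# shellcount

Single-cell quantification of viral transduction efficiency in dense living
3D tissue, from confocal stacks.

## The problem

Gene-therapy vectors (e.g. AAV serotypes) are screened by expressing a
fluorescent reporter in treated tissue — typically stem-cell-derived
organoids imaged live by confocal microscopy. Bulk fluorescence cannot
distinguish one bright transduced cell from many dim ones, flow cytometry
destroys the tissue, and per-cell cytoplasm segmentation in densely packed
neural tissue is unreliable. `shellcount` implements a shell-based per-cell
readout that avoids cytoplasm instance segmentation entirely:

1. **Nuclei** are instance-segmented by an external deep-learning tool
   (Cellpose or similar); the label volume is the package's input.
2. **The transduced volume** is segmented semantically by a
   sparse-annotation random-forest pixel classifier trained on a handful of
   voxels marked at three depths in both dim and bright regions
   (probability ≥ 50 %, objects > 10 µm³).
3. **Each cell is classified** by building a thin *virtual shell* around its
   nucleus — a morphological dilation (2 voxels, ≈ 0.8 µm laterally on the
   standard 50 %-binned grid) minus the union of all nuclei — and measuring
   the fraction of shell voxels inside the transduced volume. A cell is
   transduced iff that overlap fraction reaches a threshold calibrated
   against manual counting (default **0.4**).

The transduction efficiency is

```
E = N_Td / N_Tot
```

with `N_Tot` the number of nuclei surviving the volume (> 100 µm³) and
shell-size (≥ 50 µm³ human / 30 µm³ mouse tissue) filters, and `N_Td` those
whose shell overlap is ≥ 0.4. Efficiencies aggregate hierarchically — imaged
areas average to an organoid value, organoid values average (unweighted) to
a condition/timepoint mean with SEM = σ/√N — and resolve spatially in 10-µm
depth bins (bin "5 µm" = [0, 10) µm; empty bins are excluded). A
median-centered Levene (Brown–Forsythe) test gates a pooled two-sample
t-test for condition comparisons.

A seeded synthetic **phantom generator** produces 3D stacks of densely
packed ellipsoidal nuclei with a nuclear-density gap between two layers,
cytoplasmic reporter rinds with strongly varying per-cell brightness,
residual depth gain, PSF blur and Poisson+Gaussian noise — with exact
ground truth, so every pipeline stage is testable without microscope data.

## Worked example

Entirely synthetic: generate a phantom whose true per-cell transduction
probability is 0.8, train the pixel classifier from annotations drawn at
25/50/75 µm, and run the shell classification:

```r
library(shellcount)

ph  <- generate_phantom(phantom_config(n_nuclei = 300L,
                                       transduction_prob = 0.8, seed = 42L))
ann <- annotate_phantom_planes(ph, planes_um = c(25, 50, 75), seed = 42L)
seg <- segment_reporter_channel(ph$reporter_channel, ann, seed = 42L)
res <- classify_cells(ph$labels, seg$mask)

res$efficiency
#> # A tibble: 1 × 3
#>    N_Td N_Tot     E
#>   <int> <int> <dbl>
#> 1    43    57 0.754

res$stage_counts
#>    input_nuclei volume_filtered  shell_filtered      transduced
#>             300              57              57              43
```

Of the 300 placed nuclei, 57 pass the > 100 µm³ nuclear volume filter (the
generator draws ~5 µm nuclei, most of which are below 100 µm³) and all 57
shells pass the size filter; 43 classify as transduced, so E = 0.754. The
ground-truth transduced fraction among those same 57 cells is 0.7544 — the
pipeline reproduces it exactly up to per-cell agreement. The depth profile
of the same run:

```r
depth_profile(res$cells)
#> # A tibble: … bin_center_um  N_Td N_Tot     E
#> 1                         5     5     5 1
#> 2                        15     3     6 0.5
#> 3                        25     3     4 0.75
#> 4                        35     2     3 0.667
```

`plot_depth_profile()`, `plot_threshold_sweep()` and
`plot_efficiency_timecourse()` render the standard figures;
`calibrate_threshold()` reproduces the manual-count threshold sweep;
`run_pipeline()` drives everything from a manifest CSV, and
`inst/cli/shellcount` exposes segment/classify/quantify/phantom/run
subcommands for shell use.

## Method details

See the methods vignette (`vignettes/shell-quantification.Rmd`) for the
model, its assumptions, all tunable parameters with defaults, what the
phantom does and does not emulate, and known limitations.
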