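---
title: "Shell-based quantification of transduction efficiency in 3D tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shell-based quantification of transduction efficiency in 3D tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shellcount)
```

## The measurement model

A living organoid is imaged as a two-channel confocal stack: a nuclear stain
and a cytoplasmic fluorescent reporter expressed only by transduced cells.
The quantity of interest is the transduction efficiency

$$E = N_{Td} / N_{Tot},$$

the fraction of cells expressing the reporter. Two obstacles make the naive
approach — segment every cell's cytoplasm and measure its intensity —
unreliable in dense neural tissue: cells are tightly packed with little
cytoplasm between nuclei, and per-cell expression levels span orders of
magnitude, so intensity is not a per-cell indicator.

`shellcount` sidesteps both. Nuclei, which a deep-learning instance
segmenter handles well even in dense tissue, define the cell population.
The reporter channel is segmented *semantically* (transduced volume vs
background) rather than per cell. The per-cell decision is then purely
geometric: a thin **virtual shell** around each nucleus samples the
perinuclear cytoplasm, and the cell is called transduced when the fraction
of its shell inside the transduced volume reaches a threshold.

Assumptions worth stating explicitly:

* Reporter fluorescence is cytoplasmic, so it surrounds the nucleus of an
  expressing cell; a nuclear-localised reporter would need a different
  overlap region.
* Nuclear segmentation errors propagate: a merged pair of nuclei becomes a
  single cell, a missed nucleus is not counted. `degrade_labels()` exists to
  probe this sensitivity.
* The shell threshold is a *calibrated* constant, not a universal one: it
  absorbs shell thickness, cytoplasm thickness and packing density, and is
  set once against manual counting (`calibrate_threshold()`); tissues with
  different cell density may need recalibration.

## Pipeline stages and parameters

| Stage | Parameter (unit) | Default | Role |
|---|---|---|---|
| Binning | block size | 2×2×2 mean | variance reduction before nuclear segmentation |
| Denoising | Gaussian diameter (µm) | 0.829 | speckle suppression; per-axis sigma = (d/2)/spacing |
| Pixel classifier | feature scales (µm) | 0.8, 2 | smoothed intensity, gradient magnitude, Laplacian per scale |
| | trees | 50 | probability random forest, fixed seed |
| | probability cut | 0.5 | voxels with P ≥ 0.5 retained |
| | min object (µm³) | 10 | components kept iff volume > 10 (strict) |
| Nuclei | instance band (µm³) | (10, ∞) | applied to segmenter output |
| | volume filter (µm³) | 100 | nuclei kept iff volume > 100 (strict) |
| Shells | dilation (voxels) | 2 | Euclidean ball, pixel units; ≈0.8 µm laterally on the 50%-binned grid |
| | min shell (µm³) | 50 human / 30 mouse | artifact removal; kept iff ≥ threshold |
| | overlap threshold | 0.4 | transduced iff fraction ≥ 0.4 |
| Profiles | bin width (µm) | 10 | half-open [10k, 10(k+1)) bins labelled by center |
| Statistics | alpha | 0.05 | Brown–Forsythe gate, pooled t-test |

All thresholds stated in µm³ are converted to voxel counts through the
stack's voxel geometry with `ceiling()`, and "larger than" is implemented
strictly: an object of exactly the threshold volume is removed. The overlap
comparator, by contrast, is inclusive (fraction = 0.4 classifies as
transduced), and the shell size filter keeps shells at exactly its
threshold. These boundary conventions are fixed, documented in each
function, and covered by tests.

## The shell construction

Each nucleus label is dilated by a discrete Euclidean ball of radius 2
voxels and the union of all *undilated* nuclei is subtracted. Two choices
are deliberate:

* **Pixel-unit dilation.** The dilation is defined in voxels, not µm, so the
  shell is anisotropic on anisotropic grids. This matches how the
  morphological operation is specified in practice; a physically specified
  dilation (`dilation_um`) is available as an extension.
* **Exclusive ownership.** In dense tissue dilations collide. Contested
  voxels are assigned to the label whose nucleus is nearest (Euclidean
  distance to the nearest nucleus voxel), with ties going to the smaller
  label id. This makes shells pairwise disjoint, so every transduced-volume
  voxel is counted toward at most one cell and `N_Td` is well defined. The
  alternative — overlapping shells — would double-count boundary signal
  between adjacent cells.

The overlap fraction is normalised by the shell's *own* voxel count, the
only normalisation under which a single dimensionless threshold applies to
cells of different sizes. Equivalence of the compiled implementation with an
exhaustive per-voxel nearest-nucleus computation is asserted on dozens of
random small volumes in the test suite.

## The pixel classifier

The reporter channel is segmented by a probability random forest over
multiscale features (Gaussian-smoothed intensity, gradient magnitude,
Laplacian at 0.8 and 2 µm), trained from sparse annotations: a few hundred
voxels marked transduced/background on three planes (25, 50, 75 µm deep),
deliberately covering both dim and bright cells. Training at several depths
is what makes the classifier robust to residual depth-dependent gain — no
explicit gain correction is applied, because acquisition already ramps
illumination with depth and the classifier absorbs what remains. The forest
is seeded, single-threaded and bit-reproducible; prediction uses a compiled
evaluator of the flattened trees that is exactly equal to the forest's own
prediction (asserted in tests).

## Aggregation and statistics

Area efficiencies are *not* pooled cell counts: each imaged area's E is
averaged to its organoid's E, and organoid values are averaged unweighted
to the condition/timepoint mean. This treats each organoid as one
biological replicate regardless of how many cells or areas it contributed;
the tests construct a case where pooled and hierarchical values differ and
pin the hierarchy. Dispersion uses the unbiased (N−1) SD; SEM = SD/√N over
organoids and is reported as missing (not zero) for a single organoid.
Depth profiles apply the same hierarchy per 10-µm bin, and bins without
cells are excluded from averaging rather than imputed.

Condition comparisons use a median-centered Levene test (Brown–Forsythe:
one-way ANOVA on absolute deviations from group medians) as the
equal-variance gate, then a pooled-variance two-sided t-test. Significance
stars: `n.s.` p > 0.05, `**` p ≤ 0.01, `******` p ≤ 10⁻⁶; the conventional
`*` tier (p ≤ 0.05) is included for completeness. Degenerate inputs (zero
pooled variance) short-circuit to p = 1 (equal means) or p = 0 (flagged)
instead of erroring.

The normalisation of depth profiles is genuinely underdetermined; the
default divides each unit's bins by its whole-stack pooled efficiency, with
`max-bin` and `none` as alternatives, and the chosen mode is recorded in
the output's metadata. None of the modes should be treated as canonical.

## Threshold calibration

`calibrate_threshold()` mirrors the manual-count comparison: three
annotators count transduced and total cells on extracted 2D planes; the
software plane population is defined as the cells whose shells intersect
that plane (the closest 3D analogue of "cells visible in this plane"). The
chosen overlap threshold minimises the mean absolute deviation between
software and manual efficiencies over the upper (25 µm) and center (50 µm)
planes — the deepest plane is noisier for human annotation and is used as a
held-out check rather than for fitting. Ties go to the larger, more
conservative threshold. Whether calibration should match the two planes
jointly (as here) or separately is ambiguous in principle; the joint mean
is the single-number criterion and the full sweep table is always emitted
so the choice is auditable.

## The phantom generator

`generate_phantom()` emulates the standardized acquisition: a
(211 × 211 × 100) µm³ field, ellipsoidal nuclei of 5 ± 1 µm diameter placed
by dart throwing with a 1 µm minimum gap, a 4 µm nucleus-free gap at 40 µm
depth separating two layers with independently settable transduction
probabilities, a 1.5 µm cytoplasmic rind per transduced cell filled with
per-cell brightness from a bimodal model (35 % dim cells at mean 300
counts, bright cells at 3000, lognormal σ = 0.4 within class), ±15 %
residual linear depth gain, 0.4 µm Gaussian PSF, and Poisson + Gaussian
noise. Truth volumes (labels, transduced mask, per-cell table) are
noise-free, and identical config + seed gives bit-identical output without
touching the caller's RNG state.

What the phantom does *not* emulate — and hence what passing tests do not
demonstrate about real data: optical anisotropy of the PSF and its depth
dependence, spectral crosstalk between channels, nuclear segmentation
errors (nuclei labels are exact unless degraded explicitly), non-ellipsoidal
nuclear shapes, spatially correlated background (autofluorescence, debris),
and cell-type-dependent expression. Classifier performance on phantoms is
therefore an upper bound; the controls (0 % and 100 %) and the calibration
procedure are the bridge to real stacks.

One interaction deserves emphasis: with 5 ± 1 µm nuclei most instances fall
below the 100 µm³ nuclear volume filter, so only the larger tail of the
population (roughly a fifth) is counted. Because the generator assigns
transduction independently of nuclear size, the surviving subpopulation's
true transduced fraction is an unbiased estimate of the configured
probability, and recovery tests compare against the configured value — at
correspondingly reduced cell numbers per stack.

## Problem sizes and numerical choices

The packaged tests and the acceptance script run at 256 × 256 × 100 voxels
(0.82 × 0.82 × 1.0 µm sampling of the standard field) with 200–500 nuclei
per stack — large enough that every stage (three annotated planes, layered
profiles, shell collisions) is exercised, small enough that the full
parameter-recovery study (3 fractions × 10 seeds, full pipeline including
classifier training) completes in a few minutes. Unit tests use 64³-scale
volumes and exhaustive oracles on ≤ 32³ volumes.

Other numerical conventions: arrays are `[z, y, x]` with plane 1 the
shallowest; coordinates are 0-based voxel centers, a cell's depth is its
centroid z index × dz; Gaussian kernels are truncated at 3σ and normalised;
50 % binning is block *mean* (not subsampling), chosen as the
variance-reducing reading of a denoise-then-segment pipeline; moment-based
ellipsoid semi-axes use the factor √5·√eigenvalue, which exactly reproduces
a uniform solid ellipsoid's second moments (the ellipsoids are QC and
rendering artifacts only — classification never uses them); degenerate
(coplanar) voxel sets fall back to a one-spacing floor and are flagged; the
upper nuclear band bound is +∞ by default, treating the nominal upper bound
of the instance filter as unbounded.

## Known limitations

* Label volumes are stored as 16-bit TIFF (≤ 65 535 instances per stack).
* The classifier is a generic stand-in for proprietary annotation-trained
  segmenters; parity with any specific tool can only be checked behaviorally
  (controls, manual comparison), not reproduced bit-for-bit.
* Shell ownership for contested voxels is a modelling decision; different
  exclusivity rules shift overlap fractions slightly in very dense tissue,
  which is one reason the overlap threshold is calibrated rather than fixed
  a priori.
* No multiple-testing correction is applied to pairwise condition tests,
  and repeated measures across timepoints are not modelled.
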