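#' Build the virtual shell around every nucleus
#'
#' Each nucleus is dilated by a discrete Euclidean ball of `dilation_voxels`
#' voxels (default 2; on a 50%-binned lateral grid of 0.412 µm this is the
#' nominal 0.8 µm shell thickness) and the union of all undilated nuclei is
#' subtracted, leaving a thin rind per cell that samples the perinuclear
#' cytoplasm. In dense tissue dilations collide: contested voxels are owned by
#' the label whose nucleus is nearest (Euclidean distance in voxel units),
#' ties going to the smaller label id, so shells are pairwise disjoint and a
#' shell never contains any nucleus voxel of any cell.
#'
#' @param nuclei A [label_volume()] of (volume-filtered) nuclei.
#' @param dilation_voxels Ball radius in voxels (>= 1). Anisotropy is not
#'   corrected: the dilation is defined in pixel units. For a physically
#'   specified shell use `dilation_um` instead.
#' @param dilation_um Optional physical radius; converted per-stack as
#'   `round(dilation_um / min(dx, dy, dz))` voxels.
#' @return A [label_volume()] of shells carrying the nucleus ids.
#' @export
build_shells <- function(nuclei, dilation_voxels = 2L, dilation_um = NULL) {
  stopifnot(inherits(nuclei, "label_volume"))
  if (!is.null(dilation_um)) {
    g <- nuclei$geometry
    dilation_voxels <- max(1L, as.integer(round(dilation_um / min(g$dx, g$dy, g$dz))))
  }
  dilation_voxels <- as.integer(dilation_voxels)
  if (dilation_voxels < 1L) stop("`dilation_voxels` must be >= 1", call. = FALSE)
  d <- dim(nuclei$data)
  sh <- cpp_build_shells(as.vector(nuclei$data), d[1], d[2], d[3], dilation_voxels)
  label_volume(array(sh, d), nuclei$geometry)
}

#' Remove artifact shells below a minimal physical size
#'
#' Shells smaller than `min_shell_um3` (default 50 µm³ for human organoid
#' tissue; 30 µm³ for mouse) are artifacts of truncated or clipped nuclei and
#' are removed; their nuclei are excluded from the total cell count. The
#' nuclei-to-shells count ratio is reported as a diagnostic and should be ~1.
#'
#' @param shells Shell [label_volume()] from [build_shells()].
#' @param min_shell_um3 Shells with volume < this are removed.
#' @param n_nuclei Optional nucleus count used for the ratio diagnostic.
#' @return A list: `shells` (filtered [label_volume()]), `surviving_ids`,
#'   `nuclei_to_shells_ratio` (`NA` if `n_nuclei` not given).
#' @export
filter_shells <- function(shells, min_shell_um3 = 50, n_nuclei = NULL) {
  stopifnot(inherits(shells, "label_volume"), min_shell_um3 >= 0)
  st <- label_stats(shells)
  vol <- st$voxel_count * shells$geometry$voxel_volume
  keep <- vol >= min_shell_um3
  out <- drop_labels(shells, st$label_id[!keep])
  if (!any(keep)) warning("no shells pass the size filter")
  ratio <- if (is.null(n_nuclei)) NA_real_ else n_nuclei / max(sum(keep), 1L)
  if (!is.na(ratio) && is.finite(ratio) && abs(ratio - 1) > 0.1) {
    warning(sprintf("nuclei-to-shells ratio %.3f deviates from 1; check shell size threshold",
                    ratio))
  }
  list(shells = out, surviving_ids = st$label_id[keep],
       nuclei_to_shells_ratio = ratio)
}

#' Per-shell overlap with the transduced volume
#'
#' Exact integer counting of `|shell intersect mask|` per shell label; the
#' overlap fraction is normalised by the shell's own voxel count, so it is a
#' dimensionless value in \[0, 1\] per cell.
#'
#' @param shells Shell [label_volume()].
#' @param transduced A [binary_mask()] of the segmented transduced volume
#'   (same shape).
#' @return A tibble of shell records: `label_id`, `shell_voxel_count`,
#'   `shell_volume_um3`, `overlap_voxels`, `overlap_fraction`.
#' @export
overlap_fractions <- function(shells, transduced) {
  stopifnot(inherits(shells, "label_volume"), inherits(transduced, "binary_mask"))
  assert_same_shape(shells, transduced)
  st <- label_stats(shells)
  if (nrow(st) == 0L) {
    return(tibble::tibble(label_id = integer(), shell_voxel_count = integer(),
                          shell_volume_um3 = numeric(), overlap_voxels = integer(),
                          overlap_fraction = numeric()))
  }
  inside <- shells$data[transduced$data]
  inside <- inside[inside > 0L]
  ov <- table(factor(inside, levels = st$label_id))
  tibble::tibble(
    label_id = st$label_id,
    shell_voxel_count = st$voxel_count,
    shell_volume_um3 = st$voxel_count * shells$geometry$voxel_volume,
    overlap_voxels = as.integer(ov),
    overlap_fraction = as.integer(ov) / st$voxel_count
  )
}

#' Classify cells by shell overlap
#'
#' A cell is transduced iff the fraction of its shell covered by the
#' transduced volume reaches the threshold (default 0.4, the value calibrated
#' against manual counting; the comparator is `>=`, so a fraction of exactly
#' 0.4 classifies as transduced).
#'
#' @param records Shell records from [overlap_fractions()].
#' @param threshold Overlap fraction threshold in \[0, 1\].
#' @return The records tibble with a logical `transduced` column. `N_Tot` is
#'   `nrow(records)` (cells surviving all filters), `N_Td` is
#'   `sum(transduced)`; see [efficiency_from_records()].
#' @export
classify_shells <- function(records, threshold = 0.4) {
  stopifnot(is.data.frame(records), threshold >= 0, threshold <= 1)
  dplyr::mutate(records, transduced = .data$overlap_fraction >= threshold)
}

#' Transduction efficiency of a set of classified records
#'
#' @param records Classified shell records (with a `transduced` column).
#' @return A one-row tibble: `N_Td`, `N_Tot`, `E`.
#' @export
efficiency_from_records <- function(records) {
  n_tot <- nrow(records)
  n_td <- sum(records$transduced)
  tibble::tibble(N_Td = n_td, N_Tot = n_tot,
                 E = efficiency(n_td, n_tot))
}

#' Full per-cell classification from nuclei labels and a transduced mask
#'
#' Runs the shell stage end to end: nuclear volume filter, shell
#' construction, shell size filter, overlap computation and classification.
#'
#' @param nuclei A [label_volume()] (raw segmenter output or phantom truth).
#' @param transduced A [binary_mask()] of the transduced volume.
#' @param min_nucleus_um3 Nuclear volume filter (keep > this), default 100 µm³.
#' @param dilation_voxels Shell dilation radius in voxels.
#' @param min_shell_um3 Shell size filter, default 50 µm³ (human tissue).
#' @param threshold Overlap threshold, default 0.4.
#' @return A list: `cells` (classified shell records joined with nucleus
#'   centroids/depths), `efficiency` (one-row tibble `N_Td`, `N_Tot`, `E`),
#'   `shells` (filtered shell [label_volume()]), `stage_counts` (named counts
#'   through the filter cascade), `nuclei_to_shells_ratio`.
#' @export
classify_cells <- function(nuclei, transduced, min_nucleus_um3 = 100,
                           dilation_voxels = 2L, min_shell_um3 = 50,
                           threshold = 0.4) {
  n_input <- nrow(label_stats(nuclei))
  filt <- filter_nuclei(nuclei, min_nucleus_um3)
  shells <- build_shells(filt$labels, dilation_voxels)
  sf <- filter_shells(shells, min_shell_um3, n_nuclei = nrow(filt$nuclei))
  rec <- overlap_fractions(sf$shells, transduced)
  rec <- classify_shells(rec, threshold)
  cells <- dplyr::inner_join(
    rec,
    dplyr::select(filt$nuclei, "label_id", "cx_um", "cy_um", "cz_um",
                  "depth_um", nucleus_voxel_count = "voxel_count",
                  nucleus_volume_um3 = "volume_um3"),
    by = "label_id"
  )
  eff <- efficiency_from_records(cells)
  list(
    cells = cells,
    efficiency = eff,
    shells = sf$shells,
    stage_counts = c(input_nuclei = n_input,
                     volume_filtered = nrow(filt$nuclei),
                     shell_filtered = nrow(cells),
                     transduced = eff$N_Td),
    nuclei_to_shells_ratio = sf$nuclei_to_shells_ratio
  )
}

#' Shell ids intersecting one imaging plane
#'
#' Defines the cell population of a 2D plane for comparison with manual
#' counting: the cells whose shells intersect that plane.
#'
#' @param shells Shell [label_volume()].
#' @param plane_z 1-based plane index.
#' @return Integer vector of shell label ids present in the plane.
#' @export
plane_shell_ids <- function(shells, plane_z) {
  stopifnot(plane_z >= 1L, plane_z <= dim(shells$data)[1])
  ids <- unique(as.vector(shells$data[plane_z, , ]))
  sort(ids[ids > 0L])
}
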