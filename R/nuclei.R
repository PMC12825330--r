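label_stats <- function(labels) {
  # per-label voxel counts and centroid voxel indices (1-based), fast path
  a <- labels$data
  d <- dim(a)
  idx <- which(a > 0L)
  if (length(idx) == 0L) {
    return(tibble::tibble(label_id = integer(), voxel_count = integer(),
                          zc = numeric(), yc = numeric(), xc = numeric()))
  }
  lab <- a[idx]
  i0 <- idx - 1L
  z <- i0 %% d[1] + 1L
  y <- (i0 %/% d[1]) %% d[2] + 1L
  x <- i0 %/% (d[1] * d[2]) + 1L
  s <- rowsum(cbind(n = 1, z = z, y = y, x = x), lab)
  tibble::tibble(
    label_id = as.integer(rownames(s)),
    voxel_count = as.integer(s[, "n"]),
    zc = unname(s[, "z"] / s[, "n"]),
    yc = unname(s[, "y"] / s[, "n"]),
    xc = unname(s[, "x"] / s[, "n"])
  )
}

records_from_stats <- function(stats, geometry) {
  # physical coordinates: 0-based voxel centers, depth measured from plane 1
  tibble::tibble(
    label_id = stats$label_id,
    voxel_count = stats$voxel_count,
    volume_um3 = stats$voxel_count * geometry$voxel_volume,
    cx_um = (stats$xc - 1) * geometry$dx,
    cy_um = (stats$yc - 1) * geometry$dy,
    cz_um = (stats$zc - 1) * geometry$dz,
    depth_um = (stats$zc - 1) * geometry$dz
  )
}

drop_labels <- function(labels, drop_ids) {
  if (length(drop_ids) == 0L) return(labels)
  a <- labels$data
  a[a %in% drop_ids] <- 0L
  label_volume(a, labels$geometry)
}

#' Summarise an instance segmentation as one record per nucleus
#'
#' @param labels A [label_volume()].
#' @return A tibble: `label_id`, `voxel_count`, `volume_um3`, centroid
#'   `cx_um/cy_um/cz_um` (µm from the stack origin, 0-based voxel centers) and
#'   `depth_um` (= `cz_um`, distance from the first imaged plane).
#' @export
nucleus_records <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  records_from_stats(label_stats(labels), labels$geometry)
}

#' Volume-band filter applied at segmentation time
#'
#' Removes instances outside `(min_um3, max_um3]` — the band applied directly
#' to the segmenter output (default lower bound 10 µm³; the upper bound is
#' effectively unbounded by default).
#'
#' @param labels A [label_volume()].
#' @param min_um3 Instances must be strictly larger than this.
#' @param max_um3 Instances at most this large are kept.
#' @return The filtered [label_volume()].
#' @export
filter_nuclei_band <- function(labels, min_um3 = 10, max_um3 = Inf) {
  st <- label_stats(labels)
  vol <- st$voxel_count * labels$geometry$voxel_volume
  drop_labels(labels, st$label_id[vol <= min_um3 | vol > max_um3])
}

#' Nuclear volume filter before shell construction
#'
#' Nuclei not larger than `min_volume_um3` (default 100 µm³) are removed;
#' the survivors are the candidate cell population for shell construction
#' (the final total count additionally requires the shell size filter, see
#' [filter_shells()]).
#'
#' @param labels A [label_volume()].
#' @param min_volume_um3 Keep nuclei with volume strictly greater than this.
#' @return A list: `labels` (filtered [label_volume()]) and `nuclei` (tibble
#'   of surviving [nucleus_records()]).
#' @export
filter_nuclei <- function(labels, min_volume_um3 = 100) {
  stopifnot(inherits(labels, "label_volume"), min_volume_um3 >= 0)
  st <- label_stats(labels)
  vol <- st$voxel_count * labels$geometry$voxel_volume
  keep <- vol > min_volume_um3
  out <- drop_labels(labels, st$label_id[!keep])
  list(labels = out, nuclei = records_from_stats(st[keep, ], labels$geometry))
}

#' Moment-based minimal ellipsoid of one nucleus
#'
#' Center = centroid; axes = eigenvectors of the physical-coordinate
#' covariance; semi-axis_i = sqrt(5 * eigenvalue_i), the scaling under which a
#' uniform solid ellipsoid reproduces its own second moments. A degenerate
#' (coplanar or tiny) voxel set falls back to a floor of one voxel spacing on
#' the deficient axes and is flagged. Ellipsoids are rendering/QC artifacts;
#' classification never uses them.
#'
#' @param voxels Matrix of 1-based voxel indices, columns `z, y, x` (>= 4 rows
#'   for a proper fit).
#' @param geometry A [voxel_geometry()].
#' @return A list: `center_um` (x, y, z), `semi_axes_um` (descending),
#'   `axes` (3x3 orthonormal columns, rows ordered x, y, z), `degenerate`.
#' @export
fit_ellipsoid <- function(voxels, geometry) {
  assert_geometry(geometry)
  voxels <- as.matrix(voxels)
  if (ncol(voxels) != 3L || nrow(voxels) < 1L) {
    stop("`voxels` must be an n x 3 matrix of (z, y, x) indices", call. = FALSE)
  }
  # physical coordinates in (x, y, z) order
  p <- cbind(
    x = (voxels[, 3] - 1) * geometry$dx,
    y = (voxels[, 2] - 1) * geometry$dy,
    z = (voxels[, 1] - 1) * geometry$dz
  )
  center <- colMeans(p)
  floor_ax <- min(geometry$dx, geometry$dy, geometry$dz)
  if (nrow(p) < 4L) {
    return(list(center_um = center,
                semi_axes_um = rep(floor_ax, 3L),
                axes = diag(3), degenerate = TRUE))
  }
  cv <- stats::cov(p) * (nrow(p) - 1) / nrow(p)   # population moments
  e <- eigen(cv, symmetric = TRUE)
  degenerate <- any(e$values < 1e-12)
  semi <- sqrt(5 * pmax(e$values, 0))
  semi[semi < floor_ax] <- floor_ax
  list(center_um = center, semi_axes_um = semi, axes = e$vectors,
       degenerate = degenerate)
}

#' Fit ellipsoids for every nucleus in a label volume
#'
#' @param labels A [label_volume()].
#' @return A tibble: `label_id`, semi-axes (descending), `degenerate` flag,
#'   plus centroid columns; axis matrices in a list column `axes`.
#' @export
nucleus_ellipsoids <- function(labels) {
  a <- labels$data
  d <- dim(a)
  idx <- which(a > 0L)
  lab <- a[idx]
  i0 <- idx - 1L
  vox <- cbind(z = i0 %% d[1] + 1L,
               y = (i0 %/% d[1]) %% d[2] + 1L,
               x = i0 %/% (d[1] * d[2]) + 1L)
  ids <- sort(unique(lab))
  purrr::map_dfr(ids, function(id) {
    fit <- fit_ellipsoid(vox[lab == id, , drop = FALSE], labels$geometry)
    tibble::tibble(
      label_id = id,
      cx_um = fit$center_um[["x"]], cy_um = fit$center_um[["y"]],
      cz_um = fit$center_um[["z"]],
      a_um = fit$semi_axes_um[1], b_um = fit$semi_axes_um[2],
      c_um = fit$semi_axes_um[3],
      degenerate = fit$degenerate,
      axes = list(fit$axes)
    )
  })
}

#' Adapter for an external deep-learning nuclear segmenter
#'
#' The pipeline takes its nuclear instance segmentation from an external tool
#' (Cellpose-style; typical settings: 50% binning, 0.829 µm Gaussian
#' denoising, estimated diameter 5 µm, flow threshold 1.0, mask inclusion
#' threshold -6). This adapter passes those settings to a user-supplied runner
#' and applies the instance volume-band filter to the result. When no runner
#' is available the pipeline is still fully usable with precomputed label
#' volumes ([read_labels()]).
#'
#' @param vol Nuclear-channel [intensity_volume()].
#' @param settings Named list passed through to the runner.
#' @param runner Function `(vol, settings) -> label_volume`; `NULL` when no
#'   external segmenter is installed.
#' @param band_um3 Length-2 instance volume band applied to the output.
#' @return A [label_volume()].
#' @export
cellpose_adapter <- function(vol, settings = list(diameter_um = 5, flow_threshold = 1,
                                                  cellprob_threshold = -6),
                             runner = NULL, band_um3 = c(10, Inf)) {
  if (is.null(runner)) {
    stop(paste0("no external nuclear segmenter is configured; supply a `runner` ",
                "function or provide precomputed labels via read_labels()"),
         call. = FALSE)
  }
  labels <- runner(vol, settings)
  stopifnot(inherits(labels, "label_volume"))
  filter_nuclei_band(labels, band_um3[1], band_um3[2])
}
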