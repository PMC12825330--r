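#' Physical voxel calibration
#'
#' Binds voxel indices to physical micrometres. All stacks in a pipeline run
#' carry one of these; every physical threshold (object volumes, shell sizes,
#' depth bins) is converted through it.
#'
#' @param dx,dy,dz Micrometres per voxel along x, y and z. All must be
#'   strictly positive. The z spacing is the distance between consecutive
#'   imaging planes.
#' @return A `voxel_geometry` object: a named list with `dx`, `dy`, `dz` and
#'   the derived `voxel_volume` (µm³).
#' @examples
#' # the standard confocal sampling: 1024 x 1024 x 400 voxels over
#' # (211 x 211 x 100) µm³
#' voxel_geometry(dx = 211 / 1024, dy = 211 / 1024, dz = 100 / 400)
#' @export
voxel_geometry <- function(dx, dy, dz) {
  for (v in c(dx = dx, dy = dy, dz = dz)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("voxel spacings dx, dy, dz must be single positive numbers", call. = FALSE)
    }
  }
  structure(
    list(dx = dx, dy = dy, dz = dz, voxel_volume = dx * dy * dz),
    class = "voxel_geometry"
  )
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf(
    "<voxel_geometry> dx = %.4f, dy = %.4f, dz = %.4f um; voxel volume %.6f um^3\n",
    x$dx, x$dy, x$dz, x$voxel_volume
  ))
  invisible(x)
}

is_voxel_geometry <- function(x) inherits(x, "voxel_geometry")

assert_geometry <- function(geometry) {
  if (!is_voxel_geometry(geometry)) {
    stop("`geometry` must be a voxel_geometry object", call. = FALSE)
  }
  geometry
}

#' Convert a physical volume threshold to a voxel count
#'
#' Size filters are stated in µm³ but applied to voxel counts. The returned
#' count is `ceiling(threshold_um3 / voxel_volume)`; an object "larger than
#' T µm³" is kept iff `voxel_count * voxel_volume > T`, i.e. strictly greater.
#'
#' @param threshold_um3 Non-negative physical volume in µm³.
#' @param geometry A [voxel_geometry()].
#' @return An integer voxel count.
#' @export
um3_to_voxels <- function(threshold_um3, geometry) {
  assert_geometry(geometry)
  if (!is.numeric(threshold_um3) || any(threshold_um3 < 0)) {
    stop("`threshold_um3` must be non-negative", call. = FALSE)
  }
  as.integer(ceiling(threshold_um3 / geometry$voxel_volume))
}

#' Halve the resolution of an intensity volume (50% binning)
#'
#' 2x2x2 block-mean downsampling, the variance-reducing preprocessing applied
#' before nuclear segmentation. Voxel spacings double; odd trailing planes,
#' rows and columns are dropped.
#'
#' @param vol An [intensity_volume()] whose every axis has length >= 2.
#' @return An [intensity_volume()] at half resolution.
#' @export
bin_volume_50pct <- function(vol) {
  stopifnot(inherits(vol, "intensity_volume"))
  d <- dim(vol$data)
  if (any(d < 2L)) {
    stop("every axis must have length >= 2 to bin by 50%", call. = FALSE)
  }
  h <- d %/% 2L
  a <- vol$data[seq_len(2L * h[1]), seq_len(2L * h[2]), seq_len(2L * h[3]), drop = FALSE]
  iz <- seq(1L, 2L * h[1], by = 2L)
  iy <- seq(1L, 2L * h[2], by = 2L)
  ix <- seq(1L, 2L * h[3], by = 2L)
  out <- (a[iz, iy, ix, drop = FALSE] + a[iz + 1L, iy, ix, drop = FALSE] +
          a[iz, iy + 1L, ix, drop = FALSE] + a[iz, iy, ix + 1L, drop = FALSE] +
          a[iz + 1L, iy + 1L, ix, drop = FALSE] + a[iz + 1L, iy, ix + 1L, drop = FALSE] +
          a[iz, iy + 1L, ix + 1L, drop = FALSE] + a[iz + 1L, iy + 1L, ix + 1L, drop = FALSE]) / 8
  g <- vol$geometry
  intensity_volume(out, voxel_geometry(2 * g$dx, 2 * g$dy, 2 * g$dz),
                   channel_name = vol$channel_name)
}
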