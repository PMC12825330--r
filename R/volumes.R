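#' Image volume containers
#'
#' Three thin containers pair a 3D array with its physical calibration.
#' Arrays are always indexed `[z, y, x]`: z is the imaging-plane axis,
#' plane 1 is the shallowest (first imaged) plane.
#'
#' * `intensity_volume()` — a raw or processed scalar channel (non-negative).
#' * `label_volume()` — an instance segmentation: 0 is background, each
#'   positive integer one object. Ids need not be contiguous and no
#'   connectivity is enforced (upstream segmenters differ).
#' * `binary_mask()` — a logical volume, e.g. the segmented transduced volume.
#'
#' @param data A 3D array in `[z, y, x]` order (a matrix is promoted to a
#'   single-plane volume).
#' @param geometry A [voxel_geometry()].
#' @param channel_name Optional channel label carried through processing.
#' @return An object of the corresponding class wrapping `data` and `geometry`.
#' @name volumes
NULL

as_vol_array <- function(data) {
  if (is.matrix(data)) dim(data) <- c(1L, dim(data))
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array in (z, y, x) order", call. = FALSE)
  }
  data
}

#' @rdname volumes
#' @export
intensity_volume <- function(data, geometry, channel_name = "channel") {
  data <- as_vol_array(data)
  assert_geometry(geometry)
  if (any(data < 0)) stop("intensity values must be non-negative", call. = FALSE)
  structure(list(data = data, geometry = geometry, channel_name = channel_name),
            class = "intensity_volume")
}

#' @rdname volumes
#' @export
label_volume <- function(data, geometry) {
  data <- as_vol_array(data)
  assert_geometry(geometry)
  if (any(data < 0) || any(data != trunc(data))) {
    stop("labels must be non-negative integers", call. = FALSE)
  }
  storage.mode(data) <- "integer"
  structure(list(data = data, geometry = geometry), class = "label_volume")
}

#' @rdname volumes
#' @export
binary_mask <- function(data, geometry) {
  data <- as_vol_array(data)
  assert_geometry(geometry)
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1))) {
      stop("mask values must be logical or 0/1", call. = FALSE)
    }
    data <- array(as.logical(data), dim(data))
  }
  structure(list(data = data, geometry = geometry), class = "binary_mask")
}

vol_dims <- function(vol) dim(vol$data)

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<intensity_volume '%s'> %d x %d x %d (z,y,x), range [%.3g, %.3g]\n",
              x$channel_name, d[1], d[2], d[3], min(x$data), max(x$data)))
  print(x$geometry)
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  ids <- setdiff(unique(as.vector(x$data)), 0L)
  cat(sprintf("<label_volume> %d x %d x %d (z,y,x), %d instances\n",
              d[1], d[2], d[3], length(ids)))
  print(x$geometry)
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d (z,y,x), %d foreground voxels (%.2f%%)\n",
              d[1], d[2], d[3], sum(x$data), 100 * mean(x$data)))
  invisible(x)
}

assert_same_shape <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) {
    stop(sprintf("volume shapes differ: (%s) vs (%s)",
                 paste(dim(a$data), collapse = ","),
                 paste(dim(b$data), collapse = ",")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Label the connected components of a binary mask
#'
#' 26-connected component labelling in 3D (the most permissive connectivity:
#' voxels sharing a face, edge or corner are connected, so thin cytoplasmic
#' structures are not split).
#'
#' @param mask A [binary_mask()].
#' @return A [label_volume()] with components numbered from 1 in scan order.
#' @export
label_components <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$data)
  lab <- cpp_label_components(as.vector(mask$data), d[1], d[2], d[3])
  label_volume(array(lab, d), mask$geometry)
}
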