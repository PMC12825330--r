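#' Read a 3D stack from TIFF / OME-TIFF
#'
#' Pages become the z axis (first imaged plane = plane 1); the returned array
#' is `[z, y, x]`. Voxel spacing is resolved, in order of precedence, from
#' OME `PhysicalSizeX/Y/Z` metadata in the ImageDescription tag, from a
#' `<path>.geometry.yaml` sidecar written by [write_stack()], or from
#' `override_geometry`.
#'
#' @param path Path to a single- or multi-page TIFF/OME-TIFF.
#' @param override_geometry Optional [voxel_geometry()] used when the file
#'   carries no calibration metadata.
#' @param channel_name Channel label attached to the result.
#' @return An [intensity_volume()].
#' @export
read_stack <- function(path, override_geometry = NULL, channel_name = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read stack: no such file '%s'", path), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- read_pages_to_array(pages)
  geometry <- resolve_geometry(path, pages, override_geometry)
  intensity_volume(arr, geometry,
                   channel_name = channel_name %||% tools::file_path_sans_ext(basename(path)))
}

read_pages_to_array <- function(pages) {
  d2 <- dim(pages[[1]])
  if (length(d2) == 3L) {           # multi-sample page: keep first sample
    pages <- lapply(pages, function(p) p[, , 1])
    d2 <- dim(pages[[1]])
  }
  arr <- array(0, dim = c(length(pages), d2[1], d2[2]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  arr
}

resolve_geometry <- function(path, pages, override_geometry) {
  desc <- attr(pages[[1]], "description")
  g <- if (!is.null(desc)) parse_physical_sizes(desc) else NULL
  if (is.null(g)) {
    sidecar <- paste0(path, ".geometry.yaml")
    if (file.exists(sidecar)) {
      y <- yaml::read_yaml(sidecar)
      g <- voxel_geometry(y$dx, y$dy, y$dz)
    }
  }
  if (is.null(g)) g <- override_geometry
  if (is.null(g)) {
    stop(paste0("no voxel calibration: file carries no PhysicalSizeX/Y/Z metadata ",
                "and no sidecar; supply `override_geometry` (dx, dy, dz in um)"),
         call. = FALSE)
  }
  assert_geometry(g)
}

#' Parse OME PhysicalSize voxel spacings from an ImageDescription string
#'
#' @param description The TIFF ImageDescription text (typically OME-XML).
#' @return A [voxel_geometry()] or `NULL` when any of the three sizes is absent.
#' @export
parse_physical_sizes <- function(description) {
  grab <- function(axis) {
    m <- regmatches(description,
                    regexpr(sprintf('PhysicalSize%s\\s*=\\s*"[0-9.eE+-]+"', axis),
                            description))
    if (length(m) == 0L) return(NULL)
    as.numeric(sub('.*"([0-9.eE+-]+)"', "\\1", m))
  }
  px <- grab("X"); py <- grab("Y"); pz <- grab("Z")
  if (is.null(px) || is.null(py) || is.null(pz)) return(NULL)
  voxel_geometry(px, py, pz)
}

#' Write a volume to multi-page TIFF
#'
#' Intensity volumes are stored as 16-bit unsigned integers (values must be
#' integers in 0..65535, the native confocal range), label volumes as 16-bit
#' ids (<= 65535 instances per stack), masks as 8-bit 0/1. Geometry is written
#' to a `<path>.geometry.yaml` sidecar so round trips need no override.
#'
#' @param vol An [intensity_volume()], [label_volume()] or [binary_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(vol, path) {
  a <- vol$data
  if (inherits(vol, "binary_mask")) {
    pages <- lapply(seq_len(dim(a)[1]), function(z) a[z, , ] / 255)
    bits <- 8L
  } else {
    if (any(a != trunc(a)) || max(a) > 65535) {
      stop("stored volumes must hold integers in 0..65535", call. = FALSE)
    }
    pages <- lapply(seq_len(dim(a)[1]), function(z) a[z, , ] / 65535)
    bits <- 16L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none",
                  reduce = FALSE)
  g <- vol$geometry
  yaml::write_yaml(list(dx = g$dx, dy = g$dy, dz = g$dz),
                   paste0(path, ".geometry.yaml"))
  invisible(path)
}

#' Read an instance-label volume from TIFF
#'
#' @inheritParams read_stack
#' @return A [label_volume()].
#' @export
read_labels <- function(path, override_geometry = NULL) {
  v <- read_stack(path, override_geometry)
  label_volume(v$data, v$geometry)
}

#' Read a binary transduced mask from TIFF
#'
#' Any strictly positive stored value is foreground.
#'
#' @inheritParams read_stack
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, override_geometry = NULL) {
  v <- read_stack(path, override_geometry)
  binary_mask(v$data > 0, v$geometry)
}

#' Read an experiment manifest
#'
#' The manifest maps each imaged stack to its place in the experimental
#' hierarchy: `stack_id, organoid_id, condition, timepoint, area_index,
#' include, reason`. `(organoid_id, area_index, timepoint)` must be unique and
#' every excluded record must carry a reason (stacks are dropped e.g. when
#' non-retinal tissue grew into the imaged volume).
#'
#' @param path CSV file with a header row.
#' @return A tibble with one row per stack, `include` as logical.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("stack_id", "organoid_id", "condition", "timepoint",
                "area_index", "include", "reason")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0L) {
    stop(sprintf("manifest lacks column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  m <- tibble::as_tibble(m)
  m$include <- as.logical(m$include)
  validate_manifest(m)
}

validate_manifest <- function(m) {
  key <- paste(m$organoid_id, m$area_index, m$timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    stop("manifest keys (organoid_id, area_index, timepoint) must be unique",
         call. = FALSE)
  }
  bad <- !m$include & (is.na(m$reason) | m$reason == "")
  if (any(bad)) {
    stop(sprintf("excluded manifest record(s) without a reason: %s",
                 paste(m$stack_id[bad], collapse = ", ")), call. = FALSE)
  }
  m
}

#' Read sparse voxel annotations
#'
#' Annotations for the transduced-channel pixel classifier, drawn on a few
#' planes (typically 25, 50 and 75 µm depth) in both dim and bright regions.
#' Two forms are accepted:
#'
#' * CSV with columns `z, y, x, label` (1-based voxel indices; label one of
#'   `"transduced"`/`"background"` or `2`/`1`),
#' * paint-style uint8 TIFF: 0 unlabeled, 1 background, 2 transduced.
#'
#' @param path Annotation file (.csv or .tif/.tiff).
#' @param geometry Geometry of the annotated stack (used for depth reporting
#'   and TIFF reading).
#' @return A `sparse_annotation`: tibble of `z, y, x, label` plus the set of
#'   annotated plane depths (µm) as attribute `plane_depths_um`.
#' @export
read_annotations <- function(path, geometry) {
  assert_geometry(geometry)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    a <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
    stopifnot(all(c("z", "y", "x", "label") %in% names(a)))
    if (is.numeric(a$label)) {
      a$label <- c("background", "transduced")[a$label]
    }
  } else {
    paint <- read_stack(path, override_geometry = geometry)$data
    idx <- which(paint > 0, arr.ind = TRUE)
    a <- tibble::tibble(z = idx[, 1], y = idx[, 2], x = idx[, 3],
                        label = c("background", "transduced")[paint[idx]])
  }
  sparse_annotation(a, geometry)
}

#' Build a sparse annotation from a coordinate table
#'
#' @param coords Tibble/data frame with `z, y, x` (1-based voxel indices) and
#'   `label` in `{"transduced", "background"}`.
#' @param geometry The annotated stack's [voxel_geometry()].
#' @return A `sparse_annotation` tibble.
#' @export
sparse_annotation <- function(coords, geometry) {
  assert_geometry(geometry)
  coords <- tibble::as_tibble(coords)[, c("z", "y", "x", "label")]
  if (!all(coords$label %in% c("transduced", "background"))) {
    stop("annotation labels must be 'transduced' or 'background'", call. = FALSE)
  }
  if (length(unique(coords$label)) < 2L) {
    stop("annotations must contain both classes", call. = FALSE)
  }
  structure(coords,
            class = c("sparse_annotation", class(coords)),
            plane_depths_um = sort(unique((coords$z - 1) * geometry$dz)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
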