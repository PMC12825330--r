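#' Configuration of the synthetic organoid phantom
#'
#' The phantom emulates a confocal stack of dense neural tissue: ellipsoidal
#' nuclei of ~5 µm diameter packed with a minimal gap, a nuclear-density gap
#' at a configurable depth separating two layers (outer/inner nuclear layer),
#' a cytoplasmic reporter rind around each transduced cell with strongly
#' varying per-cell brightness (bimodal dim/bright, lognormal within class),
#' residual depth-dependent gain, Gaussian PSF blur and Poisson-plus-Gaussian
#' noise on the intensity channels. Truth volumes are noise-free.
#'
#' @param volume_shape Stack shape `(nz, ny, nx)` in voxels.
#' @param geometry A [voxel_geometry()]. The default samples a
#'   (211 x 211 x 100) µm³ field at 256 x 256 x 100 voxels.
#' @param n_nuclei Number of nuclei to place (dart throwing with rejection;
#'   partial placement with a warning when the density is infeasible).
#' @param nucleus_diameter_um Mean and SD of the nucleus diameter (µm).
#' @param packing_min_gap_um Minimal surface gap between nuclei (µm).
#' @param transduction_prob Per-layer transduction probabilities
#'   `c(upper, lower)`; a scalar applies to both layers.
#' @param layer_boundary_um Depth of the layer boundary (µm from plane 1).
#' @param layer_gap_um Width of the nucleus-free density gap at the boundary.
#' @param cytoplasm_um Thickness of the cytoplasmic reporter rind (µm).
#' @param dim_fraction Fraction of transduced cells with dim expression.
#' @param dim_mean,bright_mean Mean reporter intensity of dim/bright cells.
#' @param sigma_log Lognormal sigma of per-cell brightness within class.
#' @param nuclei_mean Mean intensity of the nuclear stain channel.
#' @param depth_gain Residual linear gain across depth (fractional swing,
#'   e.g. 0.3 means ±15% across the stack).
#' @param psf_sigma_um PSF sigma (µm) applied to intensity channels.
#' @param poisson_scale,gaussian_sd Noise model: intensities are Poisson
#'   resampled in units of `poisson_scale` counts, then Gaussian read noise
#'   of `gaussian_sd` is added.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(volume_shape = c(100L, 256L, 256L),
                           geometry = voxel_geometry(211 / 256, 211 / 256, 1),
                           n_nuclei = 500L,
                           nucleus_diameter_um = c(mean = 5, sd = 1),
                           packing_min_gap_um = 1,
                           transduction_prob = c(upper = 0.8, lower = 0.8),
                           layer_boundary_um = 40,
                           layer_gap_um = 4,
                           cytoplasm_um = 1.5,
                           dim_fraction = 0.35,
                           dim_mean = 300,
                           bright_mean = 3000,
                           sigma_log = 0.4,
                           nuclei_mean = 2000,
                           depth_gain = 0.3,
                           psf_sigma_um = 0.4,
                           poisson_scale = 4,
                           gaussian_sd = 30,
                           seed = 1L) {
  if (length(transduction_prob) == 1L) {
    transduction_prob <- c(upper = unname(transduction_prob),
                           lower = unname(transduction_prob))
  }
  stopifnot(all(transduction_prob >= 0), all(transduction_prob <= 1),
            length(volume_shape) == 3L, n_nuclei >= 1L)
  assert_geometry(geometry)
  structure(as.list(environment()), class = "phantom_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a synthetic organoid stack with ground truth
#'
#' @param config A [phantom_config()].
#' @return A `phantom` list: `nuclei_channel` and `reporter_channel`
#'   ([intensity_volume()], noisy), `labels` (truth [label_volume()]),
#'   `transduced_mask` (truth [binary_mask()] of all transduced cells'
#'   cytoplasm), `truth` (per-cell tibble: `label_id`, centroid, `volume_um3`,
#'   `layer`, `transduced`, `brightness_class`, `brightness`), and `config`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, build_phantom(config))
}

build_phantom <- function(cf) {
  g <- cf$geometry
  d <- as.integer(cf$volume_shape)
  sp <- c(g$dz, g$dy, g$dx)
  extent <- d * sp                       # (z, y, x) physical size

  # --- place nuclei by dart throwing ------------------------------------
  n <- cf$n_nuclei
  centers <- matrix(NA_real_, n, 3)      # (z, y, x) um
  radii <- matrix(NA_real_, n, 3)        # semi-axes um (unsorted)
  rots <- vector("list", n)
  max_r <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 200L * n
  gap_lo <- cf$layer_boundary_um - cf$layer_gap_um / 2
  gap_hi <- cf$layer_boundary_um + cf$layer_gap_um / 2
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    dia <- stats::rnorm(1, cf$nucleus_diameter_um[["mean"]],
                        cf$nucleus_diameter_um[["sd"]])
    if (dia < 2) next
    semi <- (dia / 2) * stats::runif(3, 0.85, 1.15)
    rmax <- max(semi)
    c_zyx <- stats::runif(3, min = rmax, max = extent - rmax)
    if (c_zyx[1] > gap_lo && c_zyx[1] < gap_hi) next      # density gap
    if (placed > 0L) {
      prev <- centers[seq_len(placed), , drop = FALSE]
      dist2 <- (prev[, 1] - c_zyx[1])^2 + (prev[, 2] - c_zyx[2])^2 +
               (prev[, 3] - c_zyx[3])^2
      min_sep <- (max_r[seq_len(placed)] + rmax + cf$packing_min_gap_um)^2
      if (any(dist2 < min_sep)) next
    }
    placed <- placed + 1L
    centers[placed, ] <- c_zyx
    radii[placed, ] <- semi
    rots[[placed]] <- random_rotation()
    max_r[placed] <- rmax
  }
  if (placed < n) {
    warning(sprintf("packing density infeasible: placed %d of %d nuclei",
                    placed, n))
    centers <- centers[seq_len(placed), , drop = FALSE]
    radii <- radii[seq_len(placed), , drop = FALSE]
    max_r <- max_r[seq_len(placed)]
    n <- placed
  }
  if (n == 0L) stop("could not place any nucleus", call. = FALSE)

  # --- per-cell truth ----------------------------------------------------
  layer <- ifelse(centers[, 1] < cf$layer_boundary_um, "upper", "lower")
  transduced <- stats::runif(n) < cf$transduction_prob[
    ifelse(layer == "upper", "upper", "lower")]
  brightness_class <- ifelse(stats::runif(n) < cf$dim_fraction, "dim", "bright")
  mu <- ifelse(brightness_class == "dim", cf$dim_mean, cf$bright_mean)
  brightness <- stats::rlnorm(n, meanlog = log(mu), sdlog = cf$sigma_log)

  # --- rasterize nuclei and cytoplasm rinds ------------------------------
  labels <- array(0L, d)
  reporter <- array(0, d)
  nuc_chan <- array(0, d)
  nuc_int <- stats::rlnorm(n, meanlog = log(cf$nuclei_mean), sdlog = 0.15)

  for (i in seq_len(n)) {
    ras <- rasterize_ellipsoid(centers[i, ], radii[i, ], rots[[i]], d, sp, 0)
    labels[ras] <- i
    nuc_chan[ras] <- nuc_int[i]
  }
  mask <- array(FALSE, d)
  for (i in which(transduced)) {
    rind <- rasterize_ellipsoid(centers[i, ], radii[i, ], rots[[i]], d, sp,
                                cf$cytoplasm_um)
    rind <- rind[labels[rind] == 0L]     # cytoplasm excludes every nucleus
    mask[rind] <- TRUE
    reporter[rind] <- pmax(reporter[rind], brightness[i])
  }

  # --- optics and noise on the intensity channels only -------------------
  zdepth <- (seq_len(d[1]) - 1) * g$dz
  gain <- 1 + cf$depth_gain * (zdepth / max(extent[1], 1e-9) - 0.5)
  reporter <- sweep_gain(reporter, gain)
  nuc_chan <- sweep_gain(nuc_chan, gain)
  psf <- cf$psf_sigma_um / sp
  reporter <- array(cpp_gaussian_blur(as.vector(reporter), d[1], d[2], d[3],
                                      psf[1], psf[2], psf[3]), d)
  nuc_chan <- array(cpp_gaussian_blur(as.vector(nuc_chan), d[1], d[2], d[3],
                                      psf[1], psf[2], psf[3]), d)
  reporter <- add_noise(reporter, cf$poisson_scale, cf$gaussian_sd)
  nuc_chan <- add_noise(nuc_chan, cf$poisson_scale, cf$gaussian_sd)

  truth <- tibble::tibble(
    label_id = seq_len(n),
    cx_um = centers[, 3], cy_um = centers[, 2], cz_um = centers[, 1],
    depth_um = centers[, 1],
    volume_um3 = as.numeric(tabulate(labels[labels > 0L], nbins = n)) *
      g$voxel_volume,
    layer = layer,
    transduced = transduced,
    brightness_class = brightness_class,
    brightness = brightness
  )
  structure(list(
    nuclei_channel = intensity_volume(nuc_chan, g, "nuclei"),
    reporter_channel = intensity_volume(reporter, g, "reporter"),
    labels = label_volume(labels, g),
    transduced_mask = binary_mask(mask, g),
    truth = truth,
    config = cf
  ), class = "phantom")
}

rasterize_ellipsoid <- function(center_zyx, semi, rot, d, sp, grow_um) {
  # voxel indices (flat) inside the rotated ellipsoid grown by grow_um
  s <- semi + grow_um
  rmax <- max(s)
  lo <- pmax(1L, floor((center_zyx - rmax) / sp) + 1L)
  hi <- pmin(d, ceiling((center_zyx + rmax) / sp) + 1L)
  zz <- seq.int(lo[1], hi[1]); yy <- seq.int(lo[2], hi[2]); xx <- seq.int(lo[3], hi[3])
  gz <- (zz - 1) * sp[1] - center_zyx[1]
  gy <- (yy - 1) * sp[2] - center_zyx[2]
  gx <- (xx - 1) * sp[3] - center_zyx[3]
  pts <- as.matrix(expand.grid(z = gz, y = gy, x = gx))
  local <- pts %*% rot                   # coordinates in ellipsoid frame
  q <- (local[, 1] / s[1])^2 + (local[, 2] / s[2])^2 + (local[, 3] / s[3])^2
  idx <- as.matrix(expand.grid(z = zz, y = yy, x = xx))[q <= 1, , drop = FALSE]
  idx[, 1] + d[1] * (idx[, 2] - 1L) + d[1] * d[2] * (idx[, 3] - 1L)
}

sweep_gain <- function(a, gain) {
  d <- dim(a)
  a * array(rep(gain, d[2] * d[3]), d)
}

add_noise <- function(a, poisson_scale, gaussian_sd) {
  d <- dim(a)
  v <- a
  if (poisson_scale > 0) {
    v <- stats::rpois(length(v), v / poisson_scale) * poisson_scale
  }
  v <- round(pmax(v + stats::rnorm(length(v), sd = gaussian_sd), 0))
  dim(v) <- d
  v
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d nuclei (%d transduced), seed %d\n",
              nrow(x$truth), sum(x$truth$transduced), x$config$seed))
  print(x$labels)
  invisible(x)
}

#' Perturb a truth segmentation with realistic errors
#'
#' Robustness testing against imperfect upstream segmentation: random merges
#' of neighbouring nuclei, random splits, and isotropic erosion.
#'
#' @param labels A truth [label_volume()].
#' @param merge_rate Per-nucleus probability of being merged into its nearest
#'   neighbour.
#' @param split_rate Per-nucleus probability of being split in two along the
#'   axial plane through its centroid.
#' @param erosion_voxels Erosion iterations (6-connected) applied to every
#'   instance.
#' @param seed Integer seed.
#' @return The degraded [label_volume()].
#' @export
degrade_labels <- function(labels, merge_rate = 0, split_rate = 0,
                           erosion_voxels = 0L, seed = 1L) {
  stopifnot(inherits(labels, "label_volume"),
            merge_rate >= 0, merge_rate <= 1, split_rate >= 0, split_rate <= 1)
  with_seed(seed, {
    a <- labels$data
    st <- label_stats(labels)
    if (merge_rate > 0 && nrow(st) >= 2L) {
      for (i in seq_len(nrow(st))) {
        if (stats::runif(1) >= merge_rate) next
        id <- st$label_id[i]
        others <- st[st$label_id != id, ]
        d2 <- (others$zc - st$zc[i])^2 + (others$yc - st$yc[i])^2 +
              (others$xc - st$xc[i])^2
        a[a == id] <- others$label_id[which.min(d2)]
      }
    }
    if (split_rate > 0) {
      next_id <- max(a) + 1L
      for (id in sort(unique(a[a > 0L]))) {
        if (stats::runif(1) >= split_rate) next
        idx <- which(a == id)
        z <- (idx - 1L) %% dim(a)[1] + 1L
        upper <- idx[z > stats::median(z)]
        if (length(upper) > 0L && length(upper) < length(idx)) {
          a[upper] <- next_id
          next_id <- next_id + 1L
        }
      }
    }
    if (erosion_voxels > 0L) {
      for (k in seq_len(erosion_voxels)) a <- erode_once(a)
    }
    label_volume(a, labels$geometry)
  })
}

dilate_plane <- function(m, r) {
  # square dilation of a logical matrix by r pixels
  out <- m
  d <- dim(m)
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0L && dx == 0L) next
    ys <- pmin(pmax(seq_len(d[1]) + dy, 1L), d[1])
    xs <- pmin(pmax(seq_len(d[2]) + dx, 1L), d[2])
    out <- out | m[ys, xs]
  }
  out
}

erode_once <- function(a) {
  # 6-connected erosion: keep a voxel only if all face neighbours share its id
  d <- dim(a)
  keep <- array(TRUE, d)
  pad <- function(shift_axis, dir) {
    b <- array(0L, d)
    if (shift_axis == 1L) {
      if (dir > 0) b[2:d[1], , ] <- a[1:(d[1] - 1), , ] else
        b[1:(d[1] - 1), , ] <- a[2:d[1], , ]
    } else if (shift_axis == 2L) {
      if (dir > 0) b[, 2:d[2], ] <- a[, 1:(d[2] - 1), ] else
        b[, 1:(d[2] - 1), ] <- a[, 2:d[2], ]
    } else {
      if (dir > 0) b[, , 2:d[3]] <- a[, , 1:(d[3] - 1)] else
        b[, , 1:(d[3] - 1)] <- a[, , 2:d[3]]
    }
    b
  }
  for (ax in 1:3) for (dir in c(-1L, 1L)) keep <- keep & (pad(ax, dir) == a)
  out <- a
  out[!keep] <- 0L
  out
}

#' Sample training annotations from phantom truth
#'
#' Emulates the sparse user annotation protocol: voxels are drawn at a few
#' imaging depths (default 25, 50, 75 µm), `n_per_class` per plane per class,
#' transduced voxels from the truth cytoplasm mask (so both dim and bright
#' cells contribute) and background voxels from outside it.
#'
#' @param phantom A `phantom` from [generate_phantom()].
#' @param planes_um Annotated plane depths (µm).
#' @param n_per_class Voxels per class per plane.
#' @param seed Integer seed.
#' @return A [sparse_annotation()].
#' @export
annotate_phantom_planes <- function(phantom, planes_um = c(25, 50, 75),
                                    n_per_class = 150L, seed = 1L) {
  g <- phantom$labels$geometry
  d <- dim(phantom$transduced_mask$data)
  with_seed(seed, {
    rows <- purrr::map_dfr(planes_um, function(depth) {
      z <- as.integer(round(depth / g$dz)) + 1L
      z <- min(max(z, 1L), d[1])
      plane <- phantom$transduced_mask$data[z, , ]
      pos <- which(plane)
      # annotators trace object boundaries: half the background examples come
      # from the halo just outside the signal, half from anywhere outside it
      halo <- dilate_plane(plane, 3L) & !plane
      neg_near <- which(halo)
      neg_far <- which(!plane & !halo)
      n_near <- min(n_per_class %/% 2L, length(neg_near))
      neg <- c(neg_near[sample.int(length(neg_near), n_near)],
               neg_far[sample.int(length(neg_far),
                                  min(n_per_class - n_near, length(neg_far)))])
      pos <- pos[sample.int(length(pos), min(n_per_class, length(pos)))]
      to_coords <- function(flat, label) {
        tibble::tibble(z = z,
                       y = (flat - 1L) %% d[2] + 1L,
                       x = (flat - 1L) %/% d[2] + 1L,
                       label = label)
      }
      dplyr::bind_rows(to_coords(pos, "transduced"), to_coords(neg, "background"))
    })
    sparse_annotation(rows, g)
  })
}
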