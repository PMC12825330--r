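#' Gaussian denoising of an intensity volume
#'
#' Discrete Gaussian smoothing specified by a physical kernel diameter; the
#' per-axis sigma is `(diameter / 2) / spacing_axis` voxels, so anisotropic
#' sampling is compensated. Default diameter 0.829 µm, the preprocessing used
#' before segmentation.
#'
#' @param vol An [intensity_volume()].
#' @param gaussian_diameter_um Kernel diameter in µm (> 0).
#' @return The smoothed [intensity_volume()].
#' @export
denoise <- function(vol, gaussian_diameter_um = 0.829) {
  stopifnot(inherits(vol, "intensity_volume"))
  if (gaussian_diameter_um <= 0) stop("diameter must be > 0", call. = FALSE)
  g <- vol$geometry
  s <- (gaussian_diameter_um / 2) / c(g$dz, g$dy, g$dx)
  d <- dim(vol$data)
  sm <- cpp_gaussian_blur(as.vector(vol$data), d[1], d[2], d[3], s[1], s[2], s[3])
  intensity_volume(array(pmax(sm, 0), d), g, channel_name = vol$channel_name)
}

#' Multiscale per-voxel features for pixel classification
#'
#' For each physical scale: Gaussian-smoothed intensity, gradient magnitude
#' and Laplacian (both in physical units, central differences on the smoothed
#' volume). These capture local brightness, edges and blob/ridge curvature —
#' the cue set an annotation-trained segmenter needs to separate cytoplasmic
#' reporter signal from background independently of absolute intensity.
#'
#' @param vol An [intensity_volume()].
#' @param scales_um Smoothing scales in µm (>= 1 value). A scale smaller than
#'   one voxel is clamped to one voxel with a warning.
#' @return A numeric matrix with one row per voxel (column-major voxel order)
#'   and `3 * length(scales_um)` named columns.
#' @export
extract_features <- function(vol, scales_um = c(0.8, 2)) {
  stopifnot(inherits(vol, "intensity_volume"), length(scales_um) >= 1L)
  g <- vol$geometry
  d <- dim(vol$data)
  spacing <- c(g$dz, g$dy, g$dx)
  out <- matrix(0, nrow = prod(d), ncol = 3L * length(scales_um))
  nm <- character(3L * length(scales_um))
  for (i in seq_along(scales_um)) {
    s_um <- scales_um[i]
    if (s_um < min(spacing)) {
      warning(sprintf("scale %.3g um is below one voxel; clamped", s_um))
    }
    sig <- pmax(s_um / spacing, 1)
    sm <- cpp_gaussian_blur(as.vector(vol$data), d[1], d[2], d[3],
                            sig[1], sig[2], sig[3])
    gl <- cpp_gradient_laplacian(sm, d[1], d[2], d[3], g$dz, g$dy, g$dx)
    j <- 3L * (i - 1L)
    out[, j + 1L] <- sm
    out[, j + 2L] <- gl$gradient
    out[, j + 3L] <- gl$laplacian
    nm[j + 1:3] <- sprintf(c("smooth_%g", "grad_%g", "lap_%g"), s_um)
  }
  colnames(out) <- nm
  attr(out, "dims") <- d
  attr(out, "scales_um") <- scales_um
  out
}

feature_row_index <- function(z, y, x, d) {
  # column-major flat index of voxel (z, y, x), 1-based
  z + d[1] * (y - 1) + d[1] * d[2] * (x - 1)
}

#' Train the sparse-annotation pixel classifier
#'
#' A probability random forest (bagged decision trees) on multiscale features,
#' trained from a handful of voxels annotated as transduced or background —
#' typically drawn at three depths in both dim and bright regions so that
#' low-expressing cells and residual depth-dependent gain are represented.
#' The fixed seed makes training bit-reproducible.
#'
#' @param features Feature matrix from [extract_features()].
#' @param annotation A [sparse_annotation()] with >= 10 voxels per class.
#' @param seed Integer RNG seed for the forest.
#' @param num_trees Number of trees.
#' @return A `pixel_classifier` with the fitted forest, the feature scales and
#'   the resubstitution accuracy (also reported via `message()`).
#' @export
train_pixel_classifier <- function(features, annotation, seed = 1L,
                                   num_trees = 50L) {
  if (!inherits(annotation, "sparse_annotation")) {
    stop("`annotation` must be a sparse_annotation", call. = FALSE)
  }
  counts <- table(annotation$label)
  if (length(counts) < 2L) stop("annotations must contain both classes", call. = FALSE)
  if (any(counts < 10L)) {
    stop("need at least 10 annotated voxels per class", call. = FALSE)
  }
  d <- attr(features, "dims")
  rows <- feature_row_index(annotation$z, annotation$y, annotation$x, d)
  if (any(rows < 1L | rows > nrow(features))) {
    stop("annotation coordinates outside the volume", call. = FALSE)
  }
  x <- features[rows, , drop = FALSE]
  y <- factor(annotation$label, levels = c("background", "transduced"))
  fit <- ranger::ranger(
    x = x, y = y, probability = TRUE, num.trees = num_trees,
    seed = seed, num.threads = 1L, verbose = FALSE
  )
  p <- stats::predict(fit, data = x, num.threads = 1L)$predictions[, "transduced"]
  acc <- mean((p >= 0.5) == (y == "transduced"))
  message(sprintf("pixel classifier: %d training voxels, resubstitution accuracy %.3f",
                  length(y), acc))
  structure(
    list(forest = fit, flat = flatten_forest(fit),
         scales_um = attr(features, "scales_um"),
         n_train = length(y), class_counts = as.list(counts),
         training_accuracy = acc, seed = seed),
    class = "pixel_classifier"
  )
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier> %d trees, %d training voxels, resubstitution accuracy %.3f\n",
              x$forest$num.trees, x$n_train, x$training_accuracy))
  invisible(x)
}

flatten_forest <- function(fit) {
  # per-node arrays concatenated over trees for the compiled tree walker;
  # leftChild < 0 marks a terminal node carrying the transduced probability
  trees <- lapply(seq_len(fit$num.trees), function(t) {
    ti <- ranger::treeInfo(fit, t)
    list(
      left = ifelse(is.na(ti$leftChild), -1L, as.integer(ti$leftChild)),
      right = ifelse(is.na(ti$rightChild), -1L, as.integer(ti$rightChild)),
      splitvar = ifelse(is.na(ti$splitvarID), 0L, as.integer(ti$splitvarID)),
      splitval = ifelse(is.na(ti$splitval), 0, ti$splitval),
      pred = ifelse(is.na(ti$pred.transduced), 0, ti$pred.transduced)
    )
  })
  sizes <- vapply(trees, function(t) length(t$left), integer(1))
  list(
    tree_offsets = as.integer(cumsum(c(0L, sizes[-length(sizes)]))),
    left = unlist(lapply(trees, `[[`, "left")),
    right = unlist(lapply(trees, `[[`, "right")),
    splitvar = unlist(lapply(trees, `[[`, "splitvar")),
    splitval = unlist(lapply(trees, `[[`, "splitval")),
    pred = unlist(lapply(trees, `[[`, "pred"))
  )
}

#' Per-voxel transduction probability
#'
#' Applies a trained [train_pixel_classifier()] model to every voxel, using a
#' compiled evaluator of the flattened forest (identical output to the
#' forest's own prediction).
#'
#' @param classifier A `pixel_classifier`.
#' @param features Feature matrix from [extract_features()] (same scales).
#' @param geometry The stack's [voxel_geometry()].
#' @return A `probability_volume`: values in \[0, 1\].
#' @export
predict_probability <- function(classifier, features, geometry) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  d <- attr(features, "dims")
  fl <- classifier$flat
  p <- cpp_forest_predict(t(features), fl$tree_offsets, fl$left, fl$right,
                          fl$splitvar, fl$splitval, fl$pred)
  probability_volume(array(p, d), geometry)
}

#' @rdname predict_probability
#' @param data 3D array of probabilities in \[0, 1\].
#' @export
probability_volume <- function(data, geometry) {
  data <- as_vol_array(data)
  assert_geometry(geometry)
  if (any(data < 0 | data > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(data = data, geometry = geometry), class = "probability_volume")
}

#' Segment the transduced volume from a probability field
#'
#' Voxels with probability below the threshold are excluded (default 50%:
#' `prob >= 0.5` is retained), then 26-connected components whose physical
#' volume is not larger than `min_object_um3` (default 10 µm³, strict ">")
#' are removed.
#'
#' @param prob A [probability_volume()].
#' @param prob_threshold Retained iff probability >= this fraction.
#' @param min_object_um3 Components with volume <= this are removed.
#' @return A [binary_mask()] of the transduced volume.
#' @export
segment_transduced <- function(prob, prob_threshold = 0.5, min_object_um3 = 10) {
  stopifnot(inherits(prob, "probability_volume"),
            prob_threshold >= 0, prob_threshold <= 1, min_object_um3 >= 0)
  mask <- binary_mask(prob$data >= prob_threshold, prob$geometry)
  filter_mask_components(mask, min_object_um3)
}

#' Remove small connected components from a mask
#'
#' @param mask A [binary_mask()].
#' @param min_object_um3 Components with physical volume <= this are removed
#'   (an object "larger than T" is kept).
#' @return The filtered [binary_mask()].
#' @export
filter_mask_components <- function(mask, min_object_um3) {
  if (min_object_um3 <= 0 || !any(mask$data)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab$data[lab$data > 0L])
  vv <- mask$geometry$voxel_volume
  keep <- which(sizes * vv > min_object_um3)
  binary_mask(array(lab$data %in% keep, dim(mask$data)), mask$geometry)
}

#' Train and apply the reporter-channel segmentation in one call
#'
#' Convenience wrapper: denoise, extract features, train the classifier on
#' the annotations, predict, threshold and size-filter.
#'
#' @inheritParams denoise
#' @inheritParams extract_features
#' @inheritParams train_pixel_classifier
#' @inheritParams segment_transduced
#' @return A list: `mask` ([binary_mask()]), `probability`
#'   ([probability_volume()]), `classifier` (`pixel_classifier`).
#' @export
segment_reporter_channel <- function(vol, annotation, scales_um = c(0.8, 2),
                                     gaussian_diameter_um = 0.829,
                                     prob_threshold = 0.5, min_object_um3 = 10,
                                     seed = 1L, num_trees = 50L) {
  den <- denoise(vol, gaussian_diameter_um)
  feats <- extract_features(den, scales_um)
  clf <- train_pixel_classifier(feats, annotation, seed = seed,
                                num_trees = num_trees)
  prob <- predict_probability(clf, feats, vol$geometry)
  mask <- segment_transduced(prob, prob_threshold, min_object_um3)
  list(mask = mask, probability = prob, classifier = clf)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-feature importance of a pixel classifier
#'
#' @param x A `pixel_classifier`.
#' @param ... Unused.
#' @return A tibble with `feature` and `importance` (impurity importance is
#'   only populated when the forest was grown with it; otherwise one row per
#'   feature with `NA`).
#' @export
tidy.pixel_classifier <- function(x, ...) {
  imp <- x$forest$variable.importance
  nm <- x$forest$forest$independent.variable.names
  tibble::tibble(
    feature = nm,
    importance = if (is.null(imp)) rep(NA_real_, length(nm)) else unname(imp[nm])
  )
}

#' One-row summary of a pixel classifier
#'
#' @param x A `pixel_classifier`.
#' @param ... Unused.
#' @return A tibble with training size, class counts, tree count, OOB
#'   prediction error and resubstitution accuracy.
#' @export
glance.pixel_classifier <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    n_background = x$class_counts$background,
    n_transduced = x$class_counts$transduced,
    num_trees = x$forest$num.trees,
    oob_error = x$forest$prediction.error,
    training_accuracy = x$training_accuracy
  )
}
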