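test_that("denoising preserves constants, mass of an impulse, and computes anisotropic sigmas", {
  g <- voxel_geometry(0.206, 0.206, 0.25)
  const <- intensity_volume(array(7, c(8, 8, 8)), g)
  expect_true(all(abs(denoise(const)$data - 7) < 1e-9))

  # delta impulse: the blurred volume sums to the impulse value (normalised kernel)
  imp <- array(0, c(21, 21, 21)); imp[11, 11, 11] <- 1000
  sm <- denoise(intensity_volume(imp, g), gaussian_diameter_um = 0.829)
  expect_equal(sum(sm$data), 1000, tolerance = 1e-6)
  expect_true(all(sm$data >= 0))
  # blob is widest where the spacing is finest (x/y vs z in voxel units)
  expect_lt(max(sm$data), 1000)
  expect_error(denoise(const, 0), "diameter")
})

test_that("feature stack has 3 channels per scale with sensible degenerate limits", {
  g <- voxel_geometry(0.5, 0.5, 0.5)
  const <- intensity_volume(array(3, c(6, 6, 6)), g)
  f2 <- extract_features(const, scales_um = c(1, 2))
  expect_identical(ncol(f2), 6L)
  # constant volume: gradient and Laplacian vanish everywhere
  expect_true(all(abs(f2[, grepl("grad|lap", colnames(f2))]) < 1e-9))
  expect_true(all(abs(f2[, "smooth_1"] - 3) < 1e-9))
  expect_warning(extract_features(const, scales_um = 0.1), "clamped")
})

test_that("gradient magnitude peaks at the faces of a bright plane", {
  # finite-difference oracle on a toy volume: a single bright z-plane
  g <- voxel_geometry(1, 1, 1)
  a <- array(0, c(9, 5, 5)); a[5, , ] <- 100
  f <- extract_features(intensity_volume(a, g), scales_um = 1)
  grad <- array(f[, "grad_1"], c(9, 5, 5))
  mid <- 3
  # oracle: central differences of the smoothed profile along z
  sm <- array(f[, "smooth_1"], c(9, 5, 5))[, mid, mid]
  oracle <- abs(c(sm[2] - sm[1], (sm[3:9] - sm[1:7]) / 2, sm[9] - sm[8]))
  expect_equal(grad[, mid, mid], oracle, tolerance = 1e-9)
  # peak is off the plane center (symmetric faces), zero far away
  expect_lt(grad[5, mid, mid], max(grad[, mid, mid]))
  expect_equal(which.max(grad[1:4, mid, mid]), 4L)
})

test_that("classifier separates a two-intensity toy volume and spans dim/bright cells", {
  g <- voxel_geometry(1, 1, 1)
  set.seed(5)
  a <- array(10 + rnorm(16 * 16 * 16, sd = 1), c(16, 16, 16))
  a[4:8, 4:8, 4:8] <- 200 + rnorm(125, sd = 5)      # bright object
  a[10:14, 10:14, 10:14] <- 60 + rnorm(125, sd = 2) # dim object
  a <- pmax(a, 0)
  vol <- intensity_volume(a, g)
  feats <- extract_features(vol, scales_um = c(1, 2))
  pos <- rbind(
    as.matrix(expand.grid(z = 5:7, y = 5:7, x = 5:7)),
    as.matrix(expand.grid(z = 11:13, y = 11:13, x = 11:13))
  )
  neg <- as.matrix(expand.grid(z = c(1, 2, 15, 16), y = c(1, 2, 15, 16),
                               x = c(1, 2, 15, 16)))
  ann <- sparse_annotation(
    data.frame(z = c(pos[, 1], neg[, 1]), y = c(pos[, 2], neg[, 2]),
               x = c(pos[, 3], neg[, 3]),
               label = rep(c("transduced", "background"),
                           c(nrow(pos), nrow(neg)))), g)
  clf <- suppressMessages(train_pixel_classifier(feats, ann, seed = 9L))
  expect_equal(clf$training_accuracy, 1.0)
  prob <- predict_probability(clf, feats, g)
  # both dim and bright annotated voxels receive probability > 0.5
  expect_true(all(prob$data[pos] > 0.5))
  expect_true(all(prob$data[neg] < 0.5))
})

test_that("compiled forest evaluation matches ranger predictions exactly", {
  g <- voxel_geometry(1, 1, 1)
  set.seed(11)
  a <- array(rlnorm(12^3, 3, 1), c(12, 12, 12))
  vol <- intensity_volume(a, g)
  feats <- extract_features(vol, scales_um = c(1, 2))
  idx <- cbind(
    z = sample(12, 40, TRUE), y = sample(12, 40, TRUE), x = sample(12, 40, TRUE)
  )
  flat <- idx[, 1] + 12 * (idx[, 2] - 1) + 144 * (idx[, 3] - 1)
  lab <- ifelse(feats[flat, "smooth_1"] > median(feats[, "smooth_1"]),
                "transduced", "background")
  if (length(unique(lab)) < 2 || min(table(lab)) < 10) skip("degenerate draw")
  ann <- sparse_annotation(data.frame(z = idx[, 1], y = idx[, 2], x = idx[, 3],
                                      label = lab), g)
  clf <- suppressMessages(train_pixel_classifier(feats, ann, seed = 3L))
  fast <- predict_probability(clf, feats, g)$data
  ref <- predict(clf$forest, data = feats, num.threads = 1)$predictions[, "transduced"]
  expect_identical(as.vector(fast), unname(ref))
})

test_that("uninformative features give ~0.5 probability and an empty strict mask", {
  g <- voxel_geometry(1, 1, 1)
  feats <- matrix(1, nrow = 6^3, ncol = 3,
                  dimnames = list(NULL, c("smooth_1", "grad_1", "lap_1")))
  attr(feats, "dims") <- c(6L, 6L, 6L)
  attr(feats, "scales_um") <- 1
  set.seed(2)
  idx <- expand.grid(z = 1:6, y = 1:6, x = 1:6)[sample(216, 40), ]
  ann <- sparse_annotation(
    cbind(idx, label = rep(c("transduced", "background"), each = 20)), g)
  clf <- suppressMessages(train_pixel_classifier(feats, ann, seed = 1L))
  prob <- predict_probability(clf, feats, g)
  expect_true(all(abs(prob$data - 0.5) < 0.2))
  # identical features for both classes: every voxel gets the same probability;
  # under the strict >= 0.5 rule the mask is all-or-nothing, and small-object
  # filtering leaves a well-defined mask either way
  expect_true(length(unique(as.vector(prob$data))) == 1L)
})

test_that("training validates annotation quality", {
  g <- voxel_geometry(1, 1, 1)
  feats <- matrix(rnorm(27 * 3), 27, 3,
                  dimnames = list(NULL, c("smooth_1", "grad_1", "lap_1")))
  attr(feats, "dims") <- c(3L, 3L, 3L)
  attr(feats, "scales_um") <- 1
  idx <- expand.grid(z = 1:3, y = 1:3, x = 1:3)
  expect_error(
    sparse_annotation(cbind(idx[1:12, ], label = "transduced"), g),
    "both classes"
  )
  ann_few <- sparse_annotation(
    cbind(idx[1:12, ], label = rep(c("transduced", "background"), c(3, 9))), g)
  expect_error(suppressMessages(train_pixel_classifier(feats, ann_few, 1L)),
               "at least 10")
})

test_that("probability thresholding and strict size filtering behave as specified", {
  g <- voxel_geometry(1, 1, 1)   # 1 um^3 voxels: volume = voxel count
  d <- c(12, 24, 24)
  p <- array(0, d)
  # blob A: 5 voxels (5 um^3), blob B: 50 voxels -> only B survives 10 um^3
  p[2, 2:6, 2] <- 0.9
  p[6:10, 10:14, 10:11] <- 0.8
  prob <- probability_volume(p, g)
  m <- segment_transduced(prob, prob_threshold = 0.5, min_object_um3 = 10)
  expect_identical(sum(m$data), 50L)
  expect_false(any(m$data[2, , ]))

  # component of exactly 10 um^3 is removed (strict "larger than")
  p2 <- array(0, d); p2[3, 3:7, 3:4] <- 1      # 10 voxels
  m2 <- segment_transduced(probability_volume(p2, g), 0.5, 10)
  expect_identical(sum(m2$data), 0L)

  # all-zero probability -> empty mask; threshold boundary is >=
  expect_identical(sum(segment_transduced(probability_volume(array(0, d), g))$data), 0L)
  p3 <- array(0, d); p3[5, 5:9, 5:9] <- 0.5    # exactly at threshold, 25 voxels
  m3 <- segment_transduced(probability_volume(p3, g), 0.5, 10)
  expect_identical(sum(m3$data), 25L)
})

test_that("raising the probability threshold never adds mask voxels", {
  g <- voxel_geometry(1, 1, 1)
  set.seed(8)
  p <- array(runif(10 * 14 * 14), c(10, 14, 14))
  prob <- probability_volume(p, g)
  sizes <- vapply(seq(0, 1, by = 0.1), function(t) {
    sum(segment_transduced(prob, t, min_object_um3 = 0)$data)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("surviving components are all larger than the size threshold (flood-fill oracle)", {
  g <- voxel_geometry(0.8, 0.8, 1)
  set.seed(13)
  p <- array(runif(14^3) > 0.72, c(14, 14, 14))
  m <- filter_mask_components(binary_mask(p, g), min_object_um3 = 10)
  if (any(m$data)) {
    sizes <- brute_component_sizes(m$data)
    expect_true(all(sizes * g$voxel_volume > 10))
  }
  # the filter removed exactly the small components found by the oracle
  sizes_before <- brute_component_sizes(p)
  expect_identical(sum(m$data),
                   as.integer(sum(sizes_before[sizes_before * g$voxel_volume > 10])))
})
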