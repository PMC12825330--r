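test_that("efficiency is the exact quotient with guarded domain", {
  expect_equal(efficiency(84, 100), 0.84)
  expect_equal(efficiency(0, 250), 0)
  expect_equal(efficiency(17, 17), 1)
  expect_error(efficiency(0, 0), "undefined")
  expect_error(efficiency(5, 3), "N_Td")
})

test_that("areas average to organoids, organoids to conditions, with N-1 SD and SEM", {
  areas <- tibble::tibble(
    condition = "AAV2.NN", timepoint = "Td+7",
    organoid_id = c("o1", "o1", "o2"),
    E = c(0.8, 0.6, 0.9)
  )
  agg <- aggregate_efficiency(areas)
  expect_equal(agg$organoid$E, c(0.7, 0.9))
  # organoids (0.7, 0.9): mean 0.8, SD = 0.1414..., SEM = 0.1
  expect_equal(agg$condition$E, 0.8)
  expect_equal(agg$condition$SD, sqrt(((0.7 - 0.8)^2 + (0.9 - 0.8)^2) / 1))
  expect_equal(agg$condition$SD, 0.1414, tolerance = 1e-3)
  expect_equal(agg$condition$SEM, 0.1)
  expect_identical(agg$condition$n_organoids, 2L)

  # single organoid: SEM reported missing, not zero
  agg1 <- aggregate_efficiency(areas[3, ])
  expect_true(is.na(agg1$condition$SEM))
})

test_that("the hierarchy reports mean-of-areas, not the pooled cell ratio", {
  # constructed case where the two disagree: areas 1/10 and 90/100
  areas <- tibble::tibble(
    condition = "c", timepoint = "t", organoid_id = "o",
    N_Td = c(1L, 90L), N_Tot = c(10L, 100L),
    E = c(0.1, 0.9)
  )
  pooled <- sum(areas$N_Td) / sum(areas$N_Tot)
  agg <- aggregate_efficiency(areas)
  expect_false(isTRUE(all.equal(agg$organoid$E, pooled)))
  expect_equal(agg$organoid$E, 0.5)
  expect_equal(agg$condition$E, 0.5)
})

test_that("excluded areas are dropped with their reason", {
  areas <- tibble::tibble(
    condition = "c", timepoint = "t", organoid_id = c("o1", "o1"),
    E = c(0.2, 0.8), include = c(TRUE, FALSE),
    reason = c("", "non-retinal tissue")
  )
  expect_message(agg <- aggregate_efficiency(areas), "non-retinal")
  expect_equal(agg$organoid$E, 0.2)
})

test_that("depth bins are half-open 10-um slices labelled by their center", {
  cells <- tibble::tibble(
    depth_um = c(0, 3, 9.999, 10, 15, 99),
    transduced = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)
  )
  prof <- depth_profile(cells)
  expect_equal(prof$bin_center_um, c(5, 15, 95))
  expect_identical(prof$N_Tot, c(3L, 2L, 1L))
  expect_equal(prof$E, c(2 / 3, 1, 0))
  # all cells at 3 um populate only the "5 um" bin
  one <- depth_profile(tibble::tibble(depth_um = rep(3, 7),
                                      transduced = rep(TRUE, 7)))
  expect_identical(one$bin_center_um, 5)
})

test_that("bin efficiencies recompose the area efficiency exactly", {
  ph <- small_phantom(seed = 3L)
  res <- classify_cells(ph$labels, ph$transduced_mask)
  prof <- depth_profile(res$cells)
  expect_equal(sum(prof$N_Td) / sum(prof$N_Tot), res$efficiency$E)
  # weighted recomposition
  expect_equal(sum(prof$E * prof$N_Tot) / sum(prof$N_Tot), res$efficiency$E)
})

test_that("uniform transduction gives a flat profile; layered phantoms recover the step", {
  set.seed(21)
  cells <- tibble::tibble(
    depth_um = runif(4000, 0, 80),
    transduced = runif(4000) < 0.6
  )
  prof <- depth_profile(cells)
  expect_true(all(abs(prof$E - 0.6) < 3 * sqrt(0.24 / prof$N_Tot)))

  # phantom with 0.9 above the boundary and 0.2 below
  ph <- small_phantom(seed = 12L, n_nuclei = 150L,
                      transduction_prob = c(upper = 0.9, lower = 0.2))
  truth_prof <- ph$truth |>
    dplyr::mutate(depth_um = cz_um) |>
    depth_profile()
  shallow <- truth_prof[truth_prof$bin_center_um < 20, ]
  deep <- truth_prof[truth_prof$bin_center_um > 20, ]
  binom3 <- function(p, n) 3 * sqrt(p * (1 - p) / n)
  expect_true(all(abs(shallow$E - 0.9) <= binom3(0.9, shallow$N_Tot)))
  expect_true(all(abs(deep$E - 0.2) <= binom3(0.2, deep$N_Tot)))
})

test_that("profile aggregation follows the area-organoid hierarchy per bin", {
  cells <- tibble::tibble(
    condition = "c", timepoint = "t",
    organoid_id = rep(c("o1", "o1", "o2"), each = 4),
    area_index = rep(c(1L, 2L, 1L), each = 4),
    depth_um = rep(c(2, 2, 12, 12), 3),
    transduced = c(TRUE, TRUE, TRUE, FALSE,   # o1 a1: bin5 1.0, bin15 0.5
                   FALSE, FALSE, TRUE, TRUE,  # o1 a2: bin5 0.0, bin15 1.0
                   TRUE, FALSE, FALSE, FALSE) # o2 a1: bin5 0.5, bin15 0.0
  )
  agg <- aggregate_profile(depth_profile(cells))
  # bin 5: o1 mean(1, 0) = 0.5, o2 = 0.5 -> 0.5; bin 15: o1 0.75, o2 0 -> 0.375
  expect_equal(agg$E[agg$bin_center_um == 5], 0.5)
  expect_equal(agg$E[agg$bin_center_um == 15], 0.375)
  expect_identical(agg$n_organoids, c(2L, 2L))
  expect_equal(agg$SEM[agg$bin_center_um == 5], 0)
})

test_that("normalization modes rescale as documented and reject zero references", {
  cells <- tibble::tibble(depth_um = c(rep(2, 10), rep(12, 10)),
                          transduced = c(rep(TRUE, 2), rep(FALSE, 8),
                                         rep(TRUE, 4), rep(FALSE, 6)))
  prof <- depth_profile(cells)        # E = (0.2, 0.4), whole-stack 0.3
  ws <- normalize_profile(prof, "whole-stack")
  expect_equal(ws$E, c(0.2, 0.4) / 0.3)
  mx <- normalize_profile(prof, "max-bin")
  expect_equal(mx$E, c(0.5, 1))
  none <- normalize_profile(prof, "none")
  expect_equal(none$E, c(0.2, 0.4))
  expect_identical(attr(ws, "normalization"), "whole-stack")

  # flat profile at the whole-stack value -> all ones
  flat <- depth_profile(tibble::tibble(depth_um = c(rep(2, 10), rep(12, 10)),
                                       transduced = rep(c(TRUE, FALSE), 10)))
  expect_true(all(normalize_profile(flat, "whole-stack")$E == 1))

  zero <- depth_profile(tibble::tibble(depth_um = 1:5,
                                       transduced = rep(FALSE, 5)))
  expect_error(normalize_profile(zero, "whole-stack"), "zero")
})

test_that("median-centered Levene test matches hand arithmetic and car's implementation", {
  # hand oracle: groups (0,0,10,10) and (4,5,5,6)
  g1 <- c(0, 0, 10, 10); g2 <- c(4, 5, 5, 6)
  dev1 <- abs(g1 - median(g1)); dev2 <- abs(g2 - median(g2))
  n <- 4
  grand <- mean(c(dev1, dev2))
  ssb <- n * ((mean(dev1) - grand)^2 + (mean(dev2) - grand)^2)
  ssw <- sum((dev1 - mean(dev1))^2) + sum((dev2 - mean(dev2))^2)
  f_hand <- (ssb / 1) / (ssw / 6)
  res <- levene_median_test(list(g1, g2))
  expect_equal(res$statistic, f_hand, tolerance = 1e-12)
  expect_equal(res$p, stats::pf(f_hand, 1, 6, lower.tail = FALSE))

  # cross-check against car::leveneTest(center = median)
  skip_if_not_installed("car")
  lt <- car::leveneTest(c(g1, g2), factor(rep(1:2, each = 4)), center = median)
  expect_equal(res$statistic, lt$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p, lt$`Pr(>F)`[1], tolerance = 1e-10)

  # identical groups: statistic 0, p 1; location shifts change nothing
  same <- levene_median_test(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_true(same$equal_variance)
  shifted <- levene_median_test(list(c(1, 2, 3), c(1, 2, 3) + 100))
  expect_equal(shifted$statistic, 0)
  expect_error(levene_median_test(list(1, c(2, 3))), "2 values")
})

test_that("pooled t-test matches stats::t.test and handles degenerate variance", {
  set.seed(7)
  g1 <- rnorm(8, 0.8, 0.05); g2 <- rnorm(6, 0.6, 0.05)
  res <- unpaired_t_test(g1, g2)
  ref <- stats::t.test(g1, g2, var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$dof, unname(ref$parameter))
  expect_equal(res$p, unname(ref$p.value))
  # textbook pooled formula recomputed by hand
  sp2 <- (7 * var(g1) + 5 * var(g2)) / 12
  t_hand <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 8 + 1 / 6))
  expect_equal(res$t, t_hand, tolerance = 1e-12)

  same <- unpaired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_identical(same$stars, "n.s.")

  degen <- unpaired_t_test(c(0, 0, 0), c(1, 1, 1))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 0)
})

test_that("significance stars follow the published tiers", {
  expect_identical(significance_stars(c(0.2, 0.05, 0.04, 0.01, 1e-3, 1e-6, 1e-9)),
                   c("n.s.", "*", "*", "**", "**", "******", "******"))
})

test_that("threshold calibration picks the sweep value closest to the manual reference", {
  # software sweep {0.2: 0.95, 0.4: 0.84, 0.6: 0.60} vs manual 0.73 -> 0.4
  sweep <- tidyr::expand_grid(threshold = c(0.2, 0.4, 0.6),
                              plane_depth_um = c(25, 50))
  sweep$E <- rep(c(0.95, 0.84, 0.60), each = 2)
  manual <- tidyr::expand_grid(plane_depth_um = c(25, 50), annotator_id = 1:3)
  manual$n_transduced <- 73L
  manual$n_total <- 100L
  cal <- calibrate_threshold(sweep, manual)
  expect_equal(cal$threshold, 0.4)
  expect_equal(cal$manual_reference$manual_E, c(0.73, 0.73))
  expect_equal(min(cal$sweep$mean_abs_dev), 0.84 - 0.73, tolerance = 1e-12)

  # exact match -> that threshold, deviation 0
  sweep2 <- sweep; sweep2$E[sweep2$threshold == 0.6] <- 0.73
  cal2 <- calibrate_threshold(sweep2, manual)
  expect_equal(cal2$threshold, 0.6)
  expect_equal(min(cal2$sweep$mean_abs_dev), 0)

  # ties go to the larger threshold
  sweep3 <- sweep
  sweep3$E <- rep(c(0.7, 0.76, 0.7), each = 2)   # 0.2 and 0.6 tie at 0.03
  expect_equal(calibrate_threshold(sweep3, manual)$threshold, 0.6)

  # single candidate comes back unchanged
  cal1 <- calibrate_threshold(sweep[sweep$threshold == 0.2, ], manual)
  expect_equal(cal1$threshold, 0.2)

  # missing plane -> validation error
  expect_error(calibrate_threshold(sweep, manual[manual$plane_depth_um == 25, ]),
               "lacks plane")
  bad <- manual; bad$n_transduced[1] <- 200L
  expect_error(calibrate_threshold(sweep, bad), "<=")

  # tidy/glance surfaces
  td <- tidy(cal)
  expect_true(td$chosen[td$threshold == 0.4])
  expect_equal(glance(cal)$manual_E, 0.73)
})

test_that("threshold_sweep computes plane-restricted efficiencies from shells", {
  g <- voxel_geometry(1, 1, 1)
  a <- array(0L, c(30, 20, 20))
  a[24:26, 5:7, 5:7] <- 1L     # intersects plane z=26 (depth 25)
  a[24:26, 12:14, 12:14] <- 2L
  labs <- label_volume(a, g)
  sh <- build_shells(labs, 2L)
  mask <- array(FALSE, c(30, 20, 20))
  mask[sh$data == 1L] <- TRUE              # cell 1 fully covered, cell 2 not
  rec <- overlap_fractions(sh, binary_mask(mask, g))
  sw <- threshold_sweep(sh, rec, planes_um = 25, thresholds = c(0.3, 0.9))
  expect_identical(sw$N_Tot, c(2L, 2L))
  expect_equal(sw$E, c(0.5, 0.5))
})
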