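#' Transduction efficiency
#'
#' `E = N_Td / N_Tot`: the fraction of segmented cells classified as
#' transduced.
#'
#' @param n_td Number of transduced cells (>= 0).
#' @param n_tot Total number of cells (>= 1; an empty population has no
#'   defined efficiency and must be excluded by the caller, mirroring the
#'   empty-depth-bin rule).
#' @return The exact quotient.
#' @export
efficiency <- function(n_td, n_tot) {
  if (any(n_tot < 1)) {
    stop("efficiency undefined for N_Tot = 0; exclude empty populations",
         call. = FALSE)
  }
  if (any(n_td < 0 | n_td > n_tot)) {
    stop("need 0 <= N_Td <= N_Tot", call. = FALSE)
  }
  n_td / n_tot
}

sd_unbiased <- function(x) stats::sd(x)   # N-1 denominator

sem <- function(x) {
  # SEM = sigma / sqrt(N) with unbiased SD; undefined (NA) for N = 1
  n <- length(x)
  if (n < 2L) return(NA_real_)
  stats::sd(x) / sqrt(n)
}

#' Hierarchical aggregation of area-level efficiencies
#'
#' Imaged areas of one organoid are averaged and the mean is treated as a
#' single measurement of that organoid; the condition/timepoint mean then
#' averages over organoids (unweighted — not a pooled cell-count ratio).
#' Dispersion uses the unbiased (N-1) SD; SEM = SD / sqrt(N organoids) and is
#' reported as missing for a single organoid.
#'
#' @param areas Tibble with one row per imaged area: columns `condition`,
#'   `timepoint`, `organoid_id`, `E` (and optionally `include`/`reason`;
#'   excluded rows are dropped with a message).
#' @return A list of tibbles: `organoid` (`condition`, `timepoint`,
#'   `organoid_id`, `E`, `n_areas`) and `condition` (`condition`, `timepoint`,
#'   `E`, `SD`, `SEM`, `n_organoids`).
#' @export
aggregate_efficiency <- function(areas) {
  areas <- tibble::as_tibble(areas)
  stopifnot(all(c("condition", "timepoint", "organoid_id", "E") %in% names(areas)))
  if ("include" %in% names(areas)) {
    dropped <- areas[!areas$include, ]
    if (nrow(dropped) > 0L) {
      message(sprintf("excluding %d area(s): %s", nrow(dropped),
                      paste(unique(dropped$reason %||% "unspecified"), collapse = "; ")))
    }
    areas <- areas[areas$include, ]
  }
  organoid <- areas |>
    dplyr::group_by(.data$condition, .data$timepoint, .data$organoid_id) |>
    dplyr::summarise(E = mean(.data$E), n_areas = dplyr::n(), .groups = "drop")
  condition <- organoid |>
    dplyr::group_by(.data$condition, .data$timepoint) |>
    dplyr::summarise(
      SD = sd_unbiased(.data$E),
      SEM = sem(.data$E),
      n_organoids = dplyr::n(),
      E = mean(.data$E),
      .groups = "drop"
    ) |>
    dplyr::select("condition", "timepoint", "E", "SD", "SEM", "n_organoids")
  list(organoid = organoid, condition = condition)
}

#' Depth-binned transduction efficiency
#'
#' Cells are assigned by nucleus centroid depth to half-open 10-µm bins
#' (`[0, 10)` µm is the "5 µm" bin, labelled by its center) and the
#' efficiency is computed per bin and per grouping unit. Bins without
#' segmented cells are simply absent and therefore excluded from any
#' cross-unit averaging.
#'
#' @param cells Tibble of classified cells with `depth_um` and `transduced`;
#'   any of `condition`, `timepoint`, `organoid_id`, `area_index` present are
#'   used as grouping columns.
#' @param bin_width_um Bin width (default 10 µm).
#' @return A `depth_profile` tibble: grouping columns, `bin_center_um`,
#'   `bin_lo_um`, `bin_hi_um`, `N_Td`, `N_Tot`, `E`.
#' @export
depth_profile <- function(cells, bin_width_um = 10) {
  cells <- tibble::as_tibble(cells)
  stopifnot(all(c("depth_um", "transduced") %in% names(cells)), bin_width_um > 0)
  grouping <- intersect(c("condition", "timepoint", "organoid_id", "area_index"),
                        names(cells))
  k <- floor(cells$depth_um / bin_width_um)
  cells$bin_center_um <- (k + 0.5) * bin_width_um
  prof <- cells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grouping, "bin_center_um")))) |>
    dplyr::summarise(N_Td = sum(.data$transduced), N_Tot = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(
      bin_lo_um = .data$bin_center_um - bin_width_um / 2,
      bin_hi_um = .data$bin_center_um + bin_width_um / 2,
      E = efficiency(.data$N_Td, .data$N_Tot)
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grouping, "bin_center_um"))))
  structure(prof, class = c("depth_profile", class(prof)),
            bin_width_um = bin_width_um, grouping = grouping)
}

#' Aggregate a depth profile across areas and organoids
#'
#' Within each bin the area-to-organoid-to-condition hierarchy of
#' [aggregate_efficiency()] is applied: per-organoid bin efficiency is the
#' mean over that organoid's areas holding cells in the bin, and the
#' condition-level bin value averages over organoids, with SEM over organoids.
#'
#' @param profile A [depth_profile()] with grouping columns.
#' @return A tibble: `condition`, `timepoint` (when present), `bin_center_um`,
#'   `E`, `SD`, `SEM`, `n_organoids`.
#' @export
aggregate_profile <- function(profile) {
  grouping <- attr(profile, "grouping")
  upper <- intersect(c("condition", "timepoint"), grouping)
  prof <- tibble::as_tibble(profile)
  by_org <- prof |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(upper, intersect("organoid_id", grouping), "bin_center_um")))) |>
    dplyr::summarise(E = mean(.data$E), .groups = "drop")
  by_org |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(upper, "bin_center_um")))) |>
    dplyr::summarise(
      SD = sd_unbiased(.data$E),
      SEM = sem(.data$E),
      n_organoids = dplyr::n(),
      E = mean(.data$E),
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(upper), "bin_center_um", "E", "SD", "SEM",
                  "n_organoids")
}

#' Normalise a depth profile
#'
#' @param profile A [depth_profile()].
#' @param mode `"whole-stack"` (default): each unit's bins are divided by that
#'   unit's overall pooled efficiency; `"max-bin"`: divided by the unit's
#'   maximal bin efficiency; `"none"`: identity. The mode is recorded in the
#'   `normalization` attribute. No mode is canonical; choose one and report it.
#' @return The profile with `E` replaced by the normalised value (column
#'   `E_raw` keeps the input).
#' @export
normalize_profile <- function(profile, mode = c("whole-stack", "max-bin", "none")) {
  mode <- match.arg(mode)
  grouping <- attr(profile, "grouping")
  out <- tibble::as_tibble(profile)
  out$E_raw <- out$E
  if (mode != "none") {
    out <- out |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
      dplyr::mutate(.ref = if (mode == "whole-stack") {
        sum(.data$N_Td) / sum(.data$N_Tot)
      } else {
        max(.data$E)
      }) |>
      dplyr::ungroup()
    if (any(out$.ref == 0)) {
      stop("normalization reference is zero for at least one unit", call. = FALSE)
    }
    out$E <- out$E / out$.ref
    out$.ref <- NULL
  }
  structure(out, class = c("depth_profile", class(tibble::tibble())),
            bin_width_um = attr(profile, "bin_width_um"),
            grouping = grouping, normalization = mode)
}

#' Brown-Forsythe test for equal group variances
#'
#' Levene's test centered on the group median: a one-way ANOVA on the
#' absolute deviations from each group's median. Used as the gate before the
#' pooled-variance t-test.
#'
#' @param groups A list (>= 2 elements, each >= 2 values) of per-organoid
#'   efficiencies.
#' @param alpha Significance level (default 0.05).
#' @return A tibble: `statistic` (F), `df1`, `df2`, `p`,
#'   `equal_variance` (`p > alpha`).
#' @export
levene_median_test <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L || any(lengths(groups) < 2L)) {
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  dev <- unlist(lapply(groups, function(g) abs(g - stats::median(g))))
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  df1 <- length(groups) - 1L
  df2 <- length(dev) - length(groups)
  if (stats::var(dev) < .Machine$double.eps) {
    res <- tibble::tibble(statistic = 0, df1 = df1, df2 = df2, p = 1)
  } else {
    ow <- stats::oneway.test(dev ~ grp, var.equal = TRUE)
    res <- tibble::tibble(statistic = unname(ow$statistic), df1 = df1, df2 = df2,
                          p = unname(ow$p.value))
  }
  res$equal_variance <- res$p > alpha
  res
}

#' Unpaired pooled-variance t-test with significance stars
#'
#' Two-sided two-sample t-test assuming equal variances (call only after the
#' equal-variance gate passes). Stars: `n.s.` for p > 0.05, `*` p <= 0.05,
#' `**` p <= 0.01, `******` p <= 1e-6.
#'
#' @param g1,g2 Numeric vectors (>= 2 values each).
#' @param alpha Significance level.
#' @return A tibble: `t`, `dof`, `p`, `significant`, `stars`, `degenerate`
#'   (TRUE when the pooled variance is zero).
#' @export
unpaired_t_test <- function(g1, g2, alpha = 0.05) {
  stopifnot(length(g1) >= 2L, length(g2) >= 2L)
  dof <- length(g1) + length(g2) - 2L
  pooled_var <- ((length(g1) - 1) * stats::var(g1) +
                 (length(g2) - 1) * stats::var(g2)) / dof
  if (pooled_var < .Machine$double.eps) {
    if (isTRUE(all.equal(mean(g1), mean(g2)))) {
      res <- tibble::tibble(t = 0, dof = dof, p = 1, degenerate = TRUE)
    } else {
      res <- tibble::tibble(t = sign(mean(g1) - mean(g2)) * Inf, dof = dof,
                            p = 0, degenerate = TRUE)
    }
  } else {
    tt <- stats::t.test(g1, g2, var.equal = TRUE)
    res <- tibble::tibble(t = unname(tt$statistic),
                          dof = unname(tt$parameter),
                          p = unname(tt$p.value), degenerate = FALSE)
  }
  res$significant <- res$p <= alpha
  res$stars <- significance_stars(res$p)
  res[, c("t", "dof", "p", "significant", "stars", "degenerate")]
}

#' @rdname unpaired_t_test
#' @param p A p-value.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    p <= 1e-6 ~ "******",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    .default = "n.s."
  )
}

#' Software per-plane efficiency over a threshold sweep
#'
#' For comparison with manual 2D counts: the cell population of a plane is
#' the set of cells whose shells intersect that plane; the plane efficiency at
#' a given overlap threshold is the transduced fraction among them.
#'
#' @param shells Filtered shell [label_volume()].
#' @param records Shell records from [overlap_fractions()].
#' @param planes_um Plane depths in µm (converted to plane indices through the
#'   stack's z spacing).
#' @param thresholds Candidate overlap thresholds.
#' @return A tibble: `threshold`, `plane_depth_um`, `N_Td`, `N_Tot`, `E`.
#' @export
threshold_sweep <- function(shells, records, planes_um = c(25, 50, 75),
                            thresholds = seq(0.1, 0.9, by = 0.1)) {
  g <- shells$geometry
  plane_ids <- lapply(planes_um, function(depth) {
    plane_shell_ids(shells, as.integer(round(depth / g$dz)) + 1L)
  })
  grid <- tidyr::expand_grid(threshold = thresholds, plane_depth_um = planes_um)
  purrr::pmap_dfr(grid, function(threshold, plane_depth_um) {
    ids <- plane_ids[[match(plane_depth_um, planes_um)]]
    fr <- records$overlap_fraction[records$label_id %in% ids]
    n_td <- sum(fr >= threshold)
    tibble::tibble(threshold = threshold, plane_depth_um = plane_depth_um,
                   N_Td = n_td, N_Tot = length(fr),
                   E = efficiency(n_td, length(fr)))
  })
}

#' Calibrate the overlap threshold against manual counts
#'
#' The manual reference per plane is the mean over annotators of
#' `n_transduced / n_total`, restricted to the upper and center planes
#' (default 25 and 50 µm). The chosen threshold minimises the mean absolute
#' deviation between the software plane efficiencies and the manual
#' reference over those planes; ties go to the larger (more conservative)
#' threshold.
#'
#' @param sweep Software sweep tibble with `threshold`, `plane_depth_um`, `E`
#'   (from [threshold_sweep()] or assembled by hand).
#' @param manual Manual count tibble: `plane_depth_um`, `annotator_id`,
#'   `n_transduced`, `n_total`.
#' @param calibration_planes_um Planes entering the criterion.
#' @return A `threshold_calibration`: list with `threshold` (chosen),
#'   `sweep` (per-threshold mean absolute deviation), `manual_reference`
#'   (per-plane manual means) and `calibration_planes_um`.
#' @export
calibrate_threshold <- function(sweep, manual,
                                calibration_planes_um = c(25, 50)) {
  sweep <- tibble::as_tibble(sweep)
  manual <- tibble::as_tibble(manual)
  stopifnot(all(c("threshold", "plane_depth_um", "E") %in% names(sweep)),
            all(c("plane_depth_um", "n_transduced", "n_total") %in% names(manual)))
  if (any(manual$n_transduced > manual$n_total)) {
    stop("manual counts: n_transduced must be <= n_total", call. = FALSE)
  }
  missing <- setdiff(calibration_planes_um, manual$plane_depth_um)
  if (length(missing) > 0L) {
    stop(sprintf("manual table lacks plane(s) at %s um",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  missing_sw <- setdiff(calibration_planes_um, sweep$plane_depth_um)
  if (length(missing_sw) > 0L) {
    stop(sprintf("sweep lacks plane(s) at %s um",
                 paste(missing_sw, collapse = ", ")), call. = FALSE)
  }
  ref <- manual |>
    dplyr::filter(.data$plane_depth_um %in% calibration_planes_um) |>
    dplyr::group_by(.data$plane_depth_um) |>
    dplyr::summarise(manual_E = mean(.data$n_transduced / .data$n_total),
                     n_annotators = dplyr::n(), .groups = "drop")
  dev <- sweep |>
    dplyr::filter(.data$plane_depth_um %in% calibration_planes_um) |>
    dplyr::inner_join(ref, by = "plane_depth_um") |>
    dplyr::group_by(.data$threshold) |>
    dplyr::summarise(mean_abs_dev = mean(abs(.data$E - .data$manual_E)),
                     .groups = "drop")
  best <- dev$mean_abs_dev == min(dev$mean_abs_dev)
  chosen <- max(dev$threshold[best])   # ties -> larger threshold
  structure(
    list(threshold = chosen, sweep = dev, manual_reference = ref,
         calibration_planes_um = calibration_planes_um, full_sweep = sweep),
    class = "threshold_calibration"
  )
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("<threshold_calibration> chosen overlap threshold %.3g (mean |software - manual| = %.4f)\n",
              x$threshold, min(x$sweep$mean_abs_dev)))
  invisible(x)
}

#' Tidy a threshold calibration: the per-threshold deviation table
#'
#' @param x A `threshold_calibration`.
#' @param ... Unused.
#' @return A tibble with `threshold`, `mean_abs_dev` and `chosen`.
#' @export
tidy.threshold_calibration <- function(x, ...) {
  dplyr::mutate(x$sweep, chosen = .data$threshold == x$threshold)
}

#' One-row summary of a threshold calibration
#'
#' @param x A `threshold_calibration`.
#' @param ... Unused.
#' @return A tibble with the chosen threshold, its deviation, and the manual
#'   reference averaged over calibration planes.
#' @export
glance.threshold_calibration <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold,
    mean_abs_dev = min(x$sweep$mean_abs_dev),
    manual_E = mean(x$manual_reference$manual_E),
    n_planes = nrow(x$manual_reference)
  )
}
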