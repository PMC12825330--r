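#' Resolved run configuration
#'
#' All tunable parameters of the pipeline with their calibrated defaults:
#' probability threshold 0.5 and minimal object volume 10 µm³ for the
#' transduced volume; nuclear instance band (10 µm³, Inf); nuclear volume
#' filter 100 µm³; shell size filter 50 µm³ for human organoid tissue
#' (30 µm³ for mouse, via `tissue_preset`); 2-voxel shell dilation; overlap
#' threshold 0.4; 10-µm depth bins; alpha 0.05. Every run writes the fully
#' resolved configuration next to its outputs.
#'
#' @param tissue_preset `"human"` or `"mouse"` (sets `min_shell_um3` unless
#'   given explicitly).
#' @param prob_threshold Transduction probability cut (retain >= this).
#' @param min_object_um3 Transduced-component size filter (keep > this).
#' @param nuclei_band_um3 Instance volume band applied at segmentation time.
#' @param min_nucleus_um3 Nuclear volume filter before shells (keep > this).
#' @param min_shell_um3 Shell size filter (>= this kept); `NULL` = preset.
#' @param dilation_voxels Shell dilation radius in voxels.
#' @param overlap_threshold Shell overlap classification threshold.
#' @param bin_width_um Depth bin width.
#' @param alpha Significance level for the statistical tests.
#' @param scales_um Feature scales of the pixel classifier.
#' @param gaussian_diameter_um Denoising kernel diameter.
#' @param num_trees Trees in the pixel classifier forest.
#' @param seed Integer seed (mandatory; no wall-clock seeding).
#' @return A `run_config` list.
#' @export
run_config <- function(tissue_preset = c("human", "mouse"),
                       prob_threshold = 0.5,
                       min_object_um3 = 10,
                       nuclei_band_um3 = c(10, Inf),
                       min_nucleus_um3 = 100,
                       min_shell_um3 = NULL,
                       dilation_voxels = 2L,
                       overlap_threshold = 0.4,
                       bin_width_um = 10,
                       alpha = 0.05,
                       scales_um = c(0.8, 2),
                       gaussian_diameter_um = 0.829,
                       num_trees = 50L,
                       seed = 1L) {
  tissue_preset <- match.arg(tissue_preset)
  if (is.null(min_shell_um3)) {
    min_shell_um3 <- if (tissue_preset == "human") 50 else 30
  }
  structure(as.list(environment()), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file holding any subset of the configuration fields.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(run_config, y)
}

write_run_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(v) {
    if (identical(v, Inf)) ".inf" else v
  }), path)
  invisible(path)
}

#' Run the full quantification pipeline over a manifest
#'
#' For every included stack: read the nuclear instance labels, obtain the
#' transduced mask (precomputed, or segmented from the reporter channel with
#' the sparse-annotation classifier), build and filter shells, classify
#' cells, and compute area-, organoid- and condition-level efficiencies plus
#' depth profiles. Deterministic given config, inputs and seed.
#'
#' @param manifest Manifest tibble ([read_manifest()]) extended with a
#'   `labels_path` column and either `mask_path` or both `reporter_path` and
#'   `annotations_path` per stack.
#' @param config A [run_config()].
#' @param out_dir Output directory (created). Writes `cells.csv`,
#'   `efficiency_by_area.csv`, `efficiency_by_organoid.csv`,
#'   `efficiency_by_condition.csv`, `depth_profile.csv`, `stats_tests.json`,
#'   `resolved_config.yaml` and `pipeline_log.csv`.
#' @param override_geometry Optional [voxel_geometry()] for files without
#'   metadata.
#' @return Invisibly, a list with `cells`, `areas`, `organoid`, `condition`,
#'   `profile`, `stats`, `log` tibbles.
#' @export
run_pipeline <- function(manifest, config = run_config(), out_dir,
                         override_geometry = NULL) {
  stopifnot(inherits(config, "run_config"))
  manifest <- validate_manifest(tibble::as_tibble(manifest))
  if (!"labels_path" %in% names(manifest)) {
    stop("manifest needs a `labels_path` column", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  active <- manifest[manifest$include, ]
  cells_all <- list()
  log_rows <- list()
  for (i in seq_len(nrow(active))) {
    row <- active[i, ]
    res <- tryCatch(
      process_stack(row, config, override_geometry),
      error = function(e) {
        stop(sprintf("stack '%s' failed at %s", row$stack_id, conditionMessage(e)),
             call. = FALSE)
      }
    )
    cells <- res$cells
    cells$stack_id <- row$stack_id
    cells$condition <- row$condition
    cells$timepoint <- row$timepoint
    cells$organoid_id <- row$organoid_id
    cells$area_index <- row$area_index
    cells_all[[i]] <- cells
    log_rows[[i]] <- tibble::tibble(stack_id = row$stack_id,
                                    stage = names(res$stage_counts),
                                    count = as.integer(res$stage_counts))
  }
  cells <- dplyr::bind_rows(cells_all)
  areas <- cells |>
    dplyr::group_by(.data$condition, .data$timepoint, .data$organoid_id,
                    .data$area_index) |>
    dplyr::summarise(N_Td = sum(.data$transduced), N_Tot = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(E = efficiency(.data$N_Td, .data$N_Tot))
  agg <- aggregate_efficiency(areas)
  prof <- depth_profile(cells, config$bin_width_um)
  stats_tbl <- pairwise_condition_tests(agg$organoid, config$alpha)
  log_tbl <- dplyr::bind_rows(log_rows)

  utils::write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(areas, file.path(out_dir, "efficiency_by_area.csv"),
                   row.names = FALSE)
  utils::write.csv(agg$organoid, file.path(out_dir, "efficiency_by_organoid.csv"),
                   row.names = FALSE)
  utils::write.csv(agg$condition, file.path(out_dir, "efficiency_by_condition.csv"),
                   row.names = FALSE)
  utils::write.csv(tibble::as_tibble(prof), file.path(out_dir, "depth_profile.csv"),
                   row.names = FALSE)
  utils::write.csv(log_tbl, file.path(out_dir, "pipeline_log.csv"),
                   row.names = FALSE)
  jsonlite::write_json(stats_tbl, file.path(out_dir, "stats_tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_config(config, file.path(out_dir, "resolved_config.yaml"))

  invisible(list(cells = cells, areas = areas, organoid = agg$organoid,
                 condition = agg$condition, profile = prof, stats = stats_tbl,
                 log = log_tbl))
}

process_stack <- function(row, config, override_geometry) {
  labels <- read_labels(row$labels_path, override_geometry)
  labels <- filter_nuclei_band(labels, config$nuclei_band_um3[1],
                               config$nuclei_band_um3[2])
  if (!is.null(row$mask_path) && !is.na(row$mask_path) && row$mask_path != "") {
    mask <- read_mask(row$mask_path, override_geometry)
  } else if (!is.null(row$reporter_path) && !is.na(row$reporter_path)) {
    vol <- read_stack(row$reporter_path, override_geometry)
    ann <- read_annotations(row$annotations_path, vol$geometry)
    mask <- segment_reporter_channel(
      vol, ann, scales_um = config$scales_um,
      gaussian_diameter_um = config$gaussian_diameter_um,
      prob_threshold = config$prob_threshold,
      min_object_um3 = config$min_object_um3,
      seed = config$seed, num_trees = config$num_trees
    )$mask
  } else {
    stop("manifest row supplies neither mask_path nor reporter_path")
  }
  classify_cells(labels, mask,
                 min_nucleus_um3 = config$min_nucleus_um3,
                 dilation_voxels = config$dilation_voxels,
                 min_shell_um3 = config$min_shell_um3,
                 threshold = config$overlap_threshold)
}

pairwise_condition_tests <- function(organoid, alpha = 0.05) {
  out <- list()
  for (tp in unique(organoid$timepoint)) {
    sub <- organoid[organoid$timepoint == tp, ]
    conds <- unique(sub$condition)
    if (length(conds) < 2L) next
    pairs <- utils::combn(conds, 2L, simplify = FALSE)
    for (pr in pairs) {
      g1 <- sub$E[sub$condition == pr[1]]
      g2 <- sub$E[sub$condition == pr[2]]
      if (length(g1) < 2L || length(g2) < 2L) next
      lev <- levene_median_test(list(g1, g2), alpha)
      tt <- unpaired_t_test(g1, g2, alpha)
      out[[length(out) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(timepoint = tp, condition_1 = pr[1], condition_2 = pr[2],
                       levene_statistic = lev$statistic, levene_p = lev$p,
                       equal_variance = lev$equal_variance),
        tt
      )
    }
  }
  if (length(out) == 0L) return(tibble::tibble())
  dplyr::bind_rows(out)
}
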