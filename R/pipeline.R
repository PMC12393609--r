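#' Default pipeline configuration
#'
#' All analysis thresholds at their standard values: 35% exploration
#' cutoff, 2-s event merge gap, 10x/20x/3x event-classifier multipliers,
#' 10-voxel mask-assignment overlap, 12-um comparison voxels, alpha
#' 0.05, clustering start t = 3 with 20% stability, 0.8 connectivity
#' threshold. Cohort sizes here are the bundled demo scale; override for
#' larger runs.
#'
#' @param seed Master seed; each stage derives its own seed from it.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    # synthetic cohort (demo scale)
    n_control = 4L, n_deficient = 4L, neurons_per_larva = 40L,
    duration_s = 300, frame_rate_hz = 1,
    effect_active_neurons = 0.30, effect_firing_rate = -0.25,
    n_regions = 6L, affected_regions = c("region02", "region05"),
    atlas_shape = c(72L, 144L, 36L),
    # tail
    tail_frame_rate = 100, tail_noise_sd = 1.5,
    baseline_window_s = 60, resample_outlier_q = 0.90,
    # events
    gap_s = 2, peak_k = 3, struggle_k = 10, flip_ratio = 20,
    flip_floor_k = 3,
    # calcium
    calcium_window_s = 120, gamma = 0.9,
    # mapping / comparison
    min_overlap = 10L, voxel_um = 12, alpha = 0.05,
    cutoff_pct = 35,
    # clustering / connectivity
    t0 = 3L, stability = 0.2, connectivity_threshold = 0.8
  ), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Unknown keys are rejected with a message listing them; missing keys
#' fall back to [default_config()] values.
#'
#' @param config Named list of overrides (or a full `run_config`).
#' @return A complete validated `run_config`.
#' @export
validate_config <- function(config = list()) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  base[names(config)] <- config
  base
}

# per-stage seed derived from the master seed by stable hashing of the
# stage name, so stages can be rerun in isolation
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 48271 + h * 10007) %% 2147483629)
}

#' Run the full pipeline on synthetic data
#'
#' Orchestrates simulation, tail-event analysis, calcium processing,
#' atlas mapping, two-group comparison and motor clustering, writing
#' every stage's tables under `out_dir` plus a manifest with the
#' configuration and MD5 checksums of all outputs. Deterministic given
#' the config seed.
#'
#' @param config Configuration overrides (see [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- if (inherits(config, "run_config")) config
    else validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }
  wr_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <<- c(files, path)
    path
  }

  ## -- simulate -----------------------------------------------------
  atlas <- generate_toy_atlas(shape_voxels = cfg$atlas_shape,
                              n_regions = cfg$n_regions,
                              seed = stage_seed(cfg$seed, "atlas"))
  spec <- cohort_spec(
    n_control = cfg$n_control, n_deficient = cfg$n_deficient,
    neurons_per_larva = cfg$neurons_per_larva,
    effect_active_neurons = cfg$effect_active_neurons,
    effect_firing_rate = cfg$effect_firing_rate,
    affected_region_labels = cfg$affected_regions,
    duration_s = cfg$duration_s, frame_rate_hz = cfg$frame_rate_hz,
    seed = stage_seed(cfg$seed, "cohort"))
  cohort <- generate_calcium_cohort(spec, atlas = atlas,
                                    gamma = cfg$gamma)
  wr_csv(cohort$ground_truth$neurons, "ground_truth_neurons.csv")

  ## -- tail traces + events -----------------------------------------
  tail_rows <- list()
  tails_1hz <- list()
  for (i in seq_along(cohort$larvae)) {
    lv <- cohort$larvae[[i]]
    # event density scales with the planted struggle phenotype and the
    # plan always fits the recording
    slots <- max(2L, floor((cfg$duration_s - 12) / 15))
    n_ev <- if (lv$group == "deficient") slots else
      max(2L, round(slots * 0.6))
    types <- rep(c("swim", "struggle", "right_flip", "left_flip"),
                 length.out = n_ev)
    spacing <- (cfg$duration_s - 10) / n_ev - 0.6 - 1
    plan <- tail_event_plan(types, noise_sd = cfg$tail_noise_sd,
                            spacing_s = spacing, start_s = 5)
    gen <- generate_tail_trace(plan, noise_sd = cfg$tail_noise_sd,
                               frame_rate = cfg$tail_frame_rate,
                               duration_s = cfg$duration_s,
                               seed = stage_seed(cfg$seed,
                                                 paste0("tail", i)))
    tr <- remove_baseline(fill_nans(gen$trace), cfg$baseline_window_s)
    ev <- detect_tail_events(tr, gap_s = cfg$gap_s, peak_k = cfg$peak_k,
                             struggle_k = cfg$struggle_k,
                             flip_ratio = cfg$flip_ratio,
                             flip_floor_k = cfg$flip_floor_k)
    sm <- summarize_events(ev, tr)
    tail_rows[[i]] <- data.frame(
      larva = lv$id, group = lv$group,
      n_events = nrow(ev), n_struggle = unname(sm$counts["struggle"]),
      n_swim = unname(sm$counts["swim"]),
      cum_trace_deg = sm$cum_trace_deg,
      noise_floor = attr(ev, "noise_floor"))
    tails_1hz[[i]] <- resample_to_imaging(
      tr, target_hz = cfg$frame_rate_hz,
      outlier_q = cfg$resample_outlier_q)$angle_deg
  }
  wr_csv(do.call(rbind, tail_rows), "tail_summary.csv")

  ## -- calcium + mapping --------------------------------------------
  tables <- list()
  larv_stats <- list()
  for (i in seq_along(cohort$larvae)) {
    lv <- cohort$larvae[[i]]
    proc <- process_calcium_traces(lv$raw, fs = cfg$frame_rate_hz,
                                   gamma = cfg$gamma,
                                   duration_s = cfg$duration_s)
    tab <- region_table(lv$centroid_um, proc$cum_dff_z,
                        proc$firing_rate_hz, proc$active, atlas,
                        min_overlap = cfg$min_overlap)
    tab <- cbind(larva = lv$id, group = lv$group, tab)
    tables[[i]] <- tab
    larv_stats[[i]] <- list(centroid_um = lv$centroid_um,
                            cum_dff_z = proc$cum_dff_z,
                            firing_rate_hz = proc$firing_rate_hz,
                            active = proc$active,
                            dff = proc$dff, group = lv$group)
  }
  wr_csv(do.call(rbind, tables), "region_tables.csv")

  ## -- group comparison ---------------------------------------------
  is_ctrl <- vapply(larv_stats, function(l) l$group == "control",
                    logical(1))
  hm_c <- build_heatmaps(larv_stats[is_ctrl], atlas$grid, cfg$voxel_um)
  hm_d <- build_heatmaps(larv_stats[!is_ctrl], atlas$grid, cfg$voxel_um)
  cmp <- voxelwise_test(hm_c, hm_d, alpha = cfg$alpha)
  rel <- map_to_masks(cmp, atlas, atlas$grid)
  wr_csv(rel, "relevance_table.csv")
  tc <- lapply(tables[is_ctrl], identity)
  td <- lapply(tables[!is_ctrl], identity)
  rt <- region_test(tc, td, metric = "n_active", alpha = cfg$alpha)
  wr_csv(rt, "region_test_active.csv")

  ## -- motor clustering ---------------------------------------------
  part_rows <- list()
  for (i in seq_along(larv_stats)) {
    act <- t(larv_stats[[i]]$dff)
    tail1 <- tails_1hz[[i]][seq_len(ncol(act))]
    part <- tryCatch(
      motor_partition(act, tail1, t0 = cfg$t0,
                      stability = cfg$stability),
      error = function(e) NULL)
    part_rows[[i]] <- data.frame(
      larva = cohort$larvae[[i]]$id,
      group = cohort$larvae[[i]]$group,
      n_motor = if (is.null(part)) NA_integer_ else sum(part$motor),
      t_final = if (is.null(part)) NA_integer_ else part$t)
  }
  wr_csv(do.call(rbind, part_rows), "motor_partition.csv")

  ## -- manifest ------------------------------------------------------
  sums <- tools::md5sum(files)
  manifest <- list(config = unclass(cfg),
                   files = c(basename(files), "manifest.json"),
                   md5 = as.list(stats::setNames(unname(sums),
                                                 basename(files))))
  wr_json(manifest, "manifest.json")
  invisible(manifest)
}
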