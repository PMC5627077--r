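#' Pipeline run configuration
#'
#' Bundles everything an end-to-end run needs: either an input directory of
#' trajectory files (with a `metadata.csv`) or a simulation design, plus
#' calibration, windowing, binning and output settings.
#'
#' @param out_dir output directory (created if missing).
#' @param input_dir directory with `metadata.csv` (columns `trial_id`,
#'   `treatment`, `file`, optionally `period`) and trajectory CSVs; `NULL`
#'   when simulating.
#' @param sim_design,sim_base a [study_design_config()] and [sim_config()]
#'   used when `input_dir` is `NULL`.
#' @param fps,mm_per_unit calibration applied when reading trajectories.
#' @param windows list of [sampling_window()]s applied to full-length trials
#'   (ignored when the metadata already carries a `period` column);
#'   default [period_windows()].
#' @param max_gap gap-fill cap in frames (see [fill_gaps()]).
#' @param diff_method,min_heading_speed kinematics settings
#'   (see [compute_kinematics()]).
#' @param speed_edges,distance_edges pairwise-correlation grid edges.
#' @param xy_edges focal-map edges (used for both axes).
#' @param min_count per-cell minimum for exported surfaces.
#' @param write_figures also render heat-map PNGs (default `FALSE`).
#' @param seed seed for any simulation stage.
#' @param verbose print stage progress.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, input_dir = NULL, sim_design = NULL,
                       sim_base = NULL, fps = 25, mm_per_unit = 1,
                       windows = NULL, max_gap = 5,
                       diff_method = "central", min_heading_speed = 1,
                       speed_edges = seq(0, 200, by = 10),
                       distance_edges = seq(0, 200, by = 10),
                       xy_edges = seq(-100, 100, by = 10),
                       min_count = 10, write_figures = FALSE,
                       seed = 1, verbose = FALSE) {
  structure(list(out_dir = out_dir, input_dir = input_dir,
                 sim_design = sim_design, sim_base = sim_base,
                 fps = fps, mm_per_unit = mm_per_unit, windows = windows,
                 max_gap = max_gap, diff_method = diff_method,
                 min_heading_speed = min_heading_speed,
                 speed_edges = speed_edges, distance_edges = distance_edges,
                 xy_edges = xy_edges, min_count = min_count,
                 write_figures = write_figures, seed = seed,
                 verbose = verbose),
            class = "run_config")
}

#' Simulate a study and write trajectory files
#'
#' Writes one canonical tabular CSV per trial x period plus a
#' `metadata.csv` (trial_id, treatment, period, file, seed) into
#' `cfg$out_dir`.
#'
#' @param cfg a [run_config()] with `sim_design`/`sim_base` set (defaults
#'   are used when `NULL`).
#' @return the metadata data.frame, invisibly.
#' @export
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  design <- cfg$sim_design
  if (is.null(design)) design <- study_design_config(seed = cfg$seed)
  base <- cfg$sim_base
  if (is.null(base)) base <- sim_config()
  validate_sim_config(base)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(design, base)
  rows <- list()
  for (id in names(study$trials)) for (per in c("period1", "period2")) {
    ts <- study$trials[[id]][[per]]
    fn <- sprintf("%s_%s.csv", id, per)
    write_trajectories(ts, file.path(cfg$out_dir, fn))
    rows[[length(rows) + 1L]] <- data.frame(
      trial_id = id, treatment = ts$treatment, period = per, file = fn,
      seed = study$metadata[study$metadata$trial_id == id,
                            paste0("seed_", per)],
      stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, rows)
  write.csv(meta, file.path(cfg$out_dir, "metadata.csv"), row.names = FALSE)
  if (cfg$verbose)
    message("simulated ", length(study$trials), " trials -> ", cfg$out_dir)
  invisible(meta)
}

#' Analyse a set of windowed trials
#'
#' The pure core of the pipeline: takes windowed [trajectory_set()]s and
#' returns metric tables, per-treatment-x-period pairwise-correlation grids
#' and focal alignment maps, and the three repeated-measures model fits.
#'
#' @param trials named list; each element a list with `$period1` and
#'   `$period2` trajectory sets.
#' @param cfg a [run_config()] (binning/kinematics settings are read from
#'   it).
#' @return list with `group_metrics`, `individual_metrics`, `grids`,
#'   `maps` (named `treatment.period`), and `models` (a `model_fit`
#'   data.frame stacking polarization, log_speed and log_nnd fits).
#' @export
analyze_study <- function(trials, cfg = run_config(out_dir = tempdir())) {
  grp <- list(); ind <- list()
  pair_obs <- list(); focal_obs <- list()
  for (id in names(trials)) for (per in c("period1", "period2")) {
    t0 <- trials[[id]][[per]]
    if (is.null(t0)) stop("trial ", id, " lacks ", per)
    t1 <- fill_gaps(t0, max_gap = cfg$max_gap)
    k <- compute_kinematics(t1, method = cfg$diff_method,
                            min_heading_speed = cfg$min_heading_speed)
    m <- metric_records_from(t1, k, per)
    grp[[length(grp) + 1L]] <- m$group
    ind[[length(ind) + 1L]] <- m$individual
    key <- paste(t1$treatment, per, sep = ".")
    po <- pair_observations(k, t1)
    fo <- focal_transform(k, t1)
    pair_obs[[key]] <- c(pair_obs[[key]], list(po))
    focal_obs[[key]] <- c(focal_obs[[key]], list(fo))
  }
  group_metrics <- do.call(rbind, grp)
  individual_metrics <- do.call(rbind, ind)
  grids <- lapply(pair_obs, function(l)
    bin_speed_distance(do.call(rbind, l), cfg$speed_edges, cfg$distance_edges))
  maps <- lapply(focal_obs, function(l)
    bin_focal_map(do.call(rbind, l), cfg$xy_edges, cfg$xy_edges))
  models <- rbind(fit_group_model(group_metrics),
                  fit_individual_model(individual_metrics, "log_speed"),
                  fit_individual_model(individual_metrics, "log_nnd"))
  list(group_metrics = group_metrics, individual_metrics = individual_metrics,
       grids = grids, maps = maps, models = models)
}

# metric_records() recomputes kinematics; this variant reuses an existing one
metric_records_from <- function(t, k, period) {
  p <- mean_polarization(polarization_timeseries(k))
  nnd <- nearest_neighbour_distances(t)
  list(group = data.frame(trial_id = t$trial_id, treatment = t$treatment,
                          period = period,
                          mean_polarization = as.numeric(p),
                          n_frames_used = attr(p, "n_frames_used"),
                          stringsAsFactors = FALSE),
       individual = data.frame(
         trial_id = t$trial_id, treatment = t$treatment, period = period,
         fish_id = seq_len(t$n_individuals),
         median_speed = vapply(seq_len(t$n_individuals), function(i)
           suppressWarnings(median_speed(k, i)), numeric(1)),
         mean_nnd = vapply(seq_len(t$n_individuals), function(i)
           mean(nnd[, i], na.rm = TRUE), numeric(1)),
         stringsAsFactors = FALSE))
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) trajectories, windows them, computes all metrics,
#' surfaces and model fits, and writes every output as CSV into
#' `cfg$out_dir` together with a `manifest.csv` listing the files produced.
#' Deterministic: the same inputs, configuration and seed give byte-identical
#' CSVs.
#'
#' @param cfg a [run_config()].
#' @return the [analyze_study()] bundle, with `$manifest` added, invisibly.
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- load_study_trials(cfg)
  res <- analyze_study(trials, cfg)
  out <- character()
  wr <- function(d, fn) {
    path <- file.path(cfg$out_dir, fn)
    write.csv(d, path, row.names = FALSE)
    out <<- c(out, fn)
  }
  wr(res$group_metrics, "group_metrics.csv")
  wr(res$individual_metrics, "individual_metrics.csv")
  for (key in names(res$grids))
    wr(as.data.frame(res$grids[[key]], min_count = cfg$min_count),
       sprintf("pair_correlation_%s.csv", key))
  for (key in names(res$maps))
    wr(as.data.frame(res$maps[[key]], min_count = cfg$min_count),
       sprintf("focal_alignment_%s.csv", key))
  wr(res$models, "models.csv")
  if (isTRUE(cfg$write_figures)) {
    for (key in names(res$grids)) {
      fn <- sprintf("pair_correlation_%s.png", key)
      ok <- tryCatch({
        ggplot2::ggsave(file.path(cfg$out_dir, fn),
                        plot_speed_distance_grid(res$grids[[key]],
                                                 min_count = cfg$min_count),
                        width = 6, height = 5, dpi = 150)
        TRUE
      }, error = function(e) FALSE)
      if (ok) out <- c(out, fn)
    }
    for (key in names(res$maps)) {
      fn <- sprintf("focal_alignment_%s.png", key)
      ok <- tryCatch({
        ggplot2::ggsave(file.path(cfg$out_dir, fn),
                        plot_focal_map(res$maps[[key]],
                                       min_count = cfg$min_count),
                        width = 6, height = 5, dpi = 150)
        TRUE
      }, error = function(e) FALSE)
      if (ok) out <- c(out, fn)
    }
  }
  manifest <- data.frame(file = out, stringsAsFactors = FALSE)
  write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
            row.names = FALSE)
  res$manifest <- manifest
  if (cfg$verbose) message("wrote ", nrow(manifest), " files to ", cfg$out_dir)
  invisible(res)
}

load_study_trials <- function(cfg) {
  if (is.null(cfg$input_dir)) {
    design <- cfg$sim_design
    if (is.null(design)) design <- study_design_config(seed = cfg$seed)
    base <- cfg$sim_base
    if (is.null(base)) base <- sim_config()
    return(simulate_study(design, base)$trials)
  }
  meta_path <- file.path(cfg$input_dir, "metadata.csv")
  if (!file.exists(meta_path))
    stop("input error: missing ", meta_path)
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("trial_id", "treatment", "file")
  if (!all(need %in% names(meta)))
    stop("metadata.csv must have columns trial_id, treatment, file")
  windows <- cfg$windows
  if (is.null(windows)) windows <- period_windows(cfg$fps)
  trials <- list()
  for (r in seq_len(nrow(meta))) {
    path <- file.path(cfg$input_dir, meta$file[r])
    if (!file.exists(path))
      stop("input error: trial ", meta$trial_id[r], ": missing file ", path)
    ts <- read_trajectories(path, format = "tabular_csv", fps = cfg$fps,
                            mm_per_unit = cfg$mm_per_unit,
                            trial_id = meta$trial_id[r],
                            treatment = meta$treatment[r])
    id <- meta$trial_id[r]
    if ("period" %in% names(meta)) {
      trials[[id]][[meta$period[r]]] <- ts
    } else {
      trials[[id]] <- list(period1 = extract_window(ts, windows$period1),
                           period2 = extract_window(ts, windows$period2))
    }
  }
  trials
}
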