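#' Simulator configuration
#'
#' Defaults describe the reference study conditions: groups of 4 fish in an
#' annular arena of inner/outer radius 135/330 mm (a 195 mm channel), filmed
#' at 25 fps for 5-minute windows. Speeds are drawn per frame from a
#' lognormal (positively skewed, median `exp(speed_log_mean)` mm/s);
#' headings relax toward a desired direction combining alignment with
#' neighbours, attraction to the neighbour centroid, and wall avoidance,
#' then receive wrapped-normal noise.
#'
#' @param n_fish number of fish (default 4).
#' @param inner_radius,outer_radius annulus radii in mm (135 / 330).
#' @param fps frames per second (25).
#' @param duration simulated seconds (default 300, one 5-min window).
#' @param alignment_weight weight of the mean neighbour heading (default 0.5).
#' @param attraction_weight weight of the unit vector toward the neighbour
#'   centroid (default 0.2).
#' @param wall_weight weight of the inward normal near walls (default 1.5).
#' @param heading_noise_sd wrapped-normal heading noise, radians per step
#'   (default 0.5).
#' @param speed_log_mean,speed_log_sd lognormal speed parameters
#'   (defaults `log(60)` and 0.5: median 60 mm/s, right-skewed).
#' @param interaction_range neighbourhood radius in mm (default 100, a few
#'   body lengths: alignment and attraction are local).
#' @param gap_rate per-frame per-fish probability of a deleted fix,
#'   mimicking occlusions (default 0.005).
#' @param turn_rate fraction of the angle to the desired direction turned
#'   per step, in (0, 1] (default 0.5).
#' @param wall_zone width in mm of the wall-avoidance ramp (default 20).
#' @param seed integer; if non-NULL, `simulate_trial` seeds R's RNG with it.
#' @param init_positions optional `[n_fish, 2]` matrix of start positions in
#'   mm (must lie inside the annulus); default random.
#' @param init_heading optional start heading angles (radians).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_fish = 4, inner_radius = 135, outer_radius = 330,
                       fps = 25, duration = 300,
                       alignment_weight = 0.5, attraction_weight = 0.2,
                       wall_weight = 1.5, heading_noise_sd = 0.5,
                       speed_log_mean = log(60), speed_log_sd = 0.5,
                       interaction_range = 100, gap_rate = 0.005,
                       turn_rate = 0.5, wall_zone = 20,
                       seed = NULL, init_positions = NULL,
                       init_heading = NULL) {
  cfg <- list(n_fish = n_fish, inner_radius = inner_radius,
              outer_radius = outer_radius, fps = fps, duration = duration,
              alignment_weight = alignment_weight,
              attraction_weight = attraction_weight,
              wall_weight = wall_weight, heading_noise_sd = heading_noise_sd,
              speed_log_mean = speed_log_mean, speed_log_sd = speed_log_sd,
              interaction_range = interaction_range, gap_rate = gap_rate,
              turn_rate = turn_rate, wall_zone = wall_zone, seed = seed,
              init_positions = init_positions, init_heading = init_heading)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(c) {
  if (!(c$inner_radius > 0 && c$inner_radius < c$outer_radius))
    stop("need 0 < inner_radius < outer_radius")
  for (w in c("alignment_weight", "attraction_weight", "wall_weight"))
    if (c[[w]] < 0) stop("`", w, "` must be >= 0")
  if (c$gap_rate < 0 || c$gap_rate >= 1) stop("`gap_rate` must be in [0, 1)")
  if (c$fps <= 0 || c$duration <= 0) stop("fps and duration must be positive")
  if (c$n_fish < 2) stop("need at least 2 fish")
  if (c$turn_rate <= 0 || c$turn_rate > 1) stop("`turn_rate` must be in (0, 1]")
  if (!is.null(c$init_positions)) {
    p <- c$init_positions
    if (!is.matrix(p) || nrow(p) != c$n_fish || ncol(p) != 2)
      stop("`init_positions` must be an [n_fish, 2] matrix")
    r <- sqrt(rowSums(p^2))
    if (any(r < c$inner_radius | r > c$outer_radius))
      stop("initial position outside the annulus (radius ",
           paste(round(r[r < c$inner_radius | r > c$outer_radius], 1),
                 collapse = ", "), " mm)")
  }
  invisible(c)
}

#' Simulate one trial
#'
#' Runs the agent-based shoal model (see [sim_config()]) and returns the
#' trajectories as a [trajectory_set()] in mm, with fixes deleted at
#' `gap_rate` to mimic tracking occlusions. Fully reproducible: the same
#' `seed` yields bit-identical trajectories.
#'
#' @param config a [sim_config()].
#' @param trial_id,treatment metadata for the emitted trajectory set.
#' @return a [trajectory_set()].
#' @export
simulate_trial <- function(config, trial_id = "sim",
                           treatment = c("unfamiliar", "familiar")) {
  treatment <- match.arg(treatment)
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_fish
  n_frames <- max(2L, as.integer(round(config$duration * config$fps)))
  if (is.null(config$init_positions)) {
    # release-style start: the group begins clustered (as if freed from a
    # holding cylinder) at a random spot in the middle of the channel
    mid <- (config$inner_radius + config$outer_radius) / 2
    spread <- min(60, (config$outer_radius - config$inner_radius) / 3)
    ang0 <- runif(1, 0, 2 * pi)
    cx <- mid * cos(ang0); cy <- mid * sin(ang0)
    oa <- runif(n, 0, 2 * pi)
    orr <- spread * sqrt(runif(n))
    init_x <- cx + orr * cos(oa); init_y <- cy + orr * sin(oa)
    rad <- sqrt(init_x^2 + init_y^2)
    clamp <- pmin(config$outer_radius, pmax(config$inner_radius, rad))
    init_x <- init_x * clamp / rad; init_y <- init_y * clamp / rad
  } else {
    init_x <- config$init_positions[, 1]
    init_y <- config$init_positions[, 2]
  }
  init_theta <- if (is.null(config$init_heading))
    runif(n, -pi, pi) else rep_len(config$init_heading, n)
  pos <- sim_annulus_core(n, n_frames,
                          config$inner_radius, config$outer_radius,
                          config$fps, config$alignment_weight,
                          config$attraction_weight, config$wall_weight,
                          config$heading_noise_sd, config$speed_log_mean,
                          config$speed_log_sd, config$interaction_range,
                          config$turn_rate, config$wall_zone,
                          init_x, init_y, init_theta)
  dim(pos) <- c(n_frames, n, 2)
  gap <- matrix(runif(n_frames * n) < config$gap_rate, n_frames, n)
  pos[, , 1][gap] <- NA_real_
  pos[, , 2][gap] <- NA_real_
  trajectory_set(pos, gap_mask = gap, trial_id = trial_id,
                 treatment = treatment, fps = config$fps, mm_per_unit = 1)
}

#' Study design configuration
#'
#' Describes a two-treatment repeated-measures study: `n_groups_per_treatment`
#' familiar and unfamiliar groups, each observed in two sampling periods.
#' Familiar groups receive `alignment_weight + familiarity_alignment_delta`;
#' period-2 segments are regenerated with each named parameter multiplied by
#' its `period2_modifiers` entry (e.g. `list(alignment_weight = 0.8)` for a
#' habituation-like decline).
#'
#' @param n_groups_per_treatment groups per treatment (default 6).
#' @param familiarity_alignment_delta added alignment weight for familiar
#'   groups (default 0.5).
#' @param period2_modifiers named list of multiplicative modifiers applied
#'   to sim parameters in period 2 (default none).
#' @param seed master seed; per-trial, per-period seeds are derived from it
#'   deterministically.
#' @return a `study_design_config` list.
#' @export
study_design_config <- function(n_groups_per_treatment = 6,
                                familiarity_alignment_delta = 0.5,
                                period2_modifiers = list(),
                                seed = 1) {
  if (n_groups_per_treatment < 1) stop("need at least 1 group per treatment")
  structure(list(n_groups_per_treatment = n_groups_per_treatment,
                 familiarity_alignment_delta = familiarity_alignment_delta,
                 period2_modifiers = period2_modifiers, seed = seed),
            class = "study_design_config")
}

# deterministic sub-stream seed, kept below 2^31
derive_seed <- function(master, index) {
  as.integer((as.double(master %% 2147483647L) * 69069 +
                index * 1013904223) %% 2147483647)
}

#' Simulate a full study
#'
#' Generates `2 * n_groups_per_treatment` trials, each with two sampling
#' periods simulated independently (the period-2 segment with
#' `period2_modifiers` applied). Per-trial seeds are derived from the design
#' seed so trials are independent yet the whole study is reproducible.
#'
#' @param design a [study_design_config()].
#' @param base a [sim_config()] used for unfamiliar groups in period 1.
#' @return list with `trials` (named list; each element has `$period1` and
#'   `$period2` [trajectory_set()]s) and `metadata` (data.frame: trial_id,
#'   treatment, seed_period1, seed_period2).
#' @export
simulate_study <- function(design, base = sim_config()) {
  stopifnot(inherits(design, "study_design_config"))
  n_per <- design$n_groups_per_treatment
  treatments <- rep(c("familiar", "unfamiliar"), each = n_per)
  trial_ids <- sprintf("%s%02d", ifelse(treatments == "familiar", "fam", "unf"),
                       c(seq_len(n_per), seq_len(n_per)))
  trials <- vector("list", length(trial_ids))
  names(trials) <- trial_ids
  meta <- data.frame(trial_id = trial_ids, treatment = treatments,
                     seed_period1 = NA_integer_, seed_period2 = NA_integer_,
                     stringsAsFactors = FALSE)
  for (i in seq_along(trial_ids)) {
    cfg <- base
    if (treatments[i] == "familiar")
      cfg$alignment_weight <- cfg$alignment_weight +
        design$familiarity_alignment_delta
    cfg2 <- cfg
    for (nm in names(design$period2_modifiers)) {
      if (!nm %in% names(cfg2)) stop("unknown period2 modifier: ", nm)
      cfg2[[nm]] <- cfg2[[nm]] * design$period2_modifiers[[nm]]
    }
    s1 <- derive_seed(design$seed, 2L * i - 1L)
    s2 <- derive_seed(design$seed, 2L * i)
    cfg$seed <- s1; cfg2$seed <- s2
    trials[[i]] <- list(
      period1 = simulate_trial(cfg, trial_id = trial_ids[i],
                               treatment = treatments[i]),
      period2 = simulate_trial(cfg2, trial_id = trial_ids[i],
                               treatment = treatments[i]))
    meta$seed_period1[i] <- s1
    meta$seed_period2[i] <- s2
  }
  list(trials = trials, metadata = meta)
}
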