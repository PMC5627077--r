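# Builders and independent oracles shared across the suite.

# trajectory set from a list of per-fish [frames x 2] matrices
ts_from_list <- function(paths, fps = 25, ...) {
  n_fr <- nrow(paths[[1]])
  pos <- array(NA_real_, c(n_fr, length(paths), 2))
  for (i in seq_along(paths)) pos[, i, ] <- paths[[i]]
  trajectory_set(pos, fps = fps, ...)
}

# constant-velocity trajectories: each fish starts at `origin[i, ]` and moves
# by `step[i, ]` mm per frame
straight_ts <- function(origins, steps, n_fr = 10, fps = 25, ...) {
  paths <- lapply(seq_len(nrow(origins)), function(i) {
    cbind(origins[i, 1] + (0:(n_fr - 1)) * steps[i, 1],
          origins[i, 2] + (0:(n_fr - 1)) * steps[i, 2])
  })
  ts_from_list(paths, fps = fps, ...)
}

# minimal kinematic_series with prescribed heading angles (frames x fish);
# used where a test needs exact headings rather than differentiated paths
ks_from_angles <- function(theta, speed = 100, fps = 25) {
  n_fr <- nrow(theta); n_id <- ncol(theta)
  valid <- !is.na(theta)
  heading <- array(NA_real_, c(n_fr, n_id, 2))
  heading[, , 1][valid] <- cos(theta[valid])
  heading[, , 2][valid] <- sin(theta[valid])
  vel <- heading * speed
  structure(list(velocity = vel,
                 speed = matrix(ifelse(valid, speed, NA_real_), n_fr, n_id),
                 heading = heading, heading_angle = theta,
                 valid_mask = valid, speed_valid = valid,
                 fps = fps, n_frames = n_fr, n_individuals = n_id),
            class = "kinematic_series")
}

# rotate all positions of a trajectory set by phi around the origin
rotate_ts <- function(t, phi) {
  x <- t$positions[, , 1]; y <- t$positions[, , 2]
  p <- t$positions
  p[, , 1] <- cos(phi) * x - sin(phi) * y
  p[, , 2] <- sin(phi) * x + cos(phi) * y
  trajectory_set(p, gap_mask = t$gap_mask, trial_id = t$trial_id,
                 treatment = t$treatment, fps = t$fps,
                 mm_per_unit = t$mm_per_unit)
}

translate_ts <- function(t, dx, dy) {
  p <- t$positions
  p[, , 1] <- p[, , 1] + dx
  p[, , 2] <- p[, , 2] + dy
  trajectory_set(p, gap_mask = t$gap_mask, trial_id = t$trial_id,
                 treatment = t$treatment, fps = t$fps,
                 mm_per_unit = t$mm_per_unit)
}

# brute-force nearest-neighbour distances for one frame of points
bf_nnd_frame <- function(xy) {
  n <- nrow(xy)
  sapply(seq_len(n), function(i) {
    d <- sqrt((xy[i, 1] - xy[-i, 1])^2 + (xy[i, 2] - xy[-i, 2])^2)
    min(d)
  })
}

# brute-force per-cell averaging oracle for the speed x distance grid
bf_bin_oracle <- function(obs, s_edges, d_edges) {
  ns <- length(s_edges) - 1L; nd <- length(d_edges) - 1L
  mean_r <- matrix(NA_real_, ns, nd)
  count <- matrix(0L, ns, nd)
  overflow <- 0L
  for (o in seq_len(nrow(obs))) {
    s <- obs$mutual_speed[o]; d <- obs$distance[o]
    si <- NA; di <- NA
    for (i in seq_len(ns)) if (s >= s_edges[i] && s < s_edges[i + 1]) si <- i
    for (j in seq_len(nd)) if (d >= d_edges[j] && d < d_edges[j + 1]) di <- j
    if (is.na(si) || is.na(di)) { overflow <- overflow + 1L; next }
    count[si, di] <- count[si, di] + 1L
    mean_r[si, di] <- if (is.na(mean_r[si, di])) obs$r[o] else
      mean_r[si, di] + obs$r[o]
  }
  nz <- count > 0
  mean_r[nz] <- mean_r[nz] / count[nz]
  list(mean_r = mean_r, count = count, overflow = overflow)
}

# direct unit-vector-sum circular statistics oracle
circ_oracle <- function(angles) {
  z <- sum(complex(argument = angles)) / length(angles)
  list(R = Mod(z), mean_direction = Arg(z))
}

# independent Benjamini-Hochberg step-up enumeration
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  sig <- rep(FALSE, m)
  if (k > 0) sig[o[seq_len(k)]] <- TRUE
  sig
}

# balanced synthetic metric tables for the inference module
make_group_records <- function(n_groups = 12, fam_effect = 0,
                               time_effect = 0, sd = 0.05, base = 0.7,
                               seed = 1) {
  set.seed(seed)
  treatment <- rep(c("unfamiliar", "familiar"), each = n_groups / 2)
  g <- expand.grid(trial_id = sprintf("g%02d", seq_len(n_groups)),
                   period = c("period1", "period2"),
                   stringsAsFactors = FALSE)
  g$treatment <- treatment[as.integer(sub("g", "", g$trial_id))]
  g$mean_polarization <- base +
    fam_effect * (g$treatment == "familiar") +
    time_effect * (g$period == "period2") +
    rnorm(nrow(g), 0, sd)
  g$n_frames_used <- 1000L
  g
}

make_individual_records <- function(n_groups = 12, n_fish = 4,
                                    fam_effect = 0, time_effect = 0,
                                    sd = 0.1, base = 60, seed = 1) {
  set.seed(seed)
  treatment <- rep(c("unfamiliar", "familiar"), each = n_groups / 2)
  g <- expand.grid(trial_id = sprintf("g%02d", seq_len(n_groups)),
                   fish_id = seq_len(n_fish),
                   period = c("period1", "period2"),
                   stringsAsFactors = FALSE)
  g$treatment <- treatment[as.integer(sub("g", "", g$trial_id))]
  lin <- fam_effect * (g$treatment == "familiar") +
    time_effect * (g$period == "period2") + rnorm(nrow(g), 0, sd)
  g$median_speed <- base * exp(lin)
  g$mean_nnd <- 50 * exp(lin)
  g
}

# group-polarization records from a simulated study (fast path used by the
# calibration-style tests: kinematics + polarization only)
study_group_records <- function(study) {
  rows <- lapply(names(study$trials), function(id) {
    tr <- study$trials[[id]]
    do.call(rbind, lapply(c("period1", "period2"), function(per) {
      ts <- tr[[per]]
      p <- mean_polarization(polarization_timeseries(compute_kinematics(ts)))
      data.frame(trial_id = id, treatment = ts$treatment, period = per,
                 mean_polarization = as.numeric(p),
                 n_frames_used = attr(p, "n_frames_used"),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

table1_pvalues <- function() {
  # nine p-values of the published repeated-measures family;
  # "<0.001" encoded as 0.0005 (any value <= 0.001 gives the same decision)
  c(polarization_familiarity = 0.007, polarization_time = 0.057,
    polarization_interaction = 0.096, speed_familiarity = 0.023,
    speed_time = 0.0005, speed_interaction = 0.021,
    nnd_familiarity = 0.164, nnd_time = 0.035, nnd_interaction = 0.235)
}
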