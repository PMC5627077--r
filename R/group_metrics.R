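#' Per-frame group polarization
#'
#' Polarization is the standard order parameter of collective motion: the
#' mean resultant length of the group's unit heading vectors,
#' `P = || sum_i h_i || / m` over the `m` individuals with a valid heading
#' in the frame. `P = 1` when all fish head the same way; directions that
#' cancel give `P = 0`. Frames with fewer than two valid headings carry no
#' information about alignment and are returned as `NA`.
#'
#' @param k a [compute_kinematics()] result.
#' @return numeric vector, one value per frame (`NA` for skipped frames).
#' @export
polarization_timeseries <- function(k) {
  stopifnot(inherits(k, "kinematic_series"))
  hx <- matrix(k$heading[, , 1], k$n_frames, k$n_individuals)
  hy <- matrix(k$heading[, , 2], k$n_frames, k$n_individuals)
  hx[!k$valid_mask] <- 0; hy[!k$valid_mask] <- 0
  m <- rowSums(k$valid_mask)
  p <- sqrt(rowSums(hx)^2 + rowSums(hy)^2) / m
  p <- ifelse(m >= 2L, p, NA_real_)
  if (all(is.na(p))) warning("no frame has 2 or more valid headings")
  p
}

#' Mean polarization over a window
#'
#' Arithmetic mean of the usable per-frame polarization values.
#'
#' @param series output of [polarization_timeseries()].
#' @return scalar in `[0, 1]`, with attribute `n_frames_used`.
#' @export
mean_polarization <- function(series) {
  ok <- !is.na(series)
  if (!any(ok)) stop("no usable frames in polarization series")
  structure(mean(series[ok]), n_frames_used = sum(ok))
}

#' Per-fish per-frame nearest-neighbour distances
#'
#' For each fish with a valid fix, the Euclidean distance (mm) to the
#' nearest other fish with a valid fix in the same frame. Frames with fewer
#' than two fixes give `NA` for every fish.
#'
#' @param t a [trajectory_set()].
#' @return numeric matrix `[frames, individuals]` of distances in mm.
#' @export
nearest_neighbour_distances <- function(t) {
  stopifnot(inherits(t, "trajectory_set"))
  n_fr <- t$n_frames; n_id <- t$n_individuals
  out <- matrix(NA_real_, n_fr, n_id)
  x <- t$positions[, , 1]; y <- t$positions[, , 2]
  ok <- !t$gap_mask
  # pairwise squared distances, vectorised over frames for each pair
  d2 <- array(Inf, c(n_fr, n_id, n_id))
  for (i in seq_len(n_id - 1L)) for (j in (i + 1L):n_id) {
    dd <- (x[, i] - x[, j])^2 + (y[, i] - y[, j])^2
    dd[!(ok[, i] & ok[, j])] <- Inf
    d2[, i, j] <- dd; d2[, j, i] <- dd
  }
  for (i in seq_len(n_id)) {
    mn <- apply(d2[, i, -i, drop = FALSE], 1, min)
    out[, i] <- ifelse(ok[, i] & is.finite(mn), sqrt(mn), NA_real_)
  }
  out
}

#' Median speed of one fish
#'
#' The median, not the mean, because individual speed distributions are
#' positively skewed; the median is robust to bursts.
#'
#' @param k a [compute_kinematics()] result.
#' @param fish_id individual index.
#' @return median speed in mm/s over frames with a computable speed
#'   (`NA` with a warning if there are none).
#' @export
median_speed <- function(k, fish_id) {
  stopifnot(inherits(k, "kinematic_series"))
  s <- k$speed[k$speed_valid[, fish_id], fish_id]
  if (length(s) == 0L) {
    warning("fish ", fish_id, " has no valid speed; returning NA")
    return(NA_real_)
  }
  median(s)
}

#' Group- and individual-level metric records for one trial window
#'
#' Computes the three response variables for one trial x sampling period:
#' the group's mean polarization, and each fish's median speed (mm/s) and
#' mean nearest-neighbour distance (mm).
#'
#' @param t a [trajectory_set()] already windowed to one sampling period.
#' @param period `"period1"` or `"period2"` label for the records.
#' @param ... passed to [compute_kinematics()].
#' @return list with `group` (1-row data.frame: trial_id, treatment, period,
#'   mean_polarization, n_frames_used) and `individual` (one row per fish:
#'   trial_id, treatment, period, fish_id, median_speed, mean_nnd).
#' @export
metric_records <- function(t, period = c("period1", "period2"), ...) {
  period <- match.arg(period)
  k <- compute_kinematics(t, ...)
  p <- mean_polarization(polarization_timeseries(k))
  nnd <- nearest_neighbour_distances(t)
  group <- data.frame(trial_id = t$trial_id, treatment = t$treatment,
                      period = period,
                      mean_polarization = as.numeric(p),
                      n_frames_used = attr(p, "n_frames_used"),
                      stringsAsFactors = FALSE)
  individual <- data.frame(
    trial_id = t$trial_id, treatment = t$treatment, period = period,
    fish_id = seq_len(t$n_individuals),
    median_speed = vapply(seq_len(t$n_individuals),
                          function(i) suppressWarnings(median_speed(k, i)),
                          numeric(1)),
    mean_nnd = vapply(seq_len(t$n_individuals),
                      function(i) mean(nnd[, i], na.rm = TRUE), numeric(1)),
    stringsAsFactors = FALSE)
  list(group = group, individual = individual)
}
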