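#' Compute velocities, speeds and unit headings
#'
#' Differentiates positions to per-frame velocity (mm/s), speed and unit
#' heading per individual. Central differences are the default:
#' `v[k] = (pos[k+1] - pos[k-1]) * fps / 2`, with one-sided differences at
#' the trial endpoints; `method = "forward"` uses `pos[k+1] - pos[k]`
#' throughout (backward at the last frame).
#'
#' Two validity masks are produced. `speed_valid` marks frames where the
#' velocity is computable (all positions the difference needs, plus the
#' frame's own fix, are present); speeds enter the median-speed statistic
#' wherever `speed_valid` holds. `valid_mask` additionally requires
#' `speed >= min_heading_speed`: headings taken from near-zero velocities
#' are dominated by tracking jitter and would corrupt polarization and
#' alignment statistics, so those frames carry no heading.
#'
#' @param t a [trajectory_set()].
#' @param method `"central"` (default) or `"forward"` differencing.
#' @param min_heading_speed minimum speed (mm/s) for a heading to be
#'   considered meaningful; default 1 mm/s.
#' @param smooth_window optional centred moving-average window (frames,
#'   odd, applied to positions before differencing); 0 = off (default, no
#'   smoothing).
#' @return an object of class `kinematic_series` with fields `velocity`
#'   (`[frames, individuals, 2]`, mm/s), `speed`, `heading_angle` (radians),
#'   `heading` (`[frames, individuals, 2]`, unit vectors), `valid_mask`,
#'   `speed_valid`, and `fps`.
#' @export
compute_kinematics <- function(t, method = c("central", "forward"),
                               min_heading_speed = 1, smooth_window = 0) {
  stopifnot(inherits(t, "trajectory_set"))
  method <- match.arg(method)
  n_fr <- t$n_frames; n_id <- t$n_individuals
  if (n_fr < 3L && method == "central")
    stop("central differences need at least 3 frames")
  if (n_fr < 2L) stop("need at least 2 frames to differentiate")

  pos <- t$positions
  present <- !t$gap_mask
  if (smooth_window > 1) {
    if (smooth_window %% 2 == 0) stop("`smooth_window` must be odd")
    pos <- smooth_positions(pos, present, smooth_window)
  }

  vel <- array(NA_real_, c(n_fr, n_id, 2))
  speed_valid <- matrix(FALSE, n_fr, n_id)
  fps <- t$fps
  if (method == "central") {
    k <- 2:(n_fr - 1L)
    for (c2 in 1:2)
      vel[k, , c2] <- (pos[k + 1L, , c2] - pos[k - 1L, , c2]) * fps / 2
    speed_valid[k, ] <- present[k - 1L, ] & present[k, ] & present[k + 1L, ]
    # one-sided differences at the endpoints
    for (c2 in 1:2) {
      vel[1L, , c2] <- (pos[2L, , c2] - pos[1L, , c2]) * fps
      vel[n_fr, , c2] <- (pos[n_fr, , c2] - pos[n_fr - 1L, , c2]) * fps
    }
    speed_valid[1L, ] <- present[1L, ] & present[2L, ]
    speed_valid[n_fr, ] <- present[n_fr - 1L, ] & present[n_fr, ]
  } else {
    k <- 1:(n_fr - 1L)
    for (c2 in 1:2) {
      vel[k, , c2] <- (pos[k + 1L, , c2] - pos[k, , c2]) * fps
      vel[n_fr, , c2] <- (pos[n_fr, , c2] - pos[n_fr - 1L, , c2]) * fps
    }
    speed_valid[k, ] <- present[k, ] & present[k + 1L, ]
    speed_valid[n_fr, ] <- present[n_fr - 1L, ] & present[n_fr, ]
  }
  vel[, , 1][!speed_valid] <- NA_real_
  vel[, , 2][!speed_valid] <- NA_real_

  speed <- sqrt(vel[, , 1]^2 + vel[, , 2]^2)
  speed <- matrix(speed, n_fr, n_id)
  valid <- speed_valid & !is.na(speed) & speed >= min_heading_speed

  heading <- array(NA_real_, c(n_fr, n_id, 2))
  heading[, , 1][valid] <- (vel[, , 1] / speed)[valid]
  heading[, , 2][valid] <- (vel[, , 2] / speed)[valid]
  angle <- matrix(NA_real_, n_fr, n_id)
  angle[valid] <- atan2(vel[, , 2][valid], vel[, , 1][valid])

  dead <- colSums(valid) == 0L
  if (any(dead))
    warning(sum(dead), " individual(s) have no valid heading in any frame")

  structure(list(velocity = vel, speed = speed, heading = heading,
                 heading_angle = angle, valid_mask = valid,
                 speed_valid = speed_valid, fps = fps,
                 n_frames = n_fr, n_individuals = n_id),
            class = "kinematic_series")
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("<kinematic_series> %d fish x %d frames; %.1f%% frames with valid heading\n",
              x$n_individuals, x$n_frames, 100 * mean(x$valid_mask)))
  invisible(x)
}

# centred moving average per individual/coordinate, NA-aware:
# a smoothed value is emitted only where the centre fix is present.
smooth_positions <- function(pos, present, w) {
  half <- (w - 1L) %/% 2L
  n_fr <- dim(pos)[1]; n_id <- dim(pos)[2]
  out <- pos
  for (i in seq_len(n_id)) {
    for (c2 in 1:2) {
      v <- pos[, i, c2]
      sm <- vapply(seq_len(n_fr), function(k) {
        idx <- max(1L, k - half):min(n_fr, k + half)
        vv <- v[idx][present[idx, i]]
        if (length(vv) == 0L) NA_real_ else mean(vv)
      }, numeric(1))
      out[, i, c2] <- ifelse(present[, i], sm, NA_real_)
    }
  }
  out
}
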