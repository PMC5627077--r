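#' Pairwise directional-correlation observations
#'
#' For every unordered pair of fish and every frame where both have a valid
#' heading and fix, records the pair's mutual speed (arithmetic mean of the
#' two instantaneous speeds, mm/s), the distance between them (mm), and the
#' zero-lag directional correlation `r` — the dot product of the two unit
#' headings, i.e. the cosine of the angle between the fish's directions of
#' travel, bounded in `[-1, 1]`.
#'
#' @param k a [compute_kinematics()] result.
#' @param t the matching [trajectory_set()].
#' @return data.frame with columns `fish_a`, `fish_b` (`a < b`), `frame`
#'   (1-based), `mutual_speed`, `distance`, `r`.
#' @export
pair_observations <- function(k, t) {
  stopifnot(inherits(k, "kinematic_series"), inherits(t, "trajectory_set"),
            k$n_frames == t$n_frames, k$n_individuals == t$n_individuals)
  n_id <- t$n_individuals
  ok <- k$valid_mask & !t$gap_mask
  res <- vector("list", n_id * (n_id - 1L) / 2L)
  idx <- 0L
  for (a in seq_len(n_id - 1L)) for (b in (a + 1L):n_id) {
    use <- which(ok[, a] & ok[, b])
    idx <- idx + 1L
    if (length(use) == 0L) next
    dx <- t$positions[use, a, 1] - t$positions[use, b, 1]
    dy <- t$positions[use, a, 2] - t$positions[use, b, 2]
    res[[idx]] <- data.frame(
      fish_a = a, fish_b = b, frame = use,
      mutual_speed = (k$speed[use, a] + k$speed[use, b]) / 2,
      distance = sqrt(dx^2 + dy^2),
      r = k$heading[use, a, 1] * k$heading[use, b, 1] +
        k$heading[use, a, 2] * k$heading[use, b, 2])
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(fish_a = integer(), fish_b = integer(),
                      frame = integer(), mutual_speed = numeric(),
                      distance = numeric(), r = numeric())
  # clamp rounding spill just outside [-1, 1]
  out$r <- pmin(1, pmax(-1, out$r))
  out
}

#' Bin pair observations on a speed x distance grid
#'
#' Assigns each observation to its half-open cell
#' `[speed_i, speed_{i+1}) x [dist_j, dist_{j+1})` and averages `r` per
#' cell, the surface behind directional-correlation heat maps.
#' Observations outside the outermost edges are dropped and tallied in
#' `overflow`, so `sum(count) + overflow` equals the input size.
#'
#' @param obs data.frame from [pair_observations()].
#' @param speed_edges,distance_edges strictly increasing bin boundaries
#'   (defaults: 0--200 mm/s and 0--200 mm in steps of 10).
#' @return object of class `speed_distance_grid` with matrices `mean_r`
#'   (`NA` where `count == 0`) and `count` (rows = speed bins, cols =
#'   distance bins), the edges, and `overflow`.
#' @export
bin_speed_distance <- function(obs, speed_edges = seq(0, 200, by = 10),
                               distance_edges = seq(0, 200, by = 10)) {
  check_edges(speed_edges, "speed_edges")
  check_edges(distance_edges, "distance_edges")
  ns <- length(speed_edges) - 1L
  nd <- length(distance_edges) - 1L
  si <- findInterval(obs$mutual_speed, speed_edges, left.open = FALSE)
  di <- findInterval(obs$distance, distance_edges, left.open = FALSE)
  inside <- si >= 1L & si <= ns & di >= 1L & di <= nd &
    obs$mutual_speed < speed_edges[ns + 1L] & obs$distance < distance_edges[nd + 1L]
  cell <- (di[inside] - 1L) * ns + si[inside]
  count <- matrix(0L, ns, nd)
  sum_r <- matrix(0, ns, nd)
  if (any(inside)) {
    tab <- tapply(obs$r[inside], cell, sum)
    cnt <- tapply(obs$r[inside], cell, length)
    ii <- as.integer(names(tab))
    sum_r[ii] <- tab
    count[ii] <- cnt
  }
  mean_r <- ifelse(count > 0L, sum_r / count, NA_real_)
  structure(list(speed_edges = speed_edges, distance_edges = distance_edges,
                 mean_r = mean_r, count = count,
                 overflow = sum(!inside)),
            class = "speed_distance_grid")
}

check_edges <- function(e, what) {
  if (length(e) < 2L || any(diff(e) <= 0))
    stop("`", what, "` must be strictly increasing with at least 2 values")
  invisible(e)
}

#' @export
print.speed_distance_grid <- function(x, ...) {
  cat(sprintf("<speed_distance_grid> %d x %d cells, %d observations binned, %d overflow\n",
              nrow(x$count), ncol(x$count), sum(x$count), x$overflow))
  invisible(x)
}

#' Long-form export of a speed x distance grid
#'
#' Cells with fewer than `min_count` observations are reported with
#' `mean_r = NA`: sparsely populated cells are noise-dominated and would
#' clutter a heat map.
#'
#' @param x a `speed_distance_grid`.
#' @param row.names,optional ignored (S3 signature).
#' @param min_count smallest per-cell count for `mean_r` to be reported
#'   (default 10).
#' @param ... unused.
#' @return data.frame with `speed_lo`, `speed_hi`, `distance_lo`,
#'   `distance_hi`, `mean_r`, `count`.
#' @export
as.data.frame.speed_distance_grid <- function(x, row.names = NULL,
                                              optional = FALSE,
                                              min_count = 10, ...) {
  ns <- nrow(x$count); nd <- ncol(x$count)
  d <- data.frame(
    speed_lo = rep(x$speed_edges[seq_len(ns)], times = nd),
    speed_hi = rep(x$speed_edges[seq_len(ns) + 1L], times = nd),
    distance_lo = rep(x$distance_edges[seq_len(nd)], each = ns),
    distance_hi = rep(x$distance_edges[seq_len(nd) + 1L], each = ns),
    mean_r = as.vector(x$mean_r),
    count = as.vector(x$count))
  d$mean_r[d$count < min_count] <- NA_real_
  d
}
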