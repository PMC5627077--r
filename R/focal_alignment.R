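#' Focal-frame observations of partner position and heading
#'
#' Every fish serves as focal in turn. For each ordered (focal, partner)
#' pair and frame where both have valid headings (and the partner a valid
#' fix), the world is translated so the focal fish sits at the origin and
#' rotated so it travels along the positive x-axis. The partner's position
#' in that frame (`rel_x`, `rel_y`, mm) and the difference in heading angle
#' `delta_theta = theta_partner - theta_focal`, wrapped to `(-pi, pi]`, are
#' recorded. The construction is invariant to any rigid motion of the
#' original coordinates.
#'
#' @param k a [compute_kinematics()] result.
#' @param t the matching [trajectory_set()].
#' @return data.frame with columns `focal`, `partner`, `frame`, `rel_x`,
#'   `rel_y`, `delta_theta`.
#' @export
focal_transform <- function(k, t) {
  stopifnot(inherits(k, "kinematic_series"), inherits(t, "trajectory_set"),
            k$n_frames == t$n_frames, k$n_individuals == t$n_individuals)
  n_id <- t$n_individuals
  ok <- k$valid_mask & !t$gap_mask
  res <- list()
  for (f in seq_len(n_id)) for (p in seq_len(n_id)) {
    if (p == f) next
    use <- which(ok[, f] & ok[, p])
    if (length(use) == 0L) next
    dx <- t$positions[use, p, 1] - t$positions[use, f, 1]
    dy <- t$positions[use, p, 2] - t$positions[use, f, 2]
    # rotate by -theta_focal: heading components are (cos, sin) of theta_f
    cf <- k$heading[use, f, 1]; sf <- k$heading[use, f, 2]
    res[[length(res) + 1L]] <- data.frame(
      focal = f, partner = p, frame = use,
      rel_x = cf * dx + sf * dy,
      rel_y = -sf * dx + cf * dy,
      delta_theta = wrap_angle(k$heading_angle[use, p] - k$heading_angle[use, f]))
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(focal = integer(), partner = integer(),
                      frame = integer(), rel_x = numeric(),
                      rel_y = numeric(), delta_theta = numeric())
  out
}

#' Wrap angles to (-pi, pi]
#' @param a angles in radians.
#' @return wrapped angles.
#' @export
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  # the modulo maps odd multiples of pi to -pi; convention here is (-pi, pi]
  w[w == -pi] <- pi
  w
}

#' Bin focal-frame observations into an alignment map
#'
#' Per spatial cell of the focal frame, the circular mean direction and the
#' mean resultant length `R` of the heading differences `delta_theta`:
#' `R = |mean(exp(i * delta_theta))|`, 1 when partners at that relative
#' position always travel parallel to the focal fish's heading offset by the
#' same angle, 0 when the differences cancel. The arrow field of an
#' alignment figure is `mean_direction`; the heat surface is `R`.
#'
#' @param obs data.frame from [focal_transform()].
#' @param x_edges,y_edges strictly increasing bin boundaries in mm
#'   (default -100..100 in 10 mm cells).
#' @return object of class `focal_alignment_map` with matrices
#'   `mean_direction` (radians), `R`, `count` (rows = x bins, cols = y
#'   bins), the edges, and `overflow`.
#' @export
bin_focal_map <- function(obs, x_edges = seq(-100, 100, by = 10),
                          y_edges = seq(-100, 100, by = 10)) {
  check_edges(x_edges, "x_edges")
  check_edges(y_edges, "y_edges")
  nx <- length(x_edges) - 1L
  ny <- length(y_edges) - 1L
  xi <- findInterval(obs$rel_x, x_edges)
  yi <- findInterval(obs$rel_y, y_edges)
  inside <- xi >= 1L & xi <= nx & yi >= 1L & yi <= ny &
    obs$rel_x < x_edges[nx + 1L] & obs$rel_y < y_edges[ny + 1L]
  cell <- (yi[inside] - 1L) * nx + xi[inside]
  count <- matrix(0L, nx, ny)
  sum_c <- matrix(0, nx, ny)
  sum_s <- matrix(0, nx, ny)
  if (any(inside)) {
    cs <- cos(obs$delta_theta[inside]); sn <- sin(obs$delta_theta[inside])
    tc <- tapply(cs, cell, sum); ts <- tapply(sn, cell, sum)
    cnt <- tapply(cs, cell, length)
    ii <- as.integer(names(tc))
    sum_c[ii] <- tc; sum_s[ii] <- ts; count[ii] <- cnt
  }
  R <- matrix(NA_real_, nx, ny)
  mean_dir <- matrix(NA_real_, nx, ny)
  nz <- count > 0L
  R[nz] <- sqrt(sum_c[nz]^2 + sum_s[nz]^2) / count[nz]
  mean_dir[nz] <- atan2(sum_s[nz], sum_c[nz])
  structure(list(x_edges = x_edges, y_edges = y_edges,
                 mean_direction = mean_dir, R = R, count = count,
                 overflow = sum(!inside)),
            class = "focal_alignment_map")
}

#' @export
print.focal_alignment_map <- function(x, ...) {
  cat(sprintf("<focal_alignment_map> %d x %d cells, %d observations binned, %d overflow\n",
              nrow(x$count), ncol(x$count), sum(x$count), x$overflow))
  invisible(x)
}

#' Long-form export of a focal alignment map
#'
#' @param x a `focal_alignment_map`.
#' @param row.names,optional ignored (S3 signature).
#' @param min_count smallest per-cell count for `mean_direction`/`R` to be
#'   reported (default 10).
#' @param ... unused.
#' @return data.frame with `x_lo`, `x_hi`, `y_lo`, `y_hi`,
#'   `mean_direction`, `R`, `count`.
#' @export
as.data.frame.focal_alignment_map <- function(x, row.names = NULL,
                                              optional = FALSE,
                                              min_count = 10, ...) {
  nx <- nrow(x$count); ny <- ncol(x$count)
  d <- data.frame(
    x_lo = rep(x$x_edges[seq_len(nx)], times = ny),
    x_hi = rep(x$x_edges[seq_len(nx) + 1L], times = ny),
    y_lo = rep(x$y_edges[seq_len(ny)], each = nx),
    y_hi = rep(x$y_edges[seq_len(ny) + 1L], each = nx),
    mean_direction = as.vector(x$mean_direction),
    R = as.vector(x$R),
    count = as.vector(x$count))
  low <- d$count < min_count
  d$mean_direction[low] <- NA_real_
  d$R[low] <- NA_real_
  d
}
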