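#' Construct a trajectory set
#'
#' A `trajectory_set` holds the calibrated per-frame positions of all
#' individuals in one trial: a `frames x individuals x 2` array of planar
#' coordinates in millimetres, a logical `gap_mask` marking frames where a
#' fish has no fix (occlusions, tracking failures), and trial metadata.
#'
#' @param positions numeric array `[frames, individuals, 2]`, coordinates in
#'   mm (after calibration). Entries may be `NA` only where `gap_mask` is
#'   `TRUE`.
#' @param gap_mask logical matrix `[frames, individuals]`; `TRUE` marks a
#'   missing fix. Defaults to marking any non-finite position.
#' @param trial_id character scalar identifying the trial.
#' @param treatment `"familiar"` or `"unfamiliar"`.
#' @param fps frames per second of the recording (must be > 0).
#' @param mm_per_unit scale already applied to `positions` (recorded for
#'   provenance; must be > 0).
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(positions, gap_mask = NULL, trial_id = "trial",
                           treatment = c("unfamiliar", "familiar"),
                           fps = 25, mm_per_unit = 1) {
  treatment <- match.arg(treatment)
  if (length(dim(positions)) != 3L || dim(positions)[3] != 2L)
    stop("`positions` must be a [frames, individuals, 2] array")
  n_frames <- dim(positions)[1]
  n_ind <- dim(positions)[2]
  if (n_ind < 2L)
    stop("a trajectory set needs at least 2 individuals, got ", n_ind)
  if (fps <= 0) stop("`fps` must be positive")
  if (mm_per_unit <= 0) stop("`mm_per_unit` must be positive")
  if (is.null(gap_mask))
    gap_mask <- !(is.finite(positions[, , 1, drop = FALSE])[, , 1, drop = TRUE] &
                    is.finite(positions[, , 2, drop = FALSE])[, , 1, drop = TRUE])
  gap_mask <- matrix(as.logical(gap_mask), n_frames, n_ind)
  ok <- is.finite(positions[, , 1]) & is.finite(positions[, , 2])
  if (any(!ok & !gap_mask))
    stop("non-finite positions present where gap_mask is FALSE")
  structure(
    list(trial_id = as.character(trial_id), treatment = treatment,
         fps = fps, mm_per_unit = mm_per_unit,
         positions = positions, gap_mask = gap_mask,
         n_individuals = n_ind, n_frames = n_frames),
    class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> trial %s (%s): %d fish x %d frames @ %g fps, %d missing fixes\n",
              x$trial_id, x$treatment, x$n_individuals, x$n_frames, x$fps,
              sum(x$gap_mask)))
  invisible(x)
}

#' Number of frames in a trajectory set
#' @param t a `trajectory_set`.
#' @return integer frame count.
#' @export
n_frames <- function(t) t$n_frames

#' Read trajectories from file
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`tabular_csv`}{CSV with header `frame,id,x,y`; `frame` is 0-based,
#'     coordinates in raw (pixel) units; missing fixes as empty/NA `x,y`.}
#'   \item{`idtracker_text`}{whitespace-separated, one row per frame, columns
#'     `x1 y1 [prob1] x2 y2 [prob2] ...`; `NaN`/blank marks a missing fix.
#'     Probability columns are detected from the column count when
#'     unambiguous; pass `has_prob` when the count is a multiple of 6.}
#' }
#' Coordinates are converted to mm at read time (`mm_per_unit`); all
#' downstream computation is in mm and seconds.
#'
#' @param path file to read.
#' @param format `"tabular_csv"` or `"idtracker_text"`.
#' @param fps frames per second of the recording.
#' @param mm_per_unit mm per raw coordinate unit (calibration).
#' @param trial_id,treatment metadata attached to the result.
#' @param has_prob for `idtracker_text`: `TRUE` if every fish has a
#'   probability column; `NULL` to infer from the column count.
#' @return a [trajectory_set()].
#' @export
read_trajectories <- function(path,
                              format = c("tabular_csv", "idtracker_text"),
                              fps = 25, mm_per_unit = 1,
                              trial_id = basename(path),
                              treatment = c("unfamiliar", "familiar"),
                              has_prob = NULL) {
  format <- match.arg(format)
  treatment <- match.arg(treatment)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tabular_csv") {
    pos_mask <- read_tabular_csv(path)
  } else {
    pos_mask <- read_idtracker_text(path, has_prob = has_prob)
  }
  trajectory_set(pos_mask$positions * mm_per_unit,
                 gap_mask = pos_mask$gap_mask,
                 trial_id = trial_id, treatment = treatment,
                 fps = fps, mm_per_unit = mm_per_unit)
}

read_tabular_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "id", "x", "y")
  if (!all(need %in% names(d)))
    stop("tabular trajectory file must have header frame,id,x,y; got: ",
         paste(names(d), collapse = ","))
  if (!is.numeric(d$frame))
    stop("parse error: non-numeric 'frame' values in ", path)
  ids <- sort(unique(d$id))
  frames <- sort(unique(d$frame))
  if (!identical(frames, seq(min(frames), max(frames))))
    stop("structural error: frame indices are not contiguous in ", path)
  n_fr <- length(frames)
  n_id <- length(ids)
  tab <- table(d$frame, d$id)
  if (any(tab != 1L))
    stop("structural error: each (frame, id) must appear exactly once; ",
         sum(tab != 1L), " violations in ", path)
  positions <- array(NA_real_, c(n_fr, n_id, 2))
  fi <- match(d$frame, frames)
  ii <- match(d$id, ids)
  positions[cbind(fi, ii, 1L)] <- d$x
  positions[cbind(fi, ii, 2L)] <- d$y
  gap_mask <- is.na(positions[, , 1, drop = FALSE])[, , 1, drop = TRUE] |
    is.na(positions[, , 2, drop = FALSE])[, , 1, drop = TRUE]
  gap_mask <- matrix(gap_mask, n_fr, n_id)
  positions[, , 1][gap_mask] <- NA_real_
  positions[, , 2][gap_mask] <- NA_real_
  list(positions = positions, gap_mask = gap_mask)
}

read_idtracker_text <- function(path, has_prob = NULL) {
  first <- readLines(path, n = 1L)
  header <- grepl("[A-Za-z]", first)  # idTracker exports may carry x1 y1 ... names
  d <- read.table(path, header = header, fill = FALSE,
                  na.strings = c("NA", "NaN", ""), stringsAsFactors = FALSE)
  nc <- ncol(d)
  if (is.null(has_prob)) {
    if (nc %% 6 == 0)
      stop("column count ", nc, " is compatible with both 2- and 3-column ",
           "layouts; pass has_prob explicitly")
    if (nc %% 3 == 0) has_prob <- TRUE
    else if (nc %% 2 == 0) has_prob <- FALSE
    else stop("cannot interpret ", nc, " columns as idTracker output")
  }
  stride <- if (has_prob) 3L else 2L
  if (nc %% stride != 0)
    stop("column count ", nc, " not a multiple of ", stride)
  n_id <- nc %/% stride
  n_fr <- nrow(d)
  positions <- array(NA_real_, c(n_fr, n_id, 2))
  for (i in seq_len(n_id)) {
    positions[, i, 1] <- as.numeric(d[[stride * (i - 1L) + 1L]])
    positions[, i, 2] <- as.numeric(d[[stride * (i - 1L) + 2L]])
  }
  gap_mask <- matrix(FALSE, n_fr, n_id)
  for (i in seq_len(n_id))
    gap_mask[, i] <- !is.finite(positions[, i, 1]) | !is.finite(positions[, i, 2])
  positions[, , 1][gap_mask] <- NA_real_
  positions[, , 2][gap_mask] <- NA_real_
  list(positions = positions, gap_mask = gap_mask)
}

#' Write a trajectory set as canonical tabular CSV
#'
#' Writes `frame,id,x,y` rows (frame 0-based) in raw units, i.e. positions
#' divided by `mm_per_unit`, with full double precision so that a
#' write/read round-trip reproduces the positions bit-exactly. Missing fixes
#' are written as empty fields.
#'
#' @param t a [trajectory_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(t, path) {
  stopifnot(inherits(t, "trajectory_set"))
  n_fr <- t$n_frames; n_id <- t$n_individuals
  frame <- rep(seq_len(n_fr) - 1L, times = n_id)
  id <- rep(seq_len(n_id), each = n_fr)
  x <- as.vector(t$positions[, , 1]) / t$mm_per_unit
  y <- as.vector(t$positions[, , 2]) / t$mm_per_unit
  gap <- as.vector(t$gap_mask)
  fmt <- function(v) ifelse(gap | is.na(v), "", sprintf("%.17g", v))
  lines <- c("frame,id,x,y",
             sprintf("%d,%d,%s,%s", frame, id, fmt(x), fmt(y)))
  writeLines(lines, path)
  invisible(path)
}

#' Interpolate short tracking gaps
#'
#' Runs of missing fixes no longer than `max_gap` frames that are flanked by
#' valid fixes on both sides are filled by linear interpolation and unmasked.
#' Longer runs, and runs touching the start or end of the trial, are left
#' masked. Measured positions are never altered, and applying the operation
#' twice is a no-op.
#'
#' @param t a [trajectory_set()].
#' @param max_gap largest run length (frames) to fill; default 5 frames
#'   (0.2 s at 25 fps), i.e. short occlusions only.
#' @return a new `trajectory_set`.
#' @export
fill_gaps <- function(t, max_gap = 5) {
  stopifnot(inherits(t, "trajectory_set"), max_gap >= 0)
  if (max_gap == 0 || !any(t$gap_mask)) return(t)
  pos <- t$positions
  mask <- t$gap_mask
  for (i in seq_len(t$n_individuals)) {
    g <- mask[, i]
    if (!any(g)) next
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      len <- r$lengths[k]
      a <- starts[k] - 1L   # last valid frame before the run
      b <- ends[k] + 1L     # first valid frame after the run
      if (len > max_gap || a < 1L || b > t$n_frames) next
      if (mask[a, i] || mask[b, i]) next
      w <- seq_len(len) / (len + 1)
      idx <- starts[k]:ends[k]
      pos[idx, i, 1] <- pos[a, i, 1] + w * (pos[b, i, 1] - pos[a, i, 1])
      pos[idx, i, 2] <- pos[a, i, 2] + w * (pos[b, i, 2] - pos[a, i, 2])
      mask[idx, i] <- FALSE
    }
  }
  out <- t
  out$positions <- pos
  out$gap_mask <- mask
  out
}

#' Define a sampling window
#'
#' Half-open frame interval `[start_frame, end_frame)` tagged `period1` or
#' `period2`.
#'
#' @param label `"period1"` or `"period2"`.
#' @param start_frame,end_frame 0-based frame indices, `start < end`.
#' @return a `sampling_window` object.
#' @export
sampling_window <- function(label = c("period1", "period2"),
                            start_frame, end_frame) {
  label <- match.arg(label)
  start_frame <- as.integer(start_frame); end_frame <- as.integer(end_frame)
  if (start_frame < 0 || start_frame >= end_frame)
    stop("need 0 <= start_frame < end_frame")
  structure(list(label = label, start_frame = start_frame,
                 end_frame = end_frame),
            class = "sampling_window")
}

#' Standard 5-minute sampling windows
#'
#' The two observation windows used throughout: the 5 minutes immediately
#' after release into the arena (`period1`) and minutes 35--40 (`period2`).
#'
#' @param fps frames per second.
#' @param period_min window length in minutes (default 5).
#' @param period2_start_min start of the second window in minutes (default 35).
#' @return named list of two [sampling_window()]s.
#' @export
period_windows <- function(fps = 25, period_min = 5, period2_start_min = 35) {
  f <- function(min0, min1, lab)
    sampling_window(lab, round(min0 * 60 * fps), round(min1 * 60 * fps))
  list(period1 = f(0, period_min, "period1"),
       period2 = f(period2_start_min, period2_start_min + period_min, "period2"))
}

#' Extract a sampling window from a trajectory set
#'
#' @param t a [trajectory_set()].
#' @param w a [sampling_window()]; must lie within the trial.
#' @return a `trajectory_set` with exactly `end_frame - start_frame` frames;
#'   metadata preserved.
#' @export
extract_window <- function(t, w) {
  stopifnot(inherits(t, "trajectory_set"), inherits(w, "sampling_window"))
  if (w$end_frame > t$n_frames)
    stop(sprintf("window [%d, %d) out of range for trial of %d frames",
                 w$start_frame, w$end_frame, t$n_frames))
  idx <- (w$start_frame + 1L):w$end_frame
  trajectory_set(t$positions[idx, , , drop = FALSE],
                 gap_mask = t$gap_mask[idx, , drop = FALSE],
                 trial_id = t$trial_id, treatment = t$treatment,
                 fps = t$fps, mm_per_unit = t$mm_per_unit)
}
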