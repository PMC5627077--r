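test_that("tabular CSV parses complete files and records gaps", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,id,x,y",
               "0,1,0,0", "0,2,5,0",
               "1,1,1,0", "1,2,6,0",
               "2,1,2,0", "2,2,7,0"), path)
  t <- read_trajectories(path, "tabular_csv", fps = 25, mm_per_unit = 2)
  expect_equal(t$n_frames, 3L)
  expect_equal(t$n_individuals, 2L)
  expect_false(any(t$gap_mask))
  # calibration applied at read time
  expect_equal(t$positions[1, 2, 1], 10)

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,id,x,y",
               "0,1,0,0", "0,2,5,0",
               "1,1,,", "1,2,6,0",
               "2,1,2,0", "2,2,7,0"), path2)
  t2 <- read_trajectories(path2, "tabular_csv")
  expect_identical(which(t2$gap_mask), 2L)  # frame 2 (index), fish 1
  expect_true(is.na(t2$positions[2, 1, 1]))
})

test_that("malformed tabular files raise structural errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,id,x,y", "0,1,0,0", "0,1,1,1", "0,2,5,0",
               "1,1,1,0", "1,2,6,0"), path)
  expect_error(read_trajectories(path, "tabular_csv"), "structural")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), path2)
  expect_error(read_trajectories(path2, "tabular_csv"), "header")
  expect_error(read_trajectories(tempfile(), "tabular_csv"), "not found")
})

test_that("idTracker text dialect reads with and without probability columns", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("10 20 0.99 30 40 0.98 50 60 0.97",
               "11 21 0.99 NaN NaN 0.0 51 61 0.97"), path)
  t <- read_trajectories(path, "idtracker_text")
  expect_equal(t$n_individuals, 3L)
  expect_equal(t$positions[1, 2, ], c(30, 40))
  expect_true(t$gap_mask[2, 2])
  expect_false(any(t$gap_mask[, c(1, 3)]))

  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("x1 y1 x2 y2", "10 20 30 40", "11 21 31 41"), path2)
  t2 <- read_trajectories(path2, "idtracker_text")
  expect_equal(t2$n_individuals, 2L)
  expect_equal(t2$positions[2, 1, ], c(11, 21))

  # 6 columns: ambiguous between 2 fish + prob and 3 fish without
  path3 <- withr::local_tempfile(fileext = ".txt")
  writeLines("1 2 3 4 5 6", path3)
  expect_error(read_trajectories(path3, "idtracker_text"), "has_prob")
  t3 <- read_trajectories(path3, "idtracker_text", has_prob = FALSE)
  expect_equal(t3$n_individuals, 3L)
})

test_that("write/read round-trip is bit-exact including the gap mask", {
  ts <- simulate_trial(sim_config(duration = 4, gap_rate = 0.05, seed = 42))
  expect_true(any(ts$gap_mask))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(ts, path)
  back <- read_trajectories(path, "tabular_csv", fps = ts$fps,
                            mm_per_unit = 1)
  expect_identical(back$positions, ts$positions)
  expect_identical(back$gap_mask, ts$gap_mask)
})

test_that("fill_gaps interpolates short runs only and is idempotent", {
  pos <- array(NA_real_, c(9, 2, 2))
  pos[, 1, 1] <- 0:8; pos[, 1, 2] <- 0
  pos[, 2, 1] <- 10;  pos[, 2, 2] <- seq(0, 16, by = 2)
  # 1-frame gap for fish 1 at frame 2; 5-frame gap for fish 2 (frames 3-7)
  pos[2, 1, ] <- NA
  pos[3:7, 2, ] <- NA
  t <- trajectory_set(pos, fps = 25)
  f <- fill_gaps(t, max_gap = 1)
  expect_equal(f$positions[2, 1, ], c(1, 0))  # midpoint of (0,0) and (2,0)
  expect_false(f$gap_mask[2, 1])
  expect_true(all(f$gap_mask[3:7, 2]))        # 5 > max_gap: untouched
  expect_identical(fill_gaps(f, max_gap = 1), f)  # idempotent

  f3 <- fill_gaps(t, max_gap = 5)
  expect_false(any(f3$gap_mask))
  expect_equal(f3$positions[3:7, 2, 2], seq(4, 12, by = 2))

  # no gaps: identity
  t0 <- straight_ts(rbind(c(0, 0), c(10, 0)), rbind(c(1, 0), c(1, 0)))
  expect_identical(fill_gaps(t0, max_gap = 5), t0)
})

test_that("gap runs touching the trial ends stay masked", {
  pos <- array(0, c(5, 2, 2))
  pos[, 1, 1] <- 0:4; pos[, 2, 1] <- 10:14
  pos[1, 1, ] <- NA; pos[5, 2, ] <- NA
  t <- trajectory_set(pos, fps = 25)
  f <- fill_gaps(t, max_gap = 3)
  expect_true(f$gap_mask[1, 1])
  expect_true(f$gap_mask[5, 2])
})

test_that("extract_window returns the half-open frame range", {
  n <- 40 * 60 * 25  # a full 40-minute trial at 25 fps
  pos <- array(0, c(n, 2, 2))
  pos[, 1, 1] <- seq_len(n); pos[, 2, 1] <- seq_len(n) + 100
  t <- trajectory_set(pos, fps = 25)
  w <- period_windows(fps = 25)
  p1 <- extract_window(t, w$period1)
  expect_equal(p1$n_frames, 7500L)  # 5 min x 25 fps
  expect_equal(p1$positions[1, 1, 1], 1)
  p2 <- extract_window(t, w$period2)
  expect_equal(w$period2$start_frame, 52500L)
  expect_equal(w$period2$end_frame, 60000L)
  expect_equal(p2$n_frames, 7500L)
  expect_equal(p2$positions[1, 1, 1], 52501)  # frame index 52500, 0-based
  expect_equal(p2$treatment, t$treatment)
  expect_equal(p2$fps, t$fps)

  bad <- sampling_window("period2", n - 10, n + 10)
  expect_error(extract_window(t, bad), "out of range")
})

test_that("extract_window preserves mask state", {
  pos <- array(1, c(10, 2, 2))
  pos[4, 1, ] <- NA
  t <- trajectory_set(pos, fps = 25)
  p <- extract_window(t, sampling_window("period1", 2, 8))
  expect_equal(p$n_frames, 6L)
  expect_true(p$gap_mask[2, 1])   # original frame 4 (0-based 3) -> local 2
  expect_equal(sum(p$gap_mask), 1L)
})

test_that("trajectory_set validates its invariants", {
  expect_error(trajectory_set(array(0, c(5, 1, 2))), "at least 2")
  expect_error(trajectory_set(array(0, c(5, 2, 2)), fps = 0), "fps")
  pos <- array(0, c(5, 2, 2)); pos[1, 1, 1] <- NA
  expect_error(trajectory_set(pos, gap_mask = matrix(FALSE, 5, 2)),
               "non-finite")
})
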