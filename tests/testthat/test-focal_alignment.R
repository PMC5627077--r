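test_that("focal transform reproduces hand-computed frames", {
  # focal heads +x, partner 10 mm ahead heading +x
  t1 <- straight_ts(rbind(c(0, 0), c(10, 0)), rbind(c(1, 0), c(1, 0)),
                    n_fr = 3)
  o1 <- focal_transform(compute_kinematics(t1), t1)
  a <- o1[o1$focal == 1 & o1$partner == 2, ]
  expect_equal(unique(a$rel_x), 10)
  expect_equal(unique(a$rel_y), 0)
  expect_equal(unique(a$delta_theta), 0)

  # focal heads +y, partner 10 mm further along +y heading +y:
  # in the focal frame the partner sits ahead on the +x axis
  t2 <- straight_ts(rbind(c(0, 0), c(0, 10)), rbind(c(0, 1), c(0, 1)),
                    n_fr = 3)
  o2 <- focal_transform(compute_kinematics(t2), t2)
  b <- o2[o2$focal == 1 & o2$partner == 2, ]
  expect_equal(unique(b$rel_x), 10)
  expect_equal(unique(round(b$rel_y, 12)), 0)
  expect_equal(unique(b$delta_theta), 0)

  # partner 5 mm behind, swimming the opposite way
  t3 <- straight_ts(rbind(c(0, 0), c(-5, 0)), rbind(c(1, 0), c(-1, 0)),
                    n_fr = 3)
  o3 <- focal_transform(compute_kinematics(t3), t3)
  cc <- o3[o3$focal == 1 & o3$partner == 2, ]
  expect_equal(cc$rel_x[cc$frame == 1], -5)
  expect_equal(unique(cc$delta_theta), pi)
})

test_that("every fish serves as focal: ordered pairs are pooled", {
  ts <- simulate_trial(sim_config(duration = 2, gap_rate = 0, seed = 12))
  k <- compute_kinematics(ts)
  obs <- focal_transform(k, ts)
  expect_setequal(unique(paste(obs$focal, obs$partner)),
                  apply(expand.grid(1:4, 1:4)[expand.grid(1:4, 1:4)[, 1] !=
                                                expand.grid(1:4, 1:4)[, 2], ],
                        1, paste, collapse = " "))
})

test_that("focal observations are invariant to rigid motion of the world", {
  ts <- simulate_trial(sim_config(duration = 4, gap_rate = 0, seed = 19))
  k <- compute_kinematics(ts)
  o0 <- focal_transform(k, ts)
  tr <- rotate_ts(ts, 2.1)
  or <- focal_transform(compute_kinematics(tr), tr)
  expect_equal(or$rel_x, o0$rel_x, tolerance = 1e-9)
  expect_equal(or$rel_y, o0$rel_y, tolerance = 1e-9)
  expect_equal(cos(or$delta_theta), cos(o0$delta_theta), tolerance = 1e-9)
})

test_that("map cells reproduce circular statistics exactly", {
  # single cell, identical angles
  obs <- data.frame(focal = 1L, partner = 2L, frame = 1:3,
                    rel_x = rep(1, 3), rel_y = rep(1, 3),
                    delta_theta = rep(0, 3))
  m <- bin_focal_map(obs, c(0, 10), c(0, 10))
  expect_equal(m$R[1, 1], 1)
  expect_equal(m$mean_direction[1, 1], 0)
  # cancellation
  obs2 <- obs[1:2, ]; obs2$delta_theta <- c(0, pi)
  m2 <- bin_focal_map(obs2, c(0, 10), c(0, 10))
  expect_equal(m2$R[1, 1], 0, tolerance = 1e-12)

  # random angle sets per cell vs the direct unit-vector-sum oracle
  set.seed(41)
  big <- data.frame(focal = 1L, partner = 2L,
                    frame = 1:500,
                    rel_x = runif(500, -100, 100),
                    rel_y = runif(500, -100, 100),
                    delta_theta = runif(500, -pi, pi))
  mm <- bin_focal_map(big, seq(-100, 100, 50), seq(-100, 100, 50))
  for (i in 1:4) for (j in 1:4) {
    inside <- big$rel_x >= seq(-100, 100, 50)[i] &
      big$rel_x < seq(-100, 100, 50)[i + 1] &
      big$rel_y >= seq(-100, 100, 50)[j] &
      big$rel_y < seq(-100, 100, 50)[j + 1]
    if (!any(inside)) next
    o <- circ_oracle(big$delta_theta[inside])
    expect_equal(mm$R[i, j], o$R, tolerance = 1e-12)
    expect_equal(mm$mean_direction[i, j], o$mean_direction,
                 tolerance = 1e-12)
  }
  expect_equal(sum(mm$count) + mm$overflow, 500L)
})

test_that("per-cell R equals the polarization operator on the cell angles", {
  ts <- simulate_trial(sim_config(duration = 20, gap_rate = 0, seed = 23))
  k <- compute_kinematics(ts)
  obs <- focal_transform(k, ts)
  m <- bin_focal_map(obs)
  xe <- m$x_edges; ye <- m$y_edges
  checked <- 0L
  for (i in seq_len(nrow(m$count))) for (j in seq_len(ncol(m$count))) {
    if (m$count[i, j] < 3) next
    inside <- obs$rel_x >= xe[i] & obs$rel_x < xe[i + 1] &
      obs$rel_y >= ye[j] & obs$rel_y < ye[j + 1]
    th <- obs$delta_theta[inside]
    p <- polarization_timeseries(ks_from_angles(matrix(th, nrow = 1)))
    expect_equal(m$R[i, j], p, tolerance = 1e-12)
    checked <- checked + 1L
  }
  expect_gt(checked, 5L)
})

test_that("strong alignment concentrates R near the focal fish", {
  ts <- simulate_trial(sim_config(duration = 120, alignment_weight = 2,
                                  attraction_weight = 0.05,
                                  interaction_range = 60, gap_rate = 0,
                                  seed = 61))
  k <- compute_kinematics(ts)
  m <- bin_focal_map(focal_transform(k, ts),
                     seq(-150, 150, 30), seq(-150, 150, 30))
  d <- as.data.frame(m, min_count = 30)
  d$dist <- sqrt(((d$x_lo + d$x_hi) / 2)^2 + ((d$y_lo + d$y_hi) / 2)^2)
  near <- mean(d$R[d$dist < 60], na.rm = TRUE)
  far <- mean(d$R[d$dist > 100], na.rm = TRUE)
  expect_gt(near, far)
})

test_that("the full map is unchanged by a global rotation of coordinates", {
  ts <- simulate_trial(sim_config(duration = 10, gap_rate = 0, seed = 29))
  k0 <- compute_kinematics(ts)
  m0 <- bin_focal_map(focal_transform(k0, ts))
  tr <- rotate_ts(ts, 0.777)
  m1 <- bin_focal_map(focal_transform(compute_kinematics(tr), tr))
  expect_identical(m0$count, m1$count)
  expect_equal(m0$R, m1$R, tolerance = 1e-9)
})
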