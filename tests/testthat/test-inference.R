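test_that("group model reproduces the repeated-measures design structure", {
  g <- make_group_records(n_groups = 12, fam_effect = 0.1, sd = 0.03,
                          seed = 5)
  fit <- fit_group_model(g)
  expect_setequal(fit$term, c("(Intercept)", "familiarity", "time",
                              "familiarity:time"))
  # containment df with 12 groups: 10 in both strata
  expect_equal(fit$df[fit$term != "(Intercept)"], rep(10L, 3))
  fam <- fit[fit$term == "familiarity", ]
  expect_gt(fam$estimate, 0)
  expect_true(fam$ci_low <= fam$estimate && fam$estimate <= fam$ci_high)
  expect_true(all(fit$std_error > 0))
  expect_true(all(fit$p_value >= 0 & fit$p_value <= 1))
})

test_that("group model estimates shift predictably under translation", {
  g <- make_group_records(n_groups = 8, fam_effect = 0.05, sd = 0.02,
                          seed = 9)
  f0 <- fit_group_model(g)
  g2 <- g; g2$mean_polarization <- g2$mean_polarization + 0.1
  f1 <- fit_group_model(g2)
  expect_equal(f1$estimate[f1$term == "(Intercept)"],
               f0$estimate[f0$term == "(Intercept)"] + 0.1,
               tolerance = 1e-8)
  expect_equal(f1$estimate[f1$term != "(Intercept)"],
               f0$estimate[f0$term != "(Intercept)"], tolerance = 1e-8)
  # relabelling trials leaves the fit unchanged
  g3 <- g; g3$trial_id <- sprintf("z%s", g3$trial_id)
  f2 <- fit_group_model(g3)
  expect_equal(f2$estimate, f0$estimate, tolerance = 1e-10)
})

test_that("unbalanced designs are rejected with named cells", {
  g <- make_group_records(n_groups = 6, seed = 2)
  expect_error(fit_group_model(g[-1, ]), "g01")
  g$treatment <- "familiar"
  expect_error(fit_group_model(g), "both treatments")
})

test_that("individual model uses nesting and the log scale", {
  d <- make_individual_records(n_groups = 12, n_fish = 4,
                               time_effect = -0.2, sd = 0.05, seed = 13)
  fit <- fit_individual_model(d, "log_speed")
  # containment df: familiarity at the group stratum (10), time within (46)
  expect_equal(fit$df[fit$term == "familiarity"], 10L)
  expect_equal(fit$df[fit$term == "time"], 46L)
  expect_equal(fit$df[fit$term == "familiarity:time"], 46L)
  tm <- fit[fit$term == "time", ]
  expect_lt(abs(tm$estimate - (-0.2)), 3 * tm$std_error)
  expect_lt(tm$p_value, 0.01)

  fit2 <- fit_individual_model(d, "log_nnd")
  expect_equal(unique(fit2$response), "log_nnd")

  d$median_speed[3] <- -1
  expect_error(fit_individual_model(d, "log_speed"), "positive")
})

test_that("constant responses give exactly zero effect estimates", {
  d <- make_individual_records(n_groups = 6, n_fish = 3, sd = 0, seed = 1)
  d$median_speed <- 50
  expect_warning(fit <- fit_individual_model(d, "log_speed"),
                 "constant response")
  eff <- fit$estimate[fit$term != "(Intercept)"]
  expect_equal(eff, rep(0, 3), tolerance = 1e-10)
})

test_that("parameter recovery: injected effects come back within 2 se", {
  ok <- 0L
  for (r in 1:25) {
    g <- make_group_records(n_groups = 12, fam_effect = 0.08,
                            time_effect = -0.04, sd = 0.03, seed = 100 + r)
    fit <- fit_group_model(g)
    fam <- fit[fit$term == "familiarity", ]
    if (abs(fam$estimate - 0.08) <= 2 * fam$std_error) ok <- ok + 1L
  }
  expect_gte(ok, 22L)  # ~95% coverage, allow sampling slack
})

test_that("assumption checks flag skew and detect equal variances", {
  set.seed(71)
  x <- rnorm(500)
  a <- assumption_checks(x)
  expect_gt(a$shapiro$p_value[1], 0.05)
  expect_equal(nrow(a$qq), 500L)
  expect_true(is.na(a$levene$p_value))  # single cell

  y <- rlnorm(100, 0, 1)
  b <- assumption_checks(y)
  expect_lt(b$shapiro$p_value[1], 0.05)

  # two groups with identical spread: median-centred Levene statistic ~ 0
  v <- rnorm(40)
  cc <- assumption_checks(c(v, v + 5), rep(c("a", "b"), each = 40))
  expect_lt(cc$levene$statistic, 1e-10)
  expect_equal(nrow(cc$shapiro), 2L)

  # degenerate cells are flagged, not fatal
  dd <- assumption_checks(c(rep(1, 5), rnorm(5)), rep(c("a", "b"), each = 5))
  expect_true(dd$shapiro$degenerate[dd$shapiro$group == "a"])
})

test_that("Benjamini-Hochberg matches the independent step-up oracle", {
  p <- unname(table1_pvalues())
  res <- benjamini_hochberg(p, q = 0.05)
  expect_identical(res$significant, bh_stepup_oracle(p, 0.05))
  expect_equal(res$n_significant, 2L)
  expect_true(all(sort(p[res$significant]) == sort(c(0.0005, 0.007))))

  expect_equal(benjamini_hochberg(rep(1, 6))$n_significant, 0L)
  expect_true(benjamini_hochberg(0.04, q = 0.05)$significant)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")

  # random families agree with the oracle, and the significant set is a
  # prefix of the ascending p-values
  set.seed(99)
  for (i in 1:20) {
    pv <- runif(sample(3:12, 1))^2
    r <- benjamini_hochberg(pv, q = 0.1)
    expect_identical(r$significant, bh_stepup_oracle(pv, 0.1))
    sig_sorted <- r$significant[order(pv)]
    if (any(sig_sorted))
      expect_true(all(sig_sorted[seq_len(max(which(sig_sorted)))]))
  }
})

test_that("lowering a p-value never shrinks the BH significant set", {
  set.seed(55)
  for (i in 1:10) {
    pv <- runif(8)
    r0 <- benjamini_hochberg(pv, q = 0.05)
    j <- sample(8, 1)
    pv2 <- pv; pv2[j] <- pv[j] / 2
    r1 <- benjamini_hochberg(pv2, q = 0.05)
    expect_true(all(r1$significant[r0$significant]))
    expect_gte(r1$n_significant, r0$n_significant)
  }
})
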