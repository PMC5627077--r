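#' Repeated-measures model for the group-level response
#'
#' Fits mean polarization with familiarity (familiar vs unfamiliar) as the
#' between-subjects factor and sampling period as the within-subjects
#' factor, with a random intercept per group:
#' `polarization ~ familiarity * period, random = ~1 | trial`, estimated by
#' REML (nlme). With the standard design of `g` groups measured in both
#' periods, nlme's containment denominator df are `g - 2` for the
#' between-groups familiarity term and `g - 2` for the within-group terms
#' (e.g. df = 10 with 12 groups).
#'
#' Reference levels are `unfamiliar` and `period1`, so the `familiarity`
#' estimate is the familiar-minus-unfamiliar difference in period 1 and
#' `time` the period2-minus-period1 change in the unfamiliar groups. t
#' statistics are reported signed.
#'
#' @param records data.frame of group metric records with columns
#'   `trial_id`, `treatment`, `period`, `mean_polarization` (one row per
#'   trial x period; see [metric_records()]).
#' @return a `model_fit` data.frame: one row per fixed-effect term
#'   (`familiarity`, `time`, `familiarity:time`, plus the intercept) with
#'   `estimate`, `std_error`, `ci_low`, `ci_high` (95%, fitted scale),
#'   `t_value`, `df`, `p_value`.
#' @export
fit_group_model <- function(records) {
  d <- prepare_model_frame(records, response = "mean_polarization",
                           unit_cols = "trial_id")
  if (stats::var(d$resp) == 0)
    return(degenerate_fit(d, response = "polarization",
                          df = c(rep(nlevels(d$trial_id) - 2L, 4L))))
  fit <- nlme::lme(resp ~ treatment * period, random = ~ 1 | trial_id,
                   data = d, method = "REML",
                   control = nlme::lmeControl(opt = "optim"))
  tidy_lme(fit, response = "polarization")
}

#' Repeated-measures model for individual-level responses
#'
#' Median speed and mean nearest-neighbour distance are analysed on the
#' natural-log scale (both are positively skewed on the raw scale), with
#' individual ID nested within group as random intercepts:
#' `log(y) ~ familiarity * period, random = ~1 | trial/fish`. With `g`
#' groups of `n` fish in two periods, containment df are `g - 2` for
#' familiarity and `2 g n - g n - 2` for the within-individual terms
#' (df = 10 and 46 for 12 groups of 4).
#'
#' @param records data.frame of individual metric records with columns
#'   `trial_id`, `treatment`, `period`, `fish_id`, and the response column.
#' @param response `"log_speed"` (uses `median_speed`) or `"log_nnd"`
#'   (uses `mean_nnd`); the log is taken here.
#' @return a `model_fit` data.frame as in [fit_group_model()].
#' @export
fit_individual_model <- function(records, response = c("log_speed", "log_nnd")) {
  response <- match.arg(response)
  raw_col <- if (response == "log_speed") "median_speed" else "mean_nnd"
  if (!raw_col %in% names(records))
    stop("records lack column `", raw_col, "`")
  bad <- which(!is.na(records[[raw_col]]) & records[[raw_col]] <= 0)
  if (length(bad))
    stop("log transform needs positive values; offending records (rows): ",
         paste(utils::head(bad, 10), collapse = ", "))
  records$resp_raw <- log(records[[raw_col]])
  d <- prepare_model_frame(records, response = "resp_raw",
                           unit_cols = c("trial_id", "fish_id"))
  if (stats::var(d$resp) == 0) {
    g <- nlevels(d$trial_id)
    n_units <- nrow(unique(d[c("trial_id", "fish_id")]))
    return(degenerate_fit(d, response = response,
                          df = c(nrow(d) - n_units - 2L, g - 2L,
                                 nrow(d) - n_units - 2L,
                                 nrow(d) - n_units - 2L)))
  }
  fit <- nlme::lme(resp ~ treatment * period,
                   random = ~ 1 | trial_id / fish_id,
                   data = d, method = "REML",
                   control = nlme::lmeControl(opt = "optim"))
  tidy_lme(fit, response = response)
}

prepare_model_frame <- function(records, response, unit_cols) {
  need <- c(unit_cols, "treatment", "period", response)
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack column(s): ", paste(miss, collapse = ", "))
  d <- records
  d$resp <- d[[response]]
  d$trial_id <- factor(d$trial_id)
  if ("fish_id" %in% unit_cols)
    d$fish_id <- factor(d$fish_id)
  d$treatment <- factor(as.character(d$treatment),
                        levels = c("unfamiliar", "familiar"))
  d$period <- factor(as.character(d$period), levels = c("period1", "period2"))
  if (any(is.na(d$treatment)) || any(is.na(d$period)))
    stop("treatment must be familiar/unfamiliar and period period1/period2")
  if (nlevels(droplevels(d$treatment)) < 2L)
    stop("both treatments must be present")
  # balance: every unit must appear exactly once per period
  unit <- interaction(d[unit_cols], drop = TRUE)
  tab <- table(unit, d$period)
  if (any(tab != 1L)) {
    off <- which(tab != 1L, arr.ind = TRUE)
    stop("unbalanced design; missing/duplicated unit x period cells: ",
         paste(sprintf("%s:%s", rownames(tab)[off[, 1]],
                       colnames(tab)[off[, 2]]), collapse = ", "))
  }
  if (any(is.na(d$resp))) stop("missing response values")
  d
}

# a constant response carries no information for the mixed model (the
# variance components are unidentifiable); effects are exactly zero and the
# uncertainty columns undefined
degenerate_fit <- function(d, response, df) {
  warning("constant response; effect estimates are exactly 0 and ",
          "standard errors undefined")
  out <- data.frame(
    response = response,
    term = c("(Intercept)", "familiarity", "time", "familiarity:time"),
    estimate = c(d$resp[1], 0, 0, 0),
    std_error = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    t_value = NA_real_, df = as.integer(df), p_value = NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("model_fit", "data.frame")
  out
}

tidy_lme <- function(fit, response) {
  tt <- summary(fit)$tTable
  ci <- nlme::intervals(fit, which = "fixed")$fixed
  term_map <- c("(Intercept)" = "(Intercept)",
                "treatmentfamiliar" = "familiarity",
                "periodperiod2" = "time",
                "treatmentfamiliar:periodperiod2" = "familiarity:time")
  terms <- unname(term_map[rownames(tt)])
  out <- data.frame(
    response = response,
    term = ifelse(is.na(terms), rownames(tt), terms),
    estimate = tt[, "Value"],
    std_error = tt[, "Std.Error"],
    ci_low = ci[rownames(tt), "lower"],
    ci_high = ci[rownames(tt), "upper"],
    t_value = tt[, "t-value"],
    df = as.integer(tt[, "DF"]),
    p_value = tt[, "p-value"],
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("model_fit", "data.frame")
  out
}

#' Normality and homoscedasticity diagnostics
#'
#' Per cell (group of values): Shapiro-Wilk statistic and p-value, and the
#' theoretical/sample quantile pairs behind a Q-Q plot. Across cells:
#' Levene's test, median-centred (Brown-Forsythe variant), for equality of
#' error variances. Constant cells are flagged, not fatal.
#'
#' @param values numeric vector.
#' @param groups factor (or coercible) of the same length assigning each
#'   value to a cell; a single cell is allowed (Levene then `NA`).
#' @return list with `shapiro` (data.frame: group, n, statistic, p_value,
#'   degenerate), `levene` (data.frame: statistic, df1, df2, p_value), and
#'   `qq` (data.frame: group, theoretical, sample).
#' @export
assumption_checks <- function(values, groups = rep("all", length(values))) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  sh <- lapply(levels(groups), function(g) {
    v <- values[groups == g]
    degenerate <- length(unique(v)) == 1L
    if (length(v) < 3L)
      stop("need at least 3 values per group for Shapiro test (group ", g, ")")
    if (degenerate)
      return(data.frame(group = g, n = length(v), statistic = NA_real_,
                        p_value = NA_real_, degenerate = TRUE))
    s <- shapiro.test(v)
    data.frame(group = g, n = length(v), statistic = unname(s$statistic),
               p_value = s$p.value, degenerate = FALSE)
  })
  shapiro <- do.call(rbind, sh)
  if (nlevels(groups) >= 2L && !all(shapiro$degenerate)) {
    lv <- car::leveneTest(values ~ groups, center = stats::median)
    levene <- data.frame(statistic = lv[1, "F value"],
                         df1 = lv[1, "Df"], df2 = lv[2, "Df"],
                         p_value = lv[1, "Pr(>F)"])
  } else {
    levene <- data.frame(statistic = NA_real_, df1 = NA_integer_,
                         df2 = NA_integer_, p_value = NA_real_)
  }
  qq <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- sort(values[groups == g])
    data.frame(group = g, theoretical = qnorm(ppoints(length(v))), sample = v)
  }))
  list(shapiro = shapiro, levene = levene, qq = qq)
}

#' Benjamini-Hochberg false-discovery-rate decisions
#'
#' Step-up procedure at level `q`: sort the m p-values ascending, find the
#' largest k with `p_(k) <= k q / m`, and declare the k smallest
#' significant. Implemented through [stats::p.adjust()] ("BH"); the
#' significant set is always a prefix of the ascending order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `p_values` (as given), `q`, `significant` (logical,
#'   aligned with the input), and `n_significant`.
#' @export
benjamini_hochberg <- function(p_values, q = 0.05) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p_values, method = "BH")
  sig <- adj <= q
  list(p_values = p_values, q = q, significant = sig,
       n_significant = sum(sig))
}
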