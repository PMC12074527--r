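#' Hazard ratio per SD of the log odds of predicted risk
#'
#' Association between a risk score and outcome: the predicted risks are
#' transformed to log odds, scaled to unit SD, and used as the single
#' covariate in a delayed-entry Cox model on the age axis.
#'
#' @param cohort Cohort tibble with `age_entry`, `age_exit`, `event`.
#' @param risks Predicted horizon risks in (0, 1), one per subject.
#' @param conf.level Confidence level.
#' @return A one-row tibble: `hr_per_sd`, confidence bounds, `std.error`
#'   (log scale), `p.value`.
#' @export
hr_per_sd_of_score <- function(cohort, risks, conf.level = 0.95) {
  if (any(risks <= 0 | risks >= 1)) abort("risks must lie strictly in (0, 1)")
  lo <- qlogis(risks)
  s <- sd(lo)
  if (!is.finite(s) || s == 0) abort("risks are constant; no SD to scale by")
  cohort$.score_sd <- lo / s
  fit <- fit_cox_age_axis(cohort, ".score_sd")
  td <- tidy(fit, conf.level = conf.level)
  tibble::tibble(hr_per_sd = td$hazard.ratio, conf.low = td$conf.low,
                 conf.high = td$conf.high, std.error = td$std.error,
                 p.value = td$p.value)
}

#' Harrell's C-index with delayed entry
#'
#' Discrimination of a risk score under left truncation: over pairs
#' `(i, j)` where `i` fails at `t_i = age_exit_i` and `j` is at risk at
#' that age (`age_entry_j < t_i <= age_exit_j`, excluding `j` failing at
#' exactly `t_i`), a pair is concordant when the failing subject has the
#' higher predicted risk; tied risks earn half credit. The standard error
#' comes from leave-one-out jackknife influence values, which also feed
#' the correlated C-index comparison of [compare_c()].
#'
#' @param cohort Cohort tibble with `age_entry`, `age_exit`, `event`.
#' @param risks Numeric risk score, one per subject (any monotone scale).
#' @return An object of class `crc_concordance`: `c`, `se`, `n_pairs`,
#'   plus jackknife values used by [compare_c()].
#' @export
harrell_c <- function(cohort, risks) {
  n <- nrow(cohort)
  if (length(risks) != n) abort("risks must match the cohort length")
  entry <- cohort$age_entry
  exit <- cohort$age_exit
  event <- cohort$event
  conc_tot <- 0
  comp_tot <- 0
  subj_conc <- numeric(n)
  subj_comp <- numeric(n)
  for (i in which(event == 1)) {
    t_i <- exit[i]
    at_risk <- entry < t_i & exit >= t_i & !(event == 1 & exit == t_i)
    if (!any(at_risk)) next
    credit <- (risks[i] > risks[at_risk]) + 0.5 * (risks[i] == risks[at_risk])
    m <- sum(at_risk)
    conc_tot <- conc_tot + sum(credit)
    comp_tot <- comp_tot + m
    subj_conc[i] <- subj_conc[i] + sum(credit)
    subj_comp[i] <- subj_comp[i] + m
    subj_conc[at_risk] <- subj_conc[at_risk] + credit
    subj_comp[at_risk] <- subj_comp[at_risk] + 1
  }
  if (comp_tot == 0) abort("no comparable pairs")
  cval <- conc_tot / comp_tot
  # leave-one-out values: removing subject k removes every pair it is in
  denom <- comp_tot - subj_comp
  jack <- ifelse(denom > 0, (conc_tot - subj_conc) / denom, cval)
  se <- sqrt((n - 1) / n * sum((jack - mean(jack))^2))
  structure(
    list(c = cval, se = se, n_pairs = comp_tot, n = n, jackknife = jack),
    class = "crc_concordance"
  )
}

#' @export
print.crc_concordance <- function(x, ...) {
  cat(sprintf("Harrell's C = %.4f (SE %.4f), %d comparable pairs, n = %d\n",
              x$c, x$se, x$n_pairs, x$n))
  invisible(x)
}

#' Compare two C-indices
#'
#' Correlated comparison (two scores on the same cohort): a z-test using
#' the jackknife influence values of the two C estimates, the DeLong
#' construction generalised from AUC to Harrell's C. Independent
#' comparison (scores on disjoint cohorts): `z = (cA - cB) /
#' sqrt(seA^2 + seB^2)`.
#'
#' @param a,b `crc_concordance` objects from [harrell_c()].
#' @param paired `"correlated"` or `"independent"`.
#' @return A one-row tibble: `delta_c`, `z`, `p.value`.
#' @export
compare_c <- function(a, b, paired = c("correlated", "independent")) {
  paired <- match.arg(paired)
  stopifnot(inherits(a, "crc_concordance"), inherits(b, "crc_concordance"))
  d <- a$c - b$c
  if (paired == "correlated") {
    if (a$n != b$n) abort("correlated comparison needs the same cohort")
    dj <- a$jackknife - b$jackknife
    v <- (a$n - 1) / a$n * sum((dj - mean(dj))^2)
    z <- if (v > 0) d / sqrt(v) else 0
  } else {
    z <- d / sqrt(a$se^2 + b$se^2)
  }
  tibble::tibble(delta_c = d, z = z, p.value = 2 * pnorm(-abs(z)))
}

#' Calibration of predicted risks
#'
#' The calibration slope is the coefficient of a logistic regression of
#' the binary horizon outcome on the log odds of predicted risk (slope
#' < 1 indicates over-dispersion of the predictions, > 1
#' under-dispersion). The intercept is estimated in a second logistic
#' fit with the slope constrained to 1 (log odds of predicted risk as an
#' offset); negative values indicate systematic over-prediction. A
#' decile table of mean predicted risk against the observed event
#' proportion supports calibration plots.
#'
#' @param pred Predicted horizon risks in (0, 1).
#' @param outcome Binary event-within-horizon indicator.
#' @param conf.level Confidence level.
#' @return An object of class `crc_calibration` with `slope`,
#'   `intercept` (each with confidence bounds) and a 10-row `deciles`
#'   tibble.
#' @export
calibration <- function(pred, outcome, conf.level = 0.95) {
  if (any(pred <= 0 | pred >= 1)) abort("pred must lie strictly in (0, 1)")
  if (all(outcome == 0) || all(outcome == 1)) {
    abort("outcomes are all 0 or all 1; calibration is undefined")
  }
  lo <- qlogis(pred)
  slope_fit <- glm(outcome ~ lo, family = binomial())
  int_fit <- glm(outcome ~ 1 + offset(lo), family = binomial())
  zq <- qnorm(1 - (1 - conf.level) / 2)
  sl <- coef(slope_fit)[["lo"]]
  sl_se <- sqrt(vcov(slope_fit)["lo", "lo"])
  ic <- coef(int_fit)[[1]]
  ic_se <- sqrt(vcov(int_fit)[1, 1])
  dec <- dplyr::mutate(
    tibble::tibble(pred = pred, outcome = outcome),
    decile = risk_group(pred, 10)
  )
  dec <- dplyr::summarise(
    dplyr::group_by(dec, .data$decile),
    n = dplyr::n(),
    mean_predicted = mean(.data$pred),
    observed = mean(.data$outcome),
    .groups = "drop"
  )
  structure(
    list(slope = sl, slope_low = sl - zq * sl_se, slope_high = sl + zq * sl_se,
         slope_se = sl_se,
         slope_p = 2 * pnorm(-abs((sl - 1) / sl_se)),  # test of slope = 1
         intercept = ic, intercept_low = ic - zq * ic_se,
         intercept_high = ic + zq * ic_se, intercept_se = ic_se,
         deciles = dec),
    class = "crc_calibration"
  )
}

#' @export
print.crc_calibration <- function(x, ...) {
  cat(sprintf("Calibration slope %.3f (%.3f, %.3f); intercept %.3f (%.3f, %.3f)\n",
              x$slope, x$slope_low, x$slope_high,
              x$intercept, x$intercept_low, x$intercept_high))
  invisible(x)
}

#' @rdname calibration
#' @param x A `crc_calibration` object.
#' @param ... Unused.
#' @export
tidy.crc_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    conf.low = c(x$slope_low, x$intercept_low),
    conf.high = c(x$slope_high, x$intercept_high),
    std.error = c(x$slope_se, x$intercept_se)
  )
}

#' Expected events from population rates
#'
#' Person-year-weighted expected event count: each subject contributes
#' their follow-up (from entry to the earliest of exit and
#' `entry + horizon`), sliced at integer ages with fractional time
#' apportioned linearly, multiplied by the population rate for their sex,
#' age band and (when the table has a `year` dimension) calendar year.
#' Follow-up already ends at death or diagnosis because `age_exit`
#' records it.
#'
#' @param cohort Cohort tibble with `sex`, `age_entry`, `age_exit` and
#'   optionally `calendar_year_entry`.
#' @param rates A `crc_rate_table` of incidence rates.
#' @param horizon Maximum follow-up counted, in years.
#' @return Expected number of events (scalar).
#' @export
expected_events <- function(cohort, rates, horizon = 10) {
  entry <- cohort$age_entry
  end <- pmin(cohort$age_exit, cohort$age_entry + horizon)
  if (any(end < entry)) abort("age_exit before age_entry")
  use_year <- "year" %in% names(rates) &&
    "calendar_year_entry" %in% names(cohort)
  total <- 0
  for (k in seq(floor(min(entry)), ceiling(max(end)) - 1)) {
    overlap <- pmax(0, pmin(end, k + 1) - pmax(entry, k))
    live <- overlap > 0
    if (!any(live)) next
    yrs <- if (use_year) {
      floor(cohort$calendar_year_entry[live] + (k - entry[live]))
    } else {
      NULL
    }
    r <- rate_at(rates, cohort$sex[live], rep(k, sum(live)), yrs)
    total <- total + sum(overlap[live] * r)
  }
  total
}

#' Standardised incidence ratio with exact Poisson interval
#'
#' `SIR = observed / expected`, with a Garwood exact-Poisson 95%
#' interval on the observed count divided by the expected count.
#'
#' @param observed Observed event count.
#' @param expected Expected event count (> 0).
#' @param conf.level Confidence level.
#' @return A one-row tibble: `observed`, `expected`, `sir`, `conf.low`,
#'   `conf.high`.
#' @export
sir <- function(observed, expected, conf.level = 0.95) {
  if (any(expected <= 0)) abort("expected must be positive")
  n <- max(length(observed), length(expected))
  observed <- rep_len(observed, n)
  expected <- rep_len(expected, n)
  alpha <- 1 - conf.level
  lo <- ifelse(observed == 0, 0, qchisq(alpha / 2, 2 * observed) / 2)
  hi <- qchisq(1 - alpha / 2, 2 * (observed + 1)) / 2
  tibble::tibble(observed = observed, expected = expected,
                 sir = observed / expected,
                 conf.low = lo / expected, conf.high = hi / expected)
}

#' Nelson-Aalen cumulative hazard curves by group
#'
#' The nonparametric cumulative hazard `H(t) = sum d(t)/n_at_risk(t)`
#' over failure ages up to `t`, with delayed-entry risk sets
#' (`entry < t <= exit`), computed separately within each group (e.g.
#' quintiles of predicted risk).
#'
#' @param cohort Cohort tibble with `age_entry`, `age_exit`, `event`.
#' @param groups Group label per subject.
#' @param extract_ages Ages at which to tabulate the curves (attribute
#'   `extracted` of the result).
#' @return A tibble of step points (`group`, `age`, `cumhaz`) with class
#'   `crc_cumhaz`; `attr(, "extracted")` holds the curve values at
#'   `extract_ages`.
#' @export
nelson_aalen_by_group <- function(cohort, groups,
                                  extract_ages = c(55, 65, 75)) {
  groups <- as.character(rep_len(groups, nrow(cohort)))
  pieces <- list()
  extracted <- list()
  for (g in unique(groups)) {
    sub <- cohort[groups == g, , drop = FALSE]
    if (nrow(sub) == 0) {
      warn(paste0("empty group ", g))
      next
    }
    ft <- sort(unique(sub$age_exit[sub$event == 1]))
    if (length(ft) == 0) {
      pieces[[g]] <- tibble::tibble(group = g, age = numeric(),
                                    cumhaz = numeric())
      extracted[[g]] <- tibble::tibble(group = g, age = extract_ages,
                                       cumhaz = 0)
      next
    }
    d <- vapply(ft, function(t) sum(sub$event == 1 & sub$age_exit == t),
                numeric(1))
    at_risk <- vapply(ft, function(t) sum(sub$age_entry < t &
                                            sub$age_exit >= t), numeric(1))
    H <- cumsum(d / at_risk)
    pieces[[g]] <- tibble::tibble(group = g, age = ft, cumhaz = H)
    extracted[[g]] <- tibble::tibble(
      group = g, age = extract_ages,
      cumhaz = vapply(extract_ages, function(a) {
        if (any(ft <= a)) H[max(which(ft <= a))] else 0
      }, numeric(1))
    )
  }
  out <- dplyr::bind_rows(pieces)
  attr(out, "extracted") <- dplyr::bind_rows(extracted)
  class(out) <- c("crc_cumhaz", class(out))
  out
}

#' Assign quantile risk groups
#'
#' Groups subjects into `k` near-equal groups by a score, with cut
#' points from the scored cohort itself and ties broken by stable sort
#' order so group sizes differ by at most one subject.
#'
#' @param x Numeric score.
#' @param k Number of groups.
#' @return Integer group index 1..k (1 = lowest score).
#' @export
risk_group <- function(x, k = 5) {
  ord <- order(x)  # stable
  grp <- integer(length(x))
  grp[ord] <- ceiling(seq_along(x) / (length(x) / k))
  pmin(grp, k)
}

#' SIRs by risk group
#'
#' Observed versus expected events within the first four quintiles and
#' the top two deciles of predicted risk (the layout used to show risk
#' stratification), plus overall.
#'
#' @param cohort Cohort tibble.
#' @param risks Predicted risks used for grouping.
#' @param rates Population incidence rate table for the expecteds.
#' @param horizon Follow-up horizon in years.
#' @return A tibble with one row per group: median predicted risk,
#'   observed, expected, SIR and exact-Poisson interval.
#' @export
sir_by_risk_group <- function(cohort, risks, rates, horizon = 10) {
  q5 <- risk_group(risks, 5)
  d10 <- risk_group(risks, 10)
  groups <- list(
    overall = rep(TRUE, nrow(cohort)),
    quintile_1 = q5 == 1, quintile_2 = q5 == 2,
    quintile_3 = q5 == 3, quintile_4 = q5 == 4,
    decile_9 = d10 == 9, decile_10 = d10 == 10
  )
  purrr::map_dfr(names(groups), function(g) {
    sel <- groups[[g]]
    exp_g <- expected_events(cohort[sel, , drop = FALSE], rates, horizon)
    obs_g <- sum(cohort$event[sel])
    res <- sir(obs_g, exp_g)
    dplyr::bind_cols(tibble::tibble(group = g,
                                    median_risk = stats::median(risks[sel])),
                     res)
  })
}

#' Full evaluation report for a set of models
#'
#' Runs the testing-side battery for each model on one cohort:
#' association (hazard ratio per SD of the log odds of 10-year risk),
#' discrimination (Harrell's C), calibration (slope and constrained
#' intercept), and the overall SIR against population rates. Detailed
#' per-model results (decile calibration tables, SIRs by risk group,
#' concordance objects) are attached as the `details` attribute.
#'
#' @param cohort Testing cohort tibble.
#' @param models Named list of `crc_model` objects.
#' @param incidence,mortality Rate tables for risk prediction and SIR
#'   expecteds.
#' @param horizon Risk horizon in years.
#' @return A tibble with one row per model; `attr(, "details")` holds
#'   the per-model component results.
#' @export
evaluate_report <- function(cohort, models, incidence, mortality,
                            horizon = 10) {
  details <- list()
  rows <- purrr::map_dfr(names(models), function(nm) {
    model <- models[[nm]]
    scored <- predict_risk(cohort, model, incidence, mortality, horizon)
    assoc_ok <- sd(qlogis(scored$risk)) > 0
    assoc <- if (assoc_ok) {
      hr_per_sd_of_score(scored, scored$risk)
    } else {
      tibble::tibble(hr_per_sd = NA_real_, conf.low = NA_real_,
                     conf.high = NA_real_, std.error = NA_real_,
                     p.value = NA_real_)
    }
    conc <- if (assoc_ok) harrell_c(scored, scored$risk) else NULL
    outcome <- as.integer(scored$event == 1 &
                            scored$age_exit <= scored$age_entry + horizon)
    cal <- if (assoc_ok) calibration(scored$risk, outcome) else NULL
    sir_tbl <- sir_by_risk_group(scored, scored$risk, incidence, horizon)
    details[[nm]] <<- list(concordance = conc, calibration = cal,
                           sir = sir_tbl, scored = scored)
    tibble::tibble(
      model = nm,
      hr_per_sd = assoc$hr_per_sd,
      c_index = if (is.null(conc)) NA_real_ else conc$c,
      c_se = if (is.null(conc)) NA_real_ else conc$se,
      cal_slope = if (is.null(cal)) NA_real_ else cal$slope,
      cal_intercept = if (is.null(cal)) NA_real_ else cal$intercept,
      sir_overall = sir_tbl$sir[sir_tbl$group == "overall"]
    )
  })
  attr(rows, "details") <- details
  rows
}
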