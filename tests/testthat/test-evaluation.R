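test_that("Harrell's C equals exhaustive pair enumeration", {
  coh <- sim_test_cohort(n = 200, seed = 61, inc_scale = 20)
  risks <- runif(200)
  got <- harrell_c(coh, risks)
  oracle <- brute_harrell_c(coh, risks)
  expect_equal(got$c, oracle$c, tolerance = 1e-12)
  expect_equal(got$n_pairs, oracle$n_pairs)
})

test_that("Harrell's C hits its reference points", {
  # perfect discrimination: common entry, risks order the failure ages
  coh <- tibble::tibble(age_entry = 40, age_exit = c(41, 43, 45, 47, 50),
                        event = c(1, 1, 1, 1, 0))
  expect_equal(harrell_c(coh, c(5, 4, 3, 2, 1))$c, 1.0)
  expect_equal(harrell_c(coh, c(1, 2, 3, 4, 5))$c, 0.0)
  # tied risks earn half credit
  expect_equal(harrell_c(coh, rep(1, 5))$c, 0.5)
  # risks independent of outcome: near-chance discrimination
  set.seed(62)
  big <- sim_test_cohort(n = 2000, seed = 63, inc_scale = 30)
  cnull <- harrell_c(big, runif(2000))
  expect_gt(cnull$c, 0.47)
  expect_lt(cnull$c, 0.53)
  expect_error(harrell_c(coh[5, ], 1), "comparable")
})

test_that("C-index comparisons behave in both modes", {
  coh <- sim_test_cohort(n = 1000, seed = 64, inc_scale = 20)
  r <- runif(1000)
  a <- harrell_c(coh, r)
  self <- compare_c(a, a, "correlated")
  expect_equal(self$z, 0)
  expect_equal(self$p.value, 1)
  # independent-mode arithmetic
  b1 <- structure(list(c = 0.69, se = 0.011, n = 500, n_pairs = 1,
                       jackknife = NULL), class = "crc_concordance")
  b2 <- structure(list(c = 0.64, se = 0.011, n = 400, n_pairs = 1,
                       jackknife = NULL), class = "crc_concordance")
  z <- compare_c(b1, b2, "independent")$z
  expect_equal(z, 0.05 / sqrt(2 * 0.011^2), tolerance = 1e-12)
  expect_equal(z, 3.2, tolerance = 0.01)
  # correlated mode agrees in sign with independent on nested scores
  scored <- predict_risk(coh, crc_models("new_multivariable", "female"),
                         uk_rates_synthetic("incidence"),
                         uk_rates_synthetic("mortality"))
  good <- harrell_c(coh, scored$risk)
  noisy <- harrell_c(coh, scored$risk + rnorm(1000, sd = 2))
  corr <- compare_c(good, noisy, "correlated")
  indep <- compare_c(good, noisy, "independent")
  expect_equal(sign(corr$z), sign(indep$z))
  expect_error(compare_c(good, b2, "correlated"), "same cohort")
})

test_that("calibration recovers generating slopes and offsets", {
  set.seed(65)
  n <- 100000
  pred <- plogis(rnorm(n, -3, 0.8))
  # perfectly calibrated outcomes
  cal1 <- calibration(pred, rbinom(n, 1, pred))
  expect_equal(cal1$slope, 1, tolerance = 0.05)
  expect_equal(cal1$intercept, 0, tolerance = 0.05)
  expect_equal(nrow(cal1$deciles), 10)
  expect_equal(sum(cal1$deciles$n), n)
  # over-dispersed predictions: true logit = 0.5 * logit(pred) + c
  over <- rbinom(n, 1, plogis(0.5 * qlogis(pred) - 1.5))
  expect_equal(calibration(pred, over)$slope, 0.5, tolerance = 0.05)
  # doubled odds shift the constrained intercept by -log 2
  y <- rbinom(n, 1, pred)
  pred2 <- plogis(qlogis(pred) + log(2))
  expect_equal(calibration(pred2, y)$intercept, -log(2), tolerance = 0.05)
  expect_error(calibration(pred, rep(0, n)), "all 0")
})

test_that("expected events integrate person-time against the rate table", {
  rates <- flat_rates(0.02)
  one <- tibble::tibble(sex = "female", age_entry = 50, age_exit = 51,
                        event = 0)
  expect_equal(expected_events(one, rates), 0.02)
  # death two years in truncates the contribution
  dead <- tibble::tibble(sex = "female", age_entry = 50, age_exit = 52,
                         event = 0)
  expect_equal(expected_events(dead, rates, horizon = 10), 2 * 0.02)
  # the horizon truncates long follow-up
  long <- tibble::tibble(sex = "female", age_entry = 50, age_exit = 65,
                         event = 0)
  expect_equal(expected_events(long, rates, horizon = 10), 10 * 0.02)
  # fractional person-time apportioned linearly across age bands
  frac <- tibble::tibble(sex = "female", age_entry = 50.5, age_exit = 52.25,
                         event = 0)
  expect_equal(expected_events(frac, rates), 1.75 * 0.02)
  # calendar-year-specific rates are honoured
  ytbl <- as_rate_table(tibble::tibble(
    sex = "female", age_lo = 0, age_hi = 90,
    rate = c(0.01, 0.03), year = c(2006, 2007)))
  ycoh <- tibble::tibble(sex = "female", age_entry = 50, age_exit = 52,
                         event = 0, calendar_year_entry = 2006)
  expect_equal(expected_events(ycoh, ytbl), 0.01 + 0.03)
})

test_that("SIR arithmetic and exact-Poisson interval are correct", {
  expect_equal(sir(50, 50)$sir, 1)
  res <- sir(723, 821.5)
  expect_equal(res$sir, 0.880, tolerance = 0.0005)
  expect_true(res$conf.low < res$sir & res$sir < res$conf.high)
  expect_equal(sir(0, 10)$conf.low, 0)
  expect_error(sir(5, 0), "positive")
  # coverage of the exact interval over Poisson draws at expected = 50
  set.seed(66)
  draws <- stats::rpois(500, 50)
  ci <- sir(draws, 50)
  true_sir <- 1
  covered <- mean(ci$conf.low <= true_sir & true_sir <= ci$conf.high)
  expect_gte(covered, 0.94)
})

test_that("Nelson-Aalen curves match hand-enumerated risk sets", {
  # one event among 10 at risk jumps by 0.1
  coh <- tibble::tibble(age_entry = 40, age_exit = c(45, rep(50, 9)),
                        event = c(1, rep(0, 9)))
  curve <- nelson_aalen_by_group(coh, rep("all", 10), extract_ages = 55)
  expect_equal(curve$cumhaz, 0.1)
  expect_equal(attr(curve, "extracted")$cumhaz, 0.1)
  # no events: flat zero
  none <- tibble::tibble(age_entry = 40, age_exit = 50, event = c(0, 0))
  flat <- nelson_aalen_by_group(none, c("g", "g"))
  expect_equal(nrow(flat), 0)
  expect_equal(attr(flat, "extracted")$cumhaz, c(0, 0, 0))
  # brute-force oracle on a simulated cohort
  sim <- sim_test_cohort(n = 100, seed = 67, inc_scale = 30)
  got <- nelson_aalen_by_group(sim, rep("all", 100))
  ft <- sort(unique(sim$age_exit[sim$event == 1]))
  oracle <- cumsum(vapply(ft, function(t) {
    sum(sim$event == 1 & sim$age_exit == t) /
      sum(sim$age_entry < t & sim$age_exit >= t)
  }, numeric(1)))
  expect_equal(got$cumhaz, oracle, tolerance = 1e-12)
  expect_true(all(diff(got$cumhaz) >= 0))
  # agreement with the survival package estimator
  sf <- survival::survfit(survival::Surv(age_entry, age_exit, event) ~ 1,
                          data = sim, ctype = 1)
  expect_equal(got$cumhaz, sf$cumhaz[sf$n.event > 0], tolerance = 1e-12)
})

test_that("risk grouping partitions into near-equal quantile groups", {
  set.seed(68)
  x <- rnorm(1003)
  g <- risk_group(x, 5)
  expect_true(all(table(g) >= floor(1003 / 5)))
  expect_true(all(table(g) <= ceiling(1003 / 5) + 1))
  expect_true(all(x[g == 5] >= max(x[g == 1])))
})

test_that("the HR per SD of log odds wires the Cox fit correctly", {
  coh <- sim_test_cohort(n = 20000, seed = 69, inc_scale = 5)
  scored <- predict_risk(coh, crc_models("new_fh_prs", "female"),
                         uk_rates_synthetic("incidence"),
                         uk_rates_synthetic("mortality"))
  got <- hr_per_sd_of_score(scored, scored$risk)
  # oracle: fit the same Cox model by hand
  x <- qlogis(scored$risk)
  scored$z <- x / sd(x)
  oracle <- tidy(fit_cox_age_axis(scored, "z"))
  expect_equal(got$hr_per_sd, oracle$hazard.ratio, tolerance = 1e-10)
  expect_gt(got$hr_per_sd, 1)
  expect_error(hr_per_sd_of_score(coh, rep(0.5, nrow(coh))), "constant")
})

test_that("permuted risks show null association", {
  coh <- sim_test_cohort(n = 4000, seed = 70, inc_scale = 15)
  scored <- predict_risk(coh, crc_models("new_fh_prs", "female"),
                         uk_rates_synthetic("incidence"),
                         uk_rates_synthetic("mortality"))
  set.seed(71)
  hits <- 0
  for (r in 1:20) {
    perm <- sample(scored$risk)
    res <- hr_per_sd_of_score(scored, perm)
    if (res$conf.low < 1 && 1 < res$conf.high) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("the evaluation report assembles one complete row per model", {
  coh <- sim_test_cohort(n = 8000, seed = 72,
                         model = crc_models("new_multivariable", "female"),
                         inc_scale = 5)
  inc <- uk_rates_synthetic("incidence")
  inc$rate <- inc$rate * 5
  models <- list(
    average = crc_models("average", "female"),
    fh_alone = crc_models("fh_alone", "female"),
    current_fh_prs = crc_models("current_fh_prs", "female"),
    new_fh_prs = crc_models("new_fh_prs", "female"),
    new_multivariable = crc_models("new_multivariable", "female")
  )
  rep <- evaluate_report(coh, models, inc, uk_rates_synthetic("mortality"))
  expect_equal(nrow(rep), 5)
  expect_false(anyNA(rep$c_index))
  details <- attr(rep, "details")
  expect_named(details, names(models))
  expect_equal(nrow(details$new_multivariable$sir), 7)
  # quintile assignment puts ~20% per quintile
  q <- risk_group(details$new_multivariable$scored$risk, 5)
  expect_true(max(abs(table(q) - 8000 / 5)) <= 1)
  # richer models discriminate at least as well as family history alone
  expect_gt(rep$c_index[rep$model == "new_multivariable"],
            rep$c_index[rep$model == "fh_alone"])
})

test_that("quintile-5 cumulative hazard dominates quintile-1 at age 75", {
  coh <- sim_test_cohort(n = 20000, seed = 73,
                         model = crc_models("new_fh_prs", "female"),
                         inc_scale = 5)
  inc <- uk_rates_synthetic("incidence")
  inc$rate <- inc$rate * 5
  scored <- predict_risk(coh, crc_models("new_fh_prs", "female"), inc,
                         uk_rates_synthetic("mortality"))
  curves <- nelson_aalen_by_group(scored, risk_group(scored$risk, 5))
  ex <- attr(curves, "extracted")
  expect_gt(ex$cumhaz[ex$group == "5" & ex$age == 75],
            ex$cumhaz[ex$group == "1" & ex$age == 75])
})

test_that("plot builders return ggplot objects", {
  set.seed(74)
  pred <- plogis(rnorm(2000, -3, 0.6))
  cal <- calibration(pred, rbinom(2000, 1, pred))
  expect_s3_class(plot_calibration(cal), "ggplot")
  coh <- sim_test_cohort(n = 500, seed = 75, inc_scale = 20)
  curves <- nelson_aalen_by_group(coh, rep(c("a", "b"), 250))
  expect_s3_class(autoplot(curves), "ggplot")
})
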