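# Shared fixtures and independent oracles used across the suite.

# flat rate table covering ages 0-90 for both sexes
flat_rates <- function(rate) {
  as_rate_table(tibble::tibble(
    sex = rep(c("female", "male"), each = 1),
    age_lo = 0, age_hi = 90, rate = rate
  ))
}

# random step rate table on unit intervals, both sexes, ages 0-90
random_rates <- function(seed, max_rate = 0.05) {
  set.seed(seed)
  tibble::tibble(
    sex = rep(c("female", "male"), each = 90),
    age_lo = rep(0:89, 2),
    age_hi = rep(1:90, 2),
    rate = runif(180, 0, max_rate)
  ) |> as_rate_table()
}

# minimal cohort with no ties in exit ages (distinct continuous exits)
toy_cox_cohort <- function(n = 25, beta = 0.7, seed = 42) {
  set.seed(seed)
  x <- rnorm(n)
  entry <- runif(n, 40, 60)
  gap <- rexp(n, rate = 0.2 * exp(beta * x)) + 0.01
  exit <- entry + gap
  event <- as.integer(gap < 8)
  exit[event == 0] <- entry[event == 0] + 8
  tibble::tibble(id = seq_len(n), sex = "female", age_entry = entry,
                 age_exit = exit, event = event, x = x)
}

# brute-force Cox partial log-likelihood with delayed entry (no ties)
brute_cox_loglik <- function(cohort, terms, beta) {
  X <- as.matrix(cohort[terms])
  lp <- as.numeric(X %*% beta)
  ll <- 0
  for (i in which(cohort$event == 1)) {
    t_i <- cohort$age_exit[i]
    riskset <- cohort$age_entry < t_i & cohort$age_exit >= t_i
    ll <- ll + lp[i] - log(sum(exp(lp[riskset])))
  }
  ll
}

# exhaustive-pair Harrell's C with delayed entry
brute_harrell_c <- function(cohort, risks) {
  conc <- 0
  comp <- 0
  n <- nrow(cohort)
  for (i in seq_len(n)) {
    if (cohort$event[i] != 1) next
    t_i <- cohort$age_exit[i]
    for (j in seq_len(n)) {
      if (j == i) next
      if (!(cohort$age_entry[j] < t_i && cohort$age_exit[j] >= t_i)) next
      if (cohort$event[j] == 1 && cohort$age_exit[j] == t_i) next
      comp <- comp + 1
      if (risks[i] > risks[j]) conc <- conc + 1
      else if (risks[i] == risks[j]) conc <- conc + 0.5
    }
  }
  list(c = conc / comp, n_pairs = comp)
}

# cohort with arbitrary covariates x1..x5, events generated under a
# multiplicative model with the given log-HRs (defaults: signal on x1, x2;
# x3..x5 stay null)
signal_cohort <- function(n, log_hrs = c(x1 = 0.4, x2 = 0.4), seed = 1,
                          inc_scale = 5) {
  set.seed(seed)
  coh <- tibble::tibble(
    id = seq_len(n), sex = "female",
    age_entry = sample(40:69, n, replace = TRUE),
    x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n),
    x5 = rnorm(n)
  )
  model <- crc_model("signal", "female", "multiplicative",
                     hazard_ratios = exp(log_hrs))
  inc <- uk_rates_synthetic("incidence")
  inc$rate <- inc$rate * inc_scale
  simulate_event_times(coh, model, inc, uk_rates_synthetic("mortality"),
                       followup_years = 10, seed = seed + 1)
}

# a small cohort with events for evaluation tests
sim_test_cohort <- function(n = 5000, sex = "female", seed = 11,
                            model = crc_models("new_multivariable", sex),
                            inc_scale = 1) {
  inc <- uk_rates_synthetic("incidence")
  inc$rate <- inc$rate * inc_scale
  cfg <- sim_config(n, sex, model = model, incidence = inc, seed = seed)
  simulate_cohort(cfg)
}
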