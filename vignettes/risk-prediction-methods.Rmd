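---
title: "Methods: 10-year colorectal cancer risk prediction with competing mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 10-year colorectal cancer risk prediction with competing mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcrisk)
```

# The problem

Population colorectal-cancer screening is triggered by age alone, yet most
cancers arise in people with no recognised risk factor. Risk-stratified
screening needs a per-person estimate of the probability of a colorectal
cancer diagnosis over a fixed horizon — here 10 years — that combines
inherited susceptibility (a polygenic risk score, PRS), first-degree family
history (FH) and simple clinical covariates, and that accounts for the
competing possibility of dying of something else first.

`crcrisk` implements that pipeline end to end: PRS scoring from allele
dosages, a registry of sex-specific relative-risk models, an absolute-risk
engine over piecewise-constant population rates, Cox training on the age
time axis, and an evaluation battery (discrimination, calibration,
standardised incidence ratios, risk-stratified cumulative hazards). A
piecewise-exponential competing-risks simulator generates cohorts with
exactly the statistical structure the models assume, so every analytic
component can be validated against a Monte-Carlo oracle.

# Relative-risk models

## Polygenic risk score

The raw PRS is the linear combination of published per-allele log-odds
weights and effect-allele dosages over a 140-variant panel,
$\mathrm{raw}_i = \sum_k \beta_k d_{ik}$, standardised to mean 0 and SD 1 in
the scoring cohort (`compute_raw_prs()`, `standardize_prs()`). Missing
dosages default to the Hardy–Weinberg expectation $2p_k$ (policy
`impute_2pq`), which is unbiased and keeps scores comparable across
missingness patterns; `drop` is available as a sensitivity option. No strand
flipping is attempted: dosage files must already be oriented to the panel's
effect alleles. The packaged panel is a *synthetic* stand-in of the right
shape (140 variants, including the corrected identifier rs9537756);
analyses of real data should load the published weights with
`load_weights()`.

The *population-adjusted* PRS re-expresses the z-score as a relative risk,
$rr = \exp(\beta z - \beta^2/2)$ with $\beta$ the log hazard ratio per SD.
The $-\beta^2/2$ term is the lognormal-mean correction, so that
$\mathbb{E}[rr] = 1$ exactly when $z \sim N(0,1)$. The source describing
this adjustment gives no closed form, so the lognormal normalisation is a
design choice of this package; it is the unique multiplicative form that is
log-linear in $z$ with population mean 1.

## Model registry

Five models are packaged per sex (`crc_models()`):

* **new multivariable** — log-linear in standardised PRS, FH, ever-smoking,
  screening in the last 10 years, and triglycerides (women) or log BMI
  (men), with the published hazard ratios (women: 1.515, 1.238, 1.242,
  0.594, 1.100; men: 1.492, 1.387, 1.343, 0.669, 2.410);
* **new FH + PRS** — PRS and FH only (women 1.514/1.212, men 1.493/1.375);
* **current FH + PRS** — the population-adjusted PRS multiplied by 0.92
  (no FH) or 2.10 (FH);
* **FH alone** — 0.92 or 2.10;
* **average** — relative risk identically 1 (population-average risk).

For the multiplicative models the relative risk is the exponential of the
cohort-centred linear predictor, $rr_i = \exp(LP_i - \overline{LP})$, so its
geometric mean is 1 over the scored cohort. Centring is applied at scoring
time over the cohort being scored; a frozen centring mean can be supplied
for deploy-time scoring of single subjects. Continuous terms flagged as
"centred" (triglycerides, log BMI) are shifted by the cohort mean unless a
constant is given — the original constants were never published, so cohort
means are the defensible default. The 0.92/2.10 FH constants make the
population-average relative risk exactly 1 at an FH prevalence of
$(1-0.92)/(2.10-0.92) \approx 6.8\%$.

The current FH+PRS model needs a per-SD log hazard ratio to form the
population-adjusted PRS when only `prs_std` is available; the packaged
value is the new models' PRS coefficient for the matching sex
(log 1.515 / log 1.492), a stipulation documented here because the
originally published constant is not restated in the sources this package
is built from. A precomputed `prs_rr` column always takes precedence.

# Absolute risk with competing mortality

Let $\lambda_1(j) = rr \times \text{incidence}(j)$ be the cause-specific
colorectal-cancer hazard at integer age $j$ and $\lambda_2(j)$ the
non-colorectal-cancer mortality hazard, both constant on one-year age
intervals (population rates are in fact constant on 5- or 10-year bands).
With $S_k(t) = \exp(-\sum_{u<t}\lambda_k(u))$, the probability that an
unaffected individual aged $a$ is diagnosed within $h$ years is

$$\sum_{j=a}^{a+h-1}
  \frac{\lambda_1(j)}{\lambda_1(j)+\lambda_2(j)}\,
  \frac{S_1(j)}{S_1(a)}\frac{S_2(j)}{S_2(a)}
  \left[1-e^{-\lambda_1(j)-\lambda_2(j)}\right].$$

The relative risk multiplies incidence only — never mortality — and enters
$S_1$ as well. Lifetime risk is the same sum from age 0 through 89. Two
exact identities anchor the implementation and are enforced in tests to
1e-12: replacing the cause-splitting factor by 1 telescopes the sum to
$1 - S_1 S_2$ ratio (all-cause probability), and with zero mortality and a
flat hazard the sum collapses to $1-e^{-h\lambda_1}$.

Numerical choices: ages and horizons are integers (the step-function
assumption makes sub-annual resolution meaningless); fractional entry ages
are floored for rate lookup; intervals with $\lambda_1+\lambda_2=0$
contribute zero by convention (the limit of the term). The survival ratios
are computed as $S(j)/S(a) = \exp(-\sum_{u=a}^{j-1}\lambda(u))$, so rates
below the starting age are never needed for horizon risks.

# The synthetic-cohort generator

`simulate_covariates()` draws a cohort of one sex with entry ages uniform
on the integers 40–69 (no entry-age distribution is published; uniform is
the neutral choice over the eligible range), FH prevalence 0.10 (the
population figure for an affected first-degree relative), ever-smoking
0.45, screening-in-10-years 0.35, triglycerides log-normal
(median 1.4 mmol/L, log-SD 0.45), log BMI normal (median 27.5 kg/m²,
log-SD 0.15), entry calendar year uniform 2006–2009, and a standard-normal
PRS — or, when a weight panel with allele frequencies is supplied, per-SNP
dosages Binomial(2, p) that are scored and standardised through the PRS
module. Menopause/HRT status for women is drawn and resolved through the
adjudication rule (ever-HRT ⇒ menopausal; otherwise premenopausal under 51
and menopausal at 51+). Covariates are independent by default; a Gaussian
copula correlation `rho` couples the continuous covariates so that
adjusted-SD standardisation is distinguishable from naive standardisation.
Missingness injection is opt-in and MCAR.

`simulate_event_times()` inverts a single Exp(1) draw through the
cumulative total hazard $rr\cdot\lambda_1^{base}+\lambda_2$ accumulated
across annual age intervals from entry, then assigns the cause at the fired
interval with probability $\lambda_1/(\lambda_1+\lambda_2)$ — exact under
the step-function model, with no discretisation error, and therefore a
valid Monte-Carlo oracle for the analytic risk formula (the two are
cross-checked within three binomial standard errors at n = 200,000 in the
acceptance suite). Survivors are administratively censored at
entry + 10 years.

The packaged rate tables (`uk_rates_synthetic()`) are synthetic
England-like step functions: incidence rising from about 1 to 26 per
10,000 person-years across ages 40–89 for women and about 1.5× that for
men, and Gompertz-like competing mortality. They were chosen once so that
mean 10-year risks at entry ages 40–69 land near 0.9% (women) and 1.5%
(men) and lifetime risks near 4–6%, the ballpark of the real population
tables; they carry no calendar-year trend and no cohort effects. What
passing tests therefore show is that the *machinery* is correct under the
assumed data-generating process — not that the packaged coefficients are
well calibrated for any real population, which requires official rate
tables and real cohorts.

# Training

`fit_cox_age_axis()` fits Cox proportional hazards models with age as the
time axis and delayed entry: subjects are left-truncated at entry age, so
the risk set at a failure age $t$ is $\{j: \text{entry}_j < t \le
\text{exit}_j\}$. Ties use the Efron approximation (accurate for the
moderate tie rates that near-continuous simulated ages produce).
Confidence intervals are Wald on the log scale. `stepwise_bic()` performs
greedy forward or backward selection accepting only BIC-decreasing steps,
with the number of *events* as the BIC sample size — the conventional
effective sample size for Cox partial likelihood.

`hr_per_adjusted_sd()` puts coefficients on a common scale: each risk
factor is regressed on all the others (linear for continuous, logistic for
binary with *response* residuals $y-\hat p$, exactly as the procedure is
described — no studentisation), the residuals are divided by their SD, and
the Cox model is refit on the full set of unit-SD residual covariates. For
mutually independent covariates this collapses to raising the raw hazard
ratio to the power of the covariate's marginal SD, which is why a rare
binary factor (FH at ~10% prevalence, SD ≈ 0.3) shows an adjusted-SD HR
much closer to 1 than its raw HR.

# Evaluation

* **Association** — `hr_per_sd_of_score()`: Cox on the age axis with the
  risk score's log odds scaled to unit SD.
* **Discrimination** — `harrell_c()`: delayed-entry Harrell's C; over
  pairs where one subject fails and the other is in the risk set at that
  age (tied failure ages not comparable), the fraction where the failing
  subject had the higher score, ties counting half. Standard errors come
  from exact leave-one-out jackknife values, computed in closed form from
  per-subject pair counts; `compare_c()` uses the same influence values
  for the correlated z-test (the DeLong construction generalised from AUC
  to Harrell's C — an interpretation, since the original is defined for
  AUC) and the usual independent z-test otherwise.
* **Calibration** — `calibration()`: logistic slope of outcome on the log
  odds of predicted risk (<1 = over-dispersion), and the intercept of a
  second fit with the slope constrained to 1 via an offset (<0 =
  over-prediction), plus a decile table for plotting. Subjects censored
  event-free before the horizon count as non-events — the simplest reading
  of the published procedure; under purely administrative 10-year
  censoring and competing death this is exact, because the predicted risk
  already integrates the competing hazard.
* **Risk stratification** — `nelson_aalen_by_group()`: delayed-entry
  Nelson–Aalen cumulative hazards per risk group, tabulated at ages
  55/65/75; `sir_by_risk_group()`: observed versus expected events in the
  first four quintiles and top two deciles of predicted risk, with cut
  points from the evaluated cohort and ties broken by stable sort.
* **SIR** — `expected_events()` integrates person-time at integer-age
  slices (fractional time apportioned linearly) against sex-, age- and
  optionally calendar-year-specific rates, with follow-up ending at
  diagnosis, death or the horizon; `sir()` reports observed/expected with
  a Garwood exact-Poisson interval, which reproduces the asymmetry of
  published intervals better than a normal approximation.

`evaluate_report()` assembles the battery for a set of models on one
cohort; per-model detail (decile tables, SIR tables, concordance objects)
rides along as an attribute.

# Self-consistency and problem sizes

The test suite validates every operation against an independent oracle:
brute-force dot products and partial likelihoods, exhaustive pair
enumeration for C, hand-enumerated risk sets for Nelson–Aalen, closed
forms for degenerate rate tables, and the simulator/formula cross-check.
The end-to-end check simulates under the current FH+PRS model at FH
prevalence 6.8% — the prevalence at which that model's population-average
relative risk is exactly 1 — and verifies overall SIR ≈ 1 and calibration
slope ≈ 1 within three standard errors.

Simulation sizes were chosen to keep Monte-Carlo error well below the
assertion tolerances while keeping the default test run fast: n = 200,000
for the simulator/formula oracle (binomial SE ≈ 0.02% against ~1% risks),
n = 50,000 × 20 replicates for coefficient-recovery coverage, n = 100,000
for calibration-distortion recovery (±0.05 tolerances), and smaller
cohorts with proportionally inflated incidence for unit tests where only
the event *machinery*, not the rate scale, is under test.

# Known limitations

* Packaged weights and rate tables are synthetic; published performance
  figures on real cohorts (C ≈ 0.69, slopes ≈ 0.9) cannot be reproduced
  without the real data and are not targets of the test suite.
* Multiple imputation (chained equations, Rubin's rules) is out of scope;
  fitting assumes complete or simply-imputed data.
* Proportional-hazards diagnostics, time-varying covariates and frailty
  models are out of scope.
* The population-adjustment formula and the current model's per-SD
  constant are stipulations, as flagged above.
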