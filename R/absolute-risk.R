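#' Step-function survival from annual hazards
#'
#' With a hazard that is constant on unit age intervals,
#' `S(t) = exp(-(lambda(0) + lambda(1) + ... + lambda(t-1)))` for integer
#' `t >= 1` and `S(0) = 1`.
#'
#' @param hazards Numeric vector of annual hazards; `hazards[u + 1]` is
#'   the hazard on the interval `[u, u + 1)`, starting at age 0.
#' @param t Integer time(s); `S(t)` needs hazards defined for ages
#'   `0 .. t - 1`.
#' @return Numeric vector of survival probabilities.
#' @export
step_survival <- function(hazards, t) {
  if (any(t < 0) || any(t != floor(t))) abort("t must be non-negative integers")
  if (any(!is.finite(hazards)) || any(hazards < 0)) {
    abort("hazards must be finite and non-negative")
  }
  if (max(t) > length(hazards)) {
    abort("hazard undefined within [0, t): extend the hazard vector")
  }
  cum <- c(0, cumsum(hazards))
  exp(-cum[t + 1])
}

#' Absolute risk under competing mortality
#'
#' The probability that an unaffected individual aged `a` is diagnosed
#' with colorectal cancer within the next `h` years, with piecewise
#' constant annual cause-specific hazards: colorectal-cancer incidence
#' `lambda1(j) = rr * incidence(j)` and competing (non-colorectal-cancer)
#' mortality `lambda2(j)`. With both hazards constant on unit intervals
#' the risk reduces to the explicit sum
#' \deqn{\sum_{j=a}^{a+h-1} \frac{\lambda_1(j)}{\lambda_1(j)+\lambda_2(j)}
#'   \frac{S_1(j)}{S_1(a)} \frac{S_2(j)}{S_2(a)}
#'   \left[1 - e^{-\lambda_1(j)-\lambda_2(j)}\right],}
#' where \eqn{S_k(t) = \exp(-\sum_{u<t} \lambda_k(u))}. The relative risk
#' multiplies incidence only, never mortality, and enters \eqn{S_1} as
#' well. Terms with `lambda1 + lambda2 = 0` contribute 0.
#'
#' @param age Integer age(s) at the start of the risk period (fractional
#'   ages are floored).
#' @param horizon Integer number of years `h`.
#' @param rr Relative risk(s); recycled against `age`.
#' @param incidence,mortality `crc_rate_table`s covering
#'   `[age, age + horizon)`.
#' @param sex `"female"` or `"male"` (scalar or vector).
#' @return A tibble with columns `age_start`, `horizon`, `rr`, `risk`.
#' @export
absolute_risk <- function(age, horizon, rr, incidence, mortality, sex) {
  if (horizon < 0 || horizon != floor(horizon)) {
    abort("horizon must be a non-negative integer")
  }
  if (any(!is.finite(rr)) || any(rr < 0)) abort("rr must be finite and >= 0")
  n <- max(length(age), length(rr), length(sex))
  age <- floor(rep_len(age, n))
  rr <- rep_len(rr, n)
  sex <- rep_len(sex, n)
  risk <- numeric(n)
  if (horizon > 0) {
    grp <- paste(sex, age)
    for (g in unique(grp)) {
      idx <- which(grp == g)
      a <- age[idx[1]]
      s <- sex[idx[1]]
      ages_j <- a:(a + horizon - 1)
      inc_j <- rate_at(incidence, s, ages_j)
      mor_j <- rate_at(mortality, s, ages_j)
      # prefix cumulative hazards from a to j (exclusive), so the
      # S(j)/S(a) ratios need no rates below age a
      c1 <- c(0, cumsum(inc_j))[seq_len(horizon)]
      c2 <- c(0, cumsum(mor_j))[seq_len(horizon)]
      r <- rr[idx]
      lam1 <- outer(r, inc_j)                      # n_g x h
      lam2 <- matrix(mor_j, length(r), horizon, byrow = TRUE)
      tot <- lam1 + lam2
      frac <- ifelse(tot > 0, lam1 / tot, 0)
      surv <- exp(-outer(r, c1) - matrix(c2, length(r), horizon, byrow = TRUE))
      risk[idx] <- rowSums(frac * surv * (1 - exp(-tot)))
    }
  }
  tibble::tibble(age_start = age, horizon = horizon, rr = rr, risk = risk)
}

#' Lifetime absolute risk
#'
#' The absolute risk from birth over ages 0 to 89, i.e.
#' `absolute_risk(a = 0, h = 90, ...)`. Requires rate tables covering
#' ages 0-89.
#'
#' @inheritParams absolute_risk
#' @return A tibble as from [absolute_risk()].
#' @export
lifetime_risk <- function(rr, incidence, mortality, sex) {
  absolute_risk(0, 90, rr, incidence, mortality, sex)
}

#' Add predicted absolute risks to a cohort
#'
#' Scores a cohort with a model's relative risk and converts it to the
#' `horizon`-year absolute risk at each subject's entry age.
#'
#' @param data Cohort tibble with `sex`, `age_entry` and the model's
#'   covariates.
#' @param model A `crc_model`.
#' @param incidence,mortality Rate tables.
#' @param horizon Risk horizon in years (default 10).
#' @param ... Passed to [relative_risk()].
#' @return The cohort with columns `rr` and `risk` appended.
#' @export
predict_risk <- function(data, model, incidence, mortality, horizon = 10, ...) {
  rr <- relative_risk(data, model, ...)
  res <- absolute_risk(data$age_entry, horizon, rr, incidence, mortality,
                       data$sex)
  data$rr <- rr
  data$risk <- res$risk
  data
}
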