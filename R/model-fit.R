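#' Cox regression on the age time axis with delayed entry
#'
#' Fits a Cox proportional hazards model using age as the time axis:
#' subjects enter the risk set at `age_entry` (left truncation) and leave
#' at `age_exit`, failing if `event == 1`. The risk set at a failure age
#' `t` is `{j : age_entry_j < t <= age_exit_j}`. Ties are handled with
#' the Efron approximation. The reported BIC uses the number of events as
#' the effective sample size.
#'
#' @param cohort Cohort tibble with `age_entry`, `age_exit`, `event` and
#'   the term columns.
#' @param terms Character vector of covariate names.
#' @return An object of class `crc_cox` wrapping the `survival::coxph`
#'   fit with `loglik`, `n_events` and `bic`.
#' @export
fit_cox_age_axis <- function(cohort, terms) {
  if (any(cohort$age_exit <= cohort$age_entry)) {
    abort("age_exit must exceed age_entry for every subject")
  }
  n_events <- sum(cohort$event)
  if (n_events < 1) abort("no events in cohort")
  if (length(terms) == 0) abort("supply at least one term")
  f <- as.formula(paste("survival::Surv(age_entry, age_exit, event) ~",
                        paste(terms, collapse = " + ")))
  fit <- survival::coxph(f, data = cohort, ties = "efron")
  if (any(is.na(coef(fit)))) {
    abort(paste0("collinear or inestimable term(s): ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  ll <- fit$loglik[2]
  structure(
    list(fit = fit, terms = terms, n = nrow(cohort), n_events = n_events,
         loglik = ll, loglik_null = fit$loglik[1],
         bic = -2 * ll + length(terms) * log(n_events)),
    class = "crc_cox"
  )
}

#' @export
print.crc_cox <- function(x, ...) {
  cat("<crc_cox> age-axis Cox fit:", paste(x$terms, collapse = " + "), "\n")
  cat("  n =", x$n, " events =", x$n_events,
      " loglik =", format(x$loglik), " BIC =", format(x$bic), "\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x A `crc_cox` object.
#' @param conf.level Confidence level for the Wald interval.
#' @param ... Unused.
#' @return A tibble with one row per term: log-HR estimate, standard
#'   error, hazard ratio with Wald confidence bounds and p-value.
#' @export
tidy.crc_cox <- function(x, conf.level = 0.95, ...) {
  est <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  zq <- qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    hazard.ratio = exp(unname(est)),
    conf.low = exp(unname(est) - zq * se),
    conf.high = exp(unname(est) + zq * se),
    p.value = 2 * pnorm(-abs(unname(est) / se))
  )
}

#' Glance at a Cox fit
#'
#' @param x A `crc_cox` object.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `n_events`, `loglik`, `bic`.
#' @export
glance.crc_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, loglik = x$loglik,
                 bic = x$bic)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Stepwise covariate selection by BIC
#'
#' Greedy forward addition or backward elimination over candidate terms,
#' accepting a step only when it lowers the Bayesian information
#' criterion `-2 loglik + k log(n_events)`. BIC is preferred over AIC
#' because it penalises additional parameters more, yielding simple
#' models. The empty model's BIC is `-2` times the null partial
#' log-likelihood.
#'
#' @param cohort Cohort tibble.
#' @param candidates Character vector of candidate terms.
#' @param direction `"forward"` or `"backward"`.
#' @return Character vector of selected terms (possibly empty).
#' @export
stepwise_bic <- function(cohort, candidates,
                         direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (length(candidates) == 0) return(character())
  n_events <- sum(cohort$event)
  bic_of <- function(terms) {
    if (length(terms) == 0) {
      # null model: partial likelihood with no covariates
      ref <- fit_cox_age_axis(cohort, candidates[1])
      -2 * ref$loglik_null
    } else {
      fit_cox_age_axis(cohort, terms)$bic
    }
  }
  current <- if (direction == "forward") character() else candidates
  current_bic <- bic_of(current)
  repeat {
    moves <- if (direction == "forward") {
      setdiff(candidates, current)
    } else {
      current
    }
    if (length(moves) == 0) break
    trial_sets <- lapply(moves, function(m) {
      if (direction == "forward") c(current, m) else setdiff(current, m)
    })
    trial_bics <- vapply(trial_sets, bic_of, numeric(1))
    best <- which.min(trial_bics)
    if (trial_bics[best] < current_bic) {
      current <- trial_sets[[best]]
      current_bic <- trial_bics[best]
    } else {
      break
    }
  }
  current
}

#' Hazard ratios per adjusted standard deviation
#'
#' Puts effect sizes on a common scale across covariates measured on
#' different scales. Each term is regressed on all the other terms
#' (linear regression for continuous terms, logistic for binary terms
#' with response residuals `y - fitted probability`); the residuals are
#' divided by their SD; and a Cox model on the age axis is refitted with
#' all the unit-SD residual covariates together. The hazard ratio per
#' adjusted SD for a term with little residual variance (e.g. a rare
#' binary factor) is compressed towards 1 relative to its raw hazard
#' ratio.
#'
#' @param cohort Cohort tibble.
#' @param terms Character vector (length >= 2) of model terms.
#' @param conf.level Confidence level.
#' @return A tibble with one row per term: `hr_adj_sd`, confidence
#'   bounds, standard error of the log-HR and p-value.
#' @export
hr_per_adjusted_sd <- function(cohort, terms, conf.level = 0.95) {
  if (length(terms) < 2) abort("supply at least two terms")
  adj <- cohort
  for (t in terms) {
    x <- cohort[[t]]
    if (length(unique(x)) < 2) {
      abort(paste0("term `", t, "` is constant; cannot adjust"))
    }
    others <- setdiff(terms, t)
    f <- as.formula(paste(t, "~", paste(others, collapse = " + ")))
    is_binary <- all(x %in% c(0, 1))
    res <- if (is_binary) {
      g <- glm(f, data = cohort, family = binomial())
      x - fitted(g)
    } else {
      residuals(lm(f, data = cohort))
    }
    adj[[t]] <- res / sd(res)
  }
  fit <- fit_cox_age_axis(adj, terms)
  td <- tidy(fit, conf.level = conf.level)
  tibble::tibble(term = td$term, hr_adj_sd = td$hazard.ratio,
                 conf.low = td$conf.low, conf.high = td$conf.high,
                 std.error = td$std.error, p.value = td$p.value)
}
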