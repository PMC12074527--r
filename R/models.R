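#' Construct a relative-risk model (coefficient set)
#'
#' A coefficient set names a risk model and carries its per-term log
#' hazard ratios and centring rules. Four model types exist:
#' \describe{
#'   \item{`multiplicative`}{log-linear in the covariates: relative risk
#'     is `exp(LP - mean(LP))` over the scored cohort (the new
#'     multivariable and new family-history+PRS models).}
#'   \item{`current_fh_prs`}{the population-adjusted PRS relative risk
#'     multiplied by 0.92 (no first-degree family history) or 2.10
#'     (family history).}
#'   \item{`fh_alone`}{0.92 or 2.10 by family history only; the constants
#'     make the population-average relative risk 1 at a family-history
#'     prevalence of (1 - 0.92)/(2.10 - 0.92), about 6.8%.}
#'   \item{`average`}{relative risk identically 1 (population-average
#'     risk).}
#' }
#'
#' @param name Model name.
#' @param sex `"female"` or `"male"`.
#' @param type One of `"multiplicative"`, `"current_fh_prs"`,
#'   `"fh_alone"`, `"average"`.
#' @param hazard_ratios Named numeric vector of per-term hazard ratios
#'   (multiplicative models).
#' @param centering Character vector naming continuous terms centred at
#'   the cohort mean before scoring.
#' @param beta_per_sd Log hazard ratio per PRS SD used to form the
#'   population-adjusted PRS (current model).
#' @param ci Optional list of per-term confidence bounds (metadata only).
#' @return An object of class `crc_model`.
#' @export
crc_model <- function(name, sex = c("female", "male"),
                      type = c("multiplicative", "current_fh_prs",
                               "fh_alone", "average"),
                      hazard_ratios = NULL, centering = character(),
                      beta_per_sd = NULL, ci = NULL) {
  sex <- match.arg(sex)
  type <- match.arg(type)
  if (type == "multiplicative") {
    if (is.null(hazard_ratios) || length(hazard_ratios) == 0 ||
        is.null(names(hazard_ratios))) {
      abort("multiplicative models need a named `hazard_ratios` vector")
    }
    if (any(!is.finite(log(hazard_ratios)))) {
      abort("hazard ratios must be positive and finite")
    }
  }
  structure(
    list(name = name, sex = sex, type = type,
         hazard_ratios = hazard_ratios,
         terms = if (!is.null(hazard_ratios)) log(hazard_ratios),
         centering = centering, beta_per_sd = beta_per_sd, ci = ci),
    class = "crc_model"
  )
}

#' @export
print.crc_model <- function(x, ...) {
  cat("<crc_model> ", x$name, " (", x$sex, ", ", x$type, ")\n", sep = "")
  if (!is.null(x$terms)) {
    for (t in names(x$terms)) {
      cat(sprintf("  %-16s HR %.3f  (log-HR %+.4f)%s\n", t,
                  x$hazard_ratios[[t]], x$terms[[t]],
                  if (t %in% x$centering) "  [centred]" else ""))
    }
  }
  invisible(x)
}

# Family-history relative-risk constants: chosen so that the population
# average risk equals 1 at the implied FH prevalence.
FH_RR_NO <- 0.92
FH_RR_YES <- 2.10

#' Registry of packaged colorectal-cancer risk models
#'
#' The published sex-specific hazard ratios for the new 10-year models:
#' the new multivariable model (PRS, first-degree family history, ever
#' smoking, screening in the last 10 years, plus triglycerides for women
#' or log body-mass index for men) and the new family-history+PRS model;
#' alongside the pre-existing family-history+population-adjusted-PRS
#' model, the family-history-alone model and the population-average
#' model.
#'
#' @param name One of `"new_multivariable"`, `"new_fh_prs"`,
#'   `"current_fh_prs"`, `"fh_alone"`, `"average"`.
#' @param sex `"female"` or `"male"`.
#' @return A `crc_model`.
#' @examples
#' crc_models("new_multivariable", "female")
#' @export
crc_models <- function(name = c("new_multivariable", "new_fh_prs",
                                "current_fh_prs", "fh_alone", "average"),
                       sex = c("female", "male")) {
  name <- match.arg(name)
  sex <- match.arg(sex)
  if (name == "new_multivariable" && sex == "female") {
    crc_model(name, sex, "multiplicative",
              hazard_ratios = c(prs_std = 1.515, fh = 1.238,
                                smoke_ever = 1.242, screening_10y = 0.594,
                                triglycerides = 1.100),
              centering = "triglycerides")
  } else if (name == "new_multivariable" && sex == "male") {
    crc_model(name, sex, "multiplicative",
              hazard_ratios = c(prs_std = 1.492, fh = 1.387,
                                smoke_ever = 1.343, screening_10y = 0.669,
                                log_bmi = 2.410),
              centering = "log_bmi")
  } else if (name == "new_fh_prs" && sex == "female") {
    crc_model(name, sex, "multiplicative",
              hazard_ratios = c(prs_std = 1.514, fh = 1.212))
  } else if (name == "new_fh_prs" && sex == "male") {
    crc_model(name, sex, "multiplicative",
              hazard_ratios = c(prs_std = 1.493, fh = 1.375))
  } else if (name == "current_fh_prs") {
    # per-SD log-HR for the population adjustment taken from the new
    # models' PRS coefficient for the matching sex (a stipulation: the
    # originally published constant is not restated here)
    crc_model(name, sex, "current_fh_prs",
              beta_per_sd = if (sex == "female") log(1.515) else log(1.492))
  } else if (name == "fh_alone") {
    crc_model(name, sex, "fh_alone")
  } else {
    crc_model(name, sex, "average")
  }
}

#' Linear predictor of a multiplicative model
#'
#' `LP_i = sum_t beta_t * x_it`, with continuous terms named in the
#' model's centring rule shifted by `centers` (defaulting to the cohort
#' mean of the term).
#'
#' @param data Data frame supplying one column per model term.
#' @param model A multiplicative `crc_model`.
#' @param centers Optional named numeric vector of frozen centring
#'   constants for the centred terms; defaults to cohort means.
#' @return Numeric vector of linear predictors.
#' @export
linear_predictor <- function(data, model, centers = NULL) {
  stopifnot(inherits(model, "crc_model"))
  if (model$type != "multiplicative") {
    abort("linear_predictor() applies to multiplicative models only")
  }
  missing_terms <- setdiff(names(model$terms), names(data))
  if (length(missing_terms) > 0) {
    abort(paste0("data is missing model term(s): ",
                 paste(missing_terms, collapse = ", ")))
  }
  lp <- rep(0, nrow(data))
  for (t in names(model$terms)) {
    x <- as.numeric(data[[t]])
    if (anyNA(x)) abort(paste0("missing values in term `", t,
                               "`; impute first (see impute_simple)"))
    if (t %in% model$centering) {
      ctr <- if (!is.null(centers) && t %in% names(centers)) {
        centers[[t]]
      } else {
        mean(x)
      }
      x <- x - ctr
    }
    lp <- lp + model$terms[[t]] * x
  }
  lp
}

#' Relative risk under a multiplicative model
#'
#' Exponentiates the cohort-centred linear predictor:
#' `rr_i = exp(LP_i - mean(LP))`, so the geometric mean of the relative
#' risk over the scored cohort is 1. A frozen centring mean can be
#' supplied for deploy-time scoring of single subjects.
#'
#' @inheritParams linear_predictor
#' @param center_lp Optional frozen value of `mean(LP)`; defaults to the
#'   mean over `data`.
#' @return Numeric vector of relative risks.
#' @export
relative_risk_multivariable <- function(data, model, centers = NULL,
                                        center_lp = NULL) {
  if (nrow(data) == 0) abort("empty cohort")
  lp <- linear_predictor(data, model, centers)
  if (is.null(center_lp)) center_lp <- mean(lp)
  exp(lp - center_lp)
}

#' Relative risk from family history alone
#'
#' Assigns 0.92 to participants without and 2.10 to participants with an
#' affected first-degree relative, constants chosen so that the
#' population-average relative risk is 1.
#'
#' @param fh Binary (0/1) first-degree family history indicator.
#' @return Numeric vector of relative risks (0.92 or 2.10).
#' @export
relative_risk_family_history <- function(fh) {
  if (!all(fh %in% c(0, 1))) abort("fh must be binary 0/1")
  ifelse(fh == 1, FH_RR_YES, FH_RR_NO)
}

#' Relative risk under the current family-history + PRS model
#'
#' Multiplies the population-adjusted PRS relative risk by the
#' family-history constants 0.92/2.10.
#'
#' @param fh Binary (0/1) family-history indicator.
#' @param prs_rr Population-adjusted PRS relative risk (positive).
#' @return Numeric vector of relative risks.
#' @export
relative_risk_current <- function(fh, prs_rr) {
  if (!all(fh %in% c(0, 1))) abort("fh must be binary 0/1")
  if (any(!is.finite(prs_rr)) || any(prs_rr <= 0)) {
    abort("prs_rr must be positive and finite")
  }
  prs_rr * relative_risk_family_history(fh)
}

#' Relative risk of a cohort under any packaged model
#'
#' Dispatches on the model type. For the current family-history+PRS model
#' a `prs_rr` column is used if present, otherwise it is derived from
#' `prs_std` with the model's `beta_per_sd`.
#'
#' @param data Cohort data frame.
#' @param model A `crc_model`.
#' @param ... Passed to [relative_risk_multivariable()] for
#'   multiplicative models.
#' @return Numeric vector of relative risks.
#' @export
relative_risk <- function(data, model, ...) {
  stopifnot(inherits(model, "crc_model"))
  switch(model$type,
    multiplicative = relative_risk_multivariable(data, model, ...),
    fh_alone = relative_risk_family_history(data$fh),
    current_fh_prs = {
      prs_rr <- if ("prs_rr" %in% names(data)) {
        data$prs_rr
      } else {
        population_adjust_prs(data$prs_std, model$beta_per_sd)
      }
      relative_risk_current(data$fh, prs_rr)
    },
    average = rep(1, nrow(data))
  )
}
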