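#' Read a piecewise-constant annual rate table
#'
#' Rate tables hold annual event rates (events per person-year) that are
#' constant on age intervals `[age_lo, age_hi)`, separately by sex and
#' optionally by calendar year. Two tables drive the absolute-risk engine:
#' colorectal-cancer incidence (the baseline cause-specific hazard that a
#' relative risk multiplies) and non-colorectal-cancer mortality (the
#' competing hazard).
#'
#' @param path Path to a CSV file with header columns `sex`, `age_lo`,
#'   `age_hi`, `rate` and optionally `year`.
#' @return A validated tibble with class `crc_rate_table`.
#' @seealso [uk_rates_synthetic()] for the packaged England-like tables.
#' @export
load_rate_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_rate_table(tbl)
}

#' Validate a data frame as a rate table
#'
#' @param tbl Data frame with columns `sex`, `age_lo`, `age_hi`, `rate`
#'   and optionally `year`.
#' @return The table as a `crc_rate_table` tibble.
#' @export
as_rate_table <- function(tbl) {
  needed <- c("sex", "age_lo", "age_hi", "rate")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("rate table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl <- tibble::as_tibble(tbl)
  if (!all(tbl$sex %in% c("female", "male"))) {
    abort("rate table `sex` must be 'female' or 'male'")
  }
  if (any(!is.finite(tbl$rate)) || any(tbl$rate < 0)) {
    abort("rate table rates must be finite and non-negative")
  }
  if (any(tbl$age_hi <= tbl$age_lo)) {
    abort("rate table intervals must have age_hi > age_lo")
  }
  # overlap check within each sex (x year) stratum
  strata <- if ("year" %in% names(tbl)) {
    split(tbl, interaction(tbl$sex, tbl$year, drop = TRUE))
  } else {
    split(tbl, tbl$sex)
  }
  for (s in strata) {
    s <- s[order(s$age_lo), ]
    if (nrow(s) > 1 && any(s$age_lo[-1] < s$age_hi[-nrow(s)])) {
      abort("rate table has overlapping age intervals")
    }
  }
  class(tbl) <- c("crc_rate_table", class(tbl))
  tbl
}

#' Look up annual rates at integer ages
#'
#' Step-function semantics: the rate at age `a` is the rate of the interval
#' `[age_lo, age_hi)` containing `a`. If the table has a `year` column and
#' `years` is supplied, lookup is also matched on calendar year.
#'
#' @param rates A `crc_rate_table` (or data frame coercible to one).
#' @param sex `"female"` or `"male"` (scalar or vector recycled to `ages`).
#' @param ages Vector of ages (fractional ages are floored).
#' @param years Optional vector of calendar years.
#' @return Numeric vector of annual rates, same length as `ages`.
#' @export
rate_at <- function(rates, sex, ages, years = NULL) {
  if (!inherits(rates, "crc_rate_table")) rates <- as_rate_table(rates)
  ages <- floor(ages)
  n <- length(ages)
  sex <- rep_len(sex, n)
  has_year <- "year" %in% names(rates) && !is.null(years)
  if (has_year) years <- rep_len(floor(years), n)
  out <- rep(NA_real_, n)
  key <- if (has_year) paste(sex, ages, years) else paste(sex, ages)
  uk <- !duplicated(key)
  for (i in which(uk)) {
    hit <- rates$sex == sex[i] & rates$age_lo <= ages[i] & ages[i] < rates$age_hi
    if (has_year) hit <- hit & rates$year == years[i]
    w <- which(hit)
    if (length(w) == 0) {
      abort(paste0("rate table does not cover sex=", sex[i],
                   " age=", ages[i],
                   if (has_year) paste0(" year=", years[i]) else ""))
    }
    if (length(w) > 1) abort("ambiguous rate table lookup (overlapping rows)")
    out[key == key[i]] <- rates$rate[w[1]]
  }
  out
}

#' Packaged synthetic England-like rate tables
#'
#' Annual colorectal-cancer incidence and non-colorectal-cancer mortality
#' step functions by sex, constant on 5-year age bands, covering ages 0-90.
#' These are synthetic stand-ins with the broad shape of the England
#' population rates used in 10-year risk work (incidence rising from
#' roughly 1 to 26 per 10,000 person-years between ages 40 and 89 for
#' women, about 1.5 times that for men; Gompertz-like all-cause mortality
#' net of colorectal cancer). They make lifetime-risk and simulation
#' examples self-contained; analyses of real cohorts should load official
#' rate tables with [load_rate_table()].
#'
#' @param type `"incidence"` for colorectal-cancer incidence or
#'   `"mortality"` for competing (non-colorectal-cancer) mortality.
#' @return A `crc_rate_table` tibble covering ages 0-90 for both sexes.
#' @export
uk_rates_synthetic <- function(type = c("incidence", "mortality")) {
  type <- match.arg(type)
  lo <- c(0, 30, 35, seq(40, 85, by = 5))
  hi <- c(30, 35, seq(40, 85, by = 5), 90)
  if (type == "incidence") {
    f <- c(2e-6, 1.0e-5, 3.0e-5, 1.0e-4, 1.6e-4, 2.8e-4, 4.5e-4,
           7.0e-4, 1.05e-3, 1.5e-3, 1.9e-3, 2.3e-3, 2.6e-3)
    m <- c(3e-6, 1.2e-5, 4.0e-5, 1.4e-4, 2.4e-4, 4.5e-4, 7.5e-4,
           1.2e-3, 1.8e-3, 2.5e-3, 3.1e-3, 3.6e-3, 4.0e-3)
  } else {
    f <- c(3e-4, 4e-4, 6e-4, 1.0e-3, 1.5e-3, 2.5e-3, 4.0e-3,
           6.5e-3, 1.1e-2, 1.8e-2, 3.0e-2, 5.5e-2, 1.0e-1)
    m <- c(4e-4, 6e-4, 9e-4, 1.5e-3, 2.2e-3, 3.6e-3, 5.8e-3,
           9.5e-3, 1.6e-2, 2.6e-2, 4.3e-2, 7.5e-2, 1.3e-1)
  }
  as_rate_table(tibble::tibble(
    sex = rep(c("female", "male"), each = length(lo)),
    age_lo = rep(lo, 2),
    age_hi = rep(hi, 2),
    rate = c(f, m)
  ))
}
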