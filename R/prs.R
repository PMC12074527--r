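#' Load a SNP weight panel
#'
#' A weight panel defines a polygenic risk score (PRS): for each variant,
#' the effect allele and its per-allele log-odds weight. The packaged
#' 140-variant panel (see [crc_panel_synthetic()]) mirrors the size and
#' identifier conventions of the published 140-SNP colorectal-cancer PRS,
#' including the corrected identifier rs9537756 for the 13:34092164_C/T
#' variant; its weights are synthetic stand-ins.
#'
#' @param path Tab-separated file with header columns `rsid`,
#'   `effect_allele`, `other_allele`, `beta` and optionally `freq`
#'   (effect-allele frequency, used by the `impute_2pq` missing-dosage
#'   policy).
#' @return A tibble with class `crc_weight_panel`.
#' @export
load_weights <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_weight_panel(tbl)
}

#' Validate a data frame as a weight panel
#' @param tbl Data frame with columns `rsid`, `effect_allele`,
#'   `other_allele`, `beta` and optionally `freq`.
#' @return The panel as a `crc_weight_panel` tibble.
#' @export
as_weight_panel <- function(tbl) {
  needed <- c("rsid", "effect_allele", "other_allele", "beta")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("weight panel is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl <- tibble::as_tibble(tbl)
  dup <- duplicated(tbl$rsid)
  if (any(dup)) {
    abort(paste0("duplicate rsid in weight panel: ",
                 paste(unique(tbl$rsid[dup]), collapse = ", "),
                 " (first duplicate at line ", which(dup)[1] + 1L, ")"))
  }
  if (!is.numeric(tbl$beta) || any(!is.finite(tbl$beta))) {
    abort("weight panel betas must be finite numbers")
  }
  bases <- c("A", "C", "G", "T")
  if (!all(tbl$effect_allele %in% bases) || !all(tbl$other_allele %in% bases)) {
    abort("alleles must be single bases A/C/G/T")
  }
  if (any(tbl$effect_allele == tbl$other_allele)) {
    abort("effect and other allele must differ")
  }
  if ("freq" %in% names(tbl) &&
      any(!is.na(tbl$freq) & (tbl$freq <= 0 | tbl$freq >= 1))) {
    abort("effect-allele frequencies must lie in (0, 1)")
  }
  class(tbl) <- c("crc_weight_panel", class(tbl))
  tbl
}

#' The packaged synthetic 140-SNP panel
#'
#' @return A `crc_weight_panel` of 140 variants with synthetic weights and
#'   effect-allele frequencies.
#' @export
crc_panel_synthetic <- function() {
  load_weights(system.file("extdata", "prs_panel_140snp_synthetic.tsv",
                           package = "crcrisk", mustWork = TRUE))
}

#' Read a wide dosage table
#'
#' The dosage dialect produced by common genotype-export tools: one row per
#' participant, an `id` column, and one column per rsID holding the
#' effect-allele dosage in `[0, 2]` (missing allowed, encoded as empty
#' fields).
#'
#' @param path CSV file path.
#' @return A tibble with `id` plus one numeric column per variant.
#' @export
read_dosages <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"id" %in% names(tbl)) abort("dosage file must have an `id` column")
  vals <- as.matrix(tbl[setdiff(names(tbl), "id")])
  if (any(vals < 0 | vals > 2, na.rm = TRUE)) {
    abort("dosages must lie in [0, 2]")
  }
  tbl
}

#' Compute the raw polygenic risk score
#'
#' The raw score is the linear combination of panel weights and
#' effect-allele dosages, `raw_i = sum_k beta_k * dosage_ik`.
#'
#' @param dosages A data frame with an `id` column and one column per
#'   panel rsID (dosages in `[0, 2]`, `NA` allowed), as from
#'   [read_dosages()].
#' @param panel A `crc_weight_panel`.
#' @param missing_policy How to handle missing dosages: `"impute_2pq"`
#'   replaces a missing dosage with twice the panel effect-allele
#'   frequency (the Hardy-Weinberg expectation, keeping scores comparable
#'   across missingness patterns); `"drop"` treats the missing variant as
#'   contributing zero for that participant.
#' @return A tibble with columns `id` and `prs_raw`.
#' @export
compute_raw_prs <- function(dosages, panel,
                            missing_policy = c("impute_2pq", "drop")) {
  missing_policy <- match.arg(missing_policy)
  if (!inherits(panel, "crc_weight_panel")) panel <- as_weight_panel(panel)
  snp_cols <- setdiff(names(dosages), "id")
  unknown <- setdiff(snp_cols, panel$rsid)
  if (length(unknown) > 0) {
    abort(paste0("dosage column(s) not in panel: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  d <- as.matrix(dosages[snp_cols])
  beta <- panel$beta[match(snp_cols, panel$rsid)]
  if (anyNA(d)) {
    if (missing_policy == "impute_2pq") {
      if (!"freq" %in% names(panel)) {
        abort("missing dosages with impute_2pq policy, but panel has no `freq` column")
      }
      freq <- panel$freq[match(snp_cols, panel$rsid)]
      if (anyNA(freq[colSums(is.na(d)) > 0])) {
        abort("missing dosages at variants without an effect-allele frequency")
      }
      fill <- matrix(2 * freq, nrow = nrow(d), ncol = ncol(d), byrow = TRUE)
      d[is.na(d)] <- fill[is.na(d)]
    } else {
      d[is.na(d)] <- 0
    }
  }
  tibble::tibble(
    id = if ("id" %in% names(dosages)) dosages$id else seq_len(nrow(d)),
    prs_raw = as.numeric(d %*% beta)
  )
}

#' Standardise raw PRS values
#'
#' Standardised to mean 0 and SD 1 with respect to a reference cohort;
#' when reference moments are omitted they are taken from the scores
#' themselves.
#'
#' @param raw Numeric vector of raw scores.
#' @param reference_mean,reference_sd Reference moments; default to the
#'   mean and SD of `raw`.
#' @return Numeric vector of z-scores.
#' @export
standardize_prs <- function(raw, reference_mean = NULL, reference_sd = NULL) {
  if (is.null(reference_mean)) reference_mean <- mean(raw)
  if (is.null(reference_sd)) reference_sd <- sd(raw)
  if (!is.finite(reference_sd) || reference_sd <= 0) {
    abort("reference SD must be positive (degenerate panel or single score?)")
  }
  (raw - reference_mean) / reference_sd
}

#' Population-adjusted PRS on the relative-risk scale
#'
#' Re-expresses a standardised PRS as a multiplicative risk relative to the
#' population average, `rr = exp(beta * z - beta^2 / 2)`, the lognormal
#' normalisation under which `mean(rr) = 1` exactly when `z` is standard
#' normal. `beta` is the log hazard ratio per SD of the PRS.
#'
#' @param z Standardised PRS values.
#' @param beta_per_sd Log hazard ratio per SD of PRS.
#' @return Numeric vector of relative risks (population mean 1).
#' @export
population_adjust_prs <- function(z, beta_per_sd) {
  if (!is.finite(beta_per_sd)) abort("beta_per_sd must be finite")
  exp(beta_per_sd * z - beta_per_sd^2 / 2)
}

#' Score a dosage table against a panel in one step
#'
#' Convenience pipeline: raw linear combination, standardisation, and
#' population adjustment.
#'
#' @inheritParams compute_raw_prs
#' @param beta_per_sd Log hazard ratio per SD used for the population
#'   adjustment.
#' @inheritParams standardize_prs
#' @return Tibble with `id`, `prs_raw`, `prs_std`, `prs_rr`.
#' @export
score_prs <- function(dosages, panel, beta_per_sd,
                      missing_policy = c("impute_2pq", "drop"),
                      reference_mean = NULL, reference_sd = NULL) {
  out <- compute_raw_prs(dosages, panel, missing_policy)
  out$prs_std <- standardize_prs(out$prs_raw, reference_mean, reference_sd)
  out$prs_rr <- population_adjust_prs(out$prs_std, beta_per_sd)
  out
}
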