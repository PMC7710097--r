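# Per-patient clinical scores: daily and 5-day-summed modified Hyder-Pawlik
# morbidity scores, the day-3 Hyder-Pawlik score, the Hepatica composite
# risk score, achieved-regeneration scores and outcome labelling.

#' SI unit conversions for bilirubin and creatinine
#'
#' Scoring weights expect bilirubin and creatinine in mg/dL; UK laboratories
#' report umol/L. The conversion constants (17.1 for bilirubin, 88.4 for
#' creatinine) numerically coincide with the Hyder-Pawlik weights, so the
#' daily score in SI units reduces to `2.5*INR + bilirubin(umol/L) +
#' creatinine(umol/L)` -- documented, not exploited.
#'
#' @param x value(s) to convert.
#' @return converted value(s).
#' @name unit_conversions
NULL

#' @rdname unit_conversions
#' @export
bilirubin_umol_to_mgdl <- function(x) x / 17.1

#' @rdname unit_conversions
#' @export
bilirubin_mgdl_to_umol <- function(x) x * 17.1

#' @rdname unit_conversions
#' @export
creatinine_umol_to_mgdl <- function(x) x / 88.4

#' @rdname unit_conversions
#' @export
creatinine_mgdl_to_umol <- function(x) x * 88.4

#' Carry-forward imputation of post-operative bloods
#'
#' Longitudinal blood sampling over post-operative days 1-5 is often
#' incomplete owing to early discharge; each missing value is imputed from
#' the value of the previous day, per analyte. Day 1 must be observed
#' unless `allow_preop = TRUE` and a `preop` row is supplied.
#'
#' @param bloods data.frame with columns `day` (subset of 1..5), `inr`,
#'   `bilirubin_umol_l`, `creatinine_umol_l`; missing days may be absent
#'   rows or `NA` entries.
#' @param preop optional single-row data.frame with the same analyte
#'   columns (pre-operative values).
#' @param allow_preop permit the pre-op values to seed a missing day 1.
#' @return complete 5-row data.frame with logical columns `imputed_inr`,
#'   `imputed_bilirubin`, `imputed_creatinine` and `imputed` (any analyte).
#' @export
impute_carry_forward <- function(bloods, preop = NULL, allow_preop = FALSE) {
  cols <- c("inr", "bilirubin_umol_l", "creatinine_umol_l")
  stopifnot(all(c("day", cols) %in% names(bloods)))
  if (any(!bloods$day %in% 1:5)) {
    stop("`bloods$day` must lie in 1..5", call. = FALSE)
  }
  out <- data.frame(day = 1:5)
  for (col in cols) {
    v <- rep(NA_real_, 5)
    v[bloods$day] <- bloods[[col]]
    imp <- logical(5)
    if (is.na(v[1])) {
      if (allow_preop && !is.null(preop) && is.finite(preop[[col]][1])) {
        v[1] <- preop[[col]][1]
        imp[1] <- TRUE
      } else {
        stop("day 1 ", col, " is missing and no pre-operative fallback is ",
             "allowed", call. = FALSE)
      }
    }
    for (d in 2:5) {
      if (is.na(v[d])) {
        v[d] <- v[d - 1]
        imp[d] <- TRUE
      }
    }
    out[[col]] <- v
    out[[paste0("imputed_", sub("_umol_l$", "", col))]] <- imp
  }
  out$imputed <- out$imputed_inr | out$imputed_bilirubin |
    out$imputed_creatinine
  out
}

#' Daily modified Hyder-Pawlik score
#'
#' The weighted blood score `2.5*INR + 17.1*bilirubin(mg/dL) +
#' 88.4*creatinine(mg/dL)`, i.e. the Hyder-Pawlik blood components without
#' the Clavien-Dindo term.
#'
#' @param inr INR (dimensionless).
#' @param bilirubin_mgdl bilirubin in mg/dL.
#' @param creatinine_mgdl creatinine in mg/dL.
#' @return daily score (vectorised).
#' @export
modified_hp_daily <- function(inr, bilirubin_mgdl, creatinine_mgdl) {
  if (any(c(inr, bilirubin_mgdl, creatinine_mgdl) < 0, na.rm = TRUE)) {
    stop("blood values must be non-negative", call. = FALSE)
  }
  2.5 * inr + 17.1 * bilirubin_mgdl + 88.4 * creatinine_mgdl
}

#' Five-day sum of the modified Hyder-Pawlik score
#'
#' @param daily either a numeric vector of 5 daily scores, or a complete
#'   (possibly imputed) 5-row bloods data.frame as returned by
#'   [impute_carry_forward()] (SI units, converted internally).
#' @return the 5-day sum.
#' @export
modified_hp_sum <- function(daily) {
  if (is.data.frame(daily)) {
    if (nrow(daily) != 5L || anyNA(daily[c("inr", "bilirubin_umol_l",
                                           "creatinine_umol_l")])) {
      stop("bloods series is incomplete; impute first", call. = FALSE)
    }
    daily <- modified_hp_daily(daily$inr,
                               bilirubin_umol_to_mgdl(daily$bilirubin_umol_l),
                               creatinine_umol_to_mgdl(daily$creatinine_umol_l))
  }
  if (length(daily) != 5L || anyNA(daily)) {
    stop("need 5 complete daily scores", call. = FALSE)
  }
  sum(daily)
}

#' Hyder-Pawlik score weights
#'
#' The blood weights are fixed by the published score (2.5, 17.1, 88.4);
#' the Clavien-Dindo weight is not restated here and must be supplied
#' explicitly from the original publication's model.
#'
#' @param clavien weight for the maximum Clavien-Dindo grade (required).
#' @param inr,bilirubin,creatinine blood weights.
#' @return named list of weights.
#' @export
hp_weights <- function(clavien, inr = 2.5, bilirubin = 17.1,
                       creatinine = 88.4) {
  if (missing(clavien) || is.null(clavien) || !is.finite(clavien)) {
    stop("configuration error: the Clavien-Dindo weight must be supplied ",
         "(it is not part of this package's defaults)", call. = FALSE)
  }
  list(inr = inr, bilirubin = bilirubin, creatinine = creatinine,
       clavien = clavien)
}

#' Day-3 Hyder-Pawlik score
#'
#' Weighted sum of day-3 INR, bilirubin (mg/dL), creatinine (mg/dL) and the
#' maximum Clavien-Dindo grade. Scores above 9 flag an increased risk of
#' 90-day mortality.
#'
#' @param inr,bilirubin_mgdl,creatinine_mgdl day-3 blood values.
#' @param clavien_dindo maximum Clavien-Dindo grade, 0-5.
#' @param weights a [hp_weights()] list.
#' @param flag_threshold risk flag threshold (default 9, strict).
#' @return list with `score` and `flagged`.
#' @export
hp_day3 <- function(inr, bilirubin_mgdl, creatinine_mgdl, clavien_dindo,
                    weights, flag_threshold = 9) {
  if (missing(weights)) {
    stop("configuration error: `weights` (see hp_weights) is required",
         call. = FALSE)
  }
  if (any(clavien_dindo < 0 | clavien_dindo > 5)) {
    stop("Clavien-Dindo grade must lie in 0..5", call. = FALSE)
  }
  score <- weights$inr * inr + weights$bilirubin * bilirubin_mgdl +
    weights$creatinine * creatinine_mgdl + weights$clavien * clavien_dindo
  list(score = score, flagged = score > flag_threshold)
}

#' Hepatica composite-score coefficients
#'
#' Defaults are the published composite: intercept 1.24, ln(FLR%) weight
#' -2.26, cT1 weight 0.013 per ms. Override to refit on new data.
#'
#' @param intercept,beta_logflr,beta_ct1 model coefficients.
#' @return named list of coefficients.
#' @export
hepatica_coefficients <- function(intercept = 1.24, beta_logflr = -2.26,
                                  beta_ct1 = 0.013) {
  list(intercept = intercept, beta_logflr = beta_logflr, beta_ct1 = beta_ct1)
}

#' Hepatica composite risk score
#'
#' `exp(-(intercept + ln(FLR%) * beta_logflr + cT1 * beta_ct1))`: a
#' composite of the planned future liver remnant and pre-operative cT1.
#' The score increases with FLR and decreases with cT1; lower values
#' indicate a higher risk of poor post-operative liver performance.
#'
#' @param flr_percent planned FLR as a percentage (> 0).
#' @param ct1_ms pre-operative liver cT1 in ms (> 0).
#' @param coeffs a [hepatica_coefficients()] list.
#' @return the score (vectorised, always > 0).
#' @export
hepatica_score <- function(flr_percent, ct1_ms,
                           coeffs = hepatica_coefficients()) {
  if (any(flr_percent <= 0, na.rm = TRUE)) {
    stop("`flr_percent` must be strictly positive", call. = FALSE)
  }
  if (any(ct1_ms <= 0, na.rm = TRUE)) {
    stop("`ct1_ms` must be strictly positive", call. = FALSE)
  }
  exp(-(coeffs$intercept + log(flr_percent) * coeffs$beta_logflr +
          ct1_ms * coeffs$beta_ct1))
}

#' Achieved-regeneration score
#'
#' Two definitions are supported. `"preop_ratio"` (default) divides the
#' pre-operative liver volume by the follow-up volume measured ~3 months
#' after resection. `"resected_relative"` reports the fraction of the
#' resected volume that was regained:
#' `(followup - (preop - resected)) / resected`.
#'
#' @param preop_volume_ml pre-operative liver volume (mL).
#' @param followup_volume_ml follow-up liver volume (mL).
#' @param resected_volume_ml resected volume (mL); required for
#'   `"resected_relative"`.
#' @param mode `"preop_ratio"` or `"resected_relative"`.
#' @return the regeneration score (vectorised).
#' @export
regeneration_score <- function(preop_volume_ml, followup_volume_ml,
                               resected_volume_ml = NULL,
                               mode = c("preop_ratio", "resected_relative")) {
  mode <- match.arg(mode)
  if (any(preop_volume_ml <= 0 | followup_volume_ml <= 0, na.rm = TRUE)) {
    stop("volumes must be strictly positive", call. = FALSE)
  }
  if (mode == "preop_ratio") {
    return(preop_volume_ml / followup_volume_ml)
  }
  if (is.null(resected_volume_ml) ||
      any(resected_volume_ml <= 0, na.rm = TRUE)) {
    stop("`resected_volume_ml` must be strictly positive for ",
         "resected_relative mode", call. = FALSE)
  }
  if (any(resected_volume_ml > preop_volume_ml, na.rm = TRUE)) {
    stop("resected volume cannot exceed the pre-operative volume",
         call. = FALSE)
  }
  (followup_volume_ml - (preop_volume_ml - resected_volume_ml)) /
    resected_volume_ml
}

#' Poor-outcome labels from 5-day modified Hyder-Pawlik sums
#'
#' Two rules: `"threshold"` flags sums strictly over 22 (the discriminator
#' used to train the composite); `"upper_quartile"` flags sums strictly
#' above the cohort's 75th percentile (linear-interpolation quantile).
#'
#' @param mhp_sums numeric vector of 5-day sums over the cohort.
#' @param rule `"threshold"` or `"upper_quartile"`.
#' @param threshold cut-point for the threshold rule (default 22).
#' @return logical vector of poor-outcome flags.
#' @export
outcome_label <- function(mhp_sums, rule = c("threshold", "upper_quartile"),
                          threshold = 22) {
  rule <- match.arg(rule)
  if (rule == "threshold") {
    return(mhp_sums > threshold)
  }
  if (length(mhp_sums) < 4L) {
    stop("upper-quartile rule needs at least 4 patients", call. = FALSE)
  }
  mhp_sums > stats::quantile(mhp_sums, 0.75, names = FALSE, type = 7)
}
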