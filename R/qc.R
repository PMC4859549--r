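# Bioanalytical quality control: incurred sample reanalysis (ISR),
# quantification-range censoring, and in vitro blood:plasma partition-ratio
# estimation.

#' ISR percentage difference
#'
#' `(repeat - original) * 100 / mean(repeat, original)`. Antisymmetric under
#' swapping the arguments and bounded by +/-200% for nonnegative inputs.
#'
#' @param original,repeat_conc Original and repeat concentrations, ug/ml.
#' @return Percentage difference(s); `NA` where both values are zero.
#' @export
isr_percentage_difference <- function(original, repeat_conc) {
  denom <- (original + repeat_conc) / 2
  ifelse(denom > 0, (repeat_conc - original) * 100 / denom, NA_real_)
}

#' Assess an ISR pair table against the acceptance rule
#'
#' A reanalysis campaign passes when at least `required_fraction` of the
#' pairs (default two out of three) deviate by no more than `threshold_pct`
#' (default 20%, boundary inclusive), the rule recommended by the European
#' bioanalytical guidelines.
#'
#' @param pairs Tibble with columns original, repeat_conc and optionally
#'   matrix (for the per-matrix breakdown).
#' @param threshold_pct Maximal tolerated absolute percentage difference.
#' @param required_fraction Minimal fraction of pairs within the threshold.
#' @return List of class `isr_report`: n_pairs, n_within, pct_within,
#'   threshold_pct, required_fraction, pass, by_matrix (tibble).
#' @export
isr_assess <- function(pairs, threshold_pct = 20, required_fraction = 2 / 3) {
  d <- isr_percentage_difference(pairs$original, pairs$repeat_conc)
  valid <- !is.na(d)
  if (!any(valid)) stop("no valid ISR pairs")
  within <- abs(d[valid]) <= threshold_pct
  pct_within <- 100 * mean(within)
  by_matrix <- NULL
  if ("matrix" %in% names(pairs)) {
    bm <- tibble::tibble(matrix = pairs$matrix[valid], within = within)
    by_matrix <- dplyr::summarise(dplyr::group_by(bm, .data$matrix),
                                  n_pairs = dplyr::n(),
                                  n_within = sum(.data$within),
                                  pct_within = 100 * mean(.data$within),
                                  .groups = "drop")
  }
  structure(list(n_pairs = sum(valid), n_within = sum(within),
                 pct_within = pct_within, threshold_pct = threshold_pct,
                 required_fraction = required_fraction,
                 pass = pct_within >= 100 * required_fraction,
                 by_matrix = by_matrix),
            class = "isr_report")
}

#' @export
print.isr_report <- function(x, ...) {
  cat(sprintf("ISR: %d/%d pairs (%.1f%%) within +/-%g%%; %s\n",
              x$n_within, x$n_pairs, x$pct_within, x$threshold_pct,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Censor a concentration table to the assay calibration range
#'
#' Concentrations below the analyte LLOQ are flagged BLQ and the stored value
#' cleared; concentrations above the ULOQ are flagged `above_uloq` but
#' retained (dilution and reassay are not modelled). Idempotent.
#'
#' @param records Concentration tibble (subject_id, analyte, matrix, time_h,
#'   conc_ug_ml, blq).
#' @param lloq_ug_ml,uloq_ug_ml Named numeric vectors per analyte.
#' @return The table with updated `blq` and a `range_flag` column; censoring
#'   counts attached as attribute `n_censored`.
#' @export
censor_to_range <- function(records,
                            lloq_ug_ml = c("R-PZQ" = 0.01, "S-PZQ" = 0.01,
                                           "R-trans-4-OH" = 0.1),
                            uloq_ug_ml = c("R-PZQ" = 2.5, "S-PZQ" = 2.5,
                                           "R-trans-4-OH" = 25)) {
  stopifnot(all(lloq_ug_ml[names(uloq_ug_ml)] < uloq_ug_ml))
  if (nrow(records) == 0) {
    records$range_flag <- character(0)
    attr(records, "n_censored") <- c(blq = 0L, above_uloq = 0L)
    return(records)
  }
  lloq <- unname(lloq_ug_ml[records$analyte])
  uloq <- unname(uloq_ug_ml[records$analyte])
  if ("blq" %in% names(records)) {
    blq <- records$blq
  } else {
    blq <- rep(0L, nrow(records))
  }
  newly_blq <- !is.na(records$conc_ug_ml) & records$conc_ug_ml < lloq
  blq[newly_blq] <- 1L
  records$conc_ug_ml[newly_blq] <- NA_real_
  records$blq <- blq
  above <- !is.na(records$conc_ug_ml) & records$conc_ug_ml > uloq
  records$range_flag <- ifelse(above, "above_uloq",
                               ifelse(blq == 1, "blq", ""))
  attr(records, "n_censored") <- c(blq = sum(newly_blq),
                                   above_uloq = sum(above))
  records
}

#' Blood:plasma partition ratios from a spiked experiment
#'
#' Per replicate the ratio is
#' `100 * (blood_response / is_response_blood) / (plasma_response /
#' is_response_plasma)`; internal-standard normalisation cancels the
#' per-aliquot instrument response. Summarised as mean +/- SD per analyte and
#' nominal level. Replicates with a non-positive plasma response are excluded
#' (count attached as attribute `n_excluded`).
#'
#' @param spiked Tibble: analyte, level, replicate, blood_response,
#'   plasma_response, is_response_blood, is_response_plasma. Missing IS
#'   columns default to 1 (responses already normalised).
#' @return Tibble: analyte, nominal_level, mean_ratio_pct, sd_pct,
#'   n_replicates.
#' @export
partition_ratio <- function(spiked) {
  if (!"is_response_blood" %in% names(spiked)) spiked$is_response_blood <- 1
  if (!"is_response_plasma" %in% names(spiked)) spiked$is_response_plasma <- 1
  ok <- spiked$plasma_response > 0 & spiked$is_response_plasma > 0 &
    spiked$is_response_blood > 0
  n_excluded <- sum(!ok)
  spiked <- spiked[ok, ]
  stopifnot(nrow(spiked) >= 1)
  spiked$ratio_pct <- 100 * (spiked$blood_response / spiked$is_response_blood) /
    (spiked$plasma_response / spiked$is_response_plasma)
  out <- dplyr::summarise(
    dplyr::group_by(spiked, .data$analyte, nominal_level = .data$level),
    mean_ratio_pct = mean(.data$ratio_pct),
    sd_pct = ifelse(dplyr::n() > 1, stats::sd(.data$ratio_pct), NA_real_),
    n_replicates = dplyr::n(), .groups = "drop")
  attr(out, "n_excluded") <- n_excluded
  out
}
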