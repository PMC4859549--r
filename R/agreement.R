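# Cross-matrix agreement: pooled Pearson correlation, percentage ratios,
# conventional and repeated-measures Bland-Altman limits of agreement (LoA)
# with confidence intervals, at the sample-concentration and PK-parameter
# levels.

#' Pair test-matrix against reference-matrix measurements
#'
#' Inner join on (subject, analyte, time) for concentration tables, or on
#' (subject, analyte) for parameter tables (detected by the presence of a
#' `time_h` column). Pairs with a BLQ or missing value on either side are
#' dropped; the number dropped is attached as attribute `n_dropped`.
#'
#' @param x Concentration tibble (subject_id, analyte, matrix, time_h,
#'   conc_ug_ml, blq) or a parameter tibble (subject_id, analyte, matrix,
#'   value).
#' @param test_matrix,reference_matrix Matrix labels, e.g. "blood", "plasma".
#' @return Tibble: subject_id, analyte, (time_h,) test_value, reference_value.
#' @export
pair_measurements <- function(x, test_matrix, reference_matrix = "plasma") {
  conc_level <- "time_h" %in% names(x)
  value_col <- if (conc_level) "conc_ug_ml" else "value"
  keys <- c("subject_id", "analyte", if (conc_level) "time_h")
  take <- function(m, nm) {
    out <- dplyr::filter(x, .data$matrix == m)
    if ("blq" %in% names(out)) out <- dplyr::filter(out, .data$blq == 0)
    out <- dplyr::select(out, dplyr::all_of(c(keys, value_col)))
    stats::setNames(out, c(keys, nm))
  }
  test <- take(test_matrix, "test_value")
  ref <- take(reference_matrix, "reference_value")
  n_before <- max(nrow(test), nrow(ref))
  pairs <- dplyr::inner_join(test, ref, by = keys)
  pairs <- dplyr::filter(pairs, !is.na(.data$test_value),
                         !is.na(.data$reference_value))
  if (nrow(pairs) == 0) stop("no surviving measurement pairs")
  attr(pairs, "n_dropped") <- n_before - nrow(pairs)
  pairs
}

#' Pooled Pearson correlation over measurement pairs
#'
#' Product-moment correlation over all pairs pooled across subjects and
#' times.
#'
#' @param pairs Output of [pair_measurements()].
#' @return Correlation coefficient; `NA` (with a warning) if either side has
#'   zero variance.
#' @export
pearson_pooled <- function(pairs) {
  stopifnot(nrow(pairs) >= 3)
  if (stats::sd(pairs$test_value) == 0 || stats::sd(pairs$reference_value) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(pairs$test_value, pairs$reference_value)
}

#' Percentage ratios of test to reference
#'
#' 100 x test / reference per pair; pairs with a non-positive reference are
#' excluded (count attached as attribute `n_excluded`).
#'
#' @param pairs Output of [pair_measurements()].
#' @return Input tibble with a `ratio_pct` column, restricted to valid pairs.
#' @export
percentage_ratios <- function(pairs) {
  ok <- pairs$reference_value > 0
  out <- dplyr::mutate(pairs[ok, ],
                       ratio_pct = 100 * .data$test_value / .data$reference_value)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

agreement_row <- function(method, n_pairs, n_subjects, mean_ratio, sd_total,
                          sigma_between = NA_real_, sigma_within = NA_real_,
                          flag = "") {
  tibble::tibble(
    method = method, n_pairs = n_pairs, n_subjects = n_subjects,
    mean_ratio_pct = mean_ratio, sd_total_pct = sd_total,
    sigma_between_pct = sigma_between, sigma_within_pct = sigma_within,
    loa_lower_pct = mean_ratio - 1.96 * sd_total,
    loa_upper_pct = mean_ratio + 1.96 * sd_total,
    flag = flag)
}

#' Conventional Bland-Altman limits of agreement on percentage ratios
#'
#' LoA = mean percentage ratio +/- 1.96 x sample standard deviation (n - 1
#' denominator).
#'
#' @param ratios Numeric vector of percentage ratios (n >= 2).
#' @param n_subjects Number of independent subjects contributing; defaults to
#'   `length(ratios)` (one observation per subject).
#' @return One-row tibble: method, n_pairs, n_subjects, mean_ratio_pct,
#'   sd_total_pct, sigma components (NA), loa_lower_pct, loa_upper_pct, flag.
#' @export
loa_conventional <- function(ratios, n_subjects = length(ratios)) {
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) < 2) stop("need at least 2 ratios")
  agreement_row("conventional", length(ratios), n_subjects,
                mean(ratios), stats::sd(ratios))
}

#' Repeated-measures Bland-Altman limits of agreement
#'
#' One-way ANOVA decomposition of percentage ratios with subjects as the
#' grouping factor, for designs with multiple measurements per individual.
#' With d_ij the ratio for subject i, observation j, k subjects, n_i
#' observations and N their total:
#' MS_between = sum(n_i (dbar_i - dbar)^2) / (k - 1),
#' MS_within = sum((d_ij - dbar_i)^2) / (N - k),
#' n0 = (N - sum(n_i^2) / N) / (k - 1),
#' sigma^2_within = MS_within,
#' sigma^2_between = max(0, (MS_between - MS_within) / n0),
#' sd_total = sqrt(sigma^2_between + sigma^2_within),
#' LoA = dbar +/- 1.96 sd_total, with dbar the mean pooled over all
#' observations. If every subject contributes a single observation the
#' conventional method is used and flagged.
#'
#' @param ratios Numeric vector of percentage ratios.
#' @param subjects Subject identifier per ratio.
#' @return One-row tibble as in [loa_conventional()], `method = "repeated"`.
#' @export
loa_repeated <- function(ratios, subjects) {
  keep <- !is.na(ratios)
  ratios <- ratios[keep]; subjects <- as.character(subjects)[keep]
  k <- length(unique(subjects))
  if (k < 2) stop("need >= 2 subjects")
  n_i <- table(subjects)
  if (all(n_i == 1)) {
    out <- loa_conventional(ratios, n_subjects = k)
    out$flag <- "singleton_fallback"
    return(out)
  }
  n_tot <- length(ratios)
  grand <- mean(ratios)
  means_i <- tapply(ratios, subjects, mean)
  ss_between <- sum(n_i * (means_i[names(n_i)] - grand)^2)
  ms_between <- ss_between / (k - 1)
  ss_within <- sum((ratios - means_i[subjects])^2)
  ms_within <- ss_within / (n_tot - k)
  n0 <- (n_tot - sum(n_i^2) / n_tot) / (k - 1)
  sigma2_within <- ms_within
  sigma2_between <- max(0, (ms_between - ms_within) / n0)
  agreement_row("repeated", n_tot, k, grand,
                sqrt(sigma2_between + sigma2_within),
                sigma_between = sqrt(sigma2_between),
                sigma_within = sqrt(sigma2_within))
}

#' Confidence intervals for the mean ratio and the limits of agreement
#'
#' 95% confidence intervals with m = number of independent subjects as the
#' effective sample size:
#' CI(mean) = mean +/- t(0.975, m-1) sd_total / sqrt(m);
#' CI(LoA limit) = limit +/- t(0.975, m-1) sd_total
#'   sqrt(1/m + 1.96^2 / (2 (m - 1))).
#'
#' @param result One-row tibble from [loa_conventional()] or [loa_repeated()].
#' @param conf_level Confidence level.
#' @return Input with columns ci_mean_lo/hi, ci_loa_lower_lo/hi,
#'   ci_loa_upper_lo/hi added (all `NA`, flagged, when m < 3).
#' @export
loa_confidence_intervals <- function(result, conf_level = 0.95) {
  m <- result$n_subjects
  if (m < 3) {
    result$ci_mean_lo <- result$ci_mean_hi <- NA_real_
    result$ci_loa_lower_lo <- result$ci_loa_lower_hi <- NA_real_
    result$ci_loa_upper_lo <- result$ci_loa_upper_hi <- NA_real_
    result$flag <- paste0(result$flag, ";ci_unavailable")
    return(result)
  }
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = m - 1)
  se_mean <- result$sd_total_pct / sqrt(m)
  se_loa <- result$sd_total_pct * sqrt(1 / m + 1.96^2 / (2 * (m - 1)))
  result$ci_mean_lo <- result$mean_ratio_pct - tq * se_mean
  result$ci_mean_hi <- result$mean_ratio_pct + tq * se_mean
  result$ci_loa_lower_lo <- result$loa_lower_pct - tq * se_loa
  result$ci_loa_lower_hi <- result$loa_lower_pct + tq * se_loa
  result$ci_loa_upper_lo <- result$loa_upper_pct - tq * se_loa
  result$ci_loa_upper_hi <- result$loa_upper_pct + tq * se_loa
  result
}

#' Concentration-level agreement table
#'
#' For each analyte and test matrix: number of pairs, pooled Pearson
#' correlation, and repeated-measures Bland-Altman mean ratio and LoA with
#' confidence intervals.
#'
#' @param concentrations Long concentration tibble.
#' @param test_matrices Matrices compared against the reference.
#' @param reference_matrix Reference matrix.
#' @return Tibble, one row per analyte x test matrix.
#' @export
agreement_concentrations <- function(concentrations,
                                     test_matrices = c("blood", "DBS"),
                                     reference_matrix = "plasma") {
  grid <- expand.grid(analyte = pzq_analytes(), matrix = test_matrices,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- dplyr::filter(concentrations, .data$analyte == grid$analyte[i])
    pairs <- pair_measurements(sub, grid$matrix[i], reference_matrix)
    ratios <- percentage_ratios(pairs)
    res <- loa_repeated(ratios$ratio_pct, ratios$subject_id)
    res <- loa_confidence_intervals(res)
    dplyr::bind_cols(tibble::tibble(analyte = grid$analyte[i],
                                    matrix = grid$matrix[i],
                                    pearson_r = pearson_pooled(pairs)),
                     res)
  })
  dplyr::bind_rows(rows)
}

#' PK-parameter percentage-ratio tables
#'
#' Per analyte and parameter, the per-subject percentage ratio of the test
#' matrix to the reference matrix, averaged across subjects. For the AUC the
#' conventional Bland-Altman LoA and their confidence intervals are added;
#' for t1/2, Cmax and Tmax the mean ratio is reported.
#'
#' @param pk Output of [nca_analyze()] covering both matrices.
#' @param test_matrix,reference_matrix Matrix labels.
#' @param parameters Parameters to ratio.
#' @return Tibble: analyte, parameter, n_subjects, mean_ratio_pct and (AUC
#'   rows) LoA and CI columns.
#' @export
parameter_ratio_table <- function(pk, test_matrix,
                                  reference_matrix = "plasma",
                                  parameters = c("auc_0_24", "t_half", "cmax",
                                                 "tmax")) {
  long <- tidyr::pivot_longer(
    dplyr::select(pk, "subject_id", "analyte", "matrix",
                  dplyr::all_of(parameters)),
    dplyr::all_of(parameters), names_to = "parameter", values_to = "value")
  rows <- list()
  for (a in unique(long$analyte)) {
    for (p in parameters) {
      sub <- dplyr::filter(long, .data$analyte == a, .data$parameter == p)
      pairs <- tryCatch(pair_measurements(sub, test_matrix, reference_matrix),
                        error = function(e) NULL)
      if (is.null(pairs)) next
      ratios <- percentage_ratios(pairs)
      if (nrow(ratios) == 0) next
      base <- tibble::tibble(analyte = a, parameter = p,
                             n_subjects = nrow(ratios),
                             mean_ratio_pct = mean(ratios$ratio_pct))
      if (p == "auc_0_24" && nrow(ratios) >= 2) {
        res <- loa_confidence_intervals(loa_conventional(ratios$ratio_pct))
        base <- dplyr::bind_cols(base,
                                 dplyr::select(res, -"method", -"n_pairs",
                                               -"n_subjects",
                                               -"mean_ratio_pct", -"flag"))
      }
      rows[[length(rows) + 1]] <- base
    }
  }
  dplyr::bind_rows(rows)
}

#' Bland-Altman plot data
#'
#' Per pair: the mean of the two measurements (x axis) and the percentage
#' ratio (y axis), with subject and analyte labels.
#'
#' @inheritParams pair_measurements
#' @return Tibble: subject_id, analyte, (time_h,) pair_mean, ratio_pct,
#'   matrix.
#' @export
bland_altman_points <- function(x, test_matrix, reference_matrix = "plasma") {
  pairs <- percentage_ratios(pair_measurements(x, test_matrix,
                                               reference_matrix))
  dplyr::mutate(pairs,
                pair_mean = (.data$test_value + .data$reference_value) / 2,
                matrix = test_matrix)
}
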