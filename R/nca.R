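# Non-compartmental analysis: linear trapezoidal AUC, Cmax/Tmax, terminal
# log-linear slope, per-cell analysis and cohort summaries.

# Resolve BLQ values within a profile:
#  * leading BLQ (predose / before the first quantifiable point) -> 0
#  * embedded BLQ (between quantifiable points) -> dropped, interval bridges
#  * trailing BLQ -> profile truncated at the last quantifiable point
prepare_profile <- function(time_h, conc_ug_ml, blq = NULL) {
  if (is.null(blq)) blq <- as.integer(is.na(conc_ug_ml))
  ord <- order(time_h)
  time_h <- time_h[ord]; conc_ug_ml <- conc_ug_ml[ord]; blq <- blq[ord]
  if (any(duplicated(time_h))) stop("duplicated sampling times in profile")
  quant <- blq == 0
  if (!any(quant)) {
    return(list(time = numeric(0), conc = numeric(0), n_quant = 0L))
  }
  first_q <- which(quant)[1]
  last_q <- max(which(quant))
  keep_zero <- which(!quant & seq_along(quant) < first_q)
  keep <- sort(c(keep_zero, which(quant & seq_along(quant) <= last_q)))
  conc <- conc_ug_ml
  conc[keep_zero] <- 0
  list(time = time_h[keep], conc = conc[keep], n_quant = sum(quant))
}

#' Area under the curve by the linear trapezoidal rule
#'
#' Integrates the piecewise-linear concentration-time profile from the first
#' observation to `min(t_last, t_end)`. Below-LLOQ values are set to zero
#' before the first quantifiable point, bridged over when embedded, and
#' truncate the profile when trailing. If the profile ends before `t_end` and
#' a terminal rate constant is supplied, the remaining area is added as
#' `(C_last / lambda_z) * (1 - exp(-lambda_z * (t_end - t_last)))` and the
#' extrapolated fraction recorded; without `lambda_z` the AUC is truncated and
#' flagged.
#'
#' @param time_h Sampling times, hours.
#' @param conc_ug_ml Concentrations, ug/ml (`NA` for BLQ).
#' @param blq Optional 0/1 below-LLOQ flags; defaults to `is.na(conc_ug_ml)`.
#' @param t_end Upper integration limit, hours.
#' @param lambda_z Optional terminal rate constant, 1/h.
#' @return List: `auc` (ug/ml*h), `extrapolated_fraction`, `flags`.
#' @export
auc_linear_trapezoid <- function(time_h, conc_ug_ml, blq = NULL, t_end = 24,
                                 lambda_z = NULL) {
  prof <- prepare_profile(time_h, conc_ug_ml, blq)
  if (prof$n_quant < 2) stop("insufficient profile: need >= 2 quantifiable points")
  tt <- prof$time; cc <- prof$conc
  if (t_end <= tt[1]) stop("t_end must exceed the first observation time")
  if (t_end < tt[length(tt)]) {
    cend <- stats::approx(tt, cc, xout = t_end)$y
    keep <- tt < t_end
    tt <- c(tt[keep], t_end); cc <- c(cc[keep], cend)
  }
  auc_obs <- sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
  flags <- character(0)
  auc_extra <- 0
  t_last <- tt[length(tt)]
  if (t_last < t_end) {
    if (!is.null(lambda_z) && is.finite(lambda_z) && lambda_z > 0) {
      auc_extra <- (cc[length(cc)] / lambda_z) *
        (1 - exp(-lambda_z * (t_end - t_last)))
      flags <- c(flags, "extrapolated")
    } else {
      flags <- c(flags, "truncated")
    }
  }
  auc <- auc_obs + auc_extra
  list(auc = auc,
       extrapolated_fraction = if (auc > 0) auc_extra / auc else 0,
       flags = flags)
}

#' Maximal concentration and its time
#'
#' @inheritParams auc_linear_trapezoid
#' @return List: `cmax` (ug/ml), `tmax` (h). Ties in concentration are broken
#'   by the earliest time.
#' @export
cmax_tmax <- function(time_h, conc_ug_ml, blq = NULL) {
  if (is.null(blq)) blq <- as.integer(is.na(conc_ug_ml))
  quant <- blq == 0
  if (!any(quant)) stop("no quantifiable points")
  tt <- time_h[quant]; cc <- conc_ug_ml[quant]
  ord <- order(tt)
  tt <- tt[ord]; cc <- cc[ord]
  i <- which.max(cc)  # first maximum = earliest time on ties
  list(cmax = cc[i], tmax = tt[i])
}

#' Terminal elimination rate constant and half-life
#'
#' Fits ordinary least squares of log concentration on time over candidate
#' terminal windows: the last m quantifiable points strictly after Tmax, for
#' m = 3 up to all available, choosing the window with maximal adjusted R^2
#' among fits with a positive rate. Returns missing (not an error) when fewer
#' than three eligible points exist or no candidate yields a positive rate.
#'
#' @inheritParams auc_linear_trapezoid
#' @param allow_sparse If `TRUE`, when the standard rule fails but exactly
#'   two quantifiable points follow Tmax (short DBS schedules), estimate the
#'   slope from those two points. Off by default.
#' @return List: `lambda_z` (1/h), `t_half` (h), `n_points`, `r2` (adjusted),
#'   `times_used`; all `NA` (with `n_points = 0`) when not estimable.
#' @export
terminal_lambda_z <- function(time_h, conc_ug_ml, blq = NULL,
                              allow_sparse = FALSE) {
  if (is.null(blq)) blq <- as.integer(is.na(conc_ug_ml))
  quant <- blq == 0 & conc_ug_ml > 0 & !is.na(conc_ug_ml)
  none <- list(lambda_z = NA_real_, t_half = NA_real_, n_points = 0L,
               r2 = NA_real_, times_used = numeric(0))
  if (!any(quant)) return(none)
  tt <- time_h[quant]; cc <- conc_ug_ml[quant]
  ord <- order(tt); tt <- tt[ord]; cc <- cc[ord]
  peak <- cmax_tmax(tt, cc)
  after <- tt > peak$tmax
  tt <- tt[after]; cc <- cc[after]
  n <- length(tt)
  if (n < 3) {
    if (allow_sparse && n == 2 && tt[2] > tt[1]) {
      slope <- (log(cc[2]) - log(cc[1])) / (tt[2] - tt[1])
      if (is.finite(slope) && slope < 0) {
        return(list(lambda_z = -slope, t_half = log(2) / (-slope),
                    n_points = 2L, r2 = NA_real_, times_used = tt))
      }
    }
    return(none)
  }
  best <- NULL
  for (m in 3:n) {
    idx <- (n - m + 1):n
    x <- tt[idx]; y <- log(cc[idx])
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope >= 0) next
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    adj <- 1 - (1 - r2) * (m - 1) / (m - 2)
    if (is.null(best) || adj > best$adj) {
      best <- list(adj = adj, lambda = -slope, m = m, times = x)
    }
  }
  if (is.null(best)) return(none)
  list(lambda_z = unname(best$lambda), t_half = unname(log(2) / best$lambda),
       n_points = best$m, r2 = best$adj, times_used = best$times)
}

#' Non-compartmental analysis of a long concentration table
#'
#' Computes AUC(0-`t_end`), Cmax, Tmax, lambda_z and t1/2 for every
#' subject x analyte x matrix cell. Cells with fewer than two quantifiable
#' points are skipped (absent from the output). Profiles ending before
#' `t_end` (e.g. six-point DBS schedules ending at 12 h) are extrapolated
#' with lambda_z when estimable, and flagged. On short DBS schedules the
#' terminal fit falls back to the two points after Tmax when three are not
#' available (flag `lambda_z_sparse`); when even that fails the AUC is
#' truncated at the last quantifiable point (flags `truncated`,
#' `lambda_z_missing`).
#'
#' @param concentrations Tibble with columns subject_id, analyte, matrix,
#'   time_h, conc_ug_ml, blq.
#' @param t_end AUC horizon, hours.
#' @return Tibble, one row per cell: subject_id, analyte, matrix, auc_0_24,
#'   auc_extrapolated_fraction, cmax, tmax, lambda_z, t_half,
#'   n_terminal_points, terminal_r2, flags (semicolon-separated).
#' @export
nca_analyze <- function(concentrations, t_end = 24) {
  cells <- dplyr::group_split(dplyr::group_by(concentrations, .data$subject_id,
                                              .data$analyte, .data$matrix))
  rows <- lapply(cells, function(cell) {
    quantn <- sum(cell$blq == 0)
    if (quantn < 2) return(NULL)
    lz <- terminal_lambda_z(cell$time_h, cell$conc_ug_ml, cell$blq,
                            allow_sparse = TRUE)
    aa <- auc_linear_trapezoid(cell$time_h, cell$conc_ug_ml, cell$blq,
                               t_end = t_end, lambda_z = lz$lambda_z)
    pk <- cmax_tmax(cell$time_h, cell$conc_ug_ml, cell$blq)
    flags <- aa$flags
    if (lz$n_points == 0) flags <- c(flags, "lambda_z_missing")
    if (lz$n_points == 2L) flags <- c(flags, "lambda_z_sparse")
    tibble::tibble(
      subject_id = cell$subject_id[1], analyte = cell$analyte[1],
      matrix = cell$matrix[1],
      auc_0_24 = aa$auc, auc_extrapolated_fraction = aa$extrapolated_fraction,
      cmax = pk$cmax, tmax = pk$tmax,
      lambda_z = lz$lambda_z, t_half = lz$t_half,
      n_terminal_points = lz$n_points, terminal_r2 = lz$r2,
      flags = paste(flags, collapse = ";"))
  })
  dplyr::bind_rows(rows)
}

#' Cohort summary of NCA parameters
#'
#' Median and (min, max) of each PK parameter per analyte x matrix. For even
#' n the median is the mean of the two central order statistics.
#'
#' @param pk Output of [nca_analyze()].
#' @param parameters Parameter columns to summarise.
#' @return Long tibble: analyte, matrix, parameter, median, min, max, n.
#' @export
pk_summarize <- function(pk, parameters = c("auc_0_24", "t_half", "cmax",
                                            "tmax")) {
  long <- tidyr::pivot_longer(
    dplyr::select(pk, "analyte", "matrix", dplyr::all_of(parameters)),
    dplyr::all_of(parameters), names_to = "parameter", values_to = "value")
  long <- dplyr::filter(long, !is.na(.data$value))
  dplyr::summarise(
    dplyr::group_by(long, .data$analyte, .data$matrix, .data$parameter),
    median = stats::median(.data$value), min = min(.data$value),
    max = max(.data$value), n = dplyr::n(), .groups = "drop")
}
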