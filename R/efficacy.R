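# Parasitological efficacy: eggs per gram from quadruplicate Kato-Katz
# smears, geometric means, cure rate and egg-reduction rate.

#' Eggs per gram of stool from quadruplicate Kato-Katz smears
#'
#' EPG = 6 x the sum of the four smear counts (41.7 mg template).
#'
#' @param counts Numeric vector of exactly four nonnegative integer smear
#'   counts.
#' @return Eggs per gram.
#' @export
epg <- function(counts) {
  if (length(counts) != 4) stop("exactly four smear counts required")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("smear counts must be nonnegative integers")
  }
  6 * sum(counts)
}

# Add an epg column to a long egg-count table (subject_id, visit, c1..c4).
epg_table <- function(eggs) {
  dplyr::mutate(dplyr::rowwise(eggs),
                epg = epg(c(.data$c1, .data$c2, .data$c3, .data$c4))) |>
    dplyr::ungroup()
}

#' Geometric mean of egg counts
#'
#' `exp(mean(log(x)))` when all values are positive. When zeros are present
#' the shifted form `exp(mean(log(x + 1))) - 1` is used and the result
#' carries attribute `shifted = TRUE`; an all-zero input returns 0.
#'
#' @param values Nonnegative EPG values (n >= 1).
#' @return Geometric mean EPG.
#' @export
geometric_mean_epg <- function(values) {
  stopifnot(length(values) >= 1, all(values >= 0))
  if (all(values == 0)) return(structure(0, shifted = FALSE))
  if (any(values == 0)) {
    structure(exp(mean(log(values + 1))) - 1, shifted = TRUE)
  } else {
    structure(exp(mean(log(values))), shifted = FALSE)
  }
}

#' Cure rate
#'
#' Percentage of assessed subjects that are egg-negative (post-treatment EPG
#' of zero) at follow-up. Subjects without a post-treatment record are
#' excluded; the count is attached as attribute `n_excluded`.
#'
#' @param eggs Egg-count tibble: subject_id, visit ("pre"/"post"), c1..c4.
#' @return Cure rate in percent.
#' @export
cure_rate <- function(eggs) {
  tab <- epg_table(eggs)
  post <- dplyr::filter(tab, .data$visit == "post")
  pre_ids <- unique(dplyr::filter(tab, .data$visit == "pre")$subject_id)
  missing_post <- setdiff(pre_ids, post$subject_id)
  if (nrow(post) == 0) stop("no post-treatment records")
  structure(100 * mean(post$epg == 0), n_excluded = length(missing_post))
}

#' Egg-reduction rate
#'
#' `100 * (1 - gm_post / gm_pre)` on the group geometric means.
#'
#' @param gm_pre,gm_post Pre- and post-treatment geometric mean EPG;
#'   `gm_pre` must be positive.
#' @return Egg-reduction rate in percent.
#' @export
egg_reduction_rate <- function(gm_pre, gm_post) {
  if (gm_pre <= 0) stop("undefined egg-reduction rate: gm_pre must be > 0")
  100 * (1 - gm_post / gm_pre)
}

#' Infection-intensity class
#'
#' Light < 1,000 EPG, moderate 1,000-10,000 EPG, heavy > 10,000 EPG.
#'
#' @param epg_values Numeric EPG values.
#' @return Character vector of classes.
#' @export
intensity_class <- function(epg_values) {
  ifelse(epg_values > 10000, "heavy",
         ifelse(epg_values >= 1000, "moderate", "light"))
}

#' Efficacy summary
#'
#' Geometric mean EPG before and after treatment, cure rate and egg-reduction
#' rate for a cohort.
#'
#' @param eggs Egg-count tibble: subject_id, visit ("pre"/"post"), c1..c4.
#' @return One-row tibble: n_subjects, gm_pre_epg, gm_post_epg,
#'   cure_rate_pct, err_pct.
#' @export
efficacy_summary <- function(eggs) {
  tab <- epg_table(eggs)
  pre <- dplyr::filter(tab, .data$visit == "pre")
  post <- dplyr::filter(tab, .data$visit == "post")
  gm_pre <- as.numeric(geometric_mean_epg(pre$epg))
  gm_post <- as.numeric(geometric_mean_epg(post$epg))
  tibble::tibble(
    n_subjects = length(unique(pre$subject_id)),
    gm_pre_epg = gm_pre, gm_post_epg = gm_post,
    cure_rate_pct = as.numeric(cure_rate(eggs)),
    err_pct = egg_reduction_rate(gm_pre, gm_post))
}
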