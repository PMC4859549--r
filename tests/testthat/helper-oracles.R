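# Independent oracles and fixture builders shared across the suite.

# Trapezoidal integration of the piecewise-linear interpolant on a fine grid
# refined with the original knots (exact on each linear piece).
fine_grid_auc <- function(time, conc, n = 1e5) {
  grid <- sort(unique(c(seq(min(time), max(time), length.out = n), time)))
  vals <- stats::approx(time, conc, xout = grid)$y
  sum(diff(grid) * (head(vals, -1) + tail(vals, -1)) / 2)
}

# Repeated-measures variance components via stats::aov mean squares.
loa_repeated_oracle <- function(ratios, subjects) {
  fit <- stats::aov(ratios ~ factor(subjects))
  ms <- summary(fit)[[1]][["Mean Sq"]]
  k <- length(unique(subjects))
  n_tot <- length(ratios)
  n_i <- table(subjects)
  n0 <- (n_tot - sum(n_i^2) / n_tot) / (k - 1)
  s2w <- ms[2]
  s2b <- max(0, (ms[1] - ms[2]) / n0)
  sd_total <- sqrt(s2b + s2w)
  mean_r <- mean(ratios)
  list(mean = mean_r, sd_total = sd_total,
       loa = c(mean_r - 1.96 * sd_total, mean_r + 1.96 * sd_total))
}

# Hand-built subject profile with identical kinetics for all analytes.
make_profile <- function(ka = 1.5, ke = 0.3, v = 1, scale = 1, r = 0.8,
                         dose_times = c(0, 4, 8),
                         doses_taken = rep(TRUE, length(dose_times)),
                         dose = 25) {
  params <- stats::setNames(lapply(pzq_analytes(), function(a) {
    list(ka = ka, ke = ke, v_over_f = v, exposure_scale = scale,
         r_blood_plasma = r)
  }), pzq_analytes())
  list(subject_id = "T01", weight_kg = 56, hematocrit = 0.35,
       params = params, doses_taken = doses_taken, exposure_outlier = FALSE,
       regimen = dosing_regimen(dose, dose_times))
}

# Noise- and outlier-free configuration (optionally with unit partition).
noiseless_config <- function(r_one = FALSE, lloq = NULL) {
  cfg <- simulation_config(assay_cv = 0, dbs_extra_cv = 0,
                           outlier_fraction = 0)
  for (a in pzq_analytes()) {
    cfg$analyte_models[[a]]$bsv_cv <- 0
    if (r_one) cfg$analyte_models[[a]]$r_blood_plasma <- 1
  }
  if (!is.null(lloq)) {
    cfg$lloq_ug_ml[] <- lloq
  }
  cfg
}

table2_ranges <- function() {
  list(
    "R-PZQ" = list(auc_0_24 = c(0.8, 10.7), t_half = c(1.0, 3.0),
                   cmax = c(0.1, 1.1), tmax = c(4.0, 11.8)),
    "S-PZQ" = list(auc_0_24 = c(6.1, 26.3), t_half = c(1.9, 3.7),
                   cmax = c(0.6, 2.3), tmax = c(4.0, 11.8)),
    "R-trans-4-OH" = list(auc_0_24 = c(157.2, 257.4), t_half = c(4.1, 7.1),
                          cmax = c(13.1, 17.9), tmax = c(8.0, 12.0)))
}
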