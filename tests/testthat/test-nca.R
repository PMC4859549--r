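test_that("linear trapezoid matches closed forms and a fine-grid oracle", {
  tri <- auc_linear_trapezoid(c(0, 1, 2), c(0, 2, 0), t_end = 2)
  expect_equal(tri$auc, 2.0)
  expect_equal(tri$extrapolated_fraction, 0)

  const <- auc_linear_trapezoid(c(0, 6, 12, 24), rep(3.5, 4), t_end = 24)
  expect_equal(const$auc, 24 * 3.5)

  set.seed(42)
  for (i in 1:5) {
    tt <- sort(runif(50, 0, 24))
    cc <- runif(50, 0, 5)
    got <- auc_linear_trapezoid(tt, cc, t_end = max(tt))$auc
    expect_equal(got, fine_grid_auc(tt, cc), tolerance = 1e-9)
  }

  expect_error(auc_linear_trapezoid(c(0, 1), c(NA, 2),
                                    blq = c(1L, 0L), t_end = 1),
               "insufficient")
})

test_that("AUC is additive over subintervals and equivariant under scaling", {
  set.seed(9)
  tt <- sort(runif(20, 0, 24)); tt[1] <- 0; tt[20] <- 24
  cc <- runif(20, 0.5, 5)
  whole <- auc_linear_trapezoid(tt, cc, t_end = 24)$auc
  for (cut in tt[c(5, 11, 16)]) {
    left <- auc_linear_trapezoid(tt[tt <= cut], cc[tt <= cut], t_end = cut)$auc
    right <- auc_linear_trapezoid(tt[tt >= cut] - cut, cc[tt >= cut],
                                  t_end = 24 - cut)$auc
    expect_equal(left + right, whole, tolerance = 1e-12)
  }
  scaled <- auc_linear_trapezoid(tt, 3.7 * cc, t_end = 24)$auc
  expect_equal(scaled, 3.7 * whole, tolerance = 1e-12)
})

test_that("Cmax/Tmax pick the maximum with earliest-time tie-break", {
  got <- cmax_tmax(c(0, 7, 24), c(0, 1.1, 0.1))
  expect_equal(got$cmax, 1.1)
  expect_equal(got$tmax, 7)
  tie <- cmax_tmax(c(4, 8), c(2, 2))
  expect_equal(tie$tmax, 4)
  expect_error(cmax_tmax(c(0, 1), c(NA, NA), blq = c(1L, 1L)),
               "no quantifiable")

  # scaling leaves Tmax untouched, scales Cmax
  sc <- cmax_tmax(c(0, 7, 24), 5 * c(0, 1.1, 0.1))
  expect_equal(sc$cmax, 5.5)
  expect_equal(sc$tmax, 7)
})

test_that("terminal slope recovers exact exponentials and flags flat profiles", {
  tt <- c(0, 2, 10, 11, 12, 24)
  cc <- c(0.0, 5, exp(-0.2 * c(10, 11, 12, 24)))
  got <- terminal_lambda_z(tt, cc)
  expect_equal(got$lambda_z, 0.2, tolerance = 1e-10)
  expect_equal(got$t_half, log(2) / 0.2, tolerance = 1e-6)
  expect_equal(got$r2, 1, tolerance = 1e-9)

  flat <- terminal_lambda_z(c(0, 2, 10, 11, 12), c(0, 5, 1, 1, 1))
  expect_equal(flat$n_points, 0L)
  expect_true(is.na(flat$lambda_z))

  few <- terminal_lambda_z(c(0, 7, 10, 11), c(0, 5, 2, 1))
  expect_equal(few$n_points, 0L)  # only two points after Tmax

  # sparse fallback: exact two-point slope, halving over one hour
  sparse <- terminal_lambda_z(c(0, 7, 10, 11), c(0, 5, 2, 1),
                              allow_sparse = TRUE)
  expect_equal(sparse$n_points, 2L)
  expect_equal(sparse$lambda_z, log(2), tolerance = 1e-12)
  expect_equal(sparse$t_half, 1, tolerance = 1e-12)

  # ... but a rising pair stays missing even with the fallback
  rising <- terminal_lambda_z(c(0, 7, 10, 11), c(0, 5, 1, 2),
                              allow_sparse = TRUE)
  expect_equal(rising$n_points, 0L)
})

test_that("per-cell NCA respects matrix scaling and flags short DBS profiles", {
  cfg <- noiseless_config()
  coh <- generate_cohort(cfg, seed = 2)
  pk <- nca_analyze(coh$concentrations)

  # blood = r x plasma noiselessly: AUC ratio r, Tmax and t1/2 unchanged
  wide <- tidyr::pivot_wider(
    dplyr::select(pk, subject_id, analyte, matrix, auc_0_24, tmax, t_half),
    names_from = matrix, values_from = c(auc_0_24, tmax, t_half))
  r_truth <- vapply(cfg$analyte_models[wide$analyte],
                    function(m) m$r_blood_plasma, numeric(1))
  expect_equal(wide$auc_0_24_blood / wide$auc_0_24_plasma, unname(r_truth),
               tolerance = 1e-9)
  expect_equal(wide$tmax_blood, wide$tmax_plasma)
  expect_equal(wide$t_half_blood, wide$t_half_plasma, tolerance = 1e-9)

  # schedule B subjects stop at 12 h. R-PZQ peaks at 8.5 h on that grid,
  # leaving two terminal points (10, 12): the sparse two-point slope supports
  # extrapolation to 24 h, and the result is flagged.
  dbs_b <- dplyr::filter(pk, matrix == "DBS", subject_id == "S06",
                         analyte == "R-PZQ")
  expect_gt(dbs_b$auc_extrapolated_fraction, 0)
  expect_match(dbs_b$flags, "extrapolated")
  expect_match(dbs_b$flags, "lambda_z_sparse")
  expect_equal(dbs_b$lambda_z, log(2) / 1.1, tolerance = 0.15)

  # S-PZQ peaks at 10 h on the same grid, leaving a single terminal point:
  # no slope is estimable, so the AUC is truncated at 12 h and flagged.
  dbs_b_s <- dplyr::filter(pk, matrix == "DBS", subject_id == "S06",
                           analyte == "S-PZQ")
  expect_equal(dbs_b_s$auc_extrapolated_fraction, 0)
  expect_match(dbs_b_s$flags, "truncated")
  expect_match(dbs_b_s$flags, "lambda_z_missing")

  # a cell with < 2 quantifiable points is absent from the output
  crippled <- coh$concentrations
  idx <- crippled$subject_id == "S01" & crippled$analyte == "R-PZQ" &
    crippled$matrix == "DBS" & crippled$time_h > 0
  crippled$blq[idx] <- 1L
  crippled$conc_ug_ml[idx] <- NA_real_
  pk2 <- nca_analyze(crippled)
  expect_equal(nrow(dplyr::filter(pk2, subject_id == "S01",
                                  analyte == "R-PZQ", matrix == "DBS")), 0)
})

test_that("noiseless simulated half-lives recover the configured values", {
  cfg <- noiseless_config()
  coh <- generate_cohort(cfg, seed = 6)
  pk <- dplyr::filter(nca_analyze(coh$concentrations), matrix == "plasma",
                      analyte == "S-PZQ")
  expect_true(all(abs(pk$t_half - 3.3) / 3.3 < 0.15))
})

test_that("BLQ values are zeroed, bridged or truncated by position", {
  # leading BLQ -> 0; embedded BLQ bridged; trailing BLQ truncates
  tt <- c(0, 1, 2, 3, 4)
  cc <- c(NA, 2, NA, 2, NA)
  blq <- c(1L, 0L, 1L, 0L, 1L)
  got <- auc_linear_trapezoid(tt, cc, blq, t_end = 4, lambda_z = NULL)
  # 0->1: triangle (0+2)/2; 1->3 bridges the BLQ at 2: 2*2; truncated at 3
  expect_equal(got$auc, 1 + 4)
  expect_match(got$flags, "truncated", all = FALSE)
})

test_that("cohort summaries give median and range per cell", {
  pk <- tibble::tibble(subject_id = sprintf("S%02d", 1:3),
                       analyte = "R-PZQ", matrix = "plasma",
                       auc_0_24 = c(1, 2, 3), t_half = c(1, 1, 4),
                       cmax = c(0.2, 0.1, 0.3), tmax = c(7, 7, 9))
  sm <- pk_summarize(pk)
  auc <- dplyr::filter(sm, parameter == "auc_0_24")
  expect_equal(auc$median, 2)
  expect_equal(c(auc$min, auc$max), c(1, 3))
  expect_equal(auc$n, 3L)
  one <- pk_summarize(pk[1, ])
  expect_true(all(one$median == one$min & one$median == one$max))
})
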