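test_that("superposition kinetics: zero at t=0, bolus limit, dose additivity", {
  prof <- make_profile(ka = 1.5, ke = 0.3)
  expect_identical(plasma_concentration(prof, "R-PZQ", 0), 0)
  expect_error(plasma_concentration(prof, "R-PZQ", -1), "negative")

  # ka -> infinity collapses to an oral bolus: C(t) = (D/V) exp(-ke t)
  bolus <- make_profile(ka = 1e6, ke = 0.2, dose_times = 0,
                        doses_taken = TRUE)
  t_half <- log(2) / 0.2
  expect_equal(plasma_concentration(bolus, "S-PZQ", t_half), 0.5 * 25,
               tolerance = 1e-3)

  # three doses equal the sum of three shifted single-dose curves
  multi <- make_profile(ka = 1.2, ke = 0.35, dose_times = c(0, 4, 8))
  single <- make_profile(ka = 1.2, ke = 0.35, dose_times = 0,
                         doses_taken = TRUE)
  for (t in c(0.5, 3, 4.5, 9, 12, 24)) {
    parts <- sum(vapply(c(0, 4, 8), function(tau) {
      if (t >= tau) plasma_concentration(single, "R-PZQ", t - tau) else 0
    }, numeric(1)))
    expect_equal(plasma_concentration(multi, "R-PZQ", t), parts,
                 tolerance = 1e-12)
  }

  # untaken doses contribute nothing
  two <- make_profile(ka = 1.2, ke = 0.35, dose_times = c(0, 4, 8),
                      doses_taken = c(TRUE, TRUE, FALSE))
  expect_lt(plasma_concentration(two, "R-PZQ", 12),
            plasma_concentration(multi, "R-PZQ", 12))
})

test_that("matrix measurement scales by the partition ratio and adds noise", {
  prof <- make_profile(r = 0.8)
  expect_equal(matrix_concentration(1.0, "R-PZQ", "blood", prof), 0.8)
  expect_equal(matrix_concentration(1.7, "R-PZQ", "plasma", prof), 1.7)
  expect_equal(matrix_concentration(1.0, "R-PZQ", "DBS", prof), 0.8)
  expect_error(matrix_concentration(1, "R-PZQ", "serum", prof), "unknown")
  expect_error(matrix_concentration(-1, "R-PZQ", "blood", prof))

  set.seed(7)
  draws <- matrix_concentration(rep(1, 1e4), "R-PZQ", "blood", prof,
                                assay_cv = 0.1)
  expect_true(abs(mean(draws) - 0.8) < 0.01)
})

test_that("default schedules reproduce the venous and interleaved DBS design", {
  sch <- default_schedules(9)
  expect_length(sch$plasma[[1]], 11)
  expect_identical(sch$plasma, sch$blood)
  expect_true(all(vapply(sch$DBS, length, integer(1)) == 6))
  # schedule A for positions 1-5, B for 6-9
  expect_identical(sch$DBS[[1]], c(0, 4, 8, 9, 11, 24))
  expect_identical(sch$DBS[[6]], c(0, 2, 6, 8.5, 10, 12))
  expect_identical(default_schedules(1)$DBS[[1]], c(0, 4, 8, 9, 11, 24))
  # the 5 + 4 pattern cycles
  expect_identical(default_schedules(10)$DBS[[10]], c(0, 4, 8, 9, 11, 24))
})

test_that("generate_cohort has the design row counts and is deterministic", {
  cfg <- simulation_config()
  coh <- generate_cohort(cfg, seed = 11)
  counts <- table(coh$concentrations$analyte, coh$concentrations$matrix)
  expect_true(all(counts[, "plasma"] == 99))
  expect_true(all(counts[, "blood"] == 99))
  expect_true(all(counts[, "DBS"] == 54))

  again <- generate_cohort(cfg, seed = 11)
  expect_identical(coh$concentrations, again$concentrations)
  expect_identical(coh$truth, again$truth)

  # per-subject substreams: growing the cohort keeps earlier subjects intact
  big <- generate_cohort(simulation_config(n_subjects = 12), seed = 11)
  expect_identical(
    dplyr::filter(big$concentrations, subject_id %in% sprintf("S%02d", 1:9)),
    coh$concentrations)
})

test_that("noiseless cohort equals the kinetic model and censoring is exact", {
  cfg <- noiseless_config(lloq = 1e-12)
  coh <- generate_cohort(cfg, seed = 3)
  plasma <- dplyr::filter(coh$concentrations, matrix == "plasma",
                          analyte == "S-PZQ", subject_id == "S01")
  model <- plasma_concentration(coh$profiles[[1]], "S-PZQ", plasma$time_h)
  expect_equal(ifelse(plasma$blq == 1, 0, plasma$conc_ug_ml), model,
               tolerance = 1e-12)

  # default LLOQs: no stored value in (0, LLOQ); BLQ rows carry no value
  noisy <- generate_cohort(simulation_config(), seed = 3)$concentrations
  lloq <- c("R-PZQ" = 0.01, "S-PZQ" = 0.01, "R-trans-4-OH" = 0.1)
  quant <- dplyr::filter(noisy, blq == 0)
  expect_true(all(quant$conc_ug_ml >= lloq[quant$analyte]))
  expect_true(all(is.na(dplyr::filter(noisy, blq == 1)$conc_ug_ml)))
})

test_that("with unit partition and no noise all matrices agree at shared times", {
  cfg <- noiseless_config(r_one = TRUE)
  conc <- generate_cohort(cfg, seed = 5)$concentrations
  wide <- tidyr::pivot_wider(conc, id_cols = c(subject_id, analyte, time_h),
                             names_from = matrix,
                             values_from = conc_ug_ml)
  expect_equal(wide$plasma, wide$blood, tolerance = 1e-12)
  shared <- dplyr::filter(wide, !is.na(DBS))
  expect_equal(shared$plasma, shared$DBS, tolerance = 1e-12)
})

test_that("ISR pair generation preserves pairing and the sampled fraction", {
  conc <- generate_cohort(simulation_config(), seed = 21)$concentrations
  exact <- generate_isr_pairs(conc, fraction = 1, repeat_cv = 0, seed = 1)
  expect_equal(nrow(exact), sum(conc$blq == 0))
  expect_equal(exact$repeat_conc, exact$original)

  n_quant <- sum(conc$blq == 0)
  sub <- generate_isr_pairs(conc, fraction = 0.56, seed = 2)
  expect_lte(abs(nrow(sub) - 0.56 * n_quant), 2)
  expect_false(any(duplicated(sub$sample_id)))
  expect_error(generate_isr_pairs(conc[0, ]), "no quantifiable")
})

test_that("partition experiment: noiseless exactness, default levels, consistency", {
  noiseless <- generate_partition_experiment(c(0.05, 0.5), r_true = 0.8,
                                             n_replicates = 3, cv = 0)
  r <- partition_ratio(noiseless)
  expect_equal(r$mean_ratio_pct, c(80, 80), tolerance = 1e-12)
  expect_equal(r$sd_pct, c(0, 0), tolerance = 1e-12)

  dft <- default_partition_experiment(seed = 9)
  expect_setequal(unique(dft$level[dft$analyte == "R-PZQ"]), c(0.05, 0.5))
  expect_setequal(unique(dft$level[dft$analyte == "R-trans-4-OH"]),
                  c(0.5, 5))

  # estimator consistency: mean ratio within 3 SE of truth at n = 1000
  big <- generate_partition_experiment(0.5, r_true = 0.8,
                                       n_replicates = 1000, cv = 0.05,
                                       seed = 4)
  est <- partition_ratio(big)
  se <- est$sd_pct / sqrt(est$n_replicates)
  expect_lt(abs(est$mean_ratio_pct - 80), 3 * se)
})

test_that("egg-count generator matches the cure and intensity structure", {
  eggs <- generate_egg_counts(9, cure_probability = 1, seed = 8)
  post <- dplyr::filter(eggs, visit == "post")
  expect_true(all(post$c1 == 0 & post$c2 == 0 & post$c3 == 0 & post$c4 == 0))
  expect_equal(nrow(eggs), 18)

  # cure_probability 0 with reduction factor 1: pre and post agree in mean
  many <- generate_egg_counts(400, pre_mean_epg = 2400, cure_probability = 0,
                              reduction_factor = 1, seed = 12)
  sums <- 6 * rowSums(many[, c("c1", "c2", "c3", "c4")])
  pre_mean <- mean(sums[many$visit == "pre"])
  post_mean <- mean(sums[many$visit == "post"])
  expect_lt(abs(pre_mean - 2400) / 2400, 0.10)
  expect_lt(abs(post_mean - pre_mean) / pre_mean, 0.15)
})
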