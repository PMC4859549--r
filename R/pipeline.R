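# End-to-end orchestration: simulate -> qc -> nca -> agreement -> efficacy,
# with CSV interfaces, input validation and a JSON run manifest.

#' Read and write the long-format concentration CSV
#'
#' Columns: subject_id, analyte, matrix, time_h, conc_ug_ml, blq. The
#' concentration of a BLQ row is written as an empty field.
#'
#' @param path File path.
#' @return A tibble ([read_concentrations()]) or the input, invisibly.
#' @export
read_concentrations <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(), analyte = readr::col_character(),
    matrix = readr::col_character(), time_h = readr::col_double(),
    conc_ug_ml = readr::col_double(), blq = readr::col_integer()))
}

#' @rdname read_concentrations
#' @param x Concentration tibble.
#' @export
write_concentrations <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(x)
}

#' Validate a concentration table
#'
#' Checks the schema, duplicate (subject, analyte, matrix, time) keys,
#' negative times and concentrations, and unknown analyte or matrix labels.
#'
#' @param concentrations Tibble to validate.
#' @return Tibble of issues (type, message, n); zero rows when clean.
#' @export
validate_inputs <- function(concentrations) {
  issues <- list()
  note <- function(type, message, n) {
    issues[[length(issues) + 1]] <<- tibble::tibble(type = type,
                                                    message = message, n = n)
  }
  required <- c("subject_id", "analyte", "matrix", "time_h", "conc_ug_ml",
                "blq")
  missing_cols <- setdiff(required, names(concentrations))
  if (length(missing_cols) > 0) {
    note("schema", paste("missing columns:",
                         paste(missing_cols, collapse = ", ")),
         length(missing_cols))
    return(dplyr::bind_rows(issues))
  }
  key <- paste(concentrations$subject_id, concentrations$analyte,
               concentrations$matrix, concentrations$time_h)
  ndup <- sum(duplicated(key))
  if (ndup > 0) note("duplicate key",
                     "duplicated (subject, analyte, matrix, time) rows", ndup)
  nneg_t <- sum(concentrations$time_h < 0, na.rm = TRUE)
  if (nneg_t > 0) note("domain", "negative sampling times", nneg_t)
  nneg_c <- sum(concentrations$conc_ug_ml < 0, na.rm = TRUE)
  if (nneg_c > 0) note("domain", "negative concentrations", nneg_c)
  bad_a <- sum(!concentrations$analyte %in% pzq_analytes())
  if (bad_a > 0) note("domain", "unknown analyte labels", bad_a)
  bad_m <- sum(!concentrations$matrix %in% pzq_matrices())
  if (bad_m > 0) note("domain", "unknown matrix labels", bad_m)
  bad_blq <- sum(concentrations$blq == 1 & !is.na(concentrations$conc_ug_ml))
  if (bad_blq > 0) note("domain", "BLQ rows carrying a concentration",
                        bad_blq)
  if (length(issues) == 0) {
    return(tibble::tibble(type = character(0), message = character(0),
                          n = integer(0)))
  }
  dplyr::bind_rows(issues)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file mirrors the [simulation_config()] fields; omitted fields keep
#' their defaults. `analyte_models` entries are named by analyte and may
#' override any [analyte_model()] field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `simulation_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  regimen <- if (!is.null(raw$regimen)) {
    do.call(dosing_regimen, raw$regimen)
  } else {
    dosing_regimen()
  }
  models <- default_analyte_models(regimen)
  if (!is.null(raw$analyte_models)) {
    for (a in names(raw$analyte_models)) {
      fields <- raw$analyte_models[[a]]
      base <- models[[a]]
      for (f in names(fields)) base[[f]] <- fields[[f]]
      models[[a]] <- do.call(analyte_model, base[names(base) != "analyte"] |>
                               c(list(analyte = a)))
    }
  }
  args <- raw[setdiff(names(raw), c("regimen", "analyte_models"))]
  args$regimen <- regimen
  args$analyte_models <- models
  if (!is.null(args$lloq_ug_ml)) args$lloq_ug_ml <- unlist(args$lloq_ug_ml)
  if (!is.null(args$uloq_ug_ml)) args$uloq_ug_ml <- unlist(args$uloq_ug_ml)
  if (!is.null(args$outlier_fold_range)) {
    args$outlier_fold_range <- as.numeric(unlist(args$outlier_fold_range))
  }
  do.call(simulation_config, args)
}

#' Run the full pipeline
#'
#' Simulates a cohort (or consumes provided CSVs), censors to the assay
#' range, runs NCA, cross-matrix agreement, ISR and partition QC and the
#' efficacy summary, writing every table plus a JSON run manifest to
#' `out_dir`. Re-running with the same config and seed reproduces identical
#' outputs.
#'
#' @param config A [simulation_config()] or a path readable by
#'   [read_config()].
#' @param seed Integer seed driving every stochastic stage.
#' @param out_dir Output directory (created if absent).
#' @param input_concentrations Optional path to a real concentration CSV; the
#'   simulate stage is skipped and agreement/NCA run on the provided data.
#' @return The run manifest, invisibly (also written as `manifest.json`).
#' @export
run_all <- function(config = simulation_config(), seed = config$rng_seed,
                    out_dir, input_concentrations = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  warnings <- character(0)
  out <- function(f) file.path(out_dir, f)
  stage <- function(name, files, rows) {
    stages[[length(stages) + 1]] <<- list(stage = name, outputs = files,
                                          rows = rows)
  }

  if (is.null(input_concentrations)) {
    cohort <- generate_cohort(config, seed = seed)
    conc <- cohort$concentrations
    write_concentrations(conc, out("concentrations.csv"))
    readr::write_csv(cohort$truth, out("truth.csv"), na = "")
    isr <- generate_isr_pairs(conc, seed = subject_seed(seed, 0L, 3L))
    readr::write_csv(isr, out("isr.csv"))
    part <- default_partition_experiment(config$analyte_models,
                                         seed = subject_seed(seed, 0L, 4L))
    readr::write_csv(part, out("partition.csv"))
    eggs <- generate_egg_counts(config$n_subjects,
                                seed = subject_seed(seed, 0L, 5L))
    readr::write_csv(eggs, out("eggs.csv"))
    stage("simulate",
          c("concentrations.csv", "truth.csv", "isr.csv", "partition.csv",
            "eggs.csv"),
          c(nrow(conc), nrow(cohort$truth), nrow(isr), nrow(part),
            nrow(eggs)))
  } else {
    conc <- read_concentrations(input_concentrations)
    isr <- part <- eggs <- NULL
    stage("load", input_concentrations, nrow(conc))
  }

  issues <- validate_inputs(conc)
  if (nrow(issues) > 0) {
    warnings <- c(warnings, paste0("validate: ", issues$message,
                                   " (n=", issues$n, ")"))
  }

  conc <- censor_to_range(conc, config$lloq_ug_ml, config$uloq_ug_ml)
  if (!is.null(isr)) {
    isr_rep <- isr_assess(isr)
    readr::write_csv(
      tibble::tibble(scope = c("all", isr_rep$by_matrix$matrix),
                     n_pairs = c(isr_rep$n_pairs, isr_rep$by_matrix$n_pairs),
                     pct_within = c(isr_rep$pct_within,
                                    isr_rep$by_matrix$pct_within),
                     pass = isr_rep$pass),
      out("isr_report.csv"))
    part_res <- partition_ratio(part)
    readr::write_csv(part_res, out("partition_results.csv"))
    stage("qc", c("isr_report.csv", "partition_results.csv"),
          c(isr_rep$n_pairs, nrow(part_res)))
  }

  pk <- nca_analyze(conc, t_end = 24)
  readr::write_csv(pk, out("pk_parameters.csv"), na = "")
  pk_sum <- pk_summarize(pk)
  readr::write_csv(pk_sum, out("pk_summary.csv"))
  stage("nca", c("pk_parameters.csv", "pk_summary.csv"),
        c(nrow(pk), nrow(pk_sum)))

  agree_conc <- agreement_concentrations(conc)
  readr::write_csv(agree_conc, out("agreement_concentrations.csv"), na = "")
  agree_auc <- dplyr::bind_rows(
    dplyr::mutate(parameter_ratio_table(pk, "blood",
                                        parameters = "auc_0_24"),
                  matrix = "blood"),
    dplyr::mutate(parameter_ratio_table(pk, "DBS", parameters = "auc_0_24"),
                  matrix = "DBS"))
  readr::write_csv(agree_auc, out("agreement_auc.csv"), na = "")
  agree_params <- dplyr::bind_rows(
    dplyr::mutate(parameter_ratio_table(pk, "blood",
                                        parameters = c("t_half", "cmax",
                                                       "tmax")),
                  matrix = "blood"),
    dplyr::mutate(parameter_ratio_table(pk, "DBS",
                                        parameters = c("t_half", "cmax",
                                                       "tmax")),
                  matrix = "DBS"))
  readr::write_csv(agree_params, out("agreement_params.csv"), na = "")
  ba <- dplyr::bind_rows(lapply(c("blood", "DBS"), function(m) {
    bland_altman_points(conc, m)
  }))
  readr::write_csv(ba, out("bland_altman_points.csv"))
  stage("agreement",
        c("agreement_concentrations.csv", "agreement_auc.csv",
          "agreement_params.csv", "bland_altman_points.csv"),
        c(nrow(agree_conc), nrow(agree_auc), nrow(agree_params), nrow(ba)))

  if (!is.null(eggs)) {
    eff <- efficacy_summary(eggs)
    readr::write_csv(eff, out("efficacy_summary.csv"))
    stage("efficacy", "efficacy_summary.csv", nrow(eff))
  }

  manifest <- list(
    seed = seed,
    n_subjects = config$n_subjects,
    regimen = list(dose_mg_per_kg = config$regimen$dose_mg_per_kg,
                   dose_times_h = config$regimen$dose_times_h),
    stages = stages,
    warnings = warnings)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
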