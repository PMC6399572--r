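# File I/O and the end-to-end analysis pipeline.

CONSULTATION_COLUMNS <- c("consultation_id", "patient_id", "arm", "main_mode",
                          "ferry", "distance_km", "travel_time_min",
                          "companion", "extra_transport", "employment",
                          "on_sick_leave", "took_time_off_work",
                          "time_off_hours")
PATIENT_COLUMNS <- c("patient_id", "arm",
                     paste0("eq5d_", EQ5D_DIMENSIONS),
                     paste0("eq5d_fu_", EQ5D_DIMENSIONS))

#' Read a consultation-level CSV
#'
#' One row per attended consultation; schema violations raise a config/data
#' error naming the offending line.
#'
#' @param path CSV file (header documented in [write_trial()]).
#' @return validated data.frame.
#' @export
read_consultations <- function(path) {
  if (!file.exists(path)) abort_config("consultation file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(CONSULTATION_COLUMNS, names(df))
  if (length(miss))
    abort_data("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  bad <- which(!is.na(df$main_mode) & nzchar(df$main_mode) &
                 !df$main_mode %in% TRANSPORT_MODES)
  if (length(bad))
    abort_data("%s line %d: unknown transport mode '%s'", path, bad[1] + 1,
               df$main_mode[bad[1]])
  df$main_mode[!is.na(df$main_mode) & !nzchar(df$main_mode)] <- NA_character_
  bad <- which(!df$employment %in% c(EMPLOYMENT_LEVELS, NA))
  if (length(bad))
    abort_data("%s line %d: unknown employment '%s'", path, bad[1] + 1,
               df$employment[bad[1]])
  if (any(df$distance_km < 0, na.rm = TRUE) ||
      any(df$travel_time_min < 0, na.rm = TRUE))
    abort_data("%s: negative distance or travel time", path)
  for (cl in c("ferry", "companion", "extra_transport", "on_sick_leave",
               "took_time_off_work"))
    df[[cl]] <- assert_flag01(df[[cl]], cl)
  df
}

#' Read a patient-level CSV
#'
#' @param path CSV file.
#' @return validated data.frame.
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) abort_config("patient file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(PATIENT_COLUMNS, names(df))
  if (length(miss))
    abort_data("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  lv <- as.matrix(df[paste0("eq5d_", EQ5D_DIMENSIONS)])
  if (any(!is.na(lv) & !(lv %in% 1:3)))
    abort_data("%s: EQ-5D levels must be 1-3", path)
  df
}

#' Write trial tables to CSV
#'
#' @param trial list with `patients` and `consultations`
#'   ([generate_trial()] output shape).
#' @param dir output directory (created if needed).
#' @return paths of the two files, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, "patients.csv")
  cp <- file.path(dir, "consultations.csv")
  utils::write.csv(trial$patients, pp, row.names = FALSE, na = "")
  utils::write.csv(trial$consultations, cp, row.names = FALSE, na = "")
  invisible(c(patients = pp, consultations = cp))
}

md5_of <- function(df) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.csv(df, f, row.names = FALSE)
  unname(tools::md5sum(f))
}

#' Run configuration
#'
#' @param cost_config,fare_schedule,tariff paths; defaults are the bundled
#'   fixtures.
#' @param patients,consultations optional CSV paths with trial data; when
#'   absent the synthetic generator is used.
#' @param seed integer seed for the generator.
#' @param volume service volume (consultations/year) for the synthesis.
#' @param output_dir where [run_full_analysis()] writes the report bundle.
#' @return a validated `run_config` object.
#' @export
run_config <- function(cost_config = telecea_file("table2_components.yaml"),
                       fare_schedule = telecea_file("fares_synthetic.yaml"),
                       tariff = telecea_file("eq5d_uk_tto.csv"),
                       patients = NULL, consultations = NULL,
                       seed = 20190219, volume = 300, output_dir = NULL) {
  for (p in c(cost_config, fare_schedule, tariff, patients, consultations))
    if (!is.null(p) && !file.exists(p))
      abort_config("configured file does not exist: %s", p)
  if (xor(is.null(patients), is.null(consultations)))
    abort_config("provide both patients and consultations files, or neither")
  structure(list(cost_config = cost_config, fare_schedule = fare_schedule,
                 tariff = tariff, patients = patients,
                 consultations = consultations, seed = seed, volume = volume,
                 output_dir = output_dir), class = "run_config")
}

#' Full trial-based economic evaluation
#'
#' Chains every stage: load configs, obtain trial data (files or seeded
#' generator), price travel and production losses, score EQ-5D and QALYs,
#' build the service-cost tables for both equipment alternatives, synthesize
#' cost-effectiveness at the working volume, solve break-even volumes for
#' the base case and the one-way scenarios (software client; 90 km hospital
#' distance; health-sector perspective), and assemble break-even curves.
#' Deterministic for a fixed config: the log carries the seed and stage
#' checksums, no timestamps.
#'
#' @param config a [run_config()].
#' @return a `report_bundle` list; written to disk if `output_dir` is set.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "configuration"
  bundle <- tryCatch({
    cost <- read_cost_config(config$cost_config)
    fares <- read_fare_schedule(config$fare_schedule)
    tariff <- read_eq5d_tariff(config$tariff)

    stage <- "trial data"
    if (is.null(config$patients)) {
      params <- default_trial_params(seed = config$seed)
      trial <- generate_trial(params)
      recovery <- recovery_report(trial, params, tariff)
    } else {
      trial <- list(patients = read_patients(config$patients),
                    consultations = read_consultations(config$consultations))
      recovery <- NULL
    }

    stage <- "costing"
    uc <- cohort_unit_costs(trial$consultations, fares)
    table2 <- list(
      telemedicine_A = service_cost_table(cost$components, "telemedicine_A",
                                          cost$annuity, cost$reference_volume),
      telemedicine_B = service_cost_table(cost$components, "telemedicine_B",
                                          cost$annuity, cost$reference_volume))

    stage <- "outcomes"
    qr <- qaly_records(trial$patients, tariff)
    q_std <- arm_mean_qaly(qr$qaly_gain[qr$arm == "standard"])
    q_tm <- arm_mean_qaly(qr$qaly_gain[qr$arm == "telemedicine"])
    q_test <- t_test_summary(q_tm$mean, q_tm$sd, q_tm$n,
                             q_std$mean, q_std$sd, q_std$n)

    stage <- "synthesis"
    scen <- function(name, ...) {
      run_scenario(scenario_spec(name, ..., volume = config$volume),
                   cost$components, fares,
                   consultations = trial$consultations,
                   qaly_gain_std = q_std$mean, qaly_gain_tm = q_tm$mean,
                   qaly_significant = q_test$p_value < 0.05,
                   params = cost$annuity)
    }
    base <- scen("base_case")
    results <- list(
      base_case = base,
      software_client = scen("software_client",
                             equipment_alternative = "telemedicine_B"),
      health_sector = scen("health_sector", perspective = "health_sector"),
      distance_90km = scen("distance_90km", distance_scale = 90 / 148))
    arms <- build_arm_summaries(cost$components, uc, "telemedicine_A",
                                config$volume, cost$annuity)
    table5 <- cea_table(arms$std, arms$tm, config$volume,
                        q_std$mean, q_tm$mean)

    list(seed = config$seed, volume = config$volume,
         config_checksums = c(
           cost_config = unname(tools::md5sum(config$cost_config)),
           fare_schedule = unname(tools::md5sum(config$fare_schedule)),
           tariff = unname(tools::md5sum(config$tariff))),
         stage_checksums = c(patients = md5_of(trial$patients),
                             consultations = md5_of(trial$consultations),
                             unit_costs = md5_of(uc)),
         table2 = table2, unit_costs = uc, table5 = table5,
         qaly = list(standard = q_std, telemedicine = q_tm,
                     p_value = q_test$p_value),
         results = results,
         curves = attr(base, "curves"),
         recovery = recovery,
         notes = paste("Annual saving uses the rounded per-consultation",
                       "difference times the working volume; the source",
                       "trial's abstract (18,616 EUR) and discussion",
                       "(19,500 EUR) disagree on this figure."))
  }, teleCEA_error = function(e) {
    stop(errorCondition(sprintf("stage '%s' failed: %s", stage,
                                conditionMessage(e)), class = class(e)))
  })
  class(bundle) <- "report_bundle"
  if (!is.null(config$output_dir)) write_report_bundle(bundle, config$output_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' @param bundle a `report_bundle` from [run_full_analysis()].
#' @param dir output directory.
#' @return file paths, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  paths <- c(
    w(data.frame(item = names(unlist(bundle$table2$telemedicine_A)),
                 value = unlist(bundle$table2$telemedicine_A)), "table2_A.csv"),
    w(data.frame(item = names(unlist(bundle$table2$telemedicine_B)),
                 value = unlist(bundle$table2$telemedicine_B)), "table2_B.csv"),
    w(bundle$table5, "table5.csv"),
    w(bundle$unit_costs, "unit_costs.csv"),
    w(do.call(rbind, lapply(bundle$results, function(r)
      data.frame(scenario = r$scenario, perspective = r$perspective,
                 incremental_cost = r$incremental_cost_per_consultation,
                 incremental_qaly = r$incremental_qaly,
                 classification = r$classification,
                 break_even_volume = r$break_even_volume,
                 annual_saving = r$annual_saving_at_volume))),
      "cea_results.csv"),
    w(bundle$curves, "breakeven_curves.csv"))
  if (!is.null(bundle$recovery)) paths <- c(paths, w(bundle$recovery, "recovery.csv"))
  json_path <- file.path(dir, "bundle.json")
  jsonlite::write_json(
    list(seed = bundle$seed, volume = bundle$volume,
         config_checksums = as.list(bundle$config_checksums),
         stage_checksums = as.list(bundle$stage_checksums),
         qaly = bundle$qaly, notes = bundle$notes),
    json_path, auto_unbox = TRUE, digits = NA)
  log_path <- file.path(dir, "log.txt")
  writeLines(c(sprintf("seed: %d", bundle$seed),
               sprintf("volume: %d", bundle$volume),
               sprintf("config %s: %s", names(bundle$config_checksums),
                       bundle$config_checksums),
               sprintf("stage %s: %s", names(bundle$stage_checksums),
                       bundle$stage_checksums),
               bundle$notes), log_path)
  invisible(c(paths, json_path, log_path))
}
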