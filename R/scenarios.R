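# One-way sensitivity scenarios: vary a single assumption (equipment
# alternative, travel distance to the hospital, costing perspective) and
# re-run the costing -> synthesis chain.

#' Scenario specification
#'
#' @param name label.
#' @param equipment_alternative `"telemedicine_A"` (dedicated units, base
#'   case) or `"telemedicine_B"` (software client).
#' @param distance_scale multiplier (> 0) applied to the standard arm's
#'   travel distances - and, proportionally, to the travel-time share of work
#'   absences - before pricing. The remote-center journeys are unaffected:
#'   moving the hospital does not move patients' local clinic.
#' @param perspective a [perspective()] or its name.
#' @param volume consultations/year for the synthesis.
#' @param volume_range volumes for the break-even curves.
#' @return a `scenario_spec` object.
#' @export
scenario_spec <- function(name, equipment_alternative = "telemedicine_A",
                          distance_scale = 1,
                          perspective = "societal", volume = 300,
                          volume_range = seq(25, 600, by = 25)) {
  if (!equipment_alternative %in% c("telemedicine_A", "telemedicine_B"))
    abort_config("unknown equipment alternative '%s'", equipment_alternative)
  if (!is.numeric(distance_scale) || distance_scale <= 0)
    abort_config("distance_scale must be > 0")
  if (is.character(perspective)) perspective <- perspective(perspective)
  structure(list(name = name, equipment_alternative = equipment_alternative,
                 distance_scale = distance_scale, perspective = perspective,
                 volume = volume, volume_range = volume_range),
            class = "scenario_spec")
}

#' Published per-consultation unit costs
#'
#' Convenience constructor for the travel and time (production loss) costs
#' per consultation when they are supplied as published numbers rather than
#' derived from a priced cohort. The user fee is the patient-paid share of
#' the travel cost.
#'
#' @param travel_standard,travel_telemedicine total travel cost per
#'   consultation (EUR), user fee included.
#' @param time_standard,time_telemedicine production loss per consultation.
#' @param user_fee patient-paid share (EUR per consultation).
#' @return data.frame in the shape returned by [cohort_unit_costs()].
#' @export
published_unit_costs <- function(travel_standard = 149,
                                 travel_telemedicine = 41,
                                 time_standard = 34, time_telemedicine = 11,
                                 user_fee = 31.04) {
  if (travel_standard < user_fee || travel_telemedicine < user_fee)
    abort_config("travel cost cannot be below the user fee")
  data.frame(
    arm = c("standard", "telemedicine"),
    n = NA_integer_,
    travel_health_sector = c(travel_standard, travel_telemedicine) - user_fee,
    travel_patient = user_fee,
    travel_total = c(travel_standard, travel_telemedicine),
    production_loss = c(time_standard, time_telemedicine),
    travel_time_total = c(travel_standard + time_standard,
                          travel_telemedicine + time_telemedicine),
    stringsAsFactors = FALSE)
}

scale_unit_costs <- function(uc, distance_scale) {
  # Shrinks the distance-dependent fare and the time costs of the standard
  # (hospital-journey) arm; the per-consultation user fee is volume-, not
  # distance-based, and stays.
  i <- uc$arm == "standard"
  uc$travel_health_sector[i] <- uc$travel_health_sector[i] * distance_scale
  uc$production_loss[i] <- uc$production_loss[i] * distance_scale
  uc$travel_total <- uc$travel_health_sector + uc$travel_patient
  uc$travel_time_total <- uc$travel_total + uc$production_loss
  uc
}

#' Build both arm summaries from components plus unit costs
#'
#' @param components a [cost_components()] table.
#' @param unit_costs data.frame from [cohort_unit_costs()] or
#'   [published_unit_costs()] (rows `standard`, `telemedicine`).
#' @param alternative telemedicine equipment alternative.
#' @param volume consultations per year.
#' @param params an [annuity_params()] object.
#' @return list with `std` and `tm` `arm_cost_summary` objects.
#' @export
build_arm_summaries <- function(components, unit_costs,
                                alternative = "telemedicine_A", volume = 300,
                                params = annuity_params()) {
  pick <- function(a) {
    r <- unit_costs[unit_costs$arm == a, , drop = FALSE]
    if (nrow(r) != 1) abort_data("unit costs missing arm '%s'", a)
    r
  }
  us <- pick("standard"); ut <- pick("telemedicine")
  std <- add_unit_costs(
    aggregate_annual_cost(components, "standard", volume, params),
    travel_health_sector = us$travel_health_sector,
    travel_patient = us$travel_patient, production = us$production_loss)
  tm <- add_unit_costs(
    aggregate_annual_cost(components, alternative, volume, params),
    travel_health_sector = ut$travel_health_sector,
    travel_patient = ut$travel_patient, production = ut$production_loss)
  list(std = std, tm = tm)
}

#' Run a one-way sensitivity scenario
#'
#' Re-runs costing and synthesis with the single change the scenario states:
#' swapping the equipment component set, scaling the hospital-journey
#' distances before fare pricing, or switching the costing perspective.
#'
#' @param spec a [scenario_spec()].
#' @param components a [cost_components()] table.
#' @param fares a [fare_schedule()]; needed when pricing a cohort.
#' @param consultations optional consultation table; when given, unit travel
#'   and time costs are derived by pricing it (the standard arm at the
#'   scenario's scaled distances).
#' @param unit_costs optional pre-computed unit costs (used when
#'   `consultations` is `NULL`); the scenario's `distance_scale` is applied
#'   to its standard-arm fare (user fee excluded) and time cost.
#' @param qaly_gain_std,qaly_gain_tm,qaly_significant outcome inputs.
#' @param params an [annuity_params()] object.
#' @return a `cea_result` (with `curves` attached as an attribute).
#' @export
run_scenario <- function(spec, components, fares = NULL,
                         consultations = NULL, unit_costs = NULL,
                         qaly_gain_std = NA_real_, qaly_gain_tm = NA_real_,
                         qaly_significant = FALSE,
                         params = annuity_params()) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(consultations) && is.null(unit_costs))
    abort_config("scenario needs either a consultation table or unit costs")
  if (!is.null(consultations)) {
    if (is.null(fares)) abort_config("pricing a cohort requires a fare schedule")
    std_rows <- consultations[consultations$arm == "standard", , drop = FALSE]
    tm_rows <- consultations[consultations$arm == "telemedicine", , drop = FALSE]
    uc <- rbind(cohort_unit_costs(std_rows, fares, spec$distance_scale),
                cohort_unit_costs(tm_rows, fares, distance_scale = 1))
  } else {
    uc <- scale_unit_costs(unit_costs, spec$distance_scale)
  }
  arms <- build_arm_summaries(components, uc, spec$equipment_alternative,
                              spec$volume, params)
  res <- cea_result(arms$std, arms$tm, volume = spec$volume,
                    persp = spec$perspective,
                    qaly_gain_std = qaly_gain_std,
                    qaly_gain_tm = qaly_gain_tm,
                    qaly_significant = qaly_significant,
                    scenario = spec$name)
  attr(res, "curves") <- breakeven_curves(
    arms$std, stats::setNames(list(arms$tm), spec$equipment_alternative),
    spec$volume_range, spec$perspective)
  res
}
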