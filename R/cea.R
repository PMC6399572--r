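# Incremental cost-effectiveness synthesis.
#
# Combines an alternative's fixed annual service cost with per-consultation
# variable costs (service items, travel by payer, production loss) into total
# and per-consultation costs under a costing perspective, classifies
# dominance against the comparator, and solves the break-even yearly
# consultation volume: the smallest integer N at which the telemedicine
# alternative's total annual cost no longer exceeds standard care's
# (ties go to telemedicine).

#' Costing perspective
#'
#' The societal perspective includes health-sector expenditure, patient
#' out-of-pocket costs (the travel user fee) and production losses; the
#' health-sector perspective keeps only the first.
#'
#' @param name `"societal"` or `"health_sector"`.
#' @return a `perspective` object with the included payer set.
#' @export
perspective <- function(name = c("societal", "health_sector")) {
  name <- match.arg(name)
  payers <- switch(name,
                   societal = c("health_sector", "patient", "production"),
                   health_sector = "health_sector")
  structure(list(name = name, payers = payers), class = "perspective")
}

#' Add cohort unit costs to a service-cost summary
#'
#' Extends an [aggregate_annual_cost()] summary with per-consultation travel
#' costs (split health sector / patient) and production losses, either taken
#' from a priced cohort ([cohort_unit_costs()]) or supplied directly (e.g.
#' published per-consultation values).
#'
#' @param summary an `arm_cost_summary` from [aggregate_annual_cost()].
#' @param travel_health_sector,travel_patient,production EUR per consultation.
#' @return the extended `arm_cost_summary`.
#' @export
add_unit_costs <- function(summary, travel_health_sector = 0,
                           travel_patient = 0, production = 0) {
  stopifnot(inherits(summary, "arm_cost_summary"))
  v <- summary$variable_per_consultation
  v[["health_sector"]] <- v[["health_sector"]] + travel_health_sector
  v[["patient"]] <- v[["patient"]] + travel_patient
  v[["production"]] <- v[["production"]] + production
  summary$variable_per_consultation <- v
  summary$travel_unit <- c(health_sector = travel_health_sector,
                           patient = travel_patient)
  summary
}

#' Cost per consultation
#'
#' @param summary an `arm_cost_summary`.
#' @param volume consultations per year (>= 1).
#' @param persp a [perspective()].
#' @return EUR per consultation (unrounded; round for table display only).
#' @export
per_consultation_cost <- function(summary, volume,
                                  persp = perspective("societal")) {
  if (volume < 1) abort_data("volume must be >= 1")
  pay <- persp$payers
  sum(summary$fixed_annual[pay]) / volume +
    sum(summary$variable_per_consultation[pay])
}

#' Incremental cost per consultation (standard minus telemedicine)
#'
#' Positive values mean telemedicine is the cheaper alternative.
#'
#' @param std,tm `arm_cost_summary` objects for standard care and
#'   telemedicine.
#' @param volume consultations per year.
#' @param persp a [perspective()].
#' @return EUR per consultation.
#' @export
incremental_cost <- function(std, tm, volume,
                             persp = perspective("societal")) {
  per_consultation_cost(std, volume, persp) -
    per_consultation_cost(tm, volume, persp)
}

#' Break-even consultation volume
#'
#' Smallest integer N (consultations/year) at which the telemedicine
#' alternative's total annual cost is at most standard care's under the
#' given perspective. Solved in closed form (validated elsewhere against a
#' brute-force integer sweep). If telemedicine never catches up within
#' `max_volume`, returns `Inf`.
#'
#' @param std,tm `arm_cost_summary` objects.
#' @param persp a [perspective()].
#' @param max_volume sentinel bound for the search.
#' @return integer volume, or `Inf`.
#' @export
break_even_volume <- function(std, tm, persp = perspective("societal"),
                              max_volume = 10000) {
  pay <- persp$payers
  dfix <- sum(tm$fixed_annual[pay]) - sum(std$fixed_annual[pay])
  save <- sum(std$variable_per_consultation[pay]) -
    sum(tm$variable_per_consultation[pay])
  if (dfix <= 0) return(1L)
  if (save <= 0) return(Inf)
  n <- max(1, ceiling(dfix / save - 1e-9))
  if (n > max_volume) Inf else as.integer(n)
}

#' Dominance classification
#'
#' @param delta_cost telemedicine minus standard cost per consultation (EUR).
#' @param delta_qaly telemedicine minus standard QALY gain.
#' @param qaly_significant was the QALY difference statistically significant?
#'   (carried through for reporting; a nonsignificant difference with lower
#'   cost still classifies as dominant, mirroring the trial's conclusion).
#' @return list with `classification` (`"dominant"`, `"dominated"`,
#'   `"tradeoff"`) and `icer` (EUR/QALY, `NA` unless a true tradeoff).
#' @export
dominance <- function(delta_cost, delta_qaly, qaly_significant = FALSE) {
  if (delta_cost < 0 && delta_qaly >= 0) {
    cls <- "dominant"; icer <- NA_real_
  } else if (delta_cost > 0 && delta_qaly <= 0) {
    cls <- "dominated"; icer <- NA_real_
  } else if (delta_cost == 0 && delta_qaly == 0) {
    cls <- "tradeoff"; icer <- NA_real_
  } else {
    cls <- "tradeoff"; icer <- delta_cost / delta_qaly
  }
  list(classification = cls, icer = icer,
       qaly_significant = isTRUE(qaly_significant))
}

#' Cost-effectiveness synthesis at a working volume
#'
#' @param std,tm `arm_cost_summary` objects (unit travel/time costs already
#'   attached, see [add_unit_costs()]).
#' @param volume consultations per year the service is dimensioned for.
#' @param persp a [perspective()].
#' @param qaly_gain_std,qaly_gain_tm mean QALYs gained per patient by arm.
#' @param qaly_significant flag from the between-arm test.
#' @param scenario label stored in the result.
#' @return a `cea_result`: incremental cost (standard minus telemedicine,
#'   EUR/consultation), incremental QALY, dominance classification, ICER,
#'   break-even volume, and annual saving at `volume` (rounded incremental
#'   cost times volume, matching published-table arithmetic, with the
#'   unrounded value alongside).
#' @export
cea_result <- function(std, tm, volume = 300,
                       persp = perspective("societal"),
                       qaly_gain_std = NA_real_, qaly_gain_tm = NA_real_,
                       qaly_significant = FALSE, scenario = "base_case") {
  inc <- incremental_cost(std, tm, volume, persp)
  dq <- qaly_gain_tm - qaly_gain_std
  dom <- dominance(-inc, if (is.na(dq)) 0 else dq, qaly_significant)
  structure(list(
    scenario = scenario, perspective = persp$name, volume = volume,
    cost_per_consultation_std = per_consultation_cost(std, volume, persp),
    cost_per_consultation_tm = per_consultation_cost(tm, volume, persp),
    incremental_cost_per_consultation = inc,
    incremental_qaly = dq,
    classification = dom$classification, icer = dom$icer,
    qaly_significant = dom$qaly_significant,
    break_even_volume = break_even_volume(std, tm, persp),
    annual_saving_at_volume = round_half_up(inc) * volume,
    annual_saving_unrounded = inc * volume), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result: %s, %s perspective, %d consultations/year>\n",
              x$scenario, x$perspective, as.integer(x$volume)))
  cat(sprintf("  cost/consultation: standard %.2f vs telemedicine %.2f EUR\n",
              x$cost_per_consultation_std, x$cost_per_consultation_tm))
  cat(sprintf("  incremental saving %.2f EUR/consultation; %s%s\n",
              x$incremental_cost_per_consultation, x$classification,
              if (is.na(x$icer)) "" else sprintf(" (ICER %.0f EUR/QALY)", x$icer)))
  cat(sprintf("  break-even %s consultations/year; annual saving %.0f EUR at %d\n",
              format(x$break_even_volume), x$annual_saving_at_volume,
              as.integer(x$volume)))
  invisible(x)
}

#' Published-style cost-effectiveness table
#'
#' Mirrors the published synthesis layout: fixed service components per year,
#' cost per consultation, travel and time (production loss) costs per
#' consultation, totals and differences, plus QALYs gained. Monetary cells
#' are rounded half-up to whole euros at this display step.
#'
#' @param std,tm `arm_cost_summary` objects with unit costs attached.
#' @param volume consultations per year.
#' @param qaly_gain_std,qaly_gain_tm mean QALYs gained per patient.
#' @return data.frame with columns `item`, `standard`, `telemedicine`,
#'   `difference`.
#' @export
cea_table <- function(std, tm, volume = 300, qaly_gain_std = NA_real_,
                      qaly_gain_tm = NA_real_) {
  row <- function(item, s, t, digits = 0)
    data.frame(item = item, standard = round_half_up(s, digits),
               telemedicine = round_half_up(t, digits),
               difference = round_half_up(s - t, digits),
               stringsAsFactors = FALSE)
  tbl <- rbind(
    row("total_annual_service_cost",
        service_annual(std, volume), service_annual(tm, volume)),
    row("service_cost_per_consultation",
        service_annual(std, volume) / volume, service_annual(tm, volume) / volume),
    row("travel_cost_per_consultation",
        sum(unit_travel(std)), sum(unit_travel(tm))),
    row("time_cost_per_consultation",
        std$variable_per_consultation[["production"]],
        tm$variable_per_consultation[["production"]]),
    row("travel_time_per_consultation",
        sum(unit_travel(std)) + std$variable_per_consultation[["production"]],
        sum(unit_travel(tm)) + tm$variable_per_consultation[["production"]]),
    row("total_cost_per_consultation",
        per_consultation_cost(std, volume), per_consultation_cost(tm, volume)),
    row("qaly_gain", qaly_gain_std, qaly_gain_tm, digits = 2))
  tbl$difference[tbl$item == "qaly_gain"] <-
    round_half_up(qaly_gain_tm - qaly_gain_std, 2)
  tbl
}

# travel unit costs stashed on the summary by add_unit_costs bookkeeping
unit_travel <- function(summary) {
  c(health_sector = summary$travel_unit[["health_sector"]] %||% 0,
    patient = summary$travel_unit[["patient"]] %||% 0)
}

service_annual <- function(summary, volume) {
  sum(summary$fixed_annual) +
    (summary$variable_per_consultation[["health_sector"]] -
       unit_travel(summary)[["health_sector"]]) * volume
}

#' Annual-cost and per-consultation break-even curves
#'
#' Piecewise-linear total-annual-cost curves (and their per-consultation
#' analogue) across a volume range, for the standard alternative and one or
#' more telemedicine variants; the crossing point of each pair equals
#' [break_even_volume()].
#'
#' @param std an `arm_cost_summary`.
#' @param tm_variants named list of `arm_cost_summary` objects.
#' @param volumes integer vector of consultations/year.
#' @param persp a [perspective()].
#' @return long data.frame: `alternative`, `volume`, `total_annual`,
#'   `per_consultation`.
#' @export
breakeven_curves <- function(std, tm_variants, volumes,
                             persp = perspective("societal")) {
  if (!length(volumes)) abort_data("volume range must be nonempty")
  if (inherits(tm_variants, "arm_cost_summary"))
    tm_variants <- list(telemedicine = tm_variants)
  all <- c(list(standard = std), tm_variants)
  do.call(rbind, lapply(names(all), function(nm) {
    s <- all[[nm]]
    tot <- vapply(volumes, function(v)
      total_annual_cost(s, v, persp), numeric(1))
    data.frame(alternative = nm, volume = volumes, total_annual = tot,
               per_consultation = tot / volumes, stringsAsFactors = FALSE)
  }))
}
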