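# Travel-cost and production-loss valuation of consultation records.
#
# Each attended consultation is priced from a fare schedule: a round trip on
# the main transport mode (per-trip and/or per-km unit fares), a surcharge
# when a ferry leg is involved, an extra-transport surcharge when the patient
# cannot use public transport, a companion share when an accompanying person
# is needed, and a fixed per-consultation user fee borne by the patient
# (the remainder falls on the health sector). Production losses value work
# time lost for employed patients who took time off, at the average hourly
# wage (part-time counted at 50%).

TRANSPORT_MODES <- c("taxi", "bus", "private_car", "express_boat", "ferry",
                     "airplane", "other")
EMPLOYMENT_LEVELS <- c("full_time", "part_time", "homemaker", "unemployed",
                       "retired_disability", "student")

#' Read a fare schedule (YAML)
#'
#' @param path YAML file; see the bundled `fares_synthetic.yaml`. The bundled
#'   rates are calibrated synthetic values, not the official agency tariffs
#'   (which are not publicly printed); they are solved so the default
#'   synthetic cohort reproduces the published per-consultation travel and
#'   time cost averages.
#' @return a `fare_schedule` object.
#' @export
read_fare_schedule <- function(path) {
  if (!file.exists(path)) abort_config("fare schedule not found: %s", path)
  f <- yaml::read_yaml(path)
  fare_schedule(modes = f$modes, companion_multiplier = f$companion_multiplier,
                ferry_surcharge = f$ferry_surcharge %||% 0,
                extra_transport_fee = f$extra_transport_fee %||% 0,
                user_fee = f$user_fee,
                average_hourly_wage = f$average_hourly_wage)
}

#' Fare schedule
#'
#' @param modes named list; each element a list with `per_trip` and/or
#'   `per_km` EUR fares (one-way leg). Names must cover the transport modes
#'   used in the data.
#' @param companion_multiplier fraction of the main fare added when a
#'   companion travels.
#' @param ferry_surcharge flat EUR per round trip involving a ferry leg.
#' @param extra_transport_fee flat EUR per consultation needing extra
#'   (non-public) transport.
#' @param user_fee EUR per consultation paid by the patient.
#' @param average_hourly_wage EUR per hour used to value production losses.
#' @return a `fare_schedule` object.
#' @export
fare_schedule <- function(modes, companion_multiplier = 0, ferry_surcharge = 0,
                          extra_transport_fee = 0, user_fee = 0,
                          average_hourly_wage = 0) {
  unknown <- setdiff(names(modes), TRANSPORT_MODES)
  if (length(unknown))
    abort_config("unknown transport mode(s): %s", paste(unknown, collapse = ", "))
  modes <- lapply(modes, function(m)
    list(per_trip = as.numeric(m$per_trip %||% 0),
         per_km = as.numeric(m$per_km %||% 0)))
  rates <- unlist(modes)
  if (any(is.na(rates)) || any(rates < 0)) abort_config("fares must be >= 0")
  if (is.na(user_fee) || user_fee < 0) abort_config("user_fee must be >= 0")
  if (companion_multiplier < 0 || ferry_surcharge < 0 ||
      extra_transport_fee < 0 || average_hourly_wage < 0)
    abort_config("fare schedule parameters must be >= 0")
  structure(list(modes = modes,
                 companion_multiplier = companion_multiplier,
                 ferry_surcharge = ferry_surcharge,
                 extra_transport_fee = extra_transport_fee,
                 user_fee = user_fee,
                 average_hourly_wage = average_hourly_wage),
            class = "fare_schedule")
}

mode_leg_fare <- function(mode, distance_km, fares) {
  per_trip <- vapply(fares$modes, `[[`, numeric(1), "per_trip")
  per_km <- vapply(fares$modes, `[[`, numeric(1), "per_km")
  i <- match(mode, names(fares$modes))
  unname(per_trip[i] + per_km[i] * distance_km)
}

#' Price one consultation's travel
#'
#' Round-trip main-mode fare, companion share, ferry and extra-transport
#' surcharges, plus the patient user fee. The user fee is the patient-paid
#' share; everything else falls on the health sector. A record with a missing
#' main mode is returned flagged with `NA` costs; [price_travel()] imputes it
#' from the arm mean.
#'
#' @param rec one-row data.frame (or list) with `main_mode`, `distance_km`,
#'   `companion`, `extra_transport`, `ferry` fields.
#' @param fares a [fare_schedule()].
#' @return list with `total`, `health_sector`, `patient`, `flagged`.
#' @export
travel_cost <- function(rec, fares) {
  if (is.na(rec$distance_km) || rec$distance_km < 0)
    abort_data("distance_km must be nonnegative")
  if (is.na(rec$main_mode) || !nzchar(rec$main_mode)) {
    return(list(total = NA_real_, health_sector = NA_real_,
                patient = fares$user_fee, flagged = TRUE))
  }
  if (!rec$main_mode %in% TRANSPORT_MODES)
    abort_data("unknown transport mode '%s'", rec$main_mode)
  round_trip <- 2 * mode_leg_fare(rec$main_mode, rec$distance_km, fares)
  hs <- round_trip * (1 + fares$companion_multiplier * (rec$companion %||% 0)) +
    fares$ferry_surcharge * (rec$ferry %||% 0) +
    fares$extra_transport_fee * (rec$extra_transport %||% 0)
  list(total = hs + fares$user_fee, health_sector = hs,
       patient = fares$user_fee, flagged = FALSE)
}

#' Price a consultation table
#'
#' Vectorized [travel_cost()] over a consultation table. Records with a
#' missing main mode get the arm mean of the priced records (user fee kept as
#' the patient share), per the missing-mode imputation policy.
#'
#' @param consultations consultation-level data.frame with columns `arm`,
#'   `main_mode`, `distance_km`, `companion`, `extra_transport`, `ferry`.
#' @param fares a [fare_schedule()].
#' @param distance_scale optional multiplier applied to distances before
#'   pricing (one-way sensitivity scenarios).
#' @return the input with columns `travel_health_sector`, `travel_patient`,
#'   `travel_total`, `travel_imputed` appended.
#' @export
price_travel <- function(consultations, fares, distance_scale = 1) {
  if (distance_scale <= 0) abort_config("distance_scale must be > 0")
  d <- consultations$distance_km * distance_scale
  known <- !is.na(consultations$main_mode) &
    consultations$main_mode %in% TRANSPORT_MODES
  if (any(!is.na(consultations$main_mode) & !known))
    abort_data("unknown transport mode '%s'",
               consultations$main_mode[!is.na(consultations$main_mode) & !known][1])
  hs <- rep(NA_real_, nrow(consultations))
  if (any(known)) {
    rt <- 2 * mode_leg_fare(consultations$main_mode[known], d[known], fares)
    hs[known] <- rt * (1 + fares$companion_multiplier *
                         consultations$companion[known]) +
      fares$ferry_surcharge * consultations$ferry[known] +
      fares$extra_transport_fee * consultations$extra_transport[known]
  }
  # arm-mean imputation for flagged (missing-mode) records
  for (a in unique(consultations$arm)) {
    sel <- consultations$arm == a
    if (any(sel & !known)) {
      if (!any(sel & known))
        abort_data("cannot impute travel cost: no priced record in arm '%s'", a)
      hs[sel & !known] <- mean(hs[sel & known])
    }
  }
  consultations$travel_health_sector <- hs
  consultations$travel_patient <- rep(fares$user_fee, nrow(consultations))
  consultations$travel_total <- hs + fares$user_fee
  consultations$travel_imputed <- !known
  consultations
}

#' Production loss of one consultation
#'
#' Zero unless the patient is in full- or part-time employment, is not on
#' sick leave, and took time off work; otherwise hours off times the average
#' hourly wage, with part-time employment counted at 50%.
#'
#' @param rec one-row data.frame (or list) with `employment`, `on_sick_leave`,
#'   `took_time_off_work`, `time_off_hours`.
#' @param fares a [fare_schedule()] (supplies the wage).
#' @return EUR.
#' @export
production_loss <- function(rec, fares) {
  production_loss_vec(
    employment = rec$employment, on_sick_leave = rec$on_sick_leave %||% 0,
    took_time_off = rec$took_time_off_work, hours = rec$time_off_hours,
    fares = fares)
}

production_loss_vec <- function(employment, on_sick_leave, took_time_off,
                                hours, fares) {
  frac <- ifelse(employment == "full_time", 1,
                 ifelse(employment == "part_time", 0.5, 0))
  frac[is.na(frac)] <- 0
  eligible <- frac > 0 & !is.na(took_time_off) & took_time_off == 1 &
    (is.na(on_sick_leave) | on_sick_leave == 0)
  out <- numeric(length(frac))
  h <- ifelse(is.na(hours), 0, hours)
  out[eligible] <- h[eligible] * fares$average_hourly_wage * frac[eligible]
  out
}

#' Per-consultation travel and time cost means by arm
#'
#' @param consultations a priced consultation table (see [price_travel()]).
#' @param fares a [fare_schedule()].
#' @param distance_scale forwarded to [price_travel()].
#' @return data.frame, one row per arm: mean travel cost split by payer and
#'   mean production loss per consultation.
#' @export
cohort_unit_costs <- function(consultations, fares, distance_scale = 1) {
  cc <- price_travel(consultations, fares, distance_scale)
  hours <- cc$time_off_hours
  if (distance_scale != 1) {
    # A shorter journey shrinks the travel share of the absence
    # (round trip in hours), never below zero.
    hours <- pmax(0, hours - 2 * cc$travel_time_min * (1 - distance_scale) / 60)
  }
  loss <- production_loss_vec(cc$employment, cc$on_sick_leave,
                              cc$took_time_off_work, hours, fares)
  arms <- sort(unique(cc$arm))
  out <- do.call(rbind, lapply(arms, function(a) {
    sel <- cc$arm == a
    data.frame(arm = a, n = sum(sel),
               travel_health_sector = mean(cc$travel_health_sector[sel]),
               travel_patient = mean(cc$travel_patient[sel]),
               travel_total = mean(cc$travel_total[sel]),
               production_loss = mean(loss[sel]),
               stringsAsFactors = FALSE)
  }))
  out$travel_time_total <- out$travel_total + out$production_loss
  out
}
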