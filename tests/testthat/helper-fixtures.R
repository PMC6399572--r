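# Shared fixtures, built in code at test time.

bundled_components <- function() read_cost_config(telecea_file("table2_components.yaml"))
bundled_fares <- function() read_fare_schedule(telecea_file("fares_synthetic.yaml"))

# A tiny hand-made fare schedule with transparent arithmetic.
toy_fares <- function(user_fee = 10, wage = 20) {
  fare_schedule(
    modes = list(private_car = list(per_km = 0.5),
                 taxi = list(per_trip = 4, per_km = 1),
                 bus = list(per_km = 0.2),
                 express_boat = list(per_km = 2),
                 ferry = list(), airplane = list(per_km = 3),
                 other = list()),
    companion_multiplier = 0.5, ferry_surcharge = 8, extra_transport_fee = 5,
    user_fee = user_fee, average_hourly_wage = wage)
}

toy_consultation <- function(main_mode = "private_car", distance_km = 100,
                             companion = 0, extra_transport = 0, ferry = 0,
                             employment = "full_time", on_sick_leave = 0,
                             took_time_off_work = 0, time_off_hours = 0,
                             arm = "standard") {
  data.frame(main_mode = main_mode, distance_km = distance_km,
             companion = companion, extra_transport = extra_transport,
             ferry = ferry, employment = employment,
             on_sick_leave = on_sick_leave,
             took_time_off_work = took_time_off_work,
             time_off_hours = time_off_hours, arm = arm,
             travel_time_min = 60, stringsAsFactors = FALSE)
}

# Random two-arm cost structures for the break-even property tests.
random_summary_pair <- function() {
  std <- arm_cost_summary("standard",
    fixed_annual = c(health_sector = stats::runif(1, 0, 500),
                     patient = 0, production = 0),
    variable_per_consultation = c(health_sector = stats::runif(1, 5, 200),
                                  patient = stats::runif(1, 0, 40),
                                  production = stats::runif(1, 0, 60)),
    volume_assumed = 300)
  tm <- arm_cost_summary("telemedicine_A",
    fixed_annual = c(health_sector = stats::runif(1, 0, 30000),
                     patient = 0, production = 0),
    variable_per_consultation = c(health_sector = stats::runif(1, 0, 150),
                                  patient = stats::runif(1, 0, 40),
                                  production = stats::runif(1, 0, 30)),
    volume_assumed = 300)
  list(std = std, tm = tm)
}

# Independent brute-force oracle: sweep all volumes.
sweep_break_even <- function(std, tm, perspective, max_volume = 10000) {
  for (n in seq_len(max_volume)) {
    if (total_annual_cost(tm, n, perspective) <=
        total_annual_cost(std, n, perspective))
      return(n)
  }
  Inf
}
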