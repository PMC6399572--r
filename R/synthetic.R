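# Seeded synthetic trial generator.
#
# Emulates the marginal structure of the motivating randomized trial: two
# arms (standard hospital consultations vs telemedicine at a remote center),
# patients nested in four municipalities with characteristic travel
# distances, 1-6 consultations per patient, arm-specific transport-mode
# mixes, travel times drawn jointly with distance (lognormal residual,
# latent correlation rho), companion / extra-transport / time-off flags with
# exchangeable within-patient correlation, employment status, and EQ-5D-3L
# responses produced by discretizing a latent utility onto the 243-state
# grid so that *scored* utilities hit the target mean. All randomness is
# governed by the seed carried in the parameter object.

#' Default trial generator parameters
#'
#' The defaults encode the published marginals of the motivating trial:
#' arm sizes 190 (standard) / 199 (telemedicine); consultation totals 257 /
#' 302 (so per-patient means 1.353 / 1.518, pooled 1.44, support 1-6);
#' one-way travel time means 277 / 47 min (SD 94 / 43); shortest travel
#' distance means 148 / 46 km (SD 31 / 17); main-transport mixes (bus 25.7%
#' vs 2.0%, private car 38.1% vs 69.2%, ...); companion 29.8% / 26.9% and
#' extra transport 25.7% / 29.7%; employment distribution; baseline EQ-5D
#' index mean 0.70 (SD 0.25) / 0.68 (0.26); mean QALY gains 0.05 / 0.09
#' (arm difference 0.04).
#'
#' @param seed integer seed; fully determines the generated tables.
#' @return a `trial_params` object (a nested list; fields may be edited
#'   before calling [generate_trial()]).
#' @export
default_trial_params <- function(seed = 20190219) {
  arm <- function(n_patients, consult_lambda, male_prob, age_mean, age_sd,
                  muni_weights, muni_base_km, distance_sd, distance_noise_sd,
                  time_mean, time_sd, mode_probs, companion_prob, extra_prob,
                  ferry_prob, employment_probs, sick_leave_prob,
                  take_time_off_prob, utility_mean, utility_sd,
                  eq5d_missing_prob, eq5d_fu_missing_prob, gain_mean,
                  vas_mean, vas_sd, vas_missing_prob) {
    list(n_patients = n_patients, consult_lambda = consult_lambda,
         male_prob = male_prob, age_mean = age_mean, age_sd = age_sd,
         muni_weights = muni_weights, muni_base_km = muni_base_km,
         distance_sd = distance_sd, distance_noise_sd = distance_noise_sd,
         time_mean = time_mean, time_sd = time_sd, mode_probs = mode_probs,
         companion_prob = companion_prob, extra_prob = extra_prob,
         ferry_prob = ferry_prob, employment_probs = employment_probs,
         sick_leave_prob = sick_leave_prob,
         take_time_off_prob = take_time_off_prob,
         utility_mean = utility_mean, utility_sd = utility_sd,
         eq5d_missing_prob = eq5d_missing_prob,
         eq5d_fu_missing_prob = eq5d_fu_missing_prob, gain_mean = gain_mean,
         vas_mean = vas_mean, vas_sd = vas_sd,
         vas_missing_prob = vas_missing_prob)
  }
  munis <- c("kvanangen", "nordreisa", "skjervoy", "kafjord")
  structure(list(
    seed = seed,
    time_distance_corr = 0.8,
    within_patient_corr = 0.3,
    consult_overhead_hours = 1,
    gain_sd = 0.30,
    max_consultations = 6,
    duration_years = 1,
    arms = list(
      standard = arm(
        n_patients = 190, consult_lambda = 257 / 190 - 1, male_prob = 0.395,
        age_mean = 46.7, age_sd = 24.9,
        muni_weights = stats::setNames(c(0.132, 0.432, 0.247, 0.189), munis),
        muni_base_km = stats::setNames(c(200, 134.64, 165, 120), munis),
        distance_sd = 31, distance_noise_sd = 17.53,
        time_mean = 277, time_sd = 94,
        mode_probs = c(taxi = 0.183, bus = 0.257, private_car = 0.381,
                       express_boat = 0.109, airplane = 0.011, other = 0,
                       missing = 0.059),
        companion_prob = 0.298, extra_prob = 0.257, ferry_prob = 0.074,
        employment_probs = c(full_time = 0.254, part_time = 0.130,
                             homemaker = 0.068, unemployed = 0.011,
                             retired_disability = 0.311, student = 0.226),
        sick_leave_prob = 0.435, take_time_off_prob = 0.9051,
        utility_mean = 0.70, utility_sd = 0.25,
        eq5d_missing_prob = 0.132, eq5d_fu_missing_prob = 0.25,
        gain_mean = 0.05, vas_mean = 75, vas_sd = 18,
        vas_missing_prob = 0.26),
      telemedicine = arm(
        n_patients = 199, consult_lambda = 302 / 199 - 1, male_prob = 0.412,
        age_mean = 48.8, age_sd = 24.0,
        muni_weights = stats::setNames(c(0.130, 0.452, 0.227, 0.191), munis),
        muni_base_km = stats::setNames(c(60, 37.43, 50, 52), munis),
        distance_sd = 17, distance_noise_sd = 14.82,
        time_mean = 47, time_sd = 43,
        mode_probs = c(taxi = 0.199, bus = 0.020, private_car = 0.692,
                       express_boat = 0, airplane = 0, other = 0.050,
                       missing = 0.039),
        companion_prob = 0.269, extra_prob = 0.297, ferry_prob = 0.023,
        employment_probs = c(full_time = 0.295, part_time = 0.105,
                             homemaker = 0.100, unemployed = 0.011,
                             retired_disability = 0.321, student = 0.168),
        sick_leave_prob = 0.394, take_time_off_prob = 1.0,
        utility_mean = 0.68, utility_sd = 0.26,
        eq5d_missing_prob = 0.106, eq5d_fu_missing_prob = 0.25,
        gain_mean = 0.09, vas_mean = 73, vas_sd = 19,
        vas_missing_prob = 0.25))),
    class = "trial_params")
}

#' Null generator parameters (equal arms)
#'
#' Both arms share the standard-care data-generating process and the QALY
#' gain difference is zero; used for type-I-error checks of the between-arm
#' tests.
#'
#' @param n_per_arm patients per arm.
#' @param seed integer seed.
#' @return a `trial_params` object.
#' @export
null_trial_params <- function(n_per_arm = 60, seed = 1) {
  p <- default_trial_params(seed = seed)
  p$arms$telemedicine <- p$arms$standard
  p$arms$standard$n_patients <- n_per_arm
  p$arms$telemedicine$n_patients <- n_per_arm
  p
}

validate_trial_params <- function(params) {
  if (!inherits(params, "trial_params")) abort_config("not a trial_params object")
  for (a in names(params$arms)) {
    arm <- params$arms[[a]]
    for (f in c("mode_probs", "employment_probs", "muni_weights")) {
      v <- arm[[f]]
      if (any(v < 0) || abs(sum(v) - 1) > 1e-6)
        abort_config("arm '%s': %s must be nonnegative and sum to 1", a, f)
    }
    for (f in c("companion_prob", "extra_prob", "ferry_prob",
                "sick_leave_prob", "take_time_off_prob", "male_prob",
                "eq5d_missing_prob", "eq5d_fu_missing_prob",
                "vas_missing_prob")) {
      v <- arm[[f]]
      if (v < 0 || v > 1) abort_config("arm '%s': %s must be in [0,1]", a, f)
    }
    if (arm$n_patients < 0) abort_config("n_patients must be >= 0")
  }
  if (abs(params$time_distance_corr) > 1 ||
      params$within_patient_corr < 0 || params$within_patient_corr > 1)
    abort_config("correlation parameters out of range")
  invisible(params)
}

# Exchangeable correlated Bernoulli draws within a cluster: each draw uses a
# cluster-level value with probability sqrt(rho), else a fresh draw, giving
# pairwise correlation rho and marginal p.
rbern_exch <- function(n, p, rho) {
  home <- stats::rbinom(1, 1, p)
  use_home <- stats::runif(n) < sqrt(rho)
  ifelse(use_home, home, stats::rbinom(n, 1, p))
}

rcat_exch <- function(n, probs, rho) {
  lv <- names(probs)
  home <- sample(lv, 1, prob = probs)
  use_home <- stats::runif(n) < sqrt(rho)
  fresh <- sample(lv, n, replace = TRUE, prob = probs)
  ifelse(use_home, home, fresh)
}

# Expected scored EQ-5D utility when a latent N(m, s) value is snapped to the
# nearest attainable tariff utility (closed form over the 243-state grid).
eq5d_grid <- function(tariff) {
  states <- all_eq5d_states()
  u <- score_eq5d(states, tariff)
  ord <- order(u, states$state)          # deterministic tie-break
  states <- states[ord, ]
  u <- u[ord]
  uniq <- !duplicated(u)
  list(states = states[uniq, , drop = FALSE], utilities = u[uniq],
       cuts = (u[uniq][-1] + u[uniq][-sum(uniq)]) / 2)
}

expected_scored <- function(m, s, grid) {
  p <- diff(c(0, stats::pnorm(grid$cuts, m, s), 1))
  sum(grid$utilities * p)
}

# Latent mean achieving a target scored mean (the discretization is not
# mean-preserving near the ceiling at 1, so the latent mean is solved for).
solve_latent_mean <- function(target, s, grid) {
  stats::uniroot(function(m) expected_scored(m, s, grid) - target,
                 interval = c(-2, 3), tol = 1e-10)$root
}

latent_to_state <- function(latent, grid) {
  idx <- findInterval(latent, grid$cuts) + 1
  grid$states[idx, EQ5D_DIMENSIONS, drop = FALSE]
}

# Normalizing constant making E[travel time] exact under the lognormal
# residual model: time = mean * exp(c z_d + s2 eps) / E[exp(c z_d + s2 eps)],
# where z_d is the standardized (pre-truncation) distance, a normal mixture
# over municipalities.
time_norm_const <- function(arm, rho) {
  cv <- arm$time_sd / arm$time_mean
  sig <- sqrt(log(1 + cv^2))
  cc <- sig * rho
  s2 <- sig * sqrt(1 - rho^2)
  a <- (arm$muni_base_km - sum(arm$muni_weights * arm$muni_base_km)) /
    arm$distance_sd
  v <- arm$distance_noise_sd / arm$distance_sd
  list(c = cc, s2 = s2,
       norm = sum(arm$muni_weights * exp(cc * a + (cc * v)^2 / 2)) *
         exp(s2^2 / 2))
}

generate_arm <- function(arm_name, arm, params, grid) {
  n <- arm$n_patients
  rho_wp <- params$within_patient_corr
  muni <- sample(names(arm$muni_weights), n, replace = TRUE,
                 prob = arm$muni_weights)
  d_raw <- arm$muni_base_km[muni] + stats::rnorm(n, 0, arm$distance_noise_sd)
  distance <- pmax(2, d_raw)
  mu_d <- sum(arm$muni_weights * arm$muni_base_km)
  z_d <- (d_raw - mu_d) / arm$distance_sd

  employment <- sample(names(arm$employment_probs), n, replace = TRUE,
                       prob = arm$employment_probs)
  worker <- employment %in% c("full_time", "part_time")
  on_sick_leave <- ifelse(worker, stats::rbinom(n, 1, arm$sick_leave_prob), 0L)

  # EQ-5D: latent means solved so scored means hit the targets; the
  # follow-up latent shift is solved so the mean *scored* gain equals the
  # injected arm gain despite ceiling effects.
  m0 <- solve_latent_mean(arm$utility_mean, arm$utility_sd, grid)
  s1 <- sqrt(arm$utility_sd^2 + params$gain_sd^2)
  m1 <- solve_latent_mean(arm$utility_mean + arm$gain_mean, s1, grid)
  lat0 <- stats::rnorm(n, m0, arm$utility_sd)
  lat1 <- lat0 + stats::rnorm(n, m1 - m0, params$gain_sd)
  st0 <- latent_to_state(lat0, grid)
  st1 <- latent_to_state(lat1, grid)
  miss0 <- stats::runif(n) < arm$eq5d_missing_prob
  miss1 <- stats::runif(n) < arm$eq5d_fu_missing_prob
  st0[miss0, ] <- NA_integer_
  st1[miss1, ] <- NA_integer_
  names(st0) <- paste0("eq5d_", EQ5D_DIMENSIONS)
  names(st1) <- paste0("eq5d_fu_", EQ5D_DIMENSIONS)
  vas <- round(pmin(100, pmax(0, stats::rnorm(n, arm$vas_mean, arm$vas_sd))))
  vas[stats::runif(n) < arm$vas_missing_prob] <- NA

  n_cons <- 1 + stats::rpois(n, arm$consult_lambda)
  n_cons <- pmin(n_cons, params$max_consultations)

  pid <- sprintf("%s_%04d", substr(arm_name, 1, 3), seq_len(n))
  patients <- data.frame(
    patient_id = pid, arm = rep(arm_name, n),
    age = round(pmin(90, pmax(1, stats::rnorm(n, arm$age_mean, arm$age_sd)))),
    sex = ifelse(stats::rbinom(n, 1, arm$male_prob) == 1, "male", "female"),
    municipality = muni, distance_km = round(distance, 1),
    employment = employment, on_sick_leave = on_sick_leave,
    n_consultations = n_cons, stringsAsFactors = FALSE)
  patients <- cbind(patients, st0, vas = vas, st1)

  # Consultations, vectorized across all patients. Within-patient
  # exchangeable correlation rho: each consultation reuses its patient's
  # cluster-level draw with probability sqrt(rho), else draws fresh.
  tn <- time_norm_const(arm, params$time_distance_corr)
  idx <- rep(seq_len(n), n_cons)
  k <- length(idx)
  exch_bin <- function(p) {
    home <- stats::rbinom(n, 1, p)
    ifelse(stats::runif(k) < sqrt(rho_wp), home[idx], stats::rbinom(k, 1, p))
  }
  home_mode <- sample(names(arm$mode_probs), n, replace = TRUE,
                      prob = arm$mode_probs)
  fresh_mode <- sample(names(arm$mode_probs), k, replace = TRUE,
                       prob = arm$mode_probs)
  mode <- ifelse(stats::runif(k) < sqrt(rho_wp), home_mode[idx], fresh_mode)
  mode[mode == "missing"] <- NA_character_
  tt <- arm$time_mean *
    exp(tn$c * z_d[idx] + tn$s2 * stats::rnorm(k)) / tn$norm
  eligible <- (worker & on_sick_leave == 0)[idx]
  off <- as.integer(exch_bin(arm$take_time_off_prob) == 1 & eligible)
  hours <- ifelse(off == 1, 2 * tt / 60 + params$consult_overhead_hours, 0)
  consultations <- data.frame(
    patient_id = pid[idx], consultation = sequence(n_cons),
    arm = rep(arm_name, k),
    main_mode = mode, ferry = exch_bin(arm$ferry_prob),
    distance_km = round(distance[idx], 1),
    travel_time_min = round(tt, 1),
    companion = exch_bin(arm$companion_prob),
    extra_transport = exch_bin(arm$extra_prob),
    employment = employment[idx], on_sick_leave = on_sick_leave[idx],
    took_time_off_work = off, time_off_hours = round(hours, 2),
    stringsAsFactors = FALSE)
  list(patients = patients, consultations = consultations)
}

#' Generate a synthetic trial
#'
#' @param params a `trial_params` object ([default_trial_params()]).
#' @return list with `patients` (one row per patient, EQ-5D baseline and
#'   follow-up responses) and `consultations` (one row per attended
#'   consultation with travel and working-status fields). Reproducible:
#'   the same params (seed included) give identical tables.
#' @export
generate_trial <- function(params = default_trial_params()) {
  validate_trial_params(params)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)
  grid <- eq5d_grid(default_tariff())
  arms <- lapply(names(params$arms), function(a)
    generate_arm(a, params$arms[[a]], params, grid))
  patients <- do.call(rbind, lapply(arms, `[[`, "patients"))
  consultations <- do.call(rbind, lapply(arms, `[[`, "consultations"))
  if (is.null(consultations)) consultations <- data.frame()
  if (nrow(consultations))
    consultations$consultation_id <-
      paste0(consultations$patient_id, "_c", consultations$consultation)
  rownames(patients) <- rownames(consultations) <- NULL
  list(patients = patients, consultations = consultations)
}

#' Parameter-recovery report
#'
#' Compares targeted marginals with their simulated values and flags
#' |z| > 3 (z = simulated minus target over the Monte-Carlo standard error).
#'
#' @param trial output of [generate_trial()].
#' @param params the `trial_params` that produced it.
#' @param tariff tariff used to score EQ-5D responses.
#' @return data.frame with columns `arm`, `target`, `expected`, `simulated`,
#'   `se`, `z`, `flag`.
#' @export
recovery_report <- function(trial, params, tariff = default_tariff()) {
  qr <- qaly_records(trial$patients, tariff)
  out <- list()
  for (a in names(params$arms)) {
    arm <- params$arms[[a]]
    pat <- trial$patients[trial$patients$arm == a, ]
    con <- trial$consultations[trial$consultations$arm == a, ]
    prop_row <- function(target, x, p) {
      n <- sum(!is.na(x))
      ph <- mean(x, na.rm = TRUE)
      se <- sqrt(max(ph * (1 - ph), 1e-12) / n)
      data.frame(arm = a, target = target, expected = p, simulated = ph,
                 se = se, z = (ph - p) / se, stringsAsFactors = FALSE)
    }
    mean_row <- function(target, x, m) {
      x <- x[!is.na(x)]
      se <- stats::sd(x) / sqrt(length(x))
      data.frame(arm = a, target = target, expected = m, simulated = mean(x),
                 se = se, z = (mean(x) - m) / se, stringsAsFactors = FALSE)
    }
    gains <- arm_mean_qaly(qr$qaly_gain[qr$arm == a])
    out[[a]] <- rbind(
      data.frame(arm = a, target = "n_patients", expected = arm$n_patients,
                 simulated = nrow(pat), se = 0,
                 z = if (nrow(pat) == arm$n_patients) 0 else Inf,
                 stringsAsFactors = FALSE),
      mean_row("consultations_per_patient", pat$n_consultations,
               1 + arm$consult_lambda),
      mean_row("travel_time_min", con$travel_time_min, arm$time_mean),
      mean_row("distance_km", con$distance_km,
               sum(arm$muni_weights * arm$muni_base_km)),
      prop_row("main_mode_private_car",
               ifelse(is.na(con$main_mode), NA, con$main_mode == "private_car"),
               arm$mode_probs[["private_car"]] / (1 - arm$mode_probs[["missing"]])),
      prop_row("main_mode_bus",
               ifelse(is.na(con$main_mode), NA, con$main_mode == "bus"),
               arm$mode_probs[["bus"]] / (1 - arm$mode_probs[["missing"]])),
      prop_row("companion", con$companion, arm$companion_prob),
      prop_row("extra_transport", con$extra_transport, arm$extra_prob),
      prop_row("employment_full_time", pat$employment == "full_time",
               arm$employment_probs[["full_time"]]),
      mean_row("utility_baseline",
               qr$utility_baseline[qr$arm == a], arm$utility_mean),
      data.frame(arm = a, target = "qaly_gain", expected = arm$gain_mean,
                 simulated = gains$mean, se = gains$sd / sqrt(gains$n),
                 z = (gains$mean - arm$gain_mean) / (gains$sd / sqrt(gains$n)),
                 stringsAsFactors = FALSE))
  }
  rep <- do.call(rbind, out)
  rep$flag <- abs(rep$z) > 3
  rownames(rep) <- NULL
  rep
}
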