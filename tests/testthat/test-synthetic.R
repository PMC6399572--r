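test_that("generation is deterministic under a fixed seed", {
  p <- default_trial_params(seed = 123)
  t1 <- generate_trial(p)
  t2 <- generate_trial(p)
  expect_identical(t1, t2)
  t3 <- generate_trial(default_trial_params(seed = 124))
  expect_false(identical(t1$consultations, t3$consultations))
})

test_that("arm sizes are exact and empty parameters give empty tables", {
  tr <- generate_trial(default_trial_params(seed = 5))
  expect_equal(sum(tr$patients$arm == "standard"), 190)
  expect_equal(sum(tr$patients$arm == "telemedicine"), 199)
  p <- default_trial_params()
  p$arms$standard$n_patients <- 0
  p$arms$telemedicine$n_patients <- 0
  e <- generate_trial(p)
  expect_equal(nrow(e$patients), 0)
  expect_equal(nrow(e$consultations), 0)
})

test_that("generated records satisfy the record invariants", {
  tr <- generate_trial(default_trial_params(seed = 8))
  con <- tr$consultations
  expect_true(all(con$distance_km >= 0))
  expect_true(all(con$travel_time_min >= 0))
  expect_true(all(con$consultation >= 1 & con$consultation <= 6))
  # time off implies employed full- or part-time and not on sick leave
  off <- con$took_time_off_work == 1
  expect_true(all(con$employment[off] %in% c("full_time", "part_time")))
  expect_true(all(con$on_sick_leave[off] == 0))
  expect_true(all(con$time_off_hours[off] > 0))
  expect_true(all(con$time_off_hours[!off] == 0))
  expect_true(all(is.na(con$main_mode) |
                    con$main_mode %in% teleCEA:::TRANSPORT_MODES))
  lv <- as.matrix(tr$patients[paste0("eq5d_", teleCEA:::EQ5D_DIMENSIONS)])
  expect_true(all(is.na(lv) | lv %in% 1:3))
  # per-patient fields are constant across a patient's consultations
  expect_true(all(tapply(con$distance_km, con$patient_id,
                         function(x) length(unique(x))) == 1))
})

test_that("recovery report finds no drifted marginal on the default seed", {
  p <- default_trial_params(seed = 20190219)
  rep <- recovery_report(generate_trial(p), p)
  expect_true(all(c("target", "simulated", "z", "flag") %in% names(rep)))
  expect_false(any(rep$flag))
})

test_that("null parameters center the arm QALY difference at zero", {
  diffs <- vapply(1:6, function(s) {
    tr <- generate_trial(null_trial_params(n_per_arm = 150, seed = s))
    qr <- qaly_records(tr$patients)
    arm_mean_qaly(qr$qaly_gain[qr$arm == "telemedicine"])$mean -
      arm_mean_qaly(qr$qaly_gain[qr$arm == "standard"])$mean
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 4 * se + 1e-3)
})

test_that("invalid parameters are rejected", {
  p <- default_trial_params()
  p$arms$standard$mode_probs[1] <- p$arms$standard$mode_probs[1] + 0.3
  expect_error(generate_trial(p), class = "teleCEA_config_error")
  p2 <- default_trial_params()
  p2$arms$telemedicine$companion_prob <- 1.4
  expect_error(generate_trial(p2), class = "teleCEA_config_error")
  expect_error(generate_trial(list()), class = "teleCEA_config_error")
})
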