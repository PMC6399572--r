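test_that("zero distance with a per-km mode costs the user fee only", {
  tc <- travel_cost(toy_consultation(distance_km = 0), toy_fares())
  expect_equal(tc$total, 10)
  expect_equal(tc$patient, 10)
  expect_equal(tc$health_sector, 0)
})

test_that("travel cost arithmetic is transparent for a worked record", {
  # taxi: 2 x (4 + 1*30) = 68; companion +50% = 102; ferry 8; extra 5; fee 10
  rec <- toy_consultation("taxi", 30, companion = 1, extra_transport = 1,
                          ferry = 1)
  tc <- travel_cost(rec, toy_fares())
  expect_equal(tc$health_sector, 68 * 1.5 + 8 + 5)
  expect_equal(tc$total, 68 * 1.5 + 8 + 5 + 10)
})

test_that("travel cost is monotone in distance, companion, extra transport", {
  f <- toy_fares()
  base <- travel_cost(toy_consultation(distance_km = 50), f)$total
  expect_gt(travel_cost(toy_consultation(distance_km = 100), f)$total, base)
  expect_gt(travel_cost(toy_consultation(distance_km = 50, companion = 1),
                        f)$total, base)
  expect_gt(travel_cost(toy_consultation(distance_km = 50,
                                         extra_transport = 1), f)$total, base)
})

test_that("missing main mode is flagged and imputed from the arm mean", {
  f <- toy_fares()
  rec <- travel_cost(toy_consultation(main_mode = NA_character_), f)
  expect_true(rec$flagged)
  expect_true(is.na(rec$total))
  cons <- rbind(toy_consultation("private_car", 100),
                toy_consultation("private_car", 200),
                toy_consultation(NA_character_, 150))
  priced <- price_travel(cons, f)
  expect_equal(priced$travel_health_sector[3],
               mean(priced$travel_health_sector[1:2]))
  expect_true(priced$travel_imputed[3])
  # pure-missing arm cannot be imputed
  expect_error(price_travel(toy_consultation(NA_character_), f),
               class = "teleCEA_data_error")
})

test_that("unknown transport modes are rejected", {
  expect_error(travel_cost(toy_consultation("dogsled"), toy_fares()),
               class = "teleCEA_data_error")
  expect_error(price_travel(toy_consultation("dogsled"), toy_fares()),
               class = "teleCEA_data_error")
})

test_that("production loss applies only to working patients who took time off", {
  f <- toy_fares(wage = 20)
  loss <- function(...) production_loss(toy_consultation(...), f)
  expect_equal(loss(employment = "retired_disability", took_time_off_work = 1,
                    time_off_hours = 8), 0)
  expect_equal(loss(employment = "full_time", took_time_off_work = 1,
                    time_off_hours = 0), 0)
  expect_equal(loss(employment = "part_time", took_time_off_work = 1,
                    time_off_hours = 8), 4 * 20)
  expect_equal(loss(employment = "full_time", took_time_off_work = 1,
                    time_off_hours = 8), 8 * 20)
  expect_equal(loss(employment = "full_time", on_sick_leave = 1,
                    took_time_off_work = 1, time_off_hours = 8), 0)
  expect_equal(loss(employment = "student", took_time_off_work = 1,
                    time_off_hours = 8), 0)
})

test_that("payer split always conserves the total", {
  f <- bundled_fares()
  set.seed(11)
  for (i in 1:20) {
    rec <- toy_consultation(sample(c("taxi", "bus", "private_car"), 1),
                            runif(1, 0, 300), rbinom(1, 1, 0.5),
                            rbinom(1, 1, 0.5), rbinom(1, 1, 0.5))
    tc <- travel_cost(rec, f)
    expect_equal(tc$health_sector + tc$patient, tc$total)
  }
})

test_that("fare schedule validation rejects bad input", {
  expect_error(fare_schedule(modes = list(hovercraft = list(per_km = 1))),
               class = "teleCEA_config_error")
  expect_error(fare_schedule(modes = list(taxi = list(per_km = -1))),
               class = "teleCEA_config_error")
  expect_error(fare_schedule(modes = list(taxi = list(per_km = 1)),
                             user_fee = -2),
               class = "teleCEA_config_error")
})
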