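test_that("bundled cost configuration loads with the documented structure", {
  cfg <- bundled_components()
  expect_s3_class(cfg$components, "cost_components")
  expect_equal(cfg$annuity$discount_rate, 0.03)
  expect_equal(cfg$reference_volume, 300)
  # 4 alternative-specific + 7 shared components on each telemedicine path
  expect_equal(nrow(teleCEA:::components_for(cfg$components, "telemedicine_A")), 11)
  expect_equal(nrow(teleCEA:::components_for(cfg$components, "telemedicine_B")), 11)
  expect_equal(nrow(teleCEA:::components_for(cfg$components, "standard")), 1)
})

test_that("service cost tables reproduce the published annual costs", {
  cfg <- bundled_components()
  a <- service_cost_table(cfg$components, "telemedicine_A", cfg$annuity)
  expect_equal(a$total_investment, 16511)
  expect_equal(a$annualized_investment, 3605)
  expect_equal(a$subtotal, 4855)
  expect_equal(a$additional_costs, 15829)
  expect_equal(a$total_annual, 20684)
  b <- service_cost_table(cfg$components, "telemedicine_B", cfg$annuity)
  expect_equal(b$total_investment, 7811)
  expect_equal(b$annualized_investment, 1706)
  expect_equal(b$total_annual, 17535)
})

test_that("aggregate_annual_cost totals match the table route", {
  cfg <- bundled_components()
  for (alt in c("telemedicine_A", "telemedicine_B")) {
    s <- aggregate_annual_cost(cfg$components, alt, 300, cfg$annuity)
    tab <- service_cost_table(cfg$components, alt, cfg$annuity)
    expect_equal(round_half_up(total_annual_cost(s, 300)), tab$total_annual)
  }
  s_std <- aggregate_annual_cost(cfg$components, "standard", 300, cfg$annuity)
  expect_equal(round_half_up(total_annual_cost(s_std, 300)), 906)
})

test_that("empty component lists give an all-zero summary", {
  empty <- cost_components(character(0), numeric(0), character(0),
                           character(0), character(0), character(0))
  s <- aggregate_annual_cost(empty, "telemedicine_A", 300)
  expect_equal(sum(s$fixed_annual), 0)
  expect_equal(sum(s$variable_per_consultation), 0)
  expect_equal(total_annual_cost(s, 300), 0)
})

test_that("aggregation is additive over disjoint component sets (property)", {
  cfg <- bundled_components()
  set.seed(7)
  for (i in 1:10) {
    take <- runif(nrow(cfg$components)) < 0.5
    s1 <- aggregate_annual_cost(cfg$components[take, ], "telemedicine_A", 300)
    s2 <- aggregate_annual_cost(cfg$components[!take, ], "telemedicine_A", 300)
    s <- aggregate_annual_cost(cfg$components, "telemedicine_A", 300)
    expect_equal(s1$fixed_annual + s2$fixed_annual, s$fixed_annual)
    expect_equal(s1$variable_per_consultation + s2$variable_per_consultation,
                 s$variable_per_consultation)
  }
})

test_that("payer split conserves the societal total", {
  cfg <- bundled_components()
  s <- aggregate_annual_cost(cfg$components, "telemedicine_A", 300)
  s <- add_unit_costs(s, travel_health_sector = 9.69, travel_patient = 31.04,
                      production = 11.04)
  soc <- per_consultation_cost(s, 300, perspective("societal"))
  parts <- (sum(s$fixed_annual["health_sector"]) / 300 +
              s$variable_per_consultation[["health_sector"]]) +
    s$variable_per_consultation[["patient"]] +
    s$variable_per_consultation[["production"]]
  expect_equal(soc, parts)
})

test_that("bad tags and volumes are rejected", {
  cfg <- bundled_components()
  expect_error(aggregate_annual_cost(cfg$components, "carrier_pigeon", 300),
               class = "teleCEA_config_error")
  expect_error(aggregate_annual_cost(cfg$components, "telemedicine_A", 0),
               class = "teleCEA_data_error")
  expect_error(cost_components("x", -5, "investment", "hospital",
                               "telemedicine_A", "health_sector"),
               class = "teleCEA_config_error")
  expect_error(cost_components("x", 5, "one_off", "hospital",
                               "telemedicine_A", "health_sector"),
               class = "teleCEA_config_error")
})
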