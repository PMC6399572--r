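test_that("t test: summary and raw entry points agree (equivalence oracle)", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    y <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 2))
    for (ve in c(TRUE, FALSE)) {
      raw <- two_sample_t(x, y, var_equal = ve)
      smm <- t_test_summary(mean(x), sd(x), length(x),
                            mean(y), sd(y), length(y), var_equal = ve)
      expect_equal(raw$statistic, smm$statistic)
      expect_equal(raw$p_value, smm$p_value)
      # base-R oracle
      bt <- t.test(x, y, var.equal = ve)
      expect_equal(raw$statistic, unname(bt$statistic))
      expect_equal(raw$p_value, bt$p.value)
    }
  }
})

test_that("t test degenerate and identical-sample conventions", {
  expect_equal(two_sample_t(c(1, 1, 1), c(1, 1, 1))$p_value, 1)
  x <- c(3.2, 4.1, 5.0, 2.7)
  expect_equal(two_sample_t(x, x)$p_value, 1, tolerance = 1e-12)
  expect_error(two_sample_t(1, c(1, 2)), class = "teleCEA_data_error")
})

test_that("published travel-time moments give p < 0.001", {
  r <- t_test_summary(277, 94, 243, 47, 43, 293)
  expect_lt(r$p_value, 0.001)
})

test_that("chi-square matches base R and the two-proportion z identity", {
  counts <- matrix(c(66, 257 - 66, 6, 302 - 6), nrow = 2, byrow = TRUE)
  r <- chi_square_2xk(counts)
  b <- suppressWarnings(chisq.test(counts, correct = FALSE))
  expect_equal(r$statistic, unname(b$statistic))
  expect_equal(r$p_value, b$p.value)
  expect_lt(r$p_value, 0.001)
  # 2x2 Pearson statistic equals the squared two-proportion z statistic
  p1 <- 66 / 257; p2 <- 6 / 302; pp <- (66 + 6) / (257 + 302)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 257 + 1 / 302))
  expect_equal(r$statistic, z^2)
})

test_that("chi-square degenerate cases", {
  even <- matrix(c(20, 30, 40, 60), nrow = 2, byrow = TRUE)
  r <- chi_square_2xk(even)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(chi_square_2xk(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               class = "teleCEA_data_error")
  expect_error(chi_square_2xk(matrix(c(1.5, 2, 3, 4), 2)),
               class = "teleCEA_data_error")
  expect_warning(chi_square_2xk(matrix(c(2, 3, 4, 5), 2)), "below 5")
})

test_that("GEE with singleton clusters collapses to logistic regression", {
  set.seed(31)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.4 + 0.9 * x))
  g <- gee_binary(y, x, cluster = seq_len(n))
  m <- glm(y ~ x, family = binomial)
  expect_equal(g$estimate, unname(coef(m)[2]), tolerance = 1e-7)
  # robust SE equals the HC0 sandwich of the GLM (computed independently)
  X <- model.matrix(m); mu <- fitted(m); W <- mu * (1 - mu)
  B <- solve(t(X) %*% (X * W))
  M <- t(X * (y - mu)) %*% (X * (y - mu))
  expect_equal(g$std_error, sqrt((B %*% M %*% B)[2, 2]), tolerance = 1e-7)
  expect_true(g$converged)
})

test_that("GEE recovers a near-zero working correlation when none exists", {
  set.seed(32)
  cl <- rep(1:150, each = 3)
  x <- rep(rbinom(150, 1, 0.5), each = 3)
  y <- rbinom(450, 1, plogis(0.2 * x))
  g <- gee_binary(y, x, cl)
  expect_lt(abs(g$working_correlation), 0.12)
  expect_equal(g$clusters, 150)
})

test_that("GEE guards: cluster counts and separation", {
  expect_error(gee_binary(c(0, 1, 0, 1), c(0, 0, 1, 1), c(1, 1, 2, 2)),
               class = "teleCEA_data_error")
  set.seed(33)
  cl <- 1:60
  x <- rep(0:1, 30)
  y <- ifelse(x == 1, 1L, rbinom(60, 1, 0.5))  # constant in one group
  w <- capture_warnings(gee_binary(y, x, cl))
  expect_true(any(grepl("constant", w)))
})

test_that("descriptive arm report mirrors the table layout", {
  tr <- generate_trial(default_trial_params(seed = 14))
  d <- describe_arms(tr)
  expect_true(all(c("variable", "standard", "telemedicine", "p_value",
                    "p_value_gee") %in% names(d)))
  expect_true("bus_main" %in% d$variable)
  # the bus-share contrast is overwhelming by design of the arms
  expect_lt(d$p_value[d$variable == "bus_main"], 0.001)
  expect_lt(d$p_value[d$variable == "travel_time_min"], 0.001)
})
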