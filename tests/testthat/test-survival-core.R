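test_that("km_survival_at matches hand product-limit computations", {
  # no censoring: empirical survival proportion, exactly
  d <- data.frame(time = c(1, 2, 3, 11, 12, 13, 14, 15, 16, 17),
                  event = c(1, 1, 1, rep(0L, 7)))
  expect_equal(km_survival_at(d, 10), 0.7)
  # no events before t
  d2 <- data.frame(time = rep(12, 5), event = rep(0L, 5))
  expect_equal(km_survival_at(d2, 10), 1)
  # hand product-limit with interleaved censoring: (1,E),(2,C),(3,E),(4,C)
  d3 <- data.frame(time = 1:4, event = c(1L, 0L, 1L, 0L))
  expect_equal(km_survival_at(d3, 5), (1 - 1 / 4) * (1 - 1 / 2))
  # beyond last observed time: carried forward from last event
  expect_equal(km_survival_at(d3, 100), 0.375)
  # random data vs the naive oracle
  set.seed(21)
  for (i in 1:20) {
    dr <- random_dataset(sample(5:60, 1))
    expect_equal(km_survival_at(dr, 10), oracle_km(dr$time, dr$event, 10))
  }
  expect_error(km_survival_at(data.frame(time = numeric(0),
                                         event = integer(0)), 10), "rows")
})

test_that("fit_model recovers generating coefficients and flags bad input", {
  d <- generate_dataset(sim_scenario(0.02, log(2), 0, 10000,
                                     censor_ten_year_prob = 0.1, seed = 31))
  f <- fit_model(d, c("x1", "x2"))
  expect_lt(abs(f$coef[["x1"]] - log(2)), 0.07)
  expect_lt(abs(f$coef[["x2"]]), 0.07)
  expect_true(all(diff(f$baseline$cumhaz) >= 0))
  expect_true(all(f$baseline$cumhaz >= 0))

  # duplicated covariate column: collinear
  d$x3 <- d$x1
  expect_error(fit_model(d, c("x1", "x3")), "collinear")
  # no events
  dn <- data.frame(time = rexp(20) + 0.1, event = rep(0L, 20), x1 = rnorm(20))
  expect_error(fit_model(dn, "x1"), "events")
})

test_that("predicted horizon risk is calibrated and monotone", {
  d <- generate_dataset(sim_scenario(0.02, log(3), log(2), 10000, seed = 32))
  f <- fit_model(d, c("x1", "x2"))
  r <- predict_horizon_risk(f, d, 10)
  expect_true(all(r >= 0 & r <= 1))
  # calibration in the large: mean predicted risk ~ 1 - KM(10)
  expect_lt(abs(mean(r) - (1 - km_survival_at(d, 10))), 0.01)
  # monotone in a covariate with positive coefficient
  nd <- data.frame(x1 = seq(-3, 3, by = 0.5), x2 = 0)
  expect_true(all(diff(predict_horizon_risk(f, nd, 10)) > 0))
  # null model: risk equals 1 - KM within rounding
  f0 <- fit_model(transform(d, z = rnorm(nrow(d))), "z")
  r0 <- predict_horizon_risk(f0, data.frame(z = 0), 10)
  expect_lt(abs(r0 - (1 - km_survival_at(d, 10))), 0.005)
  expect_error(predict_horizon_risk(f, d, -1), "non-negative")
})

test_that("risk models survive a JSON round trip", {
  d <- generate_dataset(sim_scenario(0.02, log(2), log(1.5), 2000, seed = 33))
  f <- fit_model(d, c("x1", "x2"))
  path <- tempfile(fileext = ".json")
  write_risk_model(f, path)
  f2 <- read_risk_model(path)
  expect_equal(f2$coef, f$coef)
  expect_equal(predict_horizon_risk(f2, d[1:50, ], 10),
               predict_horizon_risk(f, d[1:50, ], 10))
})

test_that("horizon-truncated concordance matches exhaustive enumeration", {
  # perfect ordering, no censoring
  dp <- data.frame(time = 1:6, event = rep(1L, 6))
  expect_equal(harrell_c_horizon(seq(0.9, 0.4, by = -0.1), dp, 10), 1)
  # all predictions identical: every usable pair tied
  expect_equal(harrell_c_horizon(rep(0.3, 6), dp, 10), 0.5)

  set.seed(41)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    d <- random_dataset(n)
    risks <- round(runif(n), 2)   # ties on purpose
    o <- oracle_harrell_c(risks, d$time, d$event, 10)
    if (is.na(o) || sum(d$event == 1 & d$time <= 10) == 0) next
    expect_identical(harrell_c_horizon(risks, d, 10), o)
  }
  # rank-based equivalence with no censoring, all events before t
  set.seed(42)
  for (i in 1:10) {
    n <- 30
    d <- data.frame(time = runif(n, 0.1, 9), event = rep(1L, n))
    risks <- rnorm(n)
    expect_equal(harrell_c_horizon(risks, d, 10),
                 oracle_harrell_c(risks, d$time, d$event, 10))
  }
  expect_error(
    harrell_c_horizon(runif(4), data.frame(time = rep(12, 4),
                                           event = rep(1L, 4)), 10),
    "no events")
})

test_that("concordance agrees with the survival package on clean data", {
  d <- generate_dataset(sim_scenario(0.02, log(3), log(2), 3000, seed = 51))
  f <- fit_model(d, c("x1", "x2"))
  r <- predict_horizon_risk(f, d, 10)
  d10 <- transform(d, event = ifelse(time > 10, 0L, event),
                   time = pmin(time, 10))
  cs <- survival::concordance(survival::Surv(time, event) ~ r, data = d10,
                              reverse = TRUE)
  expect_equal(harrell_c_horizon(r, d, 10), unname(cs$concordance),
               tolerance = 1e-3)
})

test_that("odds ratio for a null covariate is near 1", {
  set.seed(61)
  d <- generate_dataset(sim_scenario(0.02, log(2), 0, 10000, seed = 62))
  or <- ten_year_odds_ratio(d, "x2", adjust_for = "x1")
  expect_gt(as.numeric(or), 0.9)
  expect_lt(as.numeric(or), 1.1)
  # exclusion variant runs and is also near 1
  or2 <- ten_year_odds_ratio(d, "x2", censored = "exclude")
  expect_lt(abs(as.numeric(or2) - 1), 0.1)
  # degenerate outcome class
  dd <- data.frame(time = rep(1, 50), event = rep(1L, 50), x = rnorm(50))
  expect_error(ten_year_odds_ratio(dd, "x"), "non-empty")
})
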