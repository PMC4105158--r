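make_cohort <- function(n = 1500, seed = 101, beta_added = log(1.6)) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  tt <- -log(runif(n)) / (0.02 * exp(log(2) * x1 + beta_added * x2))
  cc <- rexp(n, censor_rate_from_horizon_prob(0.1, 10))
  data.frame(time = pmin(tt, cc, 12), event = as.integer(tt <= pmin(cc, 12)),
             x1 = x1, x2 = x2)
}

test_that("point estimates equal direct calls to the measure functions", {
  d <- make_cohort()
  rep0 <- compare_models(d, "x1", "x2", B = 0)
  fb <- fit_model(d, "x1"); ff <- fit_model(d, c("x1", "x2"))
  rb <- predict_horizon_risk(fb, d, 10)
  rf <- predict_horizon_risk(ff, d, 10)
  m <- rep0$measures
  expect_equal(m$difference[m$measure == "c_statistic"],
               harrell_c_horizon(rf, d, 10) - harrell_c_horizon(rb, d, 10))
  expect_equal(m$difference[m$measure == "nri_continuous"],
               nri_continuous(rb, rf, d))
  expect_equal(m$difference[m$measure == "net_benefit_per_1000"],
               1000 * (net_benefit(rf, d, 0.2) - net_benefit(rb, d, 0.2)))
  # B = 0: no intervals
  expect_true(all(is.na(m$ci_lower)))
})

test_that("per-1000 rows are exactly 1000 times the per-person measures", {
  d <- make_cohort(seed = 102)
  rep0 <- compare_models(d, "x1", "x2", B = 0)
  m <- rep0$measures
  cfg <- utility_config(threshold = 0.2)
  ff <- fit_model(d, c("x1", "x2"))
  rf <- predict_horizon_risk(ff, d, 10)
  expect_identical(m$full[m$measure == "net_benefit_per_1000"],
                   1000 * net_benefit(rf, d, 0.2))
  expect_identical(m$full[m$measure == "efly_per_1000"],
                   1000 * efly_gain(rf, d, cfg))
})

test_that("bootstrap intervals are reproducible and bracket the estimate", {
  d <- make_cohort(n = 800, seed = 103)
  r1 <- compare_models(d, "x1", "x2", B = 60, seed = 5)
  r2 <- compare_models(d, "x1", "x2", B = 60, seed = 5)
  expect_identical(r1$measures, r2$measures)
  m <- r1$measures
  expect_true(all(m$ci_lower <= m$ci_upper, na.rm = TRUE))
  # point estimates identical to the B = 0 run: no bootstrap contamination
  m0 <- compare_models(d, "x1", "x2", B = 0)$measures
  expect_identical(m$difference, m0$difference)
})

test_that("a null added covariate gives intervals covering zero", {
  d <- make_cohort(n = 2000, seed = 104, beta_added = 0)
  r <- compare_models(d, "x1", "x2", B = 100, seed = 6)
  m <- r$measures
  dc <- m[m$measure == "c_statistic", ]
  expect_true(dc$ci_lower <= 0 && dc$ci_upper >= 0)
})

test_that("report_table has the fixed nine-row layout with dashes for gaps", {
  d <- make_cohort(n = 600, seed = 105)
  r <- compare_models(d, "x1", "x2", B = 0)
  tab <- report_table(r)
  expect_equal(nrow(tab), 9)
  expect_equal(tab$measure,
               c("sensitivity", "specificity", "c_binary", "c_statistic",
                 "nri_binary", "nri_continuous", "nri_categorical",
                 "net_benefit_per_1000", "efly_per_1000"))
  expect_true(all(c("base", "full", "difference", "ci_95") %in% names(tab)))
  # NRI rows have no per-model value; absent CIs render as dashes
  expect_equal(tab$base[tab$measure == "nri_binary"], "-")
  expect_true(all(tab$ci_95 == "-"))
  # round trip through the writers
  csv <- tempfile(fileext = ".csv"); md <- tempfile(fileext = ".md")
  write_report(r, csv = csv, md = md)
  expect_equal(nrow(utils::read.csv(csv)), 9)
  expect_length(readLines(md), 11)
})

test_that("disjoint covariate sets are enforced", {
  d <- make_cohort(n = 300, seed = 106)
  expect_error(compare_models(d, "x1", "x1", B = 0), "disjoint")
})

test_that("female-like synthetic cohorts shift sensitivity up at the 20% cutpoint", {
  # qualitative direction check on the emulated cohort: adding blood pressure
  # raises sensitivity and lowers specificity in the majority of draws
  dirs <- vapply(1:5, function(i) {
    d <- generate_framingham_like(framingham_cohort_spec("women",
                                                         seed = 200 + i))
    base_cov <- c("age", "tc", "hdl", "smoker", "diabetes", "bpmeds")
    fb <- fit_model(d, base_cov)
    ff <- fit_model(d, c(base_cov, "sbp"))
    sb <- km_sensitivity_specificity(predict_horizon_risk(fb, d, 10), d, 0.2)
    sf <- km_sensitivity_specificity(predict_horizon_risk(ff, d, 10), d, 0.2)
    c(sf$sensitivity - sb$sensitivity, sf$specificity - sb$specificity)
  }, numeric(2))
  expect_gt(mean(dirs[1, ] > 0), 0.5)
  expect_gt(mean(dirs[2, ] < 0), 0.5)
})
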