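test_that("KM sensitivity/specificity reduce to counting without censoring", {
  # four subjects, events for the two high-risk ones only
  d <- data.frame(time = c(2, 5, 12, 13), event = c(1L, 1L, 0L, 0L))
  s <- km_sensitivity_specificity(c(0.9, 0.8, 0.1, 0.05), d, 0.2)
  expect_equal(s$sensitivity, 1)
  expect_equal(s$specificity, 1)
  expect_equal(s$binary_c, 1)

  # all risks below the cutpoint
  s0 <- km_sensitivity_specificity(rep(0.05, 4), d, 0.2)
  expect_equal(s0$sensitivity, 0)
  expect_equal(s0$specificity, 1)

  # risk exactly at the cutpoint is classified low
  s1 <- km_sensitivity_specificity(c(0.2, 0.8, 0.1, 0.05), d, 0.2)
  expect_equal(s1$prop_high, 0.25)
})

test_that("KM sensitivity/specificity match a hand plug-in with censoring", {
  # 8 subjects; one censored early in the high-risk group
  time <- c(1, 4, 3, 12, 2, 11, 12, 13)
  event <- c(1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L)
  risks <- c(0.9, 0.8, 0.7, 0.6, 0.1, 0.1, 0.05, 0.05)
  d <- data.frame(time = time, event = event)
  s <- km_sensitivity_specificity(risks, d, 0.2, t = 10)
  km_high <- oracle_km(time[risks > 0.2], event[risks > 0.2], 10)
  km_low <- oracle_km(time[risks <= 0.2], event[risks <= 0.2], 10)
  km_all <- oracle_km(time, event, 10)
  expect_equal(s$sensitivity, 4 * (1 - km_high) / (8 * (1 - km_all)))
  expect_equal(s$specificity, 4 * km_low / (8 * km_all))
})

test_that("binary c difference and binary NRI follow their identities", {
  d <- data.frame(time = c(2, 5, 12, 13, 14, 3), event = c(1, 1, 0, 0, 0, 1))
  base <- km_sensitivity_specificity(c(0.9, 0.1, 0.1, 0.3, 0.1, 0.6), d, 0.2)
  full <- km_sensitivity_specificity(c(0.9, 0.5, 0.1, 0.1, 0.1, 0.7), d, 0.2)
  expect_equal(binary_c_difference(base, full),
               0.5 * ((full$sensitivity - base$sensitivity) +
                        (full$specificity - base$specificity)))
  expect_equal(nri_binary(base, full), 2 * binary_c_difference(base, full))
  expect_equal(binary_c_difference(base, base), 0)
  # offsetting changes cancel: published-style arithmetic
  expect_equal(0.5 * (0.064 + (-0.013)), 0.0255)
  expect_equal(0.5 * (0.2 + (-0.2)), 0)
  # mismatched cutpoints are not comparable
  other <- km_sensitivity_specificity(c(0.9, 0.5, 0.1, 0.1, 0.1, 0.7), d, 0.1)
  expect_error(binary_c_difference(base, other), "not comparable")
})

test_that("continuous NRI reproduces direct formula arithmetic", {
  # nU = 4 with 3 events, nD = 6 with 1 event, n = 10, 4 events, no censoring
  time <- c(1, 2, 3, 12, 4, rep(13, 5))
  event <- c(1, 1, 1, 0, 1, rep(0, 5))
  base <- rep(0.2, 10)
  full <- base + c(rep(0.1, 3), 0.1, rep(-0.1, 6))  # up: 3 events + 1 non-event
  d <- data.frame(time = time, event = event)
  expect_equal(nri_continuous(base, full, d), (3 - 1) / 4 + (5 - 1) / 6)
  # identical risks: nothing moves
  expect_equal(nri_continuous(base, base, d), 0)
})

test_that("continuous NRI matches a hand KM plug-in under censoring", {
  set.seed(71)
  n <- 20
  d <- random_dataset(n)
  base <- runif(n)
  full <- pmin(pmax(base + runif(n, -0.2, 0.2), 0), 1)
  up <- full > base; down <- full < base
  pU <- 1 - oracle_km(d$time[up], d$event[up], 10)
  pD <- 1 - oracle_km(d$time[down], d$event[down], 10)
  p <- 1 - oracle_km(d$time, d$event, 10)
  hand <- (pU * sum(up) - pD * sum(down)) / (n * p) +
    ((1 - pD) * sum(down) - (1 - pU) * sum(up)) / (n * (1 - p))
  expect_equal(nri_continuous(base, full, d), hand)
})

test_that("categorical NRI reproduces direct formula arithmetic", {
  # 50 events (10 up, 5 down), 100 non-events (10 up, 20 down), one cutpoint
  n <- 150
  ev <- c(rep(1L, 50), rep(0L, 100))
  time <- ifelse(ev == 1, 5, 12)
  base <- rep(0.15, n)
  full <- rep(0.15, n)
  full[c(1:10, 51:60)] <- 0.25        # 10 events + 10 non-events move up
  base[c(11:15, 61:80)] <- 0.25       # 5 events + 20 non-events start high
  full[c(11:15, 61:80)] <- 0.15       # ... and move down
  d <- data.frame(time = time, event = ev)
  expect_equal(nri_categorical(base, full, d, cutpoints = 0.2),
               (10 - 5) / 50 + (20 - 10) / 100)
  # no reclassification across boundaries
  expect_equal(nri_categorical(base, base, d, cutpoints = 0.2), 0)
  expect_error(nri_categorical(base, full, d, cutpoints = c(0.2, 0.1)),
               "increasing")
})

test_that("categorical NRI uses per-cell KM estimates under censoring", {
  set.seed(72)
  n <- 40
  d <- random_dataset(n)
  base <- runif(n)
  full <- pmin(pmax(base + runif(n, -0.3, 0.3), 0.01), 0.99)
  cuts <- c(0.1, 0.2)
  catg <- function(r) 1L + rowSums(outer(r, cuts, ">"))
  cb <- catg(base); cf <- catg(full)
  ev_mat <- ne_mat <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    sel <- cb == i & cf == j
    if (!any(sel)) next
    p <- if (any(d$event[sel] == 1)) 1 - oracle_km(d$time[sel], d$event[sel], 10) else 0
    ev_mat[i, j] <- sum(sel) * p
    ne_mat[i, j] <- sum(sel) * (1 - p)
  }
  hand <- (sum(ev_mat[upper.tri(ev_mat)]) - sum(ev_mat[lower.tri(ev_mat)])) /
    sum(ev_mat) +
    (sum(ne_mat[lower.tri(ne_mat)]) - sum(ne_mat[upper.tri(ne_mat)])) /
    sum(ne_mat)
  expect_equal(nri_categorical(base, full, d, cuts), hand)

  tab <- reclassification_table(base, full, d, cuts)
  expect_equal(sum(tab$counts), n)
  expect_true(all(tab$event_prob >= 0 & tab$event_prob <= 1))
  expect_equal(tab$n_up + tab$n_down, sum(cb != cf))
  df <- as.data.frame(tab)
  expect_equal(sum(df$count), n)
})

test_that("swapping base and full negates every reclassification measure", {
  set.seed(73)
  for (i in 1:5) {
    n <- 60
    d <- random_dataset(n)
    base <- runif(n, 0.01, 0.99)
    full <- pmin(pmax(base + runif(n, -0.3, 0.3), 0.01), 0.99)
    sb <- km_sensitivity_specificity(base, d, 0.2)
    sf <- km_sensitivity_specificity(full, d, 0.2)
    expect_equal(binary_c_difference(sf, sb), -binary_c_difference(sb, sf))
    expect_equal(nri_binary(sf, sb), -nri_binary(sb, sf))
    expect_equal(nri_continuous(full, base, d), -nri_continuous(base, full, d))
    expect_equal(nri_categorical(full, base, d, c(0.1, 0.2)),
                 -nri_categorical(base, full, d, c(0.1, 0.2)))
    expect_true(abs(nri_categorical(base, full, d, c(0.1, 0.2))) <= 2)
  }
})

test_that("all measures reduce to counting formulas under zero censoring", {
  set.seed(74)
  for (i in 1:10) {
    n <- sample(20:50, 1)
    time <- round(runif(n, 0.5, 20), 2)
    d <- data.frame(time = time, event = rep(1L, n))
    base <- runif(n, 0.01, 0.99)
    full <- pmin(pmax(base + runif(n, -0.3, 0.3), 0.01), 0.99)
    if (all(time <= 10) || all(time > 10)) next
    o <- oracle_counting(base, full, time, d$event, 0.2, c(0.1, 0.2))
    sb <- km_sensitivity_specificity(base, d, 0.2)
    sf <- km_sensitivity_specificity(full, d, 0.2)
    expect_equal(sb$sensitivity, o$sens_base)
    expect_equal(sf$sensitivity, o$sens_full)
    expect_equal(sb$specificity, o$spec_base)
    expect_equal(sf$specificity, o$spec_full)
    expect_equal(net_benefit(base, d, 0.2), o$nb_base)
    expect_equal(net_benefit(full, d, 0.2), o$nb_full)
    expect_equal(nri_continuous(base, full, d), o$nri_cont)
    expect_equal(nri_categorical(base, full, d, c(0.1, 0.2)), o$nri_cat)
  }
})
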