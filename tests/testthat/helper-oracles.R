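# Independent oracles used across the suite. All are deliberately naive
# (exhaustive enumeration / direct counting) and share no code with the
# package implementations they check.

# Exhaustive O(n^2) pair enumeration for the horizon-truncated concordance.
oracle_harrell_c <- function(risks, time, event, t = 10) {
  over <- time > t
  time <- pmin(time, t)
  event <- ifelse(over, 0L, as.integer(event))
  conc <- tied <- usable <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1L) next
    for (j in seq_len(n)) {
      if (j == i || time[j] <= time[i]) next
      usable <- usable + 1
      if (risks[i] > risks[j]) conc <- conc + 1
      else if (risks[i] == risks[j]) tied <- tied + 1
    }
  }
  if (usable == 0) return(NA_real_)
  (conc + 0.5 * tied) / usable
}

# Hand product-limit estimate at t (events-first at ties).
oracle_km <- function(time, event, t) {
  s <- 1
  for (u in sort(unique(time[event == 1 & time <= t]))) {
    at_risk <- sum(time > u) + sum(time == u)  # events-first convention
    d <- sum(time == u & event == 1)
    s <- s * (1 - d / at_risk)
  }
  s
}

# Counting-based measures valid only under zero censoring by t: every
# subject's horizon status is observed directly.
oracle_counting <- function(base_risks, full_risks, time, event, cutpoint,
                            cutpoints, t = 10) {
  ev <- event == 1 & time <= t
  ne <- !ev
  high_b <- base_risks > cutpoint
  high_f <- full_risks > cutpoint
  sens <- function(high) sum(high & ev) / sum(ev)
  spec <- function(high) sum(!high & ne) / sum(ne)
  nb <- function(high) {
    sum(high & ev) / length(ev) -
      sum(high & ne) / length(ev) * cutpoint / (1 - cutpoint)
  }
  up <- full_risks > base_risks
  down <- full_risks < base_risks
  n <- length(ev)
  nri_cont <- (sum(up & ev) - sum(down & ev)) / sum(ev) +
    (sum(down & ne) - sum(up & ne)) / sum(ne)
  catg <- function(r) 1L + rowSums(outer(r, cutpoints, ">"))
  cb <- catg(base_risks); cf <- catg(full_risks)
  nri_cat <- (sum(ev & cf > cb) - sum(ev & cf < cb)) / sum(ev) +
    (sum(ne & cf < cb) - sum(ne & cf > cb)) / sum(ne)
  list(sens_base = sens(high_b), sens_full = sens(high_f),
       spec_base = spec(high_b), spec_full = spec(high_f),
       nb_base = nb(high_b), nb_full = nb(high_f),
       nri_cont = nri_cont, nri_cat = nri_cat)
}

# Small random survival dataset with optional censoring.
random_dataset <- function(n, censor = TRUE) {
  time <- round(rexp(n, rate = 0.08) + 0.05, 3)
  event <- if (censor) rbinom(n, 1L, 0.7) else rep(1L, n)
  data.frame(time = time, event = event)
}
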