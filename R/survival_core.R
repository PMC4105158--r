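#' Kaplan-Meier survival probability at a time point
#'
#' Product-limit estimate of event-free survival at `t`, computed with
#' [survival::survfit()] (ties between events and censorings at the same
#' time are handled with the usual events-first convention). If `t` lies
#' beyond the last observed time while subjects were still at risk, the
#' estimate at the last event time is carried forward.
#'
#' @param data A survival `data.frame` (columns `time`, `event`), or any
#'   subset of rows of one.
#' @param t Time in years.
#' @return Survival probability in `[0, 1]`.
#' @export
km_survival_at <- function(data, t) {
  validate_survival_data(data)
  if (length(t) != 1L || is.na(t) || t < 0)
    stop("`t` must be a single non-negative time", call. = FALSE)
  .km_at(data$time, data$event, t)
}

# fast internal KM-at-t on raw vectors (callers have validated)
.km_at <- function(time, event, t) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, se.fit = FALSE)
  i <- findInterval(t, sf$time)
  if (i == 0L) 1 else sf$surv[i]
}

#' Fit a proportional-hazards model with a Breslow baseline
#'
#' Thin wrapper around [survival::coxph()] (Efron tie handling) that also
#' extracts the Breslow-type baseline cumulative hazard at covariate values
#' zero, which [predict_horizon_risk()] turns into absolute risks.
#'
#' @param data A survival `data.frame` containing `time`, `event` and the
#'   covariates.
#' @param covariates Character vector of covariate column names.
#' @return An object of class `risk_model`: coefficients (log hazard
#'   ratios), their standard errors, the baseline cumulative hazard step
#'   function (`data.frame` of `time`, `cumhaz`), and fit metadata.
#' @export
fit_model <- function(data, covariates) {
  validate_survival_data(data, covariates)
  if (sum(data$event) < 1L) stop("no events in `data`; cannot fit", call. = FALSE)
  if (length(unique(data$time[data$event == 1])) < 2L)
    stop("need at least 2 distinct event times", call. = FALSE)
  f <- stats::reformulate(covariates,
                          response = quote(survival::Surv(time, event)))
  warn <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(f, data = data, ties = "efron", x = FALSE, y = TRUE),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("model fit failed: collinear or inestimable covariates (",
         paste(names(beta)[is.na(beta)], collapse = ", "), ")", call. = FALSE)
  bad <- grepl("converge|infinite|out of iterations|coefficient may be infinite",
               warn, ignore.case = TRUE)
  if (any(bad))
    stop("model fit did not converge: ", paste(warn[bad], collapse = "; "),
         call. = FALSE)
  zero <- as.data.frame(as.list(stats::setNames(rep(0, length(covariates)),
                                                covariates)))
  sf <- survival::survfit(fit, newdata = zero, se.fit = FALSE,
                          stype = 2, ctype = 1)
  structure(
    list(coef = beta,
         se = sqrt(diag(fit$var)),
         covariates = covariates,
         baseline = data.frame(time = sf$time, cumhaz = sf$cumhaz),
         n = fit$n, nevent = fit$nevent, loglik = fit$loglik),
    class = "risk_model"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("Proportional-hazards model (%d subjects, %d events)\n",
              x$n, x$nevent))
  hr <- exp(x$coef)
  lo <- exp(x$coef - 1.96 * x$se)
  hi <- exp(x$coef + 1.96 * x$se)
  for (i in seq_along(hr))
    cat(sprintf("  %-12s HR %.3f (95%% CI %.3f, %.3f)\n",
                x$covariates[i], hr[i], lo[i], hi[i]))
  invisible(x)
}

#' Per-subject predicted risk of an event by a horizon
#'
#' Absolute risk `1 - exp(-H0(t) * exp(lp))` where `H0` is the fitted
#' Breslow baseline cumulative hazard and `lp` the subject's linear
#' predictor.
#'
#' @param model A `risk_model` from [fit_model()].
#' @param data Data containing the model covariates.
#' @param t Horizon in years (non-negative).
#' @return Numeric vector of risks in `[0, 1]`, one per row of `data`.
#' @export
predict_horizon_risk <- function(model, data, t) {
  if (!inherits(model, "risk_model"))
    stop("`model` must be a `risk_model`", call. = FALSE)
  if (length(t) != 1L || is.na(t) || t < 0)
    stop("`t` must be a single non-negative time", call. = FALSE)
  miss <- setdiff(model$covariates, names(data))
  if (length(miss))
    stop("data lacks model covariates: ", paste(miss, collapse = ", "),
         call. = FALSE)
  i <- findInterval(t, model$baseline$time)
  H0 <- if (i == 0L) 0 else model$baseline$cumhaz[i]
  lp <- drop(as.matrix(data[, model$covariates, drop = FALSE]) %*% model$coef)
  -expm1(-H0 * exp(lp))
}

#' Serialize / restore a fitted risk model
#'
#' @param model A `risk_model`.
#' @param path File path for the JSON representation.
#' @return `write_risk_model()` returns `path` invisibly;
#'   `read_risk_model()` returns the restored `risk_model`.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  obj <- list(coef = as.list(model$coef), se = as.list(model$se),
              covariates = model$covariates,
              baseline_time = model$baseline$time,
              baseline_cumhaz = model$baseline$cumhaz,
              n = model$n, nevent = model$nevent)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(coef = unlist(obj$coef), se = unlist(obj$se),
         covariates = obj$covariates,
         baseline = data.frame(time = obj$baseline_time,
                               cumhaz = obj$baseline_cumhaz),
         n = obj$n, nevent = obj$nevent, loglik = NULL),
    class = "risk_model"
  )
}

#' Harrell's c-statistic with follow-up truncated at a horizon
#'
#' Concordance between predicted risks and observed survival, with all
#' follow-up truncated at `t` first (events after `t` count as censored at
#' `t`). Each subject with an event before the horizon is paired with every
#' other subject; a pair is usable when the observed times differ and the
#' partner was still under observation at the index event time. A usable
#' pair is concordant when the subject with the shorter observed time has
#' the higher predicted risk, and tied when the predictions are equal:
#' `c = (concordant + 0.5 * tied) / usable`.
#'
#' The implementation counts pairs in `O(n log n)` with a Fenwick tree over
#' risk ranks; it agrees exactly with exhaustive pair enumeration.
#'
#' @param risks Predicted risks (any monotone risk score), one per subject.
#' @param data Survival `data.frame` aligned with `risks`.
#' @param t Horizon in years (default 10).
#' @return The c-statistic in `[0, 1]`.
#' @export
harrell_c_horizon <- function(risks, data, t = 10) {
  validate_survival_data(data)
  if (length(risks) != nrow(data))
    stop("`risks` must align with `data`", call. = FALSE)
  if (anyNA(risks)) stop("`risks` must not contain NA", call. = FALSE)
  tr <- .truncate_followup(data$time, data$event, t)
  if (sum(tr$event) == 0L)
    stop("no events before the horizon; c-statistic undefined", call. = FALSE)
  .concordance_fenwick(risks, tr$time, tr$event)
}

.truncate_followup <- function(time, event, t) {
  over <- time > t
  list(time = pmin(time, t), event = ifelse(over, 0L, as.integer(event)))
}

# Fenwick-tree pair counting. Subjects are processed in increasing time
# order; at each distinct time every subject with that time leaves the risk
# set, then each event at that time is compared against everyone remaining
# (all with strictly longer observed time).
.concordance_fenwick <- function(risks, time, event) {
  n <- length(risks)
  rk <- match(risks, sort(unique(risks)))   # 1..m, ties share a rank
  m <- max(rk)
  tree <- numeric(m)
  add <- function(i, v) {
    while (i <= m) { tree[i] <<- tree[i] + v; i <- i + bitwAnd(i, -i) }
  }
  cum <- function(i) {          # count of ranks <= i still in the risk set
    s <- 0
    while (i > 0L) { s <- s + tree[i]; i <- i - bitwAnd(i, -i) }
    s
  }
  for (i in seq_len(n)) add(rk[i], 1)
  remaining <- n
  ord <- order(time)
  conc <- 0; tied <- 0; usable <- 0
  i <- 1L
  while (i <= n) {
    j <- i
    ti <- time[ord[i]]
    while (j <= n && time[ord[j]] == ti) j <- j + 1L
    grp <- ord[i:(j - 1L)]
    for (g in grp) add(rk[g], -1)          # leave the risk set
    remaining <- remaining - length(grp)
    if (remaining > 0L) {
      for (g in grp[event[grp] == 1L]) {
        r <- rk[g]
        below <- cum(r - 1L)               # lower risk, longer time
        ateq <- cum(r) - below
        conc <- conc + below
        tied <- tied + ateq
        usable <- usable + remaining
      }
    }
    i <- j
  }
  if (usable == 0)
    stop("no usable pairs; c-statistic undefined", call. = FALSE)
  (conc + 0.5 * tied) / usable
}

#' Odds ratio for event-by-horizon status
#'
#' Fits a logistic model for the binary outcome "event by `t` years" and
#' returns the odds ratio per 1 sample standard deviation of `covariate`.
#' Because a constant hazard ratio does not translate into a constant odds
#' ratio, this odds ratio grows with the mean risk of the population; it is
#' the diagnostic that explains why rank-based measures drift upward in
#' high-risk populations.
#'
#' Subjects censored event-free before `t` have unknown horizon status. With
#' `censored = "nonevent"` (default) they are kept as non-events — with
#' light censoring this is how a cohort analysis would typically count them;
#' with `censored = "exclude"` they are dropped.
#'
#' @param data Survival `data.frame` containing `covariate`.
#' @param covariate Name of the covariate of interest.
#' @param adjust_for Character vector of additional covariates to adjust
#'   for (e.g. the baseline model covariate); default none.
#' @param t Horizon in years (default 10).
#' @param censored How to treat subjects censored event-free before `t`.
#' @return Odds ratio per 1 SD (numeric scalar) with attributes `log_or`
#'   and `se`.
#' @export
ten_year_odds_ratio <- function(data, covariate, adjust_for = character(0),
                                t = 10, censored = c("nonevent", "exclude")) {
  censored <- match.arg(censored)
  validate_survival_data(data, c(covariate, adjust_for))
  case <- data$event == 1 & data$time <= t
  known <- case | data$time >= t
  keep <- if (censored == "exclude") known else rep(TRUE, nrow(data))
  y <- as.integer(case[keep])
  if (sum(y) == 0L || sum(y) == length(y))
    stop("both horizon outcome classes must be non-empty", call. = FALSE)
  d <- data[keep, c(covariate, adjust_for), drop = FALSE]
  d <- as.data.frame(lapply(d, function(v) v / stats::sd(v)))
  d$.y <- y
  warn <- character(0)
  fit <- withCallingHandlers(
    stats::glm(stats::reformulate(c(covariate, adjust_for), response = ".y"),
               family = stats::binomial(), data = d),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
    }
  )
  if (any(grepl("fitted probabilities numerically 0 or 1", warn)) ||
      !fit$converged)
    stop("logistic estimation failed (separation or non-convergence)",
         call. = FALSE)
  b <- stats::coef(fit)[covariate]
  se <- sqrt(diag(stats::vcov(fit)))[covariate]
  structure(unname(exp(b)), log_or = unname(b), se = unname(se))
}
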