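#' Exponential censoring rate from a horizon probability
#'
#' Converts "probability `p` of being censored by `horizon` years" into the
#' rate of the exponential censoring distribution, i.e. the `r` solving
#' `1 - exp(-r * horizon) = p`.
#'
#' @param p Probability of censoring by `horizon`; in `[0, 1)`.
#' @param horizon Horizon in years; positive.
#' @return Censoring hazard rate per year (0 when `p = 0`).
#' @examples
#' censor_rate_from_horizon_prob(0.1, 10) # -log(0.9)/10
#' @export
censor_rate_from_horizon_prob <- function(p, horizon = 10) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p >= 1)
    stop("`p` must be a single probability in [0, 1)", call. = FALSE)
  if (!is.numeric(horizon) || length(horizon) != 1L || is.na(horizon) || horizon <= 0)
    stop("`horizon` must be a single positive number", call. = FALSE)
  -log1p(-p) / horizon
}

#' Simulation scenario for the Cox-exponential model
#'
#' One cell of the simulation design: event times follow
#' `T = -log(U) / (lambda * exp(beta1 * x1 + beta2 * x2))` with `x1`, `x2`
#' independent standard normal, and censoring times are exponential with a
#' given probability of censoring by the horizon.
#'
#' @param lambda Baseline hazard rate (events per person-year), positive.
#' @param beta1,beta2 Log hazard ratios per 1 SD of `x1` and `x2`.
#' @param n Number of subjects (at least 2).
#' @param censor_ten_year_prob Probability of censoring by `horizon`; in `[0, 1)`.
#' @param horizon Risk horizon in years (default 10).
#' @param seed Optional integer seed making [generate_dataset()] deterministic.
#' @return An object of class `sim_scenario`.
#' @seealso [generate_dataset()], [solve_baseline_hazard()]
#' @export
sim_scenario <- function(lambda, beta1, beta2, n,
                         censor_ten_year_prob = 0.10,
                         horizon = 10, seed = NULL) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L,
            is.numeric(beta1), length(beta1) == 1L,
            is.numeric(beta2), length(beta2) == 1L)
  if (is.na(lambda) || lambda <= 0)
    stop("`lambda` must be > 0", call. = FALSE)
  if (length(n) != 1L || is.na(n) || n < 2 || n != round(n))
    stop("`n` must be an integer >= 2", call. = FALSE)
  if (censor_ten_year_prob < 0 || censor_ten_year_prob >= 1)
    stop("`censor_ten_year_prob` must be in [0, 1)", call. = FALSE)
  if (horizon <= 0) stop("`horizon` must be > 0", call. = FALSE)
  structure(
    list(lambda = lambda, beta1 = beta1, beta2 = beta2, n = as.integer(n),
         censor_ten_year_prob = censor_ten_year_prob,
         horizon = horizon, seed = seed),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "Cox-exponential scenario: lambda=%g, HR1=%.3g, HR2=%.3g, n=%d, censor %g%% by %gy\n",
    x$lambda, exp(x$beta1), exp(x$beta2), x$n,
    100 * x$censor_ten_year_prob, x$horizon))
  invisible(x)
}

# Population mean horizon risk under the Cox-exponential model, by Gaussian
# quadrature over the linear predictor beta1*x1 + beta2*x2 ~ N(0, beta1^2+beta2^2).
.mean_risk_quadrature <- function(lambda, beta1, beta2, horizon) {
  s <- sqrt(beta1^2 + beta2^2)
  if (s == 0) return(1 - exp(-lambda * horizon))
  gh <- .gauss_hermite_101
  # E_Z[1 - exp(-lambda*horizon*exp(s Z))], Z ~ N(0,1)
  sum(gh$w * (1 - exp(-lambda * horizon * exp(s * gh$x))))
}

# Gauss-Hermite nodes/weights (probabilists', 101 points), computed once via
# the Golub-Welsch eigen decomposition of the Jacobi matrix.
.gauss_hermite_101 <- local({
  k <- 101L
  off <- sqrt(seq_len(k - 1L))
  J <- matrix(0, k, k)
  J[cbind(seq_len(k - 1L), seq_len(k - 1L) + 1L)] <- off
  J[cbind(seq_len(k - 1L) + 1L, seq_len(k - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = e$vectors[1L, ]^2)
})

#' Baseline hazard giving a target mean horizon risk
#'
#' Finds `lambda` such that the population mean `horizon`-year event risk
#' `E[1 - exp(-lambda * horizon * exp(beta1 x1 + beta2 x2))]` over independent
#' standard-normal covariates equals `target_mean_risk`. The expectation is
#' evaluated by Gauss-Hermite quadrature and inverted with a root solver;
#' accuracy is better than 1e-6 on the risk scale.
#'
#' @param target_mean_risk Desired mean risk at the horizon, in `(0, 1)`.
#' @param beta1,beta2 Log hazard ratios per 1 SD of the two covariates.
#' @param horizon Horizon in years (default 10).
#' @return Baseline hazard rate `lambda` (per person-year).
#' @examples
#' solve_baseline_hazard(0.2, 0, 0) # -log(0.8)/10
#' @export
solve_baseline_hazard <- function(target_mean_risk, beta1, beta2, horizon = 10) {
  if (!is.numeric(target_mean_risk) || length(target_mean_risk) != 1L ||
      is.na(target_mean_risk) || target_mean_risk <= 0 || target_mean_risk >= 1)
    stop("`target_mean_risk` must be in (0, 1)", call. = FALSE)
  if (horizon <= 0) stop("`horizon` must be > 0", call. = FALSE)
  f <- function(loglam)
    .mean_risk_quadrature(exp(loglam), beta1, beta2, horizon) - target_mean_risk
  # mean risk is monotone in lambda; bracket on the log scale
  lo <- log(-log1p(-target_mean_risk) / horizon) - 30
  hi <- log(-log1p(-target_mean_risk) / horizon) + 30
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
}

#' Generate one survival dataset from a simulation scenario
#'
#' Draws `x1`, `x2` iid standard normal, event times from the
#' Cox-exponential model, and censoring times from an exponential
#' distribution calibrated so the probability of censoring by the horizon is
#' `censor_ten_year_prob`. The observed time is `min(T, C)` and the event
#' indicator is `T <= C`. There is no administrative cap on follow-up; the
#' horizon-based measures truncate at the horizon themselves.
#'
#' @param scenario A [sim_scenario()].
#' @return A `data.frame` with columns `id`, `time`, `event`, `x1`, `x2`;
#'   the scenario is attached as attribute `"scenario"`.
#' @export
generate_dataset <- function(scenario) {
  if (!inherits(scenario, "sim_scenario"))
    stop("`scenario` must be a `sim_scenario`", call. = FALSE)
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  n <- scenario$n
  x1 <- stats::rnorm(n)
  x2 <- stats::rnorm(n)
  rate <- scenario$lambda * exp(scenario$beta1 * x1 + scenario$beta2 * x2)
  tt <- -log(stats::runif(n)) / rate
  cr <- censor_rate_from_horizon_prob(scenario$censor_ten_year_prob,
                                      scenario$horizon)
  if (cr > 0) {
    cc <- stats::rexp(n, rate = cr)
    time <- pmin(tt, cc)
    event <- as.integer(tt <= cc)
  } else {
    time <- tt
    event <- rep(1L, n)
  }
  out <- data.frame(id = seq_len(n), time = time, event = event,
                    x1 = x1, x2 = x2)
  attr(out, "scenario") <- scenario
  out
}

#' Validate a subject-level survival dataset
#'
#' Checks the `time`/`event` contract shared by every measure in the
#' package: positive times, 0/1 event indicator, no missing values.
#'
#' @param data A `data.frame` with numeric `time` and 0/1 `event` columns.
#' @param covariates Optional character vector of covariate columns that
#'   must also be present, numeric and complete.
#' @return `data`, invisibly.
#' @export
validate_survival_data <- function(data, covariates = NULL) {
  if (!is.data.frame(data) || !all(c("time", "event") %in% names(data)))
    stop("`data` must be a data.frame with `time` and `event` columns",
         call. = FALSE)
  if (nrow(data) == 0L) stop("`data` has no rows", call. = FALSE)
  if (anyNA(data$time) || any(data$time <= 0))
    stop("all observation times must be positive and non-missing", call. = FALSE)
  if (anyNA(data$event) || !all(data$event %in% c(0, 1)))
    stop("`event` must be 0 (censored) or 1 (event)", call. = FALSE)
  for (cv in covariates) {
    if (!cv %in% names(data))
      stop(sprintf("covariate `%s` not found in data", cv), call. = FALSE)
    if (!is.numeric(data[[cv]]) || anyNA(data[[cv]]))
      stop(sprintf("covariate `%s` must be numeric with no missing values", cv),
           call. = FALSE)
  }
  invisible(data)
}

#' Specification of a multi-covariate synthetic cohort
#'
#' Describes a cohort whose survival times follow a proportional-hazards
#' exponential model in a set of named covariates, calibrated so that the
#' cohort's mean risk at the horizon hits a target. Continuous covariates
#' are normal (given mean/SD), binary ones Bernoulli (given prevalence);
#' hazard ratios are stated per `per` units of the covariate (e.g. per
#' 20 mmHg of systolic blood pressure). Covariates are independent unless a
#' correlation matrix for the continuous ones is supplied.
#'
#' @param covariates A `data.frame` with columns `name`, `type`
#'   (`"continuous"` or `"binary"`), `mean`, `sd` (continuous only),
#'   `prevalence` (binary only), `hr` (hazard ratio), `per` (units per
#'   hazard ratio; use 1 for binary covariates).
#' @param target_mean_risk Target mean event risk at `horizon`, in `(0, 1)`.
#' @param n Cohort size.
#' @param horizon Risk horizon in years (default 10).
#' @param max_followup Administrative end of follow-up in years (default 12).
#' @param correlation Optional correlation matrix for the continuous
#'   covariates (dimnames must match their names).
#' @param seed Optional integer seed.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_framingham_like()], [framingham_cohort_spec()]
#' @export
cohort_spec <- function(covariates, target_mean_risk, n,
                        horizon = 10, max_followup = 12,
                        correlation = NULL, seed = NULL) {
  need <- c("name", "type", "hr", "per")
  if (!is.data.frame(covariates) || !all(need %in% names(covariates)))
    stop("`covariates` must be a data.frame with columns name, type, hr, per",
         call. = FALSE)
  if (!all(covariates$type %in% c("continuous", "binary")))
    stop("covariate `type` must be 'continuous' or 'binary'", call. = FALSE)
  if (any(covariates$hr <= 0) || any(covariates$per <= 0))
    stop("hazard ratios and `per` units must be positive", call. = FALSE)
  cont <- covariates$type == "continuous"
  if (any(cont)) {
    if (!all(c("mean", "sd") %in% names(covariates)) ||
        anyNA(covariates$mean[cont]) || anyNA(covariates$sd[cont]) ||
        any(covariates$sd[cont] <= 0))
      stop("continuous covariates need `mean` and positive `sd`", call. = FALSE)
  }
  if (any(!cont)) {
    if (!"prevalence" %in% names(covariates) ||
        anyNA(covariates$prevalence[!cont]) ||
        any(covariates$prevalence[!cont] < 0) ||
        any(covariates$prevalence[!cont] > 1))
      stop("binary covariates need `prevalence` in [0, 1]", call. = FALSE)
  }
  if (target_mean_risk <= 0 || target_mean_risk >= 1)
    stop("`target_mean_risk` must be in (0, 1)", call. = FALSE)
  if (n < 2 || n != round(n)) stop("`n` must be an integer >= 2", call. = FALSE)
  if (max_followup <= 0) stop("`max_followup` must be > 0", call. = FALSE)
  if (!is.null(correlation)) {
    cn <- covariates$name[cont]
    if (!is.matrix(correlation) ||
        !identical(dim(correlation), c(length(cn), length(cn))))
      stop("`correlation` must be a square matrix over the continuous covariates",
           call. = FALSE)
  }
  structure(
    list(covariates = covariates, target_mean_risk = target_mean_risk,
         n = as.integer(n), horizon = horizon, max_followup = max_followup,
         correlation = correlation, seed = seed),
    class = "cohort_spec"
  )
}

#' Built-in Framingham-like cohort specifications
#'
#' Ready-made [cohort_spec()]s emulating the classic sex-specific
#' cardiovascular risk cohorts used in 10-year CVD prediction: covariates
#' age, total cholesterol, HDL cholesterol, antihypertensive medication,
#' current smoking, diabetes and systolic blood pressure, with
#' sex-specific hazard ratios, a mean 10-year risk of about 15.6% (men) or
#' 8.2% (women), and 12 years of maximum follow-up. Marginal covariate
#' distributions are typical mid-century community-cohort values.
#'
#' @param sex `"men"` or `"women"`.
#' @param n Cohort size; defaults to 3969 (men) or 4522 (women).
#' @param seed Optional integer seed.
#' @return A [cohort_spec()].
#' @export
framingham_cohort_spec <- function(sex = c("women", "men"), n = NULL,
                                   seed = NULL) {
  sex <- match.arg(sex)
  if (sex == "men") {
    hrs <- c(age = 1.80, tc = 1.23, hdl = 0.82, bpmeds = 1.45,
             smoker = 1.93, diabetes = 1.77, sbp = 1.30)
    marg <- list(hdl_mean = 44, sbp_mean = 132, smoker = 0.42)
    target <- 0.156
    if (is.null(n)) n <- 3969L
  } else {
    hrs <- c(age = 1.56, tc = 1.23, hdl = 0.88, bpmeds = 1.31,
             smoker = 1.72, diabetes = 2.07, sbp = 1.48)
    marg <- list(hdl_mean = 55, sbp_mean = 128, smoker = 0.38)
    target <- 0.082
    if (is.null(n)) n <- 4522L
  }
  cov <- data.frame(
    name = c("age", "tc", "hdl", "bpmeds", "smoker", "diabetes", "sbp"),
    type = c("continuous", "continuous", "continuous", "binary", "binary",
             "binary", "continuous"),
    mean = c(49, 225, marg$hdl_mean, NA, NA, NA, marg$sbp_mean),
    sd = c(11, 42, 13, NA, NA, NA, 19),
    prevalence = c(NA, NA, NA, 0.11, marg$smoker, 0.05, NA),
    hr = unname(hrs),
    per = c(10, 40, 10, 1, 1, 1, 20)
  )
  cohort_spec(cov, target_mean_risk = target, n = n, seed = seed)
}

#' Generate a Framingham-like synthetic cohort
#'
#' Draws covariates from the marginal distributions in `spec`, calibrates the
#' baseline hazard so the cohort's mean risk at the horizon equals the
#' target, generates exponential proportional-hazards event times, and
#' administratively censors follow-up at `max_followup` years.
#'
#' @param spec A [cohort_spec()], e.g. from [framingham_cohort_spec()].
#' @return A `data.frame` with columns `id`, `time`, `event` and one column
#'   per covariate; the spec and calibrated baseline hazard are attached as
#'   attributes `"spec"` and `"lambda"`.
#' @export
generate_framingham_like <- function(spec) {
  if (!inherits(spec, "cohort_spec"))
    stop("`spec` must be a `cohort_spec`", call. = FALSE)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  cv <- spec$covariates
  n <- spec$n
  X <- matrix(NA_real_, n, nrow(cv), dimnames = list(NULL, cv$name))
  cont <- which(cv$type == "continuous")
  if (length(cont)) {
    Z <- matrix(stats::rnorm(n * length(cont)), n, length(cont))
    if (!is.null(spec$correlation)) Z <- Z %*% chol(spec$correlation)
    for (k in seq_along(cont)) {
      i <- cont[k]
      X[, i] <- cv$mean[i] + cv$sd[i] * Z[, k]
    }
  }
  for (i in which(cv$type == "binary"))
    X[, i] <- stats::rbinom(n, 1L, cv$prevalence[i])
  # log HR per raw covariate unit; centre so the baseline hazard refers to an
  # average subject
  beta <- log(cv$hr) / cv$per
  centre <- ifelse(cv$type == "continuous", cv$mean, cv$prevalence)
  lp <- drop((X - matrix(centre, n, nrow(cv), byrow = TRUE)) %*% beta)
  # calibrate lambda on this cohort's realized linear predictors
  f <- function(loglam)
    mean(1 - exp(-exp(loglam) * spec$horizon * exp(lp))) - spec$target_mean_risk
  lam0 <- -log1p(-spec$target_mean_risk) / spec$horizon
  lambda <- exp(stats::uniroot(f, log(lam0) + c(-30, 30), tol = 1e-12)$root)
  tt <- -log(stats::runif(n)) / (lambda * exp(lp))
  time <- pmin(tt, spec$max_followup)
  event <- as.integer(tt <= spec$max_followup)
  out <- data.frame(id = seq_len(n), time = time, event = event)
  out <- cbind(out, as.data.frame(X))
  attr(out, "spec") <- spec
  attr(out, "lambda") <- lambda
  out
}
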