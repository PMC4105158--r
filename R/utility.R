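#' Clinical-utility configuration
#'
#' Bundles the decision parameters shared by [net_benefit()] and
#' [efly_gain()]: the treatment threshold, the relative risk reduction that
#' treatment confers on the horizon risk, the horizon itself, and the
#' monetary value of one event-free life year (carried as metadata for
#' report formatting only — never used inside a measure).
#'
#' @param threshold Treatment threshold probability `p_t`, in `(0, 1)`
#'   (default 0.20, the usual 10-year CVD treatment cutpoint).
#' @param risk_reduction Relative reduction of the horizon risk under
#'   treatment, in `[0, 1)` (default 0.20, from meta-analytic estimates of
#'   statin-type interventions).
#' @param horizon Horizon `T` in years (default 10).
#' @param efly_value Currency value of one EFLY (default 20000, the NICE
#'   willingness-to-pay benchmark; metadata only).
#' @return An object of class `utility_config`.
#' @export
utility_config <- function(threshold = 0.20, risk_reduction = 0.20,
                           horizon = 10, efly_value = 20000) {
  if (length(threshold) != 1L || threshold <= 0 || threshold >= 1)
    stop("`threshold` must be in (0, 1)", call. = FALSE)
  if (length(risk_reduction) != 1L || risk_reduction < 0 || risk_reduction >= 1)
    stop("`risk_reduction` must be in [0, 1)", call. = FALSE)
  if (horizon <= 0) stop("`horizon` must be > 0", call. = FALSE)
  structure(list(threshold = threshold, risk_reduction = risk_reduction,
                 horizon = horizon, efly_value = efly_value),
            class = "utility_config")
}

#' Net benefit of a risk model at a threshold
#'
#' Decision-analytic net benefit of treating everyone with predicted risk
#' strictly greater than `p_t`:
#' `NB = TP/n - (FP/n) * p_t / (1 - p_t)`, in units of true positives per
#' person evaluated. True and false positives among the high-risk group are
#' counted with the Kaplan-Meier estimate at `t`, so censored subjects are
#' handled correctly: `TP = n_high * (1 - KM_high(t))`,
#' `FP = n_high * KM_high(t)`.
#'
#' @param risks Predicted risks aligned with `data`.
#' @param data Survival `data.frame`.
#' @param p_t Threshold probability, in `(0, 1)`.
#' @param t Horizon in years (default 10).
#' @return Net benefit per person evaluated (multiply by 1000 for the
#'   per-1000 convention). 0 when nobody is above the threshold.
#' @export
net_benefit <- function(risks, data, p_t, t = 10) {
  validate_survival_data(data)
  n <- nrow(data)
  if (length(risks) != n) stop("`risks` must align with `data`", call. = FALSE)
  if (length(p_t) != 1L || is.na(p_t) || p_t <= 0 || p_t >= 1)
    stop("`p_t` must be in (0, 1)", call. = FALSE)
  high <- risks > p_t
  if (!any(high)) return(0)
  n_high <- sum(high)
  km_high <- .km_at(data$time[high], data$event[high], t)
  tp <- n_high * (1 - km_high)
  fp <- n_high * km_high
  tp / n - (fp / n) * p_t / (1 - p_t)
}

#' Risk after treatment
#'
#' Treatment reduces the horizon risk by a relative fraction `rho`:
#' `(1 - rho) * risk`.
#'
#' @param risk Untreated risk(s) in `[0, 1]`.
#' @param rho Relative risk reduction in `[0, 1)`.
#' @return Treated risk(s).
#' @export
treated_risk <- function(risk, rho) {
  if (any(risk < 0 | risk > 1, na.rm = TRUE))
    stop("`risk` must be in [0, 1]", call. = FALSE)
  if (length(rho) != 1L || rho < 0 || rho >= 1)
    stop("`rho` must be in [0, 1)", call. = FALSE)
  (1 - rho) * risk
}

# restricted mean event-free time over [0, T] for a constant hazard h
.rmst_exp <- function(h, T) ifelse(h > 0, (1 - exp(-h * T)) / h, T)

#' Event-free life years gained by treating one subject
#'
#' Maps a subject's predicted horizon risk to a constant-hazard survival
#' curve (`h = -log(1 - risk) / T`), applies the treatment effect on the
#' risk scale (`(1 - rho) * risk`, back-deriving the treated hazard), and
#' returns the gain in restricted mean event-free time over `[0, T]`.
#' Computed from the model-predicted risk, not observed follow-up, so it is
#' well-defined for censored subjects.
#'
#' @param risk Predicted risk(s) in `[0, 1)`; a risk of 1 would imply an
#'   infinite hazard and is an error.
#' @param rho Relative risk reduction in `[0, 1)`.
#' @param T Horizon in years (default 10).
#' @return EFLYs gained per treated subject (0 at `risk = 0` or `rho = 0`).
#' @export
efly_benefit_per_subject <- function(risk, rho, T = 10) {
  if (anyNA(risk) || any(risk < 0) || any(risk >= 1))
    stop("`risk` must be in [0, 1); risk = 1 implies an infinite hazard",
         call. = FALSE)
  if (length(rho) != 1L || rho < 0 || rho >= 1)
    stop("`rho` must be in [0, 1)", call. = FALSE)
  if (T <= 0) stop("`T` must be > 0", call. = FALSE)
  h <- -log1p(-risk) / T
  h_tr <- -log1p(-treated_risk(risk, rho)) / T
  .rmst_exp(h_tr, T) - .rmst_exp(h, T)
}

#' Treatment cost in event-free life years
#'
#' The EFLY framework assumes the treatment threshold is the optimal
#' cutpoint: benefits equal costs for a subject exactly at the threshold.
#' The per-treated-person cost is therefore the benefit of a subject whose
#' risk equals `p_t`.
#'
#' @param p_t Threshold probability in `(0, 1)`.
#' @inheritParams efly_benefit_per_subject
#' @return Cost per treated person, in EFLYs.
#' @export
efly_treatment_cost <- function(p_t, rho, T = 10) {
  if (length(p_t) != 1L || p_t <= 0 || p_t >= 1)
    stop("`p_t` must be in (0, 1)", call. = FALSE)
  efly_benefit_per_subject(p_t, rho, T)
}

#' Event-free life years gained per person evaluated
#'
#' `EFLY gain = P * (B(T) - C(T))` where `P` is the fraction treated
#' (predicted risk strictly above the threshold), `B(T)` the benefit per
#' treated person and `C(T)` the threshold-calibrated cost
#' ([efly_treatment_cost()]).
#'
#' The benefit is scored against the treated group's *observed* outcomes,
#' not against the predictions of the model that selected them: the group's
#' event probability by the horizon is estimated by Kaplan-Meier (so
#' censoring is handled) and mapped through the same constant-hazard
#' machinery as the cost, `B(T) =` [efly_benefit_per_subject()] at that
#' observed risk. Scoring against observed outcomes is what lets the measure
#' penalize a model that stops treating genuinely high-risk people: a model
#' cannot improve its EFLY gain merely by being confident.
#'
#' @param risks Predicted risks aligned with `data`.
#' @param data Survival `data.frame`; supplies the treated group's observed
#'   event probability.
#' @param config A [utility_config()].
#' @param t Horizon for the observed event probability; defaults to the
#'   config horizon.
#' @return EFLYs gained per person evaluated (multiply by 1000 for the
#'   per-1000 convention). 0 when nobody is treated.
#' @export
efly_gain <- function(risks, data, config = utility_config(), t = NULL) {
  if (!inherits(config, "utility_config"))
    stop("`config` must be a `utility_config`", call. = FALSE)
  validate_survival_data(data)
  if (length(risks) != nrow(data))
    stop("`risks` must align with `data`", call. = FALSE)
  if (is.null(t)) t <- config$horizon
  treated <- risks > config$threshold
  if (!any(treated)) return(0)
  P <- mean(treated)
  observed_risk <- 1 - .km_at(data$time[treated], data$event[treated], t)
  observed_risk <- min(observed_risk, 1 - 1e-12)  # KM can reach 1
  B <- efly_benefit_per_subject(observed_risk, config$risk_reduction,
                                config$horizon)
  C <- efly_treatment_cost(config$threshold, config$risk_reduction,
                           config$horizon)
  P * (B - C)
}
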