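# internal: full measure panel for one dataset, given fitted nested models;
# returns a named numeric vector (shared by point estimates and bootstrap)
.measure_panel <- function(data, base_covariates, full_covariates,
                           cutpoints, utility, t) {
  fb <- fit_model(data, base_covariates)
  ff <- fit_model(data, full_covariates)
  rb <- predict_horizon_risk(fb, data, t)
  rf <- predict_horizon_risk(ff, data, t)
  upper <- max(cutpoints)
  sb <- km_sensitivity_specificity(rb, data, upper, t)
  sf <- km_sensitivity_specificity(rf, data, upper, t)
  nb_b <- net_benefit(rb, data, upper, t)
  nb_f <- net_benefit(rf, data, upper, t)
  ef_b <- efly_gain(rb, data, utility)
  ef_f <- efly_gain(rf, data, utility)
  c(sens_base = sb$sensitivity, sens_full = sf$sensitivity,
    spec_base = sb$specificity, spec_full = sf$specificity,
    binary_c_base = sb$binary_c, binary_c_full = sf$binary_c,
    c_base = harrell_c_horizon(rb, data, t),
    c_full = harrell_c_horizon(rf, data, t),
    nri_binary = nri_binary(sb, sf),
    nri_continuous = nri_continuous(rb, rf, data, t),
    nri_categorical = nri_categorical(rb, rf, data, cutpoints, t),
    nb_base = nb_b, nb_full = nb_f,
    efly_base = ef_b, efly_full = ef_f,
    mean_risk = mean(rf))
}

.panel_rows <- data.frame(
  measure = c("sensitivity", "specificity", "c_binary", "c_statistic",
              "nri_binary", "nri_continuous", "nri_categorical",
              "net_benefit_per_1000", "efly_per_1000"),
  base = c("sens_base", "spec_base", "binary_c_base", "c_base",
           NA, NA, NA, "nb_base", "efly_base"),
  full = c("sens_full", "spec_full", "binary_c_full", "c_full",
           NA, NA, NA, "nb_full", "efly_full"),
  scale = c(1, 1, 1, 1, 1, 1, 1, 1000, 1000),
  stringsAsFactors = FALSE
)

# difference for one panel row: paired difference, or the NRI value itself
.panel_diff <- function(panel) {
  out <- numeric(nrow(.panel_rows))
  for (i in seq_len(nrow(.panel_rows))) {
    r <- .panel_rows[i, ]
    out[i] <- if (is.na(r$base)) {
      panel[[r$measure]]
    } else {
      panel[[r$full]] - panel[[r$base]]
    }
    out[i] <- out[i] * r$scale
  }
  stats::setNames(out, .panel_rows$measure)
}

#' Compare two nested risk models on a cohort
#'
#' Fits a base Cox model and an extended model (base plus
#' `added_covariates`) to subject-level survival data, computes the full
#' measure panel (sensitivity, specificity, binary c, Harrell c, the three
#' NRIs, net benefit and EFLY gain, the latter two also per 1000 evaluated),
#' and attaches percentile bootstrap confidence intervals from `B`
#' nonparametric resamples of subjects. Point estimates always come from the
#' full data, never from bootstrap aggregation. Resamples in which a fit or
#' measure fails are dropped and counted.
#'
#' @param data Survival `data.frame` with all covariates.
#' @param base_covariates,added_covariates Covariate names; must be disjoint.
#' @param cutpoints Risk category cutpoints (default `c(0.10, 0.20)`); the
#'   largest is the high-risk/treatment cutpoint.
#' @param utility A [utility_config()]; defaults to a threshold at the upper
#'   cutpoint.
#' @param B Number of bootstrap resamples (default 2000; `B = 0` gives point
#'   estimates only).
#' @param seed Integer seed for the bootstrap (default 1).
#' @param t Horizon in years (default 10).
#' @return An object of class `comparison_report`: `measures` (a
#'   `data.frame` with base/full/difference and 95% CI per measure),
#'   `hazard_ratios` (per model), and `meta` (n, events by `t`, mean risk,
#'   `B`, failed resamples).
#' @export
compare_models <- function(data, base_covariates, added_covariates,
                           cutpoints = c(0.10, 0.20), utility = NULL,
                           B = 2000, seed = 1, t = 10) {
  if (length(intersect(base_covariates, added_covariates)))
    stop("`added_covariates` must be disjoint from `base_covariates`",
         call. = FALSE)
  validate_survival_data(data, c(base_covariates, added_covariates))
  upper <- max(cutpoints)
  if (is.null(utility)) utility <- utility_config(threshold = upper, horizon = t)
  full_covariates <- c(base_covariates, added_covariates)

  fb <- fit_model(data, base_covariates)     # aborts loudly on full-data failure
  ff <- fit_model(data, full_covariates)
  panel <- .measure_panel(data, base_covariates, full_covariates,
                          cutpoints, utility, t)
  diffs <- .panel_diff(panel)

  failed <- 0L
  ci_lo <- ci_hi <- rep(NA_real_, length(diffs))
  if (B > 0) {
    set.seed(seed)
    n <- nrow(data)
    boot <- matrix(NA_real_, B, length(diffs))
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      pb <- tryCatch(
        .panel_diff(.measure_panel(data[idx, , drop = FALSE],
                                   base_covariates, full_covariates,
                                   cutpoints, utility, t)),
        error = function(e) NULL)
      if (is.null(pb)) failed <- failed + 1L else boot[b, ] <- pb
    }
    ok <- stats::complete.cases(boot)
    if (any(ok)) {
      ci_lo <- apply(boot[ok, , drop = FALSE], 2, stats::quantile, 0.025)
      ci_hi <- apply(boot[ok, , drop = FALSE], 2, stats::quantile, 0.975)
    }
  }

  base_vals <- full_vals <- rep(NA_real_, nrow(.panel_rows))
  for (i in seq_len(nrow(.panel_rows))) {
    r <- .panel_rows[i, ]
    if (!is.na(r$base)) {
      base_vals[i] <- panel[[r$base]] * r$scale
      full_vals[i] <- panel[[r$full]] * r$scale
    }
  }
  measures <- data.frame(
    measure = .panel_rows$measure,
    base = base_vals, full = full_vals, difference = unname(diffs),
    ci_lower = unname(ci_lo), ci_upper = unname(ci_hi),
    stringsAsFactors = FALSE
  )
  hr_tab <- function(fit) data.frame(
    covariate = fit$covariates, hr = exp(fit$coef),
    ci_lower = exp(fit$coef - 1.96 * fit$se),
    ci_upper = exp(fit$coef + 1.96 * fit$se),
    row.names = NULL
  )
  structure(
    list(measures = measures,
         hazard_ratios = list(base = hr_tab(fb), full = hr_tab(ff)),
         meta = list(n = nrow(data),
                     events_by_horizon = nrow(data) * (1 - .km_at(data$time, data$event, t)),
                     mean_risk = panel[["mean_risk"]],
                     cutpoints = cutpoints, horizon = t,
                     B = B, failed_resamples = failed,
                     utility = utility)),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    "Model comparison on %d subjects (%.0f events by %gy, mean risk %.3f)\n",
    x$meta$n, x$meta$events_by_horizon, x$meta$horizon, x$meta$mean_risk))
  if (x$meta$B > 0)
    cat(sprintf("Percentile bootstrap CIs from %d resamples (%d failed)\n",
                x$meta$B, x$meta$failed_resamples))
  print(report_table(x), row.names = FALSE)
  invisible(x)
}

#' Format a comparison report as a table
#'
#' The fixed nine-row layout used for nested-model comparisons:
#' sensitivity, specificity, binary c, c-statistic, binary/continuous/
#' categorical NRI, and net benefit and EFLY gain per 1000 evaluated, each
#' with base value, extended-model value, difference and 95% CI. NRI rows
#' have no per-model value; absent CIs render as dashes, not zeros.
#'
#' @param report A [compare_models()] report.
#' @param digits Digits for the formatted columns (default 3).
#' @return A `data.frame` of formatted strings, one row per measure.
#' @export
report_table <- function(report, digits = 3) {
  if (!inherits(report, "comparison_report"))
    stop("`report` must be a `comparison_report`", call. = FALSE)
  m <- report$measures
  fm <- function(v) ifelse(is.na(v), "-", formatC(v, digits = digits,
                                                  format = "fg", flag = "#"))
  data.frame(
    measure = m$measure,
    base = fm(m$base), full = fm(m$full), difference = fm(m$difference),
    ci_95 = ifelse(is.na(m$ci_lower), "-",
                   sprintf("(%s, %s)", fm(m$ci_lower), fm(m$ci_upper))),
    stringsAsFactors = FALSE
  )
}

#' Write a comparison report to CSV and Markdown
#'
#' @param report A [compare_models()] report.
#' @param csv,md Optional output paths; only the ones given are written.
#' @return The formatted table, invisibly.
#' @export
write_report <- function(report, csv = NULL, md = NULL) {
  tab <- report_table(report)
  if (!is.null(csv))
    utils::write.csv(report$measures, csv, row.names = FALSE)
  if (!is.null(md)) {
    lines <- c(
      paste0("| ", paste(names(tab), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|"),
      apply(tab, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    )
    writeLines(lines, md)
  }
  invisible(tab)
}
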