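#' Evaluate every comparison measure on one dataset
#'
#' Fits the base model (`base_covariates`) and the extended model (base plus
#' `added_covariates`) to one survival dataset, predicts horizon risks under
#' both, and computes the full measure panel: horizon-truncated Harrell c,
#' KM sensitivity/specificity and binary c at the upper cutpoint, the three
#' NRI variants, net benefit, EFLY gain, proportions classified high risk,
#' the event-by-horizon odds ratio of the added covariate (adjusted for the
#' base covariates), and the fraction censored within the horizon. Component
#' failures (e.g. a collinear fit) do not abort: the affected fields are
#' returned as `NA` and the reason recorded in `note`.
#'
#' @param data Survival `data.frame` with the covariates.
#' @param cutpoints One or two increasing category cutpoints; the largest
#'   one is the high-risk/treatment cutpoint (default `c(0.10, 0.20)`).
#' @param utility A [utility_config()]; defaults to a threshold equal to the
#'   upper cutpoint.
#' @param t Horizon in years (default 10).
#' @param base_covariates,added_covariates Covariate names for the nested
#'   models (defaults `"x1"` and `"x2"`, the simulation columns).
#' @return A one-row `data.frame` (a measure record).
#' @export
evaluate_dataset <- function(data, cutpoints = c(0.10, 0.20),
                             utility = NULL, t = 10,
                             base_covariates = "x1",
                             added_covariates = "x2") {
  validate_survival_data(data, c(base_covariates, added_covariates))
  upper <- max(cutpoints)
  if (is.null(utility)) utility <- utility_config(threshold = upper, horizon = t)
  notes <- character(0)
  grab <- function(expr) {
    tryCatch(expr, error = function(e) {
      notes <<- c(notes, conditionMessage(e))
      NA_real_
    })
  }
  rec <- list()
  full_cov <- c(base_covariates, added_covariates)
  fit_b <- tryCatch(fit_model(data, base_covariates), error = function(e) {
    notes <<- c(notes, paste("base fit:", conditionMessage(e))); NULL
  })
  fit_f <- tryCatch(fit_model(data, full_cov), error = function(e) {
    notes <<- c(notes, paste("full fit:", conditionMessage(e))); NULL
  })
  if (!is.null(fit_b) && !is.null(fit_f)) {
    rb <- predict_horizon_risk(fit_b, data, t)
    rf <- predict_horizon_risk(fit_f, data, t)
    rec$mean_risk <- mean(rf)
    rec$mean_risk_base <- mean(rb)
    rec$c_base <- grab(harrell_c_horizon(rb, data, t))
    rec$c_full <- grab(harrell_c_horizon(rf, data, t))
    rec$delta_c <- rec$c_full - rec$c_base
    sb <- tryCatch(km_sensitivity_specificity(rb, data, upper, t),
                   error = function(e) { notes <<- c(notes, conditionMessage(e)); NULL })
    sf <- tryCatch(km_sensitivity_specificity(rf, data, upper, t),
                   error = function(e) { notes <<- c(notes, conditionMessage(e)); NULL })
    if (!is.null(sb) && !is.null(sf)) {
      rec$sens_base <- sb$sensitivity; rec$sens_full <- sf$sensitivity
      rec$delta_sens <- sf$sensitivity - sb$sensitivity
      rec$spec_base <- sb$specificity; rec$spec_full <- sf$specificity
      rec$delta_spec <- sf$specificity - sb$specificity
      rec$binary_c_base <- sb$binary_c; rec$binary_c_full <- sf$binary_c
      rec$delta_binary_c <- binary_c_difference(sb, sf)
      rec$nri_binary <- nri_binary(sb, sf)
      rec$prop_high_base <- sb$prop_high
      rec$prop_high_full <- sf$prop_high
    } else {
      rec[c("sens_base", "sens_full", "delta_sens", "spec_base", "spec_full",
            "delta_spec", "binary_c_base", "binary_c_full", "delta_binary_c",
            "nri_binary", "prop_high_base", "prop_high_full")] <- NA_real_
    }
    rec$nri_continuous <- grab(nri_continuous(rb, rf, data, t))
    rec$nri_categorical <- grab(nri_categorical(rb, rf, data, cutpoints, t))
    rec$nb_base <- grab(net_benefit(rb, data, upper, t))
    rec$nb_full <- grab(net_benefit(rf, data, upper, t))
    rec$delta_net_benefit <- rec$nb_full - rec$nb_base
    rec$efly_base <- grab(efly_gain(rb, data, utility))
    rec$efly_full <- grab(efly_gain(rf, data, utility))
    rec$delta_efly <- rec$efly_full - rec$efly_base
  } else {
    rec[c("mean_risk", "mean_risk_base", "c_base", "c_full", "delta_c",
          "sens_base", "sens_full", "delta_sens", "spec_base", "spec_full",
          "delta_spec", "binary_c_base", "binary_c_full", "delta_binary_c",
          "nri_binary", "nri_continuous", "nri_categorical",
          "nb_base", "nb_full", "delta_net_benefit",
          "efly_base", "efly_full", "delta_efly",
          "prop_high_base", "prop_high_full")] <- NA_real_
  }
  rec$odds_ratio <- grab(as.numeric(
    ten_year_odds_ratio(data, added_covariates[1], adjust_for = base_covariates,
                        t = t)))
  rec$censored_frac <- mean(data$event == 0 & data$time < t)
  rec$n <- nrow(data)
  rec$note <- if (length(notes)) paste(unique(notes), collapse = " | ") else ""
  as.data.frame(rec, stringsAsFactors = FALSE)
}

#' Configuration of the simulation study
#'
#' Defines the sweep that maps every measure against the population mean
#' risk: a grid of baseline hazards (log-spaced between the values giving
#' the lowest and highest target mean risks), crossed with baseline-model
#' and new-predictor hazard ratios, with a fixed high-risk cutpoint.
#'
#' @param baseline_hr Hazard ratios per 1 SD for the baseline covariate
#'   (default `c(1.5, 3, 6)`: weak, medium, strong baseline model).
#' @param predictor_hr Hazard ratios per 1 SD for the new predictor
#'   (default `c(1.2, 2, 3)`: weak, medium, strong predictor).
#' @param mean_risk_range Range of target mean 10-year risks the baseline
#'   hazard grid spans (default `c(0.01, 0.92)`; above ~92% essentially
#'   every subject has an event within the decade and residual censoring
#'   vanishes).
#' @param grid_size Number of baseline-hazard grid points (default 60).
#' @param n Subjects per dataset (default 10000).
#' @param replicates Datasets per (cell, grid point) (default 1000).
#' @param cutpoints Risk-category cutpoints; the largest is the high-risk /
#'   treatment cutpoint (default `c(0.10, 0.20)`).
#' @param censor_ten_year_prob Probability of censoring by the horizon
#'   (default 0.10).
#' @param horizon Horizon in years (default 10).
#' @param seed Master seed; one independent substream is spawned per
#'   (cell, grid point, replicate).
#' @return An object of class `study_config`.
#' @export
study_config <- function(baseline_hr = c(1.5, 3, 6),
                         predictor_hr = c(1.2, 2, 3),
                         mean_risk_range = c(0.01, 0.92),
                         grid_size = 60, n = 10000, replicates = 1000,
                         cutpoints = c(0.10, 0.20),
                         censor_ten_year_prob = 0.10,
                         horizon = 10, seed = 1) {
  stopifnot(all(baseline_hr > 0), all(predictor_hr > 0),
            length(mean_risk_range) == 2L,
            mean_risk_range[1] > 0, mean_risk_range[2] < 1,
            mean_risk_range[1] < mean_risk_range[2],
            grid_size >= 1, n >= 2, replicates >= 1)
  structure(
    list(baseline_hr = baseline_hr, predictor_hr = predictor_hr,
         mean_risk_range = mean_risk_range, grid_size = as.integer(grid_size),
         n = as.integer(n), replicates = as.integer(replicates),
         cutpoints = cutpoints,
         censor_ten_year_prob = censor_ten_year_prob,
         horizon = horizon, seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Desk-scale study profile
#'
#' A reduced [study_config()] (11-point hazard grid, 50 replicates,
#' n = 2000, medium/medium cell only) that exercises the full pipeline in
#' minutes rather than hours; Monte-Carlo error shrinks with more
#' replicates but no point definition changes.
#'
#' @param ... Overrides passed to [study_config()].
#' @return A `study_config`.
#' @export
desk_study_config <- function(...) {
  defaults <- list(baseline_hr = 3, predictor_hr = 2, grid_size = 11,
                   n = 2000, replicates = 50)
  args <- utils::modifyList(defaults, list(...))
  do.call(study_config, args)
}

# log-spaced baseline hazard grid spanning the target mean-risk range
.lambda_grid <- function(config, beta1, beta2) {
  lo <- solve_baseline_hazard(config$mean_risk_range[1], beta1, beta2,
                              config$horizon)
  hi <- solve_baseline_hazard(config$mean_risk_range[2], beta1, beta2,
                              config$horizon)
  exp(seq(log(lo), log(hi), length.out = config$grid_size))
}

#' Run the full simulation study
#'
#' Sweeps every (baseline HR, predictor HR) cell over the baseline-hazard
#' grid, generating `replicates` datasets per grid point and evaluating the
#' whole measure panel on each ([evaluate_dataset()]). Seeding is
#' hierarchical: the master seed deterministically spawns one substream per
#' (cell, grid point, replicate), so results are bit-reproducible and
#' replicate streams are disjoint. Records can be streamed to CSV as they
#' are produced; a sweep never aborts on a partial failure (the record's
#' `note` field carries the reason).
#'
#' @param config A [study_config()].
#' @param out Optional CSV path; records are appended as produced.
#' @param verbose Emit per-cell progress messages (default `FALSE`).
#' @return A `data.frame` with one measure record per (cell, grid point,
#'   replicate), with columns `beta1`, `beta2`, `lambda`, `replicate`,
#'   `seed` prepended.
#' @export
run_study <- function(config, out = NULL, verbose = FALSE) {
  if (!inherits(config, "study_config"))
    stop("`config` must be a `study_config`", call. = FALSE)
  cells <- expand.grid(b1 = log(config$baseline_hr),
                       b2 = log(config$predictor_hr))
  n_total <- nrow(cells) * config$grid_size * config$replicates
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, n_total)
  dim(seeds) <- c(config$replicates, config$grid_size, nrow(cells))
  res <- vector("list", n_total)
  k <- 0L
  wrote_header <- FALSE
  for (ci in seq_len(nrow(cells))) {
    b1 <- cells$b1[ci]; b2 <- cells$b2[ci]
    grid <- .lambda_grid(config, b1, b2)
    if (verbose)
      message(sprintf("cell %d/%d: HR1=%.3g HR2=%.3g",
                      ci, nrow(cells), exp(b1), exp(b2)))
    for (gi in seq_along(grid)) {
      for (ri in seq_len(config$replicates)) {
        sd_i <- seeds[ri, gi, ci]
        sc <- sim_scenario(grid[gi], b1, b2, config$n,
                           config$censor_ten_year_prob, config$horizon,
                           seed = sd_i)
        rec <- evaluate_dataset(generate_dataset(sc),
                                cutpoints = config$cutpoints,
                                t = config$horizon)
        rec <- cbind(data.frame(beta1 = b1, beta2 = b2, lambda = grid[gi],
                                replicate = ri, seed = sd_i), rec)
        k <- k + 1L
        res[[k]] <- rec
        if (!is.null(out)) {
          utils::write.table(rec, out, sep = ",", row.names = FALSE,
                             col.names = !wrote_header, append = wrote_header)
          wrote_header <- TRUE
        }
      }
    }
  }
  do.call(rbind, res[seq_len(k)])
}

#' Cubic smoothing spline of a measure against mean risk
#'
#' Fits [stats::smooth.spline()] with the smoothing parameter chosen by
#' generalized cross-validation. Duplicated x values are accepted (the
#' spline aggregates them with weights).
#'
#' @param x Mean risks (at least 10 points).
#' @param y Measure values, aligned with `x`.
#' @return An object of class `smooth_curve` with the fitted spline, the x
#'   range, and the location/value of the maximum on a fine grid. Evaluate
#'   it with `predict(curve, newx)`.
#' @export
smooth_curve <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10L)
    stop("need at least 10 points to smooth", call. = FALSE)
  fit <- stats::smooth.spline(x, y, cv = FALSE)
  grid <- seq(min(x), max(x), length.out = 512L)
  yy <- stats::predict(fit, grid)$y
  i <- which.max(yy)
  structure(
    list(fit = fit, range = range(x),
         argmax = grid[i], max_value = yy[i]),
    class = "smooth_curve"
  )
}

#' @export
predict.smooth_curve <- function(object, newx, ...) {
  stats::predict(object$fit, newx)$y
}

#' @export
print.smooth_curve <- function(x, ...) {
  cat(sprintf(
    "Cubic smoothing spline on [%.3g, %.3g]; maximum %.4g at x = %.3g\n",
    x$range[1], x$range[2], x$max_value, x$argmax))
  invisible(x)
}

#' Summarize a simulation study
#'
#' Per (baseline HR, predictor HR) cell, fits smoothed measure-vs-mean-risk
#' curves for each comparison measure, locates the peaks of the clinical
#' utility measures, and builds the proportion-above-cutpoint figure
#' contrasting the two models.
#'
#' @param records Measure records from [run_study()].
#' @param measures Record columns to smooth (defaults to the main panel).
#' @param cutpoint The high-risk cutpoint to mark in figures (default 0.20).
#' @return An object of class `study_summary`: `curves` (nested list,
#'   cell -> measure -> [smooth_curve()]), `peaks` (`data.frame` of argmax
#'   locations for the utility measures), and ggplot objects `plot_measures`
#'   and `plot_prop_high`.
#' @export
summarize_study <- function(records,
                            measures = c("delta_c", "delta_sens",
                                         "delta_spec", "delta_binary_c",
                                         "nri_binary", "nri_continuous",
                                         "nri_categorical",
                                         "delta_net_benefit", "delta_efly"),
                            cutpoint = 0.20) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a non-empty data.frame", call. = FALSE)
  records$cell <- sprintf("HR1=%.3g, HR2=%.3g",
                          exp(records$beta1), exp(records$beta2))
  cells <- unique(records$cell)
  curves <- list()
  peaks <- list()
  for (cl in cells) {
    rc <- records[records$cell == cl, ]
    curves[[cl]] <- list()
    for (ms in measures) {
      cv <- tryCatch(smooth_curve(rc$mean_risk, rc[[ms]]),
                     error = function(e) NULL)
      curves[[cl]][[ms]] <- cv
      if (!is.null(cv) && ms %in% c("delta_net_benefit", "delta_efly"))
        peaks[[length(peaks) + 1L]] <-
          data.frame(cell = cl, measure = ms, argmax = cv$argmax,
                     max_value = cv$max_value)
    }
  }
  peaks <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(cell = character(0), measure = character(0),
               argmax = numeric(0), max_value = numeric(0))

  long <- do.call(rbind, lapply(measures, function(ms) {
    data.frame(cell = records$cell, mean_risk = records$mean_risk,
               measure = ms, value = records[[ms]])
  }))
  long <- long[is.finite(long$mean_risk) & is.finite(long$value), ]
  plot_measures <- ggplot2::ggplot(
    long, ggplot2::aes(x = .data$mean_risk, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::geom_smooth(method = "gam", formula = y ~ s(x, bs = "cs"),
                         se = FALSE, linewidth = 0.6, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = cutpoint, linetype = 2,
                        colour = "grey40") +
    ggplot2::facet_grid(measure ~ cell, scales = "free_y") +
    ggplot2::labs(x = "Mean 10-year risk", y = "Difference (full - base)") +
    ggplot2::theme_bw()

  ph <- rbind(
    data.frame(cell = records$cell, mean_risk = records$mean_risk,
               model = "base", prop = records$prop_high_base),
    data.frame(cell = records$cell, mean_risk = records$mean_risk,
               model = "base + new predictor", prop = records$prop_high_full)
  )
  ph <- ph[is.finite(ph$mean_risk) & is.finite(ph$prop), ]
  plot_prop_high <- ggplot2::ggplot(
    ph, ggplot2::aes(x = .data$mean_risk, y = .data$prop,
                     colour = .data$model, linetype = .data$model)) +
    ggplot2::geom_smooth(method = "gam", formula = y ~ s(x, bs = "cs"),
                         se = FALSE, linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = cutpoint, linetype = 2,
                        colour = "grey40") +
    ggplot2::facet_wrap(~cell) +
    ggplot2::labs(x = "Mean 10-year risk", y = "Proportion above cutpoint",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_bw()

  structure(list(curves = curves, peaks = peaks,
                 plot_measures = plot_measures,
                 plot_prop_high = plot_prop_high),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat("Simulation study summary\n")
  cat(sprintf("  %d cell(s), smoothed curves for %d measure set(s)\n",
              length(x$curves),
              if (length(x$curves)) length(x$curves[[1]]) else 0))
  if (nrow(x$peaks)) {
    cat("  Peak locations of the clinical-utility measures:\n")
    print(x$peaks, row.names = FALSE)
  }
  invisible(x)
}
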