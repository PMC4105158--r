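#' Kaplan-Meier sensitivity and specificity at a risk cutpoint
#'
#' Classification accuracy of "predicted risk greater than `cutpoint`" for
#' the outcome "event by `t` years", with events and non-events counted via
#' Kaplan-Meier estimates so that censored subjects contribute correctly:
#' true positives are `n_high * (1 - KM_high(t))`, total events
#' `n * (1 - KM_all(t))`, true negatives `n_low * KM_low(t)`, total
#' non-events `n * KM_all(t)`. High risk means strictly greater than the
#' cutpoint; a risk exactly at the cutpoint is classified low.
#'
#' @param risks Predicted risks in `[0, 1]`, aligned with `data`.
#' @param data Survival `data.frame`.
#' @param cutpoint High-risk threshold probability, in `(0, 1)`.
#' @param t Horizon in years (default 10).
#' @return An object of class `classification_summary` with elements
#'   `sensitivity`, `specificity`, `binary_c`, `prop_high`, `cutpoint`,
#'   `horizon`, `n`, `events` (KM-weighted, possibly non-integer).
#' @export
km_sensitivity_specificity <- function(risks, data, cutpoint, t = 10) {
  validate_survival_data(data)
  n <- nrow(data)
  if (length(risks) != n) stop("`risks` must align with `data`", call. = FALSE)
  if (anyNA(risks) || any(risks < 0) || any(risks > 1))
    stop("`risks` must be probabilities in [0, 1]", call. = FALSE)
  if (length(cutpoint) != 1L || cutpoint <= 0 || cutpoint >= 1)
    stop("`cutpoint` must be in (0, 1)", call. = FALSE)
  high <- risks > cutpoint
  km_all <- .km_at(data$time, data$event, t)
  events <- n * (1 - km_all)
  nonevents <- n * km_all
  tp <- if (any(high))
    sum(high) * (1 - .km_at(data$time[high], data$event[high], t)) else 0
  tn <- if (any(!high))
    sum(!high) * .km_at(data$time[!high], data$event[!high], t) else 0
  if (events <= 0)
    stop("no events by the horizon; sensitivity undefined", call. = FALSE)
  if (nonevents <= 0)
    stop("no non-events at the horizon; specificity undefined", call. = FALSE)
  sens <- tp / events
  spec <- tn / nonevents
  structure(
    list(sensitivity = sens, specificity = spec,
         binary_c = 0.5 * (sens + spec),
         prop_high = mean(high), cutpoint = cutpoint, horizon = t,
         n = n, events = events, true_positives = tp, true_negatives = tn),
    class = "classification_summary"
  )
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf(
    "Classification at risk > %.3g (horizon %gy): sens %.3f, spec %.3f, binary c %.3f, %0.1f%% high risk\n",
    x$cutpoint, x$horizon, x$sensitivity, x$specificity, x$binary_c,
    100 * x$prop_high))
  invisible(x)
}

.check_comparable <- function(base, full) {
  if (!inherits(base, "classification_summary") ||
      !inherits(full, "classification_summary"))
    stop("expected `classification_summary` objects", call. = FALSE)
  if (base$cutpoint != full$cutpoint || base$horizon != full$horizon)
    stop("summaries use different cutpoints or horizons; not comparable",
         call. = FALSE)
}

#' Difference in the binary c-statistic between two models
#'
#' The binary c-statistic at a cutpoint is `(sensitivity + specificity)/2`;
#' its between-model difference is half the sum of the sensitivity and
#' specificity changes.
#'
#' @param base,full [km_sensitivity_specificity()] summaries for the base
#'   and extended model, at the same cutpoint and horizon.
#' @return The difference (full minus base), a numeric scalar.
#' @seealso [nri_binary()], which is exactly twice this quantity.
#' @export
binary_c_difference <- function(base, full) {
  .check_comparable(base, full)
  0.5 * ((full$sensitivity - base$sensitivity) +
           (full$specificity - base$specificity))
}

#' Binary net reclassification improvement
#'
#' NRI at a single cutpoint: the sensitivity change plus the specificity
#' change, identically `2 *` [binary_c_difference()].
#'
#' @inheritParams binary_c_difference
#' @return The binary NRI (full minus base).
#' @export
nri_binary <- function(base, full) {
  .check_comparable(base, full)
  (full$sensitivity - base$sensitivity) +
    (full$specificity - base$specificity)
}

#' Continuous net reclassification improvement, NRI(>0)
#'
#' Any increase in predicted risk counts as reclassified up, any decrease as
#' down. Event probabilities within the up group, the down group and
#' overall are Kaplan-Meier estimates at `t`, making the measure valid
#' under right-censoring:
#' `NRI(>0) = [P(e|up) nU - P(e|down) nD] / [n P(e)] +`
#' `[(1-P(e|down)) nD - (1-P(e|up)) nU] / [n (1-P(e))]`.
#'
#' @param base_risks,full_risks Paired predicted risks under the two models.
#' @param data Survival `data.frame` aligned with the risks.
#' @param t Horizon in years (default 10).
#' @param min_change Minimum absolute risk change that counts as
#'   reclassification (default 0: any change counts).
#' @return The NRI(>0), a numeric scalar in `[-2, 2]`.
#' @export
nri_continuous <- function(base_risks, full_risks, data, t = 10,
                           min_change = 0) {
  validate_survival_data(data)
  n <- nrow(data)
  if (length(base_risks) != n || length(full_risks) != n)
    stop("risks must align with `data`", call. = FALSE)
  up <- (full_risks - base_risks) > min_change
  down <- (base_risks - full_risks) > min_change
  p_all <- 1 - .km_at(data$time, data$event, t)
  if (p_all <= 0 || p_all >= 1)
    stop("need both events and non-events by the horizon", call. = FALSE)
  nU <- sum(up); nD <- sum(down)
  pU <- if (nU > 0) 1 - .km_at(data$time[up], data$event[up], t) else 0
  pD <- if (nD > 0) 1 - .km_at(data$time[down], data$event[down], t) else 0
  (pU * nU - pD * nD) / (n * p_all) +
    ((1 - pD) * nD - (1 - pU) * nU) / (n * (1 - p_all))
}

#' Reclassification table with per-cell Kaplan-Meier event probabilities
#'
#' Cross-classifies subjects by risk category under the base and extended
#' model. Categories are defined by 1 or 2 strictly increasing cutpoints,
#' with strict inequality: a risk belongs to the higher category only when
#' it exceeds the cutpoint. Each cell carries its subject count and its
#' Kaplan-Meier event probability at the horizon (0 for cells without
#' observed events; empty cells hold 0 subjects).
#'
#' @param base_risks,full_risks Paired predicted risks under the two models.
#' @param data Survival `data.frame` aligned with the risks.
#' @param cutpoints One or two strictly increasing probabilities in `(0, 1)`.
#' @param t Horizon in years (default 10).
#' @return An object of class `reclass_table`: matrices `counts`,
#'   `event_prob`, `events`, `nonevents` (base categories in rows, new model
#'   categories in columns), plus `n_up`, `n_down`, `cutpoints`, `horizon`.
#' @export
reclassification_table <- function(base_risks, full_risks, data, cutpoints,
                                   t = 10) {
  validate_survival_data(data)
  n <- nrow(data)
  if (length(base_risks) != n || length(full_risks) != n)
    stop("risks must align with `data`", call. = FALSE)
  if (!length(cutpoints) %in% 1:2 || any(cutpoints <= 0) ||
      any(cutpoints >= 1) || is.unsorted(cutpoints, strictly = TRUE))
    stop("`cutpoints` must be 1 or 2 strictly increasing values in (0, 1)",
         call. = FALSE)
  k <- length(cutpoints) + 1L
  cat_of <- function(r) 1L + rowSums(outer(r, cutpoints, ">"))
  cb <- cat_of(base_risks)
  cf <- cat_of(full_risks)
  labs <- c(sprintf("<=%g", cutpoints[1]),
            if (k == 3L) sprintf("(%g,%g]", cutpoints[1], cutpoints[2]),
            sprintf(">%g", cutpoints[length(cutpoints)]))
  counts <- matrix(0, k, k, dimnames = list(base = labs, full = labs))
  evp <- counts
  for (i in seq_len(k)) for (j in seq_len(k)) {
    sel <- cb == i & cf == j
    counts[i, j] <- sum(sel)
    if (any(sel)) {
      if (any(data$event[sel] == 1))
        evp[i, j] <- 1 - .km_at(data$time[sel], data$event[sel], t)
    }
  }
  structure(
    list(counts = counts, event_prob = evp,
         events = counts * evp, nonevents = counts * (1 - evp),
         n_up = sum(counts[upper.tri(counts)]),
         n_down = sum(counts[lower.tri(counts)]),
         cutpoints = cutpoints, horizon = t),
    class = "reclass_table"
  )
}

#' @export
print.reclass_table <- function(x, ...) {
  cat(sprintf("Reclassification table (horizon %gy), counts:\n", x$horizon))
  print(x$counts)
  cat("KM event probability per cell:\n")
  print(round(x$event_prob, 4))
  cat(sprintf("%d reclassified up, %d down\n", x$n_up, x$n_down))
  invisible(x)
}

#' Export a reclassification table as a data frame
#'
#' @param x A `reclass_table`.
#' @param ... Unused.
#' @return Long-format `data.frame` with one row per cell: base category,
#'   new category, count, KM event probability, KM-weighted events and
#'   non-events.
#' @export
as.data.frame.reclass_table <- function(x, ...) {
  k <- nrow(x$counts)
  g <- expand.grid(base = rownames(x$counts), full = colnames(x$counts),
                   stringsAsFactors = FALSE)
  data.frame(g, count = as.vector(x$counts),
             event_prob = as.vector(x$event_prob),
             events = as.vector(x$events),
             nonevents = as.vector(x$nonevents))
}

#' Categorical net reclassification improvement
#'
#' NRI across risk categories defined by one or two cutpoints (e.g. 10% and
#' 20%). Events and non-events per reclassification-table cell are estimated
#' from the cell's Kaplan-Meier event probability at the horizon, so counts
#' may be non-integer:
#' `NRI = p(up|events) - p(down|events) + p(down|non-events) - p(up|non-events)`.
#'
#' @inheritParams reclassification_table
#' @return The categorical NRI, a numeric scalar in `[-2, 2]`. The
#'   underlying table is available via [reclassification_table()].
#' @export
nri_categorical <- function(base_risks, full_risks, data, cutpoints,
                            t = 10) {
  tab <- reclassification_table(base_risks, full_risks, data, cutpoints, t)
  ev <- tab$events
  ne <- tab$nonevents
  E <- sum(ev); NE <- sum(ne)
  if (E <= 0) stop("no events by the horizon; NRI undefined", call. = FALSE)
  if (NE <= 0) stop("no non-events at the horizon; NRI undefined", call. = FALSE)
  up <- upper.tri(ev); down <- lower.tri(ev)
  (sum(ev[up]) - sum(ev[down])) / E + (sum(ne[down]) - sum(ne[up])) / NE
}
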