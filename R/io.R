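#' Read and write survival datasets as CSV
#'
#' Datasets use the column convention `id, time, event, <covariates>`, with
#' times in years and `event` coded 0/1.
#'
#' @param path CSV file path.
#' @return `read_survival_csv()` returns a validated `data.frame`;
#'   `write_survival_csv()` returns `path` invisibly.
#' @export
read_survival_csv <- function(path) {
  data <- utils::read.csv(path)
  covs <- setdiff(names(data), c("id", "time", "event"))
  validate_survival_data(data, covs)
  data
}

#' @rdname read_survival_csv
#' @param data Survival `data.frame`.
#' @export
write_survival_csv <- function(data, path) {
  validate_survival_data(data)
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Read a study configuration from YAML or JSON
#'
#' Accepts the keys of [study_config()] at the top level, plus an optional
#' `utility:` block (`threshold`, `risk_reduction`, `horizon`, `efly_value`)
#' parsed into a [utility_config()].
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `study` (a `study_config`) and `utility`
#'   (a `utility_config` or `NULL`).
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml, .yml or .json", call. = FALSE)
  util <- NULL
  if (!is.null(raw$utility)) {
    u <- raw$utility
    util <- utility_config(
      threshold = u$threshold %||% 0.20,
      risk_reduction = u$risk_reduction %||% 0.20,
      horizon = u$horizon %||% 10,
      efly_value = u$efly_value %||% 20000
    )
    raw$utility <- NULL
  }
  known <- names(formals(study_config))
  raw <- raw[intersect(names(raw), known)]
  # YAML sequences with mixed int/double scalars parse as lists; flatten
  for (nm in c("baseline_hr", "predictor_hr", "mean_risk_range", "cutpoints"))
    if (nm %in% names(raw)) raw[[nm]] <- as.numeric(unlist(raw[[nm]]))
  list(study = do.call(study_config, raw), utility = util)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
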