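canonical_columns <- c("region", "year", "value", "detected")

#' Read a contaminant-concentration survey from CSV
#'
#' The canonical layout has columns `region,year,cd_mg_per_kg,detected`
#' (header required, UTF-8, `detected` coded as 0/1 or true/false).
#' Other layouts are absorbed with `dialect`, a named character vector
#' mapping canonical names to the file's column names.
#'
#' Non-detect rows are stored with `value = 0` regardless of any trace value
#' reported in the file: this is the censoring convention under which all
#' downstream means are computed.
#'
#' @param path Path to a CSV file.
#' @param dialect Named character vector, e.g.
#'   `c(value = "cadmium", detected = "quantified")`; unmapped canonical
#'   names fall back to the canonical layout (`value` maps to
#'   `cd_mg_per_kg`).
#' @return A tibble of concentration records with columns
#'   `region` (character), `year` (integer), `value` (mg/kg fresh weight)
#'   and `detected` (logical).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "region,year,cd_mg_per_kg,detected",
#'   "Yilan,2018,0.10,1", "Yilan,2018,0.00,0", "Taitung,2017,0.02,1"
#' ), f)
#' read_concentration_survey(f)
#' @export
read_concentration_survey <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    stop_schema(sprintf("Survey file not found: '%s'.", path))
  }
  cols <- c(region = "region", year = "year",
            value = "cd_mg_per_kg", detected = "detected")
  if (!is.null(dialect)) {
    bad <- setdiff(names(dialect), canonical_columns)
    if (length(bad) > 0) {
      stop_schema(sprintf("Unknown dialect key(s): %s.",
                          paste(bad, collapse = ", ")))
    }
    cols[names(dialect)] <- dialect
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- cols[!cols %in% names(raw)]
  if (length(missing) > 0) {
    stop_schema(sprintf(
      "Survey file is missing required column(s): %s.",
      paste(sprintf("'%s'", missing), collapse = ", ")
    ))
  }
  out <- tibble::tibble(
    region = as.character(raw[[cols[["region"]]]]),
    year = as.integer(raw[[cols[["year"]]]]),
    value = as.numeric(raw[[cols[["value"]]]]),
    detected = parse_detected(raw[[cols[["detected"]]]])
  )
  bad_rows <- which(is.na(out$value) | out$value < 0)
  if (length(bad_rows) > 0) {
    stop_validation(sprintf(
      "Concentration values must be non-negative numbers; offending row(s): %s.",
      paste(bad_rows, collapse = ", ")
    ))
  }
  out$value[!out$detected] <- 0
  out
}

parse_detected <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "t", "yes")] <- TRUE
  out[v %in% c("0", "false", "f", "no")] <- FALSE
  if (anyNA(out)) {
    stop_validation(sprintf(
      "Column 'detected' must be 0/1 or true/false; offending row(s): %s.",
      paste(which(is.na(out)), collapse = ", ")
    ))
  }
  out
}

#' Write concentration records in the canonical CSV layout
#'
#' @param records A record tibble (see [read_concentration_survey()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentration_survey <- function(records, path) {
  records <- validate_records(records)
  out <- tibble::tibble(
    region = records$region, year = records$year,
    cd_mg_per_kg = records$value, detected = as.integer(records$detected)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

validate_records <- function(records) {
  if (!is.data.frame(records)) {
    stop_schema("`records` must be a data frame of concentration records.")
  }
  need <- c("value", "detected")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    stop_schema(sprintf("`records` is missing column(s): %s.",
                        paste(missing, collapse = ", ")))
  }
  if (any(is.na(records$value) | records$value < 0)) {
    stop_validation("Concentration values must be non-negative and non-missing.")
  }
  tibble::as_tibble(records)
}

#' Descriptive summaries of a concentration survey
#'
#' Computes n, mean, SD (sample, n-1 denominator), median, maximum and
#' detection rate, overall or grouped by region or year. All statistics
#' include non-detect zeros, matching the convention under which censored
#' survey means are reported.
#'
#' @param records A record tibble (see [read_concentration_survey()]).
#' @param by Grouping: `"none"` (one pooled row), `"region"` or `"year"`.
#' @return A tibble with one row per group and columns `n`, `mean`, `sd`,
#'   `median`, `max`, `detect_rate` (plus the grouping column, if any).
#' @examples
#' rec <- tibble::tibble(
#'   region = "A", year = 2018,
#'   value = c(0, 0.02, 0.04, 0.10), detected = c(FALSE, TRUE, TRUE, TRUE)
#' )
#' summarize_concentrations(rec)
#' @export
summarize_concentrations <- function(records, by = c("none", "region", "year")) {
  by <- match.arg(by)
  records <- validate_records(records)
  if (nrow(records) == 0) {
    stop_validation("Cannot summarize an empty record set.")
  }
  grouped <- switch(by,
    none = records,
    region = dplyr::group_by(records, .data$region),
    year = dplyr::group_by(records, .data$year)
  )
  dplyr::summarise(
    grouped,
    n = dplyr::n(),
    mean = mean(.data$value),
    sd = ifelse(dplyr::n() > 1, sd(.data$value), 0),
    median = median(.data$value),
    max = max(.data$value),
    detect_rate = mean(.data$detected),
    .groups = "drop"
  )
}

#' Yearly five-number summaries (box-plot statistics)
#'
#' Minimum, first quartile, median, third quartile and maximum per calendar
#' year, using the same linear-interpolation percentile rule as the exposure
#' engine ([percentile()]).
#'
#' @inheritParams summarize_concentrations
#' @return A tibble with columns `year`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
five_number_summary_by_year <- function(records) {
  records <- validate_records(records)
  if (nrow(records) == 0) {
    stop_validation("Cannot summarize an empty record set.")
  }
  records |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      min = percentile(.data$value, 0),
      q1 = percentile(.data$value, 25),
      median = percentile(.data$value, 50),
      q3 = percentile(.data$value, 75),
      max = percentile(.data$value, 100),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$year)
}

#' Check a survey against a regulatory maximum level
#'
#' @inheritParams summarize_concentrations
#' @param max_level Regulatory maximum level, mg/kg; must be positive
#'   (`Inf` allowed).
#' @return A one-row tibble with `n_total`, `n_exceeding` (records strictly
#'   above `max_level`) and `fraction_exceeding` (0 for an empty survey).
#' @examples
#' rec <- tibble::tibble(region = "A", year = 2018,
#'                       value = c(0.1, 0.25), detected = TRUE)
#' compliance_check(rec, max_level = 0.2)
#' @export
compliance_check <- function(records, max_level) {
  check_number(max_level, "max_level", allow_inf = TRUE)
  if (max_level <= 0) stop_domain("`max_level` must be positive.")
  records <- validate_records(records)
  n <- nrow(records)
  n_exc <- sum(records$value > max_level)
  tibble::tibble(
    n_total = n,
    n_exceeding = n_exc,
    fraction_exceeding = if (n == 0) 0 else n_exc / n
  )
}

#' Read reference constants from a YAML file
#'
#' @param path Path to a constants YAML; defaults to the packaged file (see
#'   [reference_constants()]).
#' @return A named list of constants, validated for positivity and for
#'   internal consistency of the weekly-to-daily reference-dose conversion.
#' @export
read_constants <- function(path = NULL) {
  path <- path %||% cdrice_file("constants.yaml")
  if (!file.exists(path)) {
    stop_schema(sprintf("Constants file not found: '%s'.", path))
  }
  const <- yaml::read_yaml(path)
  need <- c("rfd_efsa", "twi_efsa", "ptwi_jecfa", "ptmi_jecfa",
            "rfd_epa_water", "rfd_epa_food", "ml_taiwan", "ml_china")
  missing <- setdiff(need, names(const))
  if (length(missing) > 0) {
    stop_schema(sprintf("Constants file is missing key(s): %s.",
                        paste(missing, collapse = ", ")))
  }
  for (k in need) check_number(const[[k]], k)
  if (any(unlist(const[need]) <= 0)) {
    stop_validation("All reference constants must be strictly positive.")
  }
  if (abs(const$rfd_efsa - round(const$twi_efsa / 7, 2)) > 1e-12) {
    stop_validation("rfd_efsa must equal twi_efsa/7 rounded to two decimals.")
  }
  const
}
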