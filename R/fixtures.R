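#' Path to a packaged data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @export
cdrice_file <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "cdrice")))
  }
  path <- system.file("extdata", file, package = "cdrice")
  if (identical(path, "")) {
    stop_schema(sprintf("No packaged file named '%s'.", file))
  }
  path
}

#' Published per-region concentration summaries (survey fixture)
#'
#' Summary statistics (n, mean, SD, median, max; mg/kg fresh weight) of the
#' 1,581-sample Taiwanese rice cadmium survey, by production region, as
#' published. Per-region detection rates were not published; all rows carry
#' the overall 89% rate.
#'
#' @param include_total If `TRUE`, keep the pooled `"Total"` row.
#' @return A tibble with columns `region`, `n`, `mean`, `sd`, `median`,
#'   `max`, `detect_rate`.
#' @seealso [table1_total()], [table2_groups()]
#' @export
table1_summaries <- function(include_total = FALSE) {
  tbl <- readr::read_csv(cdrice_file("table1_summaries.csv"),
                         show_col_types = FALSE, progress = FALSE)
  if (!include_total) {
    tbl <- dplyr::filter(tbl, .data$region != "Total")
  }
  tbl
}

#' Pooled (total-survey) concentration summary row
#'
#' @return A one-row tibble: the pooled summary of the full survey
#'   (n = 1581, mean 0.04, SD 0.04, max 0.39 mg/kg, 89% detection).
#' @export
table1_total <- function() {
  dplyr::filter(table1_summaries(include_total = TRUE), .data$region == "Total")
}

#' Published consumption and body-weight parameters by age-gender stratum
#'
#' Consumer-only daily rice intake (g/day) and body weight (kg) for 14
#' age-gender strata, each given as the arithmetic mean and SD of a
#' lognormal model, with the observed intake range used as truncation
#' bounds.
#'
#' @return A tibble with columns `group`, `intake_mean`, `intake_sd`,
#'   `intake_min`, `intake_max`, `bw_mean`, `bw_sd`.
#' @export
table2_groups <- function() {
  readr::read_csv(cdrice_file("table2_groups.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Reference constants for cadmium risk characterization
#'
#' @return Named list of reference doses, tolerable intakes and maximum
#'   levels (see the packaged `constants.yaml` for units).
#' @export
reference_constants <- function() {
  read_constants(cdrice_file("constants.yaml"))
}

#' Build a consumption-group object
#'
#' @param label Stratum label, e.g. `"19-65 years, male"`.
#' @param intake A [lognormal_spec()] for daily intake in g/day (usually
#'   truncated to the observed consumption range).
#' @param bodyweight A [lognormal_spec()] for body weight in kg
#'   (untruncated).
#' @return An object of class `cd_group`.
#' @export
consumption_group <- function(label, intake, bodyweight) {
  stopifnot(is.character(label), length(label) == 1,
            inherits(intake, "cd_lognormal"),
            inherits(bodyweight, "cd_lognormal"))
  structure(list(label = label, intake = intake, bodyweight = bodyweight),
            class = "cd_group")
}

#' @export
print.cd_group <- function(x, ...) {
  cat(sprintf("<cd_group> %s\n  intake (g/day): ", x$label))
  print(x$intake)
  cat("  body weight (kg): ")
  print(x$bodyweight)
  invisible(x)
}

#' Convert a group parameter table to consumption-group objects
#'
#' @param groups A data frame in the layout of [table2_groups()]; defaults
#'   to the packaged table.
#' @return A named list of [consumption_group()] objects, keyed by label.
#' @examples
#' g <- consumption_groups()
#' g[["19-65 years, male"]]
#' @export
consumption_groups <- function(groups = table2_groups()) {
  need <- c("group", "intake_mean", "intake_sd", "intake_min", "intake_max",
            "bw_mean", "bw_sd")
  missing <- setdiff(need, names(groups))
  if (length(missing) > 0) {
    stop_schema(sprintf("`groups` is missing column(s): %s.",
                        paste(missing, collapse = ", ")))
  }
  out <- purrr::pmap(groups[need], function(group, intake_mean, intake_sd,
                                            intake_min, intake_max,
                                            bw_mean, bw_sd) {
    consumption_group(
      label = group,
      intake = lognormal_spec(intake_mean, intake_sd,
                              lower = intake_min, upper = intake_max),
      bodyweight = lognormal_spec(bw_mean, bw_sd)
    )
  })
  setNames(out, groups$group)
}
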