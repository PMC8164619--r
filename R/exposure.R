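#' Simulation settings for the exposure engine
#'
#' Bundles the deterministic factors of the lifetime-average-daily-dose
#' (LADD) equation, the reference dose used for hazard characterization,
#' and the Monte Carlo settings.
#'
#' @param af Absorption factor, fraction in (0, 1]. Default 1 (complete
#'   absorption, the conservative convention for ingested cadmium).
#' @param ed Exposure duration, years.
#' @param at Averaging time, years. The engine uses only the ratio
#'   `ed/at`, which must lie in (0, 1]; the default 1/1 averages lifetime
#'   exposure over a lifetime.
#' @param rfd Reference dose in ug/kg bw/day. Default 0.36, the EFSA
#'   tolerable weekly intake of 2.5 ug/kg bw converted to a daily basis.
#' @param iterations Monte Carlo draws per group. Default 100,000.
#' @param seed Master seed; per-group/region substreams derive from it.
#' @return An object of class `cd_params`.
#' @examples
#' exposure_params(iterations = 10000, seed = 7)
#' @export
exposure_params <- function(af = 1, ed = 1, at = 1, rfd = 0.36,
                            iterations = 100000, seed = 1L) {
  check_number(af, "af", lower = 0, upper = 1)
  if (af <= 0) stop_domain("`af` must be in (0, 1].")
  check_number(ed, "ed")
  check_number(at, "at")
  if (ed <= 0 || at <= 0 || ed / at > 1) {
    stop_domain("`ed`/`at` must be a ratio in (0, 1].")
  }
  check_number(rfd, "rfd")
  if (rfd <= 0) stop_domain("`rfd` must be positive.")
  check_number(iterations, "iterations", lower = 1)
  check_number(seed, "seed")
  structure(
    list(af = af, ed = ed, at = at, rfd = rfd,
         iterations = as.integer(iterations), seed = as.integer(seed)),
    class = "cd_params"
  )
}

#' @export
print.cd_params <- function(x, ...) {
  cat(sprintf(
    "<cd_params> AF %.3g, ED/AT %.3g, RfD %.3g ug/kg bw/day, %s iterations, seed %d\n",
    x$af, x$ed / x$at, x$rfd, format(x$iterations, big.mark = ","), x$seed
  ))
  invisible(x)
}

#' Lifetime average daily dose
#'
#' `LADD = (C x IR x AF) / BW x ED / AT`. Concentrations are carried in
#' mg/kg fresh weight, which is identical to ug/g, so with intake in g/day
#' and body weight in kg the result is in ug/kg bw/day with no further
#' conversion factor.
#'
#' @param c Contaminant concentration, mg/kg fresh weight (= ug/g).
#'   Vectorized.
#' @param ir Daily intake, g/day. Vectorized.
#' @param af Absorption factor, fraction.
#' @param bw Body weight, kg; must be positive. Vectorized.
#' @param ed,at Exposure duration and averaging time, years.
#' @return LADD in ug/kg bw/day.
#' @examples
#' compute_ladd(0.028, 121.4, 1, 68.5, 1, 1)
#' @export
compute_ladd <- function(c, ir, af, bw, ed, at) {
  if (any(bw <= 0)) stop_domain("`bw` must be strictly positive.")
  if (any(c < 0) || any(ir < 0) || af < 0 || ed < 0 || at <= 0) {
    stop_domain("LADD inputs must be non-negative (and `at` positive).")
  }
  (c * ir * af) / bw * (ed / at)
}

#' Hazard index
#'
#' `HI = LADD / RfD`: the ratio of estimated dose to the reference dose.
#' Values above 1 flag potential non-carcinogenic concern.
#'
#' @param ladd Dose in ug/kg bw/day. Vectorized.
#' @param rfd Reference dose in the same units; must be positive.
#' @return Dimensionless hazard index.
#' @export
compute_hi <- function(ladd, rfd) {
  check_number(rfd, "rfd")
  if (rfd <= 0) stop_domain("`rfd` must be positive.")
  ladd / rfd
}

#' Percentile by the linear-interpolation order-statistic rule
#'
#' A thin wrapper over the widely used "linear" rule
#' (`stats::quantile(type = 7)`), fixed package-wide so survey summaries and
#' simulation percentiles use the same estimator. `q = 0` returns the
#' minimum and `q = 100` the maximum.
#'
#' @param values Numeric vector (non-empty).
#' @param q Percentile level(s) in `[0, 100]`.
#' @return Percentile value(s), unnamed.
#' @examples
#' percentile(c(1, 2, 3, 4), 50) # 2.5
#' @export
percentile <- function(values, q) {
  if (length(values) == 0) stop_domain("`values` must be non-empty.")
  if (any(q < 0 | q > 100)) stop_domain("`q` must be in [0, 100].")
  unname(quantile(values, probs = q / 100, type = 7, names = FALSE))
}

risk_levels <- c(50, 90, 95)

#' Monte Carlo exposure simulation for one consumption stratum
#'
#' Draws `iterations` independent (concentration, intake, body-weight)
#' triples, computes the LADD for each draw, and reports the 50th, 90th and
#' 95th percentiles of LADD and of the hazard index HI = LADD/RfD. HI
#' percentiles are computed from unrounded LADD percentiles (division by a
#' positive constant commutes with order statistics).
#'
#' The RNG substream is keyed by the group label and the master seed, so a
#' stratum's result does not depend on which other strata are simulated
#' alongside it.
#'
#' @param conc_model A [zero_inflated_lognormal()] concentration model.
#' @param group A [consumption_group()] object.
#' @param params An [exposure_params()] object.
#' @return A one-row tibble of class `cd_risk` with columns `group`,
#'   `ladd_p50`, `ladd_p90`, `ladd_p95` (ug/kg bw/day) and `hi_p50`,
#'   `hi_p90`, `hi_p95` (dimensionless).
#' @examples
#' model <- from_summary(table1_total())
#' grp <- consumption_groups()[["19-65 years, male"]]
#' run_group_simulation(model, grp, exposure_params(iterations = 5000))
#' @export
run_group_simulation <- function(conc_model, group, params = exposure_params()) {
  stopifnot(inherits(conc_model, "cd_zilognormal"),
            inherits(group, "cd_group"),
            inherits(params, "cd_params"))
  set.seed(substream_seed(params$seed, paste0("group:", group$label)))
  conc <- sample_concentration(conc_model, params$iterations)
  ir <- sample_truncated_lognormal(group$intake, params$iterations)
  bw <- sample_truncated_lognormal(group$bodyweight, params$iterations)
  ladd <- compute_ladd(conc, ir, params$af, bw, params$ed, params$at)
  ladd_q <- percentile(ladd, risk_levels)
  hi_q <- compute_hi(ladd_q, params$rfd)
  out <- tibble::tibble(
    group = group$label,
    ladd_p50 = ladd_q[1], ladd_p90 = ladd_q[2], ladd_p95 = ladd_q[3],
    hi_p50 = hi_q[1], hi_p90 = hi_q[2], hi_p95 = hi_q[3]
  )
  new_cd_risk(out, params, conc_model)
}

new_cd_risk <- function(tbl, params, conc_model) {
  structure(tbl,
            class = c("cd_risk", class(tibble::tibble())),
            params = params, conc_model = conc_model)
}

#' Simulate all consumption strata
#'
#' Runs [run_group_simulation()] for every stratum. Substreams are keyed by
#' stratum label, so permuting the input rows permutes the output rows
#' without changing any stratum's numbers.
#'
#' @param conc_model A [zero_inflated_lognormal()] concentration model.
#' @param groups A parameter table in the layout of [table2_groups()], or a
#'   list of [consumption_group()] objects.
#' @param params An [exposure_params()] object.
#' @return A tibble of class `cd_risk`, one row per stratum (see
#'   [run_group_simulation()]).
#' @examples
#' model <- from_summary(table1_total())
#' run_all_groups(model, table2_groups(), exposure_params(iterations = 2000))
#' @export
run_all_groups <- function(conc_model, groups = table2_groups(),
                           params = exposure_params()) {
  grp_list <- if (is.data.frame(groups)) consumption_groups(groups) else groups
  if (length(grp_list) == 0) stop_validation("`groups` must be non-empty.")
  rows <- purrr::map(grp_list, run_group_simulation,
                     conc_model = conc_model, params = params)
  new_cd_risk(dplyr::bind_rows(rows), params, conc_model)
}

#' Per-region hazard-index table
#'
#' Builds a concentration model from each region's summary row with
#' [from_summary()] and simulates one consumption stratum against it,
#' reporting the median hazard index per region (heatmap-ready). Substreams
#' are keyed by region label: identical summary rows with the same label
#' give identical results regardless of position.
#'
#' @param summaries Per-region summary table in the layout of
#'   [table1_summaries()].
#' @param group A [consumption_group()] object (conventionally the 19-65
#'   male stratum).
#' @param params An [exposure_params()] object.
#' @return A tibble of class `cd_regional` with columns `region` and
#'   `hi_p50`, sorted by descending `hi_p50`.
#' @examples
#' grp <- consumption_groups()[["19-65 years, male"]]
#' regional_hi_table(table1_summaries()[1:3, ], grp,
#'                   exposure_params(iterations = 2000))
#' @export
regional_hi_table <- function(summaries, group, params = exposure_params()) {
  stopifnot(inherits(group, "cd_group"), inherits(params, "cd_params"))
  if (!is.data.frame(summaries) || nrow(summaries) == 0) {
    stop_validation("`summaries` must be a non-empty data frame.")
  }
  rows <- purrr::map(seq_len(nrow(summaries)), function(i) {
    s <- summaries[i, ]
    model <- from_summary(s)
    region_params <- params
    region_params$seed <- substream_seed(params$seed,
                                         paste0("region:", s$region))
    res <- run_group_simulation(model, group, region_params)
    tibble::tibble(region = s$region, hi_p50 = res$hi_p50)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$hi_p50))
  structure(out, class = c("cd_regional", class(tibble::tibble())),
            params = params, group = group$label)
}
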