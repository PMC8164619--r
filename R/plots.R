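# ggplot2 graphics for survey and simulation results

#' Yearly box plot of survey concentrations
#'
#' Five-number summaries (min, Q1, median, Q3, max) per sampling year,
#' drawn from the same percentile rule as [five_number_summary_by_year()].
#'
#' @param records A record tibble (see [read_concentration_survey()]).
#' @return A ggplot object.
#' @export
plot_yearly_concentrations <- function(records) {
  stats <- five_number_summary_by_year(records)
  ggplot2::ggplot(stats, ggplot2::aes(x = factor(.data$year))) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$min, lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$max),
      stat = "identity", width = 0.6, fill = "grey85"
    ) +
    ggplot2::labs(x = "Year", y = "Cd concentration (mg/kg fresh weight)") +
    ggplot2::theme_minimal()
}

#' Regional hazard-index chart
#'
#' @param x A `cd_regional` table from [regional_hi_table()].
#' @return A ggplot object: regions ordered by median HI, with the HI = 1
#'   concern threshold marked.
#' @export
plot_regional_hi <- function(x) {
  ggplot2::ggplot(
    tibble::as_tibble(x),
    ggplot2::aes(x = .data$hi_p50,
                 y = stats::reorder(.data$region, .data$hi_p50),
                 fill = .data$hi_p50)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::labs(x = "Hazard index (P50)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cd_regional <- function(object, ...) {
  plot_regional_hi(object)
}

#' Plot per-stratum risk percentiles
#'
#' @param object A `cd_risk` table.
#' @param quantity `"hi"` (default) or `"ladd"`.
#' @param ... Unused.
#' @return A ggplot object: P50 points with P50-P95 ranges per stratum; for
#'   HI, the concern threshold HI = 1 is marked.
#' @export
autoplot.cd_risk <- function(object, quantity = c("hi", "ladd"), ...) {
  quantity <- match.arg(quantity)
  long <- tidy.cd_risk(object) |>
    dplyr::filter(.data$quantity == !!quantity) |>
    tidyr::pivot_wider(names_from = "percentile", values_from = "value",
                       names_prefix = "p")
  lab <- if (quantity == "hi") "Hazard index" else "LADD (ug/kg bw/day)"
  p <- ggplot2::ggplot(
    long,
    ggplot2::aes(y = stats::reorder(.data$group, .data$p50))
  ) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$p50, xmax = .data$p95),
                            linewidth = 0.4, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(x = .data$p50), size = 2) +
    ggplot2::geom_point(ggplot2::aes(x = .data$p90), shape = 1) +
    ggplot2::labs(x = paste(lab, "(P50 dot, P90 circle, P95 range end)"),
                  y = NULL) +
    ggplot2::theme_minimal()
  if (quantity == "hi") {
    p <- p + ggplot2::geom_vline(xintercept = 1, linetype = "dashed")
  }
  p
}

#' Density of a lognormal exposure-factor model
#'
#' @param object A `cd_lognormal` object.
#' @param ... Unused.
#' @return A ggplot object showing the (truncated) density.
#' @export
autoplot.cd_lognormal <- function(object, ...) {
  upper <- if (is.finite(object$upper)) object$upper else
    qlnorm(0.999, object$mu_log, object$sigma_log)
  grid <- seq(max(object$lower, upper / 1000), upper, length.out = 400)
  dens <- dlnorm(grid, object$mu_log, object$sigma_log) / trunc_mass(object)
  ggplot2::ggplot(tibble::tibble(x = grid, density = dens),
                  ggplot2::aes(.data$x, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Value", y = "Density") +
    ggplot2::theme_minimal()
}
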