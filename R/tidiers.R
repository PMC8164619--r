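# broom-style methods for the package's result and model objects

#' Tidy a group-risk simulation result
#'
#' @param x A `cd_risk` object from [run_group_simulation()] or
#'   [run_all_groups()].
#' @param ... Unused.
#' @return A long tibble with columns `group`, `quantity` (`"ladd"` in
#'   ug/kg bw/day or `"hi"`, dimensionless), `percentile` (50, 90, 95) and
#'   `value`.
#' @export
tidy.cd_risk <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(-"group", names_to = c("quantity", "percentile"),
                        names_sep = "_p", values_to = "value") |>
    dplyr::mutate(percentile = as.integer(.data$percentile))
}

#' One-row summary of a simulation run
#'
#' @inheritParams tidy.cd_risk
#' @return A one-row tibble: `n_groups`, `iterations`, `seed`, `rfd`, `af`,
#'   `ed_at` (the exposure-duration / averaging-time ratio) and
#'   `p_zero` of the concentration model.
#' @export
glance.cd_risk <- function(x, ...) {
  p <- attr(x, "params")
  m <- attr(x, "conc_model")
  tibble::tibble(
    n_groups = nrow(x), iterations = p$iterations, seed = p$seed,
    rfd = p$rfd, af = p$af, ed_at = p$ed / p$at, p_zero = m$p_zero
  )
}

#' @rdname tidy.cd_risk
#' @export
tidy.cd_regional <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Tidy a lognormal exposure-factor model
#'
#' @param x A `cd_lognormal` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `value`).
#' @export
tidy.cd_lognormal <- function(x, ...) {
  tibble::tibble(
    term = c("arith_mean", "arith_sd", "mu_log", "sigma_log",
             "lower", "upper"),
    value = c(x$arith_mean, x$arith_sd, x$mu_log, x$sigma_log,
              x$lower, x$upper)
  )
}

#' @rdname tidy.cd_lognormal
#' @export
glance.cd_lognormal <- function(x, ...) {
  tibble::tibble(
    median = exp(x$mu_log),
    mean_truncated = spec_mean(x),
    cv = x$arith_sd / x$arith_mean,
    truncated = x$lower > 0 || is.finite(x$upper)
  )
}

#' @rdname tidy.cd_lognormal
#' @export
glance.cd_zilognormal <- function(x, ...) {
  tibble::tibble(
    p_zero = x$p_zero,
    mean = model_mean(x),
    positive_median = exp(x$positive$mu_log)
  )
}
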