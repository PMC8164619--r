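#' Lognormal exposure-factor model parameterized by arithmetic moments
#'
#' Exposure factors in dietary risk assessment (contaminant concentration,
#' daily intake, body weight) are usually published as an arithmetic mean and
#' standard deviation on the natural scale, often with an observed range.
#' `lognormal_spec()` builds a lognormal model from those moments by the
#' method of moments, with optional truncation bounds, so that published
#' summary tables can be used directly as simulation inputs.
#'
#' The method-of-moments mapping is
#' \deqn{\sigma^2 = \log(1 + (s/m)^2), \quad \mu = \log(m) - \sigma^2/2,}
#' where \eqn{m} and \eqn{s} are the arithmetic mean and SD. The untruncated
#' model then satisfies \eqn{\exp(\mu + \sigma^2/2) = m} exactly.
#'
#' Truncation bounds are applied at sampling time by inverse-CDF restriction
#' and the underlying \eqn{\mu, \sigma} are \emph{not} re-calibrated, so a
#' truncated model has a slightly smaller mean than `arith_mean`; the exact
#' truncated mean is available from [spec_mean()].
#'
#' @param arith_mean Arithmetic mean on the natural scale; must be positive.
#' @param arith_sd Arithmetic standard deviation, same units; non-negative.
#'   `arith_sd = 0` gives a degenerate point mass at `arith_mean`.
#' @param lower,upper Truncation bounds (default `0` and `Inf`, i.e. no
#'   truncation).
#' @return An object of class `cd_lognormal`: a list with fields
#'   `arith_mean`, `arith_sd`, `lower`, `upper`, `mu_log`, `sigma_log`.
#' @examples
#' intake <- lognormal_spec(171.2, 170.4, lower = 4.4, upper = 1923)
#' exp(intake$mu_log) # implied median, g/day
#' @seealso [fit_lognormal_moments()], [sample_truncated_lognormal()]
#' @export
lognormal_spec <- function(arith_mean, arith_sd, lower = 0, upper = Inf) {
  fit <- fit_lognormal_moments(arith_mean, arith_sd)
  check_number(lower, "lower", lower = 0)
  check_number(upper, "upper", allow_inf = TRUE)
  if (lower >= upper) {
    stop_domain("`lower` must be strictly less than `upper`.")
  }
  structure(
    list(
      arith_mean = arith_mean, arith_sd = arith_sd,
      lower = lower, upper = upper,
      mu_log = fit[["mu_log"]], sigma_log = fit[["sigma_log"]]
    ),
    class = "cd_lognormal"
  )
}

#' Method-of-moments lognormal fit from arithmetic mean and SD
#'
#' @inheritParams lognormal_spec
#' @return Named numeric vector with elements `mu_log` and `sigma_log`.
#' @examples
#' fit_lognormal_moments(171.2, 170.4)
#' @export
fit_lognormal_moments <- function(arith_mean, arith_sd) {
  check_number(arith_mean, "arith_mean")
  check_number(arith_sd, "arith_sd", lower = 0)
  if (arith_mean <= 0) {
    stop_domain("`arith_mean` must be strictly positive.")
  }
  sigma2 <- log(1 + (arith_sd / arith_mean)^2)
  c(mu_log = log(arith_mean) - sigma2 / 2, sigma_log = sqrt(sigma2))
}

#' @export
print.cd_lognormal <- function(x, ...) {
  cat(sprintf(
    "<cd_lognormal> mean %.4g, sd %.4g (mu_log %.4f, sigma_log %.4f)",
    x$arith_mean, x$arith_sd, x$mu_log, x$sigma_log
  ))
  if (x$lower > 0 || is.finite(x$upper)) {
    cat(sprintf(", truncated to [%.4g, %.4g]", x$lower, x$upper))
  }
  cat("\n")
  invisible(x)
}

#' Exact mean of a (possibly truncated) lognormal model
#'
#' Used to quantify the downward bias that truncation at an observed maximum
#' introduces relative to the nominal arithmetic mean.
#'
#' @param spec A [lognormal_spec()] object.
#' @return The exact mean of the truncated distribution.
#' @export
spec_mean <- function(spec) {
  stopifnot(inherits(spec, "cd_lognormal"))
  if (spec$sigma_log == 0) {
    return(spec$arith_mean)
  }
  mass <- trunc_mass(spec)
  zl <- lnorm_z(spec$lower, spec)
  zu <- lnorm_z(spec$upper, spec)
  spec$arith_mean *
    (stats::pnorm(zu - spec$sigma_log) - stats::pnorm(zl - spec$sigma_log)) /
    mass
}

lnorm_z <- function(x, spec) {
  if (x <= 0) return(-Inf)
  if (!is.finite(x)) return(Inf)
  (log(x) - spec$mu_log) / spec$sigma_log
}

trunc_mass <- function(spec) {
  plnorm(spec$upper, spec$mu_log, spec$sigma_log) -
    plnorm(spec$lower, spec$mu_log, spec$sigma_log)
}

#' Sample from a truncated lognormal model
#'
#' Draws are generated by inverse-CDF sampling restricted to
#' \eqn{[F(\mathrm{lower}), F(\mathrm{upper})]}, which is deterministic for
#' a fixed RNG state (no rejection loop) and guarantees every draw lies
#' inside the bounds.
#'
#' @param spec A [lognormal_spec()] object.
#' @param n Number of draws.
#' @param seed Optional integer; when supplied the RNG is seeded before
#'   drawing, otherwise the current RNG stream is used.
#' @return Numeric vector of `n` draws, all within `[spec$lower, spec$upper]`.
#' @examples
#' intake <- lognormal_spec(171.2, 170.4, lower = 4.4, upper = 1923)
#' range(sample_truncated_lognormal(intake, 1000, seed = 1))
#' @export
sample_truncated_lognormal <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "cd_lognormal"))
  check_number(n, "n", lower = 1)
  maybe_seed(seed)
  if (spec$sigma_log == 0) {
    m <- spec$arith_mean
    if (m < spec$lower || m > spec$upper) {
      stop_domain("Truncation interval excludes the point mass: infeasible truncation.")
    }
    return(rep(m, n))
  }
  fl <- plnorm(spec$lower, spec$mu_log, spec$sigma_log)
  fu <- plnorm(spec$upper, spec$mu_log, spec$sigma_log)
  if (fu - fl < 1e-12) {
    stop_domain("Truncation interval carries negligible probability mass (< 1e-12): infeasible truncation.")
  }
  x <- qlnorm(runif(n, fl, fu), spec$mu_log, spec$sigma_log)
  pmin(pmax(x, spec$lower), spec$upper)
}

#' Zero-inflated lognormal concentration model
#'
#' Left-censored contaminant surveys record non-detects as zero, so the
#' concentration distribution is a mixture of a point mass at zero (with
#' probability `p_zero`) and a lognormal for quantified values.
#'
#' @param p_zero Probability mass at exactly zero (the non-detect fraction).
#' @param positive A [lognormal_spec()] for the detected (positive) values.
#' @return An object of class `cd_zilognormal`.
#' @export
zero_inflated_lognormal <- function(p_zero, positive) {
  check_number(p_zero, "p_zero", lower = 0, upper = 1)
  stopifnot(inherits(positive, "cd_lognormal"))
  structure(list(p_zero = p_zero, positive = positive),
            class = "cd_zilognormal")
}

#' @export
print.cd_zilognormal <- function(x, ...) {
  cat(sprintf("<cd_zilognormal> p_zero %.3f\n  positive: ", x$p_zero))
  print(x$positive)
  invisible(x)
}

#' Mean of a zero-inflated lognormal model
#'
#' @param model A [zero_inflated_lognormal()] object.
#' @return `(1 - p_zero)` times the (truncation-exact) mean of the positive
#'   part.
#' @export
model_mean <- function(model) {
  stopifnot(inherits(model, "cd_zilognormal"))
  (1 - model$p_zero) * spec_mean(model$positive)
}

#' Sample concentrations from a zero-inflated lognormal model
#'
#' @param model A [zero_inflated_lognormal()] object.
#' @param n Number of draws.
#' @inheritParams sample_truncated_lognormal
#' @return Numeric vector of `n` draws; a fraction `p_zero` of them (in
#'   expectation) are exactly zero.
#' @export
sample_concentration <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "cd_zilognormal"))
  check_number(n, "n", lower = 1)
  maybe_seed(seed)
  zero <- runif(n) < model$p_zero
  x <- numeric(n)
  if (any(!zero)) {
    x[!zero] <- sample_truncated_lognormal(model$positive, sum(!zero))
  }
  x
}

#' Fit a zero-inflated lognormal to concentration records
#'
#' The zero mass is the observed non-detect fraction; the positive part is a
#' method-of-moments lognormal fit to the detected values, truncated by
#' default at the observed maximum (the survey gives no evidence beyond it).
#'
#' @param records Concentration records: a data frame with columns `value`
#'   and `detected` (see [read_concentration_survey()]).
#' @param bounds Optional length-2 numeric `(lower, upper)` truncation bounds
#'   for the positive part; defaults to `c(0, max(value))`.
#' @return A [zero_inflated_lognormal()] model.
#' @examples
#' rec <- tibble::tibble(
#'   region = "A", year = 2018,
#'   value = c(0, 0.02, 0.06), detected = c(FALSE, TRUE, TRUE)
#' )
#' fit_concentration_model(rec)
#' @export
fit_concentration_model <- function(records, bounds = NULL) {
  records <- validate_records(records)
  det <- records$value[records$detected]
  if (length(det) == 0) {
    stop_domain("All records are non-detects: concentration model is degenerate.")
  }
  if (length(det) < 2) {
    stop_domain("Need at least 2 detected records to fit the positive part.")
  }
  bounds <- bounds %||% c(0, max(records$value))
  p_zero <- mean(!records$detected)
  s <- sd(det)
  pos <- lognormal_spec(mean(det), s, lower = bounds[1], upper = bounds[2])
  zero_inflated_lognormal(p_zero, pos)
}

#' Build a concentration model from a published summary row
#'
#' When raw survey records are not deposited, a zero-inflated lognormal can
#' still be constructed from a published summary (n, mean, SD, max, detection
#' rate): the positive part is moment-fitted so that the \emph{mixture} mean
#' and SD match the published values, using
#' \deqn{m_+ = m/(1-p_0), \qquad
#'       E[X_+^2] = (m^2 + s^2)/(1-p_0),}
#' and truncated at the published maximum.
#'
#' If the implied positive-part variance is negative (possible when `p_zero`
#' is large relative to the published SD) the positive part collapses to a
#' point mass with a warning. `sd = 0` with a positive mean gives a
#' point-mass model, not an error.
#'
#' @param summary A one-row data frame or list with elements `mean`, `sd`,
#'   and optionally `max` (upper truncation) and `detect_rate`.
#' @param detect_rate Optional override for the detection rate; defaults to
#'   `summary$detect_rate`, or 1 when absent (no zero inflation).
#' @return A [zero_inflated_lognormal()] model.
#' @examples
#' total <- table1_total()
#' from_summary(total) # the pooled-survey concentration model
#' @export
from_summary <- function(summary, detect_rate = NULL) {
  m <- summary$mean
  s <- summary$sd
  check_number(m, "summary$mean")
  check_number(s, "summary$sd", lower = 0)
  if (m <= 0) stop_domain("`summary$mean` must be positive.")
  dr <- detect_rate %||% summary$detect_rate %||% 1
  if (is.na(dr)) dr <- 1
  check_number(dr, "detect_rate", lower = 0, upper = 1)
  if (dr == 0) stop_domain("detect_rate 0 gives a degenerate all-zero model.")
  p_zero <- 1 - dr
  upper <- summary$max %||% Inf
  if (is.na(upper)) upper <- Inf
  m_pos <- m / dr
  ex2_pos <- (m^2 + s^2) / dr
  var_pos <- ex2_pos - m_pos^2
  if (var_pos < 0) {
    warn(sprintf(
      "Summary moments infeasible for a zero-inflated mixture (implied positive-part variance %.3g < 0); using a point mass.",
      var_pos
    ))
    var_pos <- 0
  }
  pos <- lognormal_spec(m_pos, sqrt(var_pos), lower = 0, upper = upper)
  zero_inflated_lognormal(p_zero, pos)
}
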