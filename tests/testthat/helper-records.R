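# Shared fixtures built in code.

make_records <- function(values, detected = values > 0,
                         region = "A", year = 2018L) {
  tibble::tibble(region = region, year = as.integer(year),
                 value = values, detected = detected)
}

write_survey_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# Independent method-of-moments check: recover the arithmetic mean and SD of
# a fitted lognormal by numerical integration of its density, without using
# any package code.
lnorm_moments_by_integration <- function(mu, sigma) {
  m1 <- stats::integrate(function(x) x * stats::dlnorm(x, mu, sigma),
                         0, Inf, rel.tol = 1e-10)$value
  m2 <- stats::integrate(function(x) x^2 * stats::dlnorm(x, mu, sigma),
                         0, Inf, rel.tol = 1e-10)$value
  c(mean = m1, sd = sqrt(m2 - m1^2))
}
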