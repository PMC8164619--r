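test_that("the dose equation and hazard ratio match hand arithmetic", {
  # fitted medians: pooled concentration 0.028 ug/g, adult-male intake and
  # body weight 121.4 g/day and 68.5 kg
  expect_equal(compute_ladd(0.028, 121.4, 1, 68.5, 1, 1), 0.0496,
               tolerance = 1e-3)
  expect_equal(compute_ladd(0, 100, 1, 60, 1, 1), 0)
  expect_equal(compute_ladd(0.1, 100, 0, 60, 1, 1), 0)
  # linear in concentration
  expect_equal(compute_ladd(0.056, 121.4, 1, 68.5, 1, 1),
               2 * compute_ladd(0.028, 121.4, 1, 68.5, 1, 1))
  # the ED/AT ratio rescales the dose
  expect_equal(compute_ladd(0.028, 121.4, 1, 68.5, 30, 70),
               compute_ladd(0.028, 121.4, 1, 68.5, 1, 1) * 30 / 70)
  expect_error(compute_ladd(0.028, 121.4, 1, 0, 1, 1),
               class = "cdrice_domain_error")
  expect_error(compute_ladd(-0.1, 121.4, 1, 68.5, 1, 1),
               class = "cdrice_domain_error")

  expect_equal(compute_hi(0.36, 0.36), 1)
  expect_equal(compute_hi(0.55, 0.36), 1.527778, tolerance = 1e-6)
  expect_equal(compute_hi(0, 0.36), 0)
  expect_error(compute_hi(0.5, 0), class = "cdrice_domain_error")
})

test_that("the percentile rule is the linear-interpolation order statistic", {
  expect_equal(percentile(c(1, 2, 3, 4, 5), 50), 3)
  expect_equal(percentile(c(1, 2, 3, 4), 50), 2.5)
  expect_equal(percentile(7, c(0, 37, 100)), c(7, 7, 7))
  expect_equal(percentile(c(5, 1, 9), c(0, 100)), c(1, 9))
  expect_error(percentile(numeric(0), 50), class = "cdrice_domain_error")
  expect_error(percentile(1:3, 101), class = "cdrice_domain_error")
})

test_that("exposure settings are validated", {
  expect_error(exposure_params(af = 0), class = "cdrice_domain_error")
  expect_error(exposure_params(af = 1.5), class = "cdrice_domain_error")
  expect_error(exposure_params(ed = 80, at = 70), class = "cdrice_domain_error")
  expect_error(exposure_params(rfd = 0), class = "cdrice_domain_error")
  expect_error(exposure_params(iterations = 0), class = "cdrice_domain_error")
})

test_that("group simulation is deterministic, ordered and degenerates sanely", {
  model <- from_summary(table1_total())
  grp <- consumption_groups()[["19-65 years, male"]]
  p <- exposure_params(iterations = 20000, seed = 2)
  a <- run_group_simulation(model, grp, p)
  b <- run_group_simulation(model, grp, p)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_true(a$ladd_p50 <= a$ladd_p90 && a$ladd_p90 <= a$ladd_p95)
  # HI percentiles are LADD percentiles over RfD, exactly
  expect_equal(a$hi_p50 * p$rfd, a$ladd_p50, tolerance = 1e-12)
  expect_equal(a$hi_p95 * p$rfd, a$ladd_p95, tolerance = 1e-12)

  # all-censored concentration model zeroes every percentile
  null_model <- zero_inflated_lognormal(1, lognormal_spec(0.04, 0.04))
  z <- run_group_simulation(null_model, grp, p)
  expect_identical(unname(unlist(z[, -1])), rep(0, 6))
})

test_that("all-group simulation is invariant to stratum order", {
  model <- from_summary(table1_total())
  p <- exposure_params(iterations = 5000, seed = 3)
  tbl <- table2_groups()
  res <- run_all_groups(model, tbl, p)
  expect_equal(nrow(res), 14)
  expect_true(all(res$ladd_p50 <= res$ladd_p90 & res$ladd_p90 <= res$ladd_p95))
  res_perm <- run_all_groups(model, tbl[14:1, ], p)
  expect_equal(dplyr::arrange(tibble::as_tibble(res), group),
               dplyr::arrange(tibble::as_tibble(res_perm), group))
})

test_that("simulated dose percentiles match the closed-form lognormal ratio", {
  # censoring and truncation disabled: ln(LADD) is exactly normal with
  # mu = mu_C + mu_IR - mu_BW and variance the sum of the three variances
  conc <- zero_inflated_lognormal(0, lognormal_spec(0.04, 0.04))
  grp <- consumption_group("oracle",
                           intake = lognormal_spec(171.2, 170.4),
                           bodyweight = lognormal_spec(69.33, 11.07))
  n <- 1e5
  p <- exposure_params(iterations = n, seed = 6)
  res <- run_group_simulation(conc, grp, p)

  # oracle parameters computed from first principles, not via package code
  mom <- function(m, s) {
    s2 <- log(1 + (s / m)^2)
    c(log(m) - s2 / 2, sqrt(s2))
  }
  mc <- mom(0.04, 0.04); mi <- mom(171.2, 170.4); mb <- mom(69.33, 11.07)
  mu <- mc[1] + mi[1] - mb[1]
  sg <- sqrt(mc[2]^2 + mi[2]^2 + mb[2]^2)
  for (q in c(50, 90, 95)) {
    cf <- stats::qlnorm(q / 100, mu, sg)
    se <- sqrt(q / 100 * (1 - q / 100) / n) / stats::dlnorm(cf, mu, sg)
    got <- res[[paste0("ladd_p", q)]]
    expect_lt(abs(got - cf), 3 * se)
  }
})

test_that("scaling concentration or reference dose rescales results exactly", {
  grp <- consumption_groups()[["19-65 years, male"]]
  p <- exposure_params(iterations = 20000, seed = 8)
  m1 <- from_summary(list(mean = 0.04, sd = 0.04, detect_rate = 0.89))
  k <- 3
  mk <- from_summary(list(mean = 0.04 * k, sd = 0.04 * k, detect_rate = 0.89))
  r1 <- run_group_simulation(m1, grp, p)
  rk <- run_group_simulation(mk, grp, p)
  # same substream, fixed CV: every LADD percentile scales exactly by k
  expect_equal(rk$ladd_p50, k * r1$ladd_p50, tolerance = 1e-12)
  expect_equal(rk$ladd_p95, k * r1$ladd_p95, tolerance = 1e-12)

  p2 <- exposure_params(iterations = 20000, seed = 8, rfd = 2 * p$rfd)
  r2 <- run_group_simulation(m1, grp, p2)
  expect_equal(r2$hi_p90, r1$hi_p90 / 2, tolerance = 1e-12)
  expect_equal(r2$ladd_p90, r1$ladd_p90, tolerance = 1e-12)
})

test_that("regional tables key substreams by region label", {
  grp <- consumption_groups()[["19-65 years, male"]]
  p <- exposure_params(iterations = 5000, seed = 9)
  s <- table1_summaries()[c(1, 5, 16), ]
  reg <- regional_hi_table(s, grp, p)
  expect_equal(sort(reg$region), sort(s$region))
  # permuting regions leaves each region's value unchanged
  reg2 <- regional_hi_table(s[3:1, ], grp, p)
  expect_equal(dplyr::arrange(tibble::as_tibble(reg), region),
               dplyr::arrange(tibble::as_tibble(reg2), region))
  # duplicated region rows give identical values
  dup <- regional_hi_table(s[c(1, 1), ], grp, p)
  expect_equal(dup$hi_p50[1], dup$hi_p50[2])

  # a point-mass concentration has a closed-form check: hi_p50 is the
  # median of (c * IR / BW) / rfd
  pm <- tibble::tibble(region = "PM", mean = 0.05, sd = 0, max = NA,
                       detect_rate = 1)
  one <- regional_hi_table(pm, grp, p)
  n <- 1e5
  set.seed(31)
  ir <- sample_truncated_lognormal(grp$intake, n)
  bw <- sample_truncated_lognormal(grp$bodyweight, n)
  ref <- median(0.05 * ir / bw) / p$rfd
  expect_equal(one$hi_p50, ref, tolerance = 0.03)
})

test_that("risk tidiers reshape and summarize simulation output", {
  model <- from_summary(table1_total())
  p <- exposure_params(iterations = 2000, seed = 10)
  res <- run_all_groups(model, table2_groups()[1:3, ], p)
  long <- tidy(res)
  expect_equal(nrow(long), 3 * 6)
  expect_setequal(unique(long$quantity), c("ladd", "hi"))
  expect_setequal(unique(long$percentile), c(50L, 90L, 95L))
  gl <- glance(res)
  expect_equal(gl$n_groups, 3)
  expect_equal(gl$iterations, 2000)
  expect_equal(gl$p_zero, 0.11)
})

test_that("plot builders return ggplot objects without evaluation errors", {
  set.seed(14)
  rec <- make_records(rlnorm(50, -3, 0.8), year = rep(2010:2014, 10))
  expect_s3_class(plot_yearly_concentrations(rec), "ggplot")
  grp <- consumption_groups()[["19-65 years, male"]]
  p <- exposure_params(iterations = 1000, seed = 1)
  reg <- regional_hi_table(table1_summaries()[1:3, ], grp, p)
  expect_s3_class(autoplot(reg), "ggplot")
  res <- run_all_groups(from_summary(table1_total()), table2_groups()[1:4, ], p)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(res, quantity = "ladd"), "ggplot")
  expect_s3_class(autoplot(grp$intake), "ggplot")
})
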