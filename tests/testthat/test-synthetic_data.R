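test_that("masking and censoring switches behave at their limits", {
  sim <- simulate_cohort(simulation_config(n = 100, missing_rate = 0, seed = 2))
  expect_false(anyNA(sim$records[, setdiff(names(sim$records), c("id"))]))
  sim2 <- simulate_cohort(simulation_config(n = 100, censor_rate_target = 0,
                                            admin_cap = Inf, missing_rate = 0, seed = 2))
  expect_true(all(sim2$records$event == 1))
})

test_that("realized missingness matches the binomial closed form", {
  sim <- simulate_cohort(simulation_config(n = 10000, missing_rate = 0.25, seed = 8))
  covs <- sim$records[, schema_names_for_test(sim$schema)]
  frac <- mean(as.matrix(is.na(covs)))
  expect_lt(abs(frac - 0.25), 0.02)
  row_frac <- mean(apply(is.na(covs), 1, any))
  # 1 - 0.75^9 with a ~4-sigma normal-approximation band
  expected <- 1 - 0.75^9
  tol <- 4 * sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(row_frac - expected), tol)
})

test_that("cohorts are reproducible from the seed and differ across seeds", {
  a <- simulate_cohort(simulation_config(n = 150, seed = 5))
  b <- simulate_cohort(simulation_config(n = 150, seed = 5))
  c <- simulate_cohort(simulation_config(n = 150, seed = 6))
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$records, c$records))
})

test_that("event fraction decreases in the censoring target", {
  fracs <- vapply(c(0.2, 0.5, 0.8), function(cr) {
    sim <- simulate_cohort(simulation_config(n = 2000, censor_rate_target = cr,
                                             missing_rate = 0, seed = 31))
    mean(sim$records$event)
  }, numeric(1))
  expect_true(all(diff(fracs) < 0))
  # realized censoring lands near its target
  expect_lt(abs((1 - fracs[2]) - 0.5), 0.05)
})

test_that("KM on uncensored data equals the empirical survival function; with censoring it tracks the true Weibull", {
  sim <- simulate_cohort(simulation_config(n = 1000, censor_rate_target = 0,
                                           admin_cap = Inf, missing_rate = 0,
                                           beta = rep(0, 9), seed = 12))
  t <- sim$records$time
  km <- kaplan_meier(t, sim$records$event)
  emp <- vapply(km$time, function(tk) mean(t > tk), numeric(1))
  expect_equal(km$survival, emp)

  # with censoring and null covariate effects, KM estimates the baseline Weibull
  cfg <- simulation_config(n = 5000, censor_rate_target = 0.4, missing_rate = 0,
                           beta = rep(0, 9), weibull_shape = 1.3,
                           weibull_scale = 140, admin_cap = Inf, seed = 13)
  sim2 <- simulate_cohort(cfg)
  km2 <- kaplan_meier(sim2$records$time, sim2$records$event)
  true_surv <- exp(-(km2$time / 140)^1.3)
  keep <- km2$at_risk >= 50  # tail of the curve is dominated by variance
  expect_lt(max(abs(km2$survival[keep] - true_surv[keep])), 0.03)
})

test_that("oracle C-index is ~0.5 under the null and frozen under a fixed config", {
  simnull <- simulate_cohort(simulation_config(n = 2000, beta = rep(0, 9),
                                               missing_rate = 0, seed = 17))
  cnull <- oracle_cindex(simnull$truth, simnull$records$time, simnull$records$event)
  expect_lt(abs(cnull - 0.5), 0.03)

  cfg <- simulation_config(n = 2000, beta = c(1, -1, 0.5, rep(0, 6)),
                           weibull_shape = 1, seed = 20)
  sim <- simulate_cohort(cfg)
  co <- oracle_cindex(sim$truth, sim$records$time, sim$records$event)
  # frozen once from the brute-force pair enumeration oracle
  expect_equal(co, 0.8235529624, tolerance = 1e-9)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(simulation_config(missing_rate = 1), "missing_rate")
  expect_error(simulation_config(censor_rate_target = 1.2), "censor_rate_target")
  expect_error(simulation_config(n = 1), "at least 2")
  expect_error(simulation_config(weibull_shape = 0), "positive")
  expect_error(simulation_config(beta = c(1, 2)), "length")
})
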