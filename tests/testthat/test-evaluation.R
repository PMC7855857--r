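test_that("concordance index reproduces the worked examples", {
  t <- c(1, 2, 3, 4); s <- c(1, 1, 1, 0)
  expect_equal(concordance_index(c(4, 3, 2, 1), t, s), 1)
  expect_equal(concordance_index(c(4, 3, 1, 2), t, s), 5 / 6)
  expect_equal(concordance_index(rep(2, 4), t, s), 0.5)
  expect_error(concordance_index(1:3, c(1, 2, 3), c(0, 0, 0)), "no events")
})

test_that("concordance index equals the brute-force pair oracle", {
  set.seed(71)
  for (k in 1:40) {
    inst <- random_instance(sample(5:50, 1))
    expect_identical(concordance_index(inst$risk, inst$t, inst$s),
                     brute_cindex(inst$risk, inst$t, inst$s))
  }
})

test_that("concordance index is rank-based and reversible", {
  set.seed(72)
  inst <- random_instance(40, tie_risk = FALSE)
  c0 <- concordance_index(inst$risk, inst$t, inst$s)
  expect_equal(concordance_index(exp(3 * inst$risk), inst$t, inst$s), c0)
  expect_equal(concordance_index(-inst$risk, inst$t, inst$s), 1 - c0)
})

test_that("dichotomize thresholds at the reference median with the <= rule", {
  g <- dichotomize(c(1, 2, 3, 4))
  expect_equal(g$threshold, 2.5)
  expect_equal(as.character(g$group), c("low", "low", "high", "high"))
  g2 <- dichotomize(rep(1, 5))
  expect_true(all(g2$group == "low"))
  g3 <- dichotomize(c(1, 2, 3))  # median attained -> that subject is low
  expect_equal(as.character(g3$group), c("low", "low", "high"))
})

test_that("kaplan_meier matches the hand product-limit example", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$time, c(1, 3))
  expect_equal(km$survival, c(2 / 3, 0))
  expect_equal(km$at_risk, c(3L, 1L))
  kmn <- kaplan_meier(c(3, 5, 9), c(0, 0, 0))
  expect_equal(length(kmn$time), 0L)
})

test_that("kaplan_meier is a valid survival function; zero at last event when uncensored", {
  set.seed(5)
  t <- rexp(60) + 0.5; s <- rep(1, 60)
  km <- kaplan_meier(t, s)
  expect_true(all(diff(km$survival) <= 0))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
  expect_equal(km$survival[length(km$survival)], 0)
  expect_true(all(km$lower[-length(km$lower)] <= km$survival[-length(km$survival)]))
})

test_that("kaplan_meier agrees with the survival package", {
  library(survival)
  set.seed(14)
  for (k in 1:20) {
    n <- sample(5:40, 1)
    t <- sample(1:12, n, replace = TRUE)
    s <- rbinom(n, 1, 0.6); if (sum(s) == 0) s[1] <- 1
    km <- kaplan_meier(t, s)
    sf <- summary(survfit(Surv(t, s) ~ 1), times = km$time)
    expect_equal(km$survival, sf$surv, tolerance = 1e-8)
    expect_equal(km$at_risk, as.integer(sf$n.risk))
  }
})

test_that("logrank test reproduces the hand-computed two-group example", {
  g <- rep(c("A", "B"), each = 2)
  t <- c(1, 2, 3, 4); s <- rep(1, 4)
  lr <- logrank_test(g, t, s)
  expect_equal(lr$observed, 2)
  expect_equal(lr$expected, 5 / 6)
  expect_equal(lr$statistic, (2 - 5 / 6)^2 / (17 / 36), tolerance = 1e-12)
})

test_that("logrank test is null on identical samples and symmetric in labels", {
  t0 <- c(2, 5, 8, 11); s0 <- c(1, 0, 1, 1)
  lr <- logrank_test(rep(c("A", "B"), each = 4), c(t0, t0), c(s0, s0))
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)
  set.seed(21)
  inst <- random_instance(30)
  g <- sample(c("x", "y"), 30, replace = TRUE)
  a <- logrank_test(g, inst$t, inst$s)
  b <- logrank_test(ifelse(g == "x", "y", "x"), inst$t, inst$s)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
})

test_that("logrank test agrees with survival::survdiff", {
  library(survival)
  set.seed(22)
  for (k in 1:20) {
    n <- sample(10:40, 1)
    t <- sample(1:10, n, replace = TRUE)
    s <- rbinom(n, 1, 0.6); if (sum(s) == 0) s[1] <- 1
    g <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(g)) < 2) g[1:2] <- c("A", "B")
    lr <- logrank_test(g, t, s)
    sd <- survdiff(Surv(t, s) ~ g)
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-8)
  }
})

test_that("robustness experiment: dp = 0 reproduces the clean C, rows counted", {
  sim <- simulate_cohort(simulation_config(n = 150, missing_rate = 0.2, seed = 3))
  coh <- encode_cohort(sim$records, sim$schema)
  m <- init_model(survnet_arch(), seed = 2)
  clean <- concordance_index(survnet_forward(m, coh$X)$p_x, coh$time, coh$event)
  tab <- robustness_experiment(m, coh, dp_grid = c(0, 0.3), repeats = 4, seed = 10)
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$cindex[tab$dp == 0] == clean))
  tab2 <- robustness_experiment(m, coh, dp_grid = c(0, 0.3), repeats = 4, seed = 10)
  expect_identical(tab, tab2)
  expect_error(robustness_experiment(m, coh, dp_grid = 1), "\\[0, 1\\)")
})
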