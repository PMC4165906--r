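test_that("Kaplan-Meier matches closed forms and a hand product-limit toy", {
  # no events: constant at 1
  km0 <- km_fit(c(3, 5, 7), c(0, 0, 0))$curves[[1]]
  expect_true(all(km0$surv == 1))
  # all events at distinct times: empirical survival
  km1 <- km_fit(c(1, 2, 3), c(1, 1, 1))$curves[[1]]
  expect_equal(km1$surv, c(2/3, 1/3, 0), tolerance = 1e-12)
  # 6-subject toy with censoring, hand-computed product limit
  km2 <- km_fit(c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 0, 1, 1))$curves[[1]]
  expect_equal(km2$surv[km2$time == 1], 5/6, tolerance = 1e-12)
  expect_equal(km2$surv[km2$time == 3], 5/6 * 3/4, tolerance = 1e-12)
  expect_equal(km2$surv[km2$time == 5], 5/6 * 3/4 * 1/2, tolerance = 1e-12)
  expect_equal(km2$surv[km2$time == 6], 0, tolerance = 1e-12)
  # fully observed data: KM equals the empirical survival function
  set.seed(3)
  tt <- round(rexp(50, 0.2), 1)
  km3 <- km_fit(tt, rep(1, 50))$curves[[1]]
  expect_equal(km3$surv, vapply(km3$time, function(u) mean(tt > u), 1),
               tolerance = 1e-12)
  expect_true(all(diff(km3$surv) <= 0))
  expect_error(km_fit(numeric(0), numeric(0)), "empty")
})

test_that("log-rank matches a hand O-E/V computation and handles edge cases", {
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  group <- c("a", "b", "a", "b", "a", "b", "a", "b")
  got <- logrank_test(time, event, group)
  # independent O-E/V accumulation over event times
  O <- 0; E <- 0; V <- 0
  for (u in sort(unique(time[event == 1]))) {
    at <- time >= u
    n <- sum(at); n1 <- sum(at & group == "a")
    d <- sum(time == u & event == 1)
    O <- O + sum(time == u & event == 1 & group == "a")
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(got$statistic, (O - E)^2 / V, tolerance = 1e-12)
  expect_identical(got$df, 1L)

  # duplicated identical groups: statistic 0, p 1
  same <- logrank_test(rep(time, 2), rep(event, 2), rep(c("x", "y"), each = 8))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  # no events
  expect_warning(none <- logrank_test(c(1, 2), c(0, 0), c("a", "b")),
                 "no events")
  expect_identical(none$p_value, 1)
})

test_that("log-rank separates strongly different exponential groups", {
  set.seed(61)
  reject <- 0
  for (i in 1:20) {
    t1 <- rexp(100, 0.05); t2 <- rexp(100, 0.25)  # HR 5
    cns <- rexp(200, 0.02)
    time <- pmin(c(t1, t2), cns)
    event <- as.integer(c(t1, t2) <= cns)
    p <- logrank_test(time, event, rep(c("a", "b"), each = 100))$p_value
    if (p < 0.001) reject <- reject + 1
  }
  expect_gte(reject, 19)
})

test_that("Cox fit matches the independent maximizer on toy data", {
  skip_if_not_installed("survival")
  set.seed(19)
  n <- 80
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  time <- rexp(n, 0.1 * exp(0.6 * x[, 1] - 0.4 * x[, 2]))
  event <- rbinom(n, 1, 0.8)
  fit <- cox_fit(time, event, x)
  orc <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  expect_equal(unname(fit$coef), unname(coef(orc)), tolerance = 1e-4)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(orc)))), tolerance = 1e-4)
  expect_true(fit$converged)
  # tied data
  t2 <- ceiling(time)
  fit2 <- cox_fit(t2, event, x)
  orc2 <- survival::coxph(survival::Surv(t2, event) ~ x, ties = "efron")
  expect_equal(unname(fit2$coef), unname(coef(orc2)), tolerance = 1e-4)
})

test_that("a covariate balanced across duplicated data has zero effect", {
  time <- c(2, 4, 6, 8); event <- c(1, 1, 0, 1)
  x <- matrix(c(0, 0, 0, 0, 1, 1, 1, 1), ncol = 1,
              dimnames = list(NULL, "grp"))
  fit <- cox_fit(rep(time, 2), rep(event, 2), x)
  expect_equal(unname(fit$coef), 0, tolerance = 1e-8)
  expect_equal(unname(fit$hr), 1, tolerance = 1e-8)
})

test_that("two-group Cox score test equals the log-rank statistic on tie-free data", {
  set.seed(23)
  n <- 60
  g <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.1 * exp(0.5 * g))
  event <- rbinom(n, 1, 0.85)
  fit <- cox_fit(time, event, matrix(g, ncol = 1))
  lr <- logrank_test(time, event, g)
  expect_equal(fit$score_test, lr$statistic, tolerance = 1e-6)
})

test_that("Cox recovers a planted log hazard ratio and its CI covers the null rate", {
  set.seed(37)
  ests <- vapply(1:10, function(i) {
    n <- 500
    x <- rnorm(n)
    t_ev <- rexp(n, 0.05 * exp(0.7 * x))
    t_cn <- rexp(n, 0.03)
    unname(cox_fit(pmin(t_ev, t_cn), as.integer(t_ev <= t_cn),
                   matrix(x, ncol = 1, dimnames = list(NULL, "x")))$coef)
  }, numeric(1))
  expect_equal(mean(ests), 0.7, tolerance = 0.1)

  covered <- 0
  for (i in 1:60) {
    n <- 200
    x <- rnorm(n)
    time <- rexp(n, 0.05)
    event <- rbinom(n, 1, 0.7)
    fit <- cox_fit(time, event, matrix(x, ncol = 1))
    if (fit$ci_lower <= 1 && fit$ci_upper >= 1) covered <- covered + 1
  }
  expect_gte(covered, 52)  # ~95% coverage at 60 reps
})

test_that("rank-deficient designs and convergence failures are flagged", {
  set.seed(4)
  n <- 30
  a <- rnorm(n)
  x <- cbind(a = a, b = 2 * a)
  expect_error(cox_fit(rexp(n), rbinom(n, 1, 0.8), x), "full rank")
  # perfect separation -> monotone likelihood warning
  xs <- matrix(rep(0:1, each = 10), ncol = 1)
  ts <- c(seq(1, 10), seq(101, 110))
  fs <- suppressWarnings(cox_fit(ts, rep(1, 20), xs))
  expect_true(fs$monotone || !fs$converged)
})

test_that("proportional-hazards check holds its level and detects violations", {
  set.seed(92)
  # null: rejection rate near nominal 5%
  rejected <- 0
  for (i in 1:100) {
    n <- 100
    x <- rnorm(n)
    time <- rexp(n, 0.1 * exp(0.4 * x))
    event <- rbinom(n, 1, 0.8)
    fit <- cox_fit(time, event, matrix(x, ncol = 1))
    z <- ph_check(fit)
    if (z["x", "p_value"] < 0.05) rejected <- rejected + 1
  }
  expect_lte(rejected, 13)

  # planted time-varying effect: strong early benefit that reverses
  power <- 0
  for (i in 1:10) {
    n <- 500
    g <- rbinom(n, 1, 0.5)
    time <- ifelse(g == 1, rpiecewise(n, 0.02, 0.3, 8), rexp(n, 0.08))
    event <- rep(1L, n)
    fit <- cox_fit(time, event, matrix(g, ncol = 1, dimnames = list(NULL, "g")))
    if (ph_check(fit)["g", "p_value"] < 0.05) power <- power + 1
  }
  expect_gte(power, 8)

  # no covariates: empty result
  fit1 <- cox_fit(rexp(20), rbinom(20, 1, 0.9), matrix(rnorm(20), ncol = 1))
  fit1$coef <- numeric(0); fit1$data$x <- fit1$data$x[, 0, drop = FALSE]
  expect_identical(nrow(ph_check(fit1)), 0L)
})
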