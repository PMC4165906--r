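test_that("pre-selection applies the nominal-p any-pair rule at the boundary", {
  corr <- data.frame(probe_id = c("cg1", "cg2", "cg3", "cg3"),
                     p_raw = c(0.04, 0.06, 0.3, 0.01),
                     stringsAsFactors = FALSE)
  got <- preselect_probes(corr, alpha = 0.05)
  expect_identical(got, c("cg1", "cg3"))   # 0.04 in, 0.06 out, any-pair rule
  expect_error(preselect_probes(corr, alpha = 1e-6), "increase alpha")
})

test_that("lasso_cox reduces to the unpenalized fit at lambda 0 and to zero at large lambda", {
  set.seed(71)
  n <- 100; p <- 5
  x <- matrix(rbeta(n * p, 3, 3), n, p,
              dimnames = list(NULL, sprintf("cg%d", 1:p)))
  t_ev <- rexp(n, 0.05 * exp(x %*% c(1.5, -1, 0, 0, 0.5)))
  t_cn <- rexp(n, 0.03)
  time <- pmin(t_ev, t_cn); event <- as.integer(t_ev <= t_cn)
  cf0 <- lasso_cox(x, time, event, lambda = 0)
  nr <- cox_fit(time, event, x)
  expect_equal(unname(cf0), unname(nr$coef), tolerance = 1e-4)
  cf_big <- lasso_cox(x, time, event, lambda = 5)
  expect_identical(unname(cf_big), rep(0, p))  # exact zeros
})

test_that("a dominant probe enters the lasso path first", {
  set.seed(72)
  n <- 120; p <- 40
  x <- matrix(rbeta(n * p, 3, 3), n, p,
              dimnames = list(NULL, sprintf("cg%02d", 1:p)))
  x[, 1] <- rbeta(n, 2, 2)  # higher variance for the causal probe
  t_ev <- rexp(n, 0.05 * exp(3 * x[, 1]))
  t_cn <- rexp(n, 0.02)
  time <- pmin(t_ev, t_cn); event <- as.integer(t_ev <= t_cn)
  for (lam in c(0.3, 0.2, 0.1, 0.05, 0.02)) {
    cf <- lasso_cox(x, time, event, lam)
    nz <- names(cf)[cf != 0]
    if (length(nz) > 0) {
      expect_identical(nz[1], "cg01")
      break
    }
  }
  expect_gt(length(nz), 0)
})

test_that("consensus aggregation honours the presence boundary exactly", {
  probes <- c("in80", "out79", "always")
  support <- cbind(in80 = c(rep(TRUE, 80), rep(FALSE, 20)),
                   out79 = c(rep(TRUE, 79), rep(FALSE, 21)),
                   always = rep(TRUE, 100))
  coefs <- cbind(in80 = ifelse(support[, 1], 0.5, 0),
                 out79 = ifelse(support[, 2], 0.3, 0),
                 always = rep(0.2, 100))
  got <- methprog:::consensus_aggregate(support, coefs, 0.80)
  expect_identical(got$probes, c("in80", "always"))
  expect_false("out79" %in% got$probes)
  # mean over the runs where present (not over all runs)
  expect_equal(unname(got$coefficients["in80"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(got$coefficients["always"]), 0.2, tolerance = 1e-12)
  expect_equal(unname(got$presence), c(0.80, 0.79, 1), tolerance = 1e-12)
})

test_that("a single-run consensus is a single lasso support", {
  set.seed(73)
  n <- 80; p <- 20
  x <- matrix(rbeta(n * p, 3, 3), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("cg%02d", 1:p)))
  x[, 1:2] <- matrix(rbeta(2 * n, 2, 2), n, 2)
  t_ev <- rexp(n, 0.05 * exp(2 * x[, 1] - 2 * x[, 2]))
  t_cn <- rexp(n, 0.02)
  time <- pmin(t_ev, t_cn); event <- as.integer(t_ev <= t_cn)
  sig <- meth_signature(x, time, event, n_runs = 1, presence_threshold = 1,
                        cv_folds = 5, lambda_rule = "lambda.min", seed = 5)
  expect_true(all(sig$presence %in% c(0, 1)))
  expect_gt(length(sig$probes), 0)
  expect_identical(sig$probes, colnames(x)[sig$presence == 1])
  # training index consistent with the coefficients
  expect_equal(sig$index,
               drop(x[, sig$probes, drop = FALSE] %*% sig$coefficients),
               tolerance = 1e-12)
  expect_equal(sig$cut, median(sig$index), tolerance = 1e-12)
})

test_that("the risk index is an exact, probe-order-invariant linear form", {
  m <- make_matrix(c(0.2, 0.4, 0.6, 0.1, 0.3, 0.5), 3,
                   samples = c("s1", "s2"))
  cf <- c(cg01 = 1, cg02 = -2, cg03 = 0.5)
  idx <- compute_index(m, cf)
  expect_equal(unname(idx["s1"]), 0.2 - 0.8 + 0.3, tolerance = 1e-12)
  # permutation invariance
  expect_equal(compute_index(m, cf[c(3, 1, 2)]), idx, tolerance = 1e-15)
  # all-zero betas
  m0 <- m; m0[] <- 0
  expect_equal(unname(compute_index(m0, cf)), c(0, 0))
  # exact linearity in any single probe
  m2 <- m; m2["cg02", "s1"] <- m2["cg02", "s1"] + 0.05
  expect_equal(compute_index(m2, cf)[["s1"]], idx[["s1"]] + cf[["cg02"]] * 0.05,
               tolerance = 1e-15)
  # missing probes are an error listing them
  expect_error(compute_index(m[1:2, ], cf), "cg03")
})

test_that("risk-group assignment cuts at the median by default and carries fixed cuts", {
  idx <- c(a = -1, b = 0, c = 2)
  got <- assign_risk_groups(idx)
  expect_identical(as.character(got$group), c("low", "low", "high"))
  expect_identical(attr(got, "cut"), 0)
  fixed <- assign_risk_groups(c(a = -0.3, b = 0.4), cut = 0)
  expect_identical(as.character(fixed$group), c("low", "high"))
  expect_warning(assign_risk_groups(c(a = 1, b = 1)), "one risk group")
})

test_that("signature evaluation is deterministic and mirrors the adjusted model layout", {
  co <- small_cohort(seed = 55, n_normal = 0, n_dcis = 0, n_ibc = 80)
  cf <- setNames(co$truth$signature$coefficient, co$truth$signature$probe_id)
  risk <- assign_risk_groups(compute_index(co$beta, cf))
  ev1 <- evaluate_signature(risk, co$clinical)
  ev2 <- evaluate_signature(risk, co$clinical)
  expect_identical(ev1$logrank$p_value, ev2$logrank$p_value)
  expect_identical(ev1$cox_multivariate$coef, ev2$cox_multivariate$coef)
  expect_setequal(names(ev1$cox_multivariate$coef),
                  c("er_pos", "tp53_mut", "t2", "t3or4", "node_pos",
                    "risk_high"))
  expect_false(is.null(ev1$node_strata))
  expect_identical(length(ev1$node_strata$km$groups), 4L)
})

test_that("a planted signature term is prognostic while a noise covariate is not", {
  set.seed(81)
  hits_sig <- 0; hits_noise <- 0
  reps <- 40
  for (i in 1:reps) {
    n <- 150
    idx <- rnorm(n)
    t_ev <- rexp(n, 0.05 * exp(1.2 * idx))
    t_cn <- rexp(n, 0.03)
    x <- cbind(risk_high = as.integer(idx > median(idx)), noise = rnorm(n))
    fit <- cox_fit(pmin(t_ev, t_cn), as.integer(t_ev <= t_cn), x)
    if (fit$p_value["risk_high"] < 0.05) hits_sig <- hits_sig + 1
    if (fit$p_value["noise"] < 0.05) hits_noise <- hits_noise + 1
  }
  expect_gte(hits_sig / reps, 0.95)
  expect_lte(hits_noise / reps, 0.2)
})

test_that("the bundled 18-CpG signature loads and scores samples", {
  path <- system.file("extdata", "signature18.tsv", package = "methprog")
  sig <- read_signature(path)
  expect_identical(length(sig), 18L)
  expect_true(all(grepl("^cg[0-9]{8}$", names(sig))))
  m <- matrix(0.5, 18, 2, dimnames = list(names(sig), c("p1", "p2")))
  idx <- compute_index(m, sig)
  expect_equal(unname(idx), rep(sum(sig) * 0.5, 2), tolerance = 1e-12)
})
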