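test_that("pearson_r_p matches hand and reference values", {
  res <- pearson_r_p(c(1, 2, 3), c(2, 4, 6))
  expect_equal(res$r, 1)
  expect_equal(res$p_value, 0)

  res <- pearson_r_p(c(1, 2, 3), c(6, 4, 5))
  expect_equal(res$r, -0.5, tolerance = 1e-12)
  expect_equal(res$p_value, 2 / 3, tolerance = 1e-9)

  expect_error(pearson_r_p(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r_p(c(1, 2), c(1, 2)), "at least 3")

  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    ct <- cor.test(x, y)
    res <- pearson_r_p(x, y)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-9)
    expect_equal(res$p_value, ct$p.value, tolerance = 1e-9)
  }
})

test_that("ttest_unpaired matches the pooled-variance formula and t.test", {
  res <- ttest_unpaired(c(1, 2, 3), c(4, 5, 6))
  expect_equal(round(res$statistic, 3), -3.674)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.0213, tolerance = 1e-3)

  same <- ttest_unpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  deg <- ttest_unpaired(c(2, 2), c(2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)

  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(sample(3:15, 1)); b <- rnorm(sample(3:15, 1), mean = 0.5)
    tt <- t.test(a, b, var.equal = TRUE)
    res <- ttest_unpaired(a, b, "pooled")
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)
    tw <- t.test(a, b)
    resw <- ttest_unpaired(a, b, "welch")
    expect_equal(resw$p_value, tw$p.value, tolerance = 1e-9)
    expect_equal(resw$df, unname(tw$parameter), tolerance = 1e-9)
  }
})

test_that("holm_sidak follows the step-down formula with monotonicity", {
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04), tolerance = 1e-12)
  expect_equal(holm_sidak(0.3), 0.3)
  out <- holm_sidak(c(0.5, 0.9, 0.99))
  expect_true(all(out <= 1))
  expect_true(all(diff(sort(out)) >= 0))
  # permutation equivariance
  p <- c(0.02, 0.8, 0.004, 0.3, 0.3)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(holm_sidak(p)[perm], holm_sidak(p[perm]))
  # adjusted values never below the raw p
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    adj <- holm_sidak(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(holm_sidak(adj) >= adj - 1e-12))
  }
  expect_error(holm_sidak(c(0.2, 1.2)), "\\[0, 1\\]")
})

test_that("bh_fdr equals the step-up rule and dominates p", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4), tolerance = 1e-12)
  expect_equal(bh_fdr(0.17), 0.17)
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  set.seed(2)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    q <- bh_fdr(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
})

test_that("km_curve reproduces the product-limit estimator", {
  k <- km_curve(c(2, 4, 6, 8), c(1, 1, 1, 1))
  expect_equal(k$table$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(k$median, 4)

  expect_equal(km_curve(5, 1)$median, 5)
  expect_true(is.na(km_curve(c(3, 7), c(0, 0))$median))
  expect_error(km_curve(c(-1, 2), c(1, 1)), "positive")

  # no censoring: equals the empirical survival function exactly
  set.seed(3)
  t <- sample(1:50, 30, replace = TRUE)
  k <- km_curve(t, rep(1, 30))
  emp <- vapply(k$table$time, function(u) mean(t > u), numeric(1))
  expect_equal(k$table$surv, emp)

  # censored data vs survival::survfit
  skip_if_not_installed("survival")
  set.seed(4)
  t <- rexp(60, 0.1); ev <- rbinom(60, 1, 0.7)
  fit <- survival::survfit(survival::Surv(t, ev) ~ 1)
  k <- km_curve(t, ev)
  et <- k$table$time[k$table$n_event > 0]
  expect_equal(k$table$surv[match(et, k$table$time)],
               fit$surv[match(et, fit$time)], tolerance = 1e-9)
})

test_that("logrank_test matches the risk-set oracle and survdiff", {
  # hand enumeration for A events (1,2), B events (3,4):
  # O1 = 2, E1 = 1/2 + 1/3 = 5/6, V = 1/4 + 2/9 = 17/36 -> chisq = 49/17
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-9)

  dup <- logrank_test(rep(c(3, 5, 9), 2), rep(c(1, 1, 0), 2),
                      rep(c("A", "B"), each = 3))
  expect_equal(dup$statistic, 0)
  expect_equal(dup$p_value, 1)

  expect_warning(out <- logrank_test(c(1, 2), c(0, 0), c("A", "B")), "no events")
  expect_equal(out$p_value, 1)

  skip_if_not_installed("survival")
  set.seed(5)
  for (i in 1:10) {
    n <- 40
    t <- rexp(n, 0.2); ev <- rbinom(n, 1, 0.8)
    g <- rep(c("A", "B"), each = n / 2)
    sd <- survival::survdiff(survival::Surv(t, ev) ~ g)
    lr <- logrank_test(t, ev, g)
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-9)
  }
})

test_that("cox_univariate maximizes the Breslow partial likelihood", {
  # exchangeable groups: HR exactly 1
  t <- c(3, 5, 9, 12); ev <- c(1, 1, 1, 0)
  fit <- cox_univariate(rep(t, 2), rep(ev, 2), rep(c(0, 1), each = 4))
  expect_equal(fit$hr, 1, tolerance = 1e-6)

  # toy 8-subject table vs two-stage grid search of the partial likelihood
  time <- c(2, 4, 5, 7, 8, 10, 12, 15)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  x <- c(1, 0, 1, 1, 0, 1, 0, 0)
  fit <- cox_univariate(time, event, x)
  expect_equal(fit$beta, oracle_cox_grid(time, event, x), tolerance = 1e-4)

  # rank invariance under time rescaling
  fit10 <- cox_univariate(time * 10, event, x)
  expect_equal(fit10$hr, fit$hr, tolerance = 1e-8)

  # complete separation: all events in one group before the other is at risk
  expect_error(
    cox_univariate(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 1, 1, 1),
                   c(1, 1, 1, 0, 0, 0)),
    "monotone|converge")

  skip_if_not_installed("survival")
  set.seed(6)
  for (i in 1:10) {
    n <- 80
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.1 * exp(0.5 * x)); ev <- rbinom(n, 1, 0.8)
    ref <- survival::coxph(survival::Surv(t, ev) ~ x, ties = "breslow")
    fit <- cox_univariate(t, ev, x)
    expect_equal(fit$beta, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$se, sqrt(unname(vcov(ref)[1, 1])), tolerance = 1e-6)
  }
})

test_that("type-I error and null p-value distributions are calibrated", {
  set.seed(11)
  # pooled t-test at alpha = 0.05 under the null
  rej <- mean(vapply(1:4000, function(i) {
    ttest_unpaired(rnorm(8), rnorm(8))$p_value < 0.05
  }, logical(1)))
  expect_gt(rej, 0.04)
  expect_lt(rej, 0.06)

  # log-rank under exchangeability
  rej_lr <- mean(vapply(1:2000, function(i) {
    t <- rexp(40, 0.2); ev <- rbinom(40, 1, 0.9)
    logrank_test(t, ev, rep(c("A", "B"), each = 20))$p_value < 0.05
  }, logical(1)))
  expect_gt(rej_lr, 0.035)
  expect_lt(rej_lr, 0.065)

  # Pearson null p-values uniform (Kolmogorov-Smirnov)
  ps <- vapply(1:2000, function(i) pearson_r_p(rnorm(15), rnorm(15))$p_value,
               numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("Cox 95% CI covers a true HR of 0.6 at the nominal rate", {
  set.seed(12)
  cover <- vapply(1:500, function(i) {
    x <- rep(c(0, 1), each = 100)
    t <- rexp(200, 0.05 * 0.6^x)
    fit <- cox_univariate(t, rep(1, 200), x)
    fit$ci_low <= 0.6 && 0.6 <= fit$ci_high
  }, logical(1))
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.98)
})
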