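test_that("Kaplan-Meier estimate matches hand and brute-force computation", {
  fit <- kmEstimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(fit$surv, c(0.75, 0.5, 0.25, 0))
  # all censored: flat at 1
  fitC <- kmEstimate(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(fitC$surv == 1))
  # events at 1 and 3, censoring at 2
  fitM <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(fitM$surv[fitM$time == 1], 2 / 3)
  expect_equal(fitM$surv[fitM$time == 3], 0)
  expect_error(kmEstimate(c(1, -2), c(1, 1)), "positive")
  # oracle identity on random censored fixtures
  set.seed(37)
  for (i in 1:10) {
    n <- 30
    t <- round(rexp(n, 0.1), 1) + 0.1
    ev <- rbinom(n, 1, 0.7)
    fit <- kmEstimate(t, ev)
    for (at in sample(t, 5))
      expect_equal(fit$surv[max(which(fit$time <= at))],
                   kmOracle(t, ev, at))
  }
})

test_that("landmark survival rates interpolate the step function", {
  fit <- kmEstimate(c(1, 2, 3, 4), c(1, 1, 1, 1))  # months
  expect_equal(survivalRateAt(fit, 4 / 12), 0)     # covers all events
  expect_equal(survivalRateAt(fit, 0.5 / 12), 1)   # before first event
  expect_true(is.na(survivalRateAt(fit, 3)))       # beyond follow-up
  expect_error(survivalRateAt(fit, -1), "non-negative")
  # exponential with 36-month median: 3-year rate ~ 0.5
  set.seed(41)
  t <- rexp(500, log(2) / 36)
  fitE <- kmEstimate(t, rep(1, 500))
  expect_equal(survivalRateAt(fitE, 3), 0.5, tolerance = 0.05)
})

test_that("KM median uses the first time the curve reaches 0.5", {
  expect_equal(kmMedian(kmEstimate(c(1, 2, 3, 4), rep(1, 4)))$median, 2)
  expect_true(is.na(kmMedian(kmEstimate(c(5, 6), c(0, 0)))$median))  # NR
  set.seed(43)
  t <- rexp(500, log(2) / 36)
  md <- kmMedian(kmEstimate(t, rep(1, 500)))
  expect_equal(md$median, 36, tolerance = 4 / 36)
  expect_true(md$lcl < md$median && md$median < md$ucl)
})

test_that("log-rank test: null, extreme separation, and 3-group df", {
  t <- c(1, 2, 3, 4, 1, 2, 3, 4)
  g <- rep(c("a", "b"), each = 4)
  lr <- logrankTest(t, rep(1, 8), g)
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  # far-shifted group, no censoring
  set.seed(47)
  t2 <- c(rexp(40, 1), rexp(40, 1) + 50)
  lr2 <- logrankTest(t2, rep(1, 80), rep(c("early", "late"), each = 40))
  expect_lt(lr2$p, 0.001)
  lr3 <- logrankTest(rexp(30, 1), rep(1, 30), rep(c("a", "b", "c"), 10))
  expect_equal(lr3$df, 2L)
  expect_error(logrankTest(t, rep(1, 8), rep("a", 8)), "two groups")
})

test_that("log-rank power under proportional hazards (HRs 1, 1, 3)", {
  hits <- vapply(1:200, function(i) {
    set.seed(5000 + i)
    g <- rep(1:3, each = 100)
    t <- rexp(300, log(2) / 36 * c(1, 1, 3)[g])
    logrankTest(t, rep(1, 300), g)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Cox fit matches a brute-force partial-likelihood grid search", {
  t <- c(2, 5, 7, 11)
  x <- c(1, 0, 1, 0)
  fit <- coxFit(t, rep(1, 4), data.frame(x = x))
  expect_equal(fit$coef, coxGridOracle(t, x), tolerance = 2e-3)
  expect_equal(fit$hr, exp(fit$coef))
  expect_identical(attr(fit, "ties"), "efron")
})

test_that("Cox recovers a true hazard ratio of 3 with 20% censoring", {
  set.seed(53)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  lam <- log(2) / 36 * 3^x
  tEvent <- rexp(n, lam)
  tCens <- rexp(n, 0.25 * lam)     # ~20% censoring
  t <- pmin(tEvent, tCens)
  ev <- as.integer(tEvent <= tCens)
  fit <- coxFit(t, ev, data.frame(x = x))
  expect_gte(fit$hr, 2.4)
  expect_lte(fit$hr, 3.75)
})

test_that("Cox on a null covariate stays near zero across replicates", {
  ok <- vapply(1:100, function(i) {
    set.seed(6000 + i)
    t <- rexp(100, log(2) / 36)
    x <- rbinom(100, 1, 0.5)
    fit <- coxFit(t, rep(1, 100), data.frame(x = x))
    abs(fit$coef / fit$se) < 2
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("Cox coefficient sign follows group survival on separable data", {
  t <- c(1, 2, 3, 20, 30, 40)
  x <- c(1, 1, 1, 0, 0, 0)  # covariate group dies earlier -> positive coef
  # coxph itself also warns (infinite coefficient); both are expected here
  fit <- NULL
  suppressWarnings(
    expect_warning(fit <- coxFit(t, rep(1, 6), data.frame(x = x)),
                   "separation"))
  expect_gt(fit$coef, 0)
})

test_that("two-group log-rank chi2 equals the squared score z", {
  set.seed(59)
  t <- rexp(60, 0.05 * c(1, 2)[rep(1:2, 30)])
  g <- rep(c("a", "b"), 30)
  lr <- logrankTest(t, rep(1, 60), g)
  sd2 <- survival::survdiff(survival::Surv(t, rep(1, 60)) ~ g)
  z <- (sd2$obs[1] - sd2$exp[1]) / sqrt(sd2$var[1, 1])
  expect_equal(lr$chi2, z^2, tolerance = 1e-8)
})

test_that("PD-L1 dichotomization uses the mesenchymal median, inclusive", {
  r <- dichotomizePDL1(c(1, 2, 3, 0.5), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$cutoff, 2)
  expect_identical(r$high, c(FALSE, TRUE, TRUE, FALSE))
  # even-sized mask: midpoint convention
  r2 <- dichotomizePDL1(c(1, 2, 3, 4), rep(TRUE, 4))
  expect_equal(r2$cutoff, 2.5)
  # all equal: boundary inclusive, everything high
  r3 <- dichotomizePDL1(rep(2, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(all(r3$high))
  expect_error(dichotomizePDL1(1:3, rep(FALSE, 3)), "no samples")
})
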