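test_that("chi-square wrapper applies Yates on 2x2 and validates input", {
  flat <- chiSquareTest(matrix(c(5, 5, 5, 5), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)
  # Yates-corrected statistic never exceeds the uncorrected one
  set.seed(13)
  for (i in 1:20) {
    m <- matrix(rpois(4, 8) + 1, 2)
    y <- chiSquareTest(m, correct = TRUE)$statistic
    u <- chiSquareTest(m, correct = FALSE)$statistic
    expect_lte(y, u + 1e-12)
  }
  # doubling all counts increases the (uncorrected) statistic
  m <- matrix(c(2, 8, 9, 3), 2)
  expect_gt(chiSquareTest(2 * m, correct = FALSE)$statistic,
            chiSquareTest(m, correct = FALSE)$statistic)
  expect_error(chiSquareTest(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "zero row")
  expect_error(chiSquareTest(matrix(1:3)), "2x2")
  # Fisher option for sparse tables
  f <- chiSquareTest(matrix(c(0, 13, 7, 3), 2, byrow = TRUE),
                     method = "fisher")
  expect_true(is.na(f$statistic) && f$p.value < 0.05)
})

test_that("deleted-arm counts follow the count-chromosome-9-once convention", {
  fx <- cohortFixture()
  ds <- deletionCountSummary(fx, fx[c("case_id", "group")])
  # the two whole-chromosome-9 OIII cases contribute one deleted arm each
  mono <- ds$perCase[ds$perCase$ctrl_9q_deleted, ]
  expect_equal(nrow(mono), 2L)
  expect_true(all(mono$nDeleted == 3))  # 1p + 19q + 9p, 9q not added
  # an all-normal case counts zero
  nf <- data.frame(case_id = "x", status_1p = "NORMAL",
                   status_19q = "NORMAL", status_9p = "NORMAL",
                   status_10q = "NORMAL")
  expect_equal(deletionCountSummary(nf)$perCase$nDeleted, 0)
  # long-format calls are accepted too
  lng <- data.frame(case_id = rep("x", 4),
                    chromosome = c("chr1", "chr9", "chr10", "chr19"),
                    status = c("DELETED", "DELETED", "NORMAL", "IMBALANCED"))
  pc <- deletionCountSummary(lng)$perCase
  expect_equal(pc$nDeleted, 2)
  expect_equal(pc$nAltered, 3)
})

test_that("Kaplan-Meier estimates behave as the product-limit estimator", {
  # without censoring the curve is the empirical survival function
  rec <- data.frame(time_months = c(2, 5, 5, 9), event = TRUE)
  fit <- kmEstimate(rec)
  expect_equal(fit$surv, c(0.75, 0.25, 0), tolerance = 1e-12)
  expect_true(all(diff(fit$surv) <= 0))
  # all censored: flat at 1, median undefined (NA, not Inf)
  cens <- data.frame(time_months = c(3, 6, 10), event = FALSE)
  fitc <- kmEstimate(cens)
  expect_true(all(fitc$surv == 1))
  expect_true(is.na(medianSurvival(fitc)))
  # exponential simulation recovers the closed-form median ln2/lambda
  set.seed(99)
  lam <- 1 / 50
  big <- data.frame(time_months = rexp(2000, lam), event = TRUE)
  se <- 1.25 / (2 * dexp(log(2) / lam, lam) * sqrt(2000))  # asymptotic
  expect_lt(abs(medianSurvival(kmEstimate(big)) - log(2) / lam), 3 * se)
  expect_error(kmEstimate(data.frame(time_months = c(1, -2), event = TRUE)),
               "positive")
})

test_that("log-rank detects separated groups and rejects degenerate input", {
  set.seed(7)
  g <- rep(c("a", "b"), each = 200)
  rec <- data.frame(time_months = c(rexp(200, 1 / 20), rexp(200, 3 / 20)),
                    event = TRUE)
  lr <- logrankTest(rec, g)
  expect_equal(lr$df, 1)
  expect_lt(lr$p.value, 1e-4)
  expect_error(logrankTest(rec, rep("a", 400)), "two groups")
  # invariance under common time rescaling
  lr2 <- logrankTest(transform(rec, time_months = time_months * 7), g)
  expect_equal(lr2$statistic, lr$statistic, tolerance = 1e-12)
})

test_that("log-rank power against a threefold hazard ratio is high", {
  set.seed(123)
  rej <- vapply(1:120, function(i) {
    rec <- data.frame(time_months = c(rexp(200, 1 / 30), rexp(200, 3 / 30)),
                      event = TRUE)
    logrankTest(rec, rep(c("a", "b"), each = 200))$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.9)
})

test_that("Cox fit estimates hazard ratios and flags degeneracy", {
  set.seed(31)
  x <- rep(0:1, each = 250)
  rec <- data.frame(time_months = rexp(500, 0.02 * exp(log(2) * x)),
                    event = TRUE, x = x)
  fit <- coxFit(rec, "x")
  expect_false(fit$flagged)
  expect_true(fit$lower95 < 2 && fit$upper95 > 2)
  # null covariate: HR near 1
  rec$z <- rep(0:1, 250)
  fitz <- coxFit(rec, "z")
  expect_lt(abs(log(fitz$hr)), 0.3)
  # perfectly separating covariate is flagged
  sep <- data.frame(time_months = c(1:10, 101:110),
                    event = TRUE, s = rep(0:1, each = 10))
  fits <- suppressWarnings(coxFit(sep, "s"))
  expect_true(fits$flagged)
  # events-per-covariate warning
  tiny <- data.frame(time_months = rexp(8, 0.1), event = TRUE,
                     x = rep(0:1, 4))
  expect_warning(coxFit(tiny, "x"), "events")
})

test_that("univariate screening selects only significant covariates", {
  set.seed(55)
  x <- rep(0:1, each = 150)
  rec <- data.frame(time_months = rexp(300, 0.02 * exp(1.2 * x)),
                    event = TRUE, strong = x,
                    noise = sample(0:1, 300, replace = TRUE))
  sc <- screenCovariates(rec, c("strong", "noise"))
  expect_true(sc$selected[sc$covariate == "strong"])
  expect_false(sc$selected[sc$covariate == "noise"])
})

test_that("dichotomization applies the standard covariate cutoffs", {
  rec <- data.frame(age = c(49, 50, 61), mitoses = c(4, 5, 6),
                    ki67 = c(11, 12, 30))
  d <- dichotomize(rec)
  expect_equal(d$age_high, c(FALSE, TRUE, TRUE))
  expect_equal(d$mitoses_high, c(FALSE, TRUE, TRUE))
  expect_equal(d$ki67_high, c(FALSE, TRUE, TRUE))
})

test_that("group frequency report reproduces the reference-series cells", {
  fx <- cohortFixture()
  tab <- groupFrequencyTable(fx, variables = c("status_9p", "ina_positive",
                                               "mitoses"))
  del <- tab[tab$variable == "status_9p" & tab$level == "DELETED", ]
  expect_equal(del$Total, "11 (33)")
  expect_equal(del$OIII, "7 (70)")
  expect_equal(del$GBM, "4 (100)")
  ina <- tab[tab$variable == "ina_positive" & tab$level == "TRUE", ]
  expect_equal(ina$OII, "11 (85)")
  mit <- tab[tab$variable == "mitoses", ]
  expect_equal(mit$OII, "1.7 / 2")
  expect_equal(mit$GBM, "4.3 / 5")
  # an empty group yields zero rows without division errors
  fx2 <- rbind(fx, transform(fx[1, ], group = "EMPTYish"))
  expect_silent(groupFrequencyTable(fx2, variables = "status_9p"))
})
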