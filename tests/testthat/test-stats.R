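test_that("descriptive summaries reproduce moments and are order-free", {
  x <- c(-2, -1, 0, 1, 2)
  ds <- describeValues(x)
  expect_equal(ds$mean, 0)
  expect_equal(ds$skewness, 0)
  expect_identical(ds$n, 5L)
  expect_true(ds$min <= ds$mean && ds$mean <= ds$max)
  expect_true(ds$ci_lo >= ds$range_lo && ds$ci_hi <= ds$range_hi)
  # permutation invariance
  set.seed(5)
  y <- rnorm(100)
  expect_identical(describeValues(y), describeValues(sample(y)))
  expect_error(describeValues(3), "insufficient")
  # cross-check the moment estimators against an independent implementation
  skip_if_not_installed("e1071")
  expect_equal(ds2 <- describeValues(y)$skewness,
               e1071::skewness(y, type = 1), tolerance = 1e-12)
  expect_equal(describeValues(y)$excess_kurtosis,
               e1071::kurtosis(y, type = 1), tolerance = 1e-12)
})

test_that("large exponential samples approach skewness 2, excess kurtosis 6", {
  g1 <- g2 <- numeric(5)
  for (s in 1:5) {
    set.seed(s)
    d <- describeValues(rexp(1e5))
    g1[s] <- d$skewness; g2[s] <- d$excess_kurtosis
  }
  expect_lt(abs(mean(g1) - 2), 0.15)
  expect_lt(abs(mean(g2) - 6), 1.2)
})

test_that("both printed interval conventions are reproduced", {
  # standard-error-based CI of the mean
  ci <- intervalFromSummary(10.44, 2.53, 184, "ci_mean")
  expect_equal(unname(ci[1]), 10.0744, tolerance = 1e-4)
  # spread band: mean +/- 1.96 sd
  rg <- intervalFromSummary(12.25, 3.75, kind = "range")
  expect_equal(unname(rg[2]), 19.6)
  expect_equal(unname(intervalFromSummary(5, 0, kind = "range")), c(5, 5))
  expect_equal(unname(intervalFromSummary(5, 0, 10, "ci_mean")), c(5, 5))
  expect_error(intervalFromSummary(5, -1, kind = "range"), "sd")
  expect_error(intervalFromSummary(5, 1, kind = "ci_mean"), "n is required")
})

test_that("age grouping bins integer years into the three cohort groups", {
  expect_identical(as.character(assignAgeGroup(c(4, 12, 13, 16, 17, 20))),
                   c("4-12", "4-12", "13-16", "13-16", "17-20", "17-20"))
  expect_identical(as.character(assignAgeGroup(12.9)), "4-12")
  expect_error(assignAgeGroup(21), "range")
  expect_error(assignAgeGroup(3), "range")
})

test_that("REML fit matches the balanced one-way closed form", {
  set.seed(42)
  m <- 100; k <- 6
  d <- data.frame(patient_id = rep(sprintf("P%03d", 1:m), each = k))
  d$response <- rep(rnorm(m, 0, 2), each = k) + rnorm(m * k, 0, 1)
  fit <- fitLmm(d, response ~ 1)
  ybar <- tapply(d$response, d$patient_id, mean)
  MSB <- k * var(ybar)
  MSW <- sum((d$response - ybar[d$patient_id])^2) / (m * (k - 1))
  expect_equal(fit@sigmaE^2, MSW, tolerance = 1e-4)
  expect_equal(fit@sigmaB^2, (MSB - MSW) / k, tolerance = 1e-4)
  expect_true(fit@converged)
})

test_that("REML fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  tab <- sampleCohort(cohortSpec(n_patients = 80, seed = 3))
  f1 <- fitLmm(tab, response ~ sex + age_group + teeth + side + roi)
  f2 <- lme4::lmer(
    response ~ sex + age_group + teeth + side + roi + (1 | patient_id),
    data = tab, REML = TRUE)
  expect_equal(coefTable(f1)$estimate, unname(lme4::fixef(f2)),
               tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(f2))
  expect_equal(f1@sigmaB, vc$sdcor[1], tolerance = 1e-5)
  expect_equal(f1@sigmaE, vc$sdcor[2], tolerance = 1e-5)
})

test_that("variance boundary and design defects are handled", {
  set.seed(9)
  d <- data.frame(patient_id = rep(sprintf("P%02d", 1:40), each = 4),
                  response = rnorm(160))  # sigma_b = 0 truth
  fit <- fitLmm(d, response ~ 1)
  expect_lt(fit@sigmaB, 0.05)
  expect_true(fit@converged)
  d$dup <- rep(c("a", "b"), 80)
  d$dup2 <- d$dup
  expect_error(fitLmm(d, response ~ dup + dup2), "aliased")
  expect_error(fitLmm(data.frame(patient_id = "P1", response = rnorm(5)),
                      response ~ 1), "2 groups")
})

test_that("Wald CIs contain their estimates and p-values are calibrated", {
  tab <- sampleCohort(cohortSpec(n_patients = 100, seed = 2))
  ct <- coefTable(fitLmm(tab, response ~ sex + age_group + teeth + side + roi))
  expect_true(all(ct$lower <= ct$estimate & ct$estimate <= ct$upper))
  expect_true(all(ct$p > 0 & ct$p <= 1))
  expect_equal(ct$upper - ct$estimate, 1.96 * ct$se, tolerance = 1e-12)
})

test_that("rank tests enumerate exactly and match the reference on ties-free data", {
  mw <- mannWhitney(c(1, 2), c(3, 4))
  expect_equal(unname(mw$statistic), 0)
  expect_equal(mw$p_value, 1 / 3, tolerance = 1e-9)
  ws <- wilcoxonSignedRank(c(1, 2, 3))
  expect_equal(unname(ws$statistic), 6)
  expect_equal(ws$p_value, 0.25, tolerance = 1e-12)
  # identical samples -> p = 1
  expect_equal(mannWhitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(wilcoxonSignedRank(c(0, 0)), "undefined")
  # independent oracle: stats::wilcox.test on tie-free samples
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(6)
    expect_equal(mannWhitney(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-9)
    d <- rnorm(7)
    expect_equal(wilcoxonSignedRank(d)$p_value,
                 wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-9)
  }
  # approximate branch against the reference implementation
  x <- rnorm(30); y <- rnorm(25)
  expect_equal(mannWhitney(x, y)$p_value,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
  d <- rnorm(30)
  expect_equal(wilcoxonSignedRank(d)$p_value,
               wilcox.test(d, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("exact and approximate p-values agree near the crossover size", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    pe <- mannWhitney(x, y, exact = TRUE)$p_value
    pa <- mannWhitney(x, y, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.02)
    d <- rnorm(12)
    pe2 <- wilcoxonSignedRank(d, exact = TRUE)$p_value
    pa2 <- wilcoxonSignedRank(d, exact = FALSE)$p_value
    expect_lt(abs(pe2 - pa2), 0.02)
  }
})

test_that("dependent measurements are averaged per patient", {
  tab <- sampleCohort(cohortSpec(n_patients = 10, seed = 4))
  red <- averageDependent(tab)
  expect_identical(nrow(red), 10L)
  m1 <- mean(tab$response[tab$patient_id == "P001"])
  expect_equal(red$response[red$patient_id == "P001"], m1)
  # balanced groups preserve the grand mean
  expect_equal(mean(red$response), mean(tab$response), tolerance = 1e-12)
  # per-condition averaging keeps one row per patient x roi
  red2 <- averageDependent(tab, condition = "roi")
  expect_identical(nrow(red2), 30L)
  # already-unique rows are unchanged
  red3 <- averageDependent(red2, condition = "roi")
  expect_equal(red3$response, red2$response)
})

test_that("age-trend smoothing is exact on lines and shrinks to the mean", {
  ages <- rep(4:20, each = 3)
  values <- 2 + 0.3 * ages
  sm <- smoothAgeTrend(ages, values)
  expect_lt(max(abs(sm$fit - (2 + 0.3 * sm$age))), 1e-6)
  # heavy smoothing tends to the global mean (trend-free data: the penalty
  # null space is linear, so only the noise component is shrunk away)
  set.seed(8)
  noise <- rnorm(length(ages))
  smh <- smoothAgeTrend(ages, noise, spar = 1.4)
  expect_lt(diff(range(smh$fit)), diff(range(noise)) / 5)
  # residual sum decreases as smoothing decreases
  noisy <- values + noise
  rss <- vapply(c(1.2, 0.8, 0.4), function(sp) {
    f <- smoothAgeTrend(ages, noisy, spar = sp)
    sum((predict(f$model, ages)$y - noisy)^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-9))
  expect_error(smoothAgeTrend(c(1, 1, 2, 2), rnorm(4)), "insufficient")
})
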