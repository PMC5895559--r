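# Cox modelling, prognostic scores, tertile stratification, KM, log-rank

test_that("single-covariate fit matches 1-D partial-likelihood maximisation", {
  # non-separable four-subject fixture, all events, no ties
  dat <- data.frame(os_months = c(1, 2, 3, 4), event = c(1, 1, 1, 1),
                    x = c(1, 0, 0, 1))
  fit <- fit_cox(dat, "x")
  opt <- optimize(function(b) oracle_cox_loglik_1d(b, dat$os_months,
                                                   dat$event, dat$x),
                  c(-10, 10), maximum = TRUE, tol = 1e-10)
  expect_equal(fit$covariates$estimate, opt$maximum, tolerance = 1e-4)
  expect_equal(fit$loglik, opt$objective, tolerance = 1e-8)
  # a covariate whose risk ordering is monotone has no finite maximiser
  sep <- data.frame(os_months = c(1, 2, 3, 4), event = c(1, 1, 1, 1),
                    x = c(1, 1, 0, 0))
  expect_error(suppressWarnings(fit_cox(sep, "x")), "separation")
})

test_that("hazard ratios and CIs are exp-transforms of the estimates", {
  co <- generate_cohort(cohort_spec(n_patients = 300L, seed = 8L))
  dat <- co$clinical
  dat$age <- dat$age_years; dat$treatment <- dat$treatment_code
  dat$stage <- dat$stage_code
  fit <- fit_cox(dat, c("age", "treatment", "stage"))
  with(fit$covariates, {
    expect_equal(hazard_ratio, exp(estimate), tolerance = 1e-9)
    expect_equal(ci95_low, exp(estimate - 1.96 * se), tolerance = 1e-9)
    expect_equal(ci95_high, exp(estimate + 1.96 * se), tolerance = 1e-9)
  })
})

test_that("Wald intervals cover a null covariate at the nominal rate", {
  hits <- 0
  for (s in 1:100) {
    co <- generate_cohort(cohort_spec(
      n_patients = 500L, true_betas = c(treatment = -0.8, skewness = 0),
      seed = 400L + s))
    dat <- cbind(co$clinical, skewness = co$features$skewness)
    dat$treatment <- dat$treatment_code
    fit <- fit_cox(dat, c("treatment", "skewness"))
    row <- fit$covariates[fit$covariates$name == "skewness", ]
    if (abs(row$estimate) < 2 * row$se) hits <- hits + 1
  }
  expect_gte(hits, 93)
})

test_that("backward elimination keeps strong effects and drops pure noise", {
  co <- generate_cohort(cohort_spec(
    n_patients = 800L,
    true_betas = c(treatment = -1.0, skewness = 0.8), seed = 19L))
  dat <- cbind(co$clinical, co$features[-1])
  dat$age <- dat$age_years; dat$treatment <- dat$treatment_code
  dat$stage <- dat$stage_code
  final <- backward_conditional(dat, c("age", "treatment", "stage",
                                       "skewness", "kurtosis", "glnu"))
  expect_true(all(c("treatment", "skewness") %in% final$covariates$name))
  expect_false("kurtosis" %in% final$covariates$name)
  # p_remove = 1 returns the full model unchanged
  full <- backward_conditional(dat, c("age", "treatment", "stage"),
                               p_remove = 1.0)
  expect_identical(full$covariates$name, c("age", "treatment", "stage"))
})

test_that("prognostic scores are coefficient-weighted covariate sums", {
  eq <- prognostic_equation(c(age = 0.020, treatment = -1.075,
                              stage = 0.144))
  rec <- list(age_years = 67, treatment_code = 1, stage_code = 8)
  expect_equal(prognostic_score(eq, rec), 67 * 0.020 - 1.075 + 8 * 0.144)
  expect_equal(prognostic_score(eq, rec), 1.417)
  rec0 <- list(age_years = 0, treatment_code = 0, stage_code = 0)
  expect_equal(prognostic_score(eq, rec0), 0)
  # one extra year of age moves the score by exactly the age coefficient
  rec1 <- rec; rec1$age_years <- 68
  expect_equal(prognostic_score(eq, rec1) - prognostic_score(eq, rec),
               0.020)
  eq2 <- prognostic_equation(c(age = 0.019, skewness = -0.789))
  expect_error(prognostic_score(eq2, rec), "skewness")
  expect_equal(prognostic_score(eq2, rec, list(skewness = 1.5)),
               67 * 0.019 - 0.789 * 1.5)
})

test_that("tertile stratification follows the rank rule", {
  st <- stratify_tertiles(1:9)
  g <- split(st$assignments$score, st$assignments$risk_group)
  expect_equal(g$low, 1:3)
  expect_equal(g$intermediate, 4:6)
  expect_equal(g$high, 7:9)
  set.seed(33)
  s427 <- rnorm(427)
  st427 <- stratify_tertiles(s427)
  expect_equal(as.vector(st427$sizes), c(143, 142, 142))
  # adding a constant changes nothing
  st_shift <- stratify_tertiles(s427 + 5)
  expect_identical(st_shift$assignments$risk_group,
                   st427$assignments$risk_group)
  # boundary ties go to the lower-risk group
  st_tie <- stratify_tertiles(c(1, 1, 1, 1, 2, 3, 4, 5, 6))
  expect_equal(sum(st_tie$assignments$risk_group == "low"), 4)
  expect_warning(stratify_tertiles(rep(2, 10)), "identical")
})

test_that("stratification is a partition with ordered score ranges", {
  set.seed(12)
  st <- stratify_tertiles(rnorm(100))
  expect_equal(sum(st$sizes), 100)
  expect_lt(st$ranges["low", "max"], st$ranges["intermediate", "min"])
  expect_lt(st$ranges["intermediate", "max"], st$ranges["high", "min"])
})

test_that("Kaplan-Meier matches closed forms and the true curve", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km_survival_at(km, 2), 0.5)
  expect_equal(km$median, 2)
  # without censoring the estimator is the empirical survival function
  set.seed(3)
  t <- rexp(50, 0.2)
  km2 <- kaplan_meier(t, rep(1, 50))
  ts <- quantile(t, c(0.25, 0.5, 0.75))
  expect_equal(unname(km_survival_at(km2, ts)),
               unname(sapply(ts, function(u) mean(t > u))))
  # heavy censoring: pointwise CI still covers the true exponential curve
  set.seed(4)
  tev <- rexp(400, 0.1); cc <- runif(400, 0, 12)
  km3 <- kaplan_meier(pmin(tev, cc), tev <= cc)
  for (u in c(3, 6, 9)) {
    i <- max(which(km3$time <= u))
    expect_gt(km3$upper[i], exp(-0.1 * u))
    expect_lt(km3$lower[i], exp(-0.1 * u))
  }
})

test_that("log-rank statistic matches a hand-computed table and chi-square df", {
  t1 <- c(3, 5, 7, 9, 11); e1 <- c(1, 1, 0, 1, 1)
  t2 <- c(2, 4, 6, 8, 10); e2 <- c(1, 0, 1, 1, 1)
  lr <- logrank_test(list(a = list(times = t1, events = e1),
                          b = list(times = t2, events = e2)))
  expect_equal(lr$chi2, oracle_logrank_2g(t1, e1, t2, e2), tolerance = 1e-9)
  expect_equal(lr$df, 1L)
  # identical groups: no signal
  same <- list(times = 1:10, events = rep(1, 10))
  lr0 <- logrank_test(list(a = same, b = same))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  # four groups -> 3 degrees of freedom
  lr4 <- logrank_test(list(a = same, b = same, c = same, d = same))
  expect_equal(lr4$df, 3L)
  expect_error(logrank_test(list(a = same, b = list(times = numeric(0),
                                                    events = logical(0)))),
               "no subjects")
})

test_that("empty-model edge cases are handled", {
  co <- generate_cohort(cohort_spec(
    n_patients = 200L, true_betas = c(age = 0), seed = 77L))
  dat <- cbind(co$clinical, noise = rnorm(200))
  expect_warning(m <- backward_conditional(dat, "noise"), "all covariates")
  expect_equal(nrow(m$covariates), 0L)
  eq <- prognostic_equation(m)
  expect_equal(prognostic_score(eq, dat[1, ]), 0)
})
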