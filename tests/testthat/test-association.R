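test_that("memory scores follow the stated constructions", {
  d <- data.frame(immediate = c(10, 0), delayed = c(20, 2),
                  mem_emo = c(NA, NA))
  out <- build_scores(d)
  expect_equal(out$mem_narr, c(15, 1))

  # two-subject z-scores under the sample-SD (n-1) convention
  d2 <- data.frame(immediate = c(0, 2), delayed = c(0, 2),
                   mem_emo = c(5, 7))
  out2 <- build_scores(d2)
  z <- (out2$mem_narr - mean(out2$mem_narr)) / sd(out2$mem_narr)
  expect_equal(z, c(-sqrt(2) / 2, sqrt(2) / 2))

  # emotional score a linear function of narrative: composite == z(mem_narr)
  d3 <- data.frame(immediate = c(1, 3, 5, 9), delayed = c(1, 3, 5, 9))
  d3$mem_emo <- 2 * (d3$immediate + d3$delayed) / 2 + 7
  out3 <- build_scores(d3)
  expect_equal(out3$composite,
               (out3$mem_narr - mean(out3$mem_narr)) / sd(out3$mem_narr),
               tolerance = 1e-12)

  expect_error(build_scores(data.frame(immediate = c(1, 1), delayed = c(1, 1),
                                       mem_emo = c(2, 3))), "mem_narr")
  expect_error(build_scores(data.frame(immediate = -1, delayed = 2)),
               "non-negative")
})

test_that("standardized betas reduce to Pearson r without covariates", {
  set.seed(11)
  d <- data.frame(y = rnorm(60), x = rnorm(60))
  d$y <- d$x * 0.5 + rnorm(60)
  fit <- fit_brain_behavior(d, "y", "x", "none")
  expect_equal(fit$beta, cor(d$y, d$x), tolerance = 1e-10)
  expect_equal(fit$df, 58)
  # t^2 equals the one-predictor model F statistic
  lmfit <- lm(y ~ x, d)
  expect_equal(fit$t^2, summary(lmfit)$fstatistic[["value"]], tolerance = 1e-8)

  # exact relationship y = x gives beta 1 and p ~ 0
  d2 <- data.frame(y = rnorm(30))
  d2$x <- d2$y
  fit2 <- fit_brain_behavior(d2, "y", "x", "none")
  expect_equal(fit2$beta, 1, tolerance = 1e-10)
  expect_lt(fit2$p, 1e-20)
})

test_that("covariate-adjusted betas match lm on z-scored data", {
  set.seed(12)
  n <- 80
  d <- data.frame(x = rnorm(n), age = runif(n, 18, 50),
                  sex = rbinom(n, 1, 0.5), fd = rnorm(n, 0.14, 0.04))
  d$y <- 0.3 * d$x - 0.01 * d$age + rnorm(n)
  fit <- fit_brain_behavior(d, "y", "x", "motion_demographic")
  zd <- as.data.frame(scale(d))
  ref <- summary(lm(y ~ x + age + sex + fd, zd))
  expect_equal(fit$beta, ref$coefficients["x", "Estimate"], tolerance = 1e-10)
  expect_equal(fit$se, ref$coefficients["x", "Std. Error"], tolerance = 1e-10)
  expect_equal(fit$p, ref$coefficients["x", "Pr(>|t|)"], tolerance = 1e-10)
  expect_equal(fit$df, n - 5)
})

test_that("results are invariant to affine rescaling of the inputs", {
  set.seed(13)
  n <- 50
  d <- data.frame(x = rnorm(n), age = runif(n, 18, 50),
                  sex = rbinom(n, 1, 0.5), fd = rnorm(n, 0.14, 0.04))
  d$y <- 0.4 * d$x + rnorm(n)
  d2 <- d
  d2$x <- d2$x * 1000 + 5
  d2$y <- d2$y / 7 - 2
  f1 <- fit_brain_behavior(d, "y", "x", "motion_demographic")
  f2 <- fit_brain_behavior(d2, "y", "x", "motion_demographic")
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$p, f2$p, tolerance = 1e-10)
})

test_that("listwise deletion drops incomplete rows without side effects", {
  set.seed(14)
  n <- 40
  d <- data.frame(x = rnorm(n), age = runif(n, 18, 50),
                  sex = rbinom(n, 1, 0.5), fd = rnorm(n, 0.14, 0.04))
  d$y <- 0.4 * d$x + rnorm(n)
  base <- fit_brain_behavior(d, "y", "x", "motion_demographic")
  extra <- rbind(d, data.frame(x = 1, age = NA, sex = 1, fd = 0.1, y = 2))
  withna <- fit_brain_behavior(extra, "y", "x", "motion_demographic")
  expect_equal(base$beta, withna$beta)
  expect_equal(base$n_used, withna$n_used)
})

test_that("collinear predictors are rejected by name", {
  set.seed(15)
  d <- data.frame(x = rnorm(30), y = rnorm(30))
  d$dup <- d$x * 2
  expect_error(fit_brain_behavior(d, "y", "x", c("dup")), "dup")
})

test_that("the cohort model table covers every y-x-covariate combination", {
  fx <- planted_cohort()
  subjects <- build_scores(fx$cohort$subjects)
  summaries <- summarize_cohort(fx$cohort$connectomes, fx$atlas)
  models <- run_association_models(subjects, summaries)
  expect_setequal(unique(models$covariate_set), c("none", "motion_demographic", "full"))
  expect_setequal(unique(models$x), c("within", "between", "extra", "hipp"))
  expect_true(all(models$p >= 0 & models$p <= 1))
  expect_true(all(models$df == models$n_used - c(none = 2, motion_demographic = 5,
                                                 full = 7)[models$covariate_set]))
})
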