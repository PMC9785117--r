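test_that("imputation is a no-op on complete tables and reproducible otherwise", {
  co <- tiny_cohort(n = 30, seed = 1)
  expect_identical(impute_cohort(co), co)

  cfg <- generator_config(seed = 21)
  full <- generate_cohort(cfg)
  a <- impute_cohort(full, imputation_spec(seed = 5))
  b <- impute_cohort(full, imputation_spec(seed = 5))
  expect_identical(a$data, b$data)
  ## observed cells untouched, missing cells filled positive
  M0 <- cohort_matrix(full); M1 <- cohort_matrix(a)
  expect_equal(M1[!is.na(M0)], M0[!is.na(M0)])
  expect_false(anyNA(M1))
  expect_true(all(M1 > 0))
})

test_that("a missing cell in a collinear pair is recovered by regression", {
  n <- 40
  set.seed(2)
  age <- runif(n, 20, 70)
  a <- exp(rnorm(n, log(0.2), 0.3))
  b <- exp(1.3 * log(a) + 0.5)  # log-b exactly affine in log-a
  data <- data.frame(subject_id = sprintf("C%02d", 1:n), age = age,
                     sex = "F", bmi = rnorm(n, 24, 2),
                     met_a = a, met_b = b, stringsAsFactors = FALSE)
  truth <- data$met_b[7]
  data$met_b[7] <- NA
  co <- cohort_table(data, c(age = "age", sex = "sex", bmi = "bmi",
                             met_a = "metabolite", met_b = "metabolite"))
  out <- impute_cohort(co, imputation_spec(seed = 3))
  expect_equal(out$data$met_b[7], truth, tolerance = 1e-6)
})

test_that("study-scale missingness (2 of 138 per variable) imputes cleanly", {
  co <- generate_cohort(generator_config(missing_rate = 0, seed = 22))
  set.seed(9)
  for (v in c("valine", "glucose", "nmr_05")) {
    co$data[[v]][sample(138, 2)] <- NA
  }
  expect_no_warning(out <- impute_cohort(co, imputation_spec(seed = 1)))
  expect_false(anyNA(cohort_matrix(out)))
})

test_that("Box-Cox grid search normalizes skewed data and honours its grid", {
  set.seed(3)
  y <- exp(rnorm(300, 0, 0.8))  # strongly right-skewed
  spec <- boxcox_fit(y)
  z <- boxcox_apply(y, spec)
  skew <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  expect_lt(abs(skew(z)), abs(skew(y)))
  expect_gte(spec$lambda, -10)
  expect_lte(spec$lambda, 10)
  ## lambda lands near 0 for log-normal data
  expect_lt(abs(spec$lambda), 0.5)
  ## fitted standardization is exact on the fitting arm
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
})

test_that("Box-Cox selection agrees with the profile-likelihood optimum", {
  skip_if_not_installed("MASS")
  set.seed(4)
  y <- rgamma(250, shape = 3, rate = 2)
  spec <- boxcox_fit(y, grid_step = 0.05)
  bc <- MASS::boxcox(y ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  lambda_ml <- bc$x[which.max(bc$y)]
  expect_equal(spec$lambda, lambda_ml, tolerance = 0.1)
})

test_that("degenerate and invalid Box-Cox inputs are rejected", {
  expect_error(boxcox_fit(rep(2, 10)), "zero-variance")
  expect_error(boxcox_fit(c(1, 2)), "at least 3")
  expect_error(boxcox_fit(c(-1, 2, 3)), "positive")
})

test_that("boxcox_apply is monotone and affine at lambda = 1", {
  set.seed(5)
  y <- sort(exp(rnorm(50, 0, 0.5)))
  for (lam in c(-3, -0.5, 0, 0.7, 1, 4)) {
    spec <- boxcox_fit(y, lambda_range = c(lam, lam), grid_step = 1)
    z <- boxcox_apply(y, spec)
    expect_true(all(diff(z) > 0), info = paste("lambda =", lam))
  }
  spec1 <- boxcox_fit(y, lambda_range = c(1, 1), grid_step = 1)
  z1 <- boxcox_apply(y, spec1)
  expect_equal(abs(stats::cor(z1, y)), 1, tolerance = 1e-12)
})

test_that("the GM-scaled transform has its documented closed form", {
  ## lambda = 0 applied to y = e with unit geometric mean of the fit data
  y <- exp(c(-1, 0, 1))  # GM = 1
  spec <- boxcox_fit(y, lambda_range = c(0, 0), grid_step = 1)
  expect_equal(spec$gm, 1, tolerance = 1e-12)
  z <- boxcox_apply(exp(1), spec)
  ## GM * ln(e) = 1, standardized with train mean 0 and sd 1
  expect_equal(z, 1, tolerance = 1e-12)
})

test_that("the unscaled SD criterion is degenerate, as documented", {
  set.seed(6)
  y <- exp(rnorm(100, 2, 0.4))
  raw <- boxcox_fit(y, scaled = FALSE)
  expect_equal(raw$lambda, -10)  # SD shrinks without bound in |lambda|
})

test_that("Shapiro-Wilk wrapper is calibrated under the null and powered", {
  reps <- 600
  set.seed(7)
  p_null <- replicate(reps, shapiro_check(rnorm(80))$p_value)
  expect_lt(abs(mean(p_null < 0.05) - 0.05), 0.025)
  p_skew <- replicate(200, shapiro_check(exp(rnorm(100, 0, 1)))$p_value)
  expect_gt(mean(p_skew < 0.05), 0.99)
  expect_error(shapiro_check(c(1, 2)), "3 <= n")
})

test_that("preprocessing is train-anchored", {
  ## complete table: the transform contract is checked in isolation from
  ## imputation (which by design pools all subjects before the split)
  co <- split_cohort(generate_cohort(generator_config(missing_rate = 0,
                                                      seed = 23)),
                     seed = 24)
  pp <- preprocess_cohort(co)
  train <- pp$table$split == "train"
  z <- pp$table$data$valine
  expect_equal(mean(z[train]), 0, tolerance = 1e-10)
  expect_equal(stats::sd(z[train]), 1, tolerance = 1e-10)
  ## the test arm keeps the train scaling: mean generally != 0
  expect_gt(abs(mean(z[!train])), 1e-4)

  ## permuting test rows changes no fitted spec
  co2 <- co
  test_rows <- which(co2$split == "test")
  set.seed(1)
  perm <- sample(test_rows)
  co2$data[test_rows, ] <- co2$data[perm, ]
  pp2 <- preprocess_cohort(co2)
  expect_equal(pp$specs, pp2$specs, tolerance = 1e-12)
})
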