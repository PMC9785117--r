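test_that("generation is deterministic and respects configured sizes", {
  cfg <- generator_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$data), 138)
  expect_equal(sum(a$roles == "metabolite"), 175)

  M <- cohort_matrix(a)
  expect_true(all(M[!is.na(M)] > 0))
  expect_lte(mean(is.na(M)), 0.02)
  expect_false(anyNA(a$data$age))
  expect_false(anyNA(a$data$bmi))
  expect_true(all(a$data$bmi < 30))
  expect_true(all(a$data$age >= 20 & a$data$age <= 70))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(generator_config(n_subjects = 5), "n_subjects")
  expect_error(generator_config(missing_rate = 0.2), "missing_rate")
  expect_error(generator_config(age_range = c(50, 50)), "age_range")
  pan <- default_variable_panel()
  pan$noise_sd <- 0
  expect_error(generator_config(variables = pan), "noise_sd")
})

test_that("noiseless monotone trends give |partial r| at the boundary", {
  ## metabolite noise off, BMI scatter kept: the trends are exact functions
  ## of age, so the BMI-partialled correlation hits the boundary exactly
  cfg <- generator_config(missing_rate = 0, seed = 3)
  co <- generate_cohort(cfg, noise_scale = 0)
  x <- log(co$data$ornithine)  # linear positive trend, no noise
  r <- partial_correlation(x, co$data$age, co$data$bmi)$r
  expect_equal(r, 1, tolerance = 1e-10)
  r2 <- partial_correlation(log(co$data$tryptophan), co$data$age,
                            co$data$bmi)$r
  expect_equal(r2, -1, tolerance = 1e-10)
})

test_that("realized partial correlations are calibrated to their targets", {
  ## Monte-Carlo check against the sample partial-correlation oracle
  vars <- c(isoleucine = -0.280, ornithine = 0.269,
            total_cholesterol = 0.370, nmr_01 = 0)
  reps <- 200
  acc <- matrix(NA_real_, reps, length(vars))
  for (s in seq_len(reps)) {
    co <- generate_cohort(generator_config(seed = 1000 + s))
    for (j in seq_along(vars)) {
      x <- log(co$data[[names(vars)[j]]])
      ok <- !is.na(x)
      acc[s, j] <- bf_partial_cor(x[ok], co$data$age[ok],
                                  co$data$bmi[ok, drop = FALSE])
    }
  }
  realized <- colMeans(acc)
  expect_true(all(abs(realized - vars) < 0.05),
              info = paste(round(realized, 3), collapse = ", "))
})

test_that("the planted hinge sits exactly at the configured breakpoint age", {
  cfg <- generator_config(missing_rate = 0, breakpoint_age = 37, seed = 5)
  co <- generate_cohort(cfg, noise_scale = 0)
  age <- co$data$age
  y <- log(co$data$valine)
  pre <- age < 37
  f1 <- lm(y[pre] ~ age[pre])
  f2 <- lm(y[!pre] ~ age[!pre])
  ## both segments are exact lines, meeting at the hinge
  expect_lt(suppressWarnings(summary(f1))$sigma, 1e-10)
  expect_lt(suppressWarnings(summary(f2))$sigma, 1e-10)
  x_at <- function(f, a) unname(coef(f)[1] + coef(f)[2] * a)
  expect_equal(x_at(f1, 37), x_at(f2, 37), tolerance = 1e-8)
  expect_false(isTRUE(all.equal(coef(f1)[2], coef(f2)[2])))
})

test_that("cohort splitting reproduces the canonical 105/33 arms", {
  co <- generate_cohort(generator_config(seed = 6))
  sp <- split_cohort(co, 105 / 138, seed = 9)
  expect_equal(sum(sp$split == "train"), 105)
  expect_equal(sum(sp$split == "test"), 33)
  sp2 <- split_cohort(co, 105 / 138, seed = 9)
  expect_identical(sp$split, sp2$split)

  tiny <- tiny_cohort(n = 6, seed = 2)
  halves <- split_cohort(tiny, 0.5, seed = 1)
  expect_equal(sum(halves$split == "train"), 3)
  expect_error(split_cohort(tiny, 0.9, seed = 1), "fewer than 3")
})

test_that("feature tables encode known filter ground truth", {
  ft <- generate_feature_table(n_features = 12, n_fail_blank = 3,
                               n_fail_cv = 2, n_fail_missing = 1, seed = 4)
  expect_length(attr(ft, "truth_retained"), 6)
  expect_equal(sum(ft$injection_class == "qc") %% 3, 0)
  expect_true(all(ft$intensities[!is.na(ft$intensities)] > 0))

  ## drift-free, noise-free: QC injections of a feature are identical
  flat <- generate_feature_table(n_features = 3, drift_amplitude = 0,
                                 qc_cv = 0, seed = 5)
  qc <- flat$injection_class == "qc"
  expect_equal(stats::sd(flat$intensities[1, qc]), 0)
})

test_that("cohort and feature tables round-trip through their TSV dialects", {
  co <- split_cohort(generate_cohort(generator_config(seed = 12)), seed = 13)
  path <- file.path(withr::local_tempdir(), "cohort.tsv")
  write_cohort(co, path)
  co2 <- read_cohort(path)
  expect_equal(co2$data$age, co$data$age, tolerance = 1e-9)
  expect_identical(co2$split, co$split)
  expect_identical(co2$roles, co$roles)

  ft <- generate_feature_table(seed = 14)
  fpath <- file.path(withr::local_tempdir(), "features.tsv")
  write_feature_table(ft, fpath)
  ft2 <- read_feature_table(fpath)
  expect_equal(ft2$intensities, ft$intensities, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(ft2$injection_class, ft$injection_class)
})
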