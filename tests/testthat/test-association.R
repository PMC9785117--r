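test_that("partial correlation matches the residual-correlation oracle", {
  for (seed in 1:20) {
    f <- random_fixture(n = 8 + seed %% 5, k = 1 + seed %% 2, seed = seed)
    got <- partial_correlation(f$x, f$y, f$Z)
    expect_equal(got$r, bf_partial_cor(f$x, f$y, f$Z), tolerance = 1e-12)
    expect_equal(got$df, length(f$x) - 2 - ncol(f$Z))
  }
})

test_that("partial correlation is symmetric and affine-invariant", {
  f <- random_fixture(n = 30, k = 2, seed = 7)
  a <- partial_correlation(f$x, f$y, f$Z)
  b <- partial_correlation(f$y, f$x, f$Z)
  expect_equal(a$r, b$r, tolerance = 1e-14)
  expect_equal(a$p, b$p, tolerance = 1e-14)
  ## affine maps of x, y or Z leave r unchanged
  d <- partial_correlation(3 * f$x - 7, -2 * f$y + 1, 5 * f$Z + 2)
  expect_equal(abs(d$r), abs(a$r), tolerance = 1e-12)
  expect_equal(d$r, -a$r, tolerance = 1e-12)  # sign flips with -2 * y
})

test_that("partial correlation handles identities and degeneracies", {
  f <- random_fixture(n = 20, k = 1, seed = 3)
  expect_equal(partial_correlation(f$x, f$x, f$Z)$r, 1, tolerance = 1e-12)
  expect_error(partial_correlation(f$Z[, 1], f$y, f$Z), "zero residual")
})

test_that("covariate selection keeps a real BMI effect and drops null terms", {
  ## strong BMI-age coupling: selection should be near-certain, sex never in
  strong <- list(intercept = 20, slope = 0.09, sd = 1.8, max_bmi = 30)
  hits_bmi <- 0; hits_sex <- 0
  for (s in 1:40) {
    co <- generate_cohort(generator_config(bmi_model = strong,
                                           seed = 3000 + s))
    covs <- select_covariates(co)
    hits_bmi <- hits_bmi + ("bmi" %in% covs)
    hits_sex <- hits_sex + ("sex" %in% covs)
  }
  expect_gte(hits_bmi / 40, 0.9)
  expect_lte(hits_sex / 40, 0.2)

  ## under the global null each covariate enters at about the alpha rate
  null_bmi <- list(intercept = 24, slope = 0, sd = 2.5, max_bmi = 30)
  n_in <- sapply(1:60, function(s) {
    co <- generate_cohort(generator_config(bmi_model = null_bmi,
                                           seed = 4000 + s))
    length(select_covariates(co))
  })
  ## expected entries per run = 2 * 0.05 = 0.1
  expect_lt(mean(n_in), 0.3)
})

test_that("covariate selection rejects singular designs", {
  co <- tiny_cohort(n = 20, seed = 5)
  co$data$bmi <- 25  # constant column: design collinear with the intercept
  expect_error(select_covariates(co), "singular")
})

test_that("the dual BH + alpha rule enumerates its step-up example", {
  res <- bh_screen(c(0.01, 0.02, 0.20, 0.90), q = 0.2, alpha = 0.05)
  expect_equal(res$bh_critical, c(0.05, 0.10, 0.15, 0.20))
  expect_identical(res$significant, c(TRUE, TRUE, FALSE, FALSE))
  ## BH rejects {1, 2}: largest i with p(i) <= i*q/m is 2
  expect_identical(res$rejected_bh, c(TRUE, TRUE, FALSE, FALSE))

  none <- bh_screen(rep(1, 6), q = 0.2, alpha = 0.05)
  expect_false(any(none$significant))
  expect_equal(nrow(bh_screen(numeric(0))), 0)
})

test_that("the alpha cap only ever removes BH rejections", {
  set.seed(11)
  for (i in 1:20) {
    p <- runif(50)^2
    res <- bh_screen(p)
    expect_true(all(res$significant <= res$rejected_bh))
    expect_true(all(res$p[res$significant] < 0.05))
  }
})

test_that("screening a cohort recovers planted signals with correct signs", {
  co <- split_cohort(generate_cohort(generator_config(seed = 42)), seed = 43)
  pp <- preprocess_cohort(co, imputation = imputation_spec(seed = 44))
  scr <- screen_cohort(pp$table, covariates = "bmi")
  rec <- scr$records
  sig <- rec[rec$significant, ]
  expect_gt(nrow(sig), 3)
  neg <- c("valine", "leucine", "isoleucine", "3-hydroxyisobutyrate",
           "asparagine", "tryptophan")
  pos <- c("aspartate", "ornithine", "glucose", "total_cholesterol")
  expect_true(all(sig$partial_r[sig$variable %in% neg] < 0))
  expect_true(all(sig$partial_r[sig$variable %in% pos] > 0))
  ## correlation matrix is symmetric with unit diagonal
  expect_equal(scr$cor_matrix, t(scr$cor_matrix), tolerance = 1e-12)
  expect_equal(unname(diag(scr$cor_matrix)), rep(1, nrow(scr$cor_matrix)))
  ## records sorted by raw p
  expect_false(is.unsorted(rec$p_raw))
})

test_that("screen output matches per-variable partial_correlation calls", {
  co <- split_cohort(generate_cohort(
    generator_config(missing_rate = 0, seed = 45)), seed = 46)
  pp <- preprocess_cohort(co, imputation = imputation_spec(seed = 1))
  scr <- screen_cohort(pp$table, covariates = "bmi")
  train <- pp$table$split == "train"
  age <- pp$table$data$age[train]
  bmi <- pp$table$data$bmi[train]
  for (v in c("valine", "ornithine", "nmr_10", "hs_crp")) {
    ref <- partial_correlation(pp$table$data[[v]][train], age,
                               data.frame(bmi = bmi))
    row <- scr$records[scr$records$variable == v, ]
    expect_equal(row$partial_r, ref$r, tolerance = 1e-12)
    expect_equal(row$p_raw, ref$p, tolerance = 1e-12)
  }
})
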