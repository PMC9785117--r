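test_that("PCA loadings satisfy the correlation-matrix identities", {
  set.seed(1)
  n <- 60
  f <- rnorm(n)
  X <- cbind(a = f + rnorm(n, 0, 0.4),
             b = f + rnorm(n, 0, 0.5),
             c = rnorm(n),
             d = -f + rnorm(n, 0, 0.6))
  pca <- fit_pca(X)
  ## completeness: per-variable squared loadings over all components sum to 1
  expect_equal(unname(rowSums(pca$loadings^2)), rep(1, 4), tolerance = 1e-10)
  ## eigenvalue identity: column sums of squared loadings = eigenvalues
  expect_equal(unname(colSums(pca$loadings^2)), pca$eigenvalues,
               tolerance = 1e-10)
  expect_equal(sum(pca$explained_variance_ratio), 1, tolerance = 1e-10)
  expect_true(all(diff(pca$explained_variance_ratio) <= 1e-12))
  ## scores are centered
  expect_equal(unname(colMeans(pca$scores)), rep(0, 4), tolerance = 1e-10)
  ## anchor orientation: anchor variable loads non-negatively everywhere
  expect_true(all(pca$loadings[pca$sign_anchor, ] >= -1e-12))
})

test_that("two perfectly correlated variables collapse onto PC1", {
  set.seed(2)
  x <- rnorm(30)
  pca <- fit_pca(cbind(a = x, b = 2 * x + 3), n_components = 1)
  expect_equal(pca$explained_variance_ratio[1], 1, tolerance = 1e-12)
  expect_equal(unname(abs(pca$loadings[, 1])), c(1, 1), tolerance = 1e-10)
  expect_gte(pca$loadings[pca$sign_anchor, 1], 0)
})

test_that("PCA rejects constant variables and over-asking", {
  set.seed(3)
  X <- cbind(a = rnorm(20), b = rep(1, 20))
  expect_error(fit_pca(X), "constant")
  x <- rnorm(20)
  expect_error(fit_pca(cbind(a = x, b = x), n_components = 2), "rank")
})

test_that("a shared factor block dominates PC1 loadings", {
  co <- generate_cohort(generator_config(missing_rate = 0, seed = 31))
  vars <- c("valine", "leucine", "isoleucine", "3-hydroxyisobutyrate",
            "nmr_01", "nmr_02")
  X <- apply(cohort_matrix(co, variables = vars), 2, function(v) {
    scale(log(v))[, 1]
  })
  pca <- fit_pca(X, n_components = 1, sign_anchor = "valine")
  l <- abs(pca$loadings[, 1])
  expect_gt(min(l[1:4]), max(l[5:6]))
  expect_gt(min(l[1:3]), 0.8)  # BCAA block is strongly inter-correlated
})

test_that("test-arm refits are sign-aligned to the training loadings", {
  co <- generate_cohort(generator_config(missing_rate = 0, seed = 32))
  vars <- c("valine", "leucine", "isoleucine", "bmi")
  X <- cbind(apply(cohort_matrix(co, variables = vars[1:3]), 2,
                   function(v) scale(log(v))[, 1]),
             bmi = scale(co$data$bmi)[, 1])
  tr <- fit_pca(X[1:100, ], n_components = 2)
  te <- align_pca(fit_pca(X[101:138, ], n_components = 2), tr)
  for (j in 1:2) {
    expect_gte(sum(te$loadings[, j] * tr$loadings[, j]), 0)
  }
})

test_that("breakpoint detection matches the exhaustive brute-force oracle", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(30:60, 1)
    ages <- runif(n, 20, 70)
    tau <- runif(1, 35, 55)
    y <- -0.03 * pmax(ages - tau, 0) + 0.01 * pmin(ages - tau, 0) +
      rnorm(n, 0, 0.2)
    ms <- sample(5:8, 1)
    got <- detect_breakpoint(ages, y, min_segment = ms)
    ref <- bf_detect_breakpoint(ages, y, min_segment = ms)
    expect_equal(got$split_index, ref$split_index)
    expect_equal(got$r2_product, ref$r2_product, tolerance = 1e-12)
    expect_equal(got$intersection_age, ref$intersection_age,
                 tolerance = 1e-9)
  }
})

test_that("a noiseless hinge is recovered at the planted age", {
  set.seed(4)
  ages <- sort(runif(105, 20, 70))
  y <- -0.1 * pmin(ages - 45, 0) * 0.3 - 0.1 * pmax(ages - 45, 0)
  bp <- detect_breakpoint(ages, y, min_segment = 35)
  expect_false(bp$no_intersection)
  ## exact up to the spacing of adjacent ages around the hinge
  gap <- max(diff(ages))
  expect_lt(abs(bp$intersection_age - 45), gap + 1e-9)
  expect_gt(bp$r2_product, 0.999)
})

test_that("perfectly linear scores are flagged as non-intersecting", {
  ages <- seq(20, 70, length.out = 40)
  y <- 0.05 * ages - 1
  bp <- detect_breakpoint(ages, y, min_segment = 5)
  expect_true(bp$no_intersection)
  expect_true(is.na(bp$intersection_age))
  expect_equal(bp$r2_product, 1, tolerance = 1e-12)
})

test_that("the search trace covers every admissible split and row order is irrelevant", {
  set.seed(5)
  n <- 50
  ages <- runif(n, 20, 70)
  y <- -0.02 * ages + rnorm(n, 0, 0.1)
  bp <- detect_breakpoint(ages, y, min_segment = 10)
  expect_equal(nrow(bp$search_trace), n - 2 * 10 + 1)
  expect_true(all(bp$search_trace$r2_product >= 0 &
                    bp$search_trace$r2_product <= 1, na.rm = TRUE))
  expect_true(bp$split_index >= 10 && bp$split_index <= n - 10)

  perm <- sample(n)
  bp2 <- detect_breakpoint(ages[perm], y[perm], min_segment = 10)
  expect_equal(bp2$search_trace, bp$search_trace, tolerance = 1e-12)
  expect_equal(bp2$intersection_age, bp$intersection_age, tolerance = 1e-12)
})

test_that("zero-variance segments are skipped, not scored", {
  ## flat-then-declining noiseless scores: early splits have zero score
  ## variance in the leading segment
  ages <- seq(20, 70, length.out = 30)
  y <- c(rep(1, 15), 1 - 0.1 * (ages[16:30] - ages[15]))
  bp <- detect_breakpoint(ages, y, min_segment = 5)
  expect_true(any(is.na(bp$search_trace$r2_product)))
  expect_false(is.na(bp$r2_product))
})

test_that("noiseless recovery is tight and degrades with noise", {
  pan <- default_variable_panel(n_nmr = 10, n_lchrms = 2)
  cfg <- generator_config(n_subjects = 105, breakpoint_age = 40,
                          missing_rate = 0, variables = pan, seed = 60)
  quiet <- recover_breakpoint_stats(cfg, n_seeds = 15, noise_scale = 0,
                                    min_segment = 35, use_boxcox = FALSE)
  expect_gt(quiet$valid_fraction, 0.9)
  expect_lt(abs(quiet$bias), 2)
  noisy <- recover_breakpoint_stats(cfg, n_seeds = 15, noise_scale = 1,
                                    min_segment = 35, use_boxcox = FALSE)
  expect_gt(noisy$rmse, quiet$rmse)
})
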