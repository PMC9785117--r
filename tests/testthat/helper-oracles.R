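## Independent brute-force oracles used to check the package implementations.
## These deliberately use the most literal computation available (lm() fits,
## subset enumeration) and share no code with the package internals.

## partial correlation as the plain correlation of lm() residuals
bf_partial_cor <- function(x, y, Z) {
  rx <- stats::residuals(stats::lm(x ~ ., data = as.data.frame(Z)))
  ry <- stats::residuals(stats::lm(y ~ ., data = as.data.frame(Z)))
  stats::cor(rx, ry)
}

## two-segment search: every admissible split, two lm() fits, argmax of the
## r-squared product, analytic intersection of the two fitted lines
bf_detect_breakpoint <- function(ages, scores, min_segment) {
  o <- order(ages)
  x <- ages[o]; y <- scores[o]; n <- length(x)
  best <- list(prod = -Inf)
  for (k in min_segment:(n - min_segment)) {
    d1 <- data.frame(x = x[1:k], y = y[1:k])
    d2 <- data.frame(x = x[(k + 1):n], y = y[(k + 1):n])
    if (stats::var(d1$x) == 0 || stats::var(d1$y) == 0 ||
        stats::var(d2$x) == 0 || stats::var(d2$y) == 0) next
    f1 <- stats::lm(y ~ x, d1); f2 <- stats::lm(y ~ x, d2)
    r1 <- summary(f1)$r.squared; r2 <- summary(f2)$r.squared
    if (r1 * r2 > best$prod) {
      best <- list(prod = r1 * r2, k = k,
                   c1 = stats::coef(f1), c2 = stats::coef(f2))
    }
  }
  ia <- (best$c2[1] - best$c1[1]) / (best$c1[2] - best$c2[2])
  list(split_index = best$k, r2_product = best$prod,
       intersection_age = unname(ia))
}

## upper-tail hypergeometric probability by enumerating all query-size draws
bf_hypergeom <- function(hits, pathway_size, universe_size, query_size) {
  universe <- seq_len(universe_size)
  pathway <- seq_len(pathway_size)
  draws <- utils::combn(universe, query_size)
  mean(apply(draws, 2, function(d) sum(d %in% pathway) >= hits))
}

## small random cohort-like fixture for oracle comparisons
random_fixture <- function(n, k = 1, seed) {
  set.seed(seed)
  list(x = stats::rnorm(n), y = stats::rnorm(n),
       Z = matrix(stats::rnorm(n * k), n))
}

## minimal raw cohort built by hand (not via the generator)
tiny_cohort <- function(n = 24, seed = 1, n_mets = 4) {
  set.seed(seed)
  age <- stats::runif(n, 20, 70)
  data <- data.frame(
    subject_id = sprintf("T%02d", seq_len(n)),
    age = age,
    sex = sample(c("M", "F"), n, replace = TRUE),
    bmi = 22 + 0.04 * age + stats::rnorm(n, 0, 2),
    stringsAsFactors = FALSE
  )
  roles <- c(age = "age", sex = "sex", bmi = "bmi")
  for (i in seq_len(n_mets)) {
    v <- paste0("met_", i)
    data[[v]] <- exp(stats::rnorm(n, log(0.1), 0.3))
    roles[v] <- "metabolite"
  }
  cohort_table(data, roles)
}
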