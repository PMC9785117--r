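#' Data-driven covariate selection for age association screening
#'
#' Fits ordinary least squares of age on BMI and sex and returns the
#' covariates whose coefficients reach p < `alpha`. In a cohort where BMI
#' rises weakly with age and sex carries no signal this retains BMI and
#' drops sex, so the downstream partial correlations control for BMI only.
#'
#' @param table a [cohort_table()].
#' @param alpha coefficient significance threshold.
#' @return Character vector (subset of `c("bmi", "sex")`), possibly empty.
#' @export
select_covariates <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "cohort_table"))
  age <- cohort_column(table, "age")
  bmi <- cohort_column(table, "bmi")
  sex <- as.numeric(factor(cohort_column(table, "sex")))
  X <- cbind(1, bmi = bmi, sex = sex)
  if (qr(X)$rank < ncol(X)) stop("singular design", call. = FALSE)
  fit <- stats::lm(age ~ bmi + sex)
  p <- summary(fit)$coefficients[-1, 4]
  c("bmi", "sex")[p < alpha]
}

residualize <- function(y, Z) {
  Q <- qr(cbind(`(Intercept)` = rep(1, NROW(y)), Z))
  qr.resid(Q, y)
}

#' Partial Pearson correlation
#'
#' Correlation between `x` and `y` after linearly removing `covariates`
#' (plus an intercept) from both, i.e. the Pearson correlation of the two
#' OLS residual vectors. The p-value comes from
#' `t = r * sqrt(df / (1 - r^2))` with `df = n - 2 - k` (k covariates),
#' two-sided.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates numeric vector, matrix or data.frame of covariate
#'   columns, or `NULL` for the plain Pearson correlation.
#' @return list with `r`, `p`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  n <- length(x)
  stopifnot(length(y) == n, is.null(covariates) || nrow(covariates) == n)
  if (n < k + 4) stop("need n >= k + 4 observations", call. = FALSE)
  rx <- residualize(x, covariates)
  ry <- residualize(y, covariates)
  if (stats::sd(rx) <= 1e-10 * max(stats::sd(x), .Machine$double.eps) ||
      stats::sd(ry) <= 1e-10 * max(stats::sd(y), .Machine$double.eps)) {
    stop("zero residual variance; partial correlation undefined",
         call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tt), df), df = df)
}

## vectorized column-wise partial correlation of each column of X with y
partial_cor_columns <- function(X, y, covariates = NULL) {
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  n <- length(y)
  Q <- qr(cbind(rep(1, n), covariates))
  RX <- qr.resid(Q, X)
  ry <- qr.resid(Q, y)
  r <- as.vector(stats::cor(RX, ry))
  df <- n - 2L - k
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  data.frame(variable = colnames(X), partial_r = r, df = df,
             p_raw = 2 * stats::pt(-abs(tt), df), stringsAsFactors = FALSE)
}

#' Dual Benjamini-Hochberg + nominal-alpha significance screen
#'
#' The BH step-up procedure at FDR level `q` determines the rejection set;
#' the final significance flag additionally requires the raw p-value to fall
#' below `alpha`. Per-test step-up critical values `i * q / m` (at each
#' p-value's ascending rank) are reported. The `"critical"` rule variant
#' flags tests whose p-value falls below its own critical value without the
#' step-up sweep — a stricter, non-standard reading provided for comparison.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.2).
#' @param alpha nominal significance cap (default 0.05).
#' @param rule `"step_up"` (default) or `"critical"`.
#' @return data.frame with `p`, `rank`, `bh_critical`, `rejected_bh`,
#'   `significant`, in the input order. Empty input gives an empty frame.
#' @export
bh_screen <- function(p_values, q = 0.2, alpha = 0.05,
                      rule = c("step_up", "critical")) {
  rule <- match.arg(rule)
  stopifnot(q > 0, q < 1)
  m <- length(p_values)
  if (m == 0) {
    return(data.frame(p = numeric(0), rank = integer(0),
                      bh_critical = numeric(0), rejected_bh = logical(0),
                      significant = logical(0)))
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  rk <- rank(p_values, ties.method = "first")
  crit <- rk * q / m
  rejected <- if (rule == "step_up") {
    stats::p.adjust(p_values, method = "BH") <= q
  } else {
    p_values <= crit
  }
  data.frame(p = p_values, rank = rk, bh_critical = crit,
             rejected_bh = rejected,
             significant = rejected & p_values < alpha)
}

#' Screen a cohort for age-associated variables
#'
#' Computes the BMI-adjusted (or generally covariate-adjusted) partial
#' Pearson correlation of every clinical marker and metabolite with age,
#' applies the dual significance rule of [bh_screen()] across the combined
#' variable family, and returns the per-variable association records sorted
#' by raw p-value together with the full symmetric correlation matrix
#' (age, covariates and variables) for heatmap display.
#'
#' @param table a preprocessed [cohort_table()] (imputed and transformed);
#'   screening runs on the training arm if the cohort is split.
#' @param covariates covariate column names (default from
#'   [select_covariates()] semantics: `"bmi"`).
#' @param q,alpha,rule passed to [bh_screen()].
#' @param arm which split arm to screen (`"train"`, `"test"`, `"all"`).
#' @return list of class `age_screen`: `records` (data.frame with
#'   `variable`, `partial_r`, `df`, `p_raw`, `bh_critical`, `significant`),
#'   `cor_matrix`, `covariates`.
#' @export
screen_cohort <- function(table, covariates = "bmi", q = 0.2, alpha = 0.05,
                          rule = c("step_up", "critical"),
                          arm = c("train", "all", "test")) {
  stopifnot(inherits(table, "cohort_table"))
  arm <- match.arg(arm)
  rule <- match.arg(rule)
  keep <- if (arm == "all") rep(TRUE, nrow(table$data)) else table$split == arm
  age <- cohort_column(table, "age")[keep]
  vars <- cohort_variables(table)
  X <- cohort_matrix(table, variables = vars)[keep, , drop = FALSE]
  Z <- if (length(covariates)) {
    sapply(covariates, function(v) {
      if (v == "sex") as.numeric(factor(table$data$sex[keep]))
      else table$data[[v]][keep]
    })
  } else NULL
  if (anyNA(X)) stop("screen requires an imputed (complete) table",
                     call. = FALSE)
  rec <- partial_cor_columns(X, age, Z)
  scr <- bh_screen(rec$p_raw, q = q, alpha = alpha, rule = rule)
  rec$bh_critical <- scr$bh_critical
  rec$significant <- scr$significant
  rec <- rec[order(rec$p_raw), ]
  rownames(rec) <- NULL
  cm <- stats::cor(cbind(age = age, Z, X))
  structure(list(records = rec, cor_matrix = cm, covariates = covariates,
                 q = q, alpha = alpha, arm = arm),
            class = "age_screen")
}

#' @export
print.age_screen <- function(x, ...) {
  sig <- x$records[x$records$significant, ]
  cat("<age_screen> ", nrow(x$records), " variables, ",
      nrow(sig), " significant (q = ", x$q, ", alpha = ", x$alpha, ", ",
      x$arm, " arm)\n", sep = "")
  if (nrow(sig)) {
    print(utils::head(sig[, c("variable", "partial_r", "p_raw")], 15),
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}
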