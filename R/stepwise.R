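#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing column `j`
#' on the remaining columns (plus an intercept). Exactly collinear columns
#' are reported as `Inf`.
#'
#' @param design numeric matrix with at least two columns.
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
compute_vif <- function(design) {
  design <- as.matrix(design)
  if (ncol(design) < 2) stop("need at least 2 columns", call. = FALSE)
  vapply(seq_len(ncol(design)), function(j) {
    y <- design[, j]
    Z <- cbind(1, design[, -j, drop = FALSE])
    res <- qr.resid(qr(Z), y)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - sum(res^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) -> v
  stats::setNames(v, colnames(design))
}

step_fit <- function(Z, y) {
  fit <- stats::lm.fit(Z, y)
  rss <- sum(fit$residuals^2)
  list(fit = fit, rss = rss)
}

## t statistic and p-value of the last column of Z in OLS of y on Z
last_column_t <- function(Z, y) {
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) return(NULL)
  fit <- stats::lm.fit(Z, y)
  df <- length(y) - ncol(Z)
  if (df < 1) return(NULL)
  s2 <- sum(fit$residuals^2) / df
  xtxi <- chol2inv(qr.R(qz))
  tt <- fit$coefficients[ncol(Z)] / sqrt(s2 * xtxi[ncol(Z), ncol(Z)])
  list(t = tt, p = 2 * stats::pt(-abs(tt), df))
}

#' Forward stepwise linear regression with forced covariates
#'
#' Starts from the forced-covariate-only model (BMI by convention) and, at
#' each step, adds the candidate with the smallest partial-F entry p-value,
#' provided it falls below `p_enter`; stops when no candidate qualifies.
#' Pure forward selection — no removal step. The path is deterministic:
#' ties on p are broken by the larger `|t|`, then by variable name, so the
#' result does not depend on candidate column order. Candidates that make
#' the design singular at a step are skipped with a warning.
#'
#' @param candidates numeric matrix of candidate predictors (standardized;
#'   columns named).
#' @param target numeric response (age, in years or standardized).
#' @param forced numeric matrix of always-included covariates (default
#'   none; pass the BMI column to adjust for BMI), or `NULL`.
#' @param p_enter entry threshold on the partial-F p-value (default 0.05).
#' @return An object of class `stepwise_model`: `selected` (entry order),
#'   `forced`, `coefficients` (final-model slopes, response units per unit
#'   predictor — standardized beta when inputs are standardized),
#'   `intercept`, `entry_p`, `r_multiple`, `r2`, `r2_adjusted`, `vif`, `n`.
#' @export
forward_stepwise <- function(candidates, target, forced = NULL,
                             p_enter = 0.05) {
  X <- as.matrix(candidates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(target)
  n <- length(y)
  stopifnot(nrow(X) == n, p_enter > 0, p_enter < 1)
  Fm <- if (is.null(forced)) NULL else {
    f <- as.matrix(forced)
    if (is.null(colnames(f))) colnames(f) <- paste0("forced", seq_len(ncol(f)))
    f
  }
  selected <- character(0)
  entry_p <- numeric(0)
  remaining <- colnames(X)
  skipped <- character(0)
  repeat {
    if (!length(remaining)) break
    base <- cbind(`(Intercept)` = rep(1, n), Fm,
                  X[, selected, drop = FALSE])
    best <- NULL
    for (v in sort(remaining)) {
      cand <- last_column_t(cbind(base, X[, v, drop = FALSE]), y)
      if (is.null(cand)) {
        skipped <- union(skipped, v)
        next
      }
      if (is.null(best) || cand$p < best$p - 1e-15 ||
          (abs(cand$p - best$p) <= 1e-15 && abs(cand$t) > abs(best$t))) {
        best <- c(cand, list(v = v))
      }
    }
    if (is.null(best) || best$p >= p_enter) break
    selected <- c(selected, best$v)
    entry_p <- c(entry_p, best$p)
    remaining <- setdiff(remaining, c(selected, skipped))
  }
  if (length(skipped)) {
    warning("candidates skipped (singular design): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  Z <- cbind(`(Intercept)` = rep(1, n), Fm, X[, selected, drop = FALSE])
  fit <- stats::lm.fit(Z, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  p <- ncol(Z) - 1L
  coefs <- fit$coefficients[-1]
  vif <- if (ncol(Z) > 2) compute_vif(Z[, -1, drop = FALSE]) else {
    stats::setNames(rep(1, p), colnames(Z)[-1])
  }
  structure(list(
    selected = selected,
    forced = colnames(Fm),
    coefficients = coefs,
    intercept = unname(fit$coefficients[1]),
    entry_p = stats::setNames(entry_p, selected),
    r_multiple = sqrt(max(r2, 0)),
    r2 = r2,
    r2_adjusted = 1 - (1 - r2) * (n - 1) / (n - p - 1),
    vif = vif,
    p_enter = p_enter,
    n = n
  ), class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat("<stepwise_model> n = ", x$n, "\n", sep = "")
  cat("  forced:   ", paste(x$forced, collapse = ", "), "\n", sep = "")
  cat("  selected: ",
      if (length(x$selected)) paste(x$selected, collapse = " -> ") else "(none)",
      "\n", sep = "")
  cat(sprintf("  r_multiple = %.3f, adjusted R^2 = %.3f\n",
              x$r_multiple, x$r2_adjusted))
  invisible(x)
}

#' Predict from a stepwise model
#'
#' @param object a [stepwise_model][forward_stepwise()].
#' @param newdata data.frame or matrix containing all model variables
#'   (forced and selected), on the same (train-anchored) scale used to fit.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.stepwise_model <- function(object, newdata, ...) {
  vars <- names(object$coefficients)
  missing <- setdiff(vars, colnames(newdata))
  if (length(missing)) {
    stop("model variables missing from newdata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  M <- as.matrix(as.data.frame(newdata)[, vars, drop = FALSE])
  drop(object$intercept + M %*% object$coefficients)
}

#' Cross-validate a stepwise model on the test arm
#'
#' Pearson correlation between predicted and observed response on held-out
#' subjects. The test data must have been transformed with the
#' training-anchored Box-Cox specs for the prediction scale to be
#' meaningful.
#'
#' @param model a [stepwise_model][forward_stepwise()].
#' @param newdata test-arm predictor table (see [predict.stepwise_model()]).
#' @param target observed test-arm response.
#' @return `r_multiple_test`, the predicted-observed correlation.
#' @export
evaluate_on_test <- function(model, newdata, target) {
  pred <- stats::predict(model, newdata)
  stats::cor(pred, as.numeric(target))
}
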