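#' Principal component analysis with factor loadings
#'
#' Eigendecomposition of the correlation matrix of the chosen variables.
#' Loadings are eigenvectors scaled by the square root of their eigenvalues,
#' so a loading is interpretable as the variable-component correlation and
#' the per-variable sum of squared loadings over all components is 1.
#' Component signs are oriented so that the anchor variable (by default the
#' variable with the largest mean absolute loading) loads non-negatively on
#' every component; scores are computed from the standardized data and have
#' zero mean per component.
#'
#' @param x numeric matrix (subjects x variables), complete.
#' @param n_components number of components to keep (default: all).
#' @param sign_anchor anchor variable name, or `NULL` for the default rule.
#' @return An object of class `pca_result`: `loadings`, `scores`,
#'   `explained_variance_ratio`, `eigenvalues`, `sign_anchor`.
#' @export
fit_pca <- function(x, n_components = NULL, sign_anchor = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("PCA requires complete data", call. = FALSE)
  if (nrow(x) < ncol(x)) {
    stop("need at least as many subjects as variables", call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  R <- stats::cor(x)
  eig <- eigen(R, symmetric = TRUE)
  evals <- pmax(eig$values, 0)
  rank <- sum(evals > 1e-12 * evals[1])
  if (is.null(n_components)) n_components <- ncol(x)
  if (n_components > rank) {
    stop("n_components (", n_components, ") exceeds rank (", rank, ")",
         call. = FALSE)
  }
  k <- seq_len(n_components)
  vec <- eig$vectors[, k, drop = FALSE]
  loadings <- vec %*% diag(sqrt(evals[k]), n_components)
  dimnames(loadings) <- list(colnames(x), paste0("PC", k))
  if (is.null(sign_anchor)) {
    sign_anchor <- colnames(x)[which.max(rowMeans(abs(loadings)))]
  }
  flip <- sign(loadings[sign_anchor, ])
  flip[flip == 0] <- 1
  loadings <- sweep(loadings, 2, flip, `*`)
  vec <- sweep(vec, 2, flip, `*`)
  scores <- scale(x) %*% vec
  colnames(scores) <- paste0("PC", k)
  structure(list(loadings = loadings, scores = scores,
                 explained_variance_ratio = evals[k] / sum(evals),
                 eigenvalues = evals[k], sign_anchor = sign_anchor),
            class = "pca_result")
}

#' Sign-align one PCA fit to another
#'
#' When the analysis is cross-validated by refitting the PCA on the test
#' arm, component signs are arbitrary; this flips test components whose
#' loading vectors correlate negatively with the training loadings.
#'
#' @param pca a [fit_pca()] result to align (e.g. the test-arm fit).
#' @param reference the reference fit (e.g. the training-arm fit); must
#'   share variable names.
#' @return The aligned `pca_result`.
#' @export
align_pca <- function(pca, reference) {
  stopifnot(inherits(pca, "pca_result"), inherits(reference, "pca_result"))
  common <- intersect(rownames(pca$loadings), rownames(reference$loadings))
  k <- min(ncol(pca$loadings), ncol(reference$loadings))
  for (j in seq_len(k)) {
    if (sum(pca$loadings[common, j] * reference$loadings[common, j]) < 0) {
      pca$loadings[, j] <- -pca$loadings[, j]
      pca$scores[, j] <- -pca$scores[, j]
    }
  }
  pca
}

segment_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  if (sxx == 0 || syy == 0) return(NULL)  # r^2 undefined
  slope <- sxy / sxx
  r2 <- sxy^2 / (sxx * syy)
  list(slope = slope, intercept = my - slope * mx, r2 = r2)
}

#' Detect the aging metabolism breakpoint on component scores
#'
#' Points are ordered by ascending age (ties broken by subject identifier
#' when given). For every admissible partition into a leading and a trailing
#' set — the leading set starting at `min_segment` points and growing one
#' point at a time until the trailing set shrinks to `min_segment` — a
#' straight line is fitted to each set and the product of the two
#' coefficients of determination is recorded. The partition maximizing that
#' product (ties: smaller leading set) defines the two regression lines, and
#' the age at which they intersect is the breakpoint. Partitions in which
#' either set has zero age or score variance cannot be scored and are
#' skipped. Near-parallel fitted lines (slope difference below
#' `parallel_tol`) are flagged as having no intersection, and an
#' intersection falling outside both segments' age spans is flagged as
#' extrapolated rather than clamped.
#'
#' @param ages numeric vector of ages (years).
#' @param scores numeric vector of PC1 scores, same length.
#' @param min_segment minimum points per segment (default `floor(n / 3)`,
#'   generalizing a 35-point initial set at n = 105; must be >= 3).
#' @param subject_id optional identifiers for deterministic tie-breaking.
#' @param parallel_tol slope-difference tolerance below which the lines are
#'   declared parallel.
#' @return An object of class `breakpoint_result`: `split_index`, `line1`,
#'   `line2` (slope score/year + intercept), `r2_first`, `r2_second`,
#'   `r2_product`, `intersection_age`, `no_intersection`, `extrapolated`,
#'   `search_trace` (data.frame over all candidate splits), `n`.
#' @export
detect_breakpoint <- function(ages, scores, min_segment = NULL,
                              subject_id = NULL, parallel_tol = 1e-10) {
  n <- length(ages)
  stopifnot(length(scores) == n)
  if (is.null(min_segment)) min_segment <- floor(n / 3)
  min_segment <- as.integer(min_segment)
  if (min_segment < 3) stop("min_segment must be >= 3", call. = FALSE)
  if (n < 2 * min_segment) {
    stop("need n >= 2 * min_segment points", call. = FALSE)
  }
  ord <- if (is.null(subject_id)) order(ages) else order(ages, subject_id)
  x <- ages[ord]
  y <- scores[ord]

  ks <- seq.int(min_segment, n - min_segment)
  trace <- data.frame(split_index = ks, r2_first = NA_real_,
                      r2_second = NA_real_, r2_product = NA_real_)
  best <- list(product = -Inf, k = NA_integer_, l1 = NULL, l2 = NULL)
  for (i in seq_along(ks)) {
    k <- ks[i]
    l1 <- segment_line(x[1:k], y[1:k])
    l2 <- segment_line(x[(k + 1):n], y[(k + 1):n])
    if (is.null(l1) || is.null(l2)) next
    trace$r2_first[i] <- l1$r2
    trace$r2_second[i] <- l2$r2
    trace$r2_product[i] <- l1$r2 * l2$r2
    if (l1$r2 * l2$r2 > best$product) {
      best <- list(product = l1$r2 * l2$r2, k = k, l1 = l1, l2 = l2)
    }
  }
  if (!is.finite(best$product)) {
    stop("no partition could be scored (degenerate data)", call. = FALSE)
  }
  k <- best$k
  parallel <- abs(best$l1$slope - best$l2$slope) < parallel_tol
  ia <- if (parallel) NA_real_ else {
    (best$l2$intercept - best$l1$intercept) /
      (best$l1$slope - best$l2$slope)
  }
  structure(list(
    split_index = k,
    line1 = c(slope = best$l1$slope, intercept = best$l1$intercept),
    line2 = c(slope = best$l2$slope, intercept = best$l2$intercept),
    r2_first = best$l1$r2,
    r2_second = best$l2$r2,
    r2_product = best$product,
    intersection_age = ia,
    no_intersection = parallel,
    extrapolated = !parallel && (ia < x[1] || ia > x[n]),
    search_trace = trace,
    n = n,
    min_segment = min_segment
  ), class = "breakpoint_result")
}

#' @export
print.breakpoint_result <- function(x, ...) {
  cat("<breakpoint_result> n = ", x$n, ", split at ", x$split_index,
      "/", x$n - x$split_index, " points\n", sep = "")
  cat(sprintf("  r2 product = %.4f (%.4f x %.4f)\n",
              x$r2_product, x$r2_first, x$r2_second))
  if (x$no_intersection) {
    cat("  lines are parallel: no intersection\n")
  } else {
    cat(sprintf("  breakpoint age = %.1f years%s\n", x$intersection_age,
                if (x$extrapolated) " (extrapolated beyond data range)" else ""))
  }
  invisible(x)
}

#' Breakpoint recovery study over synthetic cohorts
#'
#' Validation harness for the breakpoint detector: for each seed, generates
#' a cohort with a planted hinge, runs the score-extraction steps the
#' analysis pipeline uses on the hinge-carrying variables plus BMI
#' (imputation if needed, Box-Cox transformation, standardization, PCA,
#' orientation), detects the breakpoint on PC1 scores versus age, and
#' compares the estimated intersection ages with the planted
#' `config$breakpoint_age`. Estimates are summarized only over *valid*
#' detections — a finite intersection inside the observed age range; the
#' fraction of valid detections is reported alongside, since the
#' two-line intersection can run away to arbitrary ages whenever the two
#' fitted slopes are nearly equal.
#'
#' @param config a [generator_config()] whose panel contains hinged
#'   variables.
#' @param n_seeds number of replicate cohorts.
#' @param noise_scale residual-noise multiplier (see [generate_cohort()]);
#'   0 gives the noiseless limit.
#' @param min_segment passed to [detect_breakpoint()]; default
#'   `floor(n / 3)`.
#' @param use_boxcox transform with the Box-Cox grid search (default) or
#'   plain log for speed.
#' @return list of class `breakpoint_recovery`: `estimates`, `valid`,
#'   `n_valid`, `valid_fraction`, `mean`, `sd`, `bias`, `rmse` (valid
#'   detections only), `breakpoint_age`, `noise_scale`.
#' @export
recover_breakpoint_stats <- function(config, n_seeds = 200, noise_scale = 1,
                                     min_segment = NULL, use_boxcox = TRUE) {
  stopifnot(inherits(config, "generator_config"), n_seeds >= 1)
  panel <- config$variables
  hinged <- panel$name[panel$hinge]
  if (!length(hinged)) {
    stop("config has no hinged variables to recover", call. = FALSE)
  }
  est <- numeric(n_seeds)
  valid <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- config$seed + s - 1L
    cohort <- generate_cohort(cfg, noise_scale = noise_scale,
                              bmi_noise_scale = noise_scale)
    age <- cohort_column(cohort, "age")
    X <- cbind(cohort_matrix(cohort, variables = hinged),
               bmi = cohort_column(cohort, "bmi"))
    ## complete the hinged block if the generator blanked cells in it
    if (anyNA(X)) {
      for (j in seq_len(ncol(X))) {
        nas <- is.na(X[, j])
        if (any(nas)) {
          fit <- stats::lm.fit(cbind(1, age[!nas]), log(X[!nas, j]))
          X[nas, j] <- exp(fit$coefficients[1] + fit$coefficients[2] * age[nas])
        }
      }
    }
    Z <- apply(X, 2, function(v) {
      if (stats::sd(v) == 0) return(rep(0, length(v)))
      if (use_boxcox) boxcox_apply(v, boxcox_fit(v)) else scale(log(v))[, 1]
    })
    sds <- apply(Z, 2, stats::sd)
    if (any(sds == 0)) { est[s] <- NA; next }
    pca <- fit_pca(Z, n_components = 1, sign_anchor = hinged[1])
    bp <- detect_breakpoint(age, pca$scores[, 1], min_segment = min_segment)
    est[s] <- bp$intersection_age
    valid[s] <- !bp$no_intersection && is.finite(bp$intersection_age) &&
      bp$intersection_age >= min(age) && bp$intersection_age <= max(age)
  }
  ev <- est[valid]
  structure(list(
    estimates = est, valid = valid, n_valid = sum(valid),
    valid_fraction = mean(valid),
    mean = mean(ev), sd = stats::sd(ev),
    bias = mean(ev) - config$breakpoint_age,
    rmse = sqrt(mean((ev - config$breakpoint_age)^2)),
    breakpoint_age = config$breakpoint_age,
    noise_scale = noise_scale
  ), class = "breakpoint_recovery")
}
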