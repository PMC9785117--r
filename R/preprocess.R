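#' Multiple imputation specification
#'
#' @param n_imputations number of completed datasets to draw and average.
#'   Averaging into a single analysis table (rather than Rubin's-rules
#'   pooling) matches downstream single-table analyses.
#' @param max_iterations Gibbs sweeps per imputation.
#' @param n_predictors number of best-correlated companion variables used in
#'   each conditional regression.
#' @param tol relative-change convergence tolerance.
#' @param seed integer seed.
#' @return An object of class `imputation_spec`.
#' @export
imputation_spec <- function(n_imputations = 5, max_iterations = 10,
                            n_predictors = 5, tol = 1e-4, seed = 1L) {
  stopifnot(n_imputations >= 1, max_iterations >= 1, n_predictors >= 1)
  structure(list(n_imputations = as.integer(n_imputations),
                 max_iterations = as.integer(max_iterations),
                 n_predictors = as.integer(n_predictors),
                 tol = tol, seed = as.integer(seed)),
            class = "imputation_spec")
}

#' Impute missing concentration values
#'
#' Iterative conditional-normal (Gibbs-style) imputation for nonmonotone
#' missing data, on the log scale (concentrations are positive and
#' right-skewed). Each continuous variable with missing cells is regressed,
#' within a sweep, on age, BMI and its most correlated companion variables;
#' missing cells are replaced by the conditional mean plus a normal draw at
#' the residual scale. `n_imputations` completed datasets are averaged into
#' one analysis table. Age is never imputed; sex is categorical and not
#' imputed; observed cells are never modified. Deterministic given the spec
#' seed.
#'
#' @param table a [cohort_table()].
#' @param spec an [imputation_spec()].
#' @return A completed [cohort_table()]; sweeps that failed to converge are
#'   listed in the `warnings` attribute.
#' @export
impute_cohort <- function(table, spec = imputation_spec()) {
  stopifnot(inherits(table, "cohort_table"), inherits(spec, "imputation_spec"))
  vars <- cohort_variables(table)
  M <- cohort_matrix(table, variables = vars)
  if (!anyNA(M)) return(table)
  for (v in vars) {
    obs <- sum(!is.na(M[, v]))
    if (obs == 0) stop("variable '", v, "' is entirely missing", call. = FALSE)
    if (obs < 2) stop("variable '", v, "' has fewer than 2 observed values",
                      call. = FALSE)
    if (mean(is.na(M[, v])) >= 0.5) {
      stop("variable '", v, "' is >= 50% missing", call. = FALSE)
    }
  }
  L <- log(M)
  miss <- is.na(L)
  miss_vars <- vars[colSums(miss) > 0]
  covar <- cbind(age = cohort_column(table, "age"),
                 bmi = cohort_column(table, "bmi"))

  warnings <- character(0)
  acc <- matrix(0, nrow(L), ncol(L), dimnames = dimnames(L))
  for (m in seq_len(spec$n_imputations)) {
    set.seed(spec$seed + m - 1L)
    cur <- L
    for (v in miss_vars) {
      cur[miss[, v], v] <- mean(cur[, v], na.rm = TRUE)
    }
    ## deterministic conditional-mean sweeps to a fixed point, then one
    ## residual-scale draw per missing cell; the draw order over variables
    ## is fixed, so the imputation is reproducible given the seed
    converged <- FALSE
    sigmas <- stats::setNames(numeric(length(miss_vars)), miss_vars)
    ## predictor sets are chosen once per imputation, from the mean-completed
    ## data, and held fixed so the sweep iteration has a fixed point
    cc <- suppressWarnings(stats::cor(cur))
    top_of <- lapply(stats::setNames(miss_vars, miss_vars), function(v) {
      others <- setdiff(vars, v)
      r <- abs(cc[v, others])
      r[is.na(r)] <- 0
      others[order(r, decreasing = TRUE)][
        seq_len(min(spec$n_predictors, length(others)))]
    })
    for (it in seq_len(spec$max_iterations)) {
      prev <- cur
      for (v in miss_vars) {
        Z <- cbind(1, covar, cur[, top_of[[v]], drop = FALSE])
        obs_v <- !miss[, v]
        fit <- stats::lm.fit(Z[obs_v, , drop = FALSE], cur[obs_v, v])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        sigmas[v] <- sqrt(sum(fit$residuals^2) / max(fit$df.residual, 1))
        cur[miss[, v], v] <- Z[miss[, v], , drop = FALSE] %*% beta
      }
      delta <- max(abs(cur[miss] - prev[miss]) /
                     (abs(prev[miss]) + .Machine$double.eps))
      if (delta < spec$tol) { converged <- TRUE; break }
    }
    if (!converged) {
      warnings <- c(warnings,
                    sprintf("imputation %d: no convergence after %d iterations",
                            m, spec$max_iterations))
    }
    for (v in miss_vars) {
      cur[miss[, v], v] <- cur[miss[, v], v] +
        stats::rnorm(sum(miss[, v]), 0, sigmas[v])
    }
    acc <- acc + cur
  }
  comp <- exp(acc / spec$n_imputations)
  out <- table
  out$data[, vars] <- comp[, vars]
  if (length(warnings)) {
    warning(paste(warnings, collapse = "; "), call. = FALSE)
    attr(out, "warnings") <- warnings
  }
  out
}

boxcox_grid <- function(lambda_range, grid_step) {
  seq(lambda_range[1], lambda_range[2], by = grid_step)
}

## geometric-mean-scaled Box-Cox transform: SDs are comparable across lambda,
## and minimizing the SD is equivalent to maximizing the profile
## log-likelihood of the normal Box-Cox model
boxcox_transform <- function(y, lambda, gm) {
  if (abs(lambda) < .Machine$double.eps) {
    gm * log(y)
  } else {
    (y^lambda - 1) / (lambda * gm^(lambda - 1))
  }
}

## z(lambda) is an affine map of w = (y/GM)^lambda, so its SD can be computed
## from the O(1)-scaled w values: for |lambda| near 10 the direct formula
## offsets tiny relative differences against enormous constants and loses all
## precision to cancellation
boxcox_w <- function(y, lambda, gm) exp(lambda * (log(y) - log(gm)))

boxcox_sd <- function(y, lambda, gm) {
  if (abs(lambda) < .Machine$double.eps) {
    gm * stats::sd(log(y))
  } else {
    (gm / abs(lambda)) * stats::sd(boxcox_w(y, lambda, gm))
  }
}

#' Fit a Box-Cox transformation by grid search
#'
#' Evaluates the geometric-mean-scaled Box-Cox transform
#' `z(lambda) = (y^lambda - 1) / (lambda * GM^(lambda - 1))` (and
#' `GM * log(y)` at `lambda = 0`) over a lambda grid and selects the lambda
#' with the smallest standard deviation of `z`. The GM scaling makes SDs
#' comparable across lambda — for the raw transform the SD shrinks without
#' bound as `|lambda|` grows, so the literal smallest-SD criterion is
#' degenerate; `scaled = FALSE` restores it for comparison. Ties (within
#' numerical tolerance) are broken toward the lambda closest to 1, then the
#' smaller `|lambda|`.
#'
#' @param values strictly positive numeric vector (after `shift`), length >= 3.
#' @param grid_step lambda grid resolution (default 0.1).
#' @param lambda_range search interval, default `c(-10, 10)`.
#' @param shift offset added to the values before transforming (0 unless the
#'   raw data contain non-positive values).
#' @param scaled use the GM-scaled transform (default) or the raw one.
#' @param variable optional variable name recorded in the spec.
#' @return An object of class `boxcox_spec`: `variable`, `lambda`, `shift`,
#'   `gm`, `train_mean`, `train_sd` (post-transform standardization
#'   constants computed from these values, i.e. the fitting arm).
#' @export
boxcox_fit <- function(values, grid_step = 0.1, lambda_range = c(-10, 10),
                       shift = 0, scaled = TRUE, variable = NA_character_) {
  stopifnot(grid_step > 0, length(lambda_range) == 2)
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  y <- values + shift
  if (any(y <= 0)) {
    stop("non-positive values after shift; Box-Cox requires positive data",
         call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    stop("zero-variance input; Box-Cox lambda is undefined", call. = FALSE)
  }
  gm <- exp(mean(log(y)))
  grid <- boxcox_grid(lambda_range, grid_step)
  sds <- vapply(grid, function(l) {
    boxcox_sd(y, l, if (scaled) gm else 1)
  }, numeric(1))
  best <- min(sds)
  cand <- which(sds <= best * (1 + 1e-12))
  cand <- cand[order(abs(grid[cand] - 1), abs(grid[cand]))]
  lambda <- grid[cand[1]]
  ## standardization constants on the w = (y/GM)^lambda scale (the z scale is
  ## an affine map of w, so standardized z is computed exactly from w)
  if (abs(lambda) < .Machine$double.eps) {
    wm <- mean(log(y)); ws <- stats::sd(log(y)); wsign <- 1
  } else {
    w <- boxcox_w(y, lambda, gm)
    wm <- mean(w); ws <- stats::sd(w); wsign <- sign(lambda)
  }
  structure(list(variable = variable, lambda = lambda, shift = shift,
                 gm = gm, w_mean = wm, w_sd = ws, w_sign = wsign,
                 train_mean = if (abs(lambda) < .Machine$double.eps)
                   gm * wm else (gm / lambda) * (wm - gm^-lambda),
                 train_sd = boxcox_sd(y, lambda, gm)),
            class = "boxcox_spec")
}

#' Apply a fitted Box-Cox spec
#'
#' Transforms with the spec's lambda and geometric mean, then standardizes
#' with the spec's (training-arm) mean and SD. Strictly monotone in the
#' input, so rank order is preserved; applied to an independent arm the
#' result generally does not have zero mean or unit SD — that is the
#' train-anchored contract.
#'
#' @param values numeric vector; `values + spec$shift` must be positive.
#' @param spec a [boxcox_spec][boxcox_fit()].
#' @return Transformed, standardized numeric vector (`NA` passes through).
#' @export
boxcox_apply <- function(values, spec) {
  stopifnot(inherits(spec, "boxcox_spec"))
  y <- values + spec$shift
  if (any(y[!is.na(y)] <= 0)) {
    stop("non-positive values after shift", call. = FALSE)
  }
  ## standardized z computed on the numerically safe w scale (see boxcox_sd)
  if (abs(spec$lambda) < .Machine$double.eps) {
    (log(y) - spec$w_mean) / spec$w_sd
  } else {
    spec$w_sign * (boxcox_w(y, spec$lambda, spec$gm) - spec$w_mean) / spec$w_sd
  }
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper recording the W statistic and p-value; used to report
#' distributional shape before and after transformation, not as a gate.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return list with `statistic` and `p_value`.
#' @export
shapiro_check <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")", call. = FALSE)
  }
  ht <- stats::shapiro.test(values)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Impute, transform and standardize a cohort
#'
#' Full preprocessing pass: multiple imputation ([impute_cohort()]), then a
#' per-variable Box-Cox fit **on the training arm only** ([boxcox_fit()]),
#' applied to all subjects with the training-arm lambda, mean and SD
#' ([boxcox_apply()]). BMI is transformed like the concentration variables;
#' age stays in years (it is the regression target and is reported on its
#' natural scale); sex is categorical and excluded. Shapiro-Wilk statistics
#' are recorded pre- and post-transform for the training arm.
#'
#' @param table a split [cohort_table()] (see [split_cohort()]).
#' @param grid_step,lambda_range passed to [boxcox_fit()].
#' @param imputation an [imputation_spec()].
#' @return list of class `preprocessed_cohort`: `table` (transformed cohort),
#'   `specs` (named list of `boxcox_spec`), `normality` (data.frame of
#'   Shapiro-Wilk W/p before and after transform).
#' @export
preprocess_cohort <- function(table, grid_step = 0.1,
                              lambda_range = c(-10, 10),
                              imputation = imputation_spec()) {
  stopifnot(inherits(table, "cohort_table"))
  table <- impute_cohort(table, imputation)
  train <- table$split == "train"
  if (!any(train)) stop("no training-arm subjects", call. = FALSE)
  vars <- c(names(table$roles)[table$roles == "bmi"],
            cohort_variables(table))
  specs <- list()
  norm <- vector("list", length(vars))
  out <- table
  for (i in seq_along(vars)) {
    v <- vars[i]
    x <- table$data[[v]]
    spec <- boxcox_fit(x[train], grid_step = grid_step,
                       lambda_range = lambda_range, variable = v)
    z <- boxcox_apply(x, spec)
    pre <- shapiro_check(x[train])
    post <- shapiro_check(z[train])
    norm[[i]] <- data.frame(variable = v, lambda = spec$lambda,
                            w_raw = pre$statistic, p_raw = pre$p_value,
                            w_transformed = post$statistic,
                            p_transformed = post$p_value)
    specs[[v]] <- spec
    out$data[[v]] <- z
  }
  out$transformed <- TRUE
  structure(list(table = out, specs = specs,
                 normality = do.call(rbind, norm)),
            class = "preprocessed_cohort")
}

#' Persist Box-Cox specs as TSV
#'
#' One row per variable (`variable`, `lambda`, `shift`, `gm`, `train_mean`,
#' `train_sd`) so the exact transform is replayable.
#'
#' @param specs named list of `boxcox_spec` objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_boxcox_specs <- function(specs, path) {
  df <- do.call(rbind, lapply(specs, function(s) {
    data.frame(variable = s$variable, lambda = s$lambda, shift = s$shift,
               gm = s$gm, w_mean = s$w_mean, w_sd = s$w_sd,
               w_sign = s$w_sign, train_mean = s$train_mean,
               train_sd = s$train_sd)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boxcox_specs
#' @export
read_boxcox_specs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(df)), function(i) {
    structure(list(variable = df$variable[i], lambda = df$lambda[i],
                   shift = df$shift[i], gm = df$gm[i],
                   w_mean = df$w_mean[i], w_sd = df$w_sd[i],
                   w_sign = df$w_sign[i],
                   train_mean = df$train_mean[i], train_sd = df$train_sd[i]),
              class = "boxcox_spec")
  })
  stats::setNames(specs, df$variable)
}
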