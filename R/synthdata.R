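#' Default synthetic variable panel
#'
#' Builds the per-variable design table behind [generate_cohort()]. The panel
#' emulates the statistical structure of a two-platform serum metabolomics
#' study of healthy adults: 47 NMR-quantified metabolites, 128 LC-HRMS
#' features and 10 clinical markers. A named subset carries an age signal
#' with BMI-adjusted partial correlations in the 0.21-0.37 magnitude range:
#' branched-chain amino acids (valine, leucine, isoleucine),
#' 3-hydroxyisobutyrate, asparagine and tryptophan decline with age;
#' aspartate and ornithine rise; lipid markers and glucose rise. The BCAA
#' block (plus 3-hydroxyisobutyrate) shares a latent subject factor so that
#' its members are strongly inter-correlated and dominate the first principal
#' component, and its age trend is piecewise linear with a hinge at the
#' configured breakpoint age (slope ratio `pre_slope_ratio` before the hinge
#' relative to a unit slope after it). All remaining variables are pure
#' noise.
#'
#' @param n_nmr,n_lchrms total NMR-like and LC-HRMS-like metabolite counts
#'   (signal variables included).
#' @param pre_slope_ratio latent pre-breakpoint slope as a fraction of the
#'   post-breakpoint slope for hinged variables. A mildly non-zero default is
#'   used: a perfectly flat early segment has zero variance and an undefined
#'   coefficient of determination in short age windows, which the two-segment
#'   breakpoint search cannot score.
#' @param noise_sd residual log-scale standard deviation shared by all
#'   variables (serum concentrations are right-skewed with coefficients of
#'   variation around 25-35%, i.e. log-SD ~ 0.3).
#'
#' @return data.frame with columns `name`, `role`, `platform`,
#'   `target_partial_r`, `hinge`, `family`, `factor_share`, `base_log`,
#'   `noise_sd`.
#' @export
default_variable_panel <- function(n_nmr = 47, n_lchrms = 128,
                                   pre_slope_ratio = 0.3, noise_sd = 0.3) {
  stopifnot(n_nmr >= 8, n_lchrms >= 1)
  signal <- data.frame(
    name = c("valine", "leucine", "isoleucine", "3-hydroxyisobutyrate",
             "asparagine", "aspartate", "ornithine", "tryptophan",
             "total_cholesterol", "hdl", "ldl", "vldl",
             "triacylglyceride", "glucose"),
    role = c(rep("metabolite", 8), rep("clinical", 6)),
    platform = c(rep("nmr", 7), "lchrms", rep("clinical", 6)),
    target_partial_r = c(-0.225, -0.215, -0.280, -0.257,
                         -0.214, 0.237, 0.269, -0.285,
                         0.370, 0.219, 0.243, 0.214, 0.212, 0.213),
    hinge = c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 10)),
    family = c(rep("bcaa", 4), rep("urea", 3), rep(NA, 7)),
    factor_share = c(0.8, 0.8, 0.8, 0.45, 0.5, 0.5, 0.5, rep(0, 7)),
    base_log = c(log(c(0.22, 0.12, 0.06, 0.03, 0.04, 0.02, 0.05, 0.06)),
                 log(c(185, 52, 110, 19, 95, 90))),
    stringsAsFactors = FALSE
  )
  null_clinical <- data.frame(
    name = c("uric_acid", "urea", "creatinine", "hs_crp"),
    role = "clinical", platform = "clinical", target_partial_r = 0,
    hinge = FALSE, family = NA, factor_share = 0,
    base_log = log(c(5.1, 31, 0.9, 0.6)), stringsAsFactors = FALSE
  )
  n_nmr_null <- n_nmr - 7L
  n_lc_null <- n_lchrms - 1L
  nulls <- data.frame(
    name = c(sprintf("nmr_%02d", seq_len(n_nmr_null)),
             sprintf("lc_%03d", seq_len(n_lc_null))),
    role = "metabolite",
    platform = c(rep("nmr", n_nmr_null), rep("lchrms", n_lc_null)),
    target_partial_r = 0, hinge = FALSE, family = NA, factor_share = 0,
    base_log = log(0.05), stringsAsFactors = FALSE
  )
  panel <- rbind(signal, null_clinical, nulls)
  panel$noise_sd <- noise_sd
  attr(panel, "pre_slope_ratio") <- pre_slope_ratio
  panel
}

#' Synthetic cohort generator configuration
#'
#' @param n_subjects cohort size.
#' @param age_range closed age interval in years; ages are sampled uniformly
#'   (only the median and range of the emulated study population are known,
#'   so a uniform draw is an explicit generator choice, not an inference).
#' @param male_fraction proportion of male subjects.
#' @param breakpoint_age hinge age (years) of the piecewise-linear latent
#'   trend carried by hinged variables.
#' @param missing_rate fraction of concentration cells set missing
#'   (missing-completely-at-random; the exact count `floor(rate * cells)` is
#'   removed, so the realized fraction never exceeds the configured rate).
#' @param bmi_model list with `intercept`, `slope` (kg/m^2 per year), `sd`
#'   and `max_bmi`; BMI is drawn from the linear-in-age normal model and
#'   resampled until below `max_bmi` (a non-obese cohort).
#' @param sex_effect additive log-scale shift applied to male subjects'
#'   metabolite levels; zero by default (sex carries no signal, matching a
#'   population in which sex is not associated with the outcome) but exposed
#'   for power studies.
#' @param variables per-variable design table, see [default_variable_panel()].
#' @param seed integer seed; generation is fully deterministic given the
#'   configuration.
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 138,
                             age_range = c(20, 70),
                             male_fraction = 0.56,
                             breakpoint_age = 32,
                             missing_rate = 0.02,
                             bmi_model = list(intercept = 22, slope = 0.04,
                                              sd = 2.5, max_bmi = 30),
                             sex_effect = 0,
                             variables = default_variable_panel(),
                             seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 9) {
    stop("config error in `n_subjects`: need at least 9 subjects ",
         "(three times the minimum breakpoint segment)", call. = FALSE)
  }
  if (length(age_range) != 2 || diff(age_range) <= 0) {
    stop("config error in `age_range`: need a nonempty interval", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 0.1) {
    stop("config error in `missing_rate`: must be in [0, 0.1)", call. = FALSE)
  }
  if (male_fraction < 0 || male_fraction > 1) {
    stop("config error in `male_fraction`: must be a proportion", call. = FALSE)
  }
  if (any(variables$noise_sd <= 0)) {
    stop("config error in `variables$noise_sd`: all noise SDs must be > 0",
         call. = FALSE)
  }
  if (anyDuplicated(variables$name)) {
    stop("config error in `variables$name`: duplicated names", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects), age_range = age_range,
         male_fraction = male_fraction, breakpoint_age = breakpoint_age,
         missing_rate = missing_rate, bmi_model = bmi_model,
         sex_effect = sex_effect, variables = variables,
         pre_slope_ratio = attr(variables, "pre_slope_ratio") %||% 0.3,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## piecewise-linear latent age trend, continuous, zero at the hinge
hinge_shape <- function(age, tau, pre_ratio) {
  pre_ratio * (pmin(age, tau) - tau) + pmax(age - tau, 0)
}

## Solve for the trend scale c such that the population BMI-partialled
## Pearson correlation of  c*h(age) + noise  with age equals `target`.
## Moments of h(age) under uniform age are taken on a fine grid; BMI
## truncation (< max_bmi) is ignored here, which the Monte-Carlo calibration
## tolerance absorbs.
calibrate_trend_scale <- function(target, shape_fun, config, noise_sd) {
  if (target == 0) return(0)
  grid <- seq(config$age_range[1], config$age_range[2], length.out = 4001)
  h <- shape_fun(grid)
  va <- stats::var(grid)
  vh <- stats::var(h)
  cha <- stats::cov(grid, h)
  b1 <- config$bmi_model$slope
  vz <- b1^2 * va + config$bmi_model$sd^2
  r_yz <- b1 * va / sqrt(va * vz)
  partial_r <- function(cc) {
    vx <- cc^2 * vh + noise_sd^2
    r_xy <- cc * cha / sqrt(vx * va)
    r_xz <- cc * b1 * cha / sqrt(vx * vz)
    (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  }
  f <- function(cc) partial_r(cc) - abs(target)
  sign(target) * sign(cha) * stats::uniroot(f, c(0, 1e3 * noise_sd / sqrt(vh)),
                                            tol = 1e-12)$root
}

#' Generate a synthetic cohort
#'
#' Draws ages uniformly over the configured range, BMI from a weakly
#' age-increasing truncated-normal model, and every concentration variable as
#' `exp(base + trend(age) + family factor + noise)`, with the trend scale
#' calibrated analytically so the realized BMI-partialled age correlation
#' matches the panel's `target_partial_r` in expectation. Hinged variables
#' follow a piecewise-linear (log-scale) trend with the hinge at
#' `config$breakpoint_age`. Concentrations are strictly positive by
#' construction (log-normal noise).
#'
#' @param config a [generator_config()].
#' @param noise_scale multiplier applied to the variables' residual noise
#'   (family factor and idiosyncratic) *after* trend calibration. `1`
#'   reproduces the configured signal-to-noise; `0` yields noiseless latent
#'   trends, under which realized partial correlations approach +/-1 for
#'   signal variables. Used by the breakpoint recovery harness to trace
#'   estimator error as a function of noise.
#' @param bmi_noise_scale multiplier for the BMI residual scatter,
#'   controlled separately because at zero BMI becomes an exact function of
#'   age and BMI-partialled correlations degenerate.
#' @return A [cohort_table()].
#' @export
generate_cohort <- function(config, noise_scale = 1, bmi_noise_scale = 1) {
  stopifnot(inherits(config, "generator_config"), noise_scale >= 0,
            bmi_noise_scale >= 0)
  set.seed(config$seed)
  n <- config$n_subjects
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- ifelse(stats::runif(n) < config$male_fraction, "M", "F")
  bm <- config$bmi_model
  bmi_sd <- bmi_noise_scale * bm$sd
  bmi <- bm$intercept + bm$slope * age + stats::rnorm(n, 0, bm$sd) * bmi_noise_scale
  while (any(bad <- bmi >= bm$max_bmi)) {
    bmi[bad] <- bm$intercept + bm$slope * age[bad] +
      stats::rnorm(sum(bad), 0, bm$sd) * bmi_noise_scale
    if (bmi_sd == 0) break
  }

  panel <- config$variables
  fams <- unique(stats::na.omit(panel$family))
  factors <- matrix(stats::rnorm(n * length(fams)), n,
                    dimnames = list(NULL, fams))

  vals <- matrix(NA_real_, n, nrow(panel),
                 dimnames = list(NULL, panel$name))
  tau <- config$breakpoint_age
  pre <- config$pre_slope_ratio
  for (i in seq_len(nrow(panel))) {
    v <- panel[i, ]
    shape <- if (v$hinge) {
      function(a) hinge_shape(a, tau, pre)
    } else {
      function(a) a
    }
    cc <- calibrate_trend_scale(v$target_partial_r, shape, config, v$noise_sd)
    trend <- cc * shape(age)
    fac <- if (!is.na(v$family)) {
      sqrt(v$factor_share) * v$noise_sd * factors[, v$family]
    } else 0
    eps <- sqrt(1 - v$factor_share) * v$noise_sd * stats::rnorm(n)
    lg <- v$base_log + (trend - mean(trend)) + noise_scale * (fac + eps) +
      config$sex_effect * (sex == "M")
    vals[, i] <- exp(lg)
  }

  data <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                     age = age, sex = sex, bmi = bmi,
                     stringsAsFactors = FALSE)
  data <- cbind(data, as.data.frame(vals, check.names = FALSE))

  ## exact-count MCAR missingness over concentration cells only
  if (config$missing_rate > 0) {
    cells <- expand.grid(row = seq_len(n), col = panel$name,
                         stringsAsFactors = FALSE)
    n_miss <- floor(config$missing_rate * nrow(cells))
    ## guard the per-variable < 10% invariant and >= 2 observed precondition
    drop <- sample(nrow(cells), n_miss)
    cap <- floor(0.1 * n) - 1L
    keep <- unlist(lapply(split(drop, cells$col[drop]),
                          function(ix) ix[seq_len(min(length(ix), cap))]))
    for (ix in keep) data[cells$row[ix], cells$col[ix]] <- NA_real_
  }

  roles <- stats::setNames(
    c("age", "sex", "bmi", panel$role),
    c("age", "sex", "bmi", panel$name)
  )
  units <- stats::setNames(
    c("years", "", "kg/m2",
      ifelse(panel$role == "clinical", "mg/dL", "mmol/L")),
    c("age", "sex", "bmi", panel$name)
  )
  cohort_table(data, roles, units = units)
}

#' Randomly split a cohort into train and test arms
#'
#' Assignment is without replacement with `round(train_fraction * n)`
#' subjects in the training arm, deterministic given `seed`.
#'
#' @param table a [cohort_table()].
#' @param train_fraction proportion in (0, 1); the default reproduces a
#'   105/33 split of a 138-subject cohort.
#' @param seed integer seed for the assignment.
#' @return The cohort with its `split` field set.
#' @export
split_cohort <- function(table, train_fraction = 105 / 138, seed = 1L) {
  stopifnot(inherits(table, "cohort_table"),
            train_fraction > 0, train_fraction < 1)
  n <- nrow(table$data)
  n_train <- round(train_fraction * n)
  if (n_train < 3 || n - n_train < 3) {
    stop("train/test split would leave an arm with fewer than 3 subjects",
         call. = FALSE)
  }
  set.seed(seed)
  idx <- sample(n, n_train)
  split <- rep("test", n)
  split[idx] <- "train"
  table$split <- split
  table
}

#' Feature table
#'
#' LC-HRMS-style features-by-injections intensity container. `injection_class`
#' tags each injection as `sample`, `blank` or `qc`; `injection_order` is the
#' acquisition rank (a permutation of `1:n_injections`).
#'
#' @param intensities numeric matrix, features in rows (rownames = feature
#'   ids), injections in columns; `NA` marks missing intensities.
#' @param injection_class character vector per injection.
#' @param injection_order integer acquisition rank per injection.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensities, injection_class, injection_order) {
  stopifnot(is.matrix(intensities),
            ncol(intensities) == length(injection_class),
            ncol(intensities) == length(injection_order))
  if (!all(sort(injection_order) == seq_along(injection_order))) {
    stop("`injection_order` must be a permutation of 1..n_injections",
         call. = FALSE)
  }
  if (!any(injection_class == "sample")) {
    stop("at least one sample injection is required", call. = FALSE)
  }
  if (any(intensities[!is.na(intensities)] < 0)) {
    stop("observed intensities must be non-negative", call. = FALSE)
  }
  structure(list(intensities = intensities,
                 injection_class = injection_class,
                 injection_order = as.integer(injection_order)),
            class = "feature_table")
}

#' Generate a synthetic LC-HRMS feature table
#'
#' Emulates a batch with blank injections, pooled-serum QC injections in
#' triplicate (so the QC injection count is `3 * n_qc_triplicates`) and a
#' smooth multiplicative intensity drift over injection order. A configurable
#' number of features violates each inclusion filter, with the violating sets
#' kept disjoint, so the filter ground truth is known by construction and
#' recorded in the `truth_retained` attribute.
#'
#' @param n_features number of features.
#' @param n_samples number of experimental sample injections.
#' @param n_blanks number of blank injections.
#' @param n_qc_triplicates number of QC triplicate groups (each contributes
#'   three injections spread through the batch).
#' @param drift_amplitude relative amplitude of the sinusoidal sensitivity
#'   drift (0 = drift-free batch).
#' @param qc_cv relative intensity noise of QC (and sample) injections; 0
#'   makes all QC injections of a feature identical in a drift-free batch.
#' @param blank_fraction blank signal as a fraction of sample signal for
#'   clean features.
#' @param n_fail_blank,n_fail_cv,n_fail_missing number of features
#'   constructed to fail the blank-ratio, QC-CV and missingness filters.
#' @param seed integer seed.
#' @return A [feature_table()] with attribute `truth_retained` (character
#'   vector of features that pass all filters by construction).
#' @export
generate_feature_table <- function(n_features = 12, n_samples = 60,
                                   n_blanks = 3, n_qc_triplicates = 4,
                                   drift_amplitude = 0.15, qc_cv = 0.05,
                                   blank_fraction = 0.01,
                                   n_fail_blank = 0, n_fail_cv = 0,
                                   n_fail_missing = 0, seed = 1L) {
  stopifnot(n_features >= 1, n_samples >= 1, n_blanks >= 1,
            n_qc_triplicates >= 1,
            n_fail_cv == 0 || n_qc_triplicates >= 2,
            n_fail_blank + n_fail_cv + n_fail_missing <= n_features)
  set.seed(seed)
  n_qc <- 3L * n_qc_triplicates
  n_inj <- n_samples + n_blanks + n_qc

  ## acquisition layout: blanks first, then QC injections spread through the
  ## run of experimental samples
  class <- rep("sample", n_inj)
  class[seq_len(n_blanks)] <- "blank"
  qc_pos <- round(seq(n_blanks + 1, n_inj, length.out = n_qc))
  qc_pos <- unique(pmin(pmax(qc_pos, n_blanks + 1), n_inj))
  while (length(qc_pos) < n_qc) {
    qc_pos <- unique(c(qc_pos, setdiff(seq(n_blanks + 1, n_inj), qc_pos)[1]))
  }
  class[qc_pos] <- "qc"
  stopifnot(sum(class == "qc") == n_qc, sum(class == "blank") == n_blanks)
  order <- seq_len(n_inj)

  base <- exp(stats::rnorm(n_features, log(1e5), 0.5))
  ## smooth monotone sensitivity drift over the acquisition run
  drift <- 1 + drift_amplitude * sin(pi * order / (2 * n_inj))

  fail_blank <- seq_len(n_fail_blank)
  fail_cv <- seq_len(n_fail_cv) + n_fail_blank
  fail_missing <- seq_len(n_fail_missing) + n_fail_blank + n_fail_cv

  X <- matrix(NA_real_, n_features, n_inj,
              dimnames = list(sprintf("F%03d", seq_len(n_features)), NULL))
  qc_idx <- which(class == "qc")
  qc_grp <- ceiling(seq_along(qc_idx) / 3)
  for (i in seq_len(n_features)) {
    bf_i <- if (i %in% fail_blank) 0.25 else blank_fraction
    noise <- function(m) m * (1 + qc_cv * stats::rnorm(length(m)))
    sig <- base[i] * drift
    x <- numeric(n_inj)
    x[class == "sample"] <- noise(sig[class == "sample"])
    x[class == "qc"] <- noise(sig[class == "qc"])
    x[class == "blank"] <- bf_i * abs(noise(sig[class == "blank"]))
    if (i %in% fail_cv) {
      ## alternate QC triplicate levels: the CV across triplicate means is
      ## ~37% regardless of the random draw, violating the 20% rule surely
      x[qc_idx] <- x[qc_idx] * c(1, 2.2)[1 + qc_grp %% 2]
    }
    x <- pmax(x, 1)
    if (i %in% fail_missing) {
      smp <- which(class == "sample")
      x[sample(smp, ceiling(0.2 * length(smp)))] <- NA_real_
    }
    X[i, ] <- x
  }

  ft <- feature_table(X, class, order)
  attr(ft, "truth_retained") <-
    rownames(X)[setdiff(seq_len(n_features),
                        c(fail_blank, fail_cv, fail_missing))]
  ft
}

#' Write / read a feature table as tab-separated text
#'
#' Intensities go to `path` (features in rows, injections in columns);
#' injection class and order go to a sidecar `<path>.injections.tsv`.
#'
#' @param table a [feature_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  m <- as.data.frame(table$intensities)
  names(m) <- sprintf("inj_%03d", seq_len(ncol(table$intensities)))
  out <- cbind(feature_id = rownames(table$intensities), m)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(injection = names(m),
                     class = table$injection_class,
                     order = table$injection_order)
  utils::write.table(meta, paste0(path, ".injections.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  m <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.delim(paste0(path, ".injections.tsv"),
                            stringsAsFactors = FALSE)
  ids <- m$feature_id
  m$feature_id <- NULL
  x <- as.matrix(m)
  rownames(x) <- ids
  feature_table(x, meta$class, meta$order)
}
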