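#' Feature inclusion filters for LC-HRMS feature tables
#'
#' Applies the three standard inclusion rules to every feature and reports
#' each intermediate quantity:
#'
#' * **blank rule** — under the default `"contaminant"` reading a feature is
#'   kept when its mean blank intensity is below `blank_threshold` times its
#'   mean sample intensity; the `"presence"` reading instead keeps features
#'   whose sample signal exceeds the blank signal by more than
#'   `blank_threshold` (i.e. mean sample > (1 + threshold) * mean blank).
#'   Both readings of the 5%-from-blank convention circulate in practice, so
#'   both are provided.
#' * **CV rule** — QC injections are acquired in triplicate; each triplicate
#'   is averaged first and the percent coefficient of variation across
#'   triplicate means must stay below `cv_threshold`.
#' * **missingness rule** — the fraction of missing cells among experimental
#'   sample injections must stay below `missing_threshold`.
#'
#' Missing intensities are excluded from means and CVs, never zero-filled.
#' The filters are order-independent and idempotent.
#'
#' @param table a [feature_table()].
#' @param blank_threshold proportion in (0, 1); default 0.05.
#' @param cv_threshold percent in (0, 100); default 20.
#' @param missing_threshold proportion in (0, 1); default 0.10.
#' @param blank_rule `"contaminant"` (default) or `"presence"`, see above.
#' @return A data.frame of class `qc_filter_report` with one row per feature:
#'   `feature_id`, `blank_ratio`, `qc_cv`, `missing_fraction`,
#'   `passed_blank`, `passed_cv`, `passed_missing`, `retained`.
#' @export
filter_features <- function(table, blank_threshold = 0.05,
                            cv_threshold = 20, missing_threshold = 0.10,
                            blank_rule = c("contaminant", "presence")) {
  stopifnot(inherits(table, "feature_table"),
            blank_threshold > 0, blank_threshold < 1,
            cv_threshold > 0, cv_threshold < 100,
            missing_threshold > 0, missing_threshold < 1)
  blank_rule <- match.arg(blank_rule)
  cls <- table$injection_class
  if (!any(cls == "blank")) {
    stop("blank rule requested but the table has no blank injections",
         call. = FALSE)
  }
  if (!any(cls == "qc")) {
    stop("CV rule requested but the table has no QC injections",
         call. = FALSE)
  }
  X <- table$intensities
  smp <- cls == "sample"
  blk <- cls == "blank"
  qc <- cls == "qc"
  ## triplicate grouping follows acquisition order within the QC class
  qc_ord <- order(table$injection_order[qc])
  qc_group <- ceiling(seq_along(qc_ord) / 3)

  res <- data.frame(feature_id = rownames(X), stringsAsFactors = FALSE)
  res$blank_ratio <- apply(X, 1, function(x) {
    mean(x[blk], na.rm = TRUE) / mean(x[smp], na.rm = TRUE)
  })
  res$qc_cv <- apply(X[, qc, drop = FALSE], 1, function(x) {
    m <- tapply(x[qc_ord], qc_group, mean, na.rm = TRUE)
    100 * stats::sd(m) / mean(m)
  })
  res$missing_fraction <- rowMeans(is.na(X[, smp, drop = FALSE]))

  res$passed_blank <- if (blank_rule == "contaminant") {
    res$blank_ratio < blank_threshold
  } else {
    1 / res$blank_ratio > 1 + blank_threshold
  }
  res$passed_cv <- res$qc_cv < cv_threshold
  res$passed_missing <- res$missing_fraction < missing_threshold
  res$retained <- res$passed_blank & res$passed_cv & res$passed_missing
  attr(res, "thresholds") <- c(blank = blank_threshold, cv = cv_threshold,
                               missing = missing_threshold)
  attr(res, "blank_rule") <- blank_rule
  class(res) <- c("qc_filter_report", "data.frame")
  res
}

#' QC-anchored LOESS drift normalization
#'
#' Fits, per feature, a degree-1 LOESS curve of QC intensity against
#' injection order, evaluates it at every injection (constant extrapolation
#' beyond the first/last QC injection) and divides each intensity by
#' `curve / median(QC)`. Instrument drift is removed while the QC intensity
#' level is anchored at its median; missing cells are untouched. Features for
#' which the fitted curve is non-positive anywhere are left unnormalized and
#' listed in the `flagged` attribute with a warning.
#'
#' @param table a [feature_table()].
#' @param span LOESS span (the upstream software this emulates does not
#'   document its parameters; 0.75 is the conventional default).
#' @return A [feature_table()] with normalized intensities.
#' @export
loess_normalize <- function(table, span = 0.75) {
  stopifnot(inherits(table, "feature_table"), span > 0)
  qc <- table$injection_class == "qc"
  if (sum(qc) < 4) {
    stop("LOESS normalization needs at least 4 QC injections", call. = FALSE)
  }
  X <- table$intensities
  ord <- table$injection_order
  qc_ord <- ord[qc]
  flagged <- character(0)
  for (i in seq_len(nrow(X))) {
    y <- X[i, qc]
    ok <- !is.na(y)
    if (sum(ok) < 4) {
      flagged <- c(flagged, rownames(X)[i])
      next
    }
    fit <- stats::loess(y[ok] ~ qc_ord[ok], span = span, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    curve <- stats::predict(fit,
                            newdata = pmin(pmax(ord, min(qc_ord[ok])),
                                           max(qc_ord[ok])))
    if (any(!is.finite(curve)) || any(curve <= 0)) {
      flagged <- c(flagged, rownames(X)[i])
      next
    }
    X[i, ] <- X[i, ] / (curve / stats::median(y[ok]))
  }
  if (length(flagged)) {
    warning("features left unnormalized (non-positive fitted curve or too ",
            "few QC values): ", paste(flagged, collapse = ", "),
            call. = FALSE)
  }
  out <- feature_table(X, table$injection_class, table$injection_order)
  attr(out, "flagged") <- flagged
  out
}
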