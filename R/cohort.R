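#' Cohort table
#'
#' Container for a subjects-by-variables analysis table. Each row is one
#' subject; columns are the subject identifier, age (years), sex, BMI
#' (kg/m^2) and a set of continuous clinical-marker and metabolite
#' concentration variables (positive scale). A per-variable role tag and a
#' per-subject train/test split label travel with the data. Missing cells are
#' `NA`; the observed/missing mask is implied by the data.
#'
#' @param data data.frame with columns `subject_id`, `age`, `sex`, `bmi` and
#'   one column per clinical/metabolite variable.
#' @param roles named character vector mapping every non-`subject_id` column
#'   to one of `"age"`, `"sex"`, `"bmi"`, `"clinical"`, `"metabolite"`.
#' @param split character vector of `"train"`/`"test"` labels, one per
#'   subject, or `NULL` for an unsplit cohort (all subjects labelled
#'   `"train"` until [split_cohort()] is applied).
#' @param units optional named character vector of per-variable units,
#'   carried through to the sidecar metadata written by [write_cohort()].
#' @param transformed set to `TRUE` for a table holding transformed
#'   standardized values rather than raw concentrations; the positivity
#'   invariant applies only to raw tables.
#'
#' @return An object of class `cohort_table`: a list with elements `data`,
#'   `roles`, `split` and `units`.
#' @seealso [generate_cohort()], [split_cohort()], [write_cohort()]
#' @export
cohort_table <- function(data, roles, split = NULL, units = NULL,
                         transformed = FALSE) {
  stopifnot(is.data.frame(data))
  if (!"subject_id" %in% names(data)) {
    stop("`data` must contain a `subject_id` column", call. = FALSE)
  }
  vars <- setdiff(names(data), "subject_id")
  if (!all(vars %in% names(roles))) {
    stop("every variable column needs a role tag; missing: ",
         paste(setdiff(vars, names(roles)), collapse = ", "), call. = FALSE)
  }
  roles <- roles[vars]
  bad <- setdiff(unique(roles), c("age", "sex", "bmi", "clinical", "metabolite"))
  if (length(bad)) {
    stop("unknown roles: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (r in c("age", "sex", "bmi")) {
    if (sum(roles == r) != 1L) {
      stop("exactly one variable must be tagged '", r, "'", call. = FALSE)
    }
  }
  if (is.null(split)) split <- rep("train", nrow(data))
  if (length(split) != nrow(data) || !all(split %in% c("train", "test"))) {
    stop("`split` must be one 'train'/'test' label per subject", call. = FALSE)
  }
  conc <- names(roles)[roles %in% c("clinical", "metabolite")]
  for (v in conc) {
    x <- data[[v]]
    if (!is.numeric(x)) stop("variable '", v, "' is not numeric", call. = FALSE)
    if (!transformed && any(x[!is.na(x)] <= 0)) {
      stop("variable '", v, "' has non-positive observed concentrations",
           call. = FALSE)
    }
    if (mean(is.na(x)) >= 0.1) {
      stop("variable '", v, "' has >= 10% missing values", call. = FALSE)
    }
  }
  structure(
    list(data = data, roles = roles, split = split, units = units,
         transformed = transformed),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  n <- nrow(x$data)
  cat("<cohort_table> ", n, " subjects, ",
      sum(x$roles == "clinical"), " clinical markers, ",
      sum(x$roles == "metabolite"), " metabolites\n", sep = "")
  cat("  split: ", sum(x$split == "train"), " train / ",
      sum(x$split == "test"), " test\n", sep = "")
  miss <- cohort_matrix(x)
  cat("  missing cells: ", sum(is.na(miss)), " of ", length(miss),
      sprintf(" (%.2f%%)\n", 100 * mean(is.na(miss))), sep = "")
  invisible(x)
}

#' Names of cohort variables by role
#'
#' @param table a [cohort_table()].
#' @param roles roles to select (default: the continuous analysis variables).
#' @return Character vector of variable names.
#' @export
cohort_variables <- function(table, roles = c("clinical", "metabolite")) {
  names(table$roles)[table$roles %in% roles]
}

#' Extract a numeric matrix of cohort variables
#'
#' @inheritParams cohort_variables
#' @param variables explicit variable names (overrides `roles`).
#' @return Numeric matrix, subjects in rows (rownames = subject ids).
#' @export
cohort_matrix <- function(table, roles = c("clinical", "metabolite"),
                          variables = NULL) {
  if (is.null(variables)) variables <- cohort_variables(table, roles)
  m <- as.matrix(table$data[, variables, drop = FALSE])
  rownames(m) <- table$data$subject_id
  m
}

cohort_column <- function(table, role) {
  table$data[[names(table$roles)[table$roles == role][1L]]]
}

#' Write / read a cohort table as tab-separated text
#'
#' The table itself goes to `path`; per-variable role tags (and units, when
#' known) go to a sidecar `<path>.meta.tsv` with columns
#' `variable`, `role`, `units`. The split label is stored as a `.split`
#' column in the main file.
#'
#' @param table a [cohort_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  out <- table$data
  out$.split <- table$split
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  vars <- names(table$roles)
  units <- if (is.null(table$units)) rep("", length(vars)) else {
    u <- table$units[vars]
    u[is.na(u)] <- ""
    u
  }
  meta <- data.frame(variable = vars, role = unname(table$roles),
                     units = unname(units),
                     transformed = isTRUE(table$transformed))
  utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  data <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  meta <- utils::read.delim(paste0(path, ".meta.tsv"), check.names = FALSE,
                            stringsAsFactors = FALSE)
  split <- data$.split
  data$.split <- NULL
  roles <- stats::setNames(meta$role, meta$variable)
  units <- stats::setNames(as.character(meta$units), meta$variable)
  cohort_table(data, roles, split = split, units = units,
               transformed = isTRUE(meta$transformed[1]))
}
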