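#' Pipeline run configuration
#'
#' Bundles every stage parameter of the end-to-end analysis with its
#' conventional default: FDR level 0.2 with a nominal alpha of 0.05 for the
#' dual screening rule, 5% blank / 20% CV / 10% missingness feature filters,
#' Box-Cox lambda searched over \[-10, 10\], a ~75% training split
#' (105 of 138), stepwise entry at p < 0.05 and a one-third minimum
#' breakpoint segment. The master `seed` drives every stochastic stage
#' (per-stage seeds are derived from it), so a run is fully reproducible.
#'
#' @param generator a [generator_config()] for synthetic input, or `NULL`
#'   when `cohort_path` points at an existing cohort TSV.
#' @param cohort_path optional path to a cohort written by [write_cohort()].
#' @param train_fraction training-arm proportion.
#' @param q,alpha dual-rule parameters for [screen_cohort()].
#' @param grid_step Box-Cox grid resolution.
#' @param p_enter stepwise entry threshold.
#' @param enrich_alpha p-value threshold declaring a pathway enriched when
#'   choosing the modeling candidate set.
#' @param min_segment breakpoint minimum segment (`NULL` = `floor(n / 3)`).
#' @param gmt_path pathway library path (`NULL` = bundled synthetic library).
#' @param seed master integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            cohort_path = NULL,
                            train_fraction = 105 / 138,
                            q = 0.2, alpha = 0.05, grid_step = 0.1,
                            p_enter = 0.05, enrich_alpha = 0.05,
                            min_segment = NULL, gmt_path = NULL,
                            seed = 1L) {
  if (is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  structure(list(generator = generator, cohort_path = cohort_path,
                 train_fraction = train_fraction, q = q, alpha = alpha,
                 grid_step = grid_step, p_enter = p_enter,
                 enrich_alpha = enrich_alpha, min_segment = min_segment,
                 gmt_path = gmt_path, seed = as.integer(seed)),
            class = "pipeline_config")
}

require_stage_file <- function(path, stage, producer) {
  if (!file.exists(path)) {
    stop("stage '", stage, "': missing input ", basename(path),
         " (produced by stage '", producer, "')", call. = FALSE)
  }
  path
}

pipeline_candidates <- function(assoc, enr, enrich_alpha) {
  sig <- assoc$variable[assoc$significant & assoc$role == "metabolite"]
  enriched <- unlist(strsplit(
    enr$hit_members[enr$p_hyper < enrich_alpha], ";", fixed = TRUE))
  cand <- intersect(sig, enriched)
  if (!length(cand)) cand <- sig
  cand
}

#' Run the full aging metabolomics analysis pipeline
#'
#' Executes the enabled stages in order, each stage reading its input from
#' the files the previous stage persisted in `output_dir` and writing its
#' own outputs there, so any stage can be re-run or audited in isolation:
#'
#' 1. `generate` — synthesize (or copy) the cohort and assign the
#'    train/test split (`cohort.tsv`).
#' 2. `preprocess` — impute, Box-Cox transform and standardize with
#'    train-anchored specs (`preprocessed.tsv`, `boxcox_specs.tsv`,
#'    `normality.tsv`).
#' 3. `screen` — covariate selection and BMI-adjusted partial correlation
#'    screening under the dual BH + alpha rule on the training arm
#'    (`associations.tsv`, `cor_matrix.tsv`).
#' 4. `enrich` — over-representation analysis of the significant set
#'    (`enrichment.tsv`).
#' 5. `model` — forward stepwise regression of age on the metabolites
#'    retained by both screening and enrichment, BMI forced in, with
#'    test-arm cross-validation (`model.json`).
#' 6. `breakpoint` — PCA of the retained metabolites plus BMI and
#'    two-segment breakpoint detection on training-arm PC1 scores
#'    (`breakpoint.json`, `pca_loadings.tsv`, `pc1_scores.tsv`).
#'
#' A machine-readable `summary.json` and a parameter-echo `run_log.txt` are
#' written last; identical configuration and seed give byte-identical
#' summaries.
#'
#' @param config a [pipeline_config()].
#' @param output_dir directory for stage outputs (created if absent).
#' @param stages character vector of stages to run, in pipeline order.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, output_dir,
                         stages = c("generate", "preprocess", "screen",
                                    "enrich", "model", "breakpoint")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  log_lines <- c("metaboaging pipeline run",
                 paste0("package version: ",
                        as.character(utils::packageVersion("metaboaging"))),
                 paste0("seed: ", config$seed),
                 paste0("stages: ", paste(stages, collapse = ", ")),
                 paste0("q = ", config$q, ", alpha = ", config$alpha,
                        ", p_enter = ", config$p_enter,
                        ", grid_step = ", config$grid_step,
                        ", enrich_alpha = ", config$enrich_alpha),
                 paste0("train_fraction = ",
                        format(config$train_fraction, digits = 6)))

  if ("generate" %in% stages) {
    cohort <- if (!is.null(config$cohort_path)) {
      read_cohort(config$cohort_path)
    } else {
      gen <- config$generator
      gen$seed <- config$seed
      generate_cohort(gen)
    }
    cohort <- split_cohort(cohort, config$train_fraction,
                           seed = config$seed + 1L)
    write_cohort(cohort, p("cohort.tsv"))
    log_lines <- c(log_lines,
                   paste0("generate: n = ", nrow(cohort$data), " (",
                          sum(cohort$split == "train"), " train / ",
                          sum(cohort$split == "test"), " test)"))
  }

  if ("preprocess" %in% stages) {
    cohort <- read_cohort(require_stage_file(p("cohort.tsv"), "preprocess",
                                             "generate"))
    prep <- preprocess_cohort(cohort, grid_step = config$grid_step,
                              imputation = imputation_spec(
                                seed = config$seed + 2L))
    write_cohort(prep$table, p("preprocessed.tsv"))
    write_boxcox_specs(prep$specs, p("boxcox_specs.tsv"))
    utils::write.table(prep$normality, p("normality.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_lines <- c(log_lines, "preprocess: train-anchored Box-Cox applied")
  }

  if ("screen" %in% stages) {
    tab <- read_cohort(require_stage_file(p("preprocessed.tsv"), "screen",
                                          "preprocess"))
    covs <- select_covariates(tab, alpha = config$alpha)
    if (!length(covs)) covs <- character(0)
    scr <- screen_cohort(tab, covariates = covs, q = config$q,
                         alpha = config$alpha, arm = "train")
    rec <- scr$records
    rec$role <- unname(tab$roles[rec$variable])
    utils::write.table(rec, p("associations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(variable = rownames(scr$cor_matrix),
                 scr$cor_matrix, check.names = FALSE),
      p("cor_matrix.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    log_lines <- c(log_lines,
                   paste0("screen: covariates = [",
                          paste(covs, collapse = ", "), "], ",
                          sum(rec$significant), " significant"))
  }

  if ("enrich" %in% stages) {
    assoc <- utils::read.delim(require_stage_file(p("associations.tsv"),
                                                  "enrich", "screen"),
                               stringsAsFactors = FALSE)
    lib <- if (is.null(config$gmt_path)) aging_pathway_library() else {
      read_gmt(config$gmt_path)
    }
    query <- assoc$variable[assoc$significant]
    enr <- ora_test(query, lib)
    utils::write.table(enr, p("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_lines <- c(log_lines,
                   paste0("enrich: query of ", length(query), " (",
                          attr(enr, "dropped"), " unmapped), top pathway: ",
                          enr$pathway[1]))
  }

  if ("model" %in% stages || "breakpoint" %in% stages) {
    tab <- read_cohort(require_stage_file(p("preprocessed.tsv"),
                                          "model/breakpoint", "preprocess"))
    assoc <- utils::read.delim(require_stage_file(p("associations.tsv"),
                                                  "model/breakpoint",
                                                  "screen"),
                               stringsAsFactors = FALSE)
    enr <- utils::read.delim(require_stage_file(p("enrichment.tsv"),
                                                "model/breakpoint", "enrich"),
                             stringsAsFactors = FALSE)
    cand <- pipeline_candidates(assoc, enr, config$enrich_alpha)
    train <- tab$split == "train"
    test <- tab$split == "test"
    age <- cohort_column(tab, "age")
    bmi_col <- names(tab$roles)[tab$roles == "bmi"]
  }

  if ("model" %in% stages) {
    if (!length(cand)) stop("stage 'model': no candidate metabolites",
                            call. = FALSE)
    Xtr <- cohort_matrix(tab, variables = cand)[train, , drop = FALSE]
    Ftr <- cohort_matrix(tab, variables = bmi_col)[train, , drop = FALSE]
    model <- forward_stepwise(Xtr, age[train], forced = Ftr,
                              p_enter = config$p_enter)
    r_test <- if (any(test) && length(c(model$forced, model$selected))) {
      evaluate_on_test(model, tab$data[test, , drop = FALSE], age[test])
    } else NA_real_
    model_out <- list(
      candidates = cand, forced = model$forced, selected = model$selected,
      coefficients = as.list(model$coefficients),
      intercept = model$intercept,
      entry_p = as.list(model$entry_p),
      r_multiple_train = model$r_multiple,
      r2_adjusted = model$r2_adjusted,
      vif = as.list(model$vif),
      r_multiple_test = r_test
    )
    jsonlite::write_json(model_out, p("model.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    log_lines <- c(log_lines,
                   paste0("model: selected [",
                          paste(model$selected, collapse = ", "),
                          "], r_train = ", format(model$r_multiple, digits = 4),
                          ", r_test = ", format(r_test, digits = 4)))
  }

  if ("breakpoint" %in% stages) {
    vars <- c(cand, bmi_col)
    Xtr <- cohort_matrix(tab, variables = vars)[train, , drop = FALSE]
    pca_tr <- fit_pca(Xtr, n_components = min(ncol(Xtr), 2))
    pca_te <- if (sum(test) > ncol(Xtr)) {
      align_pca(fit_pca(cohort_matrix(tab, variables = vars)[test, ,
                                                             drop = FALSE],
                        n_components = min(ncol(Xtr), 2)), pca_tr)
    } else NULL
    bp <- detect_breakpoint(age[train], pca_tr$scores[, 1],
                            min_segment = config$min_segment,
                            subject_id = tab$data$subject_id[train])
    load_df <- data.frame(variable = rownames(pca_tr$loadings),
                          loading_pc1_train = pca_tr$loadings[, 1])
    if (!is.null(pca_te)) {
      load_df$loading_pc1_test <- pca_te$loadings[rownames(pca_tr$loadings), 1]
    }
    utils::write.table(load_df, p("pca_loadings.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(subject_id = tab$data$subject_id[train],
                 age = age[train], pc1 = pca_tr$scores[, 1]),
      p("pc1_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    bp_out <- list(
      variables = vars,
      split_index = bp$split_index,
      line1 = as.list(bp$line1), line2 = as.list(bp$line2),
      r2_first = bp$r2_first, r2_second = bp$r2_second,
      r2_product = bp$r2_product,
      intersection_age = bp$intersection_age,
      no_intersection = bp$no_intersection,
      extrapolated = bp$extrapolated,
      pc1_explained_train = pca_tr$explained_variance_ratio[1],
      search_trace = bp$search_trace
    )
    jsonlite::write_json(bp_out, p("breakpoint.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    log_lines <- c(log_lines,
                   paste0("breakpoint: age = ",
                          format(bp$intersection_age, digits = 4),
                          " (split ", bp$split_index, ")"))
  }

  ## consolidated summary from whatever stage outputs exist
  summary <- list(seed = config$seed,
                  parameters = list(q = config$q, alpha = config$alpha,
                                    p_enter = config$p_enter,
                                    enrich_alpha = config$enrich_alpha,
                                    grid_step = config$grid_step,
                                    train_fraction = config$train_fraction))
  if (file.exists(p("associations.tsv"))) {
    assoc <- utils::read.delim(p("associations.tsv"),
                               stringsAsFactors = FALSE)
    sig <- assoc[assoc$significant, c("variable", "partial_r", "p_raw")]
    summary$significant <- sig
  }
  if (file.exists(p("enrichment.tsv"))) {
    enr <- utils::read.delim(p("enrichment.tsv"), stringsAsFactors = FALSE)
    summary$enriched_pathways <-
      enr[enr$p_hyper < config$enrich_alpha,
          c("pathway", "hits", "expected", "enrichment_ratio", "p_hyper")]
  }
  if (file.exists(p("model.json"))) {
    summary$model <- jsonlite::read_json(p("model.json"), simplifyVector = TRUE)
    summary$model$entry_p <- NULL
  }
  if (file.exists(p("breakpoint.json"))) {
    bpj <- jsonlite::read_json(p("breakpoint.json"), simplifyVector = TRUE)
    summary$breakpoint <- bpj[c("intersection_age", "split_index",
                                "r2_product", "no_intersection",
                                "extrapolated", "pc1_explained_train")]
  }
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  writeLines(log_lines, p("run_log.txt"))
  invisible(summary)
}
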