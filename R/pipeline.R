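## End-to-end batch analysis: manifest of paired scans -> per-subject
## densitometry -> cohort residual fit -> stratified correlation tables ->
## standardized joint regression models -> Markdown report. Subjects whose
## scans are missing or unreadable are dropped and counted, never silently
## skipped.

#' Pipeline run configuration
#'
#' @param manifest path to the subject manifest CSV (see
#'   \code{\link{read_manifest}}).
#' @param out_dir output directory for all artifacts.
#' @param clinical optional CSV of clinical outcomes keyed by
#'   \code{subject_id}; when present, correlation tables and joint models
#'   are produced.
#' @param emph_threshold,trap_threshold HU cutoffs for the emphysema and
#'   gas-trapping density masks; the emphysema cutoff must be the lower one.
#' @param stratify compute subgroup tables (severe / no emphysema)?
#' @param model_outcomes outcome columns for the joint regression models.
#' @param gas_measures gas-trapping measures entered (one at a time) in the
#'   joint models and correlation tables.
#' @param seed integer seed echoed into the results for provenance (the
#'   pipeline itself is deterministic).
#' @param verbose print progress messages?
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(manifest, out_dir,
                       clinical = NULL,
                       emph_threshold = -950,
                       trap_threshold = -856,
                       stratify = TRUE,
                       model_outcomes = c("fev1_l"),
                       gas_measures = c("exp_856", "ei_mla", "rvc_856_950"),
                       seed = 1L,
                       verbose = TRUE) {
  if (emph_threshold >= trap_threshold)
    stop("invalid thresholds: emphysema cutoff must be below the gas-trapping cutoff",
         call. = FALSE)
  structure(list(manifest = manifest, out_dir = out_dir, clinical = clinical,
                 emph_threshold = emph_threshold,
                 trap_threshold = trap_threshold,
                 stratify = isTRUE(stratify),
                 model_outcomes = model_outcomes,
                 gas_measures = gas_measures,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

pipeline_log <- function(state, fmt, ...) {
  line <- sprintf(fmt, ...)
  state$lines <- c(state$lines, line)
  if (state$verbose) message(line)
  state
}

#' Run the full paired-CT analysis pipeline
#'
#' Reads every manifest row, computes the per-subject densitometry panel,
#' fits the cohort residual measure, optionally joins a clinical table and
#' produces stratified correlation tables and joint regression models, and
#' writes all artifacts (metrics CSV, residual-fit JSON, correlation and
#' model CSVs, Markdown report, run log, echoed config) under
#' \code{config$out_dir}.
#'
#' @param config a \code{\link{run_config}}.
#' @return Invisibly, a list with \code{n_analyzed}, \code{n_excluded},
#'   \code{metrics} (data frame) and \code{paths} of written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list(lines = character(), verbose = config$verbose)

  man <- read_manifest(config$manifest)
  state <- pipeline_log(state, "manifest: %d subjects", nrow(man))

  rows <- vector("list", nrow(man))
  failures <- character()
  for (i in seq_len(nrow(man))) {
    r <- man[i, ]
    res <- tryCatch({
      pair <- read_scan_pair(r$insp_volume, r$insp_mask, r$exp_volume,
                             r$exp_mask, r$smoking_status, r$subject_id)
      m <- compute_scan_pair_metrics(pair, config$emph_threshold,
                                     config$trap_threshold)
      cbind(data.frame(subject_id = r$subject_id,
                       smoking_status = r$smoking_status,
                       stringsAsFactors = FALSE),
            as.data.frame(m))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    sprintf("%s: %s", r$subject_id, conditionMessage(res)))
    } else {
      rows[[i]] <- res
    }
  }
  metrics <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  n_excluded <- length(failures)
  if (is.null(metrics) || nrow(metrics) == 0L)
    stop("stage metrics: no subject could be analyzed", call. = FALSE)
  state <- pipeline_log(state, "metrics: %d analyzed, %d excluded",
                        nrow(metrics), n_excluded)
  for (f in failures) state <- pipeline_log(state, "excluded %s", f)

  paths <- list()

  # cohort residual measure
  if (nrow(metrics) >= 3 && stats::sd(metrics$insp_950) > 0) {
    fit <- fit_gas_trapping_residuals(metrics$exp_856, metrics$insp_950)
    metrics$residual <- fit$residuals
    paths$residual_fit <- file.path(config$out_dir, "residual_fit.json")
    jsonlite::write_json(list(intercept = fit$intercept, slope = fit$slope,
                              n = fit$n, n_excluded = fit$n_excluded),
                         paths$residual_fit, auto_unbox = TRUE, digits = NA)
    state <- pipeline_log(state,
                          "residual fit: slope %.4f, intercept %.4f (n = %d)",
                          fit$slope, fit$intercept, fit$n)
  } else {
    metrics$residual <- NA_real_
    state <- pipeline_log(state, "residual fit skipped: too few subjects or constant emphysema index")
  }

  paths$metrics <- file.path(config$out_dir, "metrics.csv")
  write_metrics_csv(metrics, paths$metrics)

  # join clinical table and run the cohort statistics
  analysis <- NULL
  if (!is.null(config$clinical)) {
    clin <- utils::read.csv(config$clinical, stringsAsFactors = FALSE)
    if (!"subject_id" %in% names(clin))
      stop("stage clinical: clinical table lacks subject_id", call. = FALSE)
    joined <- merge(metrics, clin, by = "subject_id",
                    suffixes = c("", ".clinical"))
    state <- pipeline_log(state, "clinical join: %d subjects with outcomes",
                          nrow(joined))
    analysis <- analyze_cohort(joined, config$out_dir,
                               model_outcomes = config$model_outcomes,
                               gas_measures = config$gas_measures,
                               stratify = config$stratify)
    paths <- c(paths, analysis$paths)
  }

  paths$report <- file.path(config$out_dir, "report.md")
  write_report(paths$report, metrics, n_excluded, analysis)
  paths$config <- file.path(config$out_dir, "run_config.json")
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                       null = "null", digits = NA)
  paths$log <- file.path(config$out_dir, "run.log")
  writeLines(state$lines, paths$log)

  invisible(list(n_analyzed = nrow(metrics), n_excluded = n_excluded,
                 metrics = metrics, paths = paths))
}

#' Cohort-level statistical analysis of a subject table
#'
#' Refits the residual gas-trapping measure, stratifies by emphysema
#' severity, computes the measure-by-outcome Pearson correlation tables per
#' stratum, and fits the standardized joint emphysema + gas-trapping models
#' for each configured outcome and gas measure. Artifacts are written under
#' \code{out_dir} when it is non-NULL.
#'
#' @param cohort data frame with the CT measure columns
#'   (\code{insp_950}, \code{exp_856}, \code{ei_mla}, \code{rvc_856_950},
#'   \code{smoking_status}) and any outcome columns.
#' @param out_dir output directory or NULL for in-memory results only.
#' @param model_outcomes outcome columns to model jointly.
#' @param gas_measures gas-trapping measures to cycle through.
#' @param outcome_cols outcome columns for the correlation tables; defaults
#'   to the clinical columns present in the table.
#' @param stratify compute severe- and no-emphysema subgroup tables?
#' @return List with \code{cohort} (residual column added),
#'   \code{correlations} (per-stratum long tables), \code{models} (data
#'   frame of joint-model fits), \code{paths}.
#' @export
analyze_cohort <- function(cohort, out_dir = NULL,
                           model_outcomes = c("fev1_l"),
                           gas_measures = c("exp_856", "ei_mla", "rvc_856_950"),
                           outcome_cols = NULL,
                           stratify = TRUE) {
  fit <- fit_gas_trapping_residuals(cohort$exp_856, cohort$insp_950)
  cohort$residual <- fit$residuals

  if (is.null(outcome_cols)) {
    candidates <- c("fev1_l", "fev1_pct_pred", "fvc_pct_pred", "fev1_fvc",
                    "fef2575", "frc_tlc", "sixmwd_ft", "sgrq_total", "mmrc",
                    "exacerbation_freq")
    outcome_cols <- intersect(candidates, names(cohort))
  }
  measures <- c(gas_measures, "residual")

  strata <- if (stratify) stratify_cohort(cohort)
            else list(all = cohort)
  correlations <- list()
  for (s in names(strata)) {
    d <- strata[[s]]
    if (nrow(d) >= 3 && length(outcome_cols))
      correlations[[s]] <- correlation_matrix(d, measures, outcome_cols)
  }

  model_rows <- list()
  for (oc in intersect(model_outcomes, names(cohort))) {
    for (gm in gas_measures) {
      res <- tryCatch(joint_outcome_model(cohort, oc, gm),
                      error = function(e) e)
      if (!inherits(res, "error"))
        model_rows[[paste(oc, gm)]] <-
          data.frame(outcome = oc, gas_measure = gm,
                     beta_emphysema = res$beta_emphysema,
                     p_emphysema = res$p_emphysema,
                     beta_gastrap = res$beta_gastrap,
                     p_gastrap = res$p_gastrap,
                     r_squared = res$r_squared, n = res$n,
                     stringsAsFactors = FALSE)
    }
  }
  models <- if (length(model_rows)) do.call(rbind, model_rows) else NULL
  if (!is.null(models)) rownames(models) <- NULL

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in names(correlations)) {
      p <- file.path(out_dir, sprintf("correlations_%s.csv", s))
      utils::write.csv(correlations[[s]], p, row.names = FALSE)
      paths[[paste0("correlations_", s)]] <- p
    }
    if (!is.null(models)) {
      paths$models <- file.path(out_dir, "models.csv")
      utils::write.csv(models, paths$models, row.names = FALSE)
    }
  }
  list(cohort = cohort, residual_fit = fit, correlations = correlations,
       models = models, paths = paths)
}

md_table <- function(df, digits = 3) {
  fmt <- function(x) if (is.numeric(x)) formatC(x, digits = digits, format = "g")
                     else as.character(x)
  body <- apply(as.data.frame(lapply(df, fmt), stringsAsFactors = FALSE),
                1, paste, collapse = " | ")
  c(paste("|", paste(names(df), collapse = " | "), "|"),
    paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
    paste("|", body, "|"))
}

write_report <- function(path, metrics, n_excluded, analysis) {
  lines <- c("# Paired inspiratory-expiratory CT analysis report", "",
             sprintf("Subjects analyzed: %d; excluded (missing/unreadable scans): %d.",
                     nrow(metrics), n_excluded), "",
             "## Per-subject metric summary", "")
  num_cols <- c("insp_950", "exp_856", "ei_mla", "rvc_856_950", "tlc_l",
                "frc_l", "frc_tlc")
  summ <- data.frame(
    metric = num_cols,
    mean = vapply(num_cols, function(c) mean(metrics[[c]], na.rm = TRUE), 0),
    sd = vapply(num_cols, function(c) stats::sd(metrics[[c]], na.rm = TRUE), 0))
  lines <- c(lines, md_table(summ), "",
             "Emphysema class counts: ",
             paste(sprintf("%s = %d", names(table(metrics$emphysema_class)),
                           as.integer(table(metrics$emphysema_class))),
                   collapse = ", "), "")
  if (!is.null(analysis)) {
    for (s in names(analysis$correlations)) {
      lines <- c(lines, sprintf("## Correlations (%s, n = %d)", s,
                                if (s == "all") nrow(analysis$cohort)
                                else max(analysis$correlations[[s]]$n, na.rm = TRUE)),
                 "", md_table(analysis$correlations[[s]]), "")
    }
    if (!is.null(analysis$models))
      lines <- c(lines, "## Joint emphysema + gas-trapping models", "",
                 md_table(analysis$models), "")
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(lines, path)
  invisible(path)
}
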