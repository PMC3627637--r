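## Cohort-level statistics: correlations of the gas-trapping measures with
## clinical outcomes, standardized joint emphysema + gas-trapping regression
## models, emphysema subgroup stratification, GOLD spirometric staging, and
## duplicate-scan reproducibility.

drop_incomplete_pairs <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  list(x = x[keep], y = y[keep], n = sum(keep))
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation on pairwise-complete observations, with the
#' usual two-sided p-value from the t transform.
#'
#' @param x,y numeric vectors of equal length.
#' @return List with \code{r}, \code{p}, \code{n}.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have the same length", call. = FALSE)
  d <- drop_incomplete_pairs(x, y)
  if (d$n < 3)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(d$x) == 0 || stats::sd(d$y) == 0)
    stop("zero variance: correlation undefined for a constant input", call. = FALSE)
  ct <- stats::cor.test(d$x, d$y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = d$n)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks). Used for
#' duplicate-scan reproducibility, where only rank agreement across subjects
#' is meaningful.
#'
#' @param x,y numeric vectors of equal length.
#' @return List with \code{rho}, \code{p}, \code{n}. The p-value comes from
#'   the t approximation on the rank correlation.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have the same length", call. = FALSE)
  d <- drop_incomplete_pairs(x, y)
  if (d$n < 3)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(d$x) == 0 || stats::sd(d$y) == 0)
    stop("zero variance: correlation undefined for a constant input", call. = FALSE)
  rho <- stats::cor(rank(d$x), rank(d$y), method = "pearson")
  tt <- rho * sqrt((d$n - 2) / (1 - rho^2))
  p <- if (is.finite(tt)) 2 * stats::pt(-abs(tt), df = d$n - 2) else 0
  list(rho = rho, p = p, n = d$n)
}

#' Standardize a vector to mean 0, SD 1
#'
#' Centers and scales by the sample (n - 1) standard deviation. Used on the
#' CT predictors before joint regression so that coefficients read as
#' outcome change per one standard deviation of the predictor.
#'
#' @param x numeric vector, length >= 2, non-constant. \code{NA}s are
#'   ignored for the mean/SD and propagated in the output.
#' @return Numeric vector of the same length.
#' @export
standardize <- function(x) {
  if (sum(is.finite(x)) < 2)
    stop("need at least 2 finite values to standardize", call. = FALSE)
  s <- stats::sd(x, na.rm = TRUE)
  if (s == 0)
    stop("zero variance: cannot standardize a constant vector", call. = FALSE)
  (x - mean(x, na.rm = TRUE)) / s
}

#' Joint emphysema + gas-trapping regression model
#'
#' Fits the outcome on the standardized emphysema index (Insp-950), one
#' standardized gas-trapping measure, and optional covariates, by ordinary
#' least squares with listwise deletion. The two CT coefficients are
#' reported per one standard deviation of the raw predictor, together with
#' their two-sided p-values and the model R-squared, so competing
#' gas-trapping measures can be compared on a common scale.
#'
#' @param cohort data frame of subject records (one row per subject).
#' @param outcome name of the outcome column.
#' @param gas_measure name of the gas-trapping column (e.g. \code{"exp_856"},
#'   \code{"ei_mla"}, \code{"rvc_856_950"}).
#' @param covariates character vector of additional predictor columns
#'   (numeric covariates are standardized too); default none.
#' @param emphysema_measure name of the emphysema column, default
#'   \code{"insp_950"}.
#' @return Object of class \code{joint_model_result}: list with
#'   \code{outcome_name}, \code{gas_measure_name}, \code{beta_emphysema},
#'   \code{beta_gastrap}, \code{p_emphysema}, \code{p_gastrap},
#'   \code{r_squared}, \code{n}, and the underlying \code{fit}.
#' @export
joint_outcome_model <- function(cohort, outcome, gas_measure,
                                covariates = character(),
                                emphysema_measure = "insp_950") {
  cols <- c(outcome, emphysema_measure, gas_measure, covariates)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("columns not found in cohort: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d <- cohort[cols]
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  if (nrow(d) <= length(cols) + 2)
    stop("too few complete records for the model", call. = FALSE)
  z <- data.frame(.y = d[[outcome]],
                  .z_emph = standardize(d[[emphysema_measure]]),
                  .z_gas = standardize(d[[gas_measure]]))
  for (cv in covariates) {
    v <- d[[cv]]
    z[[cv]] <- if (is.numeric(v) && stats::sd(v) > 0) standardize(v) else v
  }
  rhs <- c(".z_emph", ".z_gas", covariates)
  fit <- stats::lm(stats::reformulate(rhs, response = ".y"), data = z)
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased))
    stop("collinear predictors: ", paste(aliased, collapse = ", "), call. = FALSE)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(outcome_name = outcome,
                 gas_measure_name = gas_measure,
                 beta_emphysema = co[".z_emph", "Estimate"],
                 beta_gastrap = co[".z_gas", "Estimate"],
                 se_emphysema = co[".z_emph", "Std. Error"],
                 se_gastrap = co[".z_gas", "Std. Error"],
                 p_emphysema = co[".z_emph", "Pr(>|t|)"],
                 p_gastrap = co[".z_gas", "Pr(>|t|)"],
                 r_squared = sm$r.squared,
                 n = nrow(d),
                 fit = fit),
            class = "joint_model_result")
}

#' @export
print.joint_model_result <- function(x, ...) {
  cat(sprintf("<joint_model_result> %s ~ z(%s) + z(%s)  (n = %d)\n",
              x$outcome_name, "insp_950", x$gas_measure_name, x$n))
  cat(sprintf("  beta emphysema %.4g (p = %.3g), beta gas trapping %.4g (p = %.3g), R^2 = %.3f\n",
              x$beta_emphysema, x$p_emphysema, x$beta_gastrap, x$p_gastrap,
              x$r_squared))
  invisible(x)
}

#' Stratify a cohort by emphysema severity
#'
#' Splits subject records into all subjects, the severe-emphysema subgroup,
#' and the no-emphysema subgroup, using the smoking-status-specific
#' cut-points of \code{\link{classify_emphysema_severity}}. The severe,
#' intermediate and absent classes partition the cohort.
#'
#' @param cohort data frame with columns \code{insp_950} and
#'   \code{smoking_status} (an existing \code{emphysema_class} column is
#'   recomputed, never trusted).
#' @return Named list of data frames: \code{all}, \code{severe_emphysema},
#'   \code{no_emphysema}, \code{intermediate}.
#' @export
stratify_cohort <- function(cohort) {
  stopifnot(all(c("insp_950", "smoking_status") %in% names(cohort)))
  cls <- classify_emphysema_severity(cohort$insp_950, cohort$smoking_status)
  cohort$emphysema_class <- as.character(cls)
  list(all = cohort,
       severe_emphysema = cohort[cls == "severe", , drop = FALSE],
       no_emphysema = cohort[cls == "absent", , drop = FALSE],
       intermediate = cohort[cls == "intermediate", , drop = FALSE])
}

#' GOLD spirometric stage
#'
#' Stages airflow obstruction from post-bronchodilator spirometry. With
#' FEV1/FVC below 0.70, FEV1 percent predicted sets the stage: GOLD1
#' (>= 80), GOLD2 (50-79), GOLD3 (30-49), GOLD4 (< 30). With a preserved
#' ratio, normal FEV1 (>= 80 percent predicted) is GOLD0 and reduced FEV1
#' with a normal ratio is unclassified. Vectorised.
#'
#' @param fev1_fvc FEV1/FVC ratio, in [0, 1.2].
#' @param fev1_pct_pred FEV1 percent of predicted, in [0, 250].
#' @return Factor with levels GOLD0-GOLD4 and \code{unclassified}.
#' @examples
#' gold_stage(c(0.65, 0.75, 0.75), c(55, 70, 90))
#' @export
gold_stage <- function(fev1_fvc, fev1_pct_pred) {
  if (any(!is.finite(fev1_fvc)) || any(fev1_fvc < 0 | fev1_fvc > 1.2))
    stop("fev1_fvc must lie in [0, 1.2]", call. = FALSE)
  if (any(!is.finite(fev1_pct_pred)) || any(fev1_pct_pred < 0 | fev1_pct_pred > 250))
    stop("fev1_pct_pred must lie in [0, 250]", call. = FALSE)
  n <- max(length(fev1_fvc), length(fev1_pct_pred))
  r <- rep_len(fev1_fvc, n)
  p <- rep_len(fev1_pct_pred, n)
  stage <- ifelse(r < 0.7,
                  ifelse(p >= 80, "GOLD1",
                         ifelse(p >= 50, "GOLD2",
                                ifelse(p >= 30, "GOLD3", "GOLD4"))),
                  ifelse(p >= 80, "GOLD0", "unclassified"))
  factor(stage, levels = c("GOLD0", "GOLD1", "GOLD2", "GOLD3", "GOLD4",
                           "unclassified"))
}

#' Duplicate-scan reproducibility
#'
#' Spearman correlation across subjects, between two scan visits, for each
#' gas-trapping measure — the appropriate test-retest summary when only the
#' ordering of subjects needs to agree between time points.
#'
#' @param metrics_t1,metrics_t2 data frames with one row per subject (same
#'   order) and the metric columns; visits must be matched by row.
#' @param measures columns to compare; default the three gas-trapping
#'   measures.
#' @return Data frame with columns \code{measure}, \code{rho}, \code{p},
#'   \code{n}.
#' @export
duplicate_reproducibility <- function(metrics_t1, metrics_t2,
                                      measures = c("exp_856", "ei_mla",
                                                   "rvc_856_950")) {
  if (nrow(metrics_t1) != nrow(metrics_t2))
    stop("visit tables must have one row per subject in the same order",
         call. = FALSE)
  if (nrow(metrics_t1) < 3)
    stop("insufficient duplicates: need at least 3 subject pairs", call. = FALSE)
  stopifnot(all(measures %in% names(metrics_t1)),
            all(measures %in% names(metrics_t2)))
  rows <- lapply(measures, function(m) {
    s <- spearman_correlation(metrics_t1[[m]], metrics_t2[[m]])
    data.frame(measure = m, rho = s$rho, p = s$p, n = s$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlation matrix between CT measures and outcomes
#'
#' Pearson r (with p and n) for every measure-by-outcome cell, computed on
#' pairwise-complete records. Cells that cannot be computed (constant
#' column, too few pairs) are returned as \code{NA} with the reason
#' recorded, rather than failing the whole table.
#'
#' @param cohort data frame of subject records.
#' @param measures character vector of measure column names (rows).
#' @param outcomes character vector of outcome column names (columns).
#' @return Data frame in long form: \code{measure}, \code{outcome},
#'   \code{r}, \code{p}, \code{n}, \code{note}.
#' @export
correlation_matrix <- function(cohort, measures, outcomes) {
  stopifnot(all(c(measures, outcomes) %in% names(cohort)))
  grid <- expand.grid(measure = measures, outcome = outcomes,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    m <- grid$measure[i]; o <- grid$outcome[i]
    cell <- tryCatch(pearson_correlation(cohort[[m]], cohort[[o]]),
                     error = function(e) e)
    if (inherits(cell, "error")) {
      data.frame(measure = m, outcome = o, r = NA_real_, p = NA_real_,
                 n = NA_integer_, note = conditionMessage(cell),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(measure = m, outcome = o, r = cell$r, p = cell$p,
                 n = cell$n, note = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
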