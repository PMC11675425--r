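#' Run one multi-PGS PLS analysis end to end
#'
#' Orchestrates a full analysis of one subject set: optional subgroup
#' filtering by diagnosis, predictor preparation (the diagnosis covariate is
#' included only for the whole-sample run and is always excluded from the
#' VIP ranking), 7-fold cross-validated component selection, the final
#' NIPALS fit, VIP ranking with the VIP > threshold rule, per-category
#' contribution summaries, and ROC/AUC of the first latent variable (both
#' in-sample and from out-of-fold latent scores). Subgroup runs re-autoscale
#' within the subgroup.
#'
#' @param panel A [score_panel].
#' @param phenotypes A [phenotype_table] aligned with the panel.
#' @param subgroup `"all"`, `"MDD"` or `"BD"`. The diagnosis covariate is
#'   forced on for `"all"` and off for subgroup runs.
#' @param n_folds Cross-validation folds (default 7).
#' @param max_A Largest candidate component count (default 5).
#' @param vip_threshold VIP selection cutoff (default 1).
#' @param seed Integer seed for the fold draw.
#' @param out_dir Optional directory; when given, all report artifacts are
#'   written there (`vip_ranking.tsv`, `category_summary.tsv`,
#'   `roc_points.tsv`, `metrics.json`, `model.json`, `cv.json`,
#'   `run_report.json`, and `cohort_table.tsv` when demographics exist).
#' @return A list of class `run_report`: `subgroup`, `n`, `n_cases`,
#'   `selected_A`, `model` (`pls_model`), `cv` (`pls_cv`), `r2x`, `r2y`,
#'   `coefficient` (first-component y-loading on the autoscaled scale, with
#'   the alternative original-scale slope in `coefficient_raw_scale`),
#'   `vip` (ranked `vip_table`), `n_selected`, `top20`,
#'   `category_summary`, `roc_in_sample`, `roc_cv`, `auc_in_sample`,
#'   `auc_cv`, `cohort`, `config`.
#' @export
run_analysis <- function(panel, phenotypes, subgroup = c("all", "MDD", "BD"),
                         n_folds = 7L, max_A = 5L, vip_threshold = 1.0,
                         seed = 1L, out_dir = NULL) {
  subgroup <- match.arg(subgroup)
  stopifnot(inherits(panel, "score_panel"))
  if (subgroup != "all") {
    keep <- as.character(phenotypes$diagnosis) == subgroup
    if (!any(keep)) stop("subgroup '", subgroup, "' is empty", call. = FALSE)
    panel <- score_panel(panel$matrix[keep, , drop = FALSE],
                         sample_ids = panel$sample_ids[keep],
                         score_ids = panel$score_ids,
                         phenotype = panel$phenotype, category = panel$category)
    phenotypes <- phenotypes[keep, , drop = FALSE]
    class(phenotypes) <- c("phenotype_table", "data.frame")
  }
  include_cov <- subgroup == "all"
  prep <- pls_prepare(panel, phenotypes, include_diagnosis_covariate = include_cov)

  cv <- cross_validate(prep$X, prep$y01, max_A = max_A, n_folds = n_folds,
                       stratified = TRUE, seed = seed)
  A <- cv$selected_A
  model <- fit_pls(prep, A = A)

  vip <- rank_and_select(compute_vip(model), threshold = vip_threshold)
  catsum <- summarize_categories(vip)

  roc_in <- roc_first_latent(model, y01 = prep$y01)
  roc_cv <- roc_curve(cv$cv_scores, prep$y01)

  # the per-model scalar summary: first-component y-loading (autoscaled), plus
  # the slope of the raw 0/1 outcome on t1 as the original-units alternative
  coef_autoscaled <- model$q[1L]
  coef_raw <- coef_autoscaled * model$y_scale

  demo_vars <- setdiff(names(phenotypes), c("sample_id", "ppd", "diagnosis"))
  cohort <- if (length(demo_vars)) cohort_table(phenotypes, demo_vars) else NULL

  report <- structure(list(
    subgroup = subgroup, n = nrow(prep$X), n_cases = sum(prep$y01),
    selected_A = A, no_predictive_component = cv$no_predictive_component,
    model = model, cv = cv,
    r2x = model$r2x, r2y = model$r2y,
    coefficient = coef_autoscaled, coefficient_raw_scale = coef_raw,
    vip = vip, n_selected = sum(vip$selected),
    top20 = utils::head(vip, 20L),
    category_summary = catsum,
    roc_in_sample = roc_in, roc_cv = roc_cv,
    auc_in_sample = roc_in$auc, auc_cv = roc_cv$auc,
    cohort = cohort, dropped_columns = prep$dropped,
    config = list(subgroup = subgroup, n_folds = n_folds, max_A = max_A,
                  vip_threshold = vip_threshold, seed = seed,
                  include_diagnosis_covariate = include_cov)),
    class = "run_report")

  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> subgroup = %s, n = %d (%d cases)\n", x$subgroup, x$n, x$n_cases))
  cat(sprintf("selected A = %d; R2X = %s; R2Y = %s; coefficient = %.4f\n",
              x$selected_A, paste(sprintf("%.4f", x$r2x), collapse = "/"),
              paste(sprintf("%.4f", x$r2y), collapse = "/"), x$coefficient))
  cat(sprintf("%d of %d scores selected (VIP > %g); AUC in-sample = %.3f, CV = %.3f\n",
              x$n_selected, nrow(x$vip), x$config$vip_threshold,
              x$auc_in_sample, x$auc_cv))
  invisible(x)
}

#' Write all artifacts of a run report to a directory
#'
#' @param report A `run_report` from [run_analysis()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the directory path.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$vip, file.path(out_dir, "vip_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$category_summary, file.path(out_dir, "category_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_roc_tsv(report$roc_in_sample, file.path(out_dir, "roc_points.tsv"))
  write_model_json(report$model, file.path(out_dir, "model.json"))
  write_cv_json(report$cv, file.path(out_dir, "cv.json"))
  if (!is.null(report$cohort))
    utils::write.table(report$cohort, file.path(out_dir, "cohort_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(subgroup = report$subgroup, n = report$n, n_cases = report$n_cases,
         selected_A = as.integer(report$selected_A),
         no_predictive_component = isTRUE(report$no_predictive_component),
         r2x = report$r2x, r2y = report$r2y,
         coefficient = report$coefficient,
         coefficient_raw_scale = report$coefficient_raw_scale,
         n_selected = as.integer(report$n_selected),
         auc_in_sample = report$auc_in_sample, auc_cv = report$auc_cv,
         q2 = unname(report$cv$q2),
         dropped_columns = report$dropped_columns,
         config = report$config,
         package_version = as.character(utils::packageVersion("mpgspls"))),
    file.path(out_dir, "run_report.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(auc_in_sample = report$auc_in_sample, auc_cv = report$auc_cv,
         r2y_cumulative = sum(report$r2y), selected_A = as.integer(report$selected_A)),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
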