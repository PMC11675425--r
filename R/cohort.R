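#' Pooled-variance two-sample t test from summary statistics
#'
#' Student's t with a pooled variance, computable directly from group means,
#' standard deviations and sizes — the form that reproduces demographic-table
#' statistics published as mean +/- SD. Also returns Cohen's d on the pooled
#' SD scale.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @param variable Optional variable name carried into the result.
#' @return A list of class `comparison_result`: `variable`, `test` ("t"),
#'   `statistic`, `effect_size` (Cohen's d), `effect_type`, `df`, `p_value`.
#' @export
t_test_from_summary <- function(m1, s1, n1, m2, s2, n2, variable = NA_character_) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance: t statistic undefined", call. = FALSE)
  sp <- sqrt(sp2)
  tval <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  structure(list(variable = variable, test = "t", statistic = tval,
                 effect_size = (m1 - m2) / sp, effect_type = "cohens_d",
                 df = df, p_value = 2 * stats::pt(-abs(tval), df)),
            class = "comparison_result")
}

#' Pearson chi-square test of a contingency table with Cramer's V
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction) — the form
#' under which published 2x2 demographic comparisons reproduce exactly from
#' their printed cell counts. Cramer's V is `sqrt(chi2 / (n * (min(r,c)-1)))`.
#'
#' @param counts A 2x2 (or 2xk) matrix of non-negative counts with positive
#'   margins.
#' @param variable Optional variable name carried into the result.
#' @return A `comparison_result` with `test = "chi2"` and Cramer's V as the
#'   effect size.
#' @export
chi2_test <- function(counts, variable = NA_character_) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin: chi-square undefined", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  n <- sum(counts)
  v <- sqrt(as.numeric(ht$statistic) / (n * (min(dim(counts)) - 1)))
  structure(list(variable = variable, test = "chi2",
                 statistic = as.numeric(ht$statistic),
                 effect_size = v, effect_type = "cramers_v",
                 df = as.numeric(ht$parameter), p_value = ht$p.value),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s = %.3f, %s = %.3f, df = %g, p = %.4g\n",
              x$variable, x$test, x$statistic, x$effect_type, x$effect_size,
              x$df, x$p_value))
  invisible(x)
}

#' Case/control comparison battery over raw phenotype columns
#'
#' For each requested variable, dispatches on type: numeric columns get the
#' pooled-variance t test (computed through the summary-statistic path from
#' the groups' exact means/SDs, so raw and summary routes agree to machine
#' precision), and categorical columns get the uncorrected Pearson
#' chi-square on the outcome x level crosstab. Constant variables are
#' flagged and excluded.
#'
#' @param phenotypes A [phenotype_table] (or data frame) containing `ppd`
#'   and the requested columns.
#' @param variables Character vector of column names to compare.
#' @return A data frame with one row per testable variable: `variable`,
#'   `test`, `statistic`, `effect_size`, `effect_type`, `df`, `p_value`;
#'   excluded constants are listed in attribute `excluded`.
#' @export
cohort_table <- function(phenotypes, variables) {
  df <- as.data.frame(phenotypes)
  if (!"ppd" %in% names(df)) stop("phenotype table lacks the outcome column 'ppd'", call. = FALSE)
  missing <- setdiff(variables, names(df))
  if (length(missing))
    stop("variables absent from phenotype table: ", paste(missing, collapse = ", "), call. = FALSE)
  g1 <- df$ppd == 1
  rows <- list(); excluded <- character(0)
  for (v in variables) {
    x <- df[[v]]
    if (is.numeric(x)) {
      if (stats::sd(x) == 0) { excluded <- c(excluded, v); next }
      res <- t_test_from_summary(mean(x[g1]), stats::sd(x[g1]), sum(g1),
                                 mean(x[!g1]), stats::sd(x[!g1]), sum(!g1),
                                 variable = v)
    } else {
      tab <- table(factor(df$ppd, levels = c(1, 0)), x)
      if (ncol(tab) < 2L) { excluded <- c(excluded, v); next }
      res <- chi2_test(unclass(tab), variable = v)
    }
    rows[[v]] <- as.data.frame(unclass(res), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(0), test = character(0), statistic = numeric(0),
               effect_size = numeric(0), effect_type = character(0),
               df = numeric(0), p_value = numeric(0))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Published cohort demographic summary shipped with the package
#'
#' Loads the demographic comparison table of the 178-subject peripartum-
#' depression cohort (62 cases with PPD history, 116 controls without) as
#' published summary statistics: group means +/- SD for continuous variables
#' and 2x2 cell counts for categorical ones, together with the published
#' test statistic for each row and a `consistent` flag marking the rows
#' whose statistic reproduces from the printed summaries (some published
#' rows are internally inconsistent — apparent cell swaps or
#' subgroup-specific denominators — and are flagged `FALSE`).
#'
#' @return A data frame, one row per demographic variable.
#' @export
cohort_reference <- function() {
  path <- system.file("extdata", "cohort_reference.tsv", package = "mpgspls")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Recompute the cohort comparison battery from published summaries
#'
#' Applies [t_test_from_summary()] / [chi2_test()] to every row of
#' [cohort_reference()] (or a table of the same layout), returning the
#' recomputed statistic next to the published one.
#'
#' @param reference A data frame in the [cohort_reference()] layout;
#'   defaults to the shipped table.
#' @return A data frame: `variable`, `test`, `statistic` (recomputed),
#'   `effect_size`, `p_value`, `published_stat`, `consistent`.
#' @export
recompute_cohort_stats <- function(reference = cohort_reference()) {
  rows <- lapply(seq_len(nrow(reference)), function(i) {
    r <- reference[i, ]
    res <- if (r$test == "t") {
      t_test_from_summary(r$g1_mean, r$g1_sd, r$g1_n, r$g2_mean, r$g2_sd, r$g2_n,
                          variable = r$variable)
    } else {
      chi2_test(matrix(c(r$a, r$b, r$c, r$d), 2, byrow = TRUE), variable = r$variable)
    }
    data.frame(variable = r$variable, test = r$test,
               statistic = res$statistic, effect_size = res$effect_size,
               p_value = res$p_value, published_stat = r$published_stat,
               consistent = r$consistent, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
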