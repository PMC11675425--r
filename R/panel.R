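#' Score panel: a samples x scores PRS matrix with per-score metadata
#'
#' A `score_panel` bundles the numeric predictor block (one row per subject,
#' one column per polygenic risk score) with the per-score phenotype label and
#' trait category. It is the X side of every model in the package.
#'
#' @param matrix Numeric matrix, n samples x p scores. Must have no missing
#'   values; column names are taken as score IDs when `score_ids` is absent.
#' @param sample_ids Character vector of length n; unique subject identifiers.
#' @param score_ids Character vector of length p; unique score identifiers
#'   (e.g. PGS Catalog accessions).
#' @param phenotype Character vector of length p; the trait each score was
#'   trained on. Several scores may share a phenotype (near-duplicate scores
#'   from different source GWAS are common in multi-PGS panels).
#' @param category Character vector of length p; trait category of each score.
#'   The canonical panel uses `psychiatric`, `hormone_pregnancy`,
#'   `immune_inflammation` and `sleep_circadian`, but any labels are accepted.
#'
#' @return An object of class `score_panel`: a list with elements `matrix`,
#'   `sample_ids`, `score_ids`, `phenotype`, `category`.
#' @export
score_panel <- function(matrix, sample_ids = rownames(matrix),
                        score_ids = colnames(matrix),
                        phenotype = score_ids,
                        category = rep("uncategorized", ncol(matrix))) {
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix)) stop("score matrix must be numeric", call. = FALSE)
  if (ncol(matrix) < 1L) stop("score panel must contain at least one score (p >= 1)", call. = FALSE)
  if (nrow(matrix) < 3L) stop("score panel must contain at least three samples (n >= 3)", call. = FALSE)
  if (anyNA(matrix)) stop("score matrix contains missing values", call. = FALSE)
  sample_ids <- as.character(sample_ids)
  score_ids <- as.character(score_ids)
  if (length(sample_ids) != nrow(matrix)) stop("sample_ids length must equal nrow(matrix)", call. = FALSE)
  if (length(score_ids) != ncol(matrix)) stop("score_ids length must equal ncol(matrix)", call. = FALSE)
  if (anyDuplicated(score_ids)) stop("score_ids must be unique", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids in score panel", call. = FALSE)
  if (length(phenotype) != ncol(matrix) || length(category) != ncol(matrix))
    stop("phenotype and category must have one entry per score", call. = FALSE)
  rownames(matrix) <- sample_ids
  colnames(matrix) <- score_ids
  structure(list(matrix = matrix, sample_ids = sample_ids, score_ids = score_ids,
                 phenotype = as.character(phenotype), category = as.character(category)),
            class = "score_panel")
}

#' @export
print.score_panel <- function(x, ...) {
  cat(sprintf("<score_panel> %d samples x %d scores\n", nrow(x$matrix), ncol(x$matrix)))
  tab <- table(x$category)
  cat("categories:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.score_panel <- function(x) dim(x$matrix)

#' Phenotype table: per-subject outcome, diagnosis and demographics
#'
#' Holds the response side of the analysis: the binary outcome (1 = history of
#' peripartum depression, 0 = none), the mood-disorder diagnosis label used as
#' covariate and for subgroup splits, and any demographic columns consumed by
#' [cohort_table()].
#'
#' @param sample_ids Character vector of subject identifiers.
#' @param outcome Integer/logical vector coded 1 = PPD history, 0 = none.
#' @param diagnosis Character vector with levels `"MDD"` and `"BD"`.
#' @param demographics Optional data frame of extra per-subject columns.
#'
#' @return A data frame of class `phenotype_table` with columns `sample_id`,
#'   `ppd`, `diagnosis`, plus any demographics.
#' @export
phenotype_table <- function(sample_ids, outcome, diagnosis,
                            demographics = NULL) {
  sample_ids <- as.character(sample_ids)
  outcome <- as.integer(outcome)
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids in phenotype table", call. = FALSE)
  if (!all(outcome %in% c(0L, 1L))) stop("outcome must be coded 0/1", call. = FALSE)
  if (length(outcome) != length(sample_ids) || length(diagnosis) != length(sample_ids))
    stop("sample_ids, outcome and diagnosis must have equal length", call. = FALSE)
  df <- data.frame(sample_id = sample_ids, ppd = outcome,
                   diagnosis = as.character(diagnosis),
                   stringsAsFactors = FALSE)
  if (!is.null(demographics)) {
    demographics <- as.data.frame(demographics)
    if (nrow(demographics) != nrow(df))
      stop("demographics must have one row per subject", call. = FALSE)
    df <- cbind(df, demographics)
  }
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Read a score panel and phenotype table from delimited text files
#'
#' Reads the three-file on-disk dialect: `scores.tsv` (header `sample_id` plus
#' one column per score), `score_meta.tsv` (`score_id`, `phenotype`,
#' `category`) and `phenotypes.tsv` (`sample_id`, `ppd`, `diagnosis`, plus
#' optional demographics). Phenotype rows are realigned to the score-matrix
#' row order by `sample_id`; mismatching or duplicated IDs and score columns
#' missing from the metadata are rejected with diagnostics.
#'
#' @param scores_path Path to the tab-separated score matrix.
#' @param meta_path Path to the tab-separated score metadata.
#' @param pheno_path Path to the tab-separated phenotype table.
#'
#' @return A list with elements `panel` ([score_panel]) and `phenotypes`
#'   ([phenotype_table]), row-aligned.
#' @export
read_inputs <- function(scores_path, meta_path, pheno_path) {
  for (p in c(scores_path, meta_path, pheno_path))
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  scores <- utils::read.delim(scores_path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  pheno <- utils::read.delim(pheno_path, stringsAsFactors = FALSE)

  if (!identical(names(scores)[1], "sample_id"))
    stop("scores file: first column must be 'sample_id' (found '", names(scores)[1], "')", call. = FALSE)
  need_meta <- c("score_id", "phenotype", "category")
  if (!all(need_meta %in% names(meta)))
    stop("score metadata must have columns: ", paste(need_meta, collapse = ", "), call. = FALSE)
  if (!all(c("sample_id", "ppd", "diagnosis") %in% names(pheno)))
    stop("phenotype file must have columns sample_id, ppd, diagnosis", call. = FALSE)

  mat <- scores[, -1, drop = FALSE]
  bad <- names(mat)[!vapply(mat, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric score columns: ", paste(bad, collapse = ", "), call. = FALSE)
  mat <- as.matrix(mat)
  rownames(mat) <- as.character(scores$sample_id)

  missing_meta <- setdiff(colnames(mat), meta$score_id)
  if (length(missing_meta))
    stop("score columns absent from metadata: ", paste(missing_meta, collapse = ", "), call. = FALSE)
  extra_meta <- setdiff(meta$score_id, colnames(mat))
  if (length(extra_meta))
    stop("metadata rows without a matrix column: ", paste(extra_meta, collapse = ", "), call. = FALSE)
  meta <- meta[match(colnames(mat), meta$score_id), ]

  if (anyDuplicated(pheno$sample_id))
    stop("duplicate sample_ids in phenotype file", call. = FALSE)
  idx <- match(rownames(mat), as.character(pheno$sample_id))
  if (anyNA(idx)) {
    miss <- rownames(mat)[is.na(idx)]
    stop("samples missing from phenotype file: ", paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  pheno <- pheno[idx, , drop = FALSE]

  panel <- score_panel(mat, sample_ids = rownames(mat), score_ids = colnames(mat),
                       phenotype = meta$phenotype, category = meta$category)
  extra <- setdiff(names(pheno), c("sample_id", "ppd", "diagnosis"))
  phen <- phenotype_table(pheno$sample_id, pheno$ppd, pheno$diagnosis,
                          demographics = if (length(extra)) pheno[, extra, drop = FALSE] else NULL)
  list(panel = panel, phenotypes = phen)
}
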