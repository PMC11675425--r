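#' ROC curve and AUC of a continuous classifier score
#'
#' Builds the ROC curve of a score against a binary outcome over all unique
#' score thresholds and integrates the AUC by the trapezoidal rule (exactly
#' the Mann-Whitney pairwise concordance with ties counted 1/2). If the raw
#' score discriminates in the "wrong" direction (AUC < 0.5) it is flipped so
#' the reported AUC is >= 0.5, and the flip is recorded in `orientation`.
#'
#' @param score Numeric classifier score, higher = more case-like after
#'   orientation.
#' @param y01 Binary 0/1 outcome with both classes present.
#' @param orient Auto-flip the score so AUC >= 0.5 (default `TRUE`).
#' @return A list of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `orientation` (`"as-is"` or `"flipped"`),
#'   `score` (the oriented score).
#' @export
roc_curve <- function(score, y01, orient = TRUE) {
  score <- as.numeric(score)
  y01 <- as.integer(y01)
  stopifnot(length(score) == length(y01))
  if (length(unique(y01)) < 2L)
    stop("ROC needs both outcome classes present", call. = FALSE)
  orientation <- "as-is"
  if (orient && auc_concordance(score, y01) < 0.5) {
    score <- -score
    orientation <- "flipped"
  }
  n1 <- sum(y01 == 1L); n0 <- sum(y01 == 0L)
  thr <- sort(unique(score), decreasing = TRUE)
  # predicted positive when score >= threshold
  tp <- vapply(thr, function(cc) sum(score >= cc & y01 == 1L), numeric(1))
  fp <- vapply(thr, function(cc) sum(score >= cc & y01 == 0L), numeric(1))
  sens <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(list(thresholds = c(Inf, thr),
                 sensitivity = sens,
                 specificity = 1 - fpr,
                 auc = auc, orientation = orientation, score = score),
            class = "roc_result")
}

#' Pairwise-concordance (Mann-Whitney) AUC
#'
#' Rank-based computation of `P(score_case > score_control) + 1/2
#' P(tie)` — the probabilistic meaning of the AUC, used as the dual route
#' to the trapezoidal integral in [roc_curve()].
#'
#' @param score Numeric classifier score.
#' @param y01 Binary 0/1 outcome.
#' @return The concordance AUC in [0, 1].
#' @export
auc_concordance <- function(score, y01) {
  y01 <- as.integer(y01)
  n1 <- sum(y01 == 1L); n0 <- sum(y01 == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required", call. = FALSE)
  r <- rank(score)  # midranks handle ties as 1/2 concordance
  (sum(r[y01 == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC of the first latent variable of a PLS model
#'
#' The study's classifier score is the first latent variable t1 = X w1. This
#' evaluates it on the supplied data (training data by default, giving the
#' in-sample ROC) against the binary outcome.
#'
#' @param model A fitted `pls_model`.
#' @param X Predictor matrix on the training columns; `NULL` uses the
#'   training scores.
#' @param y01 Binary 0/1 outcome aligned with `X`.
#' @return A `roc_result`.
#' @export
roc_first_latent <- function(model, X = NULL, y01) {
  stopifnot(inherits(model, "pls_model"))
  t1 <- if (is.null(X)) model$T[, 1L] else predict(model, X, ncomp = 1L)$scores[, 1L]
  roc_curve(t1, y01)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%s), %d thresholds\n",
              x$auc, x$orientation, length(x$thresholds)))
  invisible(x)
}

#' Write ROC curve points to a TSV file
#'
#' @param roc A `roc_result`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_roc_tsv <- function(roc, path) {
  utils::write.table(data.frame(threshold = roc$thresholds,
                                sensitivity = roc$sensitivity,
                                specificity = roc$specificity),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
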