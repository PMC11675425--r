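#' Stratified k-fold assignments
#'
#' Assigns each subject to one of `n_folds` folds. With `stratified = TRUE`
#' (the default) cases and controls are split separately so every fold keeps
#' roughly the sample prevalence — important with an unbalanced 62/116
#' design, where plain random folds can end up with almost no cases.
#'
#' @param y01 Binary outcome vector.
#' @param n_folds Number of folds (>= 2, <= n).
#' @param stratified Stratify folds by outcome class?
#' @param seed Integer seed for the fold draw.
#' @return Integer vector of fold labels in 1..n_folds.
#' @export
make_folds <- function(y01, n_folds = 7L, stratified = TRUE, seed = 1L) {
  n <- length(y01)
  if (n_folds < 2L) stop("n_folds must be at least 2", call. = FALSE)
  if (n_folds > n) stop(sprintf("n_folds = %d exceeds sample size %d", n_folds, n), call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  folds <- integer(n)
  if (stratified) {
    for (cls in unique(y01)) {
      idx <- which(y01 == cls)
      folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  } else {
    attempt <- 0L
    repeat {
      folds <- sample(rep_len(seq_len(n_folds), n))
      ok <- all(vapply(seq_len(n_folds),
                       function(k) length(unique(y01[folds != k])) == 2L, logical(1)))
      if (ok) break
      attempt <- attempt + 1L
      warning("fold draw left a training split with a single outcome class; re-drawing",
              call. = FALSE)
      if (attempt > 100L) stop("could not draw folds with both classes in every training split",
                               call. = FALSE)
    }
  }
  folds
}

#' Cross-validate the number of PLS components
#'
#' For each candidate component count A in `1..max_A`, fits NIPALS PLS on
#' k-1 folds and predicts the held-out fold, with autoscaling re-estimated
#' inside each training split so no information leaks from the held-out
#' subjects. Accumulates the predictive residual sum of squares
#' `PRESS(A) = sum((y_held - y_hat)^2)` on the original 0/1 outcome scale
#' and reports `Q2(A) = 1 - PRESS(A) / TSS`, where TSS sums the squared
#' deviations of held-out outcomes from their training-fold means.
#'
#' @param X Predictor matrix (raw or autoscaled; folds are re-autoscaled
#'   internally either way).
#' @param y01 Binary 0/1 outcome.
#' @param max_A Largest component count to try.
#' @param n_folds Number of folds (default 7).
#' @param stratified Stratify folds by outcome (default `TRUE`).
#' @param seed Integer seed controlling the fold draw.
#' @param selection_tol Parsimony tolerance handed to [select_components()].
#' @return A list of class `pls_cv`: `press`, `q2` (named per-A vectors),
#'   `selected_A`, `no_predictive_component` flag, `fold_assignments`,
#'   `n_folds`, `seed`, `candidate_A`, and `cv_scores` (out-of-fold first
#'   latent scores, for cross-validated ROC).
#' @export
cross_validate <- function(X, y01, max_A = 5L, n_folds = 7L, stratified = TRUE,
                           seed = 1L, selection_tol = 0.01) {
  X <- as.matrix(X)
  y01 <- as.numeric(y01)
  stopifnot(max_A >= 1L, nrow(X) == length(y01))
  folds <- make_folds(y01, n_folds = n_folds, stratified = stratified, seed = seed)

  max_A <- min(max_A, ncol(X), nrow(X) - max(table(folds)) - 1L)
  press <- numeric(max_A)
  tss <- 0
  cv_scores <- numeric(length(y01))
  for (k in seq_len(n_folds)) {
    test <- folds == k
    if (!any(test)) next
    fit <- fit_nipals(X[!test, , drop = FALSE], y01[!test], A = max_A)
    for (A in seq_len(max_A)) {
      a_use <- min(A, fit$A)
      pred <- predict(fit, X[test, , drop = FALSE], ncomp = a_use)
      press[A] <- press[A] + sum((y01[test] - pred$y_hat)^2)
    }
    tss <- tss + sum((y01[test] - mean(y01[!test]))^2)
    pred1 <- predict(fit, X[test, , drop = FALSE], ncomp = 1L)
    cv_scores[test] <- pred1$scores[, 1L]
  }
  q2 <- 1 - press / tss
  names(press) <- names(q2) <- paste0("A", seq_len(max_A))

  cv <- structure(list(press = press, q2 = q2, candidate_A = seq_len(max_A),
                       fold_assignments = folds, n_folds = n_folds, seed = seed,
                       cv_scores = cv_scores),
                  class = "pls_cv")
  sel <- select_components(cv, tol = selection_tol)
  cv$selected_A <- as.integer(sel)
  cv$no_predictive_component <- isTRUE(attr(sel, "no_predictive_component"))
  cv
}

#' Choose the number of components from a cross-validation result
#'
#' Default rule: the smallest A whose Q2 comes within `tol` of the maximum
#' Q2 over all candidates — the classical parsimony rule. If no candidate
#' achieves a positive Q2, A = 1 is returned with attribute
#' `no_predictive_component = TRUE`: the model is retained as a ranking
#' device even when it has no out-of-sample predictive value.
#'
#' @param cv A `pls_cv` object (or anything with a `q2` vector).
#' @param tol Parsimony tolerance on Q2 (default 0.01).
#' @return Integer component count, with attribute
#'   `no_predictive_component`.
#' @export
select_components <- function(cv, tol = 0.01) {
  q2 <- cv$q2
  if (is.null(q2) || !length(q2)) stop("empty cross-validation result", call. = FALSE)
  if (all(q2 <= 0)) {
    return(structure(1L, no_predictive_component = TRUE))
  }
  best <- max(q2)
  a <- which(q2 >= best - tol)[1L]
  structure(as.integer(a), no_predictive_component = FALSE)
}

#' @export
print.pls_cv <- function(x, ...) {
  cat(sprintf("<pls_cv> %d-fold, candidates A = 1..%d\n", x$n_folds, length(x$q2)))
  cat("Q2:", paste(sprintf("%.4f", x$q2), collapse = ", "), "\n")
  cat("selected A =", x$selected_A,
      if (isTRUE(x$no_predictive_component)) "(no predictive component)" else "", "\n")
  invisible(x)
}

#' Write a cross-validation report to JSON
#'
#' @param cv A `pls_cv` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cv_json <- function(cv, path) {
  doc <- list(n_folds = cv$n_folds, seed = cv$seed,
              candidate_A = cv$candidate_A,
              press = unname(cv$press), q2 = unname(cv$q2),
              selected_A = as.integer(cv$selected_A),
              no_predictive_component = isTRUE(cv$no_predictive_component),
              fold_assignments = cv$fold_assignments)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
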