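#' Variable importance in projection (VIP) scores
#'
#' Computes the y-variance-weighted VIP for every ranked (non-covariate)
#' predictor of a fitted PLS model:
#' `VIP_j = sqrt( p * sum_a SSY_a * w_aj_norm^2 / sum_a SSY_a )`,
#' where `SSY_a = q_a^2 * t_a' t_a` is the response variance captured by
#' component a, `p` counts the ranked predictors, and the squared weights
#' `w_aj_norm^2` are renormalized to sum to 1 over the ranked predictors.
#' This normalization makes `mean(VIP^2) = 1` an algebraic identity over the
#' ranked set, so VIP > 1 means "more important than average". The diagnosis
#' covariate (when fitted) contributes to the model but is excluded from the
#' VIP table, its count and its normalization.
#'
#' With a single component the formula collapses to
#' `VIP_j = sqrt(p) * |w_1j| / ||w_1||`, so VIP ranking equals |weight|
#' ranking exactly.
#'
#' @param model A fitted `pls_model`.
#' @return A data frame (class `vip_table`): `score_id`, `phenotype`,
#'   `category`, `weight` (signed first-component weight), `vip`.
#' @export
compute_vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (model$A < 1L) stop("model has no fitted components", call. = FALSE)
  ranked <- model$roles == "score"
  if (!any(ranked)) stop("model has no ranked (non-covariate) predictors", call. = FALSE)
  Wr <- model$W[ranked, , drop = FALSE]
  p_r <- nrow(Wr)
  ssy <- model$ssy
  wnorm2 <- sweep(Wr^2, 2, colSums(Wr^2), "/")       # renormalize over ranked set
  vip <- sqrt(p_r * as.vector(wnorm2 %*% ssy) / sum(ssy))

  out <- data.frame(
    score_id = rownames(Wr),
    phenotype = if (!is.null(model$phenotype)) model$phenotype[ranked] else rownames(Wr),
    category = if (!is.null(model$category)) model$category[ranked] else "uncategorized",
    weight = Wr[, 1L],
    vip = vip,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("vip_table", "data.frame")
  out
}

#' Rank predictors by VIP and apply the VIP > threshold selection rule
#'
#' Sorts the table by descending VIP (ties broken by descending |weight|,
#' then score ID), assigns ranks 1..p, flags predictors with VIP strictly
#' greater than the threshold as selected, and calls the direction of each
#' association from the sign of the first-component weight: positive weight
#' predicts the outcome's presence (PPD), negative its absence.
#'
#' @param vip A `vip_table` from [compute_vip()].
#' @param threshold Selection cutoff (default 1; strict inequality, so a
#'   boundary VIP of exactly 1 is not selected).
#' @return The table sorted by rank with added columns `rank`, `selected`,
#'   `direction`.
#' @export
rank_and_select <- function(vip, threshold = 1.0) {
  stopifnot(is.data.frame(vip), all(c("vip", "weight", "score_id") %in% names(vip)))
  ord <- order(-vip$vip, -abs(vip$weight), vip$score_id)
  out <- vip[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$selected <- out$vip > threshold
  out$direction <- ifelse(out$weight > 0, "positive", "negative")
  rownames(out) <- NULL
  class(out) <- c("vip_table", "data.frame")
  out
}

#' Per-category contribution summary
#'
#' Tallies, for each trait category, how many scores were selected
#' (VIP > threshold) and how the selected scores split by direction:
#' positive weight (predicting the outcome, PPD) versus negative weight
#' (predicting its absence), plus the fraction of the category included.
#'
#' @param vip A ranked `vip_table` from [rank_and_select()].
#' @return A data frame with one row per category: `category`, `n_total`,
#'   `n_selected`, `n_positive`, `n_negative`, `prop_included`,
#'   `percent_included`.
#' @export
summarize_categories <- function(vip) {
  stopifnot(is.data.frame(vip))
  if (!"selected" %in% names(vip))
    stop("run rank_and_select() before summarizing categories", call. = FALSE)
  if (anyNA(vip$category)) stop("missing category labels", call. = FALSE)
  cats <- unique(vip$category)
  rows <- lapply(cats, function(cc) {
    sub <- vip[vip$category == cc, , drop = FALSE]
    sel <- sub[sub$selected, , drop = FALSE]
    data.frame(category = cc,
               n_total = nrow(sub),
               n_selected = nrow(sel),
               n_positive = sum(sel$weight > 0),
               n_negative = sum(sel$weight <= 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$prop_included <- out$n_selected / out$n_total
  out$percent_included <- 100 * out$prop_included
  out
}
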