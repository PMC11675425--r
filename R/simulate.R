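#' Configuration for the synthetic multi-PGS panel generator
#'
#' Defines the statistical shape of a simulated score panel: the case/control
#' split, the category composition, the block structure of correlated
#' near-duplicate scores, and a sparse linear signal planted on a latent
#' liability. Defaults reproduce the canonical study-shaped panel: 178
#' subjects (62 cases, 116 controls) and 341 scores split 67 psychiatric,
#' 89 hormone/pregnancy, 131 immune-inflammatory, 54 sleep/circadian, with
#' correlated blocks of up to three scores per phenotype.
#'
#' @param n_cases,n_controls Positive subject counts; case status is assigned
#'   by rank-thresholding the liability, so realized counts are exact.
#' @param category_sizes Named integer vector: scores per category (4 names
#'   by convention, any number accepted).
#' @param block_spec Data frame with columns `phenotype`, `category`, `size`
#'   (block size >= 1) and `rho` (within-block correlation in [0,1)). Block
#'   sizes must sum to the category sizes. `NULL` builds a default partition
#'   of each category into blocks of size 3, 2 and 1 with `rho = block_rho`.
#' @param signal_spec Data frame with columns `phenotype` and `beta`: planted
#'   per-score effects. Every score in a signal phenotype's block receives
#'   that effect. `NULL` plants the default sparse signal (see
#'   `default_signal_spec()`); use an empty data frame for a pure null.
#' @param block_rho Within-block correlation used when `block_spec` is built
#'   automatically.
#' @param global_rho Loading on a single panel-wide shared factor inducing
#'   cross-category correlation (default 0, i.e. categories independent).
#' @param noise_sd Standard deviation of the liability noise term.
#' @param mdd_fraction Fraction of subjects labelled MDD (the rest BD),
#'   assigned independently of the outcome.
#' @param demographics If `TRUE`, add demographic columns (age, menopause)
#'   with a case/control age difference, for exercising the cohort battery.
#' @param seed Integer seed; the generator is fully reproducible given it.
#'
#' @return A list of class `sim_config`.
#' @seealso [generate_panel()]
#' @export
sim_config <- function(n_cases = 62L, n_controls = 116L,
                       category_sizes = c(psychiatric = 67L,
                                          hormone_pregnancy = 89L,
                                          immune_inflammation = 131L,
                                          sleep_circadian = 54L),
                       block_spec = NULL, signal_spec = NULL,
                       block_rho = 0.9, global_rho = 0,
                       noise_sd = 1, mdd_fraction = 72 / 178,
                       demographics = FALSE, seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, all(category_sizes >= 1))
  if (is.null(names(category_sizes)) || any(!nzchar(names(category_sizes))))
    stop("category_sizes must be a named vector", call. = FALSE)
  if (block_rho < 0 || block_rho >= 1)
    stop("within-block correlation rho must lie in [0, 1)", call. = FALSE)
  if (is.null(block_spec))
    block_spec <- default_block_spec(category_sizes, block_rho)
  block_spec <- as.data.frame(block_spec)
  need <- c("phenotype", "category", "size", "rho")
  if (!all(need %in% names(block_spec)))
    stop("block_spec needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (any(block_spec$rho < 0 | block_spec$rho >= 1))
    stop("within-block correlation rho must lie in [0, 1)", call. = FALSE)
  if (anyDuplicated(block_spec$phenotype))
    stop("block_spec phenotypes must be unique", call. = FALSE)
  for (cat_name in names(category_sizes)) {
    got <- sum(block_spec$size[block_spec$category == cat_name])
    if (got != category_sizes[[cat_name]])
      stop(sprintf("block sizes in category '%s' sum to %d, expected %d",
                   cat_name, got, category_sizes[[cat_name]]), call. = FALSE)
  }
  if (is.null(signal_spec)) signal_spec <- default_signal_spec(block_spec)
  signal_spec <- as.data.frame(signal_spec)
  if (nrow(signal_spec) && !all(c("phenotype", "beta") %in% names(signal_spec)))
    stop("signal_spec needs columns phenotype, beta", call. = FALSE)
  if (nrow(signal_spec)) {
    unknown <- setdiff(signal_spec$phenotype, block_spec$phenotype)
    if (length(unknown))
      stop("signal phenotypes absent from block_spec: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  stopifnot(noise_sd > 0, global_rho >= 0, global_rho < 1)
  structure(list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
                 category_sizes = category_sizes, block_spec = block_spec,
                 signal_spec = signal_spec, global_rho = global_rho,
                 noise_sd = noise_sd, mdd_fraction = mdd_fraction,
                 demographics = isTRUE(demographics), seed = as.integer(seed)),
            class = "sim_config")
}

#' Default partition of a category into correlated phenotype blocks
#'
#' Splits each category into blocks of sizes 3, 2, 1, 3, 2, 1, ... until the
#' category size is exhausted, mimicking the multiple near-duplicate scores
#' per trait seen in multi-PGS panels (e.g. several "Monocyte count" scores
#' from different source GWAS).
#'
#' @param category_sizes Named integer vector of scores per category.
#' @param rho Shared within-block correlation.
#' @return Data frame with columns `phenotype`, `category`, `size`, `rho`.
#' @export
default_block_spec <- function(category_sizes, rho = 0.9) {
  out <- list()
  for (cat_name in names(category_sizes)) {
    left <- category_sizes[[cat_name]]
    sizes <- integer(0)
    cycle <- c(3L, 2L, 1L)
    i <- 0L
    while (left > 0L) {
      s <- min(cycle[(i %% 3L) + 1L], left)
      sizes <- c(sizes, s)
      left <- left - s
      i <- i + 1L
    }
    out[[cat_name]] <- data.frame(
      phenotype = sprintf("%s_trait_%02d", cat_name, seq_along(sizes)),
      category = cat_name, size = sizes, rho = rho,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default sparse planted signal
#'
#' Picks the first few multi-score blocks across categories so that roughly
#' 20 scores carry a nonzero effect, with alternating signs and effect size
#' 0.5 per score — a sparse signal in an otherwise null panel.
#'
#' @param block_spec Block specification as built by [default_block_spec()].
#' @param n_causal_scores Target number of score columns with nonzero effect.
#' @param beta Absolute per-score effect size.
#' @return Data frame with columns `phenotype`, `beta`.
#' @export
default_signal_spec <- function(block_spec, n_causal_scores = 20L, beta = 0.5) {
  cand <- block_spec[block_spec$size >= 2L, , drop = FALSE]
  # interleave categories so the signal is spread across all four
  cand <- cand[order(ave(seq_len(nrow(cand)), cand$category, FUN = seq_along)), , drop = FALSE]
  picked <- character(0); signs <- numeric(0); total <- 0L
  for (i in seq_len(nrow(cand))) {
    if (total >= n_causal_scores) break
    picked <- c(picked, cand$phenotype[i])
    signs <- c(signs, if (length(signs) %% 2L == 0L) 1 else -1)
    total <- total + cand$size[i]
  }
  data.frame(phenotype = picked, beta = beta * signs, stringsAsFactors = FALSE)
}

#' Generate a synthetic score panel with a planted liability signal
#'
#' Draws the score matrix from a shared-factor block construction
#' (`score = sqrt(rho) * block_factor + sqrt(1 - rho) * idiosyncratic`, all
#' standard normal, optionally plus a panel-wide factor), computes a latent
#' liability `X %*% beta + noise`, and labels the top `n_cases` subjects by
#' liability as cases — so realized case/control margins are exact, matching
#' a fixed-design case/control study rather than a Bernoulli draw.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `panel` ([score_panel]), `phenotypes`
#'   ([phenotype_table]) and `truth` (list with `true_effect_vector`,
#'   `latent_liability`, `outcome_rule`).
#' @export
generate_panel <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_cases + config$n_controls
  bs <- config$block_spec
  p <- sum(bs$size)

  X <- matrix(0, n, p)
  score_ids <- character(p)
  phenotype <- character(p)
  category <- character(p)
  col <- 0L
  for (i in seq_len(nrow(bs))) {
    k <- bs$size[i]; rho <- bs$rho[i]
    f <- stats::rnorm(n)
    for (j in seq_len(k)) {
      col <- col + 1L
      X[, col] <- sqrt(rho) * f + sqrt(1 - rho) * stats::rnorm(n)
      score_ids[col] <- sprintf("SPGS%04d", col)
      phenotype[col] <- bs$phenotype[i]
      category[col] <- bs$category[i]
    }
  }
  if (config$global_rho > 0) {
    g <- stats::rnorm(n)
    lam <- sqrt(config$global_rho)
    X <- sqrt(1 - config$global_rho) * X + lam * matrix(g, n, p)
  }

  beta <- numeric(p)
  if (nrow(config$signal_spec)) {
    for (i in seq_len(nrow(config$signal_spec))) {
      hit <- phenotype == config$signal_spec$phenotype[i]
      beta[hit] <- config$signal_spec$beta[i]
    }
  }
  liability <- as.vector(X %*% beta) + config$noise_sd * stats::rnorm(n)
  thr_rank <- rank(-liability, ties.method = "first")
  outcome <- as.integer(thr_rank <= config$n_cases)

  n_mdd <- round(config$mdd_fraction * n)
  diagnosis <- rep("BD", n)
  diagnosis[sample.int(n, n_mdd)] <- "MDD"

  sample_ids <- sprintf("S%03d", seq_len(n))
  demo <- NULL
  if (config$demographics) {
    age <- ifelse(outcome == 1L, stats::rnorm(n, 48.2, 9.4), stats::rnorm(n, 53.9, 8.9))
    menopause <- ifelse(stats::runif(n) < stats::plogis((age - 51) / 3), "yes", "no")
    demo <- data.frame(age = round(age, 1), menopause = menopause,
                       stringsAsFactors = FALSE)
  }

  panel <- score_panel(X, sample_ids = sample_ids, score_ids = score_ids,
                       phenotype = phenotype, category = category)
  phen <- phenotype_table(sample_ids, outcome, diagnosis, demographics = demo)
  truth <- list(true_effect_vector = stats::setNames(beta, score_ids),
                latent_liability = stats::setNames(liability, sample_ids),
                outcome_rule = sprintf(
                  "top %d of %d subjects by latent liability (X beta + N(0, %g^2)) labelled cases",
                  config$n_cases, n, config$noise_sd))
  list(panel = panel, phenotypes = phen, truth = truth)
}

#' Write a simulated panel as a three-file delimited-text fixture
#'
#' Emits `scores.tsv`, `score_meta.tsv` and `phenotypes.tsv` in the dialect
#' read by [read_inputs()], plus `truth.tsv` with the planted per-score
#' effects. The round trip through [read_inputs()] is lossless to full
#' double precision.
#'
#' @param panel A [score_panel].
#' @param phenotypes A [phenotype_table].
#' @param truth Ground-truth list from [generate_panel()] (optional).
#' @param directory Output directory, created if needed.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixture <- function(panel, phenotypes, truth = NULL, directory) {
  stopifnot(inherits(panel, "score_panel"))
  if (ncol(panel$matrix) < 1L) stop("refusing to write an empty panel (p = 0)", call. = FALSE)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create output directory: ", directory, call. = FALSE)

  paths <- c(scores = file.path(directory, "scores.tsv"),
             meta = file.path(directory, "score_meta.tsv"),
             phenotypes = file.path(directory, "phenotypes.tsv"))
  scores_df <- data.frame(sample_id = panel$sample_ids,
                          format(panel$matrix, digits = 17, trim = TRUE, scientific = FALSE),
                          check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(scores_df, paths[["scores"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(score_id = panel$score_ids, phenotype = panel$phenotype,
                                category = panel$category, stringsAsFactors = FALSE),
                     paths[["meta"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(phenotypes), paths[["phenotypes"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(directory, "truth.tsv"))
    utils::write.table(data.frame(score_id = names(truth$true_effect_vector),
                                  beta = truth$true_effect_vector,
                                  stringsAsFactors = FALSE),
                       paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
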