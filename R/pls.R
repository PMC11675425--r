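#' Assemble the predictor block and response for a PLS run
#'
#' Aligns a score panel with its phenotype table, optionally appends the
#' mood-disorder diagnosis (MDD vs. BD) as a numerically coded predictor
#' column flagged `covariate`, drops constant columns with a warning, and
#' autoscales everything: each column of X and the 0/1 outcome are centered
#' to mean 0 and scaled to unit standard deviation. Autoscaling puts scores
#' from heterogeneous sources on one footing and is the convention under
#' which the VIP > 1 rule is meaningful.
#'
#' @param panel A [score_panel].
#' @param phenotypes A [phenotype_table] aligned 1:1 with `panel` (checked
#'   via `sample_id`).
#' @param include_diagnosis_covariate Append the diagnosis column (coded
#'   BD = 1, MDD = 0, then autoscaled)? Used for whole-sample models only;
#'   subgroup models are fitted without it.
#' @return A list of class `pls_data`: `X` (autoscaled n x p_eff matrix),
#'   `y` (autoscaled outcome), `y01` (raw 0/1 outcome), `roles` (per-column
#'   `"score"`/`"covariate"`), `phenotype`, `category` (per score column),
#'   `dropped` (names of constant columns removed).
#' @export
pls_prepare <- function(panel, phenotypes, include_diagnosis_covariate = FALSE) {
  stopifnot(inherits(panel, "score_panel"))
  if (!identical(panel$sample_ids, as.character(phenotypes$sample_id)))
    stop("panel and phenotype table are not aligned by sample_id", call. = FALSE)
  y01 <- as.integer(phenotypes$ppd)
  if (length(unique(y01)) < 2L)
    stop("outcome has a single class; a case/control model needs both", call. = FALSE)

  X <- panel$matrix
  roles <- rep("score", ncol(X))
  phen <- panel$phenotype
  cate <- panel$category
  if (include_diagnosis_covariate) {
    dx <- as.character(phenotypes$diagnosis)
    if (length(unique(dx)) < 2L)
      stop("diagnosis covariate requested but diagnosis has a single level", call. = FALSE)
    X <- cbind(X, diagnosis = as.numeric(dx == "BD"))
    colnames(X)[ncol(X)] <- "diagnosis"
    roles <- c(roles, "covariate")
    phen <- c(phen, "diagnosis (MDD vs BD)")
    cate <- c(cate, "covariate")
  }

  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  dropped <- colnames(X)[!keep]
  if (length(dropped)) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
    roles <- roles[keep]; phen <- phen[keep]; cate <- cate[keep]
  }
  if (ncol(X) == 0L) stop("all predictor columns are constant", call. = FALSE)

  Xs <- scale(X)
  ys <- as.vector(scale(y01))
  structure(list(X = Xs, y = ys, y01 = y01, roles = roles,
                 phenotype = phen, category = cate, dropped = dropped,
                 sample_ids = panel$sample_ids),
            class = "pls_data")
}

#' Fit a single-response PLS regression with the NIPALS algorithm
#'
#' Extracts `A` latent components from autoscaled data. Each component's
#' weight vector is obtained by the NIPALS iteration (which for a single
#' response converges in one pass to `w = X'y / ||X'y||`), followed by the
#' classical deflation of X and y. Per-component R2X and R2Y are the
#' fractions of the autoscaled predictor-block and response variance carried
#' by each component; regression coefficients on the autoscaled scale are
#' `b = W (P'W)^{-1} q`.
#'
#' A deterministic sign convention is applied: each component is flipped so
#' that its largest-magnitude weight entry is positive, making weights
#' bitwise reproducible while preserving relative signs.
#'
#' @param X Numeric predictor matrix (any scale; autoscaled internally and
#'   the centering/scaling vectors stored for prediction). Zero-variance
#'   columns are tolerated: they get zero weight.
#' @param y Numeric response (typically the 0/1 outcome; autoscaled
#'   internally).
#' @param A Number of components to extract. Truncated with a warning if the
#'   residual X or y variance is exhausted earlier.
#' @param tol NIPALS convergence tolerance on the weight-vector change.
#' @param max_iter Maximum NIPALS iterations per component.
#' @param roles Optional per-column `"score"`/`"covariate"` flags carried
#'   into the model (defaults to all `"score"`).
#' @param phenotype,category Optional per-column labels carried into the
#'   model for reporting.
#'
#' @return An object of class `pls_model`: weights `W` (unit-norm columns),
#'   x-scores `T`, x-loadings `P`, y-loadings `q`, coefficients `b`,
#'   per-component `r2x` and `r2y`, centering/scaling vectors, column roles
#'   and labels, and convergence diagnostics (`iterations`).
#' @export
fit_nipals <- function(X, y, A = 1L, tol = 1e-12, max_iter = 500L,
                       roles = NULL, phenotype = NULL, category = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), A >= 1L, tol > 0, max_iter >= 1L)
  if (stats::sd(y) == 0) stop("response has zero variance", call. = FALSE)
  if (is.null(roles)) roles <- rep("score", ncol(X))
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))

  x_center <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  x_scale <- ifelse(x_sd > 0, x_sd, 1)  # constant columns become all-zero
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  ys <- (y - y_center) / y_scale

  n <- nrow(Xs); p <- ncol(Xs)
  A <- min(A, p, n - 1L)
  ssx0 <- sum(Xs^2)
  ssy0 <- sum(ys^2)

  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, n, 0)
  q <- r2x <- r2y <- numeric(0)
  iters <- integer(0)
  Xa <- Xs; ya <- ys
  for (a in seq_len(A)) {
    if (sqrt(sum(ya^2)) < 1e-12 * sqrt(ssy0) || sum(Xa^2) < 1e-24 * ssx0) {
      warning(sprintf("residual variance exhausted; truncating at A = %d", a - 1L), call. = FALSE)
      break
    }
    w <- as.vector(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) {
      warning(sprintf("zero covariance direction; truncating at A = %d", a - 1L), call. = FALSE)
      break
    }
    w <- w / nw
    it <- 1L
    delta_prev <- Inf
    repeat {  # one pass suffices for a single response; loop kept for generality
      t_vec <- as.vector(Xa %*% w)
      q_a <- sum(ya * t_vec) / sum(t_vec^2)
      u <- ya * q_a
      w_new <- as.vector(crossprod(Xa, u))
      w_new <- w_new / sqrt(sum(w_new^2))
      delta <- sqrt(sum((w_new - w)^2))
      w <- w_new
      # stop at tol, or when delta has hit its floating-point floor (late
      # components deflate X and y to near-zero, where 1e-12 is unattainable)
      if (delta < tol || delta >= delta_prev || it >= max_iter) break
      delta_prev <- delta
      it <- it + 1L
    }
    if (it >= max_iter && delta >= tol && delta < delta_prev)
      stop(sprintf("NIPALS failed to converge for component %d (delta = %g after %d iterations)",
                   a, delta, it), call. = FALSE)
    # sign convention: largest |w| entry positive
    flip <- sign(w[which.max(abs(w))])
    if (flip < 0) w <- -w
    t_vec <- as.vector(Xa %*% w)
    tt <- sum(t_vec^2)
    p_vec <- as.vector(crossprod(Xa, t_vec)) / tt
    q_a <- sum(ya * t_vec) / tt
    Xa <- Xa - tcrossprod(t_vec, p_vec)
    ya <- ya - q_a * t_vec
    W <- cbind(W, w); P <- cbind(P, p_vec); Tm <- cbind(Tm, t_vec)
    q <- c(q, q_a)
    r2x <- c(r2x, tt * sum(p_vec^2) / ssx0)
    r2y <- c(r2y, q_a^2 * tt / ssy0)
    iters <- c(iters, it)
  }
  if (ncol(W) == 0L) stop("no PLS component could be extracted", call. = FALSE)
  A_eff <- ncol(W)
  rownames(W) <- rownames(P) <- colnames(X)
  b <- as.vector(W %*% solve(crossprod(P, W), q))

  structure(list(A = A_eff, W = W, T = Tm, P = P, q = q, b = b,
                 r2x = r2x, r2y = r2y,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 roles = roles, phenotype = phenotype, category = category,
                 ssy = q^2 * colSums(Tm^2), iterations = iters),
            class = "pls_model")
}

#' Fit a PLS model from a prepared [pls_prepare()] object
#'
#' Convenience wrapper that fits on the raw 0/1 outcome (autoscaling is
#' internal to [fit_nipals()]) and carries column roles and labels into the
#' model.
#'
#' @param data A `pls_data` object from [pls_prepare()].
#' @param A Number of components.
#' @param ... Passed to [fit_nipals()].
#' @return A `pls_model`.
#' @export
fit_pls <- function(data, A = 1L, ...) {
  stopifnot(inherits(data, "pls_data"))
  fit_nipals(data$X, data$y01, A = A, roles = data$roles,
             phenotype = data$phenotype, category = data$category, ...)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), %d predictors\n", x$A, nrow(x$W)))
  cat("R2X per component:", paste(sprintf("%.4f", x$r2x), collapse = ", "), "\n")
  cat("R2Y per component:", paste(sprintf("%.4f", x$r2y), collapse = ", "), "\n")
  invisible(x)
}

#' Predict latent scores and outcome values from a fitted PLS model
#'
#' New data are centered and scaled with the training parameters; latent
#' scores are `T_new = X_new_scaled %*% W (P'W)^{-1}` (which reproduces the
#' training scores exactly on the training data), and fitted outcome values
#' are back-transformed to the original 0/1 outcome scale.
#'
#' @param object A `pls_model`.
#' @param newdata Matrix with the training predictor columns in training
#'   order. Defaults to reproducing training fitted values.
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return A list with `scores` (n_new x ncomp latent scores) and `y_hat`
#'   (predicted outcome on the 0/1 scale).
#' @export
predict.pls_model <- function(object, newdata = NULL, ncomp = object$A, ...) {
  stopifnot(ncomp >= 1L, ncomp <= object$A)
  if (is.null(newdata)) {
    Tn <- object$T[, seq_len(ncomp), drop = FALSE]
  } else {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != nrow(object$W))
      stop(sprintf("newdata has %d columns; model expects %d", ncol(newdata), nrow(object$W)),
           call. = FALSE)
    Xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
    R <- object$W[, seq_len(ncomp), drop = FALSE] %*%
      solve(crossprod(object$P[, seq_len(ncomp), drop = FALSE],
                      object$W[, seq_len(ncomp), drop = FALSE]))
    Tn <- Xs %*% R
  }
  q_sub <- object$q[seq_len(ncomp)]
  y_scaled <- as.vector(Tn %*% q_sub)
  list(scores = Tn, y_hat = y_scaled * object$y_scale + object$y_center)
}

#' Serialize a fitted PLS model to JSON
#'
#' Writes component count, weights, loadings, y-loadings, coefficients and
#' the centering/scaling vectors so a fit can be archived and re-applied.
#'
#' @param model A `pls_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  doc <- list(n_components = model$A,
              predictors = rownames(model$W),
              roles = model$roles,
              weights = unname(model$W), x_loadings = unname(model$P),
              y_loadings = model$q, coefficients = model$b,
              r2x = model$r2x, r2y = model$r2y,
              x_center = model$x_center, x_scale = model$x_scale,
              y_center = model$y_center, y_scale = model$y_scale)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
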