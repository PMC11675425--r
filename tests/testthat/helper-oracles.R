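# Independent oracles used to cross-check the package's own implementations.
# These deliberately avoid the code paths they verify.

# Closed-form single-response PLS on autoscaled data, computed directly
# (no NIPALS iteration): w_a = X_a'y_a / ||X_a'y_a||, then the classical
# deflation. Uses scale() and plain matrix algebra only.
pls1_closed_form <- function(X, y, A) {
  Xs <- scale(X)
  ys <- as.vector(scale(y))
  ssx0 <- sum(Xs^2); ssy0 <- sum(ys^2)
  W <- P <- NULL; Tm <- NULL; q <- r2x <- r2y <- numeric(0)
  for (a in seq_len(A)) {
    w <- as.vector(crossprod(Xs, ys))
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) w <- -w
    t_vec <- as.vector(Xs %*% w)
    tt <- sum(t_vec^2)
    p_vec <- as.vector(crossprod(Xs, t_vec)) / tt
    q_a <- sum(ys * t_vec) / tt
    Xs <- Xs - outer(t_vec, p_vec)
    ys <- ys - q_a * t_vec
    W <- cbind(W, w); P <- cbind(P, p_vec); Tm <- cbind(Tm, t_vec)
    q <- c(q, q_a)
    r2x <- c(r2x, tt * sum(p_vec^2) / ssx0)
    r2y <- c(r2y, q_a^2 * tt / ssy0)
  }
  list(W = W, P = P, T = Tm, q = q, r2x = r2x, r2y = r2y)
}

# OLS fitted values via the normal equations on autoscaled data,
# back-transformed to the response scale.
ols_fitted <- function(X, y) {
  Xs <- scale(X)
  ys <- as.vector(scale(y))
  b <- solve(crossprod(Xs), crossprod(Xs, ys))
  as.vector(Xs %*% b) * sd(y) + mean(y)
}

# Brute-force pairwise AUC: loop over every case/control pair, ties = 1/2.
auc_brute <- function(score, y01) {
  cases <- score[y01 == 1]
  ctrls <- score[y01 == 0]
  tot <- 0
  for (a in cases) for (b in ctrls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(ctrls))
}

# Small correlated-block panel for fast pipeline tests.
small_sim <- function(seed = 1L, n_cases = 20L, n_controls = 40L,
                      signal_spec = NULL, demographics = FALSE) {
  cfg <- sim_config(
    n_cases = n_cases, n_controls = n_controls,
    category_sizes = c(psychiatric = 6L, hormone_pregnancy = 6L,
                       immune_inflammation = 9L, sleep_circadian = 3L),
    signal_spec = signal_spec, demographics = demographics, seed = seed)
  generate_panel(cfg)
}

null_signal <- data.frame(phenotype = character(0), beta = numeric(0))
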