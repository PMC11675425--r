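test_that("stratified folds are balanced and keep both classes in training splits", {
  y <- c(rep(1L, 62), rep(0L, 116))
  folds <- make_folds(y, n_folds = 7, seed = 3L)
  sizes <- table(folds)
  expect_true(max(sizes) - min(sizes) <= 2)  # 62 and 116 each split to +/-1
  for (k in 1:7) {
    expect_true(all(c(0L, 1L) %in% y[folds != k]))
    # stratification keeps cases in every fold
    expect_gt(sum(y[folds == k] == 1L), 0)
  }
  expect_identical(folds, make_folds(y, n_folds = 7, seed = 3L))
  expect_error(make_folds(y, n_folds = 200), "exceeds sample size")
})

test_that("component selection follows the parsimony-within-tolerance rule", {
  sel <- select_components(list(q2 = c(0.30, 0.31, 0.29)), tol = 0.01)
  expect_identical(as.integer(sel), 1L)
  sel <- select_components(list(q2 = c(0.10, 0.40, 0.41)), tol = 0.01)
  expect_identical(as.integer(sel), 2L)
  sel <- select_components(list(q2 = c(-0.2, -0.1, -0.3)))
  expect_identical(as.integer(sel), 1L)
  expect_true(attr(sel, "no_predictive_component"))
  expect_error(select_components(list(q2 = numeric(0))), "empty")
})

test_that("a rank-one planted signal selects a single component", {
  sim <- generate_panel(sim_config(seed = 31L))
  prep <- pls_prepare(sim$panel, sim$phenotypes, include_diagnosis_covariate = TRUE)
  cv <- cross_validate(prep$X, prep$y01, max_A = 4L, n_folds = 7L, seed = 31L)
  expect_identical(cv$selected_A, 1L)
  expect_gt(cv$q2[1], 0.2)
})

test_that("cross-validation is deterministic given the seed and PRESS is invariant to sample order", {
  sim <- small_sim(seed = 8L)
  prep <- pls_prepare(sim$panel, sim$phenotypes)
  cv1 <- cross_validate(prep$X, prep$y01, max_A = 3L, seed = 5L)
  cv2 <- cross_validate(prep$X, prep$y01, max_A = 3L, seed = 5L)
  expect_identical(cv1$press, cv2$press)
  expect_identical(cv1$fold_assignments, cv2$fold_assignments)

  # permuting samples together with their fold labels leaves PRESS unchanged
  perm <- sample(seq_len(nrow(prep$X)))
  folds_perm <- cv1$fold_assignments[perm]
  press_perm <- numeric(3)
  for (k in 1:7) {
    test <- folds_perm == k
    fit <- fit_nipals(prep$X[perm, ][!test, ], prep$y01[perm][!test], A = 3L)
    for (A in 1:3) {
      pred <- predict(fit, prep$X[perm, ][test, , drop = FALSE], ncomp = min(A, fit$A))
      press_perm[A] <- press_perm[A] + sum((prep$y01[perm][test] - pred$y_hat)^2)
    }
  }
  expect_equal(unname(cv1$press), press_perm, tolerance = 1e-8)
})

test_that("cross-validated Q2 never beats in-sample R2Y", {
  set.seed(33)
  for (rep in 1:20) {
    n <- 60; p <- 12
    X <- matrix(rnorm(n * p), n, p)
    beta <- c(rep(0.6, 3), rep(0, p - 3))
    y <- as.integer(rank(-(X %*% beta + rnorm(n))) <= n / 3)
    cv <- cross_validate(X, y, max_A = 3L, seed = rep)
    fit <- fit_nipals(X, y, A = 3L)
    for (A in 1:fit$A)
      expect_lt(cv$q2[A], sum(fit$r2y[1:A]) + 0.05)
  }
})

test_that("pure-noise outcomes yield no predictive component", {
  worst <- -Inf
  for (s in 1:3) {
    sim <- small_sim(seed = 40L + s, n_cases = 25L, n_controls = 50L,
                     signal_spec = null_signal)
    prep <- pls_prepare(sim$panel, sim$phenotypes)
    cv <- cross_validate(prep$X, prep$y01, max_A = 3L, seed = s)
    worst <- max(worst, max(cv$q2))
  }
  expect_lt(worst, 0.05)
})

test_that("the CV report serializes to JSON", {
  sim <- small_sim(seed = 10L)
  prep <- pls_prepare(sim$panel, sim$phenotypes)
  cv <- cross_validate(prep$X, prep$y01, max_A = 2L, seed = 2L)
  path <- withr::local_tempfile(fileext = ".json")
  write_cv_json(cv, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(doc$q2, unname(cv$q2), tolerance = 1e-12)
  expect_identical(doc$selected_A, as.integer(cv$selected_A))
  expect_identical(doc$n_folds, 7L)
})
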