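test_that("prepared predictor blocks are autoscaled and carry the covariate", {
  sim <- small_sim(seed = 4L)
  prep <- pls_prepare(sim$panel, sim$phenotypes, include_diagnosis_covariate = TRUE)
  expect_true(all(abs(colMeans(prep$X)) < 1e-10))
  expect_true(all(abs(apply(prep$X, 2, sd) - 1) < 1e-10))
  expect_identical(ncol(prep$X), ncol(sim$panel$matrix) + 1L)
  expect_identical(sum(prep$roles == "covariate"), 1L)
  expect_true(abs(mean(prep$y)) < 1e-10)

  prep2 <- pls_prepare(sim$panel, sim$phenotypes, include_diagnosis_covariate = FALSE)
  expect_identical(ncol(prep2$X), ncol(sim$panel$matrix))

  # paper-shaped: 341 scores + 1 covariate column
  big <- generate_panel(sim_config(seed = 1L))
  expect_identical(ncol(pls_prepare(big$panel, big$phenotypes, TRUE)$X), 342L)
})

test_that("constant columns are dropped with a warning; degenerate outcomes error", {
  sim <- small_sim(seed = 4L)
  m <- sim$panel$matrix
  m[, 3] <- 5
  panel <- score_panel(m, sim$panel$sample_ids, sim$panel$score_ids,
                       sim$panel$phenotype, sim$panel$category)
  expect_warning(prep <- pls_prepare(panel, sim$phenotypes), "constant")
  expect_identical(ncol(prep$X), ncol(m) - 1L)
  expect_identical(prep$dropped, sim$panel$score_ids[3])

  ph_bad <- sim$phenotypes
  ph_bad$ppd <- 1L
  expect_error(pls_prepare(sim$panel, ph_bad), "single class")
})

test_that("univariate PLS reduces to simple regression", {
  set.seed(21)
  x <- matrix(rnorm(50), ncol = 1)
  y <- 0.5 * x[, 1] + rnorm(50)
  fit <- fit_nipals(x, y, A = 1)
  expect_equal(fit$r2y[1], cor(x[, 1], y)^2, tolerance = 1e-10)
})

test_that("first-component weight equals the normalized covariance direction", {
  set.seed(22)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- rbinom(30, 1, 0.4)
  fit <- fit_nipals(X, y, A = 1)
  w_direct <- crossprod(scale(X), scale(y))
  w_direct <- w_direct / sqrt(sum(w_direct^2))
  if (w_direct[which.max(abs(w_direct))] < 0) w_direct <- -w_direct
  expect_equal(unname(fit$W[, 1]), as.vector(w_direct), tolerance = 1e-8)
})

test_that("NIPALS agrees with the closed-form PLS oracle on random problems", {
  set.seed(23)
  for (rep in 1:20) {
    X <- matrix(rnorm(20 * 8), 20, 8)
    y <- rnorm(20)
    A <- sample(1:4, 1)
    fit <- fit_nipals(X, y, A = A)
    oracle <- pls1_closed_form(X, y, A)
    expect_equal(unname(fit$W), unname(oracle$W), tolerance = 1e-6)
    expect_equal(unname(fit$T), unname(oracle$T), tolerance = 1e-6)
    expect_equal(fit$q, oracle$q, tolerance = 1e-6)
    expect_equal(fit$r2x, oracle$r2x, tolerance = 1e-6)
    expect_equal(fit$r2y, oracle$r2y, tolerance = 1e-6)
  }
})

test_that("full-rank PLS reproduces ordinary least squares fitted values", {
  set.seed(24)
  for (rep in 1:5) {
    X <- matrix(rnorm(25 * 6), 25, 6)
    y <- rnorm(25)
    fit <- fit_nipals(X, y, A = 6)
    expect_equal(predict(fit)$y_hat, ols_fitted(X, y), tolerance = 1e-6)
  }
})

test_that("latent scores are orthogonal and variance fractions are coherent", {
  set.seed(25)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- rbinom(40, 1, 0.5)
  fit <- fit_nipals(X, y, A = 5)
  G <- crossprod(fit$T)
  expect_true(all(abs(G[upper.tri(G)]) < 1e-8))
  expect_true(all(fit$r2x >= 0 & fit$r2x <= 1))
  expect_true(all(fit$r2y >= 0 & fit$r2y <= 1))
  expect_true(all(cumsum(fit$r2x) <= 1 + 1e-8))
  expect_true(all(cumsum(fit$r2y) <= 1 + 1e-8))
  # each added component never decreases cumulative in-sample R2Y
  expect_true(all(diff(cumsum(fit$r2y)) >= -1e-12))
  # weight columns are unit norm
  expect_equal(unname(colSums(fit$W^2)), rep(1, 5), tolerance = 1e-10)
})

test_that("refitting the same input gives bitwise-identical weights", {
  sim <- small_sim(seed = 6L)
  prep <- pls_prepare(sim$panel, sim$phenotypes)
  f1 <- fit_pls(prep, A = 2)
  f2 <- fit_pls(prep, A = 2)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$b, f2$b)
})

test_that("prediction is consistent on training data and centering identities hold", {
  set.seed(26)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- rbinom(30, 1, 0.4)
  fit <- fit_nipals(X, y, A = 3)
  pred_train <- predict(fit, X)
  expect_equal(pred_train$y_hat, predict(fit)$y_hat, tolerance = 1e-10)
  expect_equal(unname(pred_train$scores), unname(fit$T), tolerance = 1e-10)
  # a row at the training column means predicts the training outcome mean
  pred_mean <- predict(fit, matrix(colMeans(X), 1))
  expect_equal(pred_mean$y_hat, mean(y), tolerance = 1e-10)
  expect_error(predict(fit, X[, 1:3]), "columns")
})

test_that("single held-out row matches a step-by-step manual projection", {
  X <- matrix(c(1, 2, 3, 4,
                0, 1, 0, 2,
                5, 3, 2, 1), 4, 3)
  y <- c(0, 0, 1, 1)
  x_new <- c(2.5, 1.0, 2.0)
  fit <- fit_nipals(X, y, A = 2)

  # manual: autoscale with training parameters, project through deflation
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  xs <- (x_new - ctr) / scl
  ys_sd <- sd(y); ys_m <- mean(y)
  t1 <- sum(xs * fit$W[, 1])
  xs_defl <- xs - t1 * fit$P[, 1]
  t2 <- sum(xs_defl * fit$W[, 2])
  y_manual <- (t1 * fit$q[1] + t2 * fit$q[2]) * ys_sd + ys_m

  pred <- predict(fit, matrix(x_new, 1))
  expect_equal(unname(pred$scores[1, ]), c(t1, t2), tolerance = 1e-10)
  expect_equal(pred$y_hat, y_manual, tolerance = 1e-10)
})

test_that("latent scores agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(27)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rbinom(30, 1, 0.4)
  fit <- fit_nipals(X, y, A = 3)
  ref <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = TRUE)
  for (a in 1:3) {
    expect_equal(abs(cor(fit$T[, a], ref$variates$X[, a])), 1, tolerance = 1e-6)
    expect_equal(sd(fit$T[, a]), sd(ref$variates$X[, a]), tolerance = 1e-6)
  }
})

test_that("model serialization writes a complete JSON document", {
  sim <- small_sim(seed = 13L)
  prep <- pls_prepare(sim$panel, sim$phenotypes)
  fit <- fit_pls(prep, A = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(doc$n_components, fit$A)
  expect_equal(doc$coefficients, fit$b, tolerance = 1e-12)
  expect_equal(unname(doc$x_center), unname(fit$x_center), tolerance = 1e-12)
})
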