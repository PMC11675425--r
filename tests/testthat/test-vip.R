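test_that("VIP normalization holds: mean squared VIP is exactly one", {
  set.seed(51)
  for (rep in 1:10) {
    n <- 40; p <- sample(5:15, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rbinom(n, 1, 0.4)
    fit <- fit_nipals(X, y, A = sample(1:3, 1))
    vip <- compute_vip(fit)
    expect_equal(mean(vip$vip^2), 1, tolerance = 1e-10)
    expect_equal(sum(vip$vip^2), nrow(vip), tolerance = 1e-8)
    expect_true(all(vip$vip >= 0))
  }
})

test_that("single-component VIP equals the closed form sqrt(p)*|w|/||w||", {
  sim <- small_sim(seed = 52L)
  prep <- pls_prepare(sim$panel, sim$phenotypes)
  fit <- fit_pls(prep, A = 1)
  vip <- compute_vip(fit)
  w <- fit$W[, 1]
  oracle <- sqrt(length(w)) * abs(w) / sqrt(sum(w^2))
  expect_equal(vip$vip, unname(oracle), tolerance = 1e-10)
  # and VIP ranking equals |w| ranking exactly
  expect_identical(order(-vip$vip), order(-abs(vip$weight)))
})

test_that("equal-magnitude weights give VIP exactly one everywhere", {
  # three perfectly collinear signed copies of one vector: |w| identical
  set.seed(53)
  v <- rnorm(12)
  X <- cbind(v, -v, v)
  y <- rbinom(12, 1, 0.5)
  while (sd(y) == 0 || abs(cor(v, y)) < 1e-8) y <- rbinom(12, 1, 0.5)
  fit <- fit_nipals(X, y, A = 1)
  vip <- compute_vip(fit)
  expect_equal(vip$vip, rep(1, 3), tolerance = 1e-10)
})

test_that("VIP is invariant to a global sign flip of a component", {
  set.seed(54)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- rbinom(30, 1, 0.4)
  fit <- fit_nipals(X, y, A = 2)
  vip <- compute_vip(fit)
  flipped <- fit
  flipped$W[, 2] <- -flipped$W[, 2]
  flipped$q[2] <- -flipped$q[2]
  flipped$T[, 2] <- -flipped$T[, 2]
  expect_equal(compute_vip(flipped)$vip, vip$vip, tolerance = 1e-12)
})

test_that("the covariate is fitted but excluded from ranking and normalization", {
  sim <- small_sim(seed = 55L)
  prep <- pls_prepare(sim$panel, sim$phenotypes, include_diagnosis_covariate = TRUE)
  fit <- fit_pls(prep, A = 1)
  vip <- compute_vip(fit)
  expect_false("diagnosis" %in% vip$score_id)
  expect_identical(nrow(vip), ncol(sim$panel$matrix))
  expect_equal(mean(vip$vip^2), 1, tolerance = 1e-10)  # identity over ranked set only
})

test_that("ranking and strict selection behave at the boundary and under ties", {
  tab <- data.frame(
    score_id = c("s1", "s2", "s3", "s4"),
    phenotype = paste0("ph", 1:4), category = "psychiatric",
    weight = c(0.5, -0.7, 0.7, 0.1),
    vip = c(1.0, 1.4, 1.4, 0.2))
  class(tab) <- c("vip_table", "data.frame")
  out <- rank_and_select(tab, threshold = 1.0)
  expect_identical(out$rank, 1:4)
  # tie at vip 1.4 broken by |weight| desc then score_id: s2 and s3 tie on both
  expect_identical(out$score_id[1:2], c("s2", "s3"))
  expect_identical(out$selected, c(TRUE, TRUE, FALSE, FALSE))  # vip == 1 not selected
  expect_identical(out$direction, c("negative", "positive", "positive", "positive"))

  all_small <- tab
  all_small$vip <- c(0.4, 0.3, 0.2, 0.1)
  out2 <- rank_and_select(all_small)
  expect_identical(sum(out2$selected), 0L)
  expect_identical(out2$rank, 1:4)
})

test_that("category summaries match a hand tally on a toy table", {
  tab <- data.frame(
    score_id = sprintf("s%02d", 1:12),
    phenotype = sprintf("ph%02d", 1:12),
    category = rep(c("psychiatric", "hormone_pregnancy", "immune_inflammation"), each = 4),
    weight = c(0.3, -0.2, 0.1, -0.4,   0.5, 0.2, -0.1, -0.3,   0.2, -0.2, 0.4, 0.1),
    vip = c(1.5, 1.2, 0.8, 0.3,   2.0, 0.4, 1.1, 0.9,   0.2, 1.3, 1.4, 0.5))
  class(tab) <- c("vip_table", "data.frame")
  out <- summarize_categories(rank_and_select(tab))
  out <- out[order(out$category), ]
  # hand tally: psychiatric sel {s1+,s2-}; hormone sel {s5+,s7-}; immune sel {s10-,s11+}
  expect_identical(out$n_selected, c(2L, 2L, 2L))
  expect_identical(out$n_positive[out$category == "psychiatric"], 1L)
  expect_identical(out$n_negative[out$category == "hormone_pregnancy"], 1L)
  expect_equal(out$prop_included, rep(0.5, 3))
  expect_equal(out$n_selected, out$n_positive + out$n_negative)

  none <- tab; none$vip <- 0.1
  out0 <- summarize_categories(rank_and_select(none))
  expect_true(all(out0$n_selected == 0L))
  expect_true(all(out0$percent_included == 0))
})

test_that("causal phenotypes outrank null phenotypes in planted-signal panels", {
  wins <- logical(5)
  for (s in 1:5) {
    sim <- generate_panel(sim_config(seed = 60L + s))
    prep <- pls_prepare(sim$panel, sim$phenotypes)
    vip <- rank_and_select(compute_vip(fit_pls(prep, A = 1)))
    causal <- names(sim$truth$true_effect_vector)[sim$truth$true_effect_vector != 0]
    wins[s] <- mean(vip$rank[vip$score_id %in% causal]) <
      mean(vip$rank[!vip$score_id %in% causal])
  }
  expect_true(all(wins))
})
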