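# deterministic toy problems built from labelled symmetric matrices

toy_matrix <- function(labels, fill) {
  k <- length(labels)
  m <- matrix(0, k, k, dimnames = list(labels, labels))
  m[lower.tri(m)] <- fill
  pairwise_matrix(m + t(m))
}

toy_problem <- function(k = 4, beta = 2, noise = 0, seed = 1, weights = NULL) {
  set.seed(seed)
  labels <- paste0("s", seq_len(k))
  np <- k * (k - 1) / 2
  x <- runif(np, 1, 10)
  y <- 0.5 + beta * x + rnorm(np, sd = noise)
  matrix_regression_problem(toy_matrix(labels, y),
                            list(x = toy_matrix(labels, x)),
                            weights)
}

test_that("vectorize unrolls k(k-1)/2 pairs with n_i + n_j weights", {
  prob <- toy_problem(k = 4)
  v <- vectorize_problem(prob)
  expect_equal(length(v$y), 6L)
  expect_equal(nrow(v$pairs), 6L)
  # weights from per-site sample sizes: 13 + 21 = 34
  ds <- make_ds(list(Namakia = lapply(1:13, function(i) list(c(1, 2))),
                     Marambitsy = lapply(1:21, function(i) list(c(1, 2)))))
  w <- pair_weights(ds)
  expect_equal(w["Namakia", "Marambitsy"], 34)
  expect_equal(pair_weights(ds, combine = "min")["Namakia", "Marambitsy"], 13)
})

test_that("relabelling populations leaves fitted coefficients unchanged", {
  prob <- toy_problem(k = 5, noise = 0.3)
  fit1 <- wls_fit(vectorize_problem(prob)$y, vectorize_problem(prob)$X,
                  vectorize_problem(prob)$w)
  perm <- c(3, 1, 5, 2, 4)
  relab <- matrix_regression_problem(
    pairwise_matrix(unclass(prob$response)[perm, perm]),
    list(x = pairwise_matrix(unclass(prob$predictors$x)[perm, perm])))
  v2 <- vectorize_problem(relab)
  fit2 <- wls_fit(v2$y, v2$X, v2$w)
  expect_equal(fit2$coefficients, fit1$coefficients, tolerance = 1e-10)
})

test_that("weighted least squares recovers exact fits and matches lm", {
  prob <- toy_problem(k = 5, beta = 3, noise = 0)
  v <- vectorize_problem(prob)
  fit <- wls_fit(v$y, v$X, v$w)
  expect_equal(unname(fit$coefficients["x"]), 3, tolerance = 1e-10)
  expect_lt(fit$rss_w, 1e-18)
  # equal weights reduce to OLS
  prob2 <- toy_problem(k = 6, beta = 1.5, noise = 0.4, seed = 2)
  v2 <- vectorize_problem(prob2)
  fit2 <- wls_fit(v2$y, v2$X, v2$w)
  ref <- lm(v2$y ~ v2$X)
  expect_equal(unname(fit2$coefficients), unname(coef(ref)), tolerance = 1e-10)
  # against lm with non-trivial weights
  w <- seq_along(v2$y)
  fit3 <- wls_fit(v2$y, v2$X, w)
  ref3 <- lm(v2$y ~ v2$X, weights = w)
  expect_equal(unname(fit3$coefficients), unname(coef(ref3)), tolerance = 1e-10)
  # duplicated predictor column is a rank error naming the column
  expect_error(wls_fit(v2$y, cbind(x = v2$X[, 1], dup = v2$X[, 1]), w),
               "collinear")
})

test_that("AICc prefers parsimony and guards its preconditions", {
  expect_lt(aicc(1.7, 10, 2), aicc(1.7, 10, 3))
  expect_error(aicc(1, 4, 3), "exceed")
  expect_warning(out <- aicc(0, 10, 2), "saturated")
  expect_true(is.na(out))
  # weight rescaling leaves AICc differences unchanged (mean-1 normalisation)
  prob <- toy_problem(k = 6, noise = 0.5, seed = 3)
  v <- vectorize_problem(prob)
  a1 <- sapply(list(v$w, v$w * 50), function(w) {
    f0 <- popcompare:::fit_model_aicc(
      matrix_regression_problem(prob$response, prob$predictors,
                                toy_matrix(prob$labels, w)), "x")
    f0$aicc
  })
  expect_equal(a1[1], a1[2], tolerance = 1e-10)
})

test_that("Akaike weights follow exp(-delta/2) normalisation", {
  w <- popcompare:::akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(w[1] / w[2], exp(1), tolerance = 1e-12)
  expect_equal(popcompare:::akaike_weights(c(10, 10)), c(0.5, 0.5))
  set.seed(4)
  ws <- popcompare:::akaike_weights(runif(7, 50, 80))
  expect_equal(sum(ws), 1, tolerance = 1e-12)
})

test_that("exhaustive permutation p is exact for a perfectly matching predictor", {
  prob <- toy_problem(k = 5, beta = 1, noise = 0, seed = 6)
  p_ex <- permutation_test(prob, "x", B = 0, exhaustive = TRUE)
  # identity (and any tying relabelling) over 120 permutations
  expect_gte(p_ex, 1 / 120)
  expect_lte(p_ex, 5 / 120)
})

test_that("Monte Carlo permutation p agrees with exhaustive enumeration", {
  set.seed(31)
  for (s in c(2, 9)) {
    prob <- toy_problem(k = 6, beta = 0.4, noise = 1.5, seed = s)
    p_ex <- permutation_test(prob, "x", exhaustive = TRUE)
    B <- 2000
    p_mc <- permutation_test(prob, "x", B = B, seed = s)
    se <- sqrt(p_ex * (1 - p_ex) / B)
    expect_lt(abs(p_mc - p_ex), 3 * se + 2 / B)
  }
})

test_that("null responses give well-spread permutation p-values", {
  set.seed(40)
  ps <- vapply(1:30, function(r) {
    labels <- paste0("s", 1:6)
    y <- toy_matrix(labels, rnorm(15))
    x <- toy_matrix(labels, runif(15))
    permutation_test(matrix_regression_problem(y, list(x = x)), "x",
                     B = 99, seed = r)
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_gt(mean(ps <= 0.05), -0.01)
  expect_lt(mean(ps <= 0.05), 0.2)
})

test_that("a constant focal predictor yields NA with a warning", {
  labels <- paste0("s", 1:5)
  y <- toy_matrix(labels, rnorm(10))
  x <- toy_matrix(labels, rep(2, 10))
  expect_warning(
    p <- permutation_test(matrix_regression_problem(y, list(x = x)), "x",
                          B = 99),
    "constant")
  expect_true(is.na(p))
})

test_that("model averaging weights, betas and SEs are coherent", {
  set.seed(50)
  labels <- paste0("s", 1:7)
  np <- 21
  x1 <- runif(np, 0, 5); x2 <- runif(np, 0, 5)
  y <- 1 + 0.8 * x1 + rnorm(np, sd = 0.6)
  prob <- matrix_regression_problem(
    toy_matrix(labels, y),
    list(x1 = toy_matrix(labels, x1), x2 = toy_matrix(labels, x2)))
  res <- model_average(prob, B = 199, seed = 3)
  expect_equal(sum(res$models$weight), 1, tolerance = 1e-12)
  expect_equal(nrow(res$models), 4L)  # intercept-only + 3 subsets
  expect_equal(sort(res$predictors$predictor), c("x1", "x2"))
  # informative predictor dominates
  w1 <- res$predictors$total_weight[res$predictors$predictor == "x1"]
  w2 <- res$predictors$total_weight[res$predictors$predictor == "x2"]
  expect_gt(w1, w2)
  # conditional averaged beta lies within the per-model betas' range
  b_models <- vapply(c("x1", "x1 + x2"), function(m) {
    f <- popcompare:::fit_model_aicc(prob, strsplit(m, " \\+ ")[[1]])
    f$fit$coefficients[["x1"]]
  }, numeric(1))
  b_avg <- res$predictors$beta[res$predictors$predictor == "x1"]
  expect_gte(b_avg, min(b_models) - 1e-9)
  expect_lte(b_avg, max(b_models) + 1e-9)
  # z and two-sided normal p are consistent
  row1 <- res$predictors[res$predictors$predictor == "x1", ]
  expect_equal(row1$p_value, 2 * pnorm(-row1$z), tolerance = 1e-12)
  # diagnostics exist for the best model
  expect_true(is.numeric(res$diagnostics$W))
})

test_that("Shapiro-Wilk diagnostics calibrate on normal and bimodal residuals", {
  set.seed(60)
  ok <- 0
  for (r in 1:100) {
    fit <- list(residuals = rnorm(50), w_norm = rep(1, 50))
    if (residual_normality(fit)$p_value > 0.05) ok <- ok + 1
  }
  expect_gte(ok, 90)
  bad <- 0
  for (r in 1:20) {
    fit <- list(residuals = c(rnorm(25, -4, 0.3), rnorm(25, 4, 0.3)),
                w_norm = rep(1, 50))
    if (residual_normality(fit)$p_value < 0.05) bad <- bad + 1
  }
  expect_gte(bad, 18)
  expect_error(residual_normality(list(residuals = rnorm(2), w_norm = c(1, 1))),
               "at least 3")
  expect_true(is.na(residual_normality(
    list(residuals = rep(1, 10), w_norm = rep(1, 10)))$W))
})

test_that("listwise NA handling drops pairs and errors when unidentifiable", {
  labels <- paste0("s", 1:4)
  y <- unclass(toy_matrix(labels, rnorm(6)))
  y[2, 1] <- y[1, 2] <- NA
  prob <- matrix_regression_problem(pairwise_matrix(y),
                                    list(x = toy_matrix(labels, runif(6))))
  v <- vectorize_problem(prob)
  expect_equal(length(v$y), 5L)
  expect_equal(attr(v, "n_dropped"), 1L)
  y2 <- unclass(toy_matrix(labels, rnorm(6)))
  y2[lower.tri(y2)][1:4] <- NA
  y2[upper.tri(y2)] <- t(y2)[upper.tri(y2)]
  prob2 <- matrix_regression_problem(pairwise_matrix(y2),
                                     list(x = toy_matrix(labels, runif(6))))
  expect_error(vectorize_problem(prob2), "unidentifiable")
})
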