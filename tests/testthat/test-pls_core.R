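test_that("exact low-rank case: one latent variable fits a rank-1 response", {
  set.seed(1)
  X <- tcrossprod(rnorm(8), rnorm(5))
  y <- drop(X %*% c(1, -2, 0.5, 3, 1))
  m <- fit_pls(X, y, 1)
  expect_lt(rmse(y, predict(m, X)), 1e-10)
})

test_that("maximal-LV PLS equals ordinary least squares at full rank", {
  set.seed(2)
  X <- matrix(rnorm(40), 8, 5)
  y <- rnorm(8)
  m <- fit_pls(X, y, 5)
  b_ols <- ols_coef(X, y)
  expect_equal(drop(X %*% b_ols), predict(m, X), tolerance = 1e-8)
})

test_that("NIPALS predictions match the independent Krylov-subspace oracle", {
  set.seed(3)
  for (i in 1:10) {
    X <- matrix(rnorm(200), 10, 20)
    y <- rnorm(10)
    Xnew <- matrix(rnorm(100), 5, 20)
    m <- fit_pls(X, y, 3)
    for (a in 1:3) {
      b <- krylov_pls_coef(X, y, a)
      expect_equal(drop(Xnew %*% b), predict(m, Xnew, n_lv = a),
                   tolerance = 1e-8)
    }
  }
})

test_that("score orthogonality and b-versus-deflation equivalence hold", {
  set.seed(4)
  for (i in 1:100) {
    n <- sample(6:15, 1); p <- sample(3:25, 1)
    a <- min(n - 1, p, 4)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    m <- fit_pls(X, y, a)
    G <- crossprod(m$scores)
    off <- G - diag(diag(G), a)
    expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
    # regression-vector predictions == sequential deflation predictions
    for (k in seq_len(a))
      expect_equal(drop(X %*% m$B[, k]),
                   drop(m$scores[, 1:k, drop = FALSE] %*% m$y_loadings[1:k]),
                   tolerance = 1e-10)
  }
})

test_that("training RMSE is non-increasing in the number of latent variables", {
  set.seed(5)
  X <- matrix(rnorm(120), 12, 10)
  y <- rnorm(12)
  m <- fit_pls(X, y, 6)
  rmsec <- vapply(1:6, function(a) rmse(y, drop(X %*% m$B[, a])), numeric(1))
  expect_true(all(diff(rmsec) <= 1e-12))
})

test_that("fit_pls input validation", {
  X <- matrix(rnorm(20), 5, 4)
  expect_error(fit_pls(X, rnorm(5), 5), class = "naquant_rank_error")
  expect_error(fit_pls(X, rep(0, 5), 1),
               class = "naquant_degenerate_response_error")
  m <- fit_pls(X, rnorm(5), 2)
  expect_error(predict(m, matrix(rnorm(10), 2, 5)),
               class = "naquant_alignment_error")
  # duplicated rows predict identically; calibration rows reproduce fit
  expect_equal(predict(m, X[c(2, 2), ]), rep(predict(m, X)[2], 2))
})

test_that("metrics reduce to their closed forms", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  set.seed(6)
  y <- rnorm(20); yh <- y + rnorm(20)
  expect_equal(pearson_r(y, 2.5 * yh + 3), pearson_r(y, yh))
  expect_error(pearson_r(c(1, 1), c(1, 2)),
               class = "naquant_undefined_correlation_error")
})

test_that("Monte-Carlo CV: determinism, rank-1 selection, skipped orders", {
  set.seed(7)
  t_vec <- rnorm(9)
  X <- tcrossprod(t_vec, rnorm(6)) + 5
  y <- 2 * t_vec + 10
  cv <- cross_validate(X, y, lv_grid = 1:4, leave_out = 3, n_splits = 25,
                       seed = 42)
  expect_equal(cv$chosen_lv, 1L)
  expect_lt(cv$rmsecv, 1e-8)
  expect_true(all(cv$skipped[c("2", "3", "4")] > 0))  # rank truncation
  cv2 <- cross_validate(X, y, lv_grid = 1:4, leave_out = 3, n_splits = 25,
                        seed = 42)
  expect_identical(cv, cv2)
  expect_error(cross_validate(X, y, leave_out = 9, seed = 1),
               class = "naquant_domain_error")
})

test_that("exhaustive leave-one-out matches the brute-force oracle (6x4)", {
  set.seed(8)
  X <- matrix(rnorm(24), 6, 4)
  y <- drop(X %*% c(1, 2, -1, 0.5)) + rnorm(6, sd = 0.2)
  cv <- cross_validate(X, y, lv_grid = 1:3, exhaustive = TRUE)
  oracle <- loo_rmsecv_oracle(X, y, 1:3)
  expect_equal(unname(cv$rmsecv_by_lv), oracle, tolerance = 1e-8)
  expect_equal(cv$n_splits, 6L)
})
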