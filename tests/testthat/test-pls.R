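test_that("a noiseless rank-1 relation is fully explained by one LV", {
  set.seed(41)
  x <- rnorm(20)
  X <- cbind(g = x)
  Y <- cbind(m1 = 2 * x)
  fit <- fit_pls(X, Y, ncomp = 1)
  expect_equal(unname(fit$explained_y), 100, tolerance = 1e-10)
  expect_equal(predict(fit, X), Y, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("at full rank with n > p, PLS equals ordinary least squares", {
  set.seed(42)
  for (i in 1:3) {
    n <- 40; p <- sample(3:6, 1); m <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    Y <- X %*% matrix(rnorm(p * m), p, m) + matrix(rnorm(n * m), n, m)
    fit <- fit_pls(X, Y, ncomp = p)
    expect_equal(matrix(fit$coefficients[, , p], p, m),
                 unname(oracle_ols(X, Y)), tolerance = 1e-8)
    # and predictions equal lm fitted values
    ols_fit <- lm(Y ~ X)
    expect_equal(unname(predict(fit, X)), unname(as.matrix(fitted(ols_fit))),
                 tolerance = 1e-8)
  }
})

test_that("for univariate Y the first weight is the max-covariance direction", {
  set.seed(43)
  X <- matrix(rnorm(50 * 8), 50, 8)
  y <- X %*% rnorm(8) + rnorm(50)
  fit <- fit_pls(X, cbind(y), ncomp = 3)
  w_closed <- crossprod(scale(X), scale(y))
  w_closed <- w_closed / sqrt(sum(w_closed^2))
  cosine <- abs(sum(fit$x_weights[, 1] * w_closed))
  expect_equal(cosine, 1, tolerance = 1e-8)
})

test_that("scores are orthogonal and the factor model reconstructs X", {
  set.seed(44)
  for (shape in list(c(30, 8, 3), c(10, 25, 4))) {  # includes n < p
    n <- shape[1]; p <- shape[2]; m <- shape[3]
    X <- matrix(rnorm(n * p), n, p)
    Y <- matrix(rnorm(n * m), n, m) + X[, 1:m]
    A <- min(n - 1, p, 6)
    fit <- fit_pls(X, Y, ncomp = A)
    Tm <- fit$x_scores
    G <- crossprod(Tm)
    expect_lt(max(abs(G[upper.tri(G)])) /
                max(sqrt(diag(G) %o% diag(G))[upper.tri(G)]), 1e-8)
    # X_centered = T P' + F
    Xc <- scale(X)
    recon <- tcrossprod(Tm, fit$x_loadings) + fit$x_residuals
    expect_lt(norm(Xc - recon, "F") / norm(Xc, "F"), 1e-8)
    # deflation: residual X has no covariance left with any score
    expect_lt(max(abs(crossprod(fit$x_residuals, Tm))), 1e-8)
    # fitted Y from B equals fitted Y from T and Q
    expect_equal(tcrossprod(Tm, fit$y_loadings),
                 scale(X) %*% fit$coefficients[, , A], tolerance = 1e-8,
                 ignore_attr = TRUE)
    # explained variance profiles: non-decreasing, bounded by 100
    expect_true(all(diff(fit$explained_x) >= -1e-10))
    expect_true(all(diff(fit$explained_y) >= -1e-10))
    expect_lte(max(fit$explained_x, fit$explained_y), 100 + 1e-8)
  }
})

test_that("scaling off on standardized data equals scaling on raw data", {
  set.seed(45)
  X <- matrix(rnorm(30 * 5), 30, 5) %*% diag(c(1, 10, 0.1, 5, 2))
  Y <- matrix(rnorm(30 * 2), 30, 2) %*% diag(c(3, 0.5)) + X[, 1:2]
  f_raw <- fit_pls(X, Y, ncomp = 3, scale = TRUE)
  f_std <- fit_pls(scale(X), scale(Y), ncomp = 3, scale = FALSE)
  # coefficients live on the standardized scale in both fits
  expect_equal(f_raw$coefficients, f_std$coefficients, tolerance = 1e-8,
               ignore_attr = TRUE)
  # predictions agree after mapping back
  pr_raw <- predict(f_raw, X)
  pr_std <- sweep(sweep(predict(f_std, scale(X)), 2, apply(Y, 2, sd), "*"),
                  2, colMeans(Y), "+")
  expect_equal(pr_raw, pr_std, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("prediction input is validated and ncomp = 0 is the mean baseline", {
  set.seed(46)
  X <- matrix(rnorm(20 * 4), 20, 4,
              dimnames = list(NULL, paste0("g", 1:4)))
  Y <- matrix(rnorm(20 * 2), 20, 2)
  fit <- fit_pls(X, Y, ncomp = 2)
  base <- predict(fit, X, ncomp = 0)
  expect_equal(base, matrix(colMeans(Y), 20, 2, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  Xbad <- X[, 1:3]
  expect_error(predict(fit, Xbad), "missing: g4")
  colnames(Xbad) <- c("g1", "g2", "h9")
  expect_error(predict(fit, Xbad), "extra: h9")
  # reordered columns are accepted (matched by name)
  expect_equal(predict(fit, X[, c(3, 1, 4, 2)]), predict(fit, X),
               tolerance = 1e-12)
})

test_that("fit preconditions produce the documented hard errors", {
  set.seed(47)
  X <- matrix(rnorm(15 * 4), 15, 4)
  Y <- cbind(a = rnorm(15), b = rep(1, 15))
  expect_error(fit_pls(X, Y, ncomp = 2), "zero-variance response.*b")
  expect_error(fit_pls(X, cbind(rnorm(15)), ncomp = 5), "ncomp must be in")
  expect_error(fit_pls(X, cbind(rnorm(10)), ncomp = 2), "same number")
})

test_that("LOO cross-validation equals brute-force refits on a small fixture", {
  set.seed(48)
  n <- 6
  X <- matrix(rnorm(n * 3), n, 3)
  Y <- cbind(X %*% c(1, -1, 0.5) + rnorm(n, sd = 0.2), rnorm(n))
  cv <- cross_validate(X, Y, max_ncomp = 2, scheme = "loo")
  press <- matrix(0, 2, 3)
  for (i in seq_len(n)) {
    fit <- fit_pls(X[-i, ], Y[-i, ], ncomp = 2)
    for (a in 0:2) {
      pred <- predict(fit, X[i, , drop = FALSE], ncomp = a)
      press[, a + 1] <- press[, a + 1] + as.numeric((pred - Y[i, ])^2)
    }
  }
  expect_equal(unname(cv$rmsep), sqrt(press / n), tolerance = 1e-10)
  expect_equal(cv$msep, cv$rmsep^2, tolerance = 1e-12)
  # 0-component RMSEP is the cross-validated sd of the centered response
  loo_means <- sapply(seq_len(n), function(i) colMeans(Y[-i, , drop = FALSE]))
  expect_equal(unname(cv$rmsep[, 1]),
               sqrt(colMeans((Y - t(loo_means))^2)), tolerance = 1e-12)
})

test_that("pure-noise responses gain nothing from added components", {
  set.seed(49)
  curves <- replicate(5, {
    X <- matrix(rnorm(25 * 5), 25, 5)
    Y <- matrix(rnorm(25 * 2), 25, 2)
    colMeans(cross_validate(X, Y, max_ncomp = 4, scheme = "loo")$rmsep)
  })
  avg <- rowMeans(curves)
  # beyond 0 components the average error never dips below the baseline
  expect_true(all(avg[-1] >= avg[1] * 0.98))
})

test_that("k-fold needs a seed and is reproducible given one", {
  set.seed(50)
  X <- matrix(rnorm(30 * 4), 30, 4)
  Y <- cbind(X %*% rnorm(4) + rnorm(30))
  expect_error(cross_validate(X, Y, 2, scheme = "kfold", k = 5),
               "explicit seed")
  cv1 <- cross_validate(X, Y, 2, scheme = "kfold", k = 5, seed = 9)
  cv2 <- cross_validate(X, Y, 2, scheme = "kfold", k = 5, seed = 9)
  expect_identical(cv1$rmsep, cv2$rmsep)
  expect_match(cv1$scheme, "KFOLD\\(k=5, seed=9\\)")
  # r2 grows toward 1 for a strongly predictable response
  expect_gt(cv1$r2[1, 3], 0.8)
})
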