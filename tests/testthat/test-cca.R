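random_cca_fit <- function(n, p, q, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(rnorm(n * q), n, q)
  suppressWarnings(fit_cca(X, Y))
}

test_that("with one variable per set the canonical correlation is |Pearson r|", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(30); y <- 0.5 * x * sign(rnorm(1)) + rnorm(30)
    res <- suppressWarnings(fit_cca(cbind(x), cbind(y)))
    expect_equal(res$correlations, abs(cor(x, y)), tolerance = 1e-12)
  }
})

test_that("canonical correlations are invariant to invertible affine maps", {
  set.seed(22)
  X <- matrix(rnorm(100 * 3), 100, 3)
  Y <- X[, c(2, 3, 1)] %*% diag(c(2, -0.5, 10)) + 3
  res <- suppressWarnings(fit_cca(X, Y))
  expect_equal(res$correlations, rep(1, 3), tolerance = 1e-8)

  # and to separate affine transforms of each set
  Y2 <- matrix(rnorm(100 * 3), 100, 3) + 0.6 * X
  base <- suppressWarnings(fit_cca(X, Y2))$correlations
  Tx <- matrix(rnorm(9), 3, 3) + 3 * diag(3)
  Ty <- matrix(rnorm(9), 3, 3) + 3 * diag(3)
  tr <- suppressWarnings(
    fit_cca(X %*% Tx + 7, Y2 %*% Ty - 2))$correlations
  expect_equal(base, tr, tolerance = 1e-8)
})

test_that("fit matches the brute-force alternating maximizer", {
  set.seed(23)
  for (p in 2:4) {
    X <- matrix(rnorm(200 * p), 200, p)
    Y <- matrix(rnorm(200 * p), 200, p) + 0.4 * X
    res <- fit_cca(X, Y)
    expect_equal(res$correlations, oracle_cca(X, Y, p), tolerance = 1e-6)
  }
})

test_that("fit agrees with the QR-based reference implementation", {
  set.seed(24)
  X <- matrix(rnorm(150 * 4), 150, 4)
  Y <- matrix(rnorm(150 * 3), 150, 3) + 0.3 * X[, 1:3]
  res <- fit_cca(X, Y)
  expect_equal(res$correlations, cancor(scale(X), scale(Y))$cor,
               tolerance = 1e-10)
})

test_that("variates are unit variance, internally and cross uncorrelated", {
  res <- random_cca_fit(120, 4, 3, seed = 25)
  for (M in list(res$x_variates, res$y_variates)) {
    expect_equal(apply(M, 2, sd), rep(1, ncol(M)), tolerance = 1e-10,
                 ignore_attr = TRUE)
    C <- cor(M)
    expect_lt(max(abs(C[upper.tri(C)])), 1e-8)
  }
  Cuv <- cor(res$x_variates, res$y_variates)
  expect_equal(diag(Cuv), res$correlations, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_lt(max(abs(Cuv[row(Cuv) != col(Cuv)])), 1e-8)
  # correlations sorted, in [0, 1]
  expect_true(all(diff(res$correlations) <= 1e-12))
  expect_true(all(res$correlations >= 0 & res$correlations <= 1))
})

test_that("loadings, adequacies and communalities behave as variance shares", {
  res <- random_cca_fit(90, 3, 3, seed = 26)
  set.seed(26); X <- matrix(rnorm(90 * 3), 90, 3)
  # squared loading = R^2 of the standardized variable on the variate
  for (j in 1:3) for (i in 1:3) {
    r2 <- summary(lm(scale(X[, j]) ~ res$x_variates[, i]))$r.squared
    expect_equal(res$x_loadings[j, i]^2, r2, tolerance = 1e-10)
  }
  expect_equal(res$x_adequacies, colMeans(res$x_loadings^2), tolerance = 1e-12)
  expect_true(all(res$x_adequacies >= 0 & res$x_adequacies <= 1))
  expect_true(all(res$y_adequacies >= 0 & res$y_adequacies <= 1))
  # with k = min(p, q) = p the X communalities sum squared loadings to <= 1
  expect_true(all(res$x_communalities >= 0 & res$x_communalities <= 1 + 1e-10))
})

test_that("redundancy equals r^2 times the opposite-set adequacy, exactly", {
  res <- random_cca_fit(80, 4, 2, seed = 27)
  rd <- res$redundancies
  y_given_x <- rd$redundancy[rd$direction == "Y_given_X"]
  x_given_y <- rd$redundancy[rd$direction == "X_given_Y"]
  expect_equal(y_given_x, res$correlations^2 * colMeans(res$y_loadings^2),
               tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(x_given_y, res$correlations^2 * colMeans(res$x_loadings^2),
               tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("the sign convention makes the dominant X loading positive", {
  res <- random_cca_fit(100, 5, 4, seed = 28)
  for (i in seq_len(res$k))
    expect_gt(res$x_loadings[which.max(abs(res$x_loadings[, i])), i], 0)
})

test_that("Bartlett table: closed-form value, df rule and null identity", {
  tab <- bartlett_test(0.5, n = 20, p = 1, q = 1)
  expect_equal(tab$chi_squared, -17.5 * log(0.75), tolerance = 1e-12)
  expect_equal(tab$chi_squared, 5.034, tolerance = 1e-3)
  expect_identical(tab$df, 1)
  expect_equal(tab$p_value, pchisq(-17.5 * log(0.75), 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(tab$p_value, 4), 0.0248)

  null_tab <- bartlett_test(c(0, 0), n = 50, p = 3, q = 2)
  expect_equal(null_tab$chi_squared, c(0, 0))
  expect_equal(null_tab$p_value, c(1, 1))
  # df_i = (p - i + 1)(q - i + 1)
  expect_equal(null_tab$df, c(6, 2))

  expect_error(bartlett_test(1, 20, 1, 1), "\\[0, 1\\)")
  expect_error(bartlett_test(-0.1, 20, 1, 1), "\\[0, 1\\)")
  expect_error(bartlett_test(0.5, 3, 2, 2), "multiplier")
})

test_that("a fit embeds the Bartlett table with matching df layout", {
  res <- random_cca_fit(100, 4, 3, seed = 29)
  expect_equal(nrow(res$bartlett), 3L)
  expect_equal(res$bartlett$df, (4 - 1:3 + 1) * (3 - 1:3 + 1))
  man <- bartlett_test(res$correlations, res$n, res$p, res$q)
  expect_equal(res$bartlett$chi_squared, man$chi_squared, tolerance = 1e-12)
})

test_that("degenerate inputs trigger the documented errors and warnings", {
  set.seed(30)
  X <- matrix(rnorm(30 * 3), 30, 3)
  # duplicated column within a set -> singular, advising the prune step
  expect_error(suppressWarnings(fit_cca(cbind(X, X[, 1]), X)),
               "prune_correlated")
  # n too small
  expect_error(fit_cca(matrix(rnorm(4 * 3), 4, 3), matrix(rnorm(4 * 2), 4, 2)),
               "too few samples")
  # sample-size guideline is a warning, not an error
  expect_warning(fit_cca(X, matrix(rnorm(30 * 2), 30, 2)), "guideline")
  # mismatched sample count
  expect_error(fit_cca(X, matrix(rnorm(20 * 2), 20, 2)), "same number")
})

test_that("helio tables expose one loading per variable with positions", {
  res <- random_cca_fit(100, 4, 3, seed = 31)
  h <- helio_data(res, 1)
  expect_equal(nrow(h), res$p + res$q)
  expect_identical(h$set, rep(c("X", "Y"), c(4, 3)))
  expect_true(all(h$loading >= -1 & h$loading <= 1))
  expect_true(all(diff(h$angle_deg) > 0) && max(h$angle_deg) < 360)
  # loadings match direct correlation of each column with the variate
  set.seed(31); X <- matrix(rnorm(100 * 4), 100, 4)
  expect_equal(h$loading[1:4], unname(cor(X, res$x_variates[, 1])[, 1]),
               tolerance = 1e-10)
  expect_error(helio_data(res, 5), "cv_index")

  # a variable collinear with u_1 shows loading ~1 after the sign convention:
  # with Y essentially a copy of X1, u_1 is X1 itself
  Y1 <- cbind(X[, 1] + rnorm(100, sd = 1e-6))
  res2 <- fit_cca(X, Y1)
  h2 <- helio_data(res2, 1)
  expect_equal(h2$loading[1], 1, tolerance = 1e-6)  # X1 is the first row
})
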