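# Symmetric inverse square root of a correlation matrix; errors when the
# matrix is numerically singular (collinear columns survived pruning).
inv_sqrt_corr <- function(R, label) {
  e <- eigen(R, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  if (min(e$values) < tol)
    stop("within-set correlation matrix of ", label, " is singular or nearly ",
         "singular; remove collinear features first (see prune_correlated)",
         call. = FALSE)
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

# Bartlett table; tolerates r == 1 (Lambda = 0 => chi2 = Inf, p = 0) so that
# degenerate-but-valid fits (e.g. Y an invertible map of X) still report.
bartlett_table <- function(correlations, n, p, q) {
  r <- as.numeric(correlations)
  k <- length(r)
  mult <- n - 1 - (p + q + 1) / 2
  lam <- rev(cumprod(rev(1 - r^2)))        # Lambda_i = prod_{j>=i}(1 - r_j^2)
  chi2 <- -mult * log(lam)
  df <- (p - seq_len(k) + 1) * (q - seq_len(k) + 1)
  data.frame(index = seq_len(k), canonical_correlation = r,
             chi_squared = chi2, df = df,
             p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Bartlett's sequential chi-squared test for canonical correlations
#'
#' Tests, for each index \eqn{i}, the hypothesis that the \eqn{i}-th and all
#' later canonical correlations are zero. The classic statistic is used:
#' \deqn{\chi^2_i = -[n - 1 - (p + q + 1)/2]\,\ln \Lambda_i,\quad
#'       \Lambda_i = \prod_{j \ge i} (1 - r_j^2),}
#' with \eqn{(p - i + 1)(q - i + 1)} degrees of freedom and the p-value from
#' the upper tail.
#'
#' @param correlations canonical correlations, each in \[0, 1).
#' @param n number of samples; must exceed \eqn{(p + q + 3)/2} so the
#'   multiplier is positive.
#' @param p,q numbers of variables in the two sets.
#' @return data.frame with columns `index`, `canonical_correlation`,
#'   `chi_squared`, `df`, `p_value`.
#' @export
bartlett_test <- function(correlations, n, p, q) {
  r <- as.numeric(correlations)
  if (any(r < 0 | r >= 1))
    stop("every tested canonical correlation must lie in [0, 1)",
         call. = FALSE)
  if (n <= (p + q + 3) / 2)
    stop("n must exceed (p + q + 3)/2 for Bartlett's multiplier to be ",
         "positive", call. = FALSE)
  bartlett_table(r, n, p, q)
}

#' Canonical correlation analysis with full diagnostics
#'
#' Finds coefficient vectors \eqn{a_i, b_i} maximizing
#' \eqn{\mathrm{cor}(a_i'X,\, b_i'Y)} under the usual orthogonality
#' constraints, together with the diagnostic blocks used to interpret the
#' variates: structural loadings, adequacies, communalities, redundancies and
#' Bartlett's sequential significance table.
#'
#' Both sets are standardized (mean 0, sd 1) so the weights are comparable
#' across variables. Computation is by singular value decomposition of
#' \eqn{R_{xx}^{-1/2} R_{xy} R_{yy}^{-1/2}}, numerically symmetric in the two
#' sets. Signs are fixed so the largest-magnitude X-loading of each variate is
#' positive (the paired Y-side is flipped with it, keeping every canonical
#' correlation non-negative).
#'
#' Hard errors: mismatched samples, \eqn{n \le \max(p, q) + 1} (no residual
#' degrees of freedom), or a singular within-set correlation matrix (prune
#' first). A warning — not an error — is raised when \eqn{n < 20 \max(p, q)},
#' the usual sample-size guideline for a stable canonical solution.
#'
#' @param X,Y [omics_matrix()] objects or numeric matrices over the same
#'   samples in the same order (transcripts in `X`, metabolites in `Y`, by
#'   convention).
#' @return A `cca_result`: list with `k`, `correlations` (non-increasing, in
#'   \[0, 1\]), `x_weights` (`p x k`), `y_weights` (`q x k`), `x_variates`,
#'   `y_variates` (`n x k`, unit variance), `x_loadings`, `y_loadings`
#'   (structural correlations), `x_adequacies`, `y_adequacies`,
#'   `x_communalities`, `y_communalities`, `redundancies` (data.frame per
#'   variate and direction), `bartlett` (see [bartlett_test()]), `n`, `p`,
#'   `q`.
#' @export
fit_cca <- function(X, Y) {
  Xv <- as_values(X); Yv <- as_values(Y)
  if (nrow(Xv) != nrow(Yv))
    stop("X and Y must have the same number of samples", call. = FALSE)
  if (inherits(X, "omics_matrix") && inherits(Y, "omics_matrix") &&
      !identical(X$sample_ids, Y$sample_ids))
    stop("X and Y sample ids differ or are ordered differently", call. = FALSE)

  n <- nrow(Xv); p <- ncol(Xv); q <- ncol(Yv)
  if (n <= max(p, q) + 1)
    stop("too few samples for CCA: n = ", n, " but max(p, q) + 1 = ",
         max(p, q) + 1, call. = FALSE)
  if (n < 20 * max(p, q))
    warning("n = ", n, " is below the guideline of 20 samples per variable ",
            "(20 x max(p, q) = ", 20 * max(p, q), "); canonical weights may ",
            "be unstable", call. = FALSE)

  Zx <- scale(Xv); Zy <- scale(Yv)
  if (anyNA(Zx) || anyNA(Zy))
    stop("zero-variance column present; remove constant features first",
         call. = FALSE)
  Rxx <- stats::cor(Xv); Ryy <- stats::cor(Yv); Rxy <- stats::cor(Xv, Yv)
  Ex <- inv_sqrt_corr(Rxx, "X")
  Ey <- inv_sqrt_corr(Ryy, "Y")

  k <- min(p, q)
  sv <- svd(Ex %*% Rxy %*% Ey, nu = k, nv = k)
  r <- pmin(pmax(sv$d[seq_len(k)], 0), 1)
  A <- Ex %*% sv$u            # p x k, a' Rxx a = I
  B <- Ey %*% sv$v            # q x k

  U <- Zx %*% A               # unit-variance variates
  V <- Zy %*% B
  Lx <- stats::cor(Zx, U)
  Ly <- stats::cor(Zy, V)

  # sign convention: largest-|loading| X entry positive per variate
  for (i in seq_len(k)) {
    j <- which.max(abs(Lx[, i]))
    if (Lx[j, i] < 0) {
      A[, i] <- -A[, i]; U[, i] <- -U[, i]; Lx[, i] <- -Lx[, i]
      B[, i] <- -B[, i]; V[, i] <- -V[, i]; Ly[, i] <- -Ly[, i]
    }
  }

  cv <- paste0("CV", seq_len(k))
  dimnames(A) <- list(colnames(Xv), cv); dimnames(B) <- list(colnames(Yv), cv)
  dimnames(U) <- list(rownames(Xv), cv); dimnames(V) <- list(rownames(Yv), cv)
  dimnames(Lx) <- dimnames(A); dimnames(Ly) <- dimnames(B)

  adeq_x <- colMeans(Lx^2); adeq_y <- colMeans(Ly^2)
  redundancies <- data.frame(
    variate = rep(cv, 2L),
    direction = rep(c("Y_given_X", "X_given_Y"), each = k),
    redundancy = c(r^2 * adeq_y, r^2 * adeq_x),
    stringsAsFactors = FALSE)

  structure(
    list(k = k, correlations = r, x_weights = A, y_weights = B,
         x_variates = U, y_variates = V, x_loadings = Lx, y_loadings = Ly,
         x_adequacies = adeq_x, y_adequacies = adeq_y,
         x_communalities = rowSums(Lx^2), y_communalities = rowSums(Ly^2),
         redundancies = redundancies,
         bartlett = bartlett_table(r, n, p, q),
         n = n, p = p, q = q,
         notes = "Bartlett: classic multiplier -[n - 1 - (p + q + 1)/2], no Lawley correction"),
    class = "cca_result"
  )
}

#' @export
print.cca_result <- function(x, digits = 4, ...) {
  cat("Canonical correlation analysis: n = ", x$n, ", p = ", x$p, ", q = ",
      x$q, "\n", sep = "")
  tab <- x$bartlett
  tab$canonical_correlation <- round(tab$canonical_correlation, digits)
  tab$chi_squared <- round(tab$chi_squared, digits)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Helio-plot table for one canonical variate
#'
#' Returns the plot-ready data behind a helio plot: for the chosen variate,
#' the structural loading of every X and Y variable together with an angular
#' position around the circle (X block first, then Y, evenly spaced over 360
#' degrees). Positive loadings are drawn as bars pointing outward, negative
#' ones inward; the bar length is the loading magnitude.
#'
#' @param res a [fit_cca()] result.
#' @param cv_index which canonical variate, in `1..res$k`.
#' @return data.frame with columns `variable`, `set` (`"X"`/`"Y"`),
#'   `loading`, `angle_deg`.
#' @export
helio_data <- function(res, cv_index = 1L) {
  stopifnot(inherits(res, "cca_result"))
  if (cv_index < 1L || cv_index > res$k)
    stop("cv_index must be in 1..", res$k, call. = FALSE)
  loading <- c(res$x_loadings[, cv_index], res$y_loadings[, cv_index])
  m <- length(loading)
  data.frame(
    variable = c(rownames(res$x_loadings), rownames(res$y_loadings)),
    set = rep(c("X", "Y"), c(res$p, res$q)),
    loading = unname(loading),
    angle_deg = 360 * (seq_len(m) - 0.5) / m,
    stringsAsFactors = FALSE)
}
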