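#' Partial least squares regression (NIPALS, orthogonal scores)
#'
#' Fits the latent-variable regression \eqn{Y = XB + E} by sequential NIPALS
#' extraction with X-deflation: each component finds the X-direction of
#' maximal covariance with Y, both blocks are regressed on the resulting score
#' vector, and X is deflated before the next component. Handles collinear
#' predictors and \eqn{p > n}. Regression coefficients use the standard
#' deflation-corrected form \eqn{B = W (P'W)^{-1} Q'} (the naive \eqn{B = WQ'}
#' holds only without deflation; see the `notes` field).
#'
#' Centering is always applied; unit-variance scaling of both blocks is on by
#' default, appropriate for heterogeneous omics scales.
#'
#' @param X predictors: [omics_matrix()] or numeric matrix (`n x p`).
#' @param Y responses: `omics_matrix` or numeric matrix (`n x m`).
#' @param ncomp number of latent variables, `1 <= ncomp <= min(n - 1, p)`.
#' @param scale logical: divide each column by its sd before fitting.
#' @param tol,max_iter NIPALS inner-loop convergence: relative change in the
#'   score vector below `tol`, or `max_iter` iterations, whichever first.
#' @return A `pls_fit`: list with `ncomp`, score/weight/loading matrices
#'   `x_scores` (T), `x_weights` (W), `x_loadings` (P), `y_scores` (U),
#'   `y_loadings` (Q), `coefficients` (`p x m x ncomp` array, centered/scaled
#'   scale), `x_residuals`, `y_residuals`, `explained_x`, `explained_y`
#'   (cumulative %), centering/scaling vectors, `iterations` per component.
#' @export
fit_pls <- function(X, Y, ncomp, scale = TRUE, tol = 1e-12, max_iter = 500L) {
  Xv <- as_values(X); Yv <- as_values(Y)
  n <- nrow(Xv); p <- ncol(Xv); m <- ncol(Yv)
  if (nrow(Yv) != n)
    stop("X and Y must have the same number of samples", call. = FALSE)
  if (inherits(X, "omics_matrix") && inherits(Y, "omics_matrix") &&
      !identical(X$sample_ids, Y$sample_ids))
    stop("X and Y sample ids differ or are ordered differently", call. = FALSE)
  if (ncomp < 1L || ncomp > min(n - 1L, p))
    stop("ncomp must be in 1..min(n - 1, p) = ", min(n - 1L, p), call. = FALSE)
  sy <- apply(Yv, 2L, stats::sd)
  if (any(sy == 0))
    stop("zero-variance response column(s): ",
         paste(colnames(Yv)[sy == 0], collapse = ", "), call. = FALSE)
  sx <- apply(Xv, 2L, stats::sd)
  if (scale && any(sx == 0))
    stop("zero-variance predictor column(s) cannot be scaled: ",
         paste(colnames(Xv)[sx == 0], collapse = ", "), call. = FALSE)

  x_center <- colMeans(Xv); y_center <- colMeans(Yv)
  x_scale <- if (scale) sx else rep(1, p)
  y_scale <- if (scale) sy else rep(1, m)
  Xc <- sweep(sweep(Xv, 2L, x_center), 2L, x_scale, "/")
  Yc <- sweep(sweep(Yv, 2L, y_center), 2L, y_scale, "/")
  X0 <- Xc; Y0 <- Yc
  ssx0 <- sum(Xc^2); ssy0 <- sum(Yc^2)

  Tm <- matrix(0, n, ncomp); W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp); U <- matrix(0, n, ncomp)
  Q <- matrix(0, m, ncomp)
  ssx <- ssy <- numeric(ncomp); iters <- integer(ncomp)

  for (a in seq_len(ncomp)) {
    u <- Yc[, which.max(apply(Yc, 2L, stats::var))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xc, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300)
        stop("NIPALS collapsed at component ", a,
             ": no remaining X-Y covariance", call. = FALSE)
      w <- w / nw
      tv <- Xc %*% w
      qv <- crossprod(Yc, tv) / c(crossprod(tv))
      u <- Yc %*% qv / c(crossprod(qv))
      if (sqrt(sum((tv - t_old)^2)) <= tol * sqrt(sum(tv^2))) break
      t_old <- tv
    }
    tt <- c(crossprod(tv))
    if (tt < ssx0 * 1e-14)
      stop("X block is rank deficient at component ", a,
           "; reduce ncomp", call. = FALSE)
    pv <- crossprod(Xc, tv) / tt
    Xc <- Xc - tcrossprod(tv, pv)
    Yc <- Yc - tcrossprod(tv, qv)
    Tm[, a] <- tv; W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; U[, a] <- u
    ssx[a] <- tt * sum(pv^2); ssy[a] <- tt * sum(qv^2); iters[a] <- it
  }

  lv <- paste0("LV", seq_len(ncomp))
  dimnames(Tm) <- list(rownames(Xv), lv); dimnames(U) <- list(rownames(Yv), lv)
  dimnames(W) <- list(colnames(Xv), lv); dimnames(P) <- list(colnames(Xv), lv)
  dimnames(Q) <- list(colnames(Yv), lv)

  B <- array(0, dim = c(p, m, ncomp),
             dimnames = list(colnames(Xv), colnames(Yv), lv))
  for (a in seq_len(ncomp)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    Qa <- Q[, seq_len(a), drop = FALSE]
    B[, , a] <- Wa %*% solve(crossprod(Pa, Wa), t(Qa))
  }

  structure(
    list(ncomp = ncomp, x_scores = Tm, x_weights = W, x_loadings = P,
         y_scores = U, y_loadings = Q, coefficients = B,
         x_residuals = Xc, y_residuals = Yc,
         explained_x = 100 * cumsum(ssx) / ssx0,
         explained_y = 100 * cumsum(ssy) / ssy0,
         x_center = x_center, x_scale = x_scale,
         y_center = y_center, y_scale = y_scale,
         scaled = scale, iterations = iters,
         n = n, p = p, m = m,
         notes = paste("coefficients use B = W (P'W)^{-1} Q'; the",
                       "no-deflation shorthand B = WQ' is not valid here")),
    class = "pls_fit"
  )
}

#' @export
print.pls_fit <- function(x, digits = 2, ...) {
  cat("PLS fit (NIPALS): n = ", x$n, ", p = ", x$p, ", m = ", x$m,
      ", ncomp = ", x$ncomp, "\n", sep = "")
  cat("  cumulative % variance explained:\n")
  print(round(rbind(X = x$explained_x, Y = x$explained_y), digits))
  invisible(x)
}

#' Predict responses from a PLS fit
#'
#' New predictors are centered/scaled with the training vectors, multiplied by
#' the coefficient matrix truncated at `ncomp` components, and mapped back to
#' the response scale. `ncomp = 0` is the baseline model: every sample is
#' predicted at the training response means.
#'
#' @param object a [fit_pls()] result.
#' @param newdata `omics_matrix` or numeric matrix with the training features
#'   (matched by name when column names are present).
#' @param ncomp number of components to use, `0..object$ncomp`.
#' @param ... unused.
#' @return Numeric matrix of predictions, `nrow(newdata) x m`.
#' @export
predict.pls_fit <- function(object, newdata, ncomp = object$ncomp, ...) {
  Xn <- as_values(newdata)
  train_feats <- names(object$x_center)
  if (!is.null(colnames(Xn)) && !identical(colnames(Xn), train_feats)) {
    missing <- setdiff(train_feats, colnames(Xn))
    extra <- setdiff(colnames(Xn), train_feats)
    if (length(missing) || length(extra))
      stop("feature mismatch with training data; missing: ",
           paste(missing, collapse = ", "), "; extra: ",
           paste(extra, collapse = ", "), call. = FALSE)
    Xn <- Xn[, train_feats, drop = FALSE]
  } else if (ncol(Xn) != object$p) {
    stop("newdata has ", ncol(Xn), " features; training had ", object$p,
         call. = FALSE)
  }
  if (ncomp < 0L || ncomp > object$ncomp)
    stop("ncomp must be in 0..", object$ncomp, call. = FALSE)

  out <- matrix(rep(object$y_center, each = nrow(Xn)), nrow = nrow(Xn),
                dimnames = list(rownames(Xn), names(object$y_center)))
  if (ncomp > 0L) {
    Xs <- sweep(sweep(Xn, 2L, object$x_center), 2L, object$x_scale, "/")
    Ys <- Xs %*% object$coefficients[, , ncomp]
    out <- out + sweep(Ys, 2L, object$y_scale, "*")
  }
  out
}

#' Cross-validated prediction error for PLS
#'
#' For each fold, the model is refit on the remaining samples (with the same
#' centering/scaling policy) and the held-out samples are predicted with
#' 0 to `max_ncomp` components; squared errors are pooled per response and
#' component count into RMSEP, MSEP and \eqn{R^2} curves — the basis of
#' per-response prediction-error plots and of choosing the number of latent
#' variables. The 0-component column is the response-mean baseline.
#'
#' \eqn{R^2} is defined as \eqn{1 - \mathrm{PRESS}/\mathrm{SS}_{tot}} with
#' \eqn{\mathrm{SS}_{tot}} the total sum of squares about the full-data mean.
#'
#' @inheritParams fit_pls
#' @param max_ncomp largest component count to evaluate; must be feasible in
#'   every training fold (`<= min(n_train - 1, p)`).
#' @param scheme `"loo"` (leave-one-out, deterministic; the default, suited to
#'   small-n studies) or `"kfold"`.
#' @param k number of folds for `scheme = "kfold"`.
#' @param seed integer seed for the fold shuffle (k-fold only); required there
#'   so runs are reproducible.
#' @return A `pls_cv`: list with `scheme`, and `rmsep`, `msep`, `r2` — each an
#'   `m x (max_ncomp + 1)` matrix with columns `"0comp", "1comp", ...`.
#' @export
cross_validate <- function(X, Y, max_ncomp, scheme = c("loo", "kfold"),
                           k = 10L, seed = NULL, scale = TRUE) {
  scheme <- match.arg(scheme)
  Xv <- as_values(X); Yv <- as_values(Y)
  n <- nrow(Xv); m <- ncol(Yv)
  if (nrow(Yv) != n)
    stop("X and Y must have the same number of samples", call. = FALSE)

  folds <- if (scheme == "loo") {
    as.list(seq_len(n))
  } else {
    if (k < 2L || k > n)
      stop("k must be in 2..n for k-fold cross-validation", call. = FALSE)
    if (is.null(seed))
      stop("k-fold cross-validation requires an explicit seed", call. = FALSE)
    perm <- with_local_seed(seed, sample.int(n))
    split(perm, rep_len(seq_len(k), n))
  }
  n_train_min <- n - max(lengths(folds))
  if (n_train_min < 3L)
    stop("too few samples for the requested scheme", call. = FALSE)
  if (max_ncomp < 1L || max_ncomp > min(n_train_min - 1L, ncol(Xv)))
    stop("max_ncomp must be in 1..min(n_train - 1, p) = ",
         min(n_train_min - 1L, ncol(Xv)), call. = FALSE)

  press <- matrix(0, m, max_ncomp + 1L)
  for (fold in folds) {
    fit <- fit_pls(Xv[-fold, , drop = FALSE], Yv[-fold, , drop = FALSE],
                   ncomp = max_ncomp, scale = scale)
    for (a in 0:max_ncomp) {
      pred <- predict(fit, Xv[fold, , drop = FALSE], ncomp = a)
      press[, a + 1L] <- press[, a + 1L] +
        colSums((pred - Yv[fold, , drop = FALSE])^2)
    }
  }

  ss_tot <- colSums(sweep(Yv, 2L, colMeans(Yv))^2)
  msep <- press / n
  dn <- list(colnames(Yv), paste0(0:max_ncomp, "comp"))
  dimnames(msep) <- dn
  structure(
    list(scheme = if (scheme == "loo") "LOO" else
           sprintf("KFOLD(k=%d, seed=%d)", k, seed),
         rmsep = sqrt(msep), msep = msep,
         r2 = matrix(1 - press / ss_tot, m, max_ncomp + 1L, dimnames = dn)),
    class = "pls_cv"
  )
}

#' @export
print.pls_cv <- function(x, digits = 3, ...) {
  cat("PLS cross-validation [", x$scheme, "]\nRMSEP per response:\n", sep = "")
  print(round(x$rmsep, digits))
  invisible(x)
}
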