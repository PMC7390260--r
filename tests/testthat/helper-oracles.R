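# Independent oracles used by the tests. These deliberately avoid the code
# paths of the implementation they check: CCA is maximized by alternating
# least squares instead of the whitened SVD, ontology resolution is a plain
# breadth-first search over the edge table instead of igraph, and OLS comes
# from lm/qr.

# n x p data whose *empirical* correlation matrix equals C exactly:
# orthonormalize centered Gaussian columns, then impose chol(C).
exact_corr_data <- function(n, C) {
  p <- ncol(C)
  M <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  Q <- qr.Q(qr(M))                     # centered, orthonormal columns
  Q %*% chol(C)
}

# Brute-force canonical correlations: alternating maximization of
# cor(a'X, b'Y) (each half-step is a least-squares projection, which is the
# correlation-maximizing choice given the other side), multiple random
# starts, then deflation by residualizing both blocks on the found variates.
oracle_cca <- function(X, Y, k = min(ncol(X), ncol(Y)),
                       n_starts = 5, max_iter = 20000, tol = 1e-14) {
  Zx <- scale(X); Zy <- scale(Y)
  rs <- numeric(k)
  for (i in seq_len(k)) {
    best <- list(r = -Inf)
    for (s in seq_len(n_starts)) {
      u <- Zx %*% rnorm(ncol(Zx))
      r_old <- 0
      for (it in seq_len(max_iter)) {
        v <- lm.fit(Zy, u)$fitted.values
        u <- lm.fit(Zx, v)$fitted.values
        r <- abs(cor(u, v))
        if (abs(r - r_old) < tol) break
        r_old <- r
      }
      if (r > best$r) best <- list(r = r, u = u, v = v)
    }
    rs[i] <- best$r
    Zx <- Zx - best$u %*% (crossprod(best$u, Zx) / c(crossprod(best$u)))
    Zy <- Zy - best$v %*% (crossprod(best$v, Zy) / c(crossprod(best$v)))
  }
  rs
}

# Brute-force resolver over the raw edge table: layered BFS, children first,
# ties broken by smallest numeric id.
brute_resolve <- function(query, edges, mapped) {
  if (query %in% mapped)
    return(list(status = "DIRECT", rep = query, dist = 0L))
  bfs <- function(start, down) {
    frontier <- start; seen <- start; d <- 0L
    while (length(frontier)) {
      d <- d + 1L
      nxt <- if (down)
        edges$child_chebi_id[edges$parent_chebi_id %in% frontier]
      else
        edges$parent_chebi_id[edges$child_chebi_id %in% frontier]
      nxt <- setdiff(unique(nxt), seen)
      if (!length(nxt)) return(NULL)
      hit <- intersect(nxt, mapped)
      if (length(hit))
        return(list(rep = hit[which.min(as.numeric(hit))], dist = d))
      seen <- c(seen, nxt); frontier <- nxt
    }
    NULL
  }
  r <- bfs(query, TRUE)
  if (!is.null(r)) return(list(status = "VIA_CHILD", rep = r$rep, dist = r$dist))
  r <- bfs(query, FALSE)
  if (!is.null(r)) return(list(status = "VIA_PARENT", rep = r$rep, dist = r$dist))
  list(status = "UNMAPPED", rep = NA_character_, dist = NA_integer_)
}

# OLS coefficients on the centered/scaled training scale, for the PLS limit.
oracle_ols <- function(X, Y) {
  Xs <- scale(X); Ys <- scale(Y)
  qr.solve(Xs, Ys)
}
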