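#' Prune correlated features within one omics set
#'
#' Classical CCA breaks down under within-set collinearity, so each set is
#' reduced to mutually weakly-correlated representatives before analysis.
#' The rule is a deterministic greedy scan in input column order: the first
#' column is kept; each later column is dropped if its absolute correlation
#' with any already-kept column reaches the threshold (its representative is
#' the kept column with the largest \eqn{|r|}), otherwise kept. Absolute
#' correlation is used throughout — a strong negative correlation is
#' redundancy too. Dropped features are retained in the result with their
#' representative, so they stay available for biological interpretation
#' rather than being silently lost.
#'
#' Zero-variance (constant) columns have no defined correlation; they are
#' dropped with representative `NA` and a warning.
#'
#' @param m an [omics_matrix()] or numeric matrix (samples x features).
#' @param threshold cutoff in (0, 1\]; a pair with \eqn{|r| \ge} `threshold`
#'   is considered redundant. The study-scale defaults in this field are 0.6
#'   for transcripts and 0.7 for fatty acids.
#' @param method `"pearson"` (default; the downstream engines are linear) or
#'   `"spearman"`.
#' @return A `prune_result`: list with `kept` (ordered feature ids),
#'   `dropped` (data.frame `feature_id`, `representative`, `abs_correlation`),
#'   `threshold`, `method`.
#' @export
prune_correlated <- function(m, threshold, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- as_values(m)
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must be in (0, 1]", call. = FALSE)
  if (nrow(X) < 3L)
    stop("at least 3 samples are required", call. = FALSE)

  ids <- colnames(X)
  p <- ncol(X)
  sds <- apply(X, 2L, stats::sd)
  constant <- sds == 0
  if (any(constant))
    warning("constant column(s) dropped (correlation undefined): ",
            paste(ids[constant], collapse = ", "), call. = FALSE)

  C <- matrix(NA_real_, p, p)
  ok <- which(!constant)
  if (length(ok))
    C[ok, ok] <- abs(stats::cor(X[, ok, drop = FALSE], method = method))

  kept <- integer(0)
  drop_id <- character(0); drop_rep <- character(0); drop_r <- numeric(0)
  for (j in seq_len(p)) {
    if (constant[j]) {
      drop_id <- c(drop_id, ids[j]); drop_rep <- c(drop_rep, NA_character_)
      drop_r <- c(drop_r, NA_real_)
      next
    }
    r <- if (length(kept)) C[j, kept] else numeric(0)
    if (length(r) && max(r) >= threshold) {
      best <- kept[which.max(r)]
      drop_id <- c(drop_id, ids[j]); drop_rep <- c(drop_rep, ids[best])
      drop_r <- c(drop_r, max(r))
    } else {
      kept <- c(kept, j)
    }
  }

  structure(
    list(kept = ids[kept],
         dropped = data.frame(feature_id = drop_id, representative = drop_rep,
                              abs_correlation = drop_r,
                              stringsAsFactors = FALSE),
         threshold = threshold, method = method),
    class = "prune_result"
  )
}

#' @export
print.prune_result <- function(x, ...) {
  cat("prune_result (", x$method, ", |r| >= ", x$threshold, "): ",
      length(x$kept), " kept, ", nrow(x$dropped), " dropped\n", sep = "")
  invisible(x)
}

#' Apply a prune result to its matrix
#'
#' @param m the [omics_matrix()] the result was computed from.
#' @param pr a [prune_correlated()] result.
#' @return An `omics_matrix` restricted to the kept features, order preserved.
#' @export
apply_prune <- function(m, pr) {
  stopifnot(inherits(m, "omics_matrix"), inherits(pr, "prune_result"))
  omics_matrix(m$values[, pr$kept, drop = FALSE],
               sample_ids = m$sample_ids, feature_ids = pr$kept,
               namespace = m$namespace)
}

#' Long-form prune report
#'
#' One row per original feature: `feature_id`, `status` (`kept`/`dropped`),
#' `representative`, `abs_correlation`, in original column order.
#'
#' @param pr a `prune_result`.
#' @param original_order feature ids in input column order; reconstructed from
#'   the result when omitted.
#' @return A data.frame.
#' @export
prune_report <- function(pr, original_order = NULL) {
  stopifnot(inherits(pr, "prune_result"))
  all_ids <- if (is.null(original_order))
    c(pr$kept, pr$dropped$feature_id) else original_order
  i <- match(all_ids, pr$dropped$feature_id)
  data.frame(
    feature_id = all_ids,
    status = ifelse(is.na(i), "kept", "dropped"),
    representative = ifelse(is.na(i), "", pr$dropped$representative[i]),
    abs_correlation = ifelse(is.na(i), NA_real_, pr$dropped$abs_correlation[i]),
    stringsAsFactors = FALSE)
}
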