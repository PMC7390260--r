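write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

mat_to_df <- function(M, id_col = "id") {
  df <- data.frame(rownames(M), as.data.frame(M, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  df
}

#' Write the CCA diagnostic reports
#'
#' One TSV per diagnostic block: correlations + Bartlett table, weights,
#' loadings, adequacies, communalities, redundancies, and the helio table for
#' the first canonical variate. X and Y blocks are stacked long with a `set`
#' column.
#'
#' @param res a [fit_cca()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Named character vector of the seven file paths, invisibly.
#' @export
write_cca_reports <- function(res, dir, prefix = "cca") {
  stopifnot(inherits(res, "cca_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(x) file.path(dir, paste0(prefix, "_", x, ".tsv"))

  stack2 <- function(Mx, My) {
    rbind(cbind(set = "X", mat_to_df(Mx, "variable")),
          cbind(set = "Y", mat_to_df(My, "variable")))
  }
  cv <- paste0("CV", seq_len(res$k))
  files <- c(
    correlations_bartlett = write_tsv(res$bartlett,
                                      path("correlations_bartlett")),
    weights = write_tsv(stack2(res$x_weights, res$y_weights), path("weights")),
    loadings = write_tsv(stack2(res$x_loadings, res$y_loadings),
                         path("loadings")),
    adequacies = write_tsv(
      data.frame(variate = rep(cv, 2L), set = rep(c("X", "Y"), each = res$k),
                 adequacy = c(res$x_adequacies, res$y_adequacies)),
      path("adequacies")),
    communalities = write_tsv(
      rbind(data.frame(set = "X", variable = names(res$x_communalities),
                       communality = unname(res$x_communalities)),
            data.frame(set = "Y", variable = names(res$y_communalities),
                       communality = unname(res$y_communalities))),
      path("communalities")),
    redundancies = write_tsv(res$redundancies, path("redundancies")),
    helio_cv1 = write_tsv(helio_data(res, 1L), path("helio_cv1")))
  invisible(files)
}

#' Write the PLS reports
#'
#' TSVs for the score/weight/loading matrices, the final-component coefficient
#' matrix, the cumulative explained-variance table, and (when a `pls_cv` is
#' supplied) the long-form cross-validation curve table
#' (`response x ncomp x {rmsep, msep, r2}`).
#'
#' @param fit a [fit_pls()] result.
#' @param dir output directory.
#' @param cv optional [cross_validate()] result.
#' @param prefix file-name prefix.
#' @return Named character vector of file paths, invisibly.
#' @export
write_pls_reports <- function(fit, dir, cv = NULL, prefix = "pls") {
  stopifnot(inherits(fit, "pls_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(x) file.path(dir, paste0(prefix, "_", x, ".tsv"))

  files <- c(
    scores = write_tsv(mat_to_df(fit$x_scores, "sample_id"), path("scores")),
    weights = write_tsv(mat_to_df(fit$x_weights, "feature_id"),
                        path("weights")),
    x_loadings = write_tsv(mat_to_df(fit$x_loadings, "feature_id"),
                           path("x_loadings")),
    y_scores = write_tsv(mat_to_df(fit$y_scores, "sample_id"),
                         path("y_scores")),
    y_loadings = write_tsv(mat_to_df(fit$y_loadings, "feature_id"),
                           path("y_loadings")),
    coefficients = write_tsv(
      mat_to_df(fit$coefficients[, , fit$ncomp, drop = TRUE], "feature_id"),
      path("coefficients")),
    explained_variance = write_tsv(
      data.frame(ncomp = seq_len(fit$ncomp),
                 cum_explained_x_pct = fit$explained_x,
                 cum_explained_y_pct = fit$explained_y),
      path("explained_variance")))

  if (!is.null(cv)) {
    stopifnot(inherits(cv, "pls_cv"))
    long <- expand.grid(response = rownames(cv$rmsep),
                        ncomp = seq_len(ncol(cv$rmsep)) - 1L,
                        stringsAsFactors = FALSE)
    long$rmsep <- as.vector(cv$rmsep)
    long$msep <- as.vector(cv$msep)
    long$r2 <- as.vector(cv$r2)
    files <- c(files, cv_curves = write_tsv(long, path("cv_curves")))
  }
  invisible(files)
}

#' Configuration for a full integration run
#'
#' @param x_path,y_path paths to the transcriptomic (HGNC) and metabolomic
#'   (ChEBI) TSV matrices.
#' @param kb_dir knowledge-base snapshot directory
#'   (see [parse_knowledgebase_dir()]).
#' @param out_dir run output directory.
#' @param prune_threshold_x,prune_threshold_y within-set correlation cutoffs
#'   in (0, 1\]; the study-scale conventions are 0.6 for genes and 0.7 for
#'   fatty acids.
#' @param score_threshold interaction-score cutoff for neighbour expansion.
#' @param engines subset of `c("cca", "pls")`; at least one.
#' @param pls_ncomp latent variables for the PLS fit (capped at what the data
#'   allow when `NULL`).
#' @param cv_scheme `"loo"` or `"kfold"`.
#' @param cv_k folds for k-fold.
#' @param restrict_y_mapped drop Y metabolites that resolve `UNMAPPED` before
#'   pruning (off by default: the metabolite set is usually reduced by
#'   correlation pruning alone).
#' @param seed integer seed (used for k-fold shuffling; recorded in the
#'   manifest either way).
#' @return A `run_config` list.
#' @export
run_config <- function(x_path, y_path, kb_dir, out_dir,
                       prune_threshold_x = 0.6, prune_threshold_y = 0.7,
                       score_threshold = 400, engines = c("cca", "pls"),
                       pls_ncomp = NULL, cv_scheme = "loo", cv_k = 10L,
                       restrict_y_mapped = FALSE, seed = 1L) {
  engines <- match.arg(engines, several.ok = TRUE)
  if (!length(engines)) stop("select at least one engine", call. = FALSE)
  for (thr in c(prune_threshold_x, prune_threshold_y))
    if (!(thr > 0 && thr <= 1))
      stop("prune thresholds must lie in (0, 1]", call. = FALSE)
  structure(list(x_path = x_path, y_path = y_path, kb_dir = kb_dir,
                 out_dir = out_dir, prune_threshold_x = prune_threshold_x,
                 prune_threshold_y = prune_threshold_y,
                 score_threshold = score_threshold, engines = engines,
                 pls_ncomp = pls_ncomp, cv_scheme = cv_scheme,
                 cv_k = as.integer(cv_k),
                 restrict_y_mapped = restrict_y_mapped,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full integration workflow
#'
#' Executes the pipeline stages in order: build the functional group from the
#' measured metabolites, restrict the transcriptomic matrix to the mapped
#' genes actually measured (mapped-but-unmeasured genes are reported, not
#' silently dropped), prune correlated features within each set, then run the
#' selected statistical engines and write every stage report plus a
#' reproducibility manifest (parameters, seed, per-stage feature counts, and
#' an MD5 checksum per output file). Every stage logs its input/output
#' dimensionality via `message()`.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with the output directory, the per-stage counts,
#'   and the fitted objects (`fg`, `prune_x`, `prune_y`, `cca`, `pls`,
#'   `pls_cv` as applicable).
#' @export
run_workflow <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  X <- read_omics_matrix(cfg$x_path, namespace = "HGNC")
  Y <- read_omics_matrix(cfg$y_path, namespace = "CHEBI")
  if (!identical(X$sample_ids, Y$sample_ids))
    stop("X and Y sample ids differ or are ordered differently",
         call. = FALSE)
  kb <- parse_knowledgebase_dir(cfg$kb_dir)
  message("inputs: X ", nrow(X$values), " x ", ncol(X$values), ", Y ",
          nrow(Y$values), " x ", ncol(Y$values),
          "; knowledge base species '", kb$species, "'")

  counts <- list(x_input = ncol(X$values), y_input = ncol(Y$values))

  # stage 1: functional grouping from the measured metabolites
  fg <- build_functional_group(Y$feature_ids, kb,
                               score_threshold = cfg$score_threshold)
  write_functional_group(fg, file.path(cfg$out_dir, "mapping_resolutions.tsv"),
                         file.path(cfg$out_dir, "mapping_genes.tsv"))
  counts$mapped_genes <- length(fg$expanded_genes)

  # stage 2: restrict X to mapped genes present in the matrix
  measured <- X$feature_ids[toupper(X$feature_ids) %in% fg$expanded_genes]
  unmeasured <- setdiff(fg$expanded_genes, toupper(X$feature_ids))
  write_tsv(data.frame(gene_symbol = unmeasured),
            file.path(cfg$out_dir, "mapped_unmeasured_genes.tsv"))
  if (!length(measured))
    stop("no mapped gene is present in the transcriptomic matrix; review ",
         "the snapshot and score_threshold", call. = FALSE)
  X <- omics_matrix(X$values[, measured, drop = FALSE],
                    sample_ids = X$sample_ids, feature_ids = measured,
                    namespace = X$namespace)
  counts$x_restricted <- ncol(X$values)
  message("restriction: ", counts$mapped_genes, " mapped genes -> ",
          counts$x_restricted, " measured (", length(unmeasured),
          " mapped but unmeasured)")

  if (cfg$restrict_y_mapped) {
    keep <- Y$feature_ids[fg$resolutions$status != "UNMAPPED"]
    Y <- omics_matrix(Y$values[, keep, drop = FALSE],
                      sample_ids = Y$sample_ids, feature_ids = keep,
                      namespace = Y$namespace)
  }
  counts$y_restricted <- ncol(Y$values)

  # stage 3: within-set decorrelation
  px <- prune_correlated(X, cfg$prune_threshold_x)
  py <- prune_correlated(Y, cfg$prune_threshold_y)
  write_tsv(prune_report(px, X$feature_ids),
            file.path(cfg$out_dir, "prune_x.tsv"))
  write_tsv(prune_report(py, Y$feature_ids),
            file.path(cfg$out_dir, "prune_y.tsv"))
  Xp <- apply_prune(X, px); Yp <- apply_prune(Y, py)
  counts$x_kept <- length(px$kept); counts$y_kept <- length(py$kept)
  message("prune: X ", counts$x_restricted, " -> ", counts$x_kept,
          " (|r| < ", cfg$prune_threshold_x, "), Y ", counts$y_restricted,
          " -> ", counts$y_kept, " (|r| < ", cfg$prune_threshold_y, ")")

  result <- list(out_dir = cfg$out_dir, counts = counts, fg = fg,
                 prune_x = px, prune_y = py)

  if ("cca" %in% cfg$engines) {
    result$cca <- fit_cca(Xp, Yp)
    write_cca_reports(result$cca, cfg$out_dir)
    message("cca: k = ", result$cca$k, ", first correlation = ",
            signif(result$cca$correlations[1L], 4))
  }
  if ("pls" %in% cfg$engines) {
    max_fit <- min(nrow(Xp$values) - 2L, ncol(Xp$values))
    ncomp <- if (is.null(cfg$pls_ncomp)) min(5L, max_fit)
             else min(cfg$pls_ncomp, max_fit)
    result$pls <- fit_pls(Xp, Yp, ncomp = ncomp)
    result$pls_cv <- cross_validate(Xp, Yp, max_ncomp = ncomp,
                                    scheme = cfg$cv_scheme, k = cfg$cv_k,
                                    seed = cfg$seed)
    write_pls_reports(result$pls, cfg$out_dir, cv = result$pls_cv)
    message("pls: ncomp = ", ncomp, ", cumulative %Y explained = ",
            signif(result$pls$explained_y[ncomp], 4))
  }

  # manifest: parameters + stage counts + checksums of every numeric output
  outputs <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
  manifest <- list(
    package = "omicslink",
    version = as.character(utils::packageVersion("omicslink")),
    parameters = unclass(cfg),
    species = kb$species,
    stage_counts = counts,
    checksums = as.list(tools::md5sum(file.path(cfg$out_dir, outputs))))
  names(manifest$checksums) <- outputs
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(result)
}
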