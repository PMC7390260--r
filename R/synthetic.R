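#' Specification for paired synthetic omics matrices
#'
#' Describes a pair of sample-matched matrices with planted canonical
#' structure: `length(planted_rho)` shared latent factors, each inducing one
#' population canonical correlation, embedded into feature space by random
#' orthonormal loadings and blurred with isotropic Gaussian noise. The
#' generator emulates pre-normalized, multivariate-normal omics data — the
#' distributional assumption of the downstream statistics — and deliberately
#' not platform artefacts (heteroscedasticity, batch effects).
#'
#' @param n_samples number of samples (rows).
#' @param p,q numbers of X (gene) and Y (metabolite) features.
#' @param planted_rho non-increasing canonical correlations in \[0, 1);
#'   length at most `min(p, q)`.
#' @param noise_sd isotropic noise standard deviation added to every feature;
#'   default 0.1 (small measurement noise: it attenuates each planted
#'   correlation by the factor \eqn{1/(1 + noise\_sd^2)}, about 1% at the
#'   default).
#' @param seed integer; identical spec + seed reproduces the matrices (and any
#'   files written from them) bit for bit.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples, p, q, planted_rho, noise_sd = 0.1,
                           seed = 1L) {
  planted_rho <- as.numeric(planted_rho)
  if (any(planted_rho < 0 | planted_rho >= 1))
    stop("planted_rho entries must lie in [0, 1)", call. = FALSE)
  if (is.unsorted(rev(planted_rho)))
    stop("planted_rho must be non-increasing", call. = FALSE)
  if (length(planted_rho) > min(p, q))
    stop("length(planted_rho) must not exceed min(p, q)", call. = FALSE)
  if (length(planted_rho) < 1L)
    stop("planted_rho must have at least one entry", call. = FALSE)
  if (n_samples < 3L) stop("n_samples must be at least 3", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples), p = as.integer(p),
                 q = as.integer(q), planted_rho = planted_rho,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate paired omics matrices with planted canonical structure
#'
#' For each planted correlation \eqn{\rho_i}, a shared standard-normal latent
#' \eqn{z_i} is drawn per sample; the X-side latent is \eqn{u_i = z_i} and the
#' Y-side latent \eqn{v_i = \rho_i z_i + \sqrt{1-\rho_i^2}\,\epsilon_i}, so
#' \eqn{\mathrm{cor}(u_i, v_i) = \rho_i} exactly in the population. The latent
#' blocks are embedded via random orthonormal loading matrices and isotropic
#' noise is added, giving full-rank matrices whose population canonical
#' correlations are `planted_rho / (1 + noise_sd^2)` (equal to `planted_rho`
#' in the noiseless construction). The same latent construction provides a
#' ground-truth latent count for PLS cross-validation experiments.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `X`, `Y` ([omics_matrix()] with HGNC-style / ChEBI-style
#'   synthetic feature ids), and `latents` (the `n x k` matrices `U` and `V`).
#' @export
generate_paired_omics <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples; p <- spec$p; q <- spec$q
  rho <- spec$planted_rho; k <- length(rho)

  with_local_seed(spec$seed, {
    Z <- matrix(stats::rnorm(n * k), n, k)
    Eps <- matrix(stats::rnorm(n * k), n, k)
    V <- Z %*% diag(rho, nrow = k) +
      Eps %*% diag(sqrt(1 - rho^2), nrow = k)
    Ax <- qr.Q(qr(matrix(stats::rnorm(p * k), p, k)))   # p x k orthonormal
    Ay <- qr.Q(qr(matrix(stats::rnorm(q * k), q, k)))
    X <- tcrossprod(Z, Ax) + spec$noise_sd * matrix(stats::rnorm(n * p), n, p)
    Y <- tcrossprod(V, Ay) + spec$noise_sd * matrix(stats::rnorm(n * q), n, q)

    sample_ids <- sprintf("S%04d", seq_len(n))
    list(
      X = omics_matrix(X, sample_ids = sample_ids,
                       feature_ids = sprintf("GENE%04d", seq_len(p)),
                       namespace = "HGNC"),
      Y = omics_matrix(Y, sample_ids = sample_ids,
                       feature_ids = as.character(100000L + seq_len(q)),
                       namespace = "CHEBI"),
      latents = list(U = Z, V = V))
  })
}

#' Generate a miniature knowledge-base snapshot
#'
#' Writes the four snapshot files ([parse_knowledgebase()] dialects, header
#' row included) into `dir` under the conventional names `met2pathway.tsv`,
#' `pathway2gene.tsv`, `ontology.tsv`, `interactions.tsv`. The construction
#' guarantees that the returned query metabolites exercise every resolution
#' branch: at least one resolves `DIRECT`, one `VIA_CHILD`, one `VIA_PARENT`
#' and one stays `UNMAPPED`. The `VIA_CHILD` metabolite also carries a mapped
#' parent at the same hop distance, so child precedence is observable. All
#' ontology chains have length at most `ontology_depth`, and extra filler
#' edges keep the graph acyclic by construction.
#'
#' @param n_metabolites number of query metabolites (at least 4, one per
#'   resolution branch).
#' @param n_pathways number of pathways (at least 1).
#' @param n_genes size of the gene symbol pool (at least 4).
#' @param ontology_depth maximum chain length for child/parent fallbacks.
#' @param seed integer seed; the snapshot is a deterministic function of the
#'   arguments.
#' @param dir output directory (created if needed).
#' @return List with `dir`, `files` (named paths), `metabolites` (the query
#'   ids, in branch order: direct, via-child, via-parent, unmapped, then the
#'   rest), and `species`.
#' @export
generate_fixture_knowledgebase <- function(n_metabolites = 8L,
                                           n_pathways = 3L,
                                           n_genes = 12L,
                                           ontology_depth = 2L,
                                           seed = 1L,
                                           dir = tempfile("kb")) {
  if (n_metabolites < 4L)
    stop("n_metabolites must be at least 4 to cover every resolution branch",
         call. = FALSE)
  if (n_pathways < 1L || n_genes < 4L || ontology_depth < 1L)
    stop("need n_pathways >= 1, n_genes >= 4, ontology_depth >= 1",
         call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  with_local_seed(seed, {
    genes <- sprintf("GENE%03d", seq_len(n_genes))
    pathways <- sprintf("R-FIX-%07d", seq_len(n_pathways))
    next_id <- 10000L
    new_id <- function(k = 1L) {
      ids <- next_id + seq_len(k) - 1L
      next_id <<- next_id + k
      as.character(ids)
    }

    mets <- new_id(n_metabolites)          # query metabolites, branch order
    ont <- data.frame(child_chebi_id = character(0),
                      parent_chebi_id = character(0),
                      stringsAsFactors = FALSE)
    add_edge <- function(child, parent)
      ont <<- rbind(ont, data.frame(child_chebi_id = child,
                                    parent_chebi_id = parent,
                                    stringsAsFactors = FALSE))

    mapped <- mets[1L]                     # branch 1: DIRECT

    # branch 2: VIA_CHILD — mapped descendant at depth d, plus a mapped
    # ancestor at the same depth so the child direction must win the tie.
    d <- sample.int(ontology_depth, 1L)
    chain <- new_id(d)                     # chain[d] is the mapped descendant
    add_edge(chain[1L], mets[2L])
    if (d > 1L) for (i in 2:d) add_edge(chain[i], chain[i - 1L])
    up <- new_id(d)
    add_edge(mets[2L], up[1L])
    if (d > 1L) for (i in 2:d) add_edge(up[i - 1L], up[i])
    mapped <- c(mapped, chain[d], up[d])

    # branch 3: VIA_PARENT — mapped ancestor only, no descendants at all.
    d2 <- sample.int(ontology_depth, 1L)
    anc <- new_id(d2)
    add_edge(mets[3L], anc[1L])
    if (d2 > 1L) for (i in 2:d2) add_edge(anc[i - 1L], anc[i])
    mapped <- c(mapped, anc[d2])

    # branch 4: UNMAPPED — mets[4] appears nowhere.
    # remaining queries: direct or unmapped at random
    if (n_metabolites > 4L) {
      direct_extra <- mets[5:n_metabolites][
        stats::runif(n_metabolites - 4L) < 0.5]
      mapped <- c(mapped, direct_extra)
    }

    m2p <- data.frame(
      chebi_id = mapped,
      pathway_id = sample(pathways, length(mapped), replace = TRUE),
      stringsAsFactors = FALSE)
    m2p$pathway_name <- paste0("Synthetic pathway ",
                               match(m2p$pathway_id, pathways))
    m2p$species <- "synthetic"

    p2g <- do.call(rbind, lapply(pathways, function(pw) {
      data.frame(pathway_id = pw,
                 gene_symbol = sample(genes, sample(2:4, 1L)),
                 stringsAsFactors = FALSE)
    }))

    n_edges <- max(2L * n_genes, 6L)
    pairs <- t(replicate(n_edges, sample(genes, 2L)))
    ints <- unique(data.frame(gene_a = pairs[, 1L], gene_b = pairs[, 2L],
                              stringsAsFactors = FALSE))
    ints$combined_score <- sample(0:1000, nrow(ints), replace = TRUE)

    files <- c(met2pathway = file.path(dir, "met2pathway.tsv"),
               pathway2gene = file.path(dir, "pathway2gene.tsv"),
               ontology = file.path(dir, "ontology.tsv"),
               interactions = file.path(dir, "interactions.tsv"))
    utils::write.table(m2p, files["met2pathway"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(p2g, files["pathway2gene"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(ont, files["ontology"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(ints, files["interactions"], sep = "\t", quote = FALSE,
                       row.names = FALSE)

    list(dir = dir, files = files, metabolites = mets, species = "synthetic")
  })
}
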