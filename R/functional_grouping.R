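#' Resolve a ChEBI id to a pathway-mapped representative
#'
#' A metabolite that is itself a key of the metabolite-to-pathway map resolves
#' `DIRECT`. Otherwise the ChEBI ontology is searched, children first: the
#' nearest mapped descendant (breadth-first over child->parent edges, any
#' depth) is taken as representative (`VIA_CHILD`); if no descendant is
#' mapped, the nearest mapped ancestor is taken (`VIA_PARENT`); otherwise the
#' metabolite is `UNMAPPED` and contributes nothing downstream. "Nearest"
#' means fewest ontology edges; ties at equal depth are broken by the smallest
#' numeric ChEBI id, so resolution is deterministic.
#'
#' @param query a ChEBI id (bare integer or `"CHEBI:"`-prefixed).
#' @param kb a [parse_knowledgebase()] result.
#' @return A `chebi_resolution`: list with `query_id`, `status` (one of
#'   `"DIRECT"`, `"VIA_CHILD"`, `"VIA_PARENT"`, `"UNMAPPED"`),
#'   `representative_id` (`NA` when unmapped) and `distance` (ontology hops;
#'   0 for direct, `NA` when unmapped).
#' @export
resolve_chebi <- function(query, kb) {
  stopifnot(inherits(kb, "knowledgebase"))
  id <- normalize_chebi(query)
  mapped <- names(kb$met2pathway)

  res <- function(status, rep_id, dist)
    structure(list(query_id = id, status = status,
                   representative_id = rep_id, distance = dist),
              class = "chebi_resolution")

  if (id %in% mapped) return(res("DIRECT", id, 0L))

  nodes <- igraph::V(kb$ontology)$name
  if (id %in% nodes) {
    targets <- intersect(mapped, nodes)
    if (length(targets)) {
      # child->parent edges: descendants reach the query along edge direction,
      # so from the query they lie in the "in" direction; ancestors in "out".
      for (side in c("in", "out")) {
        d <- igraph::distances(kb$ontology, v = id, to = targets, mode = side)[1L, ]
        hit <- which(is.finite(d) & d > 0)
        if (length(hit)) {
          dmin <- min(d[hit])
          cand <- targets[hit][d[hit] == dmin]
          rep_id <- cand[which.min(as.numeric(cand))]
          status <- if (side == "in") "VIA_CHILD" else "VIA_PARENT"
          return(res(status, rep_id, as.integer(dmin)))
        }
      }
    }
  }
  res("UNMAPPED", NA_character_, NA_integer_)
}

#' @export
print.chebi_resolution <- function(x, ...) {
  cat(chebi_label(x$query_id), ": ", x$status, sep = "")
  if (x$status %in% c("VIA_CHILD", "VIA_PARENT"))
    cat(" via ", chebi_label(x$representative_id),
        " (", x$distance, " hop", if (x$distance > 1L) "s", ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Expand a gene set with interaction-network neighbours
#'
#' Adds every one-hop neighbour connected to an input gene by an interaction
#' edge whose combined score meets the threshold. Exactly one hop: the
#' pipeline applies a single decoration step, so the operation is not meant to
#' be idempotent. Genes absent from the interaction graph pass through with no
#' neighbours.
#'
#' @param genes character vector of gene symbols (matched case-insensitively).
#' @param kb a `knowledgebase`.
#' @param score_threshold minimum combined score in \[0, 1000\]; 400 is
#'   STRING's conventional medium confidence.
#' @return Sorted character vector: `toupper(genes)` plus qualifying
#'   neighbours.
#' @export
expand_neighbors <- function(genes, kb, score_threshold = 400) {
  stopifnot(inherits(kb, "knowledgebase"))
  if (score_threshold < 0 || score_threshold > 1000)
    stop("score_threshold must be in [0, 1000]", call. = FALSE)
  genes <- toupper(as.character(genes))
  if (!length(genes)) return(character(0))
  g <- igraph::subgraph_from_edges(
    kb$interactions,
    igraph::E(kb$interactions)[igraph::E(kb$interactions)$score >= score_threshold],
    delete.vertices = FALSE)
  present <- intersect(genes, igraph::V(g)$name)
  nbr <- if (length(present)) {
    unique(unlist(lapply(igraph::adjacent_vertices(g, present), names)))
  } else character(0)
  sort(unique(c(genes, nbr)))
}

#' Build a functional group from a metabolite list
#'
#' The knowledge-driven dimension-reduction step: each metabolite is resolved
#' to a pathway-mapped representative ([resolve_chebi()]), the gene sets of
#' all reached pathways are pooled into the seed set, and the seed set is
#' expanded once with interaction neighbours ([expand_neighbors()]). Per-gene
#' provenance records whether a gene entered via a pathway or only as a
#' neighbour; unmapped metabolites are reported but contribute no pathways.
#'
#' @param metabolite_ids non-empty vector of ChEBI ids.
#' @param kb a `knowledgebase`.
#' @inheritParams expand_neighbors
#' @return A `functional_group`: list with `resolutions` (data.frame:
#'   `metabolite_id`, `status`, `representative_id`, `distance`),
#'   `pathway_ids`, `seed_genes`, `expanded_genes`, and `genes` (data.frame:
#'   `gene_symbol`, `provenance` in `{PATHWAY, NEIGHBOR}`, `pathway_ids`
#'   semicolon-joined), plus `score_threshold`.
#' @export
build_functional_group <- function(metabolite_ids, kb, score_threshold = 400) {
  stopifnot(inherits(kb, "knowledgebase"))
  if (!length(metabolite_ids))
    stop("metabolite_ids must be non-empty", call. = FALSE)

  rl <- lapply(metabolite_ids, resolve_chebi, kb = kb)
  resolutions <- data.frame(
    metabolite_id = vapply(rl, `[[`, character(1), "query_id"),
    status = vapply(rl, `[[`, character(1), "status"),
    representative_id = vapply(rl, `[[`, character(1), "representative_id"),
    distance = vapply(rl, `[[`, integer(1), "distance"),
    stringsAsFactors = FALSE)

  reps <- unique(resolutions$representative_id[resolutions$status != "UNMAPPED"])
  pathway_ids <- sort(unique(unlist(kb$met2pathway[reps], use.names = FALSE)))
  gene_sets <- kb$pathway2gene[intersect(pathway_ids, names(kb$pathway2gene))]
  seed_genes <- sort(unique(unlist(gene_sets, use.names = FALSE)))

  if (all(resolutions$status == "UNMAPPED"))
    warning("no metabolite could be mapped to a pathway; ",
            "functional group is empty", call. = FALSE)

  expanded_genes <- expand_neighbors(seed_genes, kb, score_threshold)

  gene_pathways <- vapply(seed_genes, function(g) {
    paste(names(gene_sets)[vapply(gene_sets, function(s) g %in% s, logical(1))],
          collapse = ";")
  }, character(1))
  genes <- data.frame(
    gene_symbol = expanded_genes,
    provenance = ifelse(expanded_genes %in% seed_genes, "PATHWAY", "NEIGHBOR"),
    pathway_ids = ifelse(expanded_genes %in% seed_genes,
                         gene_pathways[match(expanded_genes, seed_genes)], ""),
    stringsAsFactors = FALSE)

  structure(
    list(metabolite_ids = resolutions$metabolite_id, resolutions = resolutions,
         pathway_ids = pathway_ids, seed_genes = seed_genes,
         expanded_genes = expanded_genes, genes = genes,
         score_threshold = score_threshold),
    class = "functional_group"
  )
}

#' @export
print.functional_group <- function(x, ...) {
  tab <- table(factor(x$resolutions$status,
                      levels = c("DIRECT", "VIA_CHILD", "VIA_PARENT",
                                 "UNMAPPED")))
  cat("functional_group: ", nrow(x$resolutions), " metabolites (",
      paste(names(tab), tab, sep = " ", collapse = ", "), ")\n", sep = "")
  cat("  pathways: ", length(x$pathway_ids),
      " | seed genes: ", length(x$seed_genes),
      " | expanded genes: ", length(x$expanded_genes),
      " (score >= ", x$score_threshold, ")\n", sep = "")
  invisible(x)
}

#' Write the functional-group reports
#'
#' Emits the mapping report (`metabolite_id`, `resolution_status`,
#' `representative_id`, `distance`) and the gene report (`gene_symbol`,
#' `provenance`, `pathway_ids`) as TSV files.
#'
#' @param fg a [build_functional_group()] result.
#' @param resolutions_path,genes_path output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_functional_group <- function(fg, resolutions_path, genes_path) {
  stopifnot(inherits(fg, "functional_group"))
  r <- fg$resolutions
  names(r)[names(r) == "status"] <- "resolution_status"
  utils::write.table(r, resolutions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fg$genes, genes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(resolutions_path, genes_path))
}
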