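#' Normalize a ChEBI identifier
#'
#' ChEBI identifiers are stored as bare integers throughout the package; a
#' `"CHEBI:"` prefix (any case) is stripped on input. Anything that does not
#' parse to a non-negative integer is a hard error.
#'
#' @param x a single identifier, e.g. `"CHEBI:28125"`, `"28125"`, or `28125`.
#' @return The bare integer id as a character scalar, e.g. `"28125"`.
#' @export
normalize_chebi <- function(x) {
  if (length(x) != 1L || is.na(x))
    stop("ChEBI id must be a single non-missing value", call. = FALSE)
  s <- trimws(as.character(x))
  s <- sub("^[Cc][Hh][Ee][Bb][Ii]:", "", s)
  if (!grepl("^[0-9]+$", s))
    stop("not an integer-parseable ChEBI id: '", x, "'", call. = FALSE)
  # canonical form: no leading zeros
  as.character(as.numeric(s))
}

#' Display form of a ChEBI identifier
#' @param x bare integer id(s) as character or numeric.
#' @return `"CHEBI:<id>"` strings.
#' @export
chebi_label <- function(x) paste0("CHEBI:", as.character(x))

read_snapshot <- function(path, required) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          check.names = FALSE, fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("snapshot file '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df[required]
}

# Return one directed cycle (vector of node names, first == last) in g,
# assuming is_dag(g) is FALSE.
find_one_cycle <- function(g) {
  loops <- igraph::E(g)[igraph::which_loop(g)]
  if (length(loops)) {
    v <- igraph::ends(g, loops[1L])[1L]
    return(c(v, v))
  }
  comp <- igraph::components(g, mode = "strong")
  idx <- which(comp$csize > 1L)[1L]
  nodes <- names(comp$membership)[comp$membership == idx]
  v <- nodes[1L]
  succ <- intersect(names(igraph::neighbors(g, v, mode = "out")), nodes)[1L]
  back <- igraph::shortest_paths(g, from = succ, to = v, mode = "out")$vpath[[1L]]
  c(v, names(back))
}

#' Parse an offline knowledge-base snapshot
#'
#' Reads the four snapshot files that stand in for live Reactome / ChEBI /
#' STRING queries. Each is a UTF-8 TSV with a header row; extra columns are
#' ignored. Required columns:
#'
#' * metabolite-to-pathway (`ChEBI2Reactome` dialect): `chebi_id`,
#'   `pathway_id`, `pathway_name`, `species`;
#' * pathway-to-gene: `pathway_id`, `gene_symbol`;
#' * ontology edges (child to parent): `child_chebi_id`, `parent_chebi_id`;
#' * interactions (STRING dialect): `gene_a`, `gene_b`, `combined_score`
#'   (integer confidence, 0-1000).
#'
#' ChEBI ids are normalized to bare integers; gene symbols are uppercased so
#' that lookups are case-insensitive (mouse-style mixed-case symbols map onto
#' HGNC-style uppercase). The ontology must be acyclic; an interaction score
#' outside \[0, 1000\] is a hard error. Line order in the files is irrelevant.
#'
#' @param met2pathway_path,pathway2gene_path,ontology_path,interactions_path
#'   paths to the four snapshot files.
#' @return An object of class `knowledgebase`: list with `met2pathway` (named
#'   list: ChEBI id -> character vector of pathway ids), `pathway2gene` (named
#'   list: pathway id -> character vector of gene symbols), `pathway_names`
#'   (named character), `ontology` (directed acyclic `igraph`, child->parent
#'   edges), `interactions` (undirected `igraph` with integer `score` edge
#'   attribute), `species`.
#' @export
parse_knowledgebase <- function(met2pathway_path, pathway2gene_path,
                                ontology_path, interactions_path) {
  m2p <- read_snapshot(met2pathway_path,
                       c("chebi_id", "pathway_id", "pathway_name", "species"))
  p2g <- read_snapshot(pathway2gene_path, c("pathway_id", "gene_symbol"))
  ont <- read_snapshot(ontology_path, c("child_chebi_id", "parent_chebi_id"))
  ints <- read_snapshot(interactions_path,
                        c("gene_a", "gene_b", "combined_score"))

  m2p$chebi_id <- vapply(m2p$chebi_id, normalize_chebi, character(1),
                         USE.NAMES = FALSE)
  met2pathway <- lapply(split(m2p$pathway_id, m2p$chebi_id),
                        function(p) sort(unique(p)))
  pathway_names <- stats::setNames(m2p$pathway_name, m2p$pathway_id)
  pathway_names <- pathway_names[!duplicated(names(pathway_names))]
  species <- if (nrow(m2p)) sort(unique(m2p$species))[1L] else "unspecified"

  p2g$gene_symbol <- toupper(trimws(p2g$gene_symbol))
  pathway2gene <- lapply(split(p2g$gene_symbol, p2g$pathway_id),
                         function(g) sort(unique(g)))

  ont$child_chebi_id <- vapply(ont$child_chebi_id, normalize_chebi,
                               character(1), USE.NAMES = FALSE)
  ont$parent_chebi_id <- vapply(ont$parent_chebi_id, normalize_chebi,
                                character(1), USE.NAMES = FALSE)
  edges <- unique(ont[c("child_chebi_id", "parent_chebi_id")])
  ontology <- igraph::graph_from_data_frame(edges, directed = TRUE)
  if (igraph::gsize(ontology) && !igraph::is_dag(ontology)) {
    cyc <- find_one_cycle(ontology)
    stop("ontology snapshot contains a cycle: ",
         paste(chebi_label(cyc), collapse = " -> "), call. = FALSE)
  }

  score <- suppressWarnings(as.numeric(ints$combined_score))
  if (anyNA(score) || any(score < 0 | score > 1000))
    stop("interaction combined_score outside [0, 1000] (or non-numeric) at ",
         "line(s): ",
         paste(utils::head(which(is.na(score) | score < 0 | score > 1000), 5L),
               collapse = ", "), call. = FALSE)
  ints$gene_a <- toupper(trimws(ints$gene_a))
  ints$gene_b <- toupper(trimws(ints$gene_b))
  interactions <- igraph::graph_from_data_frame(
    data.frame(from = ints$gene_a, to = ints$gene_b, score = score,
               stringsAsFactors = FALSE),
    directed = FALSE)

  structure(
    list(met2pathway = met2pathway, pathway2gene = pathway2gene,
         pathway_names = pathway_names, ontology = ontology,
         interactions = interactions, species = species),
    class = "knowledgebase"
  )
}

#' Parse a knowledge-base snapshot directory
#'
#' Convenience wrapper over [parse_knowledgebase()] for a directory holding
#' the four files under their conventional names `met2pathway.tsv`,
#' `pathway2gene.tsv`, `ontology.tsv`, `interactions.tsv` (the layout written
#' by [generate_fixture_knowledgebase()]).
#'
#' @param dir directory containing the snapshot files.
#' @return A `knowledgebase`.
#' @export
parse_knowledgebase_dir <- function(dir) {
  parse_knowledgebase(file.path(dir, "met2pathway.tsv"),
                      file.path(dir, "pathway2gene.tsv"),
                      file.path(dir, "ontology.tsv"),
                      file.path(dir, "interactions.tsv"))
}

#' @export
print.knowledgebase <- function(x, ...) {
  cat("knowledgebase [", x$species, "]\n", sep = "")
  cat("  metabolites mapped : ", length(x$met2pathway), "\n", sep = "")
  cat("  pathways           : ", length(x$pathway2gene), "\n", sep = "")
  cat("  ontology           : ", igraph::gorder(x$ontology), " nodes, ",
      igraph::gsize(x$ontology), " child->parent edges\n", sep = "")
  cat("  interactions       : ", igraph::gorder(x$interactions), " genes, ",
      igraph::gsize(x$interactions), " scored edges\n", sep = "")
  invisible(x)
}
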