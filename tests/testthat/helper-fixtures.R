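# Fixture builders: write knowledge-base snapshot files from data frames
# (defaults fill in the unused components) and parse them back.

kb_from_tables <- function(m2p = NULL, ont = NULL, ints = NULL, p2g = NULL,
                           dir = tempfile("kbfix")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(m2p))
    m2p <- data.frame(chebi_id = character(0), pathway_id = character(0))
  if (is.null(m2p$pathway_name))
    m2p$pathway_name <- if (nrow(m2p)) paste("pathway", m2p$pathway_id) else character(0)
  if (is.null(m2p$species))
    m2p$species <- rep("synthetic", nrow(m2p))
  if (is.null(p2g)) {
    pw <- unique(m2p$pathway_id)
    p2g <- data.frame(pathway_id = pw,
                      gene_symbol = rep("GENEA", length(pw)))
  }
  if (is.null(ont))
    ont <- data.frame(child_chebi_id = character(0),
                      parent_chebi_id = character(0))
  if (is.null(ints))
    ints <- data.frame(gene_a = character(0), gene_b = character(0),
                       combined_score = integer(0))
  files <- c(met2pathway = file.path(dir, "met2pathway.tsv"),
             pathway2gene = file.path(dir, "pathway2gene.tsv"),
             ontology = file.path(dir, "ontology.tsv"),
             interactions = file.path(dir, "interactions.tsv"))
  write.table(m2p, files["met2pathway"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(p2g, files["pathway2gene"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ont, files["ontology"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ints, files["interactions"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(kb = parse_knowledgebase_dir(dir), dir = dir, files = files)
}

# Random DAG ontology over ids 1..n_nodes (edges child -> parent always point
# to a later node in a random topological order, hence acyclic), with a
# random subset of pathway-mapped ids. Returns tables plus a parsed kb.
random_ontology_kb <- function(n_nodes = 12, n_edges = 16, n_mapped = 3) {
  ids <- as.character(sample(1000:9999, n_nodes))
  ord <- sample(n_nodes)                # ord[i] = topological rank of ids[i]
  from <- sample(n_nodes, n_edges, replace = TRUE)
  shift <- sapply(from, function(f) {
    later <- which(ord > ord[f])
    if (length(later)) sample(c(later, later), 1L) else NA_integer_
  })
  keep <- !is.na(shift)
  ont <- unique(data.frame(child_chebi_id = ids[from[keep]],
                           parent_chebi_id = ids[shift[keep]],
                           stringsAsFactors = FALSE))
  mapped <- sample(ids, n_mapped)
  m2p <- data.frame(chebi_id = mapped, pathway_id = "R-TST-0000001",
                    stringsAsFactors = FALSE)
  fix <- kb_from_tables(m2p = m2p, ont = ont)
  list(kb = fix$kb, ont = ont, mapped = mapped, ids = ids)
}

# Paired TSV matrices + snapshot whose gene/metabolite names line up, for
# workflow tests.
workflow_inputs <- function(seed = 1, n = 40, dir = tempfile("wf")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kb_fix <- generate_fixture_knowledgebase(n_metabolites = 8L, n_pathways = 3L,
                                           n_genes = 12L, ontology_depth = 2L,
                                           seed = seed,
                                           dir = file.path(dir, "kb"))
  sim <- generate_paired_omics(synthetic_spec(n, 12, 8, c(0.8, 0.5),
                                              seed = seed))
  X <- omics_matrix(sim$X$values, sample_ids = sim$X$sample_ids,
                    feature_ids = sprintf("GENE%03d", 1:12),
                    namespace = "HGNC")
  Y <- omics_matrix(sim$Y$values, sample_ids = sim$Y$sample_ids,
                    feature_ids = kb_fix$metabolites, namespace = "CHEBI")
  x_path <- file.path(dir, "X.tsv"); y_path <- file.path(dir, "Y.tsv")
  write_omics_matrix(X, x_path)
  write_omics_matrix(Y, y_path)
  list(x_path = x_path, y_path = y_path, kb_dir = kb_fix$dir, dir = dir)
}
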