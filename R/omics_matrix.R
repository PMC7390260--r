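#' Sample-by-feature omics matrix
#'
#' Container for one omics data set. Rows are samples, columns are features;
#' feature identifiers live in a declared namespace (HGNC symbols for
#' transcriptomics, bare ChEBI integers for metabolomics). All downstream
#' statistics (pruning, CCA, PLS) operate on these objects.
#'
#' Invariants enforced at construction: no duplicate sample or feature
#' identifiers, no missing or non-finite values (incomplete data must be
#' handled upstream; no imputation rule is applied here), and at least three
#' samples so that a correlation is defined with positive degrees of freedom.
#'
#' @param values numeric matrix, `n_samples x n_features`.
#' @param sample_ids character vector of unique sample identifiers.
#' @param feature_ids character vector of unique feature identifiers; for
#'   namespace `"CHEBI"` they are normalized to bare integers (a `"CHEBI:"`
#'   prefix is stripped).
#' @param namespace one of `"HGNC"`, `"CHEBI"`, `"ENSEMBL"`, `"UNIPROT"`.
#' @return An object of class `omics_matrix`: a list with elements `values`
#'   (numeric matrix with dimnames), `sample_ids`, `feature_ids`, `namespace`.
#' @seealso [read_omics_matrix()], [write_omics_matrix()]
#' @export
omics_matrix <- function(values,
                         sample_ids = rownames(values),
                         feature_ids = colnames(values),
                         namespace = c("HGNC", "CHEBI", "ENSEMBL", "UNIPROT")) {
  namespace <- match.arg(namespace)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)

  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty matrix: no samples or no features", call. = FALSE)
  if (length(sample_ids) != nrow(values))
    stop("length of sample_ids does not match number of rows", call. = FALSE)
  if (length(feature_ids) != ncol(values))
    stop("length of feature_ids does not match number of columns", call. = FALSE)
  if (nrow(values) < 3L)
    stop("at least 3 samples are required (n_samples = ", nrow(values), ")",
         call. = FALSE)

  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  if (namespace == "CHEBI")
    feature_ids <- vapply(feature_ids, normalize_chebi, character(1),
                          USE.NAMES = FALSE)
  dup_f <- feature_ids[duplicated(feature_ids)]
  if (length(dup_f))
    stop("duplicate feature id(s): ", paste(unique(dup_f), collapse = ", "),
         call. = FALSE)

  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop("missing or non-finite value at sample '", sample_ids[bad[1L, 1L]],
         "', feature '", feature_ids[bad[1L, 2L]], "'", call. = FALSE)

  dimnames(values) <- list(sample_ids, feature_ids)
  structure(
    list(values = values, sample_ids = sample_ids,
         feature_ids = feature_ids, namespace = namespace),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat("omics_matrix: ", length(x$sample_ids), " samples x ",
      length(x$feature_ids), " features [", x$namespace, "]\n", sep = "")
  cat("  features: ",
      paste(utils::head(x$feature_ids, 5L), collapse = ", "),
      if (length(x$feature_ids) > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.omics_matrix <- function(x, ...) x$values

#' @export
dim.omics_matrix <- function(x) dim(x$values)

# Accept either an omics_matrix or a plain numeric matrix in the engines.
as_values <- function(x) {
  if (inherits(x, "omics_matrix")) return(x$values)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  m
}

#' Read a tab-delimited omics matrix
#'
#' Reads a TSV file whose first row holds feature identifiers (first cell is
#' an arbitrary label for the sample-id column) and whose first column holds
#' sample identifiers; all remaining cells must be numeric. Column order is
#' preserved exactly as in the file — it matters for the deterministic greedy
#' rule in [prune_correlated()]. UTF-8 with LF or CRLF line endings.
#'
#' @param path path to the tab-delimited file.
#' @inheritParams omics_matrix
#' @return An [omics_matrix()].
#' @export
read_omics_matrix <- function(path,
                              namespace = c("HGNC", "CHEBI", "ENSEMBL",
                                            "UNIPROT")) {
  namespace <- match.arg(namespace)
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "",
                           blank.lines.skip = TRUE, fileEncoding = "UTF-8",
                           stringsAsFactors = FALSE)
  if (nrow(raw) < 2L || ncol(raw) < 2L)
    stop("empty matrix in '", path, "': need a header row, at least one ",
         "feature column and one sample row", call. = FALSE)

  feature_ids <- trimws(as.character(raw[1L, -1L]))
  sample_ids <- trimws(as.character(raw[-1L, 1L]))
  cells <- as.matrix(raw[-1L, -1L, drop = FALSE])
  cells <- trimws(cells)

  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop("non-numeric or missing cell at row ", i + 1L, " (sample '",
         sample_ids[i], "'), column ", j + 1L, " (feature '", feature_ids[j],
         "') in '", path, "': '", cells[i, j], "'", call. = FALSE)
  }

  omics_matrix(num, sample_ids = sample_ids, feature_ids = feature_ids,
               namespace = namespace)
}

#' Write an omics matrix as tab-delimited text
#'
#' Values are written with `%.17g`, so a write/read round trip reproduces the
#' doubles bit for bit.
#'
#' @param m an [omics_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(m, path) {
  stopifnot(inherits(m, "omics_matrix"))
  header <- paste(c("sample_id", m$feature_ids), collapse = "\t")
  rows <- vapply(seq_along(m$sample_ids), function(i) {
    paste(c(m$sample_ids[i], sprintf("%.17g", m$values[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}
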