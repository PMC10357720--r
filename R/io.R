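# Readers/writers for the plain-text formats the toolkit touches: TSV
# expression matrices, GMT gene sets, GAF-like annotation TSVs, PPI edge
# lists, clinical tables and risk-coefficient tables.  Gene identifier
# matching throughout the package is exact, case-sensitive string equality.

#' Read a gene-by-patient expression matrix from TSV
#'
#' Expects gene symbols in the first column, patient ids in the header row and
#' a numeric non-negative body.  Duplicated gene rows are collapsed by their
#' mean (with a warning), which is deterministic and order-independent.
#'
#' @param path Path to a tab-separated file.
#' @param cohort Cohort label to attach.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, cohort) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || nrow(df) == 0L) stop_pu("empty or malformed expression table")
  genes <- as.character(df[[1L]])
  body <- df[-1L]
  if (!all(vapply(body, is.numeric, logical(1L))) || anyNA(body)) {
    stop_pu("expression body must be numeric with no missing values")
  }
  values <- as.matrix(body)
  if (anyDuplicated(genes)) {
    warn_pu(sum(duplicated(genes)), " duplicated gene rows collapsed by mean")
    values <- rowsum(values, group = genes, reorder = FALSE) /
      as.vector(table(genes)[unique(genes)])
    genes <- unique(genes)
  }
  rownames(values) <- genes
  expression_matrix(values, cohort)
}

#' Write an expression matrix to TSV
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene set collection
#'
#' One set per line: `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path Path to a GMT file.
#' @return A [gene_sets()] collection (empty file gives an empty collection).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_sets(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    stop_pu("GMT line with fewer than 3 fields (name, description, members...)")
  }
  nm <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nm)) stop_pu("duplicate gene set name in GMT: ",
                                 nm[duplicated(nm)][1L])
  desc <- vapply(fields, `[[`, character(1L), 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  gene_sets(stats::setNames(sets, nm), desc)
}

#' Write a gene set collection to GMT
#' @param x A [gene_sets()] collection.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  desc <- attr(x, "descriptions") %||% rep("", length(x))
  lines <- vapply(seq_along(x), function(i) {
    paste(c(names(x)[i], desc[[i]], x[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GAF-style annotation table, filtered by evidence codes
#'
#' Expects tab-separated columns `gene`, `term_id`, `term_name`, `evidence`
#' (with a header).  Records whose evidence code is not in the declared
#' vocabulary are dropped with a warning; records failing `evidence_filter`
#' are silently discarded.  The surviving records are grouped into term-keyed
#' gene sets.
#'
#' @param path Path to the annotation TSV.
#' @param evidence_filter Evidence codes to keep; defaults to
#'   [experimental_evidence()].
#' @param vocabulary Declared evidence vocabulary.
#' @return A [gene_sets()] collection keyed by term id, with term names as
#'   descriptions.
#' @export
read_annotations <- function(path, evidence_filter = experimental_evidence(),
                             vocabulary = c(experimental_evidence(),
                                            "IEA", "ISS", "TAS", "NAS", "IC")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene", "term_id", "term_name", "evidence")
  if (!all(need %in% names(df))) {
    stop_pu("annotation file must have columns ", paste(need, collapse = ", "))
  }
  unknown <- !(df$evidence %in% vocabulary)
  if (any(unknown)) {
    warn_pu(sum(unknown), " records with unknown evidence codes dropped")
    df <- df[!unknown, , drop = FALSE]
  }
  tab <- annotation_table(df$gene, df$term_id, df$term_name, df$evidence)
  annotation_sets(tab, evidence_filter)
}

#' Group an annotation table into term-keyed gene sets
#'
#' @param annotations An [annotation_table()].
#' @param evidence_filter Evidence codes to keep.
#' @return A [gene_sets()] keyed by term id (empty, with a warning, if no
#'   record survives the filter).
#' @export
annotation_sets <- function(annotations, evidence_filter = experimental_evidence()) {
  keep <- annotations[annotations$evidence %in% evidence_filter, , drop = FALSE]
  if (nrow(keep) == 0L) {
    warn_pu("no annotation records survive the evidence filter")
    return(gene_sets(list()))
  }
  sets <- split(keep$gene, keep$term_id)
  desc <- vapply(split(keep$term_name, keep$term_id), `[[`, character(1L), 1L)
  gene_sets(lapply(sets, unique), desc)
}

#' Write an annotation table to TSV
#' @param annotations An [annotation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Two tab-separated columns (no header), one interacting pair per row.
#' Self-loops and duplicate/reversed edges are dropped; counts are reported in
#' a message.  The result is an undirected simple [igraph::graph] over gene
#' symbols, idempotent under edge duplication and orientation flips.
#'
#' @param path Path to the edge list.
#' @return An undirected simple `igraph` graph (empty file gives an empty
#'   graph).
#' @export
read_ppi <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(igraph::make_empty_graph(0, directed = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L)) stop_pu("PPI rows must have exactly 2 columns")
  el <- do.call(rbind, fields)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  loops <- sum(igraph::which_loop(g))
  multi <- sum(igraph::which_multiple(g))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (loops + multi > 0L) {
    message(sprintf("read_ppi: dropped %d self-loops and %d duplicate edges",
                    loops, multi))
  }
  g
}

#' Write a PPI graph as a 2-column edge list
#' @param g An undirected `igraph` graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppi <- function(g, path) {
  el <- igraph::as_edgelist(g)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a clinical table from TSV
#' @param path Path to a TSV with at least `patient_id`, `cohort`,
#'   `survival_time`, `event`, `stage` columns.
#' @return A [clinical_table()].
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("patient_id", "cohort", "survival_time", "event", "stage")
  if (!all(need %in% names(df))) {
    stop_pu("clinical file must have columns ", paste(need, collapse = ", "))
  }
  extra <- df[setdiff(names(df), need)]
  do.call(clinical_table, c(df[need], extra))
}

#' Write a clinical table to TSV
#' @param clinical A [clinical_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-gene risk coefficients from TSV
#' @param path TSV with columns `gene` and `coefficient`.
#' @return A [risk_model()].
#' @export
read_risk_model <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene", "coefficient") %in% names(df))) {
    stop_pu("risk model file must have columns gene, coefficient")
  }
  risk_model(stats::setNames(as.numeric(df$coefficient), df$gene))
}

#' Write a risk model to TSV
#' @param model A [risk_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_risk_model <- function(model, path) {
  utils::write.table(data.frame(gene = names(model),
                                coefficient = as.numeric(model)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
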