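# Typed containers for the toolkit's inputs and outputs.  All are light S3
# wrappers over base structures so standard matrix/data.frame idioms keep
# working on them.

#' Construct a cohort expression matrix
#'
#' A gene-by-patient matrix of non-negative normalized abundances (TPM-like)
#' tagged with a cohort label.  Genes are rows, patients are columns.
#'
#' @param values Numeric matrix with unique gene symbols as `rownames` and
#'   unique patient barcodes as `colnames`.  All values must be finite and
#'   non-negative.
#' @param cohort Single short cohort label, e.g. `"BRCA"`.
#' @return A numeric matrix of class `"expr_matrix"` with a `cohort`
#'   attribute.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("p1", "p2")))
#' x <- expression_matrix(m, "TOY")
#' cohort(x)
#' @export
expression_matrix <- function(values, cohort) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_pu("expression values must be a numeric matrix")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop_pu("expression matrix is empty")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_pu("expression matrix needs gene rownames and patient colnames")
  }
  if (anyDuplicated(rownames(values))) stop_pu("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop_pu("duplicate patient ids")
  if (any(!is.finite(values))) stop_pu("expression values must be finite")
  if (any(values < 0)) stop_pu("expression values must be non-negative")
  if (!is.character(cohort) || length(cohort) != 1L || !nzchar(cohort)) {
    stop_pu("cohort must be a single non-empty label")
  }
  structure(values, cohort = cohort, class = c("expr_matrix", class(values)))
}

#' Cohort label of an expression matrix
#' @param x An `expr_matrix`.
#' @return The cohort label string.
#' @export
cohort <- function(x) attr(x, "cohort")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> cohort %s: %d genes x %d patients\n",
              cohort(x), nrow(x), ncol(x)))
  invisible(x)
}

# subsetting keeps class/cohort when result is still a matrix
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "cohort") <- cohort(x)
    class(out) <- c("expr_matrix", class(out)[class(out) != "expr_matrix"])
  }
  out
}

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors (unique set names, non-empty
#'   member vectors).
#' @param descriptions Optional character vector of per-set descriptions
#'   (recycled from `""`).
#' @return A named list of class `"gene_sets"`.
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (!is.list(sets)) stop_pu("sets must be a list")
  if (length(sets)) {
    if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
      stop_pu("every gene set needs a name")
    }
    if (anyDuplicated(names(sets))) stop_pu("duplicate gene set names")
    if (any(!vapply(sets, is.character, logical(1L)))) {
      stop_pu("gene sets must be character vectors")
    }
    if (any(lengths(sets) == 0L)) stop_pu("gene sets must be non-empty")
    sets <- lapply(sets, unique)
  }
  desc <- descriptions %||% rep("", length(sets))
  if (length(desc) != length(sets)) stop_pu("one description per set required")
  structure(sets, descriptions = stats::setNames(desc, names(sets)),
            class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("<gene_sets> %d sets; sizes %s\n", length(x),
              if (length(x)) paste(range(lengths(x)), collapse = "-") else "-"))
  invisible(x)
}

#' @export
`[.gene_sets` <- function(x, i) {
  gene_sets(unclass(x)[i], attr(x, "descriptions")[i])
}

#' Construct a gene annotation table
#'
#' GAF-style flat records linking genes to functional terms with evidence
#' codes.  `(gene, term_id, evidence)` triples must be unique.
#'
#' @param gene,term_id,term_name,evidence Character vectors of equal length.
#' @return A `data.frame` of class `"annotation_table"`.
#' @export
annotation_table <- function(gene, term_id, term_name, evidence) {
  df <- data.frame(gene = as.character(gene), term_id = as.character(term_id),
                   term_name = as.character(term_name),
                   evidence = as.character(evidence),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("gene", "term_id", "evidence")])) {
    stop_pu("duplicate (gene, term, evidence) annotation records")
  }
  class(df) <- c("annotation_table", class(df))
  df
}

#' Experimental evidence codes treated as 'experimentally validated'
#'
#' The default evidence filter used when turning annotations into term gene
#' sets or similarity profiles.
#' @return Character vector of evidence codes.
#' @export
experimental_evidence <- function() c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")

#' Construct a risk model
#'
#' Per-gene coefficients on the log-hazard scale, typically exported from a
#' pre-trained Cox regression.
#' @param coefficients Named numeric vector (names are gene symbols).
#' @return Named numeric vector of class `"risk_model"`.
#' @export
risk_model <- function(coefficients) {
  if (!is.numeric(coefficients) || is.null(names(coefficients))) {
    stop_pu("coefficients must be a named numeric vector")
  }
  if (anyDuplicated(names(coefficients))) stop_pu("duplicate genes in risk model")
  if (any(!is.finite(coefficients))) stop_pu("risk coefficients must be finite")
  structure(coefficients, class = "risk_model")
}

#' Construct a clinical table
#'
#' @param patient_id Character patient barcodes (unique).
#' @param cohort Cohort label per patient.
#' @param survival_time Follow-up time in days (non-negative).
#' @param event Event indicator, 0 = censored, 1 = death.
#' @param stage Ordinal pathologic stage, one of `"I"`, `"II"`, `"III"`,
#'   `"IV"`, `"unknown"`.
#' @param ... Additional per-patient columns (subtype flags such as
#'   `er`, `pr`, `her2`, `tnbc`).
#' @return A `data.frame` of class `"clinical_table"`.
#' @export
clinical_table <- function(patient_id, cohort, survival_time, event,
                           stage = "unknown", ...) {
  df <- data.frame(patient_id = as.character(patient_id),
                   cohort = as.character(cohort),
                   survival_time = as.numeric(survival_time),
                   event = as.integer(event),
                   stage = as.character(stage),
                   ..., stringsAsFactors = FALSE)
  if (anyDuplicated(df$patient_id)) stop_pu("duplicate patient ids")
  if (any(df$survival_time < 0, na.rm = TRUE)) stop_pu("negative survival time")
  if (!all(df$event %in% c(0L, 1L))) stop_pu("event must be 0/1")
  if (!all(df$stage %in% c("I", "II", "III", "IV", "unknown"))) {
    stop_pu("stage must be I..IV or 'unknown'")
  }
  class(df) <- c("clinical_table", class(df))
  df
}
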