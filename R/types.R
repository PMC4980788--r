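# Domain containers.  All are light S3 lists in the style of base-R
# scientific packages; each constructor validates its invariants.

#' Expression matrix container
#'
#' An `expression_matrix` holds `N` samples by `n` genes of continuous
#' expression levels, with unique gene names and (possibly synthesized)
#' sample identifiers.
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param gene_names character vector of `ncol(values)` unique identifiers.
#'   Defaults to the column names of `values`.
#' @param sample_ids character vector of row identifiers; `"S1".."SN"` is
#'   synthesized when absent.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_names`, `sample_ids`.
#' @examples
#' expression_matrix(matrix(rnorm(20), 5, 4))
#' @export
expression_matrix <- function(values, gene_names = colnames(values),
                              sample_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  gene_names <- as.character(gene_names)
  sample_ids <- as.character(sample_ids)
  if (ncol(values) < 2) stopf("expression matrix needs at least 2 genes, found %d", ncol(values))
  if (nrow(values) < 2) stopf("expression matrix needs at least 2 samples, found %d", nrow(values))
  if (length(gene_names) != ncol(values))
    stopf("gene_names length (%d) does not match gene count (%d)",
          length(gene_names), ncol(values))
  if (length(sample_ids) != nrow(values))
    stopf("sample_ids length (%d) does not match sample count (%d)",
          length(sample_ids), nrow(values))
  if (anyDuplicated(gene_names))
    stopf("duplicated gene names: %s",
          paste(unique(gene_names[duplicated(gene_names)]), collapse = ", "))
  if (!is.numeric(values) || any(!is.finite(values)))
    stopf("expression values must all be finite numbers")
  dimnames(values) <- list(sample_ids, gene_names)
  structure(list(values = values, gene_names = gene_names,
                 sample_ids = sample_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d genes\n",
              nrow(x$values), ncol(x$values)))
  cat("genes:", paste(head(x$gene_names, 8), collapse = ", "),
      if (length(x$gene_names) > 8) "..." else "", "\n")
  invisible(x)
}

#' Knockout dataset container
#'
#' Holds one wild-type expression vector plus an `n x n` matrix whose row
#' `i` is the genome-wide expression profile measured after knocking out
#' gene `i` (columns are the observed genes, in the same order).
#'
#' @param wild_type numeric length-`n` vector of unperturbed expression.
#' @param knockouts numeric `n x n` matrix; entry `(i, j)` is expression of
#'   gene `j` after gene `i` is knocked out.
#' @param gene_names character vector of `n` unique gene identifiers.
#'
#' @return An object of class `knockout_dataset`.
#' @export
knockout_dataset <- function(wild_type, knockouts,
                             gene_names = colnames(knockouts)) {
  knockouts <- as.matrix(knockouts)
  n <- length(wild_type)
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(n))
  gene_names <- as.character(gene_names)
  if (nrow(knockouts) != n || ncol(knockouts) != n)
    stopf("knockout matrix must be %d x %d to match the wild type, found %d x %d",
          n, n, nrow(knockouts), ncol(knockouts))
  if (length(gene_names) != n || anyDuplicated(gene_names))
    stopf("gene_names must be %d unique identifiers", n)
  if (any(!is.finite(wild_type)) || any(!is.finite(knockouts)))
    stopf("knockout dataset entries must all be finite")
  wild_type <- as.numeric(wild_type)
  names(wild_type) <- gene_names
  dimnames(knockouts) <- list(gene_names, gene_names)
  structure(list(wild_type = wild_type, knockouts = knockouts,
                 gene_names = gene_names),
            class = "knockout_dataset")
}

#' @export
print.knockout_dataset <- function(x, ...) {
  cat(sprintf("knockout_dataset: wild type + %d single-gene knockouts\n",
              length(x$gene_names)))
  invisible(x)
}

#' Gold-standard network container
#'
#' Binary adjacency of true regulations used for evaluation.  The matrix is
#' indexed `(target, regulator)`: entry `(i, j) = 1` means gene `j` truly
#' regulates gene `i`.  Self-loops are never scored; the diagonal is forced
#' to zero.
#'
#' @param adjacency `n x n` matrix with entries in `{0, 1}`.
#' @param gene_names character vector of `n` unique gene identifiers.
#' @return An object of class `gold_standard`.
#' @export
gold_standard <- function(adjacency, gene_names = colnames(adjacency)) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stopf("adjacency must be square")
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(n))
  gene_names <- as.character(gene_names)
  if (length(gene_names) != n || anyDuplicated(gene_names))
    stopf("gene_names must be %d unique identifiers", n)
  if (!all(adjacency %in% c(0, 1)))
    stopf("gold-standard adjacency entries must be 0 or 1")
  diag(adjacency) <- 0
  storage.mode(adjacency) <- "double"
  dimnames(adjacency) <- list(gene_names, gene_names)
  structure(list(adjacency = adjacency, gene_names = gene_names),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("gold_standard: %d genes, %d true edges\n",
              length(x$gene_names), sum(x$adjacency)))
  invisible(x)
}

#' Edge-score matrix container
#'
#' The common currency of all inference methods: a nonnegative `n x n`
#' matrix of edge confidences indexed `(target, regulator)`, with an
#' exactly-zero diagonal.
#'
#' @param scores nonnegative `n x n` numeric matrix; entry `(i, j)` is the
#'   confidence that gene `j` regulates target gene `i`.
#' @param gene_names character vector of `n` unique gene identifiers.
#' @param method optional label of the method that produced the scores.
#' @return An object of class `edge_scores`.
#' @export
edge_scores <- function(scores, gene_names = colnames(scores),
                        method = NULL) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (ncol(scores) != n) stopf("edge-score matrix must be square")
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(n))
  gene_names <- as.character(gene_names)
  if (length(gene_names) != n || anyDuplicated(gene_names))
    stopf("gene_names must be %d unique identifiers", n)
  if (any(!is.finite(scores))) stopf("edge scores must all be finite")
  if (any(scores < 0)) stopf("edge scores must be nonnegative")
  if (any(diag(scores) != 0))
    stopf("edge-score diagonal must be exactly zero (self-edges are not scored)")
  dimnames(scores) <- list(gene_names, gene_names)
  structure(list(scores = scores, gene_names = gene_names, method = method),
            class = "edge_scores")
}

#' @export
print.edge_scores <- function(x, ...) {
  cat(sprintf("edge_scores (%s): %d genes, %d candidate edges\n",
              if (is.null(x$method)) "unlabelled" else x$method,
              length(x$gene_names),
              length(x$gene_names) * (length(x$gene_names) - 1)))
  invisible(x)
}

check_same_genes <- function(a, b, what = "objects") {
  if (!identical(a$gene_names, b$gene_names))
    stopf("%s refer to different gene sets or orders", what)
  invisible(TRUE)
}
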