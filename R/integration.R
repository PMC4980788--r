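# Integration of edge-scoring criteria.
#
# IMLARF and ISLARF combine two edge-score matrices by their entry-wise
# (Hadamard) product: the symmetric factor (MI or the knockout z-score S)
# supplies a dependency strength, the LARF frequency matrix F supplies the
# direction, and an edge survives only if both criteria support it.

#' Entry-wise (Hadamard) product of two edge-score matrices
#'
#' `result[i, j] = a[i, j] * b[i, j]`.  Shapes and gene orders must match.
#' A symmetric factor times an asymmetric one yields an asymmetric result:
#' direction is inherited from the asymmetric factor.
#'
#' @param a,b [edge_scores()] matrices over the same genes.
#' @return An [edge_scores()] matrix.
#' @export
entrywise_product <- function(a, b) {
  stopifnot(inherits(a, "edge_scores"), inherits(b, "edge_scores"))
  check_same_genes(a, b, "edge-score matrices")
  lbl <- paste(c(a$method, b$method), collapse = "*")
  edge_scores(a$scores * b$scores, a$gene_names,
              method = if (nzchar(lbl)) lbl else NULL)
}

#' Convert a knockout dataset into an expression matrix
#'
#' Stacks the knockout rows (optionally preceded by the wild-type row)
#' into an expression matrix, the sample set on which MI and LARF operate
#' in knockout-only experiments.
#'
#' @param ko a [knockout_dataset()].
#' @param include_wild_type prepend the wild-type row (default `TRUE`).
#' @return An [expression_matrix()] with `n` (or `n + 1`) samples.
#' @export
ko_as_expression <- function(ko, include_wild_type = TRUE) {
  stopifnot(inherits(ko, "knockout_dataset"))
  if (include_wild_type) {
    expression_matrix(rbind(wt = ko$wild_type, ko$knockouts),
                      ko$gene_names, c("wt", ko$gene_names))
  } else {
    expression_matrix(ko$knockouts, ko$gene_names, ko$gene_names)
  }
}

#' Infer an edge-score matrix with any of the five methods
#'
#' Dispatches the five inference methods behind one interface:
#' \describe{
#'   \item{`MI`}{Gaussian mutual information, [mi_matrix()].}
#'   \item{`ZS`}{knockout z-scores, [zscore_matrix()]; needs knockout
#'     data.}
#'   \item{`LARF`}{lasso random featuring, [larf_frequency_matrix()].}
#'   \item{`IMLARF`}{entry-wise product MI * LARF.}
#'   \item{`ISLARF`}{entry-wise product ZS * LARF; needs knockout data.}
#' }
#'
#' MI and LARF run on `expression`; when `expression` is missing but
#' knockout data is supplied, the wild-type plus knockout rows are used as
#' the expression samples (the layout of knockout-only experiments; set
#' `include_wild_type = FALSE` to drop the wild-type row).  All matrices
#' are indexed `(target, regulator)`, so the factors of IMLARF and ISLARF
#' are aligned before the product.
#'
#' @param method one of `"MI"`, `"ZS"`, `"LARF"`, `"IMLARF"`, `"ISLARF"`
#'   (case-insensitive).
#' @param expression an [expression_matrix()], or `NULL`.
#' @param knockouts a [knockout_dataset()], or `NULL`.
#' @param cfg a [larf_config()] for the LARF-based methods.
#' @param exclude_self passed to [zscore_matrix()].
#' @param include_wild_type include the wild-type row when deriving
#'   expression samples from knockout data (default `TRUE`).
#' @return An [edge_scores()] matrix.
#' @export
infer <- function(method, expression = NULL, knockouts = NULL,
                  cfg = larf_config(), exclude_self = TRUE,
                  include_wild_type = TRUE) {
  method <- toupper(match.arg(tolower(method),
                              c("mi", "zs", "larf", "imlarf", "islarf")))
  needs_expr <- method %in% c("MI", "LARF", "IMLARF", "ISLARF")
  needs_ko <- method %in% c("ZS", "ISLARF")
  if (needs_ko && is.null(knockouts))
    stopf("%s is not applicable without knockout data", method)
  if (needs_expr && is.null(expression)) {
    if (is.null(knockouts))
      stopf("%s requires an expression matrix", method)
    expression <- ko_as_expression(knockouts, include_wild_type)
  }
  if (!is.null(expression) && !is.null(knockouts))
    check_same_genes(expression, knockouts,
                     "expression and knockout datasets")
  out <- switch(method,
    MI = mi_matrix(expression),
    ZS = zscore_matrix(variation_matrix(knockouts), exclude_self),
    LARF = larf_frequency_matrix(expression, cfg),
    IMLARF = entrywise_product(mi_matrix(expression),
                               larf_frequency_matrix(expression, cfg)),
    ISLARF = entrywise_product(
      zscore_matrix(variation_matrix(knockouts), exclude_self),
      larf_frequency_matrix(expression, cfg)))
  out$method <- method
  out
}
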