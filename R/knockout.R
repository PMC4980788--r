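# Knockout z-score edge scoring.
#
# The variation matrix D records how each gene moves away from wild type
# when another gene is deleted:  D[i, j] = X^{-i}_j - X^{wt}_j, row i the
# knocked-out gene, column j the observed gene.  Each column of D is then
# z-scored — the signed variations, not their absolute values — and only
# the final z is taken in absolute value:  S[j, i] = |(D[i, j] - mu_j) /
# sigma_j|, the confidence that gene i regulates target gene j.
# Z-scoring |D| instead would not reward unusually large variations and is
# deliberately not offered as a scoring method.

#' Knockout variation matrix
#'
#' `D[i, j]` is the expression change of gene `j` after knocking out gene
#' `i`, relative to wild type.
#'
#' @param ko a [knockout_dataset()].
#' @return A list of class `variation_matrix` with elements `values`
#'   (`n x n`, row = knocked-out gene, column = observed gene) and
#'   `gene_names`.
#' @examples
#' ko <- knockout_dataset(c(1, 2), matrix(c(1, 0, 5, 2), 2, 2),
#'                        c("G1", "G2"))
#' variation_matrix(ko)$values
#' @export
variation_matrix <- function(ko) {
  stopifnot(inherits(ko, "knockout_dataset"))
  d <- sweep(ko$knockouts, 2, ko$wild_type, "-")
  structure(list(values = d, gene_names = ko$gene_names),
            class = "variation_matrix")
}

#' @export
print.variation_matrix <- function(x, ...) {
  cat(sprintf("variation_matrix: %d x %d (knocked-out gene x observed gene)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Knockout z-score matrix
#'
#' Z-scores each column of the variation matrix and returns absolute
#' z-scores as an edge-score matrix: `S[j, i] = |(D[i, j] - mu_j) /
#' sigma_j|` scores the edge gene `i` -> gene `j` (row of the result is
#' the target).  `mu_j` and `sigma_j` are the mean and sample standard
#' deviation of column `j` over the included rows.
#'
#' By default the self-knockout entry `D[j, j]` — a gene's own collapse
#' when it is itself deleted — is excluded from `mu_j` and `sigma_j`, since
#' it is systematically extreme and the self-edge is never scored.  Set
#' `exclude_self = FALSE` to include all rows in the column statistics.
#'
#' @param d a [variation_matrix()].
#' @param exclude_self drop the self-knockout entry from each column's
#'   statistics (default `TRUE`).
#' @return An [edge_scores()] matrix (method `"ZS"`).
#' @export
zscore_matrix <- function(d, exclude_self = TRUE) {
  stopifnot(inherits(d, "variation_matrix"))
  v <- d$values
  n <- ncol(v)
  s <- matrix(0, n, n)
  for (j in seq_len(n)) {
    rows <- if (exclude_self) setdiff(seq_len(n), j) else seq_len(n)
    mu <- mean(v[rows, j])
    sigma <- sd(v[rows, j])
    if (!is.finite(sigma) || sigma < 1e-12)
      stopf(paste0("gene %s: knockout variations have zero spread, ",
                   "z-scores are undefined; add observation noise or ",
                   "exclude the gene"), d$gene_names[j])
    z <- abs((v[, j] - mu) / sigma)
    s[j, ] <- z          # row j of S = target j; column i = knocked-out gene
    s[j, j] <- 0
  }
  edge_scores(s, d$gene_names, method = "ZS")
}
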