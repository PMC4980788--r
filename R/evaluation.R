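# Evaluation of ranked edge lists against a gold standard.
#
# The edge-score matrix is flattened into the n(n-1) candidate directed
# edges (self-edges excluded), ranked by descending confidence, and traced
# as an ROC curve over every top-k cutoff, k = 0..n(n-1).  Ties are given
# half credit: within a tied block the expected true-positive count under
# a random tie order is used, which makes the per-k points collinear
# within the block and the trapezoidal area equal to the Mann-Whitney
# probability estimate.

#' Rank all candidate edges by confidence
#'
#' Flattens an edge-score matrix into its `n(n-1)` off-diagonal entries,
#' sorted by descending score; ties are broken by regulator index then
#' target index, so the order is deterministic.
#'
#' @param w an [edge_scores()] matrix.
#' @return A data frame with columns `regulator`, `target`, `score`.
#' @export
rank_edges <- function(w) {
  stopifnot(inherits(w, "edge_scores"))
  n <- length(w$gene_names)
  reg <- rep(seq_len(n), each = n)      # loop regulator-major for tie-break
  tgt <- rep(seq_len(n), times = n)
  keep <- reg != tgt
  reg <- reg[keep]; tgt <- tgt[keep]
  sc <- w$scores[cbind(tgt, reg)]
  ord <- order(-sc, reg, tgt)
  data.frame(regulator = w$gene_names[reg[ord]],
             target = w$gene_names[tgt[ord]],
             score = sc[ord], stringsAsFactors = FALSE)
}

#' ROC curve and AUROC of an edge-score matrix
#'
#' Calls the top-`k` ranked edges positive for every `k = 0..n(n-1)` and
#' computes TPR = TP/(TP+FN) and FPR = FP/(FP+TN) at each cutoff.  Tied
#' scores contribute their expected true-positive count under a random
#' tie order (half credit), so the trapezoidal area under the (FPR, TPR)
#' polyline equals the Mann-Whitney probability that a true edge outranks
#' a non-edge.
#'
#' @param w an [edge_scores()] matrix.
#' @param gold a [gold_standard()] over the same genes, with at least one
#'   true edge and one non-edge off the diagonal.
#' @return A list of class `roc_result` with elements `fpr`, `tpr`
#'   (non-decreasing, spanning 0 to 1), `auroc`, and `k_grid`.
#' @examples
#' g <- gold_standard(rbind(c(0, 1), c(0, 0)), c("G1", "G2"))
#' w <- edge_scores(rbind(c(0, 1), c(0, 0)), c("G1", "G2"))
#' roc_auroc(w, g)$auroc    # 1
#' @export
roc_auroc <- function(w, gold) {
  stopifnot(inherits(w, "edge_scores"), inherits(gold, "gold_standard"))
  check_same_genes(w, gold, "edge scores and gold standard")
  n <- length(w$gene_names)
  off <- which(row(w$scores) != col(w$scores))
  sc <- w$scores[off]
  lab <- gold$adjacency[off]
  pos <- sum(lab == 1)
  neg <- sum(lab == 0)
  if (pos == 0 || neg == 0)
    stopf("gold standard must contain at least one true edge and one non-edge")
  # group by distinct score, descending
  o <- order(-sc)
  sc <- sc[o]; lab <- lab[o]
  grp <- cumsum(!duplicated(sc))
  gsize <- tabulate(grp)
  gpos <- unname(vapply(split(lab, grp), sum, numeric(1)))
  m <- length(sc)
  tp_at_break <- cumsum(gpos)
  fp_at_break <- cumsum(gsize - gpos)
  k_break <- cumsum(gsize)
  # expected TP at every k: linear within each tied block
  k_grid <- 0:m
  gi <- rep(seq_along(gsize), gsize)    # block of edge at rank k
  tp_prev <- unname(c(0, tp_at_break)[gi])
  k_prev <- unname(c(0, k_break)[gi])
  tp <- c(0, tp_prev + ((1:m) - k_prev) * (gpos[gi] / gsize[gi]))
  fp <- k_grid - tp
  tpr <- tp / pos
  fpr <- fp / neg
  auroc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(fpr = fpr, tpr = tpr, auroc = auroc, k_grid = k_grid),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUROC = %.4f over %d cutoffs\n",
              x$auroc, length(x$k_grid)))
  invisible(x)
}

#' AUROC parameter grid for LARF
#'
#' Runs LARF `repeats` times for every `(alpha, r)` cell with
#' deterministically derived seeds, evaluates each run's AUROC against the
#' gold standard, and reports per-cell mean and standard deviation — the
#' protocol used to choose the featuring and sampling fractions.
#'
#' @param x an [expression_matrix()].
#' @param gold a [gold_standard()] over the same genes.
#' @param alphas,rs numeric vectors of featuring and sampling fractions in
#'   `(0, 1]`.
#' @param repeats number of repeated LARF runs per cell (>= 2).
#' @param cfg base [larf_config()]; `alpha`, `r` and the per-run seed are
#'   overridden cell by cell.
#' @return A data frame with one row per cell: `alpha`, `r`,
#'   `mean_auroc`, `sd_auroc`, `repeats`.
#' @export
parameter_grid <- function(x, gold, alphas, rs, repeats = 10,
                           cfg = larf_config()) {
  stopifnot(inherits(x, "expression_matrix"), inherits(gold, "gold_standard"))
  if (any(alphas <= 0 | alphas > 1) || any(rs <= 0 | rs > 1))
    stopf("alphas and rs must lie in (0, 1]")
  if (!is_count(repeats) || repeats < 2) stopf("repeats must be >= 2")
  rows <- vector("list", length(alphas) * length(rs))
  k <- 0
  for (ai in seq_along(alphas)) for (ri in seq_along(rs)) {
    aucs <- numeric(repeats)
    for (rep in seq_len(repeats)) {
      cell_cfg <- cfg
      cell_cfg$alpha <- alphas[ai]
      cell_cfg$r <- rs[ri]
      cell_cfg$seed <- derive_seed(cfg$seed, ai, ri, rep)
      f <- larf_frequency_matrix(x, cell_cfg)
      aucs[rep] <- roc_auroc(f, gold)$auroc
    }
    k <- k + 1
    rows[[k]] <- data.frame(alpha = alphas[ai], r = rs[ri],
                            mean_auroc = mean(aucs), sd_auroc = sd(aucs),
                            repeats = repeats)
  }
  do.call(rbind, rows)
}
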