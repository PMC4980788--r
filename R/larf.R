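# LARF: lasso-based random featuring.
#
# For each target gene, a lasso regression of the target on candidate
# regulators is repeated along an increasing grid of the L1 penalty.  At
# every penalty step a fresh random subset of candidate regulators
# (fraction alpha) and of samples (fraction r) is drawn, and every
# candidate receiving a nonzero coefficient has its selection count
# incremented.  The sweep runs from lambda = 0 until the penalty exceeds
# the level at which no candidate could be selected.  The whole sweep is
# repeated t times with fresh draws; summed counts are min-max normalized
# per target row into the frequency matrix F.
#
# Random featuring is the point: a weak true regulator that would be
# shadowed by a strongly correlated competitor in a full lasso fit still
# collects counts in the draws from which the competitor is absent.

#' LARF configuration
#'
#' Bundles the knobs of the LARF sweep.
#'
#' @param alpha fraction in `(0, 1]` of candidate regulators drawn per fit;
#'   `ceiling(alpha * (n - 1))` candidates are used.  Default 0.5.
#' @param r fraction in `(0, 1]` of samples drawn per fit;
#'   `ceiling(r * N)` samples are used.  Default 1.
#' @param stepsize increment of the L1 penalty between fits (default
#'   0.001, on the standardized-predictor scale).
#' @param t number of outer sweep repeats whose counts are summed
#'   (default 10).
#' @param lambda_max safety cap on the penalty (default 10); a sweep that
#'   reaches it is truncated with a warning.
#' @param seed integer root seed; all feature and sample draws derive from
#'   it.
#' @param stop_rule `"exhaustion"` (default) ends each sweep once the
#'   penalty exceeds the largest full-data marginal covariance between the
#'   target and any candidate — the level beyond which no candidate could
#'   be selected.  `"empty_step"` ends the sweep at the first step whose
#'   fit selects nothing; with small candidate subsets that step is often
#'   triggered by an unlucky draw rather than a high penalty, which is why
#'   it is not the default.
#' @return A list of class `larf_config`.
#' @export
larf_config <- function(alpha = 0.5, r = 1, stepsize = 0.001, t = 10,
                        lambda_max = 10, seed = 1,
                        stop_rule = c("exhaustion", "empty_step")) {
  stop_rule <- match.arg(stop_rule)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stopf("alpha must be in (0, 1], got %s", format(alpha))
  if (!is.numeric(r) || r <= 0 || r > 1)
    stopf("r must be in (0, 1], got %s", format(r))
  if (!is.numeric(stepsize) || stepsize <= 0)
    stopf("stepsize must be positive")
  if (!is_count(t) || t < 1) stopf("t must be a positive integer")
  if (!is.numeric(lambda_max) || lambda_max <= 0)
    stopf("lambda_max must be positive")
  if (!is_count(seed)) stopf("seed must be an integer")
  structure(list(alpha = alpha, r = r, stepsize = stepsize, t = as.integer(t),
                 lambda_max = lambda_max, seed = as.integer(seed),
                 stop_rule = stop_rule),
            class = "larf_config")
}

#' @export
print.larf_config <- function(x, ...) {
  cat(sprintf(
    "larf_config: alpha=%g r=%g stepsize=%g t=%d lambda_max=%g seed=%d stop_rule=%s\n",
    x$alpha, x$r, x$stepsize, x$t, x$lambda_max, x$seed, x$stop_rule))
  invisible(x)
}

#' Lasso fit
#'
#' Solves `(1 / (2 m)) * ||y - X b||^2 + lambda * ||b||_1` by coordinate
#' descent.  Predictor columns are standardized internally (mean 0, unit
#' population variance) and the response is centered; returned
#' coefficients are on the original predictor scale.  At `lambda = 0` the
#' minimum-norm least-squares solution is returned.  Under this convention
#' a lone standardized predictor leaves the model at
#' `lambda = |x' y| / m`.
#'
#' @param y numeric response vector of length `m >= 2`.
#' @param x numeric `m x p` design matrix, `p >= 1`.
#' @param lambda nonnegative penalty.
#' @param tol coordinate-descent convergence tolerance on coefficients
#'   (default `1e-8`; solutions are accurate to about `1e-6`).
#' @param maxit iteration cap.
#' @return Numeric coefficient vector of length `p` (no intercept; the
#'   response is centered).
#' @examples
#' x <- matrix(seq(-2, 2, length.out = 9))
#' fit_lasso(2 * x[, 1], x, 0)        # ~2
#' @export
fit_lasso <- function(y, x, lambda, tol = 1e-8, maxit = 100000) {
  x <- as.matrix(x)
  m <- nrow(x)
  if (ncol(x) < 1) stopf("empty candidate set")
  if (length(y) != m) stopf("response length must match design rows")
  if (m < 2) stopf("need at least 2 samples")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stopf("design and response must be finite")
  if (lambda < 0) stopf("lambda must be nonnegative")
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(x^2) - mu^2)
  xs <- sweep(x, 2, mu, "-")
  ok <- sdv > 1e-12
  xs[, ok] <- sweep(xs[, ok, drop = FALSE], 2, sdv[ok], "/")
  xs[, !ok] <- 0
  yc <- y - mean(y)
  g <- crossprod(xs) / m
  c0 <- crossprod(xs, yc) / m
  b <- if (lambda == 0) {
    drop(pinv_sym(g) %*% c0)
  } else {
    drop(cd_lasso_cpp(g, c0, lambda, tol, maxit))
  }
  out <- numeric(ncol(x))
  out[ok] <- b[ok] / sdv[ok]
  out
}

# Moore-Penrose pseudoinverse of a symmetric PSD matrix via eigen.
pinv_sym <- function(g, tol = 1e-10) {
  e <- eigen(g, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  if (!any(keep)) return(matrix(0, nrow(g), ncol(g)))
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

#' One LARF penalty sweep for a single target gene
#'
#' Runs the lambda sweep described in [larf_config()] for one target:
#' starting at `lambda = 0` and increasing by `stepsize`, each step draws
#' `ceiling(alpha * (n - 1))` candidate regulators and `ceiling(r * N)`
#' samples uniformly without replacement, fits the lasso, and increments
#' the selection count of every candidate with `|coefficient| > 1e-8`.
#'
#' @param x an [expression_matrix()].
#' @param target gene index (or name) of the target.
#' @param cfg a [larf_config()].
#' @param seed seed for this sweep's draws; defaults to `cfg$seed`.
#' @return Integer vector of selection counts, one per gene (0 for the
#'   target itself), with attributes `steps`, `capped` and `lambda_stop`.
#' @export
larf_target_sweep <- function(x, target, cfg = larf_config(),
                              seed = cfg$seed) {
  stopifnot(inherits(x, "expression_matrix"), inherits(cfg, "larf_config"))
  if (is.character(target)) target <- match(target, x$gene_names)
  if (is.na(target) || target < 1 || target > ncol(x$values))
    stopf("target out of range")
  counts <- with_local_seed(seed,
    larf_sweep_cpp(x$values, as.integer(target), cfg$alpha, cfg$r,
                   cfg$stepsize, cfg$lambda_max,
                   if (cfg$stop_rule == "exhaustion") 0L else 1L))
  if (isTRUE(attr(counts, "capped")))
    warnf("sweep for target %s hit lambda_max = %g before exhausting the penalty grid",
          x$gene_names[target], cfg$lambda_max)
  names(counts) <- x$gene_names
  counts
}

#' Min-max normalization of selection counts
#'
#' Normalizes each target row `i` of a selection-count matrix by
#' `(F[i, j] - min_offdiag(F[i, ])) / (max(F[i, ]) - min_offdiag(F[i, ]))`
#' and zeroes the diagonal, so every non-degenerate row spans exactly
#' `[0, 1]` off the diagonal.  Rows whose off-diagonal counts are all
#' equal are set to zero with a warning.
#'
#' @param counts `n x n` numeric matrix of selection counts with zero
#'   diagonal (rows = targets).
#' @return A numeric matrix of the same shape with entries in `[0, 1]`.
#' @examples
#' normalize_frequency(rbind(c(0, 2, 4, 6), c(2, 0, 4, 6),
#'                           c(2, 4, 0, 6), c(2, 4, 6, 0)))
#' @export
normalize_frequency <- function(counts) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (ncol(counts) != n) stopf("count matrix must be square")
  out <- matrix(0, n, n, dimnames = dimnames(counts))
  degenerate <- character(0)
  for (i in seq_len(n)) {
    off <- counts[i, -i]
    mn <- min(off)
    mx <- max(counts[i, ])
    if (mx - mn <= 0) {
      degenerate <- c(degenerate,
                      if (is.null(rownames(counts))) as.character(i)
                      else rownames(counts)[i])
      next
    }
    out[i, ] <- (counts[i, ] - mn) / (mx - mn)
    out[i, i] <- 0
  }
  if (length(degenerate) > 0)
    warnf("constant selection counts for target(s) %s; row(s) set to zero",
          paste(degenerate, collapse = ", "))
  out
}

#' LARF selection-frequency matrix
#'
#' For each target gene, runs `cfg$t` independent penalty sweeps
#' ([larf_target_sweep()]) with fresh random feature and sample draws at
#' every step, sums the selection counts, and min-max normalizes each
#' target row ([normalize_frequency()]).
#'
#' Per-target, per-repeat seeds are derived deterministically from
#' `cfg$seed`, so the result does not depend on the order in which targets
#' are computed.
#'
#' @param x an [expression_matrix()] with at least 3 genes of positive
#'   variance.
#' @param cfg a [larf_config()].
#' @return An [edge_scores()] matrix (method `"LARF"`); entry `(i, j)` is
#'   the normalized frequency with which gene `j` was selected for target
#'   `i`.  The raw summed counts are attached as attribute `"counts"`.
#' @export
larf_frequency_matrix <- function(x, cfg = larf_config()) {
  stopifnot(inherits(x, "expression_matrix"), inherits(cfg, "larf_config"))
  v <- x$values
  n <- ncol(v)
  vars <- apply(v, 2, var)
  if (any(vars <= 0))
    stopf("zero-variance gene(s): %s (lasso is ill-posed)",
          paste(x$gene_names[vars <= 0], collapse = ", "))
  counts <- matrix(0L, n, n, dimnames = list(x$gene_names, x$gene_names))
  for (i in seq_len(n)) {
    for (rep in seq_len(cfg$t)) {
      cts <- larf_target_sweep(x, i, cfg, seed = derive_seed(cfg$seed, i, rep))
      counts[i, ] <- counts[i, ] + as.integer(cts)
    }
  }
  f <- normalize_frequency(counts)
  out <- edge_scores(f, x$gene_names, method = "LARF")
  attr(out, "counts") <- counts
  out
}
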