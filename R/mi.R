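# Gaussian mutual-information edge scoring.
#
# Under a bivariate Gaussian model the mutual information between two genes
# has the closed form
#   I(X_i, X_j) = -1/2 * log( det(cov2(x_i, x_j)) / (var(x_i) var(x_j)) )
#               = -1/2 * log(1 - rho^2),
# with rho the Pearson correlation.  It is symmetric, nonnegative, zero iff
# the sample correlation is zero, and diverges as |rho| -> 1; perfectly
# correlated pairs are clamped (see below).  Natural logarithm (nats).

MI_RHO2_CAP <- 1 - 1e-12

#' Gaussian mutual information of one gene pair
#'
#' Computes `-1/2 * log(det(cov2(x, y)) / (var(x) var(y)))`, the mutual
#' information of a bivariate Gaussian, equal to `-1/2 * log(1 - rho^2)`
#' for the sample Pearson correlation `rho`.  Sample covariances use
#' denominator `N - 1`; the value is in nats.
#'
#' Pairs correlated beyond `|rho|^2 >= 1 - 1e-12` make the closed form
#' diverge; the value is clamped at `-1/2 * log(1e-12)` (about 13.82 nats)
#' with a warning, which keeps rankings finite and stable.
#'
#' @param x,y numeric vectors of equal length `N >= 3` with strictly
#'   positive sample standard deviation.
#' @return A single nonnegative number.
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- 0.6 * x + rnorm(50)
#' gaussian_mi_pair(x, y)
#' @export
gaussian_mi_pair <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3) stopf("need at least 3 samples, found %d", length(x))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stopf("inputs must be finite")
  vx <- var(x); vy <- var(y)
  if (vx <= 0) stopf("degenerate input: x has zero variance")
  if (vy <= 0) stopf("degenerate input: y has zero variance")
  s <- cov(cbind(x, y))
  rho2 <- min(max(1 - det(s) / (vx * vy), 0), 1)
  if (rho2 >= MI_RHO2_CAP) {
    warnf("pair is perfectly correlated within tolerance; MI clamped at %.4f nats",
          -0.5 * log(1 - MI_RHO2_CAP))
    rho2 <- MI_RHO2_CAP
  }
  -0.5 * log(1 - rho2)
}

#' Gaussian mutual-information matrix
#'
#' Applies [gaussian_mi_pair()] to every unordered gene pair of an
#' expression matrix.  The result is a symmetric [edge_scores()] matrix
#' with zero diagonal; symmetry is exact because each pair is computed
#' once.
#'
#' @param x an [expression_matrix()]; every gene must have positive sample
#'   variance.
#' @return An [edge_scores()] matrix (method `"MI"`), symmetric.
#' @export
mi_matrix <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  n <- ncol(v)
  if (nrow(v) < 3) stopf("mutual information needs at least 3 samples")
  vars <- apply(v, 2, var)
  if (any(vars <= 0))
    stopf("zero-variance gene(s): %s",
          paste(x$gene_names[vars <= 0], collapse = ", "))
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    m[i, j] <- m[j, i] <- gaussian_mi_pair(v[, i], v[, j])
  }
  edge_scores(m, x$gene_names, method = "MI")
}
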