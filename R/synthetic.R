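# Linear-Gaussian steady-state benchmark generator.
#
# A synthetic network is a sparse signed weight matrix W (indexed
# target x regulator) with basal expression b.  A sample is the solution
# of the linear steady state
#     x = b + W x + e,   e ~ Normal(0, sigma_pert^2) per gene,
# i.e. x = (I - W)^{-1} (b + e), plus observation noise
# Normal(0, noise_sd^2).  The spectral radius of W is kept below 1 so the
# steady state is unique.  Knockouts clamp one gene to zero (its equation
# is removed) and solve the reduced system — the same wild-type-plus-
# knockouts layout as the DREAM3 in-silico challenge, at a scale where
# closed-form covariance oracles are available.

#' Random sparse regulatory network
#'
#' Draws each ordered gene pair as an edge independently with probability
#' `avg_in_degree / (n - 1)` (no self-loops), assigns weights uniformly
#' from `[-1, -0.5] U [0.5, 1]`, and rescales the weight matrix to
#' spectral radius 0.9 whenever it exceeds that bound.  Basal expression
#' is drawn uniformly from `[0.5, 1.5]`.
#'
#' @param n number of genes (>= 3).
#' @param avg_in_degree expected number of regulators per gene, in
#'   `(0, n - 1)`.
#' @param seed integer seed; the network is a deterministic function of
#'   it.
#' @param noise_sd observation-noise standard deviation stored with the
#'   network (default 0.1).
#' @return A list of class `synthetic_network` with elements `adjacency`
#'   (a [gold_standard()]), `weights`, `basal`, `noise_sd`, `gene_names`.
#' @export
random_network <- function(n, avg_in_degree = 1.5, seed = 1,
                           noise_sd = 0.1) {
  if (!is_count(n) || n < 3) stopf("n must be an integer >= 3")
  if (avg_in_degree <= 0 || avg_in_degree >= n - 1)
    stopf("avg_in_degree must lie in (0, n - 1)")
  genes <- paste0("G", seq_len(n))
  p <- avg_in_degree / (n - 1)
  with_local_seed(seed, {
    adj <- matrix(rbinom(n * n, 1, p), n, n)
    diag(adj) <- 0
    w <- adj * matrix(sample(c(-1, 1), n * n, replace = TRUE) *
                        runif(n * n, 0.5, 1), n, n)
    basal <- runif(n, 0.5, 1.5)
    rho <- max(abs(eigen(w, only.values = TRUE)$values))
    if (rho > 0.9) w <- w * (0.9 / rho)
    dimnames(w) <- list(genes, genes)
    structure(list(adjacency = gold_standard(adj, genes), weights = w,
                   basal = basal, noise_sd = noise_sd, gene_names = genes),
              class = "synthetic_network")
  })
}

#' @export
print.synthetic_network <- function(x, ...) {
  cat(sprintf("synthetic_network: %d genes, %d edges, noise_sd = %g\n",
              length(x$gene_names), sum(x$adjacency$adjacency), x$noise_sd))
  invisible(x)
}

#' Three-gene regulatory motifs
#'
#' Canonical fixtures distinguishing direct from indirect regulation:
#' the cascade `G1 -> G2 -> G3` (no `G1 -> G3` edge, but the correlation
#' it induces), and the feed-forward loop `G1 -> G2`, `G1 -> G3`,
#' `G2 -> G3`.  All edge weights are 0.8, basal expression 1, observation
#' noise 0.1 — fixed, documented constants.
#'
#' @param kind `"cascade"` or `"feedforward"`.
#' @return A `synthetic_network` (see [random_network()]).
#' @export
motif_network <- function(kind = c("cascade", "feedforward")) {
  kind <- match.arg(kind)
  genes <- c("G1", "G2", "G3")
  w <- matrix(0, 3, 3, dimnames = list(genes, genes))
  w["G2", "G1"] <- 0.8
  w["G3", "G2"] <- 0.8
  if (kind == "feedforward") w["G3", "G1"] <- 0.8
  structure(list(adjacency = gold_standard((w != 0) * 1, genes),
                 weights = w, basal = rep(1, 3), noise_sd = 0.1,
                 gene_names = genes),
            class = "synthetic_network")
}

check_spectral <- function(net) {
  rho <- max(abs(eigen(net$weights, only.values = TRUE)$values))
  if (rho >= 1)
    stopf("weight matrix has spectral radius %.3f >= 1: no stable steady state",
          rho)
  invisible(rho)
}

#' Simulate steady-state expression samples
#'
#' Each sample solves `x = basal + W x + e` with an independent per-gene
#' perturbation `e ~ Normal(0, sigma_pert^2)` and adds observation noise
#' `Normal(0, noise_sd^2)`.  Samples are generated sequentially from the
#' seed, so extending `n_samples` under the same seed reproduces the
#' earlier samples as a prefix.
#'
#' @param net a `synthetic_network`.
#' @param n_samples number of samples (>= 2).
#' @param seed integer seed.
#' @param sigma_pert per-sample perturbation standard deviation
#'   (default 0.5).
#' @return An [expression_matrix()].
#' @export
simulate_expression <- function(net, n_samples, seed = 1, sigma_pert = 0.5) {
  stopifnot(inherits(net, "synthetic_network"))
  if (!is_count(n_samples) || n_samples < 2)
    stopf("n_samples must be an integer >= 2")
  check_spectral(net)
  n <- length(net$gene_names)
  a <- solve(diag(n) - net$weights)
  with_local_seed(seed, {
    values <- matrix(0, n_samples, n)
    for (s in seq_len(n_samples)) {
      e <- rnorm(n, 0, sigma_pert)
      values[s, ] <- a %*% (net$basal + e) + rnorm(n, 0, net$noise_sd)
    }
    expression_matrix(values, net$gene_names)
  })
}

#' Simulate a wild-type plus single-gene-knockout dataset
#'
#' The wild type is the noiseless steady state.  Knockout `i` clamps gene
#' `i` to zero, removes its equation, solves the reduced steady state,
#' and adds observation noise to the measured row.
#'
#' @param net a `synthetic_network`.
#' @param seed integer seed.
#' @return A [knockout_dataset()].
#' @export
simulate_knockouts <- function(net, seed = 1) {
  stopifnot(inherits(net, "synthetic_network"))
  check_spectral(net)
  n <- length(net$gene_names)
  wt <- drop(solve(diag(n) - net$weights, net$basal))
  # genes affected by knocking out i are exactly those reachable from i;
  # solving only that subsystem keeps unaffected genes bit-identical to
  # wild type, so zero-noise variation is exactly zero off the
  # downstream set
  step <- t(net$adjacency$adjacency) > 0
  reach <- step
  for (k in seq_len(n)) reach <- reach | ((reach %*% step) > 0)
  with_local_seed(seed, {
    ko <- matrix(0, n, n)
    for (i in seq_len(n)) {
      xi <- wt
      xi[i] <- 0
      aff <- setdiff(which(reach[i, ]), i)
      if (length(aff) > 0) {
        keep <- setdiff(seq_len(n), c(aff, i))
        rhs <- net$basal[aff] +
          net$weights[aff, keep, drop = FALSE] %*% wt[keep]
        xi[aff] <- solve(diag(length(aff)) -
                           net$weights[aff, aff, drop = FALSE], rhs)
      }
      ko[i, ] <- xi + rnorm(n, 0, net$noise_sd)
    }
    knockout_dataset(wt, ko, net$gene_names)
  })
}

#' Write a simulated benchmark to disk
#'
#' Convenience wrapper producing the three files consumed by the
#' inference and evaluation tools: `<prefix>_expression.tsv`,
#' `<prefix>_knockouts.tsv` and `<prefix>_gold.tsv`.
#'
#' @param net a `synthetic_network`.
#' @param prefix output path prefix.
#' @param n_samples samples in the expression file (default 21).
#' @param seed integer seed for the simulations.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_benchmark <- function(net, prefix, n_samples = 21, seed = 1) {
  stopifnot(inherits(net, "synthetic_network"))
  paths <- c(expression = paste0(prefix, "_expression.tsv"),
             knockouts = paste0(prefix, "_knockouts.tsv"),
             gold = paste0(prefix, "_gold.tsv"))
  write_expression_matrix(simulate_expression(net, n_samples,
                                              derive_seed(seed, 1)),
                          paths["expression"])
  write_knockout_dataset(simulate_knockouts(net, derive_seed(seed, 2)),
                         paths["knockouts"])
  write_gold_standard(net$adjacency, paths["gold"])
  invisible(paths)
}
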