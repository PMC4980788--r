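# Shared fixtures and independent oracles.

# Pair of vectors with sample Pearson correlation exactly `rho`,
# built by orthonormalizing a noise vector against x.
make_corr_pair <- function(n, rho, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    z <- rnorm(n)
    xc <- x - mean(x)
    e <- z - mean(z)
    e <- e - sum(e * xc) / sum(xc^2) * xc
    y <- rho * xc / sqrt(sum(xc^2)) + sqrt(1 - rho^2) * e / sqrt(sum(e^2))
    list(x = x, y = y + 1)   # shift: correlation is location-invariant
  })
}

# Mann-Whitney AUROC by brute-force pair counting (ties get half credit).
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# Transitive closure: reach[i, j] is TRUE iff gene j is downstream of
# gene i in a gold-standard adjacency (indexed target x regulator).
downstream_of <- function(adjacency) {
  step <- t(adjacency) > 0        # step[i, j]: direct edge i -> j
  reach <- step
  n <- nrow(adjacency)
  for (k in seq_len(n)) reach <- reach | ((reach %*% step) > 0)
  reach
}

# Deterministic seed mixing for parameterised cases (mirrors the
# package's internal substream derivation, independently written).
derive_seed_t <- function(...) {
  h <- 0
  for (k in c(...)) h <- (h * 7919 + k + 13) %% 2147483629
  as.integer(h)
}

# Small deterministic knockout fixture: gene 1 regulates gene 2 only;
# every other variation is balanced measurement jitter.
single_edge_knockouts <- function() {
  wt <- rep(1, 5)
  d <- rbind(c(-1.00, 5.00, 0.03, -0.03, 0.01),  # ko G1: G2 jumps
             c(0.03, -1.00, 0.01, 0.01, -0.03),
             c(0.01, 0.01, -1.00, 0.03, 0.03),
             c(-0.01, -0.03, -0.01, -1.00, -0.01),
             c(-0.03, 0.03, -0.03, -0.01, -1.00))
  knockout_dataset(wt, sweep(d, 2, wt, "+"), paste0("G", 1:5))
}

# 10-gene benchmark run shared by integration and synthetic tests: all
# five methods scored on simulated knockout data of a random network.
run_benchmark_seed <- function(net_seed, ko_seed, cfg_seed,
                               methods = c("MI", "ZS", "LARF", "IMLARF",
                                           "ISLARF")) {
  net <- random_network(10, avg_in_degree = 1.5, seed = net_seed)
  ko <- simulate_knockouts(net, seed = ko_seed)
  cfg <- larf_config(seed = cfg_seed)
  vapply(methods, function(m)
    roc_auroc(infer(m, knockouts = ko, cfg = cfg), net$adjacency)$auroc,
    numeric(1))
}
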