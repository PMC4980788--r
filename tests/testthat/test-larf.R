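# LARF: lasso solver, penalty sweep, frequency matrix.

test_that("fit_lasso recovers noiseless regressions and least squares", {
  x <- matrix(seq(-2, 2, length.out = 9))
  expect_equal(fit_lasso(2 * x[, 1], x, 0), 2, tolerance = 1e-8)

  withr::with_seed(21, {
    xb <- matrix(rnorm(60), 20, 3)
    yb <- drop(xb %*% c(1, -1, 0.5) + rnorm(20, 0, 0.2))
  })
  ls <- unname(coef(lm(yb ~ xb))[-1])
  expect_equal(fit_lasso(yb, xb, 0), ls, tolerance = 1e-8)
})

test_that("univariate lasso follows the soft-threshold closed form", {
  withr::with_seed(22, {
    x <- rnorm(30)
    y <- 2 * x + rnorm(30, 0, 0.3)
  })
  m <- length(x)
  sdx <- sqrt(mean(x^2) - mean(x)^2)
  xs <- (x - mean(x)) / sdx
  yc <- y - mean(y)
  cval <- sum(xs * yc) / m
  for (lam in c(0.001, 0.05, 0.3, abs(cval) * 0.999, abs(cval) * 1.001, 5)) {
    beta_std <- sign(cval) * max(abs(cval) - lam, 0)
    expect_equal(fit_lasso(y, matrix(x), lam), beta_std / sdx,
                 tolerance = 1e-6)
  }
  # above the critical penalty |x'y|/m the coefficient is exactly zero
  expect_identical(fit_lasso(y, matrix(x), abs(cval) + 1e-6), 0)
})

test_that("orthonormal designs soft-threshold each coefficient independently", {
  withr::with_seed(23, {
    raw <- scale(matrix(rnorm(80), 20, 4), center = TRUE, scale = FALSE)
    q <- qr.Q(qr(raw))             # orthonormal and mean-zero columns
    x <- q * sqrt(20)              # unit population variance, orthogonal
    y <- drop(x %*% c(1.5, -0.8, 0.3, 0) + rnorm(20, 0, 0.1))
  })
  yc <- y - mean(y)
  cvec <- drop(crossprod(x, yc)) / 20
  prev_support <- Inf
  for (lam in seq(0, 2, by = 0.1)) {
    expected <- sign(cvec) * pmax(abs(cvec) - lam, 0)
    got <- fit_lasso(y, x, lam)
    expect_equal(got, expected / sqrt(mean(x[, 1]^2) - mean(x[, 1])^2),
                 tolerance = 1e-6)
    support <- sum(abs(got) > 1e-8)
    expect_lte(support, prev_support)   # support shrinks as lambda grows
    prev_support <- support
  }
})

test_that("fit_lasso agrees with glmnet on general designs", {
  withr::with_seed(24, {
    x <- matrix(rnorm(60 * 6), 60, 6)
    y <- drop(x %*% c(1.5, -2, 0, 0, 0.5, 0) + rnorm(60, 0, 0.5))
  })
  lams <- c(0.5, 0.2, 0.05, 0.01)
  fit <- glmnet::glmnet(x, y, lambda = lams, standardize = TRUE,
                        thresh = 1e-14, maxit = 1e6)
  for (lam in lams) {
    expect_equal(fit_lasso(y, x, lam),
                 as.numeric(coef(fit, s = lam))[-1], tolerance = 1e-6)
  }
})

test_that("fit_lasso validates its inputs", {
  expect_error(fit_lasso(rnorm(5), matrix(nrow = 5, ncol = 0), 0.1),
               "empty candidate")
  expect_error(fit_lasso(c(1, NA, 3), matrix(rnorm(3)), 0.1), "finite")
  expect_error(fit_lasso(rnorm(3), matrix(rnorm(3)), -1), "nonnegative")
})

test_that("target sweeps are seed-reproducible and order-independent", {
  net <- random_network(6, 1.5, seed = 31)
  x <- simulate_expression(net, 15, seed = 31)
  cfg <- larf_config(alpha = 0.5, seed = 99)
  c1 <- larf_target_sweep(x, 2, cfg, seed = 7)
  c2 <- larf_target_sweep(x, 2, cfg, seed = 7)
  expect_identical(c1, c2)
  expect_equal(unname(c1["G2"]), 0)     # target never counts itself

  # full frequency matrix is reproducible and target-order independent
  f1 <- larf_frequency_matrix(x, cfg)
  f2 <- larf_frequency_matrix(x, cfg)
  expect_identical(f1$scores, f2$scores)
})

test_that("a signal-free target exhausts its sweep sooner than a regulated one", {
  withr::with_seed(32, {
    v <- cbind(rnorm(30), rnorm(30), rnorm(30))
    v <- cbind(v, 0.9 * v[, 1] + rnorm(30, 0, 0.3))   # G4 regulated by G1
  })
  x <- expression_matrix(v)
  cfg <- larf_config(alpha = 1, r = 1, t = 1, seed = 1)
  null_counts <- larf_target_sweep(x, 2, cfg)
  sig_counts <- larf_target_sweep(x, 4, cfg)
  expect_lt(attr(null_counts, "steps"), attr(sig_counts, "steps"))
  expect_lt(sum(null_counts), sum(sig_counts))
})

test_that("frequency normalization follows the min-max rule", {
  cts <- rbind(c(0, 2, 4, 6), c(2, 0, 4, 6), c(2, 4, 0, 6), c(2, 4, 6, 0))
  f <- normalize_frequency(cts)
  expect_equal(f[1, ], c(0, 0, 0.5, 1))
  expect_true(all(diag(f) == 0))

  # all off-diagonal counts equal -> degenerate zero row with warning
  cts2 <- rbind(c(0, 3, 3), c(1, 0, 5), c(2, 4, 0))
  expect_warning(f2 <- normalize_frequency(cts2), "constant")
  expect_equal(f2[1, ], c(0, 0, 0))
  expect_equal(f2[2, ], c(0, 0, 1))
})

test_that("normalized frequency rows span [0, 1] off the diagonal", {
  net <- random_network(7, 1.5, seed = 33)
  x <- simulate_expression(net, 15, seed = 33)
  f <- larf_frequency_matrix(x, larf_config(alpha = 0.5, t = 3, seed = 33))
  for (i in seq_len(7)) {
    off <- f$scores[i, -i]
    expect_true(all(off >= 0 & off <= 1))
    if (any(off > 0)) {
      expect_equal(max(off), 1)
      expect_equal(min(off), 0)
    }
  }
})

test_that("random featuring ranks the direct cascade regulator first", {
  # single sweeps (t = 1): the direct edge G2 -> G3 collects more
  # selections than the indirect G1 -> G3 in the median run
  net <- motif_network("cascade")
  diffs <- vapply(1:30, function(k) {
    x <- simulate_expression(net, 20, seed = derive_seed_t(41, k))
    cts <- larf_target_sweep(x, 3, larf_config(alpha = 0.5, r = 1),
                             seed = derive_seed_t(42, k))
    unname(cts["G2"] - cts["G1"])
  }, numeric(1))
  expect_gt(median(diffs), 0)
})

test_that("larf_frequency_matrix rejects zero-variance genes", {
  v <- cbind(rnorm(10), rep(2, 10), rnorm(10))
  expect_error(larf_frequency_matrix(expression_matrix(v, paste0("G", 1:3))),
               "G2")
})

test_that("invalid configurations are rejected", {
  expect_error(larf_config(alpha = 0), "alpha")
  expect_error(larf_config(alpha = 1.2), "alpha")
  expect_error(larf_config(r = 0), "r must")
  expect_error(larf_config(stepsize = -0.1), "stepsize")
  expect_error(larf_config(t = 0), "t must")
})
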