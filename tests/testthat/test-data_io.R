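# DREAM3-dialect readers and writers.

test_that("expression files parse, with and without sample ids", {
  f <- withr::local_tempfile()
  writeLines(c("G1\tG2", "1.0\t2.0", "3.0\t4.0"), f)
  x <- read_expression_matrix(f)
  expect_equal(unname(x$values), rbind(c(1, 2), c(3, 4)))
  expect_equal(x$gene_names, c("G1", "G2"))
  expect_equal(x$sample_ids, c("S1", "S2"))

  # trailing newline changes nothing
  cat("G1\tG2\n1.0\t2.0\n3.0\t4.0\n\n", file = f)
  expect_equal(read_expression_matrix(f)$values, x$values)

  # leading id column on every row
  writeLines(c("G1\tG2", "a\t1\t2", "b\t3\t4"), f)
  y <- read_expression_matrix(f)
  expect_equal(y$sample_ids, c("a", "b"))
  expect_equal(unname(y$values), unname(x$values))
})

test_that("malformed expression files are rejected with line numbers", {
  f <- withr::local_tempfile()
  writeLines(c("G1\tG2", "1\t2", "1\t2\t3"), f)
  expect_error(read_expression_matrix(f), "line 3")
  writeLines(c("G1\tG2", "1\tx", "3\t4"), f)
  expect_error(read_expression_matrix(f), "not numeric")
  writeLines(c("G1", "1", "2"), f)
  expect_error(read_expression_matrix(f), "at least 2 genes")
  writeLines(c("G1\tG2", "1\t2"), f)
  expect_error(read_expression_matrix(f), "at least 2 samples")
})

test_that("expression and knockout datasets round-trip bit-exactly", {
  net <- random_network(6, 1.5, seed = 4)
  x <- simulate_expression(net, 9, seed = 2)
  f <- withr::local_tempfile()
  write_expression_matrix(x, f)
  expect_identical(read_expression_matrix(f)$values, x$values)

  ko <- simulate_knockouts(net, seed = 3)
  g <- withr::local_tempfile()
  write_knockout_dataset(ko, g)
  ko2 <- read_knockout_dataset(g)
  expect_identical(ko2$wild_type, ko$wild_type)
  expect_identical(ko2$knockouts, ko$knockouts)
})

test_that("knockout reader validates layout and finds the wild type", {
  f <- withr::local_tempfile()
  writeLines(c("G1\tG2", "wt\t1\t2", "3\t4", "5\t6"), f)
  expect_error(read_knockout_dataset(f), "inconsistent|fields")

  writeLines(c("G1\tG2", "1\t2", "3\t4", "5\t6"), f)  # positional wt
  ko <- read_knockout_dataset(f)
  expect_equal(unname(ko$wild_type), c(1, 2))
  expect_equal(unname(ko$knockouts), rbind(c(3, 4), c(5, 6)))

  # label mode: wt row not first
  writeLines(c("G1\tG2", "ko1\t3\t4", "wt\t1\t2", "ko2\t5\t6"), f)
  ko <- read_knockout_dataset(f)
  expect_equal(unname(ko$wild_type), c(1, 2))
  expect_equal(unname(ko$knockouts[1, ]), c(3, 4))

  # wrong row count
  writeLines(c("G1\tG2", "1\t2", "3\t4"), f)
  expect_error(read_knockout_dataset(f), "3 rows.*found 2")

  # requested label absent
  writeLines(c("G1\tG2", "a\t1\t2", "b\t3\t4", "c\t5\t6"), f)
  expect_error(read_knockout_dataset(f), "'wt'")
})

test_that("gold-standard edge lists parse with orientation and guards", {
  f <- withr::local_tempfile()
  writeLines("G1\tG2\t1", f)
  gs <- read_gold_standard(f, c("G1", "G2"))
  expect_equal(gs$adjacency["G2", "G1"], 1)   # target row, regulator column
  expect_equal(gs$adjacency["G1", "G2"], 0)

  writeLines(character(0), f)
  expect_equal(sum(read_gold_standard(f, c("G1", "G2"))$adjacency), 0)

  writeLines("G1\tG1\t1", f)
  expect_warning(gs <- read_gold_standard(f, c("G1", "G2")), "self-edge")
  expect_equal(sum(gs$adjacency), 0)

  writeLines(c("G1\tG2\t1", "G1\tG2\t0"), f)
  expect_warning(gs <- read_gold_standard(f, c("G1", "G2")), "last flag wins")
  expect_equal(gs$adjacency["G2", "G1"], 0)

  writeLines("G1\tG9\t1", f)
  expect_error(read_gold_standard(f, c("G1", "G2")), "G9")
  writeLines("G1\tG2\t2", f)
  expect_error(read_gold_standard(f, c("G1", "G2")), "expected 0 or 1")
})

test_that("ranked edges respect theta strictly and break ties deterministically", {
  w <- matrix(0, 2, 2, dimnames = list(c("G1", "G2"), c("G1", "G2")))
  w["G2", "G1"] <- 0.9
  es <- edge_scores(w)
  f <- withr::local_tempfile()
  expect_equal(write_ranked_edges(es, f, theta = 0.5), 1)
  expect_match(readLines(f), "^G1\tG2\t0\\.9")
  expect_equal(write_ranked_edges(es, f, theta = 0.9), 0)   # strict >
  expect_equal(length(readLines(f)), 0)

  # equal scores: order fixed by (regulator, target) index
  w3 <- matrix(0.5, 3, 3); diag(w3) <- 0
  es3 <- edge_scores(w3, c("A", "B", "C"))
  write_ranked_edges(es3, f)
  expect_equal(readLines(f)[1:3],
               c("A\tB\t0.5", "A\tC\t0.5", "B\tA\t0.5"))
  es3b <- edge_scores(w3, c("A", "B", "C"))
  g <- withr::local_tempfile()
  write_ranked_edges(es3b, g)
  expect_identical(readLines(f), readLines(g))
})

test_that("ranked edge lists round-trip through read_ranked_edges", {
  net <- random_network(5, 1.5, seed = 9)
  ko <- simulate_knockouts(net, seed = 9)
  w <- infer("zs", knockouts = ko)
  f <- withr::local_tempfile()
  write_ranked_edges(w, f)
  w2 <- read_ranked_edges(f, w$gene_names)
  expect_equal(w2$scores, w$scores, tolerance = 1e-5)
})
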