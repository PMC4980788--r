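# Readers and writers for the DREAM3-dialect tab-separated files:
# expression matrices (header row of gene names, one row per sample with an
# optional leading sample-id column), knockout datasets (wild-type row plus
# one row per knocked-out gene), gold-standard edge lists
# ("regulator TAB target TAB flag"), and ranked edge lists.
#
# File edge lists are (regulator, target); in-memory matrices are indexed
# (target, regulator).  The orientation flip is centralized here.

read_table_lines <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  # drop trailing blank lines only; interior blanks are a format error
  while (length(lines) > 0 && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  lines
}

parse_expression_lines <- function(lines, path) {
  if (length(lines) < 2) stopf("%s: expected a header row and data rows", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  header <- header[nzchar(header)]
  n <- length(header)
  rows <- fields[-1]
  has_ids <- vapply(rows, function(f) length(f) == n + 1 &&
                      is.na(suppressWarnings(as.numeric(f[1]))), logical(1))
  if (any(has_ids) && !all(has_ids) && !all(lengths(rows) %in% c(n, n + 1)))
    stopf("%s: inconsistent row layout", path)
  use_ids <- all(has_ids) && length(rows) > 0
  values <- matrix(NA_real_, length(rows), n)
  ids <- character(length(rows))
  for (k in seq_along(rows)) {
    f <- rows[[k]]
    if (use_ids) {
      ids[k] <- f[1]
      f <- f[-1]
    }
    if (length(f) != n)
      stopf("%s: line %d has %d fields, expected %d", path, k + 1,
            length(f) + if (use_ids) 1L else 0L, n + if (use_ids) 1L else 0L)
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v))) {
      bad <- which(is.na(v))[1]
      stopf("%s: line %d, field %d ('%s') is not numeric", path, k + 1,
            bad + if (use_ids) 1L else 0L, f[bad])
    }
    values[k, ] <- v
  }
  list(values = values, gene_names = header,
       sample_ids = if (use_ids) ids else NULL)
}

#' Read a DREAM3-dialect expression matrix
#'
#' The expected layout is a tab-separated text file whose first row lists
#' the gene names and whose remaining rows each hold one sample.  A leading
#' non-numeric column, when present on every row, is taken as sample
#' identifiers.  Unix and Windows line endings are accepted.
#'
#' @param path path to the file.
#' @return An [expression_matrix()].
#' @examples
#' f <- tempfile()
#' writeLines(c("G1\tG2", "1.0\t2.0", "3.0\t4.0"), f)
#' read_expression_matrix(f)
#' @export
read_expression_matrix <- function(path) {
  p <- parse_expression_lines(read_table_lines(path), path)
  expression_matrix(p$values, p$gene_names, p$sample_ids)
}

#' Write an expression matrix in the DREAM3 dialect
#'
#' Values are printed with 17 significant digits so that writing and
#' re-reading reproduces the matrix bit-exactly.
#'
#' @param x an [expression_matrix()].
#' @param path output path.
#' @param sample_ids logical; write the sample-id column (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, sample_ids = TRUE) {
  stopifnot(inherits(x, "expression_matrix"))
  header <- paste(x$gene_names, collapse = "\t")
  body <- apply(x$values, 1, function(v)
    paste(sprintf("%.17g", v), collapse = "\t"))
  if (sample_ids) body <- paste(x$sample_ids, body, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a DREAM3-dialect knockout dataset
#'
#' The file must parse as an expression matrix with `n + 1` rows for `n`
#' genes: one wild-type row and one row per single-gene knockout, ordered
#' by gene index.  When the file carries sample labels, the wild-type row
#' is the one labelled `wild_type_row_label`; otherwise the first row is
#' taken as wild type.
#'
#' @param path path to the file.
#' @param wild_type_row_label label identifying the wild-type row
#'   (default `"wt"`).
#' @return A [knockout_dataset()].
#' @export
read_knockout_dataset <- function(path, wild_type_row_label = "wt") {
  p <- parse_expression_lines(read_table_lines(path), path)
  n <- length(p$gene_names)
  if (nrow(p$values) != n + 1)
    stopf("%s: a knockout dataset for %d genes needs %d rows (wild type + knockouts), found %d",
          path, n, n + 1, nrow(p$values))
  if (!is.null(p$sample_ids)) {
    wt_row <- which(p$sample_ids == wild_type_row_label)
    if (length(wt_row) != 1)
      stopf("%s: expected exactly one row labelled '%s', found %d",
            path, wild_type_row_label, length(wt_row))
  } else {
    wt_row <- 1L
  }
  knockout_dataset(p$values[wt_row, ], p$values[-wt_row, , drop = FALSE],
                   p$gene_names)
}

#' Write a knockout dataset in the DREAM3 dialect
#'
#' The wild-type row is labelled `"wt"`; knockout rows are labelled by the
#' knocked-out gene.  Round-trips bit-exactly through
#' [read_knockout_dataset()].
#'
#' @param x a [knockout_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_knockout_dataset <- function(x, path) {
  stopifnot(inherits(x, "knockout_dataset"))
  header <- paste(x$gene_names, collapse = "\t")
  rows <- rbind(x$wild_type, x$knockouts)
  labels <- c("wt", x$gene_names)
  body <- paste(labels, apply(rows, 1, function(v)
    paste(sprintf("%.17g", v), collapse = "\t")), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a gold-standard edge list
#'
#' Each line is `"regulator TAB target TAB flag"` with flag 0 or 1.  Pairs
#' absent from the file default to 0; the last flag wins when a pair is
#' repeated (with a warning); self-edges are ignored with a warning.
#'
#' @param path path to the edge-list file.
#' @param gene_names the gene universe; every name in the file must occur
#'   here.
#' @return A [gold_standard()].
#' @export
read_gold_standard <- function(path, gene_names) {
  gene_names <- as.character(gene_names)
  lines <- read_table_lines(path)
  n <- length(gene_names)
  adj <- matrix(0, n, n, dimnames = list(gene_names, gene_names))
  seen <- matrix(FALSE, n, n)
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3)
      stopf("%s: line %d has %d fields, expected 3 (regulator, target, flag)",
            path, k, length(f))
    reg <- match(f[1], gene_names)
    tgt <- match(f[2], gene_names)
    if (is.na(reg)) stopf("%s: line %d names unknown gene '%s'", path, k, f[1])
    if (is.na(tgt)) stopf("%s: line %d names unknown gene '%s'", path, k, f[2])
    flag <- suppressWarnings(as.numeric(f[3]))
    if (is.na(flag) || !flag %in% c(0, 1))
      stopf("%s: line %d has flag '%s', expected 0 or 1", path, k, f[3])
    if (reg == tgt) {
      warnf("%s: line %d is a self-edge (%s); ignored", path, k, f[1])
      next
    }
    if (seen[tgt, reg])
      warnf("%s: line %d repeats pair %s -> %s; last flag wins",
            path, k, f[1], f[2])
    seen[tgt, reg] <- TRUE
    adj[tgt, reg] <- flag
  }
  gold_standard(adj, gene_names)
}

#' Write a gold-standard edge list
#'
#' @param x a [gold_standard()].
#' @param path output path.
#' @param include_zeros also write explicit 0-flag lines for absent edges
#'   (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_gold_standard <- function(x, path, include_zeros = FALSE) {
  stopifnot(inherits(x, "gold_standard"))
  n <- length(x$gene_names)
  lines <- character(0)
  for (reg in seq_len(n)) for (tgt in seq_len(n)) {
    if (reg == tgt) next
    flag <- x$adjacency[tgt, reg]
    if (flag == 1 || include_zeros)
      lines <- c(lines, sprintf("%s\t%s\t%d", x$gene_names[reg],
                                x$gene_names[tgt], as.integer(flag)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a ranked edge list
#'
#' All `n(n-1)` candidate edges are ranked by descending score (ties broken
#' by regulator index, then target index) and written as
#' `"regulator TAB target TAB score"` with 6 significant digits.  When a
#' threshold `theta` is given, only edges with score strictly greater than
#' `theta` are written.
#'
#' @param w an [edge_scores()] matrix.
#' @param path output path.
#' @param theta optional confidence threshold in `[0, 1]`; edges are kept
#'   only if `score > theta`.
#' @return The number of edges written, invisibly.
#' @export
write_ranked_edges <- function(w, path, theta = NULL) {
  stopifnot(inherits(w, "edge_scores"))
  edges <- rank_edges(w)
  if (!is.null(theta)) edges <- edges[edges$score > theta, , drop = FALSE]
  lines <- sprintf("%s\t%s\t%.6g", edges$regulator, edges$target, edges$score)
  writeLines(lines, path)
  invisible(nrow(edges))
}

#' Read a ranked edge list back into an edge-score matrix
#'
#' The inverse of [write_ranked_edges()] up to printed precision.  Pairs
#' absent from the file get score 0.
#'
#' @param path path to a `"regulator TAB target TAB score"` file.
#' @param gene_names the gene universe; defaults to the genes seen in the
#'   file, in order of first appearance.
#' @return An [edge_scores()] matrix.
#' @export
read_ranked_edges <- function(path, gene_names = NULL) {
  lines <- read_table_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(lines) > 0 && any(lengths(parts) != 3))
    stopf("%s: expected 3 tab-separated fields per line", path)
  regs <- vapply(parts, `[`, character(1), 1)
  tgts <- vapply(parts, `[`, character(1), 2)
  sc <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3)))
  if (any(is.na(sc))) stopf("%s: non-numeric score", path)
  if (is.null(gene_names)) {
    gene_names <- unique(c(rbind(regs, tgts)))
  }
  n <- length(gene_names)
  w <- matrix(0, n, n, dimnames = list(gene_names, gene_names))
  ri <- match(regs, gene_names)
  ti <- match(tgts, gene_names)
  if (any(is.na(ri)) || any(is.na(ti)))
    stopf("%s: edge list names genes outside the given gene set", path)
  w[cbind(ti, ri)] <- sc
  edge_scores(w, gene_names)
}
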