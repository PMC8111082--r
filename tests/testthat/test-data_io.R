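test_that("expression read/write round-trips and validates structure", {
  vals <- matrix(c(0.5, 2.25, 10, 1/3, 0, 7.125), nrow = 3,
                 dimnames = list(c("A", "B", "C"), c("c1", "c2")))
  meta <- data.frame(cell_id = c("c1", "c2"), group = c("0h", "3h"),
                     is_reference = c(1, 0))
  x <- expression_matrix(vals, meta)
  expect_identical(dim(x), c(3L, 2L))

  f <- tempfile(fileext = ".tsv"); fm <- tempfile(fileext = ".tsv")
  write_expression(x, f, fm)
  y <- read_expression(f, fm)
  expect_identical(y$values, x$values)  # bit-identical round trip
  expect_identical(y$cell_meta, x$cell_meta)

  # a second write of the re-read object is byte-identical
  f2 <- tempfile(fileext = ".tsv")
  write_expression(y, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("malformed expression inputs raise distinct named errors", {
  fm <- tempfile(); writeLines("cell_id\tgroup\tis_reference\nc1\t0h\t1\nc2\t3h\t0", fm)

  f <- tempfile(); writeLines(c("gene\tc1\tc2", "A\t1\t2", "A\t3\t4"), f)
  expect_error(read_expression(f, fm), class = "ccnet_duplicate_id")

  f <- tempfile(); writeLines(c("gene\tc1\tc2", "A\t1\tNA"), f)
  expect_error(read_expression(f, fm), class = "ccnet_non_numeric")

  f <- tempfile(); writeLines(c("gene", "A"), f)
  expect_error(read_expression(f, fm), class = "ccnet_malformed_header")

  # cell in matrix but absent from metadata
  f <- tempfile(); writeLines(c("gene\tc1\tc3", "A\t1\t2"), f)
  expect_error(read_expression(f, fm), class = "ccnet_metadata_mismatch")

  # negative and non-finite values rejected at construction
  meta <- data.frame(cell_id = "c1", group = "g", is_reference = TRUE)
  m <- matrix(-1, 1, 1, dimnames = list("A", "c1"))
  expect_error(expression_matrix(m, meta), class = "ccnet_negative_value")
})

test_that("expression filter applies the ceiling prevalence rule", {
  # 84 cells at fraction 0.25 -> integer threshold 21
  set.seed(1)
  x <- tiny_expr(matrix(stats::runif(10 * 84, 2, 5), 10, 84), n_ref = 20)
  f <- filter_by_expression(x)
  expect_identical(attr(f, "filter_log")$cell_threshold, 21L)

  # 4 cells, fraction 0.25: ceil(1) = 1 cell suffices
  m <- matrix(c(5, 0, 0, 0,   # gene kept: > 1 in exactly 1 of 4 cells
                0, 0, 0, 0),  # gene dropped: > 1 nowhere
              nrow = 2, byrow = TRUE,
              dimnames = list(c("keep", "drop"), paste0("c", 1:4)))
  x2 <- tiny_expr(m, n_ref = 3)
  f2 <- filter_by_expression(x2)
  expect_identical(rownames(f2$values), "keep")
  expect_identical(attr(f2, "filter_log")$cell_threshold, 1L)
  expect_identical(ncol(f2$values), 4L)  # cell set unchanged

  # strict inequality: a value of exactly min_value does not count
  m3 <- matrix(1, 1, 4, dimnames = list("flat", paste0("c", 1:4)))
  expect_error(filter_by_expression(tiny_expr(m3, 3)),
               class = "ccnet_empty_filter")

  # idempotence
  ff <- filter_by_expression(f)
  expect_identical(ff$values, f$values)
})

test_that("ceRNA reference canonicalizes, deduplicates, and drops self-pairs", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("geneA\tgeneB", "A\tB", "B\tA", "A\tA", "C\tD", "B\tC"), f)
  ref <- suppressWarnings(read_cerna_reference(f))
  expect_identical(nrow(ref), 3L)  # (A,B) dedup; (A,A) dropped
  expect_identical(attr(ref, "n_self_dropped"), 1L)
  expect_warning(read_cerna_reference(f), class = "ccnet_self_pair")

  # symmetric membership
  expect_true(cerna_contains(ref, "B", "A"))
  expect_true(cerna_contains(ref, "A", "B"))
  expect_false(cerna_contains(ref, "A", "D"))

  # counts by distinct pairs / symbols on a 3-row toy file
  s <- cerna_summary(ref)
  expect_identical(s$n_pairs, 3L)
  expect_identical(s$n_rnas, 4L)

  f1 <- tempfile(); writeLines(c("gene", "A", "B"), f1)
  expect_error(read_cerna_reference(f1), class = "ccnet_format")
})

test_that("ceRNA evidence columns merge on deduplication", {
  ref <- suppressWarnings(
    cerna_reference(c("A", "B", "A"), c("B", "A", "A"),
                    shared_mirnas = c("miR-1|miR-2", "miR-3", "miR-9")))
  expect_identical(nrow(ref), 1L)
  expect_identical(ref$shared_mirnas, "miR-1|miR-2|miR-3")
})

test_that("GMT parsing enforces unique names and nonempty members", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB", "S2\tdesc\tC"), f)
  gs <- read_gene_sets(f)
  expect_identical(length(gs$sets), 2L)
  expect_identical(gs$sets$S1, c("A", "B"))

  writeLines(c("S\tdesc\tA", "S\tdesc\tB"), f)
  expect_error(read_gene_sets(f), class = "ccnet_duplicate_id")

  writeLines("S\tdesc", f)
  expect_error(read_gene_sets(f), class = "ccnet_empty_set")
})

test_that("symbol harmonization renames aliases but never merges silently", {
  ann <- gene_annotation(c("NEAT1", "XIST"), biotype = "lncRNA",
                         aliases = c("NEAT1v2|LINC-NEAT", ""))
  m <- matrix(1:6, 3, 2, dimnames = list(c("NEAT1v2", "XIST", "OTHER"),
                                         c("c1", "c2")))
  x <- tiny_expr(m + 0.0, n_ref = 1)
  h <- harmonize_symbols(x, ann)
  expect_identical(rownames(h$values), c("NEAT1", "XIST", "OTHER"))

  # two rows collapsing onto the same primary symbol is an error
  m2 <- matrix(1:4 + 0.0, 2, 2,
               dimnames = list(c("NEAT1", "NEAT1v2"), c("c1", "c2")))
  expect_error(harmonize_symbols(tiny_expr(m2, 1), ann),
               class = "ccnet_duplicate_id")

  # alias colliding with a different primary symbol is rejected
  expect_error(gene_annotation(c("A", "B"), aliases = c("B", "")),
               class = "ccnet_alias_conflict")
  # one alias pointing at two primaries is rejected
  expect_error(gene_annotation(c("A", "B"), aliases = c("X", "X")),
               class = "ccnet_alias_conflict")
})
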