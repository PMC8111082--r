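test_that("ranked lists are log2 fold changes with deterministic ties", {
  case <- c(a = 4, b = 1, c = 2)
  ctrl <- c(a = 1, b = 1, c = 2, d = 9)
  rl <- make_ranked_list(case, ctrl, pseudocount = 0)
  expect_identical(rl$gene, c("a", "b", "c"))  # ties b/c broken by name
  expect_equal(rl$score, c(2, 0, 0))

  # identical case and control -> all scores 0
  expect_true(all(make_ranked_list(ctrl, ctrl, 0)$score == 0))

  # zero expression without a pseudocount is an error
  expect_error(make_ranked_list(c(a = 1, b = 0), c(a = 0, b = 1), 0),
               class = "ccnet_division_by_zero")
  expect_error(make_ranked_list(c(x = 1), c(y = 1)),
               class = "ccnet_empty_background")

  # .rnk round trip
  f <- tempfile(fileext = ".rnk")
  utils::write.table(rl, f, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  expect_equal(read_ranked_list(f), rl, ignore_attr = TRUE)
})

test_that("enrichment score matches hand-worked running sums", {
  rl <- data.frame(gene = c("g1", "g2", "g3", "g4"), score = c(4, 3, 2, 1))
  class(rl) <- c("RankedList", "data.frame")
  expect_equal(gsea_es(rl, "g1"), 1)    # hit at the top
  expect_equal(gsea_es(rl, "g4"), -1)   # hit at the bottom
  expect_equal(gsea_es(rl, rl$gene), 1) # no misses: increments only
  expect_error(gsea_es(rl, "nope"), class = "ccnet_empty_overlap")
})

test_that("extremum shortcut equals the naive full running sum", {
  set.seed(5)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    scores <- sort(stats::rnorm(n), decreasing = TRUE)
    k <- sample.int(n - 1, 1)
    hit <- seq_len(n) %in% sample.int(n, k)
    rl <- data.frame(gene = sprintf("g%02d", seq_len(n)), score = scores)
    class(rl) <- c("RankedList", "data.frame")
    w <- sample(c(0, 0.5, 1, 2), 1)
    expect_equal(gsea_es(rl, rl$gene[hit], weight = w),
                 oracle_es(scores, hit, weight = w), tolerance = 1e-12)
  }
})

test_that("weight zero reduces to the Kolmogorov-Smirnov rank statistic", {
  set.seed(9)
  n <- 40
  rl <- data.frame(gene = sprintf("g%02d", 1:n),
                   score = sort(stats::rnorm(n), decreasing = TRUE))
  class(rl) <- c("RankedList", "data.frame")
  hit <- seq_len(n) %in% sample.int(n, 12)
  # classical KS running sum on ranks: +1/k at hits, -1/(n-k) at misses
  run <- cumsum(ifelse(hit, 1 / sum(hit), -1 / (n - sum(hit))))
  expect_equal(gsea_es(rl, rl$gene[hit], weight = 0),
               run[which.max(abs(run))], tolerance = 1e-12)
})

test_that("enrichment score agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(21)
  for (i in 1:25) {
    n <- sample(20:100, 1)
    stats_vec <- sort(stats::rnorm(n), decreasing = TRUE)
    names(stats_vec) <- sprintf("g%03d", seq_len(n))
    k <- sample.int(n - 2, 1) + 1
    sel <- sort(sample.int(n, k))
    rl <- data.frame(gene = names(stats_vec), score = unname(stats_vec))
    class(rl) <- c("RankedList", "data.frame")
    es_ref <- fgsea::calcGseaStat(stats_vec, selectedStats = sel,
                                  gseaParam = 1)
    expect_equal(gsea_es(rl, names(stats_vec)[sel]), es_ref,
                 tolerance = 1e-10)
  }
})

test_that("preranked permutation test is reproducible with floored p-values", {
  set.seed(31)
  n <- 200
  rl <- data.frame(gene = sprintf("g%03d", 1:n),
                   score = sort(stats::rnorm(n, sd = 2), decreasing = TRUE))
  class(rl) <- c("RankedList", "data.frame")
  gs <- gene_set_collection(list(top = rl$gene[1:10],
                                 rand = rl$gene[seq(5, 200, by = 20)]))

  r1 <- gsea_preranked(rl, gs, n_perm = 200, seed = 42)
  r2 <- gsea_preranked(rl, gs, n_perm = 200, seed = 42)
  expect_identical(r1, r2)  # same seed -> identical results

  # top-of-list set saturates the permutation floor
  expect_equal(r1$p_perm[r1$set_name == "top"], 1 / 201)
  expect_true(all(r1$p_perm >= 1 / 201))
  expect_true(r1$ES[r1$set_name == "top"] > 0)
  expect_true(r1$NES[r1$set_name == "top"] > 0)
  # leading edge lies inside the set and the ranked universe
  le <- r1$leading_edge[[which(r1$set_name == "top")]]
  expect_true(all(le %in% rl$gene[1:10]))

  # caller's RNG stream is not disturbed
  set.seed(7); before <- stats::rnorm(1)
  set.seed(7); invisible(gsea_preranked(rl, gs, n_perm = 100, seed = 3))
  expect_identical(stats::rnorm(1), before)

  expect_error(gsea_preranked(rl, gs, n_perm = 10, seed = 1),
               class = "ccnet_invalid_parameter")
  gs_big <- gene_set_collection(list(huge = sprintf("x%04d", 1:300)))
  expect_error(gsea_preranked(rl, gs_big, n_perm = 100, seed = 1),
               class = "ccnet_invalid_parameter")
})

test_that("random gene sets give roughly uniform permutation p-values", {
  set.seed(17)
  n <- 120
  rl <- data.frame(gene = sprintf("g%03d", 1:n),
                   score = sort(stats::rnorm(n), decreasing = TRUE))
  class(rl) <- c("RankedList", "data.frame")
  hits <- 0L
  for (i in 1:100) {
    gs <- gene_set_collection(list(s = sample(rl$gene, 15)))
    p <- gsea_preranked(rl, gs, n_perm = 200, seed = i)$p_perm
    if (p < 0.05) hits <- hits + 1L
  }
  # Binomial(100, 0.05): 99.9% of runs fall at or below 13
  expect_lte(hits, 13L)
})

test_that("functional enrichment is sorted, tie-broken, and truncated", {
  bg <- sprintf("G%02d", 1:50)
  net <- make_network(c("G01", "G03"), c("G02", "G04"))
  gs <- gene_set_collection(list(
    exact = c("G01", "G02", "G03", "G04"),  # contains all network genes
    tie_b = c("G01", "G02", "G40"),
    tie_a = c("G01", "G02", "G41"),
    none = c("G45", "G46")))
  e <- functional_enrichment(net, gs, bg, top_k = 3)
  expect_identical(nrow(e), 3L)
  expect_identical(e$set_name[1], "exact")
  expect_equal(e$p[1], oracle_hypergeom(50, 4, 4, 4))
  # identical counts -> alphabetical set-name tie-break
  expect_identical(e$set_name[2:3], c("tie_a", "tie_b"))
})
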