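test_that("pearson_matrix matches hand-computed and degenerate cases", {
  m <- rbind(a = c(1, 2, 3, 4),
             b = c(2, 4, 6, 8),      # 2 * a -> r = 1
             c = c(9, 8, 7, 6),      # -a + 10 -> r = -1
             d = c(1, 3, 2, 4),      # hand-computed r = 0.8 with a
             e = c(5, 5, 5, 5))      # zero variance -> NA
  colnames(m) <- paste0("c", 1:4)
  x <- tiny_expr(m, n_ref = 4)
  r <- pearson_matrix(x, paste0("c", 1:4))
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(r["a", "d"], 0.8)
  expect_true(all(is.na(r["e", ])))
  expect_equal(r["b", "d"], r["d", "b"])
  expect_equal(unname(diag(r)[1:4]), rep(1, 4))

  expect_error(pearson_matrix(x, c("c1", "c2")), class = "ccnet_too_few_cells")
  expect_error(pearson_matrix(x, c("c1", "c2", "nope")),
               class = "ccnet_unknown_cell")
})

test_that("correlation p-value matches a numeric-integration oracle", {
  expect_equal(correlation_pvalue(0, 10), 1)
  expect_equal(correlation_pvalue(1, 20), 0)
  expect_equal(correlation_pvalue(-1, 5), 0)

  # oracle: two-sided tail of the t density by numeric integration
  for (r in c(0.3, -0.55, 0.8, 0.95)) {
    for (n in c(5, 20, 50)) {
      tt <- abs(r) * sqrt((n - 2) / (1 - r^2))
      tail <- stats::integrate(function(x) stats::dt(x, n - 2), tt, Inf,
                               rel.tol = 1e-12)$value
      expect_equal(correlation_pvalue(r, n), 2 * tail, tolerance = 1e-8)
    }
  }
  # spec-level sanity for r = 0.8, n = 20: t = 5.6569, p ~ 2.3e-5
  expect_equal(correlation_pvalue(0.8, 20), 2.3e-5, tolerance = 2e-2)
})

test_that("z_pvalue matches the normal tail by numeric integration", {
  expect_equal(z_pvalue(0), 1)
  expect_equal(z_pvalue(1.959964), 0.05, tolerance = 1e-6)
  for (z in c(0.5, 2, 4, 8)) {
    tail <- stats::integrate(function(x) exp(-x^2 / 2) / sqrt(2 * pi), z, 30,
                             rel.tol = 1e-13)$value
    expect_equal(z_pvalue(z), 2 * tail, tolerance = 1e-8)
    expect_equal(z_pvalue(-z), z_pvalue(z))
    expect_equal(z_pvalue(z, "one"), tail, tolerance = 1e-8)
  }
  expect_equal(z_pvalue(8), 1.2e-15, tolerance = 5e-2)
})

test_that("differential Z statistic follows the stated null scaling", {
  expect_equal(ssn_z(0, 0.2, 10), 0)
  # sigma = (1 - 0.25) / 20 = 0.0375; Z = 0.3 / 0.0375 = 8
  expect_equal(ssn_z(0.3, 0.5, 21), 8)
  expect_equal(ssn_z(-0.3, 0.5, 21), -8)  # antisymmetry
  expect_error(ssn_z(0.1, 1, 20), class = "ccnet_undefined_variance")
  expect_true(is.na(ssn_z(0.1, 1, 20, na_degenerate = TRUE)))

  # |Z| strictly increases with |delta| at fixed rho, N, and with N at
  # fixed delta, rho
  z1 <- abs(ssn_z(seq(0.05, 0.5, by = 0.05), 0.3, 20))
  expect_true(all(diff(z1) > 0))
  z2 <- abs(vapply(5:30, function(N) ssn_z(0.2, 0.3, N), numeric(1)))
  expect_true(all(diff(z2) > 0))
})

test_that("reference panel records N, caches stats, and flags edges", {
  set.seed(42)
  x <- noise_expr(n_genes = 8, n_ref = 20, n_query = 2)
  panel <- build_reference_panel(x)
  expect_identical(panel$N, 20L)
  expect_equal(panel$rho_ref, pearson_matrix(x, panel$cell_ids),
               tolerance = 1e-10)
  expect_false(any(diag(panel$sig_ref)))

  expect_error(build_reference_panel(noise_expr(4, n_ref = 2, n_query = 3)),
               class = "ccnet_too_few_cells")
})

test_that("reference-edge significance is calibrated on independent noise", {
  # 5 independent genes -> 10 pairs; expected alpha fraction significant
  set.seed(11)
  hits <- 0L; total <- 0L
  for (i in 1:500) {
    x <- noise_expr(5, n_ref = 15, n_query = 1)
    panel <- build_reference_panel(x, alpha = 0.05)
    hits <- hits + sum(panel$sig_ref[upper.tri(panel$sig_ref)])
    total <- total + 10L
  }
  # binomial 99.9% band around 0.05 for 5000 (dependent-ish) draws
  expect_gt(hits / total, 0.035)
  expect_lt(hits / total, 0.067)
})

test_that("incremental perturbed correlation equals direct recomputation", {
  set.seed(7)
  for (i in 1:30) {
    G <- sample(3:40, 1); N <- sample(3:20, 1)
    x <- noise_expr(G, n_ref = N, n_query = 1)
    panel <- build_reference_panel(x)
    q <- x$cell_meta$cell_id[!x$cell_meta$is_reference][1]
    inc <- perturbed_correlation(panel, x, q)
    full <- pearson_matrix(x, c(panel$cell_ids, q))
    expect_lt(max(abs(inc - full), na.rm = TRUE), 1e-10)
  }
  x <- noise_expr(4, n_ref = 5, n_query = 1)
  panel <- build_reference_panel(x)
  expect_error(perturbed_correlation(panel, x, panel$cell_ids[1]),
               class = "ccnet_reference_cell")
})

test_that("RCN pipeline keeps only positive significant differential edges", {
  set.seed(99)
  x <- noise_expr(10, n_ref = 20, n_query = 1)
  q <- x$cell_meta$cell_id[21]
  panel <- build_reference_panel(x)
  rcn <- build_cell_rcn(panel, x, q)
  expect_s3_class(rcn, "CellNetwork")
  expect_identical(rcn$stage, "RCN")
  if (nrow(rcn$edges)) {
    expect_true(all(rcn$edges$delta > 0))
    expect_true(all(rcn$edges$p < 0.05))
    expect_true(all(rcn$edges$gene_a < rcn$edges$gene_b))
    expect_equal(rcn$edges$delta, rcn$edges$rho_pert - rcn$edges$rho_ref)
    expect_true(all(sign(rcn$edges$z) == sign(rcn$edges$delta)))
  }
  # determinism: identical inputs give identical edge sets
  expect_identical(build_cell_rcn(panel, x, q)$edges, rcn$edges)

  # rho_pert_positive additionally requires positive perturbed correlation
  rcn2 <- build_cell_rcn(panel, x, q, direction_rule = "rho_pert_positive")
  if (nrow(rcn2$edges)) expect_true(all(rcn2$edges$rho_pert > 0))
})

test_that("a duplicated profile on collinear reference data perturbs nothing", {
  # two exactly collinear genes; the query duplicates a reference cell, so
  # both rho_ref and rho_pert are 1 -> pair degenerate, delta undefined,
  # and every defined pair has delta 0 -> empty network
  base <- matrix(c(1, 2, 3, 4, 5,
                   2, 4, 6, 8, 10), nrow = 2, byrow = TRUE)
  vals <- cbind(base, base[, 3])
  rownames(vals) <- c("a", "b"); colnames(vals) <- paste0("c", 1:6)
  x <- tiny_expr(vals, n_ref = 5)
  panel <- build_reference_panel(x)
  rcn <- build_cell_rcn(panel, x, "c6")
  expect_identical(nrow(rcn$edges), 0L)
  expect_identical(rcn$n_degenerate, 1L)
})

test_that("a planted bivariate displacement is recovered as a positive edge", {
  recovered <- 0L
  for (seed in 1:60) {
    set.seed(seed)
    x <- noise_expr(2, n_ref = 20, n_query = 1)
    q <- x$cell_meta$cell_id[21]
    x$values[, q] <- x$values[, q] + 6  # +6 SD on both genes
    panel <- build_reference_panel(x)
    rcn <- build_cell_rcn(panel, x, q)
    if (nrow(rcn$edges) == 1 && rcn$edges$delta > 0) recovered <- recovered + 1L
  }
  expect_gte(recovered / 60, 0.9)
})
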