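test_that("barcode calling threshold is 10% of the 99th percentile", {
  # top-100 barcodes all at 1000 UMIs -> threshold 100
  umis <- c(rep(1000, 100), c(500, 120, 99, 40, 5))
  kept <- call_cell_barcodes(umis, expected_cells = 100)
  expect_setequal(kept, which(umis >= 100))
  # all equal -> all retained
  expect_length(call_cell_barcodes(rep(7, 50), 10), 50)
  # single barcode retained
  expect_equal(call_cell_barcodes(42, 10), 1L)
})

test_that("cell QC enumerates the toy matrix exactly", {
  toy <- make_fixture("qc_toy")
  expect_equal(toy$cell_meta$detected_genes, c(150, 200, 500, 7000, 7500))
  out <- apply_cell_qc(toy)
  # strict inequalities: the 200- and 7000-gene cells survive; the 6%-mito
  # cell is removed
  expect_equal(ncol(out$counts), 2)
  expect_setequal(out$barcodes, c("TOY-2", "TOY-4"))
  prov <- attr(out, "qc_provenance")
  expect_equal(prov$cells_removed, 3)
  expect_equal(prov$order, c("cells", "genes"))
})

test_that("gene filter keeps genes detected in at least 3 cells", {
  counts <- cbind(c(1L, 1L, 1L, 0L), c(1L, 1L, 0L, 0L),
                  c(1L, 0L, 0L, 0L), c(1L, 1L, 1L, 1L))
  counts <- rbind(counts, matrix(1L, 300, 4))  # keep cells above min_genes
  syms <- c(paste0("g", 1:4), paste0("bg", 1:300))
  cm <- count_matrix(counts, syms, syms, paste0("c", 1:4))
  out <- apply_cell_qc(cm, qc_thresholds(min_genes = 1))
  expect_true("g1" %in% out$gene_symbols)   # 4 cells
  expect_true("g2" %in% out$gene_symbols)   # 3 cells
  expect_false("g3" %in% out$gene_symbols)  # 2 cells
  expect_false("g4" %in% out$gene_symbols)  # 1 cell
})

test_that("QC is idempotent on its own output", {
  sim <- simulate_counts(default_simulation_spec(400, 600, seed = 8))
  once <- apply_cell_qc(sim$matrix)
  twice <- apply_cell_qc(once)
  expect_identical(as.matrix(twice$counts), as.matrix(once$counts))
})

test_that("log normalization matches the closed form and depth identity", {
  counts <- matrix(c(10L, 990L, 0L, 0L, 5L, 5L), nrow = 3)
  cm <- count_matrix(counts, paste0("g", 1:3), paste0("g", 1:3), c("a", "b"))
  norm <- log_normalize(cm)
  # count 10 in a 1000-total cell -> ln(1 + 100)
  expect_equal(norm$values["g1", "a"], log(1 + 100))
  expect_equal(norm$values["g3", "a"], 0)
  # depth identity for every cell
  expect_equal(unname(colSums(expm1(norm$values))), c(10000, 10000),
               tolerance = 1e-9)
})

test_that("zero-depth cells stay all-zero with a warning", {
  counts <- matrix(c(5L, 5L, 0L, 0L), nrow = 2)
  cm <- count_matrix(counts, c("g1", "g2"), c("g1", "g2"), c("a", "b"))
  expect_warning(norm <- log_normalize(cm), "zero-depth")
  expect_equal(unname(norm$values[, "b"]), c(0, 0))
})

test_that("HVG selection finds planted high-dispersion genes", {
  # genes share one mean distribution; 50 planted genes carry ~50x higher
  # dispersion (var/mean) at matched means, so they must win in every bin
  set.seed(31)
  n_cells <- 300
  n_genes <- 1000
  m <- stats::runif(n_genes, 1, 10)
  hot <- sample(n_genes, 50)
  shape <- rep(25, n_genes)
  shape[hot] <- 0.5
  x <- t(vapply(seq_len(n_genes), function(i)
    stats::rgamma(n_cells, shape = shape[i], scale = m[i] / shape[i]),
    numeric(n_cells)))
  genes <- sprintf("g%04d", seq_len(n_genes))
  norm <- toy_norm(log1p(x), genes = genes)
  top100 <- select_hvg(norm, n_hvg = 100)
  expect_gte(length(intersect(top100, genes[hot])), 45)
})

test_that("HVG edge cases: constant genes, n_hvg = all", {
  set.seed(5)
  vals <- matrix(stats::rexp(100 * 50), nrow = 100)
  vals[7, ] <- 1                     # constant, nonzero mean
  norm <- toy_norm(vals)
  top <- select_hvg(norm, n_hvg = 50)
  expect_false(norm$gene_symbols[7] %in% top)
  all_genes <- select_hvg(norm, n_hvg = 100)
  expect_setequal(all_genes, norm$gene_symbols)
})

test_that("cell cycle scores are centered for exchangeable genes and
           positive for elevated sets", {
  set.seed(17)
  n_cells <- 200
  vals <- matrix(stats::rexp(500 * n_cells), nrow = 500)
  genes <- sprintf("g%03d", 1:500)
  norm <- toy_norm(vals, genes = genes)
  s_set <- genes[1:43]
  g2m_set <- genes[44:97]
  sc <- score_cell_cycle(norm, s_genes = s_set, g2m_genes = g2m_set, seed = 1)
  se <- stats::sd(sc$s_score) / sqrt(n_cells)
  expect_lt(abs(mean(sc$s_score)), 3 * se)

  # uniformly elevated set scores positive
  vals2 <- vals
  vals2[1:43, ] <- vals2[1:43, ] + 1
  norm2 <- toy_norm(vals2, genes = genes)
  sc2 <- score_cell_cycle(norm2, s_genes = s_set, g2m_genes = g2m_set, seed = 1)
  expect_gt(mean(sc2$s_score), 0)
  # phase rule: G1 iff both scores <= 0
  both_neg <- sc2$s_score <= 0 & sc2$g2m_score <= 0
  expect_true(all(sc2$phase[both_neg] == "G1"))
  expect_true(all(sc2$phase[!both_neg] %in% c("S", "G2M")))
})

test_that("shipped cell-cycle sets have the standard sizes", {
  expect_length(cc_gene_sets()$g2m, 54)
  expect_length(cc_gene_sets()$s, 43)
  expect_error(score_cell_cycle(toy_norm(matrix(1, 5, 5))), "genes found")
})

test_that("regress_out removes a linear covariate and keeps constants", {
  set.seed(23)
  n_cells <- 150
  cov <- stats::rnorm(n_cells)
  vals <- rbind(2 * cov + stats::rnorm(n_cells, sd = 0.1),
                stats::rnorm(n_cells),
                rep(3, n_cells))
  norm <- toy_norm(vals)
  out <- regress_out(norm, data.frame(cv = cov))
  expect_lt(abs(stats::cor(out$values[1, ], cov)), 0.05)
  expect_equal(unname(out$values[3, ]), rep(3, n_cells))
  # all-zero covariate leaves the matrix unchanged (collinear with intercept)
  expect_warning(null <- regress_out(norm, data.frame(z = rep(0, n_cells))),
                 "collinear")
  expect_equal(null$values, norm$values)
})

test_that("multiplet rate estimation is unbiased at 3% injected doublets", {
  spec <- simulation_spec(2000, 300, list(population_spec("all", 1)),
                          seed = 19)
  sim <- simulate_barnyard(spec, doublet_rate = 0.03)
  est <- estimate_multiplet_rate(sim$matrix)
  expect_lt(abs(est$inferred_total_rate - 0.03), 0.01)
  # single-species input rejected
  half <- subset_count_matrix(sim$matrix,
                              genes = startsWith(sim$matrix$gene_symbols, "hg_"))
  expect_error(estimate_multiplet_rate(half), "two species")
})
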