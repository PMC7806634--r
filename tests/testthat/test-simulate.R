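test_that("identical spec and seed reproduce byte-identical output", {
  spec <- default_simulation_spec(n_cells = 200, n_genes = 400, seed = 42)
  a <- simulate_counts(spec)
  b <- simulate_counts(spec)
  expect_identical(as.matrix(a$matrix$counts), as.matrix(b$matrix$counts))
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("degenerate library depth yields an all-zero matrix", {
  spec <- simulation_spec(50, 100, list(population_spec("all", 1)),
                          library_size_logmean = -Inf, seed = 1)
  sim <- simulate_counts(spec)
  expect_equal(sum(sim$matrix$counts), 0)
})

test_that("planted expressing fractions are recovered within 3 binomial SEs", {
  spec <- simulation_spec(
    2000, 300,
    list(population_spec("neural", 0.5, ligand_genes = c(WNT3A = 0.10)),
         population_spec("other", 0.5)),
    seed = 7)
  sim <- simulate_counts(spec)
  lab <- sim$truth$cells$population
  n_pop <- sum(lab == "neural")
  realized <- percent_expressing(sim$matrix, lab, "WNT3A", "neural")
  se <- sqrt(0.10 * 0.90 / n_pop)
  expect_lt(abs(realized - 0.10), 3 * se)
  # restricted to the target population
  expect_equal(percent_expressing(sim$matrix, lab, "WNT3A", "other"), 0)
})

test_that("background gene means match the analytic NB mean", {
  spec <- simulation_spec(1500, 200, list(population_spec("all", 1)),
                          seed = 3)
  sim <- simulate_counts(spec)
  tg <- sim$truth$genes
  bg <- tg$gene[tg$role == "background"][1:50]
  lib_mean <- mean(sim$truth$cells$library_factor)
  for (g in bg) {
    x <- as.numeric(sim$matrix$counts[match(g, sim$matrix$gene_symbols), ])
    expected <- tg$baseline_mean[tg$gene == g] * lib_mean
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - expected), max(3 * se, 1e-8))
  }
})

test_that("planted module genes correlate more within than between modules", {
  spec <- simulation_spec(
    400, 200, list(population_spec("all", 1)),
    modules = list(module_spec("M1", 50, c(0.8, 0.8))),
    seed = 5)
  sim <- simulate_counts(spec)
  norm <- log_normalize(sim$matrix)
  tg <- sim$truth$genes
  in_mod <- tg$gene[tg$role == "module"]
  out_mod <- tg$gene[tg$role == "background"][1:50]
  cm_in <- cor(t(norm$values[in_mod, ]))
  cm_x <- cor(t(norm$values[c(in_mod, out_mod), ]))[in_mod, out_mod]
  # counting noise attenuates count-level correlations, so the gap is
  # moderate but clearly positive
  expect_gt(median(cm_in[upper.tri(cm_in)]), median(cm_x) + 0.15)
})

test_that("marker expressing-fraction calibration hits its target", {
  spec <- clustering_benchmark_spec(n_cells = 1500, seed = 11)
  sim <- simulate_counts(spec)
  lab <- sim$truth$cells$population
  pct <- sapply(sprintf("popA.MK%02d", 1:10), function(g)
    percent_expressing(sim$matrix, lab, g, "popA"))
  expect_lt(abs(mean(pct) - 0.6), 0.05)
})

test_that("doublet injection follows the rounding rule and is additive", {
  spec <- simulation_spec(1000, 150, list(population_spec("all", 1)), seed = 2)
  sim <- simulate_counts(spec)

  none <- inject_doublets(sim$matrix, 0, seed = 1)
  expect_identical(as.matrix(none$matrix$counts), as.matrix(sim$matrix$counts))

  dd <- inject_doublets(sim$matrix, 0.03, seed = 1)
  expect_equal(sum(dd$truth$is_doublet), 30)
  expect_equal(ncol(dd$matrix$counts), 1030)
  # additivity: each doublet's totals are the sum of its parents'
  tot <- Matrix::colSums(dd$matrix$counts)
  names(tot) <- dd$matrix$barcodes
  doub <- dd$truth[dd$truth$is_doublet, ]
  expect_equal(unname(tot[doub$barcode]),
               unname(tot[doub$parent1] + tot[doub$parent2]))
  # parents are distinct within each doublet
  expect_true(all(doub$parent1 != doub$parent2))
})

test_that("doublet rate outside [0, 0.5) is rejected", {
  spec <- simulation_spec(20, 50, list(population_spec("all", 1)), seed = 1)
  sim <- simulate_counts(spec)
  expect_error(inject_doublets(sim$matrix, 0.6))
  expect_error(inject_doublets(sim$matrix, -0.1))
})

test_that("barnyard singlets are pure and doublet geometry is correct", {
  spec <- simulation_spec(600, 300, list(population_spec("all", 1)), seed = 9)
  pure <- simulate_barnyard(spec, doublet_rate = 0)
  est <- estimate_multiplet_rate(pure$matrix)
  expect_true(all(est$purity$purity[Matrix::colSums(pure$matrix$counts) > 0] == 1))

  # determinism
  again <- simulate_barnyard(spec, doublet_rate = 0.05)
  again2 <- simulate_barnyard(spec, doublet_rate = 0.05)
  expect_identical(as.matrix(again$matrix$counts), as.matrix(again2$matrix$counts))

  # cross-species doublets are about half of all doublets (1:1 mixture)
  big <- simulate_barnyard(
    simulation_spec(4000, 300, list(population_spec("all", 1)), seed = 13),
    doublet_rate = 0.2)
  n_doub <- sum(big$truth$is_doublet)
  frac_cross <- sum(big$truth$is_cross) / n_doub
  se <- sqrt(0.25 / n_doub)
  expect_lt(abs(frac_cross - 0.5), 3 * se)
})

test_that("conflicting marker roles and invalid specs are rejected", {
  expect_error(simulation_spec(
    100, 200,
    list(population_spec("a", 0.5, marker_genes = "SOX9"),
         population_spec("b", 0.5, marker_genes = "SOX9"))),
    "role conflict")
  expect_error(simulation_spec(100, 200,
                               list(population_spec("a", 0.7))),
               "sum to 1")
  expect_error(simulation_spec(100, 10,
                               list(population_spec("a", 1))),
               "smaller")
})
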