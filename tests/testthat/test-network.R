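test_that("signed adjacency endpoints and closed form", {
  cm <- matrix(c(1, 0.5, -1, 0.5, 1, 0, -1, 0, 1), 3, 3)
  a <- signed_adjacency(cm, beta = 8)
  expect_equal(a[1, 3], 0)               # cor -1 -> 0
  expect_equal(diag(a), rep(1, 3))       # cor 1 -> 1
  expect_equal(a[1, 2], 0.75^8, tolerance = 1e-12)
  expect_error(signed_adjacency(cm, beta = 0.5), "beta")
})

test_that("TOM matches the hand-computed 3-gene example", {
  a <- make_fixture("tom_toy")
  tom <- compute_tom(a)
  expect_equal(tom["g1", "g2"], (0.2 * 0.4 + 0.5) / (min(0.7, 0.9) + 1 - 0.5),
               tolerance = 1e-12)
  expect_equal(diag(tom), c(g1 = 1, g2 = 1, g3 = 1))
})

test_that("TOM equals a brute-force triple loop on random matrices", {
  set.seed(71)
  for (rep in 1:25) {
    n <- 20
    a <- matrix(stats::runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    tom <- compute_tom(a)
    expect_lt(max(abs(tom - brute_tom(a))), 1e-10)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom), tolerance = 1e-12)
  }
})

test_that("no-shared-neighbor adjacency gives zero off-diagonal TOM", {
  a <- diag(4)
  expect_equal(compute_tom(a), diag(4))
})

test_that("mean connectivity strictly decreases with power", {
  set.seed(73)
  vals <- matrix(stats::rnorm(60 * 100), nrow = 60)
  norm <- toy_norm(vals, cells = sprintf("c%03d", 1:100))
  res <- suppressWarnings(pick_soft_threshold(norm, network_config(
    candidate_powers = 1:12)))
  expect_true(all(diff(res$table$mean_k) < 0))
})

test_that("engineered power-law connectivity yields a high scale-free fit", {
  # construct genes as noisy copies of a hub signal with power-law-spread
  # attenuation so connectivity spans a wide range
  set.seed(79)
  n_cells <- 200
  hub <- stats::rnorm(n_cells)
  alphas <- (1:150 / 150)^2.5
  vals <- t(vapply(alphas, function(a)
    a * hub + sqrt(1 - a^2) * stats::rnorm(n_cells), numeric(n_cells)))
  norm <- toy_norm(vals, genes = sprintf("g%03d", 1:150),
                   cells = sprintf("c%03d", seq_len(n_cells)))
  res <- suppressWarnings(pick_soft_threshold(norm, network_config()))
  expect_gte(max(res$table$signed_r2, na.rm = TRUE), 0.95)
})

test_that("degenerate inputs fall back to the default power with warning", {
  base <- stats::rnorm(80)
  vals <- t(vapply(seq_len(60), function(i) base * i, numeric(80)))
  norm <- toy_norm(vals, cells = sprintf("c%02d", 1:80))
  expect_warning(res <- pick_soft_threshold(norm, network_config()),
                 "falling back")
  expect_equal(res$beta, 8)
})

test_that("gene/sample cleaning removes constant and missing-heavy genes", {
  vals <- matrix(stats::rexp(50 * 30), nrow = 50)
  vals[3, ] <- 7                        # constant
  vals[9, 1:20] <- NA                   # > 50% missing
  norm <- toy_norm(vals)
  out <- clean_genes_samples(norm)
  expect_equal(nrow(out$values), 48)
  expect_false(norm$gene_symbols[3] %in% out$gene_symbols)
  expect_false(norm$gene_symbols[9] %in% out$gene_symbols)
  # clean matrix unchanged
  clean <- toy_norm(matrix(stats::rexp(100), 10))
  expect_equal(clean_genes_samples(clean)$values, clean$values)
})

test_that("planted orthogonal modules are recovered and labels are
           order-invariant", {
  sim <- simulate_counts(module_benchmark_spec(n_modules = 2, n_cells = 400,
                                               n_genes = 250, seed = 81))
  norm <- log_normalize(sim$matrix)
  tg <- sim$truth$genes
  keep <- !is.na(tg$module) | tg$role == "background"
  genes <- tg$gene[keep][1:150]
  normr <- norm
  normr$values <- norm$values[genes, ]
  normr$gene_symbols <- genes
  net <- build_network(normr)
  truth_mod <- tg$module[match(net$genes, tg$gene)]
  truth_mod[is.na(truth_mod)] <- "none"
  expect_gte(ari(net$modules$labels, truth_mod), 0.9)

  # permuting the gene order does not change the partition
  set.seed(82)
  perm <- sample(length(genes))
  normp <- normr
  normp$values <- normr$values[perm, ]
  normp$gene_symbols <- normr$gene_symbols[perm]
  netp <- build_network(normp)
  expect_equal(ari(net$modules$labels[net$genes],
                   netp$modules$labels[net$genes]), 1)
})

test_that("modules sharing a latent factor merge above the eigengene cut", {
  mk_spec <- function(rho, seed) simulation_spec(
    400, 150, list(population_spec("all", 1)),
    modules = list(
      module_spec("A", 40, c(0.8, 0.8)),
      module_spec("B", 40, c(0.8, 0.8), shared_latent_with = "A",
                  shared_latent_rho = rho)),
    seed = seed)
  # rho 0.85 -> eigengene correlation > 0.75 -> merged
  simh <- simulate_counts(mk_spec(0.85, 91))
  normh <- log_normalize(simh$matrix)
  normh$values <- normh$values[1:80, ]
  normh$gene_symbols <- normh$gene_symbols[1:80]
  neth <- build_network(normh)
  expect_equal(length(neth$modules$modules), 1)

  # rho 0.3 -> eigengene correlation well below 0.75 -> two modules
  siml <- simulate_counts(mk_spec(0.3, 92))
  norml <- log_normalize(siml$matrix)
  norml$values <- norml$values[1:80, ]
  norml$gene_symbols <- norml$gene_symbols[1:80]
  netl <- build_network(norml)
  expect_equal(length(netl$modules$modules), 2)
})

test_that("module eigengene behaves on degenerate and planted modules", {
  set.seed(93)
  vals <- matrix(stats::rnorm(10 * 50), nrow = 10)
  norm <- toy_norm(vals)
  # single-gene module: the z-scored gene itself
  e1 <- module_eigengene(norm, norm$gene_symbols[1])
  expect_equal(unname(e1), as.numeric(scale(vals[1, ])), tolerance = 1e-9)

  # two perfectly correlated genes: eigengene correlates 1 with each
  vals2 <- rbind(vals[1, ], 2 * vals[1, ] + 3)
  norm2 <- toy_norm(vals2, genes = c("x", "y"))
  e2 <- module_eigengene(norm2, c("x", "y"))
  expect_equal(abs(stats::cor(e2, vals2[1, ])), 1, tolerance = 1e-9)

  # planted module eigengene tracks the latent factor; the background
  # universe is kept large so depth normalization does not couple the
  # module's share of the library to its own latent factor
  sim <- simulate_counts(module_benchmark_spec(n_modules = 1, n_cells = 300,
                                               n_genes = 400, seed = 95))
  norm3 <- log_normalize(sim$matrix)
  mod_genes <- sim$truth$genes$gene[!is.na(sim$truth$genes$module)]
  e3 <- module_eigengene(norm3, mod_genes)
  expect_gte(abs(stats::cor(e3, sim$truth$latent[, 1])), 0.9)
})
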