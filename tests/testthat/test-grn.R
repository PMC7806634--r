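test_that("star and path betweenness match the closed forms", {
  star <- make_fixture("star_graph")
  hs <- hub_scores(star, top_k = 1)
  center <- hs[hs$gene == "center", ]
  expect_equal(center$degree, 4L)
  expect_equal(center$strength, 2.0)
  expect_equal(center$betweenness, 6)        # (n-1)(n-2)/2 leaf pairs
  expect_true(center$is_hub)
  expect_true(all(hs$betweenness[hs$gene != "center"] == 0))

  path <- igraph::make_graph(~ A - B, B - C)
  igraph::E(path)$weight <- 1
  hp <- hub_scores(path, top_k = 1)
  expect_equal(hp$betweenness[match(c("A", "B", "C"), hp$gene)], c(0, 1, 0))
})

test_that("betweenness equals exhaustive path enumeration on random
           graphs", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(4:8, 1)
    repeat {
      a <- matrix(stats::rbinom(n * n, 1, 0.45), n, n)
      a[lower.tri(a, diag = TRUE)] <- 0
      a <- a + t(a)
      if (sum(a) > 0) break
    }
    dimnames(a) <- list(paste0("v", 1:n), paste0("v", 1:n))
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.1, 1)
    if (igraph::vcount(g) < 3) next
    hs <- hub_scores(g, top_k = 1)
    oracle <- brute_bc(g)
    expect_equal(hs$betweenness[match(igraph::V(g)$name, hs$gene)], oracle,
                 tolerance = 1e-9)
  }
})

test_that("betweenness sums match the pairwise decomposition", {
  set.seed(103)
  a <- matrix(stats::rbinom(49, 1, 0.5), 7, 7)
  a[lower.tri(a, diag = TRUE)] <- 0
  a <- a + t(a)
  dimnames(a) <- list(paste0("v", 1:7), paste0("v", 1:7))
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  igraph::E(g)$weight <- 1
  hs <- hub_scores(g, top_k = 1)
  expect_equal(sum(hs$betweenness), sum(brute_bc(g)), tolerance = 1e-9)
})

test_that("TF neighborhoods rank genes by adjacency weight", {
  sim <- simulate_counts(module_benchmark_spec(n_modules = 1, n_cells = 300,
                                               n_genes = 120, seed = 105))
  norm <- log_normalize(sim$matrix)
  tg <- sim$truth$genes
  mod_genes <- tg$gene[!is.na(tg$module)]
  normm <- norm
  normm$values <- norm$values[c(mod_genes, tg$gene[tg$role == "background"][1:20]), ]
  normm$gene_symbols <- rownames(normm$values)
  net <- build_network(normm)
  tf <- tg$gene[tg$is_tf]

  # n_top >= module size connects every module gene to the TF
  g_all <- select_tf_neighborhoods(net, mod_genes, tf, n_top = 100)
  expect_setequal(igraph::V(g_all)$name, mod_genes)
  expect_equal(sum(igraph::V(g_all)$is_tf), 1)

  # small n_top keeps the strongest partners of the TF
  g_small <- select_tf_neighborhoods(net, mod_genes, tf, n_top = 10)
  w <- net$adjacency[tf, setdiff(mod_genes, tf)]
  top10 <- names(sort(w, decreasing = TRUE))[1:10]
  expect_setequal(setdiff(igraph::V(g_small)$name, tf), top10)

  expect_error(select_tf_neighborhoods(net, mod_genes, "NOT_A_TF"), "no TF")
})

test_that("explicit weight ranking picks the top n_top genes", {
  # weights {g1: 0.9, g2: 0.5, g3: 0.4}, n_top 2 -> {g1, g2}
  cm <- diag(4)
  dimnames(cm) <- list(c("TF", "g1", "g2", "g3"), c("TF", "g1", "g2", "g3"))
  cm["TF", c("g1", "g2", "g3")] <- c(0.9, 0.5, 0.4) * 2 - 1
  cm[c("g1", "g2", "g3"), "TF"] <- cm["TF", c("g1", "g2", "g3")]
  net <- structure(list(genes = rownames(cm),
                        adjacency = signed_adjacency(cm, beta = 1)),
                   class = "coexpression_network")
  g <- select_tf_neighborhoods(net, rownames(cm), "TF", n_top = 2,
                               edge_floor = 0)
  expect_setequal(igraph::V(g)$name, c("TF", "g1", "g2"))
})

test_that("two cliques joined by a weak edge form two communities", {
  a <- matrix(0, 10, 10)
  a[1:5, 1:5] <- 1
  a[6:10, 6:10] <- 1
  diag(a) <- 0
  a[5, 6] <- a[6, 5] <- 0.05
  dimnames(a) <- list(paste0("v", 1:10), paste0("v", 1:10))
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE)
  comm <- community_cluster(g, seed = 4)
  expect_equal(length(unique(comm)), 2)
  expect_equal(length(unique(comm[paste0("v", 1:5)])), 1)
  # complete uniform graph: one community
  full <- igraph::make_full_graph(6)
  igraph::V(full)$name <- paste0("u", 1:6)
  igraph::E(full)$weight <- 1
  expect_equal(length(unique(community_cluster(full, seed = 1))), 1)
  # determinism
  expect_identical(community_cluster(g, seed = 4), community_cluster(g, seed = 4))
})

test_that("planted hub TF contains its strongest simulated partners", {
  sim <- simulate_counts(module_benchmark_spec(n_modules = 1, loading = 0.8,
                                               n_cells = 400, n_genes = 160,
                                               seed = 107))
  norm <- log_normalize(sim$matrix)
  tg <- sim$truth$genes
  mod_genes <- tg$gene[!is.na(tg$module)]
  normm <- norm
  normm$values <- norm$values[mod_genes, ]
  normm$gene_symbols <- mod_genes
  net <- build_network(normm)
  tf <- tg$gene[tg$is_tf]
  g <- select_tf_neighborhoods(net, mod_genes, tf, n_top = 40)
  # the neighborhood holds at least 90% of the TF's strongest true partners
  expect_gte(length(intersect(igraph::V(g)$name, mod_genes)), 37)
})
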