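#' Build a TF-anchored regulatory subnetwork from a module
#'
#' For every transcription factor in the module, the `n_top` module genes
#' with the highest signed-adjacency weight to that TF are selected (ties
#' broken by gene symbol). The graph is the union of the TF-gene edges plus
#' all gene-gene edges among selected nodes with weight at or above
#' `edge_floor`.
#'
#' @param network A `coexpression_network`.
#' @param module_genes Character vector of module member genes.
#' @param tf_list Character vector of TF symbols.
#' @param n_top Neighborhood size per TF (default 100).
#' @param edge_floor Minimum gene-gene edge weight (default 0.02).
#' @return An igraph graph with vertex attribute `is_tf` and edge weights.
#' @export
select_tf_neighborhoods <- function(network, module_genes, tf_list,
                                    n_top = 100, edge_floor = 0.02) {
  stopifnot(inherits(network, "coexpression_network"))
  module_genes <- intersect(module_genes, network$genes)
  tfs <- intersect(module_genes, tf_list)
  if (!length(tfs))
    stop("no TF from tf_list found in module (",
         length(module_genes), " genes)")
  adj <- network$adjacency[module_genes, module_genes, drop = FALSE]
  picked <- character(0)
  for (tf in tfs) {
    w <- adj[tf, setdiff(module_genes, tf)]
    ord <- order(-w, names(w))
    picked <- union(picked, names(w)[ord][seq_len(min(n_top, length(w)))])
  }
  nodes <- sort(union(tfs, picked))
  sub <- adj[nodes, nodes, drop = FALSE]
  keep <- sub >= edge_floor
  # always keep TF-neighbor edges regardless of the floor
  keep[tfs, ] <- TRUE
  keep[, tfs] <- TRUE
  sub[!(keep | t(keep))] <- 0
  diag(sub) <- 0
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$is_tf <- igraph::V(g)$name %in% tf_list
  g
}

#' Cluster a regulatory subnetwork into communities
#'
#' Weighted modularity (Louvain) community detection; deterministic for a
#' fixed seed; each singleton component gets its own label.
#'
#' @param graph An igraph graph with edge weights.
#' @param seed Integer seed.
#' @return Integer community labels named by gene.
#' @export
community_cluster <- function(graph, seed = 1L) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  set.seed(derive_seed(seed, "community"))
  comm <- igraph::cluster_louvain(graph,
                                  weights = igraph::E(graph)$weight)
  stats::setNames(as.integer(igraph::membership(comm)),
                  igraph::V(graph)$name)
}

#' Rank hub genes by weight, degree and betweenness
#'
#' Per node: strength (summed edge weights), degree (edge count), and
#' betweenness centrality on the unweighted edge set (Brandes,
#' unnormalized). Each metric is dense-ranked descending (rank 1 = best)
#' and the combined rank is their arithmetic mean; the `top_k` nodes with
#' the lowest combined rank (ties by gene symbol) are flagged hubs.
#'
#' @param graph An igraph graph with edge weights.
#' @param top_k Number of hubs to flag (default 5).
#' @return data.frame sorted by `combined_rank`: `gene`, `strength`,
#'   `degree`, `betweenness`, the three ranks, `combined_rank`, `is_hub`.
#' @export
hub_scores <- function(graph, top_k = 5) {
  n <- igraph::vcount(graph)
  if (n < 3) stop("need at least 3 nodes")
  strength <- igraph::strength(graph, weights = igraph::E(graph)$weight)
  degree <- igraph::degree(graph)
  bc <- igraph::betweenness(graph, weights = NA, normalized = FALSE)
  df <- data.frame(gene = igraph::V(graph)$name,
                   strength = as.numeric(strength),
                   degree = as.integer(degree),
                   betweenness = as.numeric(bc),
                   stringsAsFactors = FALSE)
  df$rank_strength <- dense_rank_desc(df$strength)
  df$rank_degree <- dense_rank_desc(df$degree)
  df$rank_bc <- dense_rank_desc(df$betweenness)
  df$combined_rank <- (df$rank_strength + df$rank_degree + df$rank_bc) / 3
  df <- df[order(df$combined_rank, df$gene), , drop = FALSE]
  df$is_hub <- seq_len(nrow(df)) <= top_k
  rownames(df) <- NULL
  df
}

#' Run the GRN/hub stage over all modules of a network
#'
#' For each detected module containing at least one TF, builds the
#' TF-anchored subnetwork, clusters it into communities, and ranks hubs
#' within the whole subnetwork and within each community.
#'
#' @param network A `coexpression_network`.
#' @param tf_list Character vector of TF symbols.
#' @param n_top,edge_floor,top_k,seed Passed through.
#' @return Named list per module: `graph`, `communities`, `hubs`
#'   (with a `community` column).
#' @export
grn_hubs_by_module <- function(network, tf_list, n_top = 100,
                               edge_floor = 0.02, top_k = 5, seed = 1L) {
  out <- list()
  for (i in seq_along(network$modules$modules)) {
    genes <- network$modules$modules[[i]]
    if (!length(intersect(genes, tf_list))) next
    g <- select_tf_neighborhoods(network, genes, tf_list,
                                 n_top = n_top, edge_floor = edge_floor)
    comm <- community_cluster(g, seed = seed)
    hubs <- hub_scores(g, top_k = top_k)
    hubs$community <- comm[hubs$gene]
    out[[paste0("module", i)]] <- list(graph = g, communities = comm,
                                       hubs = hubs)
  }
  out
}
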