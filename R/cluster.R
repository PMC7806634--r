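#' Embed cells by PCA on highly variable genes
#'
#' HVG rows are z-scored across cells (values clipped at +/-10) and the
#' principal components are taken by SVD. Each component's sign is fixed so
#' its largest-magnitude gene loading is positive, making the embedding
#' deterministic.
#'
#' @param norm A `normalized_matrix`.
#' @param hvgs Character vector of genes to use.
#' @param n_pcs Number of components (default 20); reduced with a warning
#'   when it exceeds the data rank.
#' @return Cells x components score matrix with a `loadings` attribute.
#' @export
embed_cells <- function(norm, hvgs, n_pcs = 20) {
  stopifnot(inherits(norm, "normalized_matrix"))
  hvgs <- intersect(hvgs, norm$gene_symbols)
  X <- norm$values[hvgs, , drop = FALSE]
  mu <- rowMeans(X)
  sd <- apply(X, 1, stats::sd)
  sd[sd == 0] <- Inf   # constant genes contribute zero loading
  Xs <- (X - mu) / sd
  Xs[Xs > 10] <- 10
  Xs[Xs < -10] <- -10
  max_pcs <- min(dim(Xs)) - 1L
  if (n_pcs > max_pcs) {
    warning("n_pcs reduced to ", max_pcs)
    n_pcs <- max_pcs
  }
  sv <- svd(t(Xs), nu = n_pcs, nv = n_pcs)
  flip <- vapply(seq_len(n_pcs), function(k) {
    v <- sv$v[, k]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs), 2, flip, `*`)
  rownames(scores) <- norm$barcodes
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  loadings <- sweep(sv$v, 2, flip, `*`)
  rownames(loadings) <- hvgs
  attr(scores, "loadings") <- loadings
  scores
}

#' Cluster cells on a shared-nearest-neighbor graph
#'
#' A k-nearest-neighbor graph (Euclidean distance in the embedding) is
#' converted to shared-nearest-neighbor Jaccard weights (neighborhoods
#' include the cell itself); edges with weight below `prune` are dropped
#' and communities are found by modularity (Louvain) at the given
#' resolution.
#'
#' @param embedding Cells x components matrix from [embed_cells()].
#' @param k_neighbors Neighborhood size (default 30).
#' @param resolution Modularity resolution (default 0.6).
#' @param prune Jaccard pruning threshold (default 1/15).
#' @param seed Integer seed for the community search.
#' @return A `cluster_assignment`: integer labels (0-based, ordered by
#'   decreasing cluster size) named by barcode, with parameters attached.
#' @export
cluster_cells <- function(embedding, k_neighbors = 30, resolution = 0.6,
                          prune = 1 / 15, seed = 1L) {
  n <- nrow(embedding)
  if (n < k_neighbors + 1) stop("need at least k_neighbors + 1 cells")
  d <- as.matrix(stats::dist(embedding))
  # neighbor sets of size k including self
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_neighbors)]))
  N <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_neighbors),
                            j = as.integer(t(nn)), x = 1, dims = c(n, n))
  S <- Matrix::tcrossprod(N)                     # shared-neighbor counts
  J <- S
  J@x <- J@x / (2 * k_neighbors - J@x)           # Jaccard: |A|=|B|=k
  J@x[J@x < prune] <- 0
  J <- Matrix::drop0(J)
  Matrix::diag(J) <- 0
  g <- igraph::graph_from_adjacency_matrix(J, mode = "undirected",
                                           weighted = TRUE)
  set.seed(derive_seed(seed, "louvain"))
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  raw <- igraph::membership(comm)
  # relabel contiguously from 0, by decreasing size, ties by first member
  sizes <- sort(table(raw), decreasing = TRUE)
  labels <- match(as.character(raw), names(sizes)) - 1L
  names(labels) <- rownames(embedding)
  structure(labels, class = "cluster_assignment",
            resolution = resolution, k_neighbors = k_neighbors,
            n_pcs = ncol(embedding), seed = seed)
}
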