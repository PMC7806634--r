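# Independent oracles used to validate the package's implementations.
# These deliberately use naive enumeration / triple loops, not the code
# paths they check.

# adjusted Rand index between two labelings
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# brute-force topological overlap: literal triple loop over the formula
brute_tom <- function(a) {
  a <- as.matrix(a)
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- sum(a[i, -c(i, j)] * a[-c(i, j), j]) + a[i, j]
    tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# exhaustive betweenness: enumerate every geodesic between every pair and
# credit interior vertices, splitting across tied geodesics
brute_bc <- function(g) {
  n <- igraph::vcount(g)
  bc <- numeric(n)
  d <- igraph::distances(g, weights = NA)
  for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
    if (!is.finite(d[s, t]) || d[s, t] == 0) next
    paths <- igraph::all_simple_paths(g, from = s, to = t, cutoff = d[s, t])
    geo <- paths[vapply(paths, length, 1L) == d[s, t] + 1]
    for (p in geo) {
      interior <- setdiff(as.integer(p), c(s, t))
      bc[interior] <- bc[interior] + 1 / length(geo)
    }
  }
  bc
}

# exact two-sided Wilcoxon rank-sum p-value by full enumeration of group
# assignments (tie-free data only)
exact_wilcox_p <- function(x, y) {
  m <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  all_w <- apply(utils::combn(m + length(y), m), 2, function(idx) {
    sum(seq_len(m + length(y))[idx]) - m * (m + 1) / 2
  })
  pl <- mean(all_w <= w_obs)
  pg <- mean(all_w >= w_obs)
  min(1, 2 * min(pl, pg))
}

# small deterministic normalized matrix built from given values
toy_norm <- function(values, genes = NULL, cells = NULL) {
  genes <- genes %||% sprintf("g%02d", seq_len(nrow(values)))
  cells <- cells %||% sprintf("c%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, cells)
  structure(list(values = values, gene_symbols = genes, barcodes = cells,
                 scale_factor = 10000, provenance = NULL),
            class = "normalized_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
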