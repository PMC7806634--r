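#' Co-expression network configuration
#'
#' @param candidate_powers Candidate soft-thresholding powers.
#' @param beta Default power when scale-free selection falls back.
#' @param merge_cut_height Eigengene dissimilarity below which modules
#'   merge (modules merge when eigengene correlation exceeds
#'   `1 - merge_cut_height`).
#' @param min_module_size Smallest retained module.
#' @param scale_free_r2_target Signed R-squared required to accept a power.
#' @param n_degree_bins Equal-width connectivity bins for the scale-free
#'   fit.
#' @param cut_height Static tree-cut height on the 1 - TOM dendrogram.
#' @return A `network_config` object.
#' @export
network_config <- function(candidate_powers = 1:20, beta = 8,
                           merge_cut_height = 0.25, min_module_size = 30,
                           scale_free_r2_target = 0.8, n_degree_bins = 10,
                           cut_height = 0.99) {
  stopifnot(beta >= 1, merge_cut_height > 0, merge_cut_height < 1)
  structure(list(candidate_powers = candidate_powers, beta = beta,
                 merge_cut_height = merge_cut_height,
                 min_module_size = min_module_size,
                 scale_free_r2_target = scale_free_r2_target,
                 n_degree_bins = n_degree_bins, cut_height = cut_height),
            class = "network_config")
}

#' Remove unusable genes and cells before network construction
#'
#' Zero-variance genes and any gene or cell with more than 50% missing
#' entries are removed (UMI matrices have no missing values; the rule is
#' kept for generality). A removal log is attached as the `cleaning`
#' attribute.
#'
#' @param norm A `normalized_matrix`.
#' @return The cleaned `normalized_matrix`.
#' @export
clean_genes_samples <- function(norm) {
  stopifnot(inherits(norm, "normalized_matrix"))
  V <- norm$values
  miss_g <- rowMeans(is.na(V))
  miss_c <- colMeans(is.na(V))
  keep_c <- miss_c <= 0.5
  v <- apply(V[, keep_c, drop = FALSE], 1, function(r) stats::var(r, na.rm = TRUE))
  keep_g <- miss_g <= 0.5 & !is.na(v) & v > 0
  if (!any(keep_g) || !any(keep_c)) stop("cleaning removed everything")
  norm$values <- V[keep_g, keep_c, drop = FALSE]
  norm$gene_symbols <- norm$gene_symbols[keep_g]
  norm$barcodes <- norm$barcodes[keep_c]
  attr(norm, "cleaning") <- list(genes_removed = sum(!keep_g),
                                 cells_removed = sum(!keep_c))
  norm
}

#' Signed soft-threshold adjacency
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta`, diagonal set to 1. The signed
#' transform keeps negatively correlated genes near adjacency 0 rather than
#' folding them onto positive correlations.
#'
#' @param cor_mat Symmetric correlation matrix with entries in `[-1, 1]`.
#' @param beta Soft-thresholding power (`>= 1`; default 8).
#' @return Adjacency matrix in `[0, 1]`.
#' @export
signed_adjacency <- function(cor_mat, beta = 8) {
  if (beta < 1) stop("beta must be >= 1")
  a <- ((1 + cor_mat) / 2)^beta
  diag(a) <- 1
  a
}

# connectivity excluding the diagonal
.connectivity <- function(adj) rowSums(adj) - diag(adj)

# scale-free fit: regress log10 frequency on log10 mean connectivity over
# equal-width connectivity bins; signed R^2 = -sign(slope) * R^2
.scale_free_fit <- function(k, n_bins = 10) {
  k <- k[is.finite(k)]
  if (length(unique(k)) < 2 || diff(range(k)) < 1e-8) return(NA_real_)
  br <- unique(seq(min(k), max(k), length.out = n_bins + 1))
  if (length(br) < 4) return(NA_real_)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mk <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0 & mk > 0
  if (sum(ok) < 3) return(NA_real_)
  fit <- stats::lm(log10(freq[ok]) ~ log10(mk[ok]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' Pick the soft-thresholding power by approximate scale-free fit
#'
#' For each candidate power the signed adjacency and connectivities are
#' computed; connectivity is binned (equal width) and log10 frequency is
#' regressed on log10 mean bin connectivity. The chosen power is the
#' smallest with signed R-squared at or above the target, falling back to
#' the default power with a warning when none qualifies.
#'
#' @param norm A `normalized_matrix` (genes x cells).
#' @param config A [network_config()].
#' @return List with `table` (power, signed R2, mean and median
#'   connectivity) and `beta` (chosen power).
#' @export
pick_soft_threshold <- function(norm, config = network_config()) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (nrow(norm$values) < 50) stop("need at least 50 genes")
  cm <- stats::cor(t(norm$values))
  degenerate <- all(abs(cm[upper.tri(cm)]) < 1e-12) ||
    all(abs(cm[upper.tri(cm)] - 1) < 1e-12)
  tab <- do.call(rbind, lapply(config$candidate_powers, function(p) {
    adj <- signed_adjacency(cm, p)
    k <- .connectivity(adj)
    data.frame(power = p,
               signed_r2 = .scale_free_fit(k, config$n_degree_bins),
               mean_k = mean(k), median_k = stats::median(k))
  }))
  ok <- !is.na(tab$signed_r2) & tab$signed_r2 >= config$scale_free_r2_target
  if (degenerate || !any(ok)) {
    warning("no candidate power reached signed R2 >= ",
            config$scale_free_r2_target, "; falling back to beta = ",
            config$beta)
    beta <- config$beta
  } else {
    beta <- tab$power[which(ok)[1]]
  }
  list(table = tab, beta = beta)
}

#' Topological overlap matrix (unsigned)
#'
#' With the diagonal excluded from all sums,
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j` and `TOM_ii = 1`. Shared-neighbor structure thus reinforces
#' direct adjacency.
#'
#' @param adj Symmetric adjacency matrix in `[0, 1]`.
#' @return TOM matrix in `[0, 1]` with unit diagonal.
#' @export
compute_tom <- function(adj) {
  a <- as.matrix(adj)
  diag(a) <- 0
  k <- rowSums(a)
  L <- a %*% a
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Module eigengene
#'
#' First principal component of the z-scored member expression across
#' cells, sign-oriented so its mean correlation with the members is
#' positive.
#'
#' @param norm A `normalized_matrix`.
#' @param genes Module member gene symbols.
#' @return Numeric per-cell score named by barcode.
#' @export
module_eigengene <- function(norm, genes) {
  stopifnot(length(genes) >= 1)
  X <- norm$values[genes, , drop = FALSE]
  mu <- rowMeans(X)
  sd <- apply(X, 1, stats::sd)
  sd[sd == 0] <- 1
  Xs <- (X - mu) / sd
  if (length(genes) == 1) {
    e <- drop(Xs)
  } else {
    sv <- svd(t(Xs), nu = 1, nv = 0)
    e <- drop(sv$u[, 1] * sv$d[1])
    mc <- mean(stats::cor(e, t(Xs)))
    if (!is.na(mc) && mc < 0) e <- -e
  }
  names(e) <- norm$barcodes
  e
}

#' Detect co-expression modules from the TOM
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, static cut at
#' `cut_height`; clusters below `min_module_size` become unassigned (label
#' 0). Modules are then iteratively merged while any pair of eigengenes
#' correlates above `1 - merge_cut_height` (most-correlated pair first).
#' Final labels are 1..K ordered by decreasing size.
#'
#' @param tom TOM matrix (genes match `norm` rows).
#' @param norm A `normalized_matrix` restricted to the same genes.
#' @param config A [network_config()].
#' @return List with `labels` (integer per gene, 0 = unassigned),
#'   `modules` (list of gene vectors) and `eigengenes` (cells x modules).
#' @export
detect_modules <- function(tom, norm, config = network_config()) {
  genes <- norm$gene_symbols
  stopifnot(nrow(tom) == length(genes))
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  raw <- stats::cutree(hc, h = config$cut_height)
  sizes <- table(raw)
  raw[raw %in% as.integer(names(sizes)[sizes < config$min_module_size])] <- 0L
  labs <- sort(setdiff(unique(raw), 0L))
  if (!length(labs)) {
    warning("no module reached min_module_size; all genes unassigned")
    return(list(labels = stats::setNames(rep(0L, length(genes)), genes),
                modules = list(), eigengenes = NULL))
  }
  members <- lapply(labs, function(l) genes[raw == l])
  # iterative eigengene merging
  repeat {
    if (length(members) < 2) break
    eg <- vapply(members, function(g) module_eigengene(norm, g),
                 numeric(ncol(norm$values)))
    cc <- stats::cor(eg)
    diag(cc) <- -Inf
    mx <- max(cc)
    if (mx <= 1 - config$merge_cut_height) break
    idx <- which(cc == mx, arr.ind = TRUE)[1, ]
    i <- min(idx); j <- max(idx)
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- NULL
  }
  members <- members[order(-vapply(members, length, integer(1)))]
  labels <- stats::setNames(rep(0L, length(genes)), genes)
  for (i in seq_along(members)) labels[members[[i]]] <- i
  eg <- vapply(members, function(g) module_eigengene(norm, g),
               numeric(ncol(norm$values)))
  colnames(eg) <- paste0("ME", seq_along(members))
  list(labels = labels, modules = members, eigengenes = eg)
}

#' Build the full co-expression network
#'
#' Cleans the input, computes the Pearson gene-gene correlation (cells as
#' observations), the signed adjacency at the configured power, the
#' unsigned TOM, and the module decomposition.
#'
#' @param norm A `normalized_matrix`.
#' @param config A [network_config()].
#' @param pick_power Re-select beta by scale-free fit first
#'   (default FALSE: use `config$beta`).
#' @return A `coexpression_network`: correlation, adjacency, TOM,
#'   connectivity, modules, config.
#' @export
build_network <- function(norm, config = network_config(), pick_power = FALSE) {
  norm <- clean_genes_samples(norm)
  if (pick_power) config$beta <- pick_soft_threshold(norm, config)$beta
  cm <- stats::cor(t(norm$values))
  adj <- signed_adjacency(cm, config$beta)
  tom <- compute_tom(adj)
  mods <- detect_modules(tom, norm, config)
  structure(list(genes = norm$gene_symbols, correlation = cm,
                 adjacency = adj, tom = tom,
                 connectivity = .connectivity(adj),
                 modules = mods, config = config, norm = norm),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d genes, beta = %g, %d modules\n",
              length(x$genes), x$config$beta, length(x$modules$modules)))
  invisible(x)
}
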