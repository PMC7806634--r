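# Natural-log fold change on the back-transformed scale:
# ln(mean(exp(x)-1) + 1) in the group minus the same outside it.
.lnfc <- function(vals_in, vals_out) {
  log(mean(expm1(vals_in)) + 1) - log(mean(expm1(vals_out)) + 1)
}

#' Detect cluster marker genes
#'
#' One-vs-rest Wilcoxon rank-sum per gene per cluster. A gene is reported
#' as a marker only if it is expressed in at least 25% of the cluster's
#' cells (`pct_in >= min_pct`) and its natural-log fold change exceeds
#' `lnfc_min`, where `ln FC = ln(mean(e^x - 1) + 1)` inside minus outside
#' the cluster. P-values are Bonferroni-adjusted by the number of genes in
#' the matrix.
#'
#' @param norm A `normalized_matrix`.
#' @param assignment A `cluster_assignment` (or integer labels named by
#'   barcode).
#' @param min_pct Minimum expressing fraction within the cluster
#'   (default 0.25).
#' @param lnfc_min Minimum natural-log fold change (default 0.25, strict).
#' @return data.frame of marker records sorted by `ln_fc` descending:
#'   `gene`, `cluster`, `ln_fc`, `pct_in`, `pct_out`, `p_value`,
#'   `adjusted_p`.
#' @export
find_markers <- function(norm, assignment, min_pct = 0.25, lnfc_min = 0.25) {
  stopifnot(inherits(norm, "normalized_matrix"))
  labels <- as.integer(assignment)
  if (length(labels) != ncol(norm$values))
    stop("assignment length must match cells")
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  n_genes <- nrow(norm$values)
  expd <- norm$values > 0
  recs <- list()
  for (cl in clusters) {
    inside <- labels == cl
    if (sum(inside) < 3) {
      warning("cluster ", cl, " has fewer than 3 cells; skipped")
      next
    }
    pct_in <- rowMeans(expd[, inside, drop = FALSE])
    pct_out <- rowMeans(expd[, !inside, drop = FALSE])
    cand <- which(pct_in >= min_pct)
    if (!length(cand)) next
    Ein <- expm1(norm$values[cand, inside, drop = FALSE])
    Eout <- expm1(norm$values[cand, !inside, drop = FALSE])
    lnfc <- log(rowMeans(Ein) + 1) - log(rowMeans(Eout) + 1)
    cand2 <- which(lnfc > lnfc_min)
    if (!length(cand2)) next
    p <- vapply(cand2, function(i) {
      stats::wilcox.test(norm$values[cand[i], inside],
                         norm$values[cand[i], !inside])$p.value
    }, numeric(1))
    recs[[length(recs) + 1L]] <- data.frame(
      gene = norm$gene_symbols[cand[cand2]], cluster = cl,
      ln_fc = lnfc[cand2], pct_in = pct_in[cand[cand2]],
      pct_out = pct_out[cand[cand2]], p_value = p,
      adjusted_p = pmin(1, p * n_genes), stringsAsFactors = FALSE)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(gene = character(), cluster = integer(), ln_fc = numeric(),
               pct_in = numeric(), pct_out = numeric(), p_value = numeric(),
               adjusted_p = numeric())
  out[order(-out$ln_fc), , drop = FALSE]
}

#' Default population marker signatures
#'
#' Literature marker sets for the cell populations expected in
#' chondrogenic pellet cultures: on-target chondrocytes, off-target neural
#' cells, melanocytes and neural crest, and residual mesenchyme.
#'
#' @return Named list of character vectors.
#' @export
default_signatures <- function() {
  list(
    chondrocyte = c("SOX9", "COL2A1", "ACAN", "COMP"),
    neural = c("SOX2", "PAX6", "OTX1", "OTX2", "NES"),
    melanocyte = c("MITF"),
    neural_crest = c("PAX3", "FOXD3"),
    mesenchyme = c("PRRX1", "COL1A1", "COL3A1")
  )
}

#' Annotate clusters against marker signatures
#'
#' Each cluster is scored per signature as the mean natural-log fold change
#' of the signature's genes (cluster vs all other cells; genes absent from
#' the matrix contribute 0) and labeled with the top-scoring signature.
#' Clusters with no positive score, or tied top scores, are labeled
#' `"unassigned"`.
#'
#' @param norm A `normalized_matrix`.
#' @param assignment Cluster labels.
#' @param signatures Named list of gene sets (default
#'   [default_signatures()]).
#' @return List with `labels` (cluster -> population) and the full `scores`
#'   matrix (clusters x signatures).
#' @export
annotate_clusters <- function(norm, assignment, signatures = default_signatures()) {
  if (!length(signatures)) stop("empty signature table")
  labels <- as.integer(assignment)
  clusters <- sort(unique(labels))
  scores <- matrix(0, nrow = length(clusters), ncol = length(signatures),
                   dimnames = list(as.character(clusters), names(signatures)))
  for (ci in seq_along(clusters)) {
    inside <- labels == clusters[ci]
    for (si in seq_along(signatures)) {
      genes <- signatures[[si]]
      fc <- vapply(genes, function(g) {
        if (!g %in% norm$gene_symbols) return(0)
        .lnfc(norm$values[g, inside], norm$values[g, !inside])
      }, numeric(1))
      scores[ci, si] <- mean(fc)
    }
  }
  lab <- apply(scores, 1, function(s) {
    top <- max(s)
    if (top <= 0 || sum(s == top) > 1) "unassigned" else names(s)[which.max(s)]
  })
  list(labels = lab, scores = scores)
}
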