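#' QC thresholds for cell and gene filtering
#'
#' Defaults follow the standard droplet scRNA-seq recipe used throughout
#' the pipeline: cells with fewer than 200 or more than 7000 detected genes
#' or more than 5% mitochondrial UMIs are removed (strict inequalities),
#' then genes detected in fewer than 3 remaining cells are removed.
#'
#' @param min_genes,max_genes Detected-gene bounds.
#' @param max_mito_fraction Mitochondrial UMI fraction cutoff.
#' @param min_cells_per_gene Minimum cells a gene must be detected in.
#' @return A `qc_thresholds` object.
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 7000,
                          max_mito_fraction = 0.05, min_cells_per_gene = 3) {
  stopifnot(min_genes < max_genes,
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene = min_cells_per_gene),
            class = "qc_thresholds")
}

#' Call cell-containing barcodes from total UMI counts
#'
#' Empty-droplet removal: the retention threshold is 10% of the 99th
#' percentile of the total UMI counts of the top `expected_cells` barcodes;
#' barcodes at or above the threshold are retained. When fewer barcodes
#' than `expected_cells` exist, all barcodes enter the percentile.
#'
#' @param umi_per_barcode Named (or unnamed) numeric vector of total UMIs.
#' @param expected_cells Expected number of captured cells (`>= 1`).
#' @return Integer indices of retained barcodes.
#' @export
call_cell_barcodes <- function(umi_per_barcode, expected_cells) {
  stopifnot(expected_cells >= 1, length(umi_per_barcode) >= 1)
  top <- sort(umi_per_barcode, decreasing = TRUE)
  top <- top[seq_len(min(expected_cells, length(top)))]
  threshold <- 0.10 * stats::quantile(top, 0.99, names = FALSE)
  which(umi_per_barcode >= threshold)
}

#' Apply cell then gene quality-control filters
#'
#' Cells are removed iff detected genes < `min_genes`, detected genes >
#' `max_genes`, or mito fraction > `max_mito_fraction` (all strict); genes
#' detected in fewer than `min_cells_per_gene` of the remaining cells are
#' then removed. The order (cells first, then genes) matters and is
#' recorded, with per-step removal counts, in the `qc_provenance`
#' attribute.
#'
#' @param cm A `count_matrix` with `MT-` prefixed mitochondrial genes.
#' @param thresholds A [qc_thresholds()].
#' @return The filtered `count_matrix`.
#' @export
apply_cell_qc <- function(cm, thresholds = qc_thresholds()) {
  stopifnot(inherits(cm, "count_matrix"), inherits(thresholds, "qc_thresholds"))
  meta <- cm$cell_meta
  keep_cells <- meta$detected_genes >= thresholds$min_genes &
    meta$detected_genes <= thresholds$max_genes &
    meta$mito_fraction <= thresholds$max_mito_fraction
  n_removed_cells <- sum(!keep_cells)
  if (!any(keep_cells)) stop("all cells removed by QC")
  sub <- cm$counts[, keep_cells, drop = FALSE]
  cells_per_gene <- Matrix::rowSums(sub > 0)
  keep_genes <- cells_per_gene >= thresholds$min_cells_per_gene
  n_removed_genes <- sum(!keep_genes)
  out <- subset_count_matrix(cm, genes = keep_genes, cells = keep_cells)
  attr(out, "qc_provenance") <- list(
    thresholds = unclass(thresholds),
    cells_removed = n_removed_cells, genes_removed = n_removed_genes,
    cells_kept = sum(keep_cells), genes_kept = sum(keep_genes),
    order = c("cells", "genes"))
  out
}

#' Depth-normalize and natural-log transform
#'
#' `value = ln(1 + count / cell total x 10000)`, i.e., sequencing depth is
#' scaled to 10,000 molecules per cell before the log. For every cell with
#' nonzero depth, `sum(exp(value) - 1) == 10000` exactly (up to floating
#' point); zero-depth cells stay all-zero with a warning.
#'
#' @param cm A `count_matrix`.
#' @param scale_factor Depth target (default 10000).
#' @return A `normalized_matrix`: dense genes x cells natural-log values
#'   plus gene/barcode identities and a filter provenance record.
#' @export
log_normalize <- function(cm, scale_factor = 10000) {
  stopifnot(inherits(cm, "count_matrix"))
  tot <- Matrix::colSums(cm$counts)
  if (any(tot == 0)) warning(sum(tot == 0), " zero-depth cells left all-zero")
  denom <- ifelse(tot == 0, 1, tot)
  vals <- as.matrix(cm$counts %*% Matrix::Diagonal(x = 1 / denom)) * scale_factor
  vals <- log1p(vals)
  dimnames(vals) <- list(cm$gene_symbols, cm$barcodes)
  structure(list(values = vals, gene_symbols = cm$gene_symbols,
                 barcodes = cm$barcodes, scale_factor = scale_factor,
                 provenance = attr(cm, "qc_provenance")),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d cells (ln scale, depth %g)\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' Select highly variable genes by binned dispersion
#'
#' Per gene, the mean and dispersion (variance/mean) of the back-transformed
#' expression `exp(value) - 1` are computed; dispersions are z-scored within
#' equal-frequency bins of the mean, and the top `n_hvg` genes by z-score are
#' returned. Zero-variance genes are never selected before exhaustion; ties
#' break by gene symbol.
#'
#' @param norm A `normalized_matrix`.
#' @param n_hvg Number of genes to return (default 2000).
#' @param n_bins Number of equal-frequency mean bins (default 20).
#' @return Character vector of gene symbols, ordered by decreasing z-score.
#' @export
select_hvg <- function(norm, n_hvg = 2000, n_bins = 20) {
  stopifnot(inherits(norm, "normalized_matrix"))
  x <- expm1(norm$values)
  m <- rowMeans(x)
  v <- apply(x, 1, stats::var)
  d <- ifelse(m > 0, v / m, 0)
  if (sum(m > 0) < n_bins) stop("fewer genes with nonzero mean than bins")
  br <- unique(stats::quantile(m, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(m, breaks = br, include.lowest = TRUE)
  z <- stats::ave(d, bin, FUN = function(u) {
    s <- stats::sd(u)
    if (is.na(s) || s == 0) rep(0, length(u)) else (u - mean(u)) / s
  })
  z[v == 0] <- -Inf
  if (n_hvg > length(z)) {
    warning("n_hvg exceeds gene count; returning all genes")
    n_hvg <- length(z)
  }
  ord <- order(-z, norm$gene_symbols)
  norm$gene_symbols[ord][seq_len(n_hvg)]
}

#' Cell-cycle gene sets
#'
#' The standard S-phase (43 genes) and G2/M-phase (54 genes) marker sets
#' used for expression-based cell-cycle scoring.
#'
#' @return List with character vectors `s` and `g2m`.
#' @export
cc_gene_sets <- function() {
  list(
    s = c("MCM5", "PCNA", "TYMS", "FEN1", "MCM2", "MCM4", "RRM1", "UNG",
          "GINS2", "MCM6", "CDCA7", "DTL", "PRIM1", "UHRF1", "MLF1IP",
          "HELLS", "RFC2", "RPA2", "NASP", "RAD51AP1", "GMNN", "WDR76",
          "SLBP", "CCNE2", "UBR7", "POLD3", "MSH2", "ATAD2", "RAD51",
          "RRM2", "CDC45", "CDC6", "EXOSC8", "TIPIN", "DSCC1", "BLM",
          "CASP8AP2", "USP1", "CLSPN", "POLA1", "CHAF1B", "BRIP1", "E2F8"),
    g2m = c("HMGB2", "CDK1", "NUSAP1", "UBE2C", "BIRC5", "TPX2", "TOP2A",
            "NDC80", "CKS2", "NUF2", "CKS1B", "MKI67", "TMPO", "CENPF",
            "TACC3", "FAM64A", "SMC4", "CCNB2", "CKAP2L", "CKAP2", "AURKB",
            "BUB1", "KIF11", "ANP32E", "TUBB4B", "GTSE1", "KIF20B", "HJURP",
            "CDCA3", "HN1", "CDC20", "TTK", "CDC25C", "KIF2C", "RANGAP1",
            "NCAPD2", "DLGAP5", "CDCA2", "CDCA8", "ECT2", "KIF23", "HMMR",
            "AURKA", "PSRC1", "ANLN", "LBR", "CKAP5", "CENPE", "CTCF",
            "NEK2", "G2E3", "GAS2L3", "CBX5", "CENPA")
  )
}

#' Score cell-cycle phase per cell
#'
#' For each set gene, `n_ctrl` control genes are sampled from the gene's
#' average-expression bin (equal-frequency bins over all genes); the score
#' is the mean expression of the set genes minus the mean of the pooled
#' controls, per cell. Phase is the arg-max of the S and G2/M scores, G1
#' when both are `<= 0`.
#'
#' @param norm A `normalized_matrix`.
#' @param s_genes,g2m_genes Gene sets (defaults from [cc_gene_sets()]).
#' @param n_bins Expression bins for control matching (default 25).
#' @param n_ctrl Controls sampled per set gene (default 50).
#' @param seed Integer seed for control sampling.
#' @return data.frame with `barcode`, `s_score`, `g2m_score`, `phase`.
#' @export
score_cell_cycle <- function(norm, s_genes = cc_gene_sets()$s,
                             g2m_genes = cc_gene_sets()$g2m,
                             n_bins = 25, n_ctrl = 50, seed = 1L) {
  stopifnot(inherits(norm, "normalized_matrix"))
  for (set in list(s = s_genes, g2m = g2m_genes)) {
    if (!length(intersect(set, norm$gene_symbols)))
      stop("no cell-cycle set genes found in matrix; missing: ",
           paste(utils::head(set, 5), collapse = ", "), " ...")
  }
  set.seed(derive_seed(seed, "cellcycle"))
  avg <- rowMeans(norm$values)
  br <- unique(stats::quantile(avg, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(br) < 2) rep(1L, length(avg)) else
    as.integer(cut(avg, breaks = br, include.lowest = TRUE))
  names(bin) <- norm$gene_symbols
  score_set <- function(set, label) {
    present <- intersect(set, norm$gene_symbols)
    ctrl <- unlist(lapply(present, function(g) {
      pool <- which(bin == bin[g])
      norm$gene_symbols[sample(pool, min(n_ctrl, length(pool)))]
    }))
    colMeans(norm$values[present, , drop = FALSE]) -
      colMeans(norm$values[ctrl, , drop = FALSE])
  }
  s <- score_set(s_genes, "S-phase")
  g2m <- score_set(g2m_genes, "G2/M-phase")
  phase <- ifelse(s <= 0 & g2m <= 0, "G1", ifelse(g2m > s, "G2M", "S"))
  data.frame(barcode = norm$barcodes, s_score = s, g2m_score = g2m,
             phase = phase, stringsAsFactors = FALSE, row.names = NULL)
}

#' Regress out per-cell covariates from expression
#'
#' Per gene, ordinary least squares of expression on the covariates plus an
#' intercept; the output is residual plus gene mean. Collinear covariate
#' columns are dropped with a warning.
#'
#' @param norm A `normalized_matrix`.
#' @param covariates Per-cell numeric data.frame/matrix (rows align with
#'   cells).
#' @return A `normalized_matrix` of the same shape.
#' @export
regress_out <- function(norm, covariates) {
  stopifnot(inherits(norm, "normalized_matrix"))
  X <- as.matrix(covariates)
  if (nrow(X) != ncol(norm$values)) stop("covariate rows must align with cells")
  X <- cbind(`(Intercept)` = 1, X)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    drop <- colnames(X)[setdiff(seq_len(ncol(X)), q$pivot[seq_len(q$rank)])]
    warning("dropping collinear covariate(s): ", paste(drop, collapse = ", "))
    X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
    q <- qr(X)
  }
  # residuals for all genes at once: Y' - X beta
  Yt <- t(norm$values)
  beta <- qr.coef(q, Yt)
  res <- Yt - X %*% beta
  out <- t(res) + rowMeans(norm$values)
  dimnames(out) <- dimnames(norm$values)
  norm$values <- out
  norm
}

#' Estimate the droplet multiplet rate from a barnyard mixture
#'
#' A barcode is called cross-species when its majority-species UMI fraction
#' falls below `purity_threshold`. In a 1:1 two-species mixture only half
#' of true multiplets are cross-species, so the inferred total rate is
#' twice the observed cross-species rate.
#'
#' @param cm A `count_matrix` whose gene symbols carry species prefixes.
#' @param purity_threshold Majority-fraction cutoff (default 0.9).
#' @param species_prefixes Length-2 character; default auto-detects the
#'   prefix before the first `_`.
#' @return List with `cross_species_rate`, `inferred_total_rate`, and the
#'   per-barcode purity table.
#' @export
estimate_multiplet_rate <- function(cm, purity_threshold = 0.9,
                                    species_prefixes = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(species_prefixes)) {
    species_prefixes <- sort(unique(sub("_.*$", "", cm$gene_symbols)))
  }
  if (length(species_prefixes) != 2)
    stop("need exactly two species; found prefixes: ",
         paste(species_prefixes, collapse = ", "))
  a <- startsWith(cm$gene_symbols, species_prefixes[1])
  ta <- Matrix::colSums(cm$counts[a, , drop = FALSE])
  tb <- Matrix::colSums(cm$counts[!a, , drop = FALSE])
  tot <- ta + tb
  purity <- ifelse(tot > 0, pmax(ta, tb) / tot, 1)
  cross <- purity < purity_threshold
  rate <- mean(cross)
  list(cross_species_rate = rate, inferred_total_rate = 2 * rate,
       purity = data.frame(barcode = cm$barcodes, purity = purity,
                           is_cross = cross, stringsAsFactors = FALSE))
}
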