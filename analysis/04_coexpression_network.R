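#!/usr/bin/env Rscript
# Weighted co-expression network over the most variable genes: soft
# threshold diagnostics, signed adjacency at power 8, unsigned topological
# overlap, and module detection with eigengene merging at cut 0.25.

library(chondronet)

qc <- read_counts_10x("results/qc_counts")
norm <- log_normalize(qc)
# HVGs are ranked on the plain normalized matrix (dispersion statistics are
# defined on back-transformed expression); the network itself uses the
# mito-regressed values of those genes
net_genes <- head(select_hvg(norm, n_hvg = nrow(norm$values)), 500)
norm <- regress_out(norm, qc$cell_meta[, "mito_fraction", drop = FALSE])
norm$values <- norm$values[net_genes, ]
norm$gene_symbols <- net_genes

sft <- suppressWarnings(pick_soft_threshold(norm, network_config()))
write.table(sft$table, "results/soft_threshold.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("scale-free fit selects power %d (configured default 8)\n",
            sft$beta))

net <- build_network(norm, network_config(beta = 8))
sizes <- vapply(net$modules$modules, length, integer(1))
cat(sprintf("%d modules detected (sizes: %s)\n", length(sizes),
            paste(sizes, collapse = ", ")))

truth <- read.delim("results/truth_genes.tsv")
for (i in seq_along(net$modules$modules)) {
  hit <- truth$module[match(net$modules$modules[[i]], truth$gene)]
  planted <- names(which.max(table(hit)))
  if (!is.null(planted))
    cat(sprintf("  detected module %d: %d/%d genes from planted %s\n",
                i, max(table(hit)), sizes[i], planted))
}

write.table(data.frame(gene = names(net$modules$labels),
                       module = as.integer(net$modules$labels)),
            "results/modules.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
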