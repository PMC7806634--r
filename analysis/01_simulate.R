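#!/usr/bin/env Rscript
# Simulate the day-14 pellet dataset used throughout the analysis: four
# populations (chondrocyte 55%, neural 20%, mesenchyme 15%, melanocyte 10%),
# population-restricted WNT ligands and FZD/ROR receptors at calibrated
# expressing fractions, two planted 50-gene co-expression modules anchored
# on hub TFs, 2% baseline / 15% low-quality mitochondrial content.

library(chondronet)
seed <- 1L
dir.create("results", showWarnings = FALSE)

spec <- default_simulation_spec(n_cells = 1500, n_genes = 1500, seed = seed)
sim <- simulate_counts(spec)

write_counts_10x(sim$matrix, "results/raw_counts")
write.table(sim$truth$cells, "results/truth_cells.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth$genes, "results/truth_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d genes x %d cells (median %.0f UMIs/cell)\n",
            nrow(sim$matrix$counts), ncol(sim$matrix$counts),
            median(sim$matrix$cell_meta$total_umis)))
print(table(sim$truth$cells$population))
cat(sprintf("low-quality cells planted above the mito cutoff: %d\n",
            sum(sim$truth$cells$is_low_quality)))
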