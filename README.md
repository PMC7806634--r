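# chondronet

Single-cell analysis of off-target lineages and heterocellular WNT
signaling in hiPSC chondrogenesis.

Directed differentiation of human iPSCs toward cartilage yields pellets
that contain, beside chondrocytes, off-target neural cells, melanocytes
and residual mesenchyme. Because WNTs are secreted, these off-target
populations can signal to chondrocytes through FZD receptors and alter
chondrogenesis. `chondronet` implements the full computational chain for
making that inference from droplet scRNA-seq UMI matrices, plus a
ground-truthed simulator so every stage is testable offline:

* **QC / normalization** — barcode calling (10% of the 99th-percentile UMI
  rule), cell filters (detected genes in (200, 7000), mito fraction <= 5%,
  strict bounds), gene filter (>= 3 cells), depth normalization to 10,000
  molecules per cell on the natural-log scale, binned-dispersion HVG
  selection, expression-matched cell-cycle scoring (43 S / 54 G2M genes),
  per-gene covariate regression.
* **Clustering / markers** — PCA on z-scored HVGs, shared-nearest-neighbor
  Jaccard graph (k = 30, prune 1/15), Louvain modularity at resolution
  0.6; one-vs-rest Wilcoxon markers reported iff `pct_in >= 0.25` and
  `lnFC > 0.25` with `lnFC = ln(mean(e^x - 1) + 1)_in - ln(...)_out`;
  signature-based cluster annotation.
* **Co-expression network** — signed adjacency `((1 + r)/2)^beta`
  (beta = 8), soft-threshold selection by signed scale-free fit, unsigned
  topological overlap
  `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,
  average-linkage module detection with eigengene merging at correlation
  0.75.
* **GRN / hub genes** — top-100 adjacency neighborhoods around each module
  TF, weighted Louvain communities, and hub ranking by the mean dense rank
  of strength (summed weights), degree, and betweenness centrality.
* **Ligand-receptor model** — directed (sender population, ligand) ->
  (receiver population, receptor) records for every curated pair whose
  ligand and receptor independently pass the `lnFC > 0.25` specificity
  filter, with raw detection percentages attached.
* **Simulator** — negative-binomial UMI counts with planted populations,
  population-restricted WNT/FZD circuitry at calibrated expressing
  fractions, hub-anchored co-expression modules, low-quality cells,
  injectable doublets, and two-species barnyard mixtures (the basis of the
  2x cross-species multiplet estimator).

## Worked example

The `analysis/` directory is a numbered narrative over the package (each
script writes its tables under `results/`). Running them in order on the
default day-14 pellet simulation (1,500 cells, 1,500 genes, seed 1)
prints:

```
$ Rscript analysis/01_simulate.R
simulated 1500 genes x 1500 cells (median 1700 UMIs/cell)
chondrocyte  melanocyte  mesenchyme      neural
        812         152         242         294
low-quality cells planted above the mito cutoff: 71

$ Rscript analysis/02_qc_normalize.R
QC removed 71 cells and 0 genes; 1429 cells x 1500 genes remain
depth identity: max relative error 1.82e-16

$ Rscript analysis/03_cluster_annotate.R
4 clusters at resolution 0.6
ARI vs simulated populations: 0.990
145 marker records pass both thresholds
            0             1             2             3
"chondrocyte"      "neural"  "mesenchyme"  "melanocyte"
per-cell annotation accuracy: 0.997

$ Rscript analysis/04_coexpression_network.R
scale-free fit selects power 9 (configured default 8)
5 modules detected (sizes: 46, 44, 37, 35, 33)
  detected module 1: 46/46 genes from planted M1
  detected module 2: 44/44 genes from planted M2

$ Rscript analysis/05_grn_hubs.R
module1: planted hub TF M1.HUB holds combined rank 1.0 (top hit: M1.HUB)
module2: planted hub TF M2.HUB holds combined rank 1.0 (top hit: M2.HUB)

$ Rscript analysis/06_lr_signaling.R
3 directed interactions pass the specificity filter:
  WNT2B (melanocyte, 25.9% expressing) -> FZD4 (chondrocyte, 10.9%)
  WNT3A (neural, 9.1% expressing) -> FZD2 (chondrocyte, 28.4%)
  WNT5B (chondrocyte, 8.5% expressing) -> ROR2 (melanocyte, 29.4%)

$ Rscript analysis/07_barnyard.R
injected  0.0% -> inferred 0.00%
injected  1.0% -> inferred 1.04%
injected  3.0% -> inferred 2.60%
injected  5.0% -> inferred 5.32%
```

Reading the output: QC removed exactly the 71 planted low-quality
(high-mito) cells; clustering recovered the four populations nearly
perfectly and annotation named them from marker signatures; the network
stage found both planted 50-gene modules (plus three population-program
modules) and ranked each module's planted hub TF first by the combined
strength/degree/betweenness score; the ligand-receptor model returned
exactly the three planted directed circuits — including the
10%-sender / 30%-receiver WNT3A -> FZD2 geometry — with detection
percentages at their calibrated targets; and the barnyard estimator
recovered injected doublet rates within fractions of a percentage point.

The same run is available as one call:

```r
library(chondronet)
manifest <- run_pipeline(list(seed = 1, out_dir = "results/pipeline"))
```

See `vignettes/chondronet-methods.Rmd` for the models, parameter
rationale, and what the simulator does and does not emulate.

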