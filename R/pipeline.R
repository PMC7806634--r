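#' Default pipeline configuration
#'
#' Nested list mirroring the stage parameters, with the pipeline's
#' standard thresholds as defaults. Unknown keys in a user config are
#' rejected by [run_pipeline()].
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = tempfile("chondronet_run_"),
    simulate = list(enabled = TRUE, n_cells = 1500, n_genes = 1500,
                    marker_fold = 8, module_loading = 1.0,
                    doublet_rate = 0),
    input = list(path = NULL),
    qc = list(min_genes = 200, max_genes = 7000, max_mito_fraction = 0.05,
              min_cells_per_gene = 3),
    normalize = list(scale_factor = 10000),
    regress = list(enabled = TRUE, covariates = "mito_fraction"),
    cellcycle = list(enabled = FALSE, n_bins = 25, n_ctrl = 50),
    hvg = list(n_hvg = 1000, n_bins = 20),
    cluster = list(n_pcs = 20, k_neighbors = 30, resolution = 0.6),
    markers = list(min_pct = 0.25, lnfc_min = 0.25),
    network = list(enabled = TRUE, beta = 8, merge_cut_height = 0.25,
                   min_module_size = 30, n_genes = 500),
    grn = list(enabled = TRUE, n_top = 100, edge_floor = 0.02, top_k = 5,
               tf_list = NULL),
    lr = list(enabled = TRUE, lnfc_min = 0.25, min_pct = 0, pairs = NULL)
  )
}

.merge_config <- function(user, default, path = "") {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(default)) stop("unknown config key: ", full)
    if (is.list(default[[k]]) && !is.data.frame(user[[k]])) {
      default[[k]] <- .merge_config(as.list(user[[k]]), default[[k]], full)
    } else {
      default[[k]] <- user[[k]]
    }
  }
  default
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> barcode/cell/gene QC -> depth
#' normalization -> covariate regression -> HVG selection -> PCA/SNN
#' clustering -> marker detection and annotation -> co-expression network
#' and modules -> TF-anchored hub scoring -> ligand-receptor interaction
#' table, writing every stage's tables under `out_dir` and returning a
#' manifest of output hashes, parameters and surviving counts.
#'
#' Marker detection and the ligand-receptor model run on the plain
#' log-normalized matrix; the embedding and the network use the
#' covariate-regressed matrix when regression is enabled.
#'
#' @param config Nested list (see [default_config()]) or path to a YAML
#'   file; partial configs are merged over the defaults, unknown keys are
#'   rejected.
#' @return A `run_manifest` list: `config`, per-stage `counts`, `outputs`
#'   (file -> md5), and in-memory `results`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(config, default_config())
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  counts_log <- list()
  results <- list()

  # --- acquire counts -------------------------------------------------
  if (isTRUE(cfg$simulate$enabled)) {
    spec <- default_simulation_spec(
      n_cells = cfg$simulate$n_cells, n_genes = cfg$simulate$n_genes,
      seed = cfg$seed, marker_fold = cfg$simulate$marker_fold,
      module_loading = cfg$simulate$module_loading)
    sim <- simulate_counts(spec)
    cm <- sim$matrix
    truth <- sim$truth
    if (cfg$simulate$doublet_rate > 0) {
      dd <- inject_doublets(cm, cfg$simulate$doublet_rate, seed = cfg$seed)
      cm <- dd$matrix
      truth$doublets <- dd$truth
    }
    raw_dir <- file.path(cfg$out_dir, "raw")
    write_counts_10x(cm, raw_dir)
    outputs <- c(outputs, file.path(raw_dir,
                                    c("matrix.mtx", "genes.tsv", "barcodes.tsv")))
    outputs <- c(outputs, .write_tsv(truth$cells,
                                     file.path(cfg$out_dir, "truth_cells.tsv")))
    outputs <- c(outputs, .write_tsv(truth$genes,
                                     file.path(cfg$out_dir, "truth_genes.tsv")))
    results$truth <- truth
  } else {
    if (is.null(cfg$input$path)) stop("simulation disabled and no input path")
    cm <- read_counts_10x(cfg$input$path)
    truth <- NULL
  }
  counts_log$raw <- dim(cm)

  # --- QC -------------------------------------------------------------
  thr <- qc_thresholds(cfg$qc$min_genes, cfg$qc$max_genes,
                       cfg$qc$max_mito_fraction, cfg$qc$min_cells_per_gene)
  cm_qc <- apply_cell_qc(cm, thr)
  counts_log$qc <- dim(cm_qc)
  outputs <- c(outputs, .write_tsv(cm_qc$cell_meta,
                                   file.path(cfg$out_dir, "cell_meta_qc.tsv")))
  results$qc <- cm_qc

  # --- normalize ------------------------------------------------------
  norm <- log_normalize(cm_qc, cfg$normalize$scale_factor)
  results$norm <- norm

  norm_emb <- norm
  if (isTRUE(cfg$regress$enabled)) {
    covs <- cm_qc$cell_meta[, cfg$regress$covariates, drop = FALSE]
    if (isTRUE(cfg$cellcycle$enabled)) {
      cc <- score_cell_cycle(norm, n_bins = cfg$cellcycle$n_bins,
                             n_ctrl = cfg$cellcycle$n_ctrl, seed = cfg$seed)
      covs <- cbind(covs, s_score = cc$s_score, g2m_score = cc$g2m_score)
      outputs <- c(outputs, .write_tsv(cc, file.path(cfg$out_dir,
                                                     "cell_cycle.tsv")))
      results$cellcycle <- cc
    }
    norm_emb <- regress_out(norm, covs)
  }

  # --- HVG, embedding, clustering ------------------------------------
  hvgs <- select_hvg(norm, n_hvg = min(cfg$hvg$n_hvg, nrow(norm$values)),
                     n_bins = cfg$hvg$n_bins)
  emb <- embed_cells(norm_emb, hvgs, n_pcs = cfg$cluster$n_pcs)
  assign <- cluster_cells(emb, k_neighbors = cfg$cluster$k_neighbors,
                          resolution = cfg$cluster$resolution,
                          seed = cfg$seed)
  counts_log$clusters <- length(unique(assign))
  outputs <- c(outputs, .write_tsv(
    data.frame(barcode = names(assign), cluster = as.integer(assign)),
    file.path(cfg$out_dir, "clusters.tsv")))
  results$hvgs <- hvgs
  results$embedding <- emb
  results$assignment <- assign

  # --- markers and annotation ----------------------------------------
  markers <- find_markers(norm, assign, min_pct = cfg$markers$min_pct,
                          lnfc_min = cfg$markers$lnfc_min)
  outputs <- c(outputs, .write_tsv(markers,
                                   file.path(cfg$out_dir, "markers.tsv")))
  ann <- annotate_clusters(norm, assign)
  cell_pop <- ann$labels[as.character(as.integer(assign))]
  outputs <- c(outputs, .write_tsv(
    data.frame(cluster = rownames(ann$scores), label = ann$labels),
    file.path(cfg$out_dir, "annotation.tsv")))
  results$markers <- markers
  results$annotation <- ann
  results$cell_populations <- stats::setNames(cell_pop, names(assign))

  # --- co-expression network -----------------------------------------
  if (isTRUE(cfg$network$enabled)) {
    net_genes <- utils::head(select_hvg(norm, n_hvg = nrow(norm$values),
                                        n_bins = cfg$hvg$n_bins),
                             cfg$network$n_genes)
    norm_net <- norm_emb
    keep <- norm_net$gene_symbols %in% net_genes
    norm_net$values <- norm_net$values[keep, , drop = FALSE]
    norm_net$gene_symbols <- norm_net$gene_symbols[keep]
    ncfg <- network_config(beta = cfg$network$beta,
                           merge_cut_height = cfg$network$merge_cut_height,
                           min_module_size = cfg$network$min_module_size)
    net <- build_network(norm_net, ncfg)
    mod_tab <- data.frame(gene = names(net$modules$labels),
                          module = as.integer(net$modules$labels))
    outputs <- c(outputs, .write_tsv(mod_tab,
                                     file.path(cfg$out_dir, "modules.tsv")))
    results$network <- net

    # --- GRN hubs -----------------------------------------------------
    if (isTRUE(cfg$grn$enabled)) {
      tf_list <- cfg$grn$tf_list
      if (is.null(tf_list) && !is.null(truth))
        tf_list <- truth$genes$gene[truth$genes$is_tf]
      if (!is.null(tf_list)) {
        grn <- grn_hubs_by_module(net, tf_list, n_top = cfg$grn$n_top,
                                  edge_floor = cfg$grn$edge_floor,
                                  top_k = cfg$grn$top_k, seed = cfg$seed)
        hub_tab <- do.call(rbind, lapply(names(grn), function(m) {
          cbind(module = m, grn[[m]]$hubs)
        }))
        if (!is.null(hub_tab))
          outputs <- c(outputs, .write_tsv(hub_tab,
                                           file.path(cfg$out_dir, "hubs.tsv")))
        results$grn <- grn
      }
    }
  }

  # --- ligand-receptor model -----------------------------------------
  if (isTRUE(cfg$lr$enabled)) {
    pairs <- cfg$lr$pairs
    if (is.character(pairs)) pairs <- read_lr_pairs(pairs)
    if (is.null(pairs)) pairs <- demo_lr_pairs()
    lr <- build_interaction_table(cm_qc, norm, cell_pop, pairs,
                                  lnfc_min = cfg$lr$lnfc_min,
                                  min_pct = cfg$lr$min_pct)
    edges <- population_edge_summary(lr)
    outputs <- c(outputs, .write_tsv(lr,
                                     file.path(cfg$out_dir, "interactions.tsv")))
    outputs <- c(outputs, .write_tsv(edges,
                                     file.path(cfg$out_dir,
                                               "population_edges.tsv")))
    results$interactions <- lr
    results$population_edges <- edges
  }

  hashes <- tools::md5sum(outputs)
  manifest <- list(config = cfg, counts = counts_log,
                   outputs = as.list(hashes), results = results)
  class(manifest) <- "run_manifest"
  json <- list(config = cfg[setdiff(names(cfg), "out_dir")],
               counts = counts_log,
               outputs = as.list(stats::setNames(unname(hashes),
                                                 basename(names(hashes)))))
  jsonlite::write_json(json, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest:", length(x$outputs), "output files under",
      x$config$out_dir, "\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-10s %s\n", nm, paste(x$counts[[nm]], collapse = " x ")))
  invisible(x)
}

#' Construct a named toy fixture
#'
#' Deterministic tiny datasets backing worked examples and tests:
#' `qc_toy` (5-cell matrix exercising every QC rule), `tom_toy` (3-gene
#' adjacency with a hand-computable TOM), `star_graph` (5-node star,
#' weights 0.5), `lr_planted` (labeled counts with 3 planted directed
#' interactions), `barnyard_3pct` (1000-barcode species mixture with 3%
#' doublets), `modules_planted` (300 cells with two planted 50-gene
#' modules).
#'
#' @param name Fixture name.
#' @param path Optional directory; when given, tabular/matrix fixtures are
#'   also written there.
#' @return The fixture object (type depends on the fixture).
#' @export
make_fixture <- function(name, path = NULL) {
  fx <- switch(
    name,
    qc_toy = .fixture_qc_toy(),
    tom_toy = {
      a <- matrix(c(1, 0.5, 0.2, 0.5, 1, 0.4, 0.2, 0.4, 1), 3, 3,
                  dimnames = list(c("g1", "g2", "g3"), c("g1", "g2", "g3")))
      a
    },
    star_graph = {
      g <- igraph::make_star(5, mode = "undirected", center = 1)
      igraph::V(g)$name <- c("center", paste0("leaf", 1:4))
      igraph::E(g)$weight <- 0.5
      g
    },
    lr_planted = .fixture_lr_planted(),
    barnyard_3pct = {
      spec <- simulation_spec(1000, 400, list(population_spec("all", 1)),
                              seed = 7L)
      simulate_barnyard(spec, doublet_rate = 0.03)
    },
    modules_planted = {
      spec <- simulation_spec(
        300, 200, list(population_spec("all", 1)),
        modules = list(module_spec("M1", 50, c(0.8, 0.8)),
                       module_spec("M2", 50, c(0.8, 0.8))),
        seed = 11L)
      simulate_counts(spec)
    },
    stop("unknown fixture: ", name)
  )
  if (!is.null(path)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    if (inherits(fx, "count_matrix")) write_counts_10x(fx, path)
    if (is.list(fx) && inherits(fx$matrix %||% NULL, "count_matrix"))
      write_counts_10x(fx$matrix, path)
  }
  fx
}

# 5 cells with detected-gene counts {150, 200, 500, 7000, 7500}; the
# 500-gene cell carries 6% mito content. Under the default thresholds
# exactly the 200- and 7000-gene cells survive.
.fixture_qc_toy <- function() {
  n_genes <- 7600L
  symbols <- c(sprintf("G%05d", seq_len(n_genes - 13L)), .MT_SYMBOLS)
  det <- c(150L, 200L, 500L, 7000L, 7500L)
  cols <- lapply(seq_along(det), function(j) {
    x <- integer(n_genes)
    if (j == 3) {
      x[seq_len(499L)] <- 1L            # 499 non-mito genes
      x[n_genes - 12L] <- 32L           # one MT gene: 32/531 = 6% mito
    } else {
      x[seq_len(det[j])] <- 1L
    }
    x
  })
  counts <- do.call(cbind, cols)
  count_matrix(counts, gene_ids = symbols, gene_symbols = symbols,
               barcodes = sprintf("TOY-%d", 1:5))
}

# Deterministic labeled counts planting exactly three directed
# interactions: WNT3A(neural) -> FZD2(chondrocyte),
# WNT2B(melanocyte) -> FZD4(chondrocyte), WNT5B(chondrocyte) -> ROR2(melanocyte)
.fixture_lr_planted <- function() {
  pops <- rep(c("chondrocyte", "neural", "melanocyte"), times = c(60, 30, 30))
  n <- length(pops)
  genes <- c("WNT3A", "WNT2B", "WNT5B", "FZD2", "FZD4", "ROR2",
             sprintf("BG%03d", 1:20))
  counts <- matrix(0L, length(genes), n, dimnames = list(genes, NULL))
  counts[7:26, ] <- 3L                               # uniform background
  plant <- function(gene, pop, frac, level) {
    idx <- which(pops == pop)
    counts[gene, idx[seq_len(round(frac * length(idx)))]] <<- level
  }
  plant("WNT3A", "neural", 0.10, 8L)
  plant("FZD2", "chondrocyte", 0.30, 8L)
  plant("WNT2B", "melanocyte", 0.30, 8L)
  plant("FZD4", "chondrocyte", 0.10, 8L)
  plant("WNT5B", "chondrocyte", 0.10, 8L)
  plant("ROR2", "melanocyte", 0.30, 8L)
  cm <- count_matrix(counts, gene_ids = genes, gene_symbols = genes,
                     barcodes = sprintf("LR-%03d", seq_len(n)))
  list(matrix = cm, labels = pops,
       planted = data.frame(
         ligand = c("WNT3A", "WNT2B", "WNT5B"),
         receptor = c("FZD2", "FZD4", "ROR2"),
         sender = c("neural", "melanocyte", "chondrocyte"),
         receiver = c("chondrocyte", "chondrocyte", "melanocyte"),
         stringsAsFactors = FALSE))
}
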