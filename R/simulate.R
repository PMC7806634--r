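# Human mitochondrial protein-coding gene symbols (13 genes)
.MT_SYMBOLS <- c(
  "MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8", "MT-ATP6", "MT-CO3",
  "MT-ND3", "MT-ND4L", "MT-ND4", "MT-ND5", "MT-ND6", "MT-CYB"
)

#' Specify a simulated cell population
#'
#' A population carries marker genes (multiplicatively up-shifted in its
#' cells), and optionally population-restricted ligand and receptor genes
#' whose expressing-cell fraction (fraction of cells with count > 0) is a
#' calibrated ground truth.
#'
#' @param name Population label.
#' @param proportion Fraction of cells in `[0, 1]`.
#' @param marker_genes Character vector of marker gene symbols.
#' @param marker_fold Multiplicative mean shift for markers in this
#'   population (linear scale, `>= 1`).
#' @param ligand_genes,receptor_genes Named numeric vectors: names are gene
#'   symbols, values are target expressing-cell fractions in `[0, 1]`.
#' @param marker_expressing Target expressing-cell fraction for the markers
#'   within their population (default 0.6); the marker baseline mean is
#'   calibrated so the in-population detection frequency matches it. `NULL`
#'   leaves marker baselines on the generic planted-gene scale.
#' @return A `population_spec` object.
#' @export
population_spec <- function(name, proportion, marker_genes = character(),
                            marker_fold = 8,
                            ligand_genes = numeric(),
                            receptor_genes = numeric(),
                            marker_expressing = 0.6) {
  stopifnot(is.character(name), length(name) == 1L,
            proportion >= 0, proportion <= 1, marker_fold >= 1)
  if (!is.null(marker_expressing))
    stopifnot(marker_expressing > 0, marker_expressing <= 1)
  for (v in list(ligand_genes, receptor_genes)) {
    if (length(v) && (is.null(names(v)) || any(v < 0 | v > 1)))
      stop("ligand/receptor genes must be a named vector of fractions in [0,1]")
  }
  structure(list(name = name, proportion = proportion,
                 marker_genes = marker_genes, marker_fold = marker_fold,
                 ligand_genes = ligand_genes, receptor_genes = receptor_genes,
                 marker_expressing = marker_expressing),
            class = "population_spec")
}

#' Specify a planted co-expression module
#'
#' Module genes share a per-cell latent factor; gene `g` with loading `l_g`
#' has its negative-binomial mean multiplied by `exp(l_g * z_cell)`. The hub
#' gene is flagged as a transcription factor and carries the maximal loading,
#' making it the ground-truth hub of the module's regulatory subnetwork.
#'
#' @param name Module label; also used to auto-name member genes.
#' @param gene_count Number of member genes (`>= 5`), hub included.
#' @param loading_range Length-2 numeric, strictly positive: member
#'   loadings are drawn uniformly from this range; the hub gene gets
#'   `hub_loading` (at least the range maximum).
#' @param hub_gene Symbol of the hub TF; defaults to `<name>.HUB`.
#' @param genes Optional explicit member gene symbols (length `gene_count`);
#'   auto-generated when `NULL`.
#' @param shared_latent_with Optional name of a previously declared module;
#'   this module's latent factor is then correlated with that module's at
#'   `shared_latent_rho` (used to exercise eigengene-based module merging).
#' @param shared_latent_rho Correlation of shared latent factors in `[0, 1)`.
#' @param hub_loading Loading given to the hub gene; defaults to the top of
#'   `loading_range` and must be at least that, so the hub is always the
#'   module's strongest gene.
#' @param baseline_meanlog Log-mean of the members' baseline expression
#'   (lognormal, sdlog 0.3). Module genes default to moderately expressed
#'   programs (~1.5 mean counts) so the latent signal survives counting
#'   noise.
#' @return A `module_spec` object.
#' @export
module_spec <- function(name, gene_count = 50, loading_range = c(0.4, 0.8),
                        hub_gene = NULL, genes = NULL,
                        shared_latent_with = NULL, shared_latent_rho = 0.85,
                        hub_loading = NULL, baseline_meanlog = log(1.5)) {
  stopifnot(gene_count >= 5, length(loading_range) == 2L,
            all(loading_range > 0), loading_range[1] <= loading_range[2])
  if (is.null(hub_loading)) hub_loading <- loading_range[2]
  stopifnot(hub_loading >= loading_range[2])
  if (is.null(hub_gene)) hub_gene <- paste0(name, ".HUB")
  if (is.null(genes)) {
    genes <- c(hub_gene, sprintf("%s.G%03d", name, seq_len(gene_count - 1L)))
  } else {
    if (length(genes) != gene_count) stop("length(genes) != gene_count")
    if (!hub_gene %in% genes) stop("hub_gene must be a member of the module")
  }
  structure(list(name = name, gene_count = gene_count,
                 loading_range = loading_range, hub_gene = hub_gene,
                 genes = genes, shared_latent_with = shared_latent_with,
                 shared_latent_rho = shared_latent_rho,
                 hub_loading = hub_loading,
                 baseline_meanlog = baseline_meanlog),
            class = "module_spec")
}

#' Specify a full simulation
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param populations List of [population_spec()] objects; proportions must
#'   sum to 1.
#' @param modules List of [module_spec()] objects.
#' @param mito_gene_count Number of `MT-` prefixed genes (13, the human
#'   mitochondrial protein-coding count).
#' @param baseline_mito_fraction Expected mitochondrial UMI fraction for
#'   healthy cells.
#' @param low_quality_cell_fraction Fraction of cells simulated as
#'   low-quality (stressed/dying), with mito fraction
#'   `low_quality_mito_fraction` above the 5% QC cutoff.
#' @param low_quality_mito_fraction Expected mito fraction for those cells.
#' @param library_size_logmean,library_size_logsd Per-cell library scaling
#'   factor is `exp(rnorm(1, logmean, logsd))`; `logmean = -Inf` yields
#'   zero depth.
#' @param nb_dispersion Negative-binomial size parameter theta (variance
#'   `mu + mu^2 / theta`); shared across genes.
#' @param doublet_rate Fraction of cells turned into additional doublet
#'   barcodes by [inject_doublets()] when run through the pipeline.
#' @param seed Integer seed governing all randomness.
#' @return A validated `simulation_spec` object.
#' @export
simulation_spec <- function(n_cells, n_genes, populations, modules = list(),
                            mito_gene_count = 13,
                            baseline_mito_fraction = 0.02,
                            low_quality_cell_fraction = 0.05,
                            low_quality_mito_fraction = 0.15,
                            library_size_logmean = 0,
                            library_size_logsd = 0.35,
                            nb_dispersion = 2,
                            doublet_rate = 0,
                            seed = 1L) {
  stopifnot(n_cells >= 1, n_genes >= 1, nb_dispersion > 0,
            doublet_rate >= 0, doublet_rate < 0.5,
            low_quality_cell_fraction >= 0, low_quality_cell_fraction < 1)
  props <- vapply(populations, function(p) p$proportion, numeric(1))
  if (abs(sum(props) - 1) > 1e-9) stop("population proportions must sum to 1")
  markers <- unlist(lapply(populations, function(p) p$marker_genes))
  if (anyDuplicated(markers))
    stop("gene role conflict: marker gene assigned to more than one population: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  named <- unique(c(
    markers,
    unlist(lapply(populations, function(p) c(names(p$ligand_genes),
                                             names(p$receptor_genes)))),
    unlist(lapply(modules, function(m) m$genes))
  ))
  if (n_genes < length(named) + mito_gene_count)
    stop("n_genes smaller than named genes + mito genes")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 populations = populations, modules = modules,
                 mito_gene_count = as.integer(mito_gene_count),
                 baseline_mito_fraction = baseline_mito_fraction,
                 low_quality_cell_fraction = low_quality_cell_fraction,
                 low_quality_mito_fraction = low_quality_mito_fraction,
                 library_size_logmean = library_size_logmean,
                 library_size_logsd = library_size_logsd,
                 nb_dispersion = nb_dispersion,
                 doublet_rate = doublet_rate,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Default day-14 pellet simulation
#'
#' Emulates the composition of a day-14 TGF-beta-3 pellet: chondrocytes
#' (the on-target lineage), off-target neural cells and melanocytes, and
#' residual mesenchyme. WNT ligands are population-restricted (WNT3A, WNT4,
#' WNT7B neural; WNT2B melanocyte; WNT5B chondrocyte) and FZD/ROR receptors
#' are planted on the receiving populations, with the headline
#' 10%-sender/30%-receiver WNT3A-FZD2 geometry as calibrated expressing
#' fractions. Two co-expression modules are planted, each anchored on a hub
#' TF with the maximal loading.
#'
#' Each population additionally carries `program_gene_count` synthetic
#' population-restricted program genes at the same fold, emulating the
#' broad transcriptional differences that separate real lineages beyond
#' their canonical markers.
#'
#' @param n_cells,n_genes Dimensions (defaults 1500 x 1500).
#' @param seed Integer seed.
#' @param marker_fold Marker mean shift (default 8).
#' @param module_loading Loading given to all planted module genes.
#' @param program_gene_count Extra population-program genes per population.
#' @return A `simulation_spec`.
#' @export
default_simulation_spec <- function(n_cells = 1500, n_genes = 1500, seed = 1L,
                                    marker_fold = 8, module_loading = 1.0,
                                    program_gene_count = 30) {
  prg <- function(tag) sprintf("%s.P%02d", tag, seq_len(program_gene_count))
  pops <- list(
    population_spec("chondrocyte", 0.55,
                    marker_genes = c("SOX9", "COL2A1", "ACAN", "COMP",
                                     prg("CHON")),
                    marker_fold = marker_fold,
                    ligand_genes = c(WNT5B = 0.10),
                    receptor_genes = c(FZD2 = 0.30, FZD4 = 0.10)),
    population_spec("neural", 0.20,
                    marker_genes = c("SOX2", "PAX6", "OTX1", "OTX2", "NES",
                                     prg("NEUR")),
                    marker_fold = marker_fold,
                    ligand_genes = c(WNT3A = 0.10, WNT4 = 0.30, WNT7B = 0.20)),
    population_spec("melanocyte", 0.10,
                    marker_genes = c("MITF", "PMEL", prg("MELA")),
                    marker_fold = marker_fold,
                    ligand_genes = c(WNT2B = 0.30),
                    receptor_genes = c(ROR2 = 0.30)),
    population_spec("mesenchyme", 0.15,
                    marker_genes = c("PRRX1", "COL1A1", "COL3A1",
                                     prg("MESE")),
                    marker_fold = marker_fold)
  )
  # members span 70-90% of the nominal loading while the hub TF holds the
  # full loading: the hub is the ground-truth strongest node with a clear
  # margin, and every member stays above the counting-noise floor so the
  # module remains detectable from NB counts
  mods <- list(
    module_spec("M1", gene_count = 50,
                loading_range = c(0.7, 0.9) * module_loading,
                hub_loading = 1.25 * module_loading, hub_gene = "M1.HUB",
                baseline_meanlog = log(2.5)),
    module_spec("M2", gene_count = 50,
                loading_range = c(0.7, 0.9) * module_loading,
                hub_loading = 1.25 * module_loading, hub_gene = "M2.HUB",
                baseline_meanlog = log(2.5))
  )
  simulation_spec(n_cells, n_genes, pops, mods, seed = seed)
}

# NB zero probability at mean mu, size theta
.nb_p0 <- function(mu, theta) (theta / (theta + mu))^theta

# Solve the base mean so the population-average P(count > 0) under the
# cell-specific library factors matches the target fraction.
.calibrate_mean <- function(target, lib_factors, theta) {
  if (target <= 0 || all(lib_factors == 0)) return(0)
  f <- function(log_mu) {
    mean(1 - .nb_p0(exp(log_mu) * lib_factors, theta)) - target
  }
  if (f(log(1e-8)) > 0) return(1e-8)
  if (f(log(1e6)) < 0) return(1e6)
  exp(stats::uniroot(f, c(log(1e-8), log(1e6)), tol = 1e-10)$root)
}

#' Simulate a ground-truthed UMI count matrix
#'
#' Counts are negative binomial (gamma-Poisson) per gene and cell with mean
#' `baseline_g x marker shift x exp(loading_g x z_module,cell) x library
#' factor_cell` and shared dispersion, so dropout arises from the count
#' model itself. Ligand/receptor gene means are calibrated numerically so
#' the expected expressing-cell fraction in the target population matches
#' the configured target; those genes are silent elsewhere. Mitochondrial (`MT-`) genes
#' are scaled to the target mito UMI fraction, elevated in the planted
#' low-quality cells.
#'
#' @param spec A [simulation_spec()].
#' @return A list with `matrix` (a `count_matrix`) and `truth` (cell table,
#'   gene table, expressing-fraction targets, per-cell module latent
#'   factors).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(derive_seed(spec$seed, "simulate"))
  n <- spec$n_cells
  pops <- spec$populations
  pop_names <- vapply(pops, `[[`, "", "name")

  pop_of <- sample(pop_names, n, replace = TRUE,
                   prob = vapply(pops, `[[`, 0, "proportion"))
  lib <- exp(stats::rnorm(n, spec$library_size_logmean, spec$library_size_logsd))
  lib[!is.finite(lib)] <- 0
  low_q <- stats::runif(n) < spec$low_quality_cell_fraction

  # gene universe: markers, ligand/receptor, module genes, mito, filler
  marker_tab <- do.call(rbind, lapply(pops, function(p) {
    if (!length(p$marker_genes)) return(NULL)
    data.frame(gene = p$marker_genes, population = p$name,
               fold = p$marker_fold)
  }))
  lr_tab <- do.call(rbind, lapply(pops, function(p) {
    rbind(
      if (length(p$ligand_genes))
        data.frame(gene = names(p$ligand_genes), population = p$name,
                   role = "ligand", target = unname(p$ligand_genes)),
      if (length(p$receptor_genes))
        data.frame(gene = names(p$receptor_genes), population = p$name,
                   role = "receptor", target = unname(p$receptor_genes))
    )
  }))
  module_genes <- unlist(lapply(spec$modules, `[[`, "genes"))
  mito <- if (spec$mito_gene_count <= 13) .MT_SYMBOLS[seq_len(spec$mito_gene_count)]
          else c(.MT_SYMBOLS, sprintf("MT-G%02d", seq_len(spec$mito_gene_count - 13L)))
  named <- unique(c(marker_tab$gene, lr_tab$gene, module_genes))
  n_fill <- spec$n_genes - length(named) - length(mito)
  fillers <- sprintf("GENE%05d", seq_len(n_fill))
  symbols <- c(named, mito, fillers)
  G <- length(symbols)

  # baselines: filler genes span a wide lognormal; planted genes get a
  # detectable floor so marker folds and module loadings are identifiable
  base <- stats::rlnorm(G, meanlog = log(0.6), sdlog = 1.0)
  names(base) <- symbols
  planted <- unique(c(marker_tab$gene, module_genes))
  base[planted] <- stats::rlnorm(length(planted), meanlog = log(0.8), sdlog = 0.3)
  for (m in spec$modules)
    base[m$genes] <- stats::rlnorm(m$gene_count,
                                   meanlog = m$baseline_meanlog, sdlog = 0.3)
  base[lr_tab$gene] <- 0   # calibrated separately, silent outside target pop
  base[mito] <- 0          # scaled to mito fraction below

  # calibrate marker baselines to the target in-population expressing
  # fraction: in-pop mean = fold x baseline matches the detection target
  for (p in pops) {
    if (is.null(p$marker_expressing) || !length(p$marker_genes)) next
    idx <- pop_of == p$name
    m_star <- .calibrate_mean(p$marker_expressing, lib[idx], spec$nb_dispersion)
    base[p$marker_genes] <- m_star / p$marker_fold
  }

  mu <- matrix(base, nrow = G, ncol = n)
  rownames(mu) <- symbols

  # marker fold shifts
  if (!is.null(marker_tab)) {
    for (i in seq_len(nrow(marker_tab))) {
      idx <- pop_of == marker_tab$population[i]
      mu[marker_tab$gene[i], idx] <- mu[marker_tab$gene[i], idx] * marker_tab$fold[i]
    }
  }

  # module latent factors
  latent <- matrix(0, nrow = n, ncol = length(spec$modules))
  if (length(spec$modules)) {
    colnames(latent) <- vapply(spec$modules, `[[`, "", "name")
    gene_loading <- numeric(0)
    for (j in seq_along(spec$modules)) {
      m <- spec$modules[[j]]
      z <- stats::rnorm(n)
      if (!is.null(m$shared_latent_with)) {
        parent <- match(m$shared_latent_with, colnames(latent))
        if (is.na(parent) || parent >= j)
          stop("shared_latent_with must name an earlier module")
        rho <- m$shared_latent_rho
        z <- rho * latent[, parent] + sqrt(1 - rho^2) * z
      }
      latent[, j] <- z
      lo <- stats::runif(m$gene_count, m$loading_range[1], m$loading_range[2])
      # hub gene carries the maximal loading
      hub_i <- match(m$hub_gene, m$genes)
      lo[hub_i] <- m$hub_loading
      names(lo) <- m$genes
      gene_loading <- c(gene_loading, lo)
      mu[m$genes, ] <- mu[m$genes, ] * exp(outer(lo, z))
    }
  }

  # library scaling for everything planted so far
  mu <- sweep(mu, 2, lib, `*`)

  # ligand/receptor calibration per (gene, population)
  if (!is.null(lr_tab)) {
    for (i in seq_len(nrow(lr_tab))) {
      idx <- pop_of == lr_tab$population[i]
      m0 <- .calibrate_mean(lr_tab$target[i], lib[idx], spec$nb_dispersion)
      mu[lr_tab$gene[i], idx] <- mu[lr_tab$gene[i], idx] + m0 * lib[idx]
    }
  }

  # mitochondrial content: expected share s of the cell's total
  s <- ifelse(low_q, spec$low_quality_mito_fraction, spec$baseline_mito_fraction)
  w <- stats::rlnorm(length(mito), 0, 0.5)
  w <- w / sum(w)
  tot_nonmito <- colSums(mu)
  mu[mito, ] <- outer(w, tot_nonmito * s / (1 - s))

  counts <- matrix(stats::rnbinom(G * n, mu = as.numeric(mu),
                                  size = spec$nb_dispersion),
                   nrow = G)
  barcodes <- sprintf("CELL-%05d", seq_len(n))
  cm <- count_matrix(Matrix::Matrix(counts, sparse = TRUE),
                     gene_ids = sprintf("SYNGENE%05d", seq_len(G)),
                     gene_symbols = symbols, barcodes = barcodes)

  gene_role <- rep("background", G)
  names(gene_role) <- symbols
  gene_role[mito] <- "mito"
  if (!is.null(marker_tab)) gene_role[marker_tab$gene] <- "marker"
  if (!is.null(lr_tab)) gene_role[lr_tab$gene] <- lr_tab$role
  gene_pop <- rep(NA_character_, G)
  names(gene_pop) <- symbols
  if (!is.null(marker_tab)) gene_pop[marker_tab$gene] <- marker_tab$population
  if (!is.null(lr_tab)) gene_pop[lr_tab$gene] <- lr_tab$population
  gene_module <- rep(NA_character_, G)
  names(gene_module) <- symbols
  is_tf <- rep(FALSE, G)
  names(is_tf) <- symbols
  loading <- rep(NA_real_, G)
  names(loading) <- symbols
  for (m in spec$modules) {
    gene_module[m$genes] <- m$name
    gene_role[m$genes] <- "module"
    is_tf[m$hub_gene] <- TRUE
  }
  if (length(spec$modules)) loading[names(gene_loading)] <- gene_loading

  truth <- list(
    cells = data.frame(barcode = barcodes, population = pop_of,
                       is_doublet = FALSE, is_low_quality = low_q,
                       library_factor = lib, stringsAsFactors = FALSE),
    genes = data.frame(gene = symbols, role = unname(gene_role),
                       population = unname(gene_pop),
                       module = unname(gene_module), is_tf = unname(is_tf),
                       loading = unname(loading),
                       baseline_mean = unname(base), stringsAsFactors = FALSE),
    expressing_targets = if (is.null(lr_tab)) NULL else
      lr_tab[, c("gene", "population", "role", "target")],
    latent = latent
  )
  list(matrix = cm, truth = truth)
}

#' Inject doublet barcodes into a count matrix
#'
#' Creates `round(rate * n_cells)` doublet barcodes, each the sum of the
#' counts of two distinct uniformly sampled parent cells (droplet
#' co-encapsulation). Original barcodes are retained.
#'
#' @param cm A `count_matrix`.
#' @param rate Doublet rate in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return List of `matrix` (augmented `count_matrix`) and `truth`
#'   (data.frame of barcode, is_doublet, parent barcodes).
#' @export
inject_doublets <- function(cm, rate, seed = 1L) {
  stopifnot(inherits(cm, "count_matrix"), rate >= 0, rate < 0.5)
  n <- ncol(cm$counts)
  n_doub <- round(rate * n)
  truth <- data.frame(barcode = cm$barcodes, is_doublet = FALSE,
                      parent1 = NA_character_, parent2 = NA_character_,
                      stringsAsFactors = FALSE)
  if (n_doub == 0) return(list(matrix = cm, truth = truth))
  set.seed(derive_seed(seed, "doublets"))
  parents <- t(vapply(seq_len(n_doub), function(i) sample.int(n, 2L),
                      integer(2)))
  dbl <- cm$counts[, parents[, 1], drop = FALSE] +
         cm$counts[, parents[, 2], drop = FALSE]
  dbc <- sprintf("DBL-%05d", seq_len(n_doub))
  out <- count_matrix(cbind(cm$counts, dbl),
                      gene_ids = cm$gene_ids, gene_symbols = cm$gene_symbols,
                      barcodes = c(cm$barcodes, dbc))
  truth <- rbind(truth, data.frame(
    barcode = dbc, is_doublet = TRUE,
    parent1 = cm$barcodes[parents[, 1]], parent2 = cm$barcodes[parents[, 2]],
    stringsAsFactors = FALSE))
  list(matrix = out, truth = truth)
}

#' Simulate a two-species barnyard mixture
#'
#' A 1:1 human/mouse mixing run: each species owns a disjoint gene block
#' (`hg_` / `mm_` prefixes) and every singlet barcode draws counts only from
#' its own block. Doublet barcodes sum two independently drawn cells whose
#' species are independent fair coin flips, so the expected cross-species
#' doublet fraction is half the total doublet rate.
#'
#' @param spec A [simulation_spec()]; `n_cells` is the barcode count and
#'   `n_genes` is split evenly between the species blocks.
#' @param doublet_rate Fraction of barcodes that are doublets, in `[0, 0.5)`.
#' @return List of `matrix` (a `count_matrix`) and `truth` (barcode species
#'   and doublet flags).
#' @export
simulate_barnyard <- function(spec, doublet_rate = 0) {
  stopifnot(inherits(spec, "simulation_spec"),
            doublet_rate >= 0, doublet_rate < 0.5)
  set.seed(derive_seed(spec$seed, "barnyard"))
  n <- spec$n_cells
  g_half <- spec$n_genes %/% 2L
  symbols <- c(sprintf("hg_GENE%04d", seq_len(g_half)),
               sprintf("mm_GENE%04d", seq_len(g_half)))
  G <- length(symbols)
  base <- stats::rlnorm(G, meanlog = log(0.5), sdlog = 1.0)
  species_block <- rep(c("human", "mouse"), each = g_half)

  n_doub <- round(doublet_rate * n)
  n_sing <- n - n_doub
  # singlets 1:1
  sing_species <- sample(rep(c("human", "mouse"), length.out = n_sing))
  draw_cell <- function(species) {
    lib <- exp(stats::rnorm(1, spec$library_size_logmean, spec$library_size_logsd))
    if (!is.finite(lib)) lib <- 0
    mu <- ifelse(species_block == species, base * lib, 0)
    stats::rnbinom(G, mu = mu, size = spec$nb_dispersion)
  }
  cols <- vector("list", n)
  sp_a <- sp_b <- character(n)
  is_doub <- c(rep(FALSE, n_sing), rep(TRUE, n_doub))
  for (i in seq_len(n_sing)) {
    sp_a[i] <- sp_b[i] <- sing_species[i]
    cols[[i]] <- draw_cell(sing_species[i])
  }
  for (i in seq_len(n_doub)) {
    a <- sample(c("human", "mouse"), 1)
    b <- sample(c("human", "mouse"), 1)
    sp_a[n_sing + i] <- a
    sp_b[n_sing + i] <- b
    cols[[n_sing + i]] <- draw_cell(a) + draw_cell(b)
  }
  counts <- do.call(cbind, cols)
  barcodes <- sprintf("BC-%05d", seq_len(n))
  cm <- count_matrix(Matrix::Matrix(counts, sparse = TRUE),
                     gene_ids = symbols, gene_symbols = symbols,
                     barcodes = barcodes)
  truth <- data.frame(barcode = barcodes, species_a = sp_a, species_b = sp_b,
                      is_doublet = is_doub,
                      is_cross = is_doub & (sp_a != sp_b),
                      stringsAsFactors = FALSE)
  list(matrix = cm, truth = truth)
}

#' Benchmark spec: three well-separated populations
#'
#' Three populations (50/30/20%) with 30 synthetic marker genes each at the
#' given fold (expressed in ~60% of their population) and no planted
#' modules - the standard clustering-recovery benchmark. Thirty markers per
#' population reflects that real lineages differ across dozens of genes,
#' not only their canonical markers.
#'
#' @param n_cells,n_genes Dimensions.
#' @param marker_fold Marker mean shift (default 8).
#' @param n_markers Markers per population (default 30).
#' @param seed Integer seed.
#' @return A `simulation_spec`.
#' @export
clustering_benchmark_spec <- function(n_cells = 1500, n_genes = 1000,
                                      marker_fold = 8, n_markers = 30,
                                      seed = 1L) {
  mk <- function(p) sprintf("%s.MK%02d", p, seq_len(n_markers))
  pops <- list(
    population_spec("popA", 0.5, marker_genes = mk("popA"),
                    marker_fold = marker_fold),
    population_spec("popB", 0.3, marker_genes = mk("popB"),
                    marker_fold = marker_fold),
    population_spec("popC", 0.2, marker_genes = mk("popC"),
                    marker_fold = marker_fold)
  )
  simulation_spec(n_cells, n_genes, pops, seed = seed)
}

#' Benchmark spec: planted co-expression modules
#'
#' One homogeneous population with `n_modules` planted 50-gene modules at a
#' fixed loading - the standard module-recovery benchmark.
#'
#' @param n_modules Number of modules (default 4).
#' @param loading Latent-factor loading for every module gene.
#' @param n_cells,n_genes Dimensions.
#' @param seed Integer seed.
#' @return A `simulation_spec`.
#' @export
module_benchmark_spec <- function(n_modules = 4, loading = 0.8,
                                  n_cells = 500, n_genes = 400, seed = 1L) {
  mods <- lapply(seq_len(n_modules), function(i)
    module_spec(sprintf("M%d", i), gene_count = 50,
                loading_range = c(loading, loading)))
  simulation_spec(n_cells, n_genes, list(population_spec("all", 1)),
                  modules = mods, seed = seed)
}
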