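#' Demonstration ligand-receptor pair table
#'
#' A small WNT/FZD-family pair table covering the circuitry expected in
#' chondrogenic pellets (population-restricted WNT ligands and FZD/ROR
#' receptors), plus decoy pairs. Full curated tables (thousands of pairs)
#' are supplied by the user as a two-column TSV.
#'
#' @return data.frame with columns `ligand`, `receptor`.
#' @export
demo_lr_pairs <- function() {
  data.frame(
    ligand = c("WNT3A", "WNT2B", "WNT5B", "WNT4", "WNT7B", "WNT3A",
               "WNT5B", "WNT1"),
    receptor = c("FZD2", "FZD4", "ROR2", "FZD1", "FZD3", "FZD9",
                 "FZD6", "FZD5"),
    stringsAsFactors = FALSE)
}

#' Read a ligand-receptor pair table from TSV
#'
#' @param path Two-column TSV (`ligand` TAB `receptor`), with or without a
#'   header line.
#' @return data.frame with columns `ligand`, `receptor`; duplicate pairs
#'   rejected.
#' @export
read_lr_pairs <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("ligand", first, ignore.case = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = header,
                           colClasses = "character")
  names(tab) <- c("ligand", "receptor")
  if (any(!nzchar(tab$ligand)) || any(!nzchar(tab$receptor)))
    stop("empty gene names in pair table")
  if (anyDuplicated(paste(tab$ligand, tab$receptor)))
    stop("duplicate ligand-receptor pairs")
  tab
}

#' Fraction of a population's cells expressing a gene
#'
#' "Expressed" means raw UMI count > 0; percentages are detection
#' frequencies.
#'
#' @param cm A `count_matrix`.
#' @param labels Per-cell population labels (aligned with columns).
#' @param gene Gene symbol.
#' @param population Population label.
#' @return Fraction in `[0, 1]`.
#' @export
percent_expressing <- function(cm, labels, gene, population) {
  stopifnot(inherits(cm, "count_matrix"))
  gi <- match(gene, cm$gene_symbols)
  if (is.na(gi)) stop("unknown gene: ", gene)
  idx <- labels == population
  if (!any(idx)) stop("unknown or empty population: ", population)
  mean(cm$counts[gi, idx] > 0)
}

#' Population natural-log fold change for one gene
#'
#' Same convention as marker detection: `ln(mean(e^x - 1) + 1)` inside the
#' population minus the same over all other cells.
#'
#' @param norm A `normalized_matrix`.
#' @param labels Per-cell population labels.
#' @param gene Gene symbol.
#' @param population Population label.
#' @return Natural-log fold change.
#' @export
population_lnfc <- function(norm, labels, gene, population) {
  stopifnot(inherits(norm, "normalized_matrix"))
  gi <- match(gene, norm$gene_symbols)
  if (is.na(gi)) stop("unknown gene: ", gene)
  idx <- labels == population
  if (!any(idx) || all(idx)) stop("population and its complement must be non-empty")
  .lnfc(norm$values[gi, idx], norm$values[gi, !idx])
}

#' Build the directed population-to-population interaction table
#'
#' For every ligand-receptor pair and every ordered (sender, receiver)
#' population combination, a record is emitted iff the ligand's natural-log
#' fold change in the sender and the receptor's in the receiver both exceed
#' `lnfc_min` (specificity filter), and both expressing fractions are at
#' least `min_pct`. Records carry the percent-expressing statistics and are
#' sorted by `pct_sender * pct_receiver` descending.
#'
#' @param cm A `count_matrix` (for detection percentages).
#' @param norm The matching `normalized_matrix` (for fold changes).
#' @param labels Per-cell population labels.
#' @param pairs data.frame with `ligand`, `receptor` columns.
#' @param lnfc_min Specificity threshold (default 0.25, strict).
#' @param min_pct Minimum expressing fraction in sender and receiver
#'   (default 0: even rarely detected receptors can carry signal).
#' @return data.frame of interaction records.
#' @export
build_interaction_table <- function(cm, norm, labels, pairs,
                                    lnfc_min = 0.25, min_pct = 0) {
  if (!nrow(pairs)) stop("empty pair table")
  pops <- sort(unique(labels))
  if (length(pops) < 2) stop("need at least 2 populations")
  genes <- unique(c(pairs$ligand, pairs$receptor))
  genes <- intersect(genes, cm$gene_symbols)
  # cache per (gene, population) stats
  pct <- matrix(NA_real_, length(genes), length(pops),
                dimnames = list(genes, pops))
  fc <- pct
  for (g in genes) for (p in pops) {
    pct[g, p] <- percent_expressing(cm, labels, g, p)
    fc[g, p] <- population_lnfc(norm, labels, g, p)
  }
  recs <- list()
  for (i in seq_len(nrow(pairs))) {
    lg <- pairs$ligand[i]; rc <- pairs$receptor[i]
    if (!(lg %in% genes) || !(rc %in% genes)) next
    for (s in pops) for (r in pops) {
      if (fc[lg, s] > lnfc_min && fc[rc, r] > lnfc_min &&
          pct[lg, s] >= min_pct && pct[rc, r] >= min_pct) {
        recs[[length(recs) + 1L]] <- data.frame(
          ligand = lg, receptor = rc, sender = s, receiver = r,
          pct_sender = pct[lg, s], pct_receiver = pct[rc, r],
          lnfc_sender = fc[lg, s], lnfc_receiver = fc[rc, r],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(ligand = character(), receptor = character(),
               sender = character(), receiver = character(),
               pct_sender = numeric(), pct_receiver = numeric(),
               lnfc_sender = numeric(), lnfc_receiver = numeric())
  out[order(-(out$pct_sender * out$pct_receiver)), , drop = FALSE]
}

#' Aggregate interaction records into population-pair edges
#'
#' One edge per ordered (sender, receiver) population pair, with the count
#' of qualifying ligand-receptor pairs and the summed percent product -
#' the chord-diagram-ready summary of signaling direction.
#'
#' @param records Output of [build_interaction_table()].
#' @return data.frame with `sender`, `receiver`, `n_pairs`,
#'   `sum_pct_product`.
#' @export
population_edge_summary <- function(records) {
  if (!nrow(records))
    return(data.frame(sender = character(), receiver = character(),
                      n_pairs = integer(), sum_pct_product = numeric()))
  key <- paste(records$sender, records$receiver, sep = "\r")
  agg <- lapply(split(records, key), function(d) {
    data.frame(sender = d$sender[1], receiver = d$receiver[1],
               n_pairs = nrow(d),
               sum_pct_product = sum(d$pct_sender * d$pct_receiver),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(-out$n_pairs), , drop = FALSE]
}
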