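#' Construct a UMI count matrix container
#'
#' Light-weight container for a genes x cells UMI matrix with gene and
#' barcode identities and per-cell summary metadata (total UMIs, detected
#' genes, mitochondrial fraction).
#'
#' @param counts Non-negative integer matrix (genes as rows), dense or
#'   `Matrix` sparse.
#' @param gene_ids,gene_symbols Character vectors, one per row.
#' @param barcodes Character vector, one per column; must be unique.
#' @param cell_meta Optional per-cell data.frame; recomputed when `NULL`.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, gene_ids, gene_symbols, barcodes,
                         cell_meta = NULL) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (nrow(counts) != length(gene_ids) || nrow(counts) != length(gene_symbols))
    stop("gene annotation length does not match matrix rows")
  if (ncol(counts) != length(barcodes))
    stop("barcode count does not match matrix columns")
  if (anyDuplicated(barcodes)) stop("duplicate barcodes")
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != round(v))))
    stop("counts must be non-negative integers")
  rownames(counts) <- gene_symbols
  colnames(counts) <- barcodes
  if (is.null(cell_meta)) {
    mito <- mito_genes(gene_symbols)
    tot <- Matrix::colSums(counts)
    cell_meta <- data.frame(
      barcode = barcodes,
      total_umis = tot,
      detected_genes = Matrix::colSums(counts > 0),
      mito_fraction = ifelse(tot > 0,
                             Matrix::colSums(counts[mito, , drop = FALSE]) / tot,
                             0),
      stringsAsFactors = FALSE)
  }
  structure(list(counts = counts, gene_ids = gene_ids,
                 gene_symbols = gene_symbols, barcodes = barcodes,
                 cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells, %d nonzero entries\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Write a count matrix as a 10x-style triplet directory
#'
#' Writes `matrix.mtx` (Matrix Market coordinate, integer, genes as rows),
#' `genes.tsv` (id TAB symbol, no header) and `barcodes.tsv`.
#'
#' @param cm A `count_matrix`.
#' @param path Directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_counts_10x <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  m <- cm$counts
  dimnames(m) <- NULL
  Matrix::writeMM(m, file.path(path, "matrix.mtx"))
  utils::write.table(data.frame(cm$gene_ids, cm$gene_symbols),
                     file.path(path, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(cm$barcodes, file.path(path, "barcodes.tsv"))
  invisible(path)
}

#' Read a 10x-style triplet directory
#'
#' @param path Directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`.
#' @return A `count_matrix`; gene order as on disk.
#' @export
read_counts_10x <- function(path) {
  mtx <- file.path(path, "matrix.mtx")
  gen <- file.path(path, "genes.tsv")
  bar <- file.path(path, "barcodes.tsv")
  for (f in c(mtx, gen, bar)) if (!file.exists(f)) stop("missing file: ", f)
  m <- Matrix::readMM(mtx)
  genes <- utils::read.table(gen, sep = "\t", header = FALSE,
                             colClasses = "character")
  barcodes <- readLines(bar)
  if (nrow(m) != nrow(genes))
    stop("matrix.mtx rows disagree with genes.tsv length")
  if (ncol(m) != length(barcodes))
    stop("matrix.mtx cols disagree with barcodes.tsv length")
  count_matrix(m, gene_ids = genes[[1]],
               gene_symbols = if (ncol(genes) >= 2) genes[[2]] else genes[[1]],
               barcodes = barcodes)
}

#' Subset a count matrix by cells and/or genes
#'
#' @param cm A `count_matrix`.
#' @param genes,cells Logical or integer indices (default: keep all).
#' @return A `count_matrix`.
#' @export
subset_count_matrix <- function(cm, genes = NULL, cells = NULL) {
  g <- genes %||% seq_len(nrow(cm$counts))
  ce <- cells %||% seq_len(ncol(cm$counts))
  count_matrix(cm$counts[g, ce, drop = FALSE],
               gene_ids = cm$gene_ids[g], gene_symbols = cm$gene_symbols[g],
               barcodes = cm$barcodes[ce])
}
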