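#' Construct a cell table
#'
#' A `cell_table` holds one tissue (typically one manually cropped germinal
#' center): per-cell x/y positions in micrometres, a cells-by-genes count
#' matrix, and arbitrary per-cell metadata columns (subtype labels, GC id,
#' ...). It is the common currency of the whole pipeline.
#'
#' @param cell_ids character vector of unique cell identifiers.
#' @param x,y numeric cell centroid coordinates in micrometres. The origin is
#'   arbitrary and y increases upward; no image-coordinate flipping is applied.
#' @param counts cells-by-genes matrix of non-negative integer counts; a base
#'   matrix or any [Matrix::Matrix] sparse form (stored as `dgCMatrix`).
#' @param gene_ids character vector of unique gene symbols, one per column of
#'   `counts`.
#' @param metadata optional data.frame of per-cell annotation columns.
#'
#' @return An object of class `cell_table`: a list with elements `cell_ids`,
#'   `x`, `y`, `counts` (sparse `dgCMatrix`, dimnames set), `gene_ids` and
#'   `metadata`.
#' @export
#' @examples
#' ct <- cell_table(c("c1", "c2"), x = c(0, 10), y = c(0, 0),
#'                  counts = matrix(0:3, 2, 2), gene_ids = c("g1", "g2"))
#' n_cells(ct)
cell_table <- function(cell_ids, x, y, counts, gene_ids, metadata = NULL) {
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ", paste(unique(cell_ids[duplicated(cell_ids)]),
                                       collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]),
                                       collapse = ", "))
  if (nrow(counts) != length(cell_ids))
    stop("counts has ", nrow(counts), " rows but there are ",
         length(cell_ids), " cell ids")
  if (ncol(counts) != length(gene_ids))
    stop("counts has ", ncol(counts), " columns but there are ",
         length(gene_ids), " gene ids")
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(cell_ids) || length(y) != length(cell_ids))
    stop("x and y must have one value per cell")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite cell coordinates")
  if (any(counts@x < 0)) stop("negative counts are not allowed")
  if (is.null(metadata)) {
    metadata <- data.frame(row.names = cell_ids)
  } else {
    metadata <- as.data.frame(metadata)
    if (nrow(metadata) != length(cell_ids))
      stop("metadata must have one row per cell")
    rownames(metadata) <- cell_ids
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(cell_ids = cell_ids, x = x, y = y, counts = counts,
                 gene_ids = gene_ids, metadata = metadata),
            class = "cell_table")
}

#' @rdname cell_table
#' @param ct a `cell_table`.
#' @export
n_cells <- function(ct) length(ct$cell_ids)

#' @rdname cell_table
#' @export
n_genes <- function(ct) length(ct$gene_ids)

#' @export
print.cell_table <- function(x, ...) {
  cat("<cell_table> ", n_cells(x), " cells x ", n_genes(x), " genes\n", sep = "")
  if (ncol(x$metadata)) cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

# subset rows (cells) of a cell_table, preserving invariants
subset_cells <- function(ct, keep) {
  cell_table(ct$cell_ids[keep], ct$x[keep], ct$y[keep],
             ct$counts[keep, , drop = FALSE], ct$gene_ids,
             ct$metadata[keep, , drop = FALSE])
}

#' Read a cell table from disk
#'
#' Reads the cells-by-genes count matrix either from a MatrixMarket triplet
#' file (`.mtx`, genes and cells supplied as index files) or from a dense CSV
#' with a header row of gene symbols and one row per cell. The cells file is a
#' CSV with at least `cell_id`, `x` and `y` columns (micrometres); any further
#' columns become metadata. The genes file is a headerless single-column TSV
#' of gene symbols (ignored for dense CSV input, where the matrix header is
#' authoritative).
#'
#' @param matrix_path path to `matrix.mtx` (cells x genes) or a dense CSV.
#' @param cells_path path to the per-cell CSV.
#' @param genes_path path to the gene index TSV (required for MTX input).
#' @return a [cell_table].
#' @export
read_cell_table <- function(matrix_path, cells_path, genes_path = NULL) {
  for (p in c(matrix_path, cells_path, genes_path))
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  cells <- utils::read.csv(cells_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  for (col in c("cell_id", "x", "y"))
    if (!col %in% names(cells))
      stop("cells file ", cells_path, " is missing required column '", col, "'")
  if (grepl("\\.mtx$", matrix_path)) {
    if (is.null(genes_path)) stop("genes_path is required for MTX input")
    counts <- Matrix::readMM(matrix_path)
    genes <- utils::read.delim(genes_path, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (ncol(counts) != length(genes))
      stop("dimension mismatch: ", matrix_path, " has ", ncol(counts),
           " columns but ", genes_path, " lists ", length(genes), " genes")
  } else {
    dense <- utils::read.csv(matrix_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- names(dense)
    counts <- as.matrix(dense)
  }
  if (nrow(counts) != nrow(cells))
    stop("dimension mismatch: ", matrix_path, " has ", nrow(counts),
         " rows but ", cells_path, " lists ", nrow(cells), " cells")
  meta_cols <- setdiff(names(cells), c("cell_id", "x", "y"))
  cell_table(cells$cell_id, cells$x, cells$y, counts, genes,
             metadata = if (length(meta_cols)) cells[meta_cols])
}

#' Write a cell table to disk
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate integer), `cells.csv`
#' (cell_id, x, y plus metadata columns) and `genes.tsv` into `dir`.
#'
#' @param ct a [cell_table].
#' @param dir output directory, created if missing.
#' @return invisibly, the paths written (named list).
#' @export
write_cell_table <- function(ct, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(matrix = file.path(dir, "matrix.mtx"),
                cells = file.path(dir, "cells.csv"),
                genes = file.path(dir, "genes.tsv"))
  m <- ct$counts
  dimnames(m) <- NULL
  Matrix::writeMM(m, paths$matrix)
  cells <- data.frame(cell_id = ct$cell_ids, x = ct$x, y = ct$y,
                      check.names = FALSE)
  if (ncol(ct$metadata)) cells <- cbind(cells, ct$metadata)
  utils::write.csv(cells, paths$cells, row.names = FALSE, quote = FALSE)
  writeLines(ct$gene_ids, paths$genes)
  invisible(paths)
}

#' Quality-control filter for cells
#'
#' Retains cells with strictly fewer than `max_features` detected genes and
#' strictly more than `min_counts` total transcripts; ties are excluded on
#' both thresholds. Cell order is preserved.
#'
#' @param ct a [cell_table].
#' @param max_features upper bound (exclusive) on the number of genes with a
#'   non-zero count per cell. Default 3000.
#' @param min_counts lower bound (exclusive) on the total count per cell.
#'   Default 400.
#' @param verbose log the number of removed cells to stderr.
#' @return the filtered [cell_table], with attribute `qc_removed` giving the
#'   number of cells dropped.
#' @export
qc_filter <- function(ct, max_features = 3000, min_counts = 400,
                      verbose = FALSE) {
  stopifnot(max_features > 0, min_counts > 0)
  n_feature <- Matrix::rowSums(ct$counts > 0)
  n_count <- Matrix::rowSums(ct$counts)
  keep <- n_feature < max_features & n_count > min_counts
  if (!any(keep))
    stop("qc_filter removed every cell; review max_features/min_counts ",
         "against the library-size distribution")
  if (verbose)
    message("qc_filter: removed ", sum(!keep), " of ", length(keep), " cells")
  out <- subset_cells(ct, keep)
  attr(out, "qc_removed") <- sum(!keep)
  out
}
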