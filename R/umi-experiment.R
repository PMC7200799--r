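#' UMI count experiment container
#'
#' Bundles an integer UMI count matrix (genes in rows, cells in columns) with
#' a gene table and a cell-metadata table. This is the object every pipeline
#' stage consumes and returns; all derived results (QC reports, DEG tables,
#' noise tables, MR tables) are plain tibbles.
#'
#' @param counts integer matrix, genes x cells, non-negative. Dimnames are
#'   taken from `genes$gene_id` / `cells$cell_id` if absent.
#' @param genes tibble with at least `gene_id` (unique) and logical `is_ercc`;
#'   an `is_mito` column is optional (used only by the 10x QC preset).
#' @param cells tibble with at least `cell_id` (unique). The STRT QC preset
#'   additionally needs `aligned_reads` and `mapping_ratio`; grouped analyses
#'   need `monkey`, `age_group` (\code{"young"}/\code{"old"}) and `cell_type`.
#' @param logcounts optional numeric matrix of log-normalized expression with
#'   the same dimensions as `counts` (filled in by [log_normalize()]).
#'
#' @return An object of class `umi_experiment`.
#' @export
umi_experiment <- function(counts, genes, cells, logcounts = NULL) {
  counts <- as.matrix(counts)
  genes <- tibble::as_tibble(genes)
  cells <- tibble::as_tibble(cells)
  if (!"gene_id" %in% names(genes)) stop("`genes` must have a gene_id column")
  if (!"cell_id" %in% names(cells)) stop("`cells` must have a cell_id column")
  if (!"is_ercc" %in% names(genes)) genes$is_ercc <- FALSE
  if (nrow(genes) != nrow(counts))
    stop("`genes` has ", nrow(genes), " rows but `counts` has ", nrow(counts))
  if (nrow(cells) != ncol(counts))
    stop("`cells` has ", nrow(cells), " rows but `counts` has ", ncol(counts), " columns")
  if (anyDuplicated(genes$gene_id)) stop("gene_id values must be unique")
  if (anyDuplicated(cells$cell_id)) stop("cell_id values must be unique")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.double(counts) && all(counts == round(counts)))
    storage.mode(counts) <- "integer"
  rownames(counts) <- genes$gene_id
  colnames(counts) <- cells$cell_id
  if (!is.null(logcounts)) {
    logcounts <- as.matrix(logcounts)
    stopifnot(identical(dim(logcounts), dim(counts)))
    dimnames(logcounts) <- dimnames(counts)
  }
  structure(
    list(counts = counts, genes = genes, cells = cells, logcounts = logcounts),
    class = "umi_experiment"
  )
}

#' @export
print.umi_experiment <- function(x, ...) {
  cat("<umi_experiment> ", nrow(x$counts), " genes (",
      sum(x$genes$is_ercc), " ERCC) x ", ncol(x$counts), " cells\n", sep = "")
  cat("  cell metadata: ", paste(setdiff(names(x$cells), "cell_id"), collapse = ", "), "\n", sep = "")
  cat("  logcounts: ", if (is.null(x$logcounts)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' @export
dim.umi_experiment <- function(x) dim(x$counts)

#' Subset an experiment by gene and/or cell identifiers
#'
#' @param x a [umi_experiment()].
#' @param genes,cells character vectors of identifiers to keep (NULL = all).
#' @return A `umi_experiment` restricted to the requested rows/columns.
#' @export
subset_experiment <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "umi_experiment"))
  gi <- if (is.null(genes)) seq_len(nrow(x$counts)) else match(genes, x$genes$gene_id)
  ci <- if (is.null(cells)) seq_len(ncol(x$counts)) else match(cells, x$cells$cell_id)
  if (anyNA(gi)) stop("unknown gene identifiers")
  if (anyNA(ci)) stop("unknown cell identifiers")
  umi_experiment(
    x$counts[gi, ci, drop = FALSE],
    x$genes[gi, , drop = FALSE],
    x$cells[ci, , drop = FALSE],
    logcounts = if (!is.null(x$logcounts)) x$logcounts[gi, ci, drop = FALSE]
  )
}

#' Write / read an experiment as plain-text files
#'
#' Counts go to TSV (`counts.tsv`, genes x cells with a leading `gene_id`
#' column) or MatrixMarket (`counts.mtx` plus `genes.tsv` / `cells.tsv` name
#' files); gene and cell tables go to TSV alongside. These are the interchange
#' formats of the command-line interface.
#'
#' @param x a [umi_experiment()].
#' @param dir output directory, created if needed.
#' @param format `"tsv"` or `"mtx"`.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(x, dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "umi_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "tsv") {
    counts <- tibble::as_tibble(x$counts, rownames = "gene_id")
    readr::write_tsv(counts, file.path(dir, "counts.tsv"))
  } else {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE),
                    file.path(dir, "counts.mtx"))
  }
  readr::write_tsv(x$genes, file.path(dir, "genes.tsv"))
  readr::write_tsv(x$cells, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"), show_col_types = FALSE)
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"), show_col_types = FALSE)
  if (format == "tsv") {
    tab <- readr::read_tsv(file.path(dir, "counts.tsv"), show_col_types = FALSE)
    counts <- as.matrix(tab[-1])
    rownames(counts) <- tab$gene_id
    counts <- counts[genes$gene_id, cells$cell_id, drop = FALSE]
  } else {
    counts <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  }
  umi_experiment(counts, genes, cells)
}
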