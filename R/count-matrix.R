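#' Construct a CountMatrix
#'
#' Light container for a genes x cells UMI matrix plus per-cell annotations.
#' The matrix is stored sparse (`dgCMatrix`); `cell_data` rows align with
#' matrix columns.
#'
#' @param counts genes x cells matrix of non-negative integer UMI counts
#'   (dense or sparse; coerced to `dgCMatrix`). Must carry gene rownames and
#'   barcode colnames.
#' @param cell_data `data.frame` with one row per cell. Must contain a
#'   `barcode` column matching `colnames(counts)`; typically also
#'   `timepoint`, `replicate` and optionally `cluster`.
#' @return An object of class `CountMatrix`: a list with elements `counts`
#'   and `cell_data`.
#' @export
CountMatrix <- function(counts, cell_data) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "generalMatrix"),
                        "CsparseMatrix")
  if (!methods::is(counts, "dMatrix")) counts <- counts * 1
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and barcode colnames")
  }
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    stop("counts must be non-negative integers")
  }
  cell_data <- as.data.frame(cell_data)
  if (!"barcode" %in% names(cell_data)) {
    stop("cell_data must contain a 'barcode' column")
  }
  if (!identical(as.character(cell_data$barcode), colnames(counts))) {
    stop("cell_data$barcode must align with colnames(counts)")
  }
  structure(list(counts = counts, cell_data = cell_data),
            class = "CountMatrix")
}

#' @method print CountMatrix
#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  extra <- setdiff(names(x$cell_data), "barcode")
  if (length(extra)) cat("cell annotations:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Write a CountMatrix to a 10x-style directory
#'
#' Writes `matrix.mtx` (Matrix Market), `barcodes.tsv`, `features.tsv` and
#' `cell_metadata.tsv` (barcode, timepoint, replicate, cluster when present).
#'
#' @param x a `CountMatrix`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(x, dir) {
  stopifnot(inherits(x, "CountMatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(x$counts), file.path(dir, "features.tsv"))
  write.table(x$cell_data, file.path(dir, "cell_metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a CountMatrix from a 10x-style directory
#'
#' @param dir directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv` and optionally `cell_metadata.tsv`.
#' @return a `CountMatrix`.
#' @export
read_count_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  features <- readLines(file.path(dir, "features.tsv"))
  dimnames(m) <- list(features, barcodes)
  meta_path <- file.path(dir, "cell_metadata.tsv")
  meta <- if (file.exists(meta_path)) {
    read.delim(meta_path, stringsAsFactors = FALSE)
  } else {
    data.frame(barcode = barcodes, stringsAsFactors = FALSE)
  }
  CountMatrix(m, meta)
}

#' Write / read a PPI edge list (two-column TSV of gene symbols)
#'
#' @param edges `data.frame` with columns `gene_a`, `gene_b`.
#' @param path TSV path.
#' @return `path` invisibly / the edge `data.frame`.
#' @export
write_ppi <- function(edges, path) {
  write.table(edges[, c("gene_a", "gene_b")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ppi
#' @export
read_ppi <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             col.names = c("gene_a", "gene_b"))
}
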