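#' Call cells from a droplet barcode profile
#'
#' Orders barcodes by library size, takes the `upper_quantile` (default
#' 0.99, type-7 interpolation) of the top `expected_cells` library sizes,
#' and calls as cells every barcode with strictly more molecules than
#' `fraction` (default 10%) of that quantile.
#'
#' @param profile named numeric vector: barcode -> total UMI count.
#' @param expected_cells expected number of cells (>= 1). When it exceeds
#'   the number of barcodes, the quantile is taken over all barcodes.
#' @param upper_quantile quantile of the top library sizes used as the
#'   reference (default 0.99).
#' @param fraction fraction of the reference quantile used as the calling
#'   threshold (default 0.10).
#' @return character vector of called barcodes (in input order).
#' @export
call_cells <- function(profile, expected_cells, upper_quantile = 0.99,
                       fraction = 0.10) {
  if (length(profile) == 0) stop("profile is empty")
  if (is.null(names(profile))) stop("profile must be named by barcode")
  if (anyDuplicated(names(profile))) stop("barcodes must be unique")
  if (any(profile < 0)) stop("counts must be non-negative")
  if (expected_cells < 1) stop("expected_cells must be >= 1")
  if (all(profile == 0)) stop("all-zero profile")
  top <- sort(profile, decreasing = TRUE)
  top <- top[seq_len(min(expected_cells, length(top)))]
  ref <- quantile(top, upper_quantile, type = 7, names = FALSE)
  names(profile)[profile > fraction * ref]
}

#' Filter genes detected in too few cells
#'
#' Removes genes detected (count > 0) in strictly less than
#' `min_cell_fraction` of all cells; genes with zero counts everywhere are
#' always removed. A `qc_report` attribute records the dimensions before
#' and after.
#'
#' @param matrix a [CountMatrix].
#' @param min_cell_fraction detection fraction below which a gene is
#'   dropped (default 0.10).
#' @return the filtered [CountMatrix], with attribute `qc_report` (a
#'   `data.frame` with `stage`, `genes`, `cells`).
#' @export
filter_genes <- function(matrix, min_cell_fraction = 0.10) {
  stopifnot(inherits(matrix, "CountMatrix"))
  if (min_cell_fraction < 0 || min_cell_fraction > 1) {
    stop("min_cell_fraction must be in [0, 1]")
  }
  m <- matrix$counts
  if (nrow(m) == 0 || ncol(m) == 0) stop("matrix is empty")
  n_detected <- Matrix::rowSums(m > 0)
  keep <- n_detected > 0 & (n_detected / ncol(m)) >= min_cell_fraction
  out <- CountMatrix(m[keep, , drop = FALSE], matrix$cell_data)
  attr(out, "qc_report") <- data.frame(
    stage = c("original", "filtered"),
    genes = c(nrow(m), sum(keep)),
    cells = c(ncol(m), ncol(m)))
  out
}
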