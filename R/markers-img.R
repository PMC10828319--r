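#' IQR outlier filter
#'
#' Flags values outside `[Q1 - factor * IQR, Q3 + factor * IQR]` (type-7
#' quartiles) as outliers. Constant vectors have IQR 0 and keep every
#' point; an empty vector returns empty output.
#'
#' @param values numeric vector; at least 4 values are recommended for
#'   meaningful quartiles.
#' @param factor fence multiplier (default 1.5).
#' @return list with `kept` (values inside the fences) and `outlier`
#'   (logical mask over the input).
#' @export
iqr_filter <- function(values, factor = 1.5) {
  if (length(values) == 0) {
    return(list(kept = numeric(0), outlier = logical(0)))
  }
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  out <- values < q[1] - factor * iqr | values > q[2] + factor * iqr
  list(kept = values[!out], outlier = out)
}

#' Scale marker intensities by their global maximum
#'
#' Divides each marker's intensities by that marker's maximum across all
#' timepoints, so the per-marker maximum of the output is exactly 1.
#' Expects outlier filtering to have been applied already (pipeline order:
#' [iqr_filter()] per marker per timepoint, then [max_scale()], then
#' tests).
#'
#' @param table long `data.frame` with columns `cell_id`, `timepoint`,
#'   `marker`, `intensity`.
#' @return the table with `intensity` rescaled.
#' @export
max_scale <- function(table) {
  stopifnot(all(c("marker", "intensity") %in% names(table)))
  for (mk in unique(table$marker)) {
    idx <- table$marker == mk
    mx <- max(table$intensity[idx])
    if (mx == 0) stop("marker with all-zero intensities: ", mk)
    table$intensity[idx] <- table$intensity[idx] / mx
  }
  table
}

#' Wilcoxon rank-sum test for a marker shift between two timepoints
#'
#' Two-sided rank-sum test on (scaled) intensities of one marker between
#' two timepoints, which are independent cell populations. Exact
#' enumeration for small samples, normal approximation with tie correction
#' when either group exceeds 50 cells.
#'
#' @param table long marker `data.frame` (see [max_scale()]).
#' @param marker marker name.
#' @param tp_a,tp_b the two timepoints.
#' @return list with `statistic` (rank-sum W) and `p_value`.
#' @export
marker_shift_test <- function(table, marker, tp_a, tp_b) {
  if (!marker %in% table$marker) stop("unknown marker: ", marker)
  for (tp in c(tp_a, tp_b)) {
    if (!tp %in% table$timepoint) stop("unknown timepoint: ", tp)
  }
  xa <- table$intensity[table$marker == marker & table$timepoint == tp_a]
  xb <- table$intensity[table$marker == marker & table$timepoint == tp_b]
  if (length(xa) < 3 || length(xb) < 3) stop("need >= 3 cells per group")
  exact <- max(length(xa), length(xb)) <= 50
  ht <- suppressWarnings(
    wilcox.test(xa, xb, exact = exact, correct = !exact))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Percentage of values above a positivity threshold
#'
#' @param values non-empty numeric vector.
#' @param threshold positivity cutoff (strict).
#' @return percentage in `[0, 100]`.
#' @export
positive_fraction <- function(values, threshold) {
  if (!length(values)) stop("empty input")
  100 * sum(values > threshold) / length(values)
}

#' Pairwise Spearman correlations between markers at a timepoint
#'
#' Reshapes the long marker table to cells x markers at the given
#' timepoint and returns the Spearman correlation matrix (unit diagonal).
#' Constant markers give undefined correlations, reported as `NA`.
#'
#' @param table long marker `data.frame`.
#' @param timepoint timepoint to correlate within.
#' @return symmetric markers x markers correlation matrix.
#' @export
marker_correlations <- function(table, timepoint) {
  sub <- table[table$timepoint == timepoint, ]
  if (!nrow(sub)) stop("unknown timepoint: ", timepoint)
  markers <- unique(sub$marker)
  wide <- do.call(cbind, lapply(markers, function(mk) {
    v <- sub[sub$marker == mk, ]
    v$intensity[match(unique(sub$cell_id), v$cell_id)]
  }))
  colnames(wide) <- markers
  if (nrow(wide) < 3) stop("need >= 3 cells at the timepoint")
  rho <- suppressWarnings(
    cor(wide, method = "spearman", use = "pairwise.complete.obs"))
  diag(rho) <- 1
  rho
}

#' Read / write a long marker table CSV
#'
#' Header: `cell_id,timepoint,marker,intensity`.
#'
#' @param table marker `data.frame` / `path` CSV path.
#' @param path CSV path.
#' @return `path` invisibly / the table.
#' @export
write_marker_table <- function(table, path) {
  write.csv(table[, c("cell_id", "timepoint", "marker", "intensity")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
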