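FAMILIES <- c("P", "ZIP", "NB", "ZINB")
# Tie-break order toward fewer parameters (P < ZIP = NB < ZINB; ZIP before
# NB by listed order for fully tied fits).
FAMILY_K_ORDER <- c(P = 1L, ZIP = 2L, NB = 2L, ZINB = 3L)

#' Select the best-fitting count family for one gene at one timepoint
#'
#' Fits all four families (`P`, `ZIP`, `NB`, `ZINB`) with replicate
#' adjustment, discards non-converged fits, and selects the minimum-BIC
#' family among those that pass the parametric-bootstrap KS screen at
#' `alpha` (ties broken toward fewer parameters). Candidates are screened
#' in ascending BIC order, so the selected family is exactly the min-BIC
#' KS survivor while only as many bootstrap screens run as needed. If no
#' family passes, the assignment is `"NONE"`.
#'
#' @inheritParams fit_family
#' @param alpha KS screening level (a fit passes when p > alpha).
#' @param n_boot bootstrap replicates for [ks_gof()].
#' @param seed integer seed for the bootstrap draws.
#' @return a `ShapeAssignment` list: `family` (or `"NONE"`), the selected
#'   `fit`, its `ks_p`, and a `data.frame` `candidates` (family, loglik,
#'   k, bic, converged, ks_p where screened).
#' @export
assign_shape <- function(y, replicate_labels = NULL, alpha = 0.05,
                         n_boot = 100, seed = 1) {
  fits <- lapply(FAMILIES, function(f) {
    suppressWarnings(fit_family(y, replicate_labels, f))
  })
  names(fits) <- FAMILIES
  cand <- data.frame(
    family = FAMILIES,
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    ks_p = NA_real_, stringsAsFactors = FALSE)
  ok <- which(cand$converged)
  ord <- ok[order(cand$bic[ok], FAMILY_K_ORDER[cand$family[ok]])]
  selected <- "NONE"
  sel_fit <- NULL
  sel_p <- NA_real_
  for (i in ord) {
    p <- ks_gof(fits[[i]], y, n_boot = n_boot,
                seed = sub_seed(seed, i))
    cand$ks_p[i] <- as.numeric(p)
    if (p > alpha) {
      selected <- cand$family[i]
      sel_fit <- fits[[i]]
      sel_p <- as.numeric(p)
      break
    }
  }
  structure(list(family = selected, fit = sel_fit, ks_p = sel_p,
                 candidates = cand), class = "ShapeAssignment")
}

#' @method print ShapeAssignment
#' @export
print.ShapeAssignment <- function(x, ...) {
  cat(sprintf("ShapeAssignment: %s (KS p = %s)\n", x$family,
              format(x$ks_p)))
  invisible(x)
}

#' Classify a gene's family triple across three timepoints
#'
#' Categories partition all triples: `unassigned` (any `NONE`), `stable`
#' (no change), `single_transition` (exactly one consecutive change),
#' `reverting` (A -> B -> A with A != B), `distinct_triple` (all three
#' differ). "Differentially distributed" genes — those changing at both
#' consecutive transitions — are the union of `reverting` and
#' `distinct_triple`.
#'
#' @param a0,a1,a2 family at T0, T1, T2: `"P"`, `"ZIP"`, `"NB"`, `"ZINB"`
#'   or `"NONE"`.
#' @return the category string.
#' @export
classify_switch <- function(a0, a1, a2) {
  allowed <- c(FAMILIES, "NONE")
  if (!all(c(a0, a1, a2) %in% allowed)) {
    stop("unknown family name")
  }
  if (any(c(a0, a1, a2) == "NONE")) return("unassigned")
  if (a0 == a1 && a1 == a2) return("stable")
  if ((a0 == a1 && a1 != a2) || (a0 != a1 && a1 == a2)) {
    return("single_transition")
  }
  if (a0 == a2) return("reverting")
  "distinct_triple"
}

#' Census of selected families per timepoint
#'
#' Counts and percentages of genes per family among KS-passing genes at
#' each timepoint. The percentage denominator is either the number of
#' non-`NONE` genes at that timepoint (`denominator = "per_timepoint"`) or
#' a fixed total (`denominator = "fixed"`, e.g. the study-wide KS-passing
#' gene count).
#'
#' @param assignments `data.frame` with columns `gene`, `timepoint`,
#'   `family` (one row per gene per timepoint).
#' @param denominator `"per_timepoint"` or `"fixed"`.
#' @param total fixed denominator when `denominator = "fixed"`.
#' @return `data.frame` with `timepoint`, `family`, `count`, `pct`.
#' @export
shape_census <- function(assignments,
                         denominator = c("per_timepoint", "fixed"),
                         total = NULL) {
  denominator <- match.arg(denominator)
  if (anyDuplicated(assignments[, c("gene", "timepoint")])) {
    stop("duplicate (gene, timepoint)")
  }
  a <- assignments[assignments$family != "NONE", ]
  tps <- sort(unique(assignments$timepoint))
  out <- do.call(rbind, lapply(tps, function(tp) {
    sub <- a[a$timepoint == tp, ]
    denom <- if (denominator == "fixed") {
      if (is.null(total)) stop("total required for fixed denominator")
      total
    } else nrow(sub)
    cnt <- vapply(FAMILIES, function(f) sum(sub$family == f), numeric(1))
    data.frame(timepoint = tp, family = FAMILIES, count = cnt,
               pct = 100 * cnt / denom, stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Census of cross-timepoint family switching
#'
#' Tabulates per-pattern counts of genes by their (T0, T1, T2) family
#' triple and the switch category, with block totals for the
#' differentially distributed categories (`distinct_triple`: change at
#' every timepoint; `reverting`: change at both transitions returning to
#' the T0 family). Percentages are relative to `denominator` (typically
#' the KS-passing gene count).
#'
#' @param records `data.frame` with columns `gene`, `t0`, `t1`, `t2`
#'   (family names), one row per gene. A `category` column is derived.
#' @param denominator gene count for the percentage of differentially
#'   distributed genes (default: number of records).
#' @return list with `patterns` (per-pattern counts with category),
#'   `category_counts`, `distinct_triple_total`, `reverting_total`,
#'   `changed_total` (their sum), `pct_changed` (of `denominator`) and
#'   `pct_all_three` (distinct triples among changed genes).
#' @export
switch_census <- function(records, denominator = nrow(records)) {
  if (nrow(records) == 0) {
    return(list(patterns = data.frame(), category_counts = setNames(
      numeric(5), c("stable", "single_transition", "reverting",
                    "distinct_triple", "unassigned")),
      distinct_triple_total = 0, reverting_total = 0, changed_total = 0,
      pct_changed = NA_real_, pct_all_three = NA_real_))
  }
  if (anyDuplicated(records$gene)) stop("one record per gene required")
  cat_vec <- mapply(classify_switch, records$t0, records$t1, records$t2)
  cats <- c("stable", "single_transition", "reverting", "distinct_triple",
            "unassigned")
  cat_counts <- vapply(cats, function(cc) sum(cat_vec == cc), numeric(1))
  key <- paste(records$t0, records$t1, records$t2, sep = "-")
  pat <- aggregate(list(count = seq_along(key)), by = list(
    t0 = records$t0, t1 = records$t1, t2 = records$t2), FUN = length)
  pat$category <- mapply(classify_switch, pat$t0, pat$t1, pat$t2)
  pat <- pat[order(match(pat$category, cats), -pat$count), ]
  rownames(pat) <- NULL
  dt <- cat_counts[["distinct_triple"]]
  rv <- cat_counts[["reverting"]]
  changed <- dt + rv
  list(patterns = pat, category_counts = cat_counts,
       distinct_triple_total = dt, reverting_total = rv,
       changed_total = changed,
       pct_changed = 100 * changed / denominator,
       pct_all_three = if (changed > 0) 100 * dt / changed else NA_real_)
}
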