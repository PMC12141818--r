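#' Apply sample-level eligibility filters
#'
#' Retains samples whose RNA integrity number (RIN) is at least
#' `rin_cutoff` and whose tissue class is not excluded. Samples with a
#' missing RIN are retained only when `rin_cutoff` is 0 (a dataset
#' without RIN annotation passes through untouched at cutoff 0;
#' otherwise exclusion is the fail-safe). Original row order is kept and
#' the operation is idempotent.
#'
#' @param samples validated sample table.
#' @param rin_cutoff minimum RIN; default 5.5.
#' @param exclude_classes tissue classes to drop; default `"cell_line"`.
#' @return the filtered sample table (possibly empty).
#' @export
apply_sample_filters <- function(samples, rin_cutoff = 5.5,
                                 exclude_classes = "cell_line") {
  stopifnot(rin_cutoff >= 0)
  samples <- validate_sample_table(samples)
  keep_rin <- if (rin_cutoff == 0) {
    is.na(samples$rin) | samples$rin >= 0
  } else {
    !is.na(samples$rin) & samples$rin >= rin_cutoff
  }
  keep_cls <- !(samples$tissue_class %in% exclude_classes)
  samples[keep_rin & keep_cls, , drop = FALSE]
}

#' Average replicate rows of a feature table
#'
#' Collapses a table that may hold several measurements per
#' (subject, tissue) — e.g. repeated proteomics runs — to one row per
#' key, taking the arithmetic mean of each feature over non-missing
#' replicate values.
#'
#' @param table feature table, replicates allowed.
#' @return feature table with one row per (subject, tissue).
#' @export
average_replicates <- function(table) {
  table <- validate_feature_table(table, allow_replicates = TRUE)
  feats <- feature_names(table)
  out <- aggregate(table[feats],
                   by = list(subject_id = table$subject_id,
                             tissue = table$tissue),
                   FUN = function(v) {
                     v <- v[!is.na(v)]
                     if (length(v)) mean(v) else NA_real_
                   })
  out[order(out$subject_id, out$tissue), , drop = FALSE]
}

#' Enumerate eligible tissue pairs
#'
#' A pair of tissues is eligible when at least `min_shared` subjects have
#' a (non-missing) measurement in both tissues. A tissue is retained only
#' if it forms eligible pairs with strictly more than `tissue_fraction`
#' of the other currently retained tissues; removals are iterated to a
#' fixed point, since dropping one tissue can disqualify another.
#'
#' @param table feature table (row presence defines tissue availability;
#'   pass `feature` to require that specific column to be non-missing).
#' @param min_shared minimum shared subjects per pair; default 10.
#' @param tissue_fraction fraction of other tissues a tissue must pair
#'   with; default 0.5.
#' @param feature optional feature column used to define availability.
#' @return data.frame with columns `tissue_a`, `tissue_b` (lexicographic
#'   canonical order, `tissue_a < tissue_b`), `n_shared`, `eligible`;
#'   retained tissues in `attr(, "retained_tissues")`.
#' @export
eligible_tissue_pairs <- function(table, min_shared = 10,
                                  tissue_fraction = 0.5, feature = NULL) {
  if (min_shared < 2)
    stop("min_shared must be at least 2", call. = FALSE)
  stopifnot(tissue_fraction >= 0, tissue_fraction <= 1)
  table <- validate_feature_table(table)
  if (!is.null(feature)) {
    if (!feature %in% names(table))
      stop("feature '", feature, "' not in table", call. = FALSE)
    table <- table[!is.na(table[[feature]]), , drop = FALSE]
  }
  tissues <- sort(unique(table$tissue))
  ntis <- length(tissues)
  if (ntis < 2L)
    return(structure(data.frame(tissue_a = character(), tissue_b = character(),
                                n_shared = integer(), eligible = logical()),
                     retained_tissues = tissues))
  # subjects-by-tissue incidence
  subjects <- unique(table$subject_id)
  inc <- matrix(FALSE, length(subjects), ntis,
                dimnames = list(subjects, tissues))
  inc[cbind(match(table$subject_id, subjects),
            match(table$tissue, tissues))] <- TRUE
  shared <- crossprod(inc)           # tissue x tissue shared-subject counts
  pair_ok <- shared >= min_shared
  diag(pair_ok) <- FALSE

  retained <- tissues
  repeat {
    k <- length(retained)
    if (k == 0L) break
    deg <- rowSums(pair_ok[retained, retained, drop = FALSE])
    keep <- deg > tissue_fraction * (k - 1L)
    if (all(keep)) break
    retained <- retained[keep]
  }

  idx <- which(upper.tri(shared), arr.ind = TRUE)
  out <- data.frame(
    tissue_a = tissues[idx[, 1L]],
    tissue_b = tissues[idx[, 2L]],
    n_shared = as.integer(shared[idx]),
    stringsAsFactors = FALSE)
  out$eligible <- out$n_shared >= min_shared &
    out$tissue_a %in% retained & out$tissue_b %in% retained
  structure(out[order(out$tissue_a, out$tissue_b), , drop = FALSE],
            retained_tissues = retained)
}
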