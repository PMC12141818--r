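#' Per-tissue association of a regulator with a mitochondrial index
#'
#' Within each tissue, correlates (Spearman) a regulator feature — e.g.
#' the nuclear-transcript percentage of PGC-1a (PPARGC1A) or of the four
#' ISR genes — with a mitochondrial index (mito_ndna_pct or mtdna_pct)
#' across subjects. Tissues with fewer than `min_n` complete subjects are
#' skipped (recorded in `attr(, "skipped")`). The result is ranked by r,
#' the form in which these tissue profiles are compared.
#'
#' @param table index feature table.
#' @param regulator regulator feature column.
#' @param mito mitochondrial index column.
#' @param min_n minimum subjects per tissue; default 10.
#' @return data.frame `tissue`, `r`, `p`, `n`, sorted by decreasing r.
#' @export
intra_tissue_association <- function(table, regulator, mito, min_n = 10) {
  for (f in c(regulator, mito))
    if (!f %in% names(table))
      stop("feature '", f, "' not in table", call. = FALSE)
  tissues <- unique(table$tissue)
  res <- vector("list", length(tissues))
  skipped <- character(0)
  for (i in seq_along(tissues)) {
    sub <- table[table$tissue == tissues[i], , drop = FALSE]
    keep <- !(is.na(sub[[regulator]]) | is.na(sub[[mito]]))
    if (sum(keep) < min_n) {
      skipped <- c(skipped, tissues[i]); next
    }
    s <- spearman_rp(sub[[regulator]][keep], sub[[mito]][keep])
    if (!s$ok) { skipped <- c(skipped, tissues[i]); next }
    res[[i]] <- data.frame(tissue = tissues[i], r = s$r, p = s$p, n = s$n,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(tissue = character(), r = numeric(), p = numeric(),
                      n = integer())
  out <- out[order(-out$r), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, skipped = skipped)
}

#' Compare two per-tissue association profiles
#'
#' Spearman correlation, across the tissues common to both profiles, of
#' the two vectors of per-tissue coefficients — are two regulators
#' associated with mitochondrial expression in the same tissues?
#'
#' @param profile_a,profile_b outputs of [intra_tissue_association()]
#'   (or any data.frame with `tissue` and `r`).
#' @return list `r`, `p`, `n` (number of common tissues).
#' @export
compare_profiles <- function(profile_a, profile_b) {
  common <- intersect(profile_a$tissue, profile_b$tissue)
  if (length(common) < 3L)
    stop("fewer than 3 tissues in common between profiles", call. = FALSE)
  ra <- profile_a$r[match(common, profile_a$tissue)]
  rb <- profile_b$r[match(common, profile_b$tissue)]
  s <- spearman_rp(ra, rb)
  if (!s$ok)
    stop("profile comparison undefined (zero rank variance)", call. = FALSE)
  list(r = s$r, p = s$p, n = s$n)
}

#' mtDNA-nuclear transcript coupling explained by proliferation
#'
#' Within each tissue, the Spearman correlation of mtDNA% with mito-nDNA%
#' across subjects ("coupling"), and the tissue's proliferation score
#' (mean over its subjects). The across-tissue meta-correlation of
#' coupling versus proliferation (Spearman over tissues, not subjects)
#' tests whether proliferative tissues couple nuclear mitochondrial
#' biogenesis to mitochondrial content more tightly.
#'
#' @param table index feature table with `mtdna_pct`, `mito_ndna_pct`,
#'   `proliferation_score`.
#' @param min_n minimum subjects per tissue; default 10.
#' @return list with `per_tissue` (tissue, coupling_r, coupling_p, n,
#'   proliferation) and `meta` (list r, p, n over tissues).
#' @export
coupling_by_proliferation <- function(table, min_n = 10) {
  need <- c("mtdna_pct", "mito_ndna_pct", "proliferation_score")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  coup <- intra_tissue_association(table, "mtdna_pct", "mito_ndna_pct",
                                   min_n = min_n)
  prolif <- tapply(table$proliferation_score, table$tissue,
                   function(x) mean(x, na.rm = TRUE))
  per_tissue <- data.frame(
    tissue = coup$tissue,
    coupling_r = coup$r, coupling_p = coup$p, n = coup$n,
    proliferation = as.numeric(prolif[coup$tissue]),
    stringsAsFactors = FALSE)
  if (nrow(per_tissue) < 3L)
    stop("fewer than 3 tissues eligible for the meta-correlation",
         call. = FALSE)
  meta <- spearman_rp(per_tissue$coupling_r, per_tissue$proliferation)
  list(per_tissue = per_tissue,
       meta = list(r = meta$r, p = meta$p, n = meta$n))
}
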