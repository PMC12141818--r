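#' Percentage of transcripts of mitochondrial-genome origin (mtDNA%)
#'
#' mtDNA-encoded genes expressed as a percentage of all transcripts in a
#' sample: `100 * sum(mtDNA genes) / sum(all genes)`. A proxy for the
#' mass/content of mitochondria in the sampled tissue.
#'
#' @param profile named numeric vector of per-gene abundances (TPM-like).
#' @param catalog a [gene_catalog()].
#' @return scalar percentage in \[0, 100\].
#' @export
mtdna_percent <- function(profile, catalog) {
  total <- sum(profile)
  if (!is.finite(total) || total <= 0)
    stop("profile total abundance must be positive", call. = FALSE)
  100 * sum(profile[names(profile) %in% catalog$mtdna_genes]) / total
}

#' Percentage of the nuclear transcriptome in a named gene set
#'
#' All mtDNA transcripts are removed from the sample first; the set is
#' then expressed as a percentage of the remaining (nuclear) transcripts:
#' `100 * sum(set) / sum(non-mtDNA genes)`. With `set_name =
#' "mito_nuclear"` this is mito-nDNA%, the fraction of the nuclear
#' transcriptome invested in mitochondrial proteins; singleton sets give
#' e.g. PGC-1a% (PPARGC1A).
#'
#' @param profile named numeric per-gene abundances.
#' @param catalog a [gene_catalog()].
#' @param set_name `"mito_nuclear"` or a name in `catalog$named_sets`.
#' @return scalar percentage in \[0, 100\].
#' @export
nuclear_set_percent <- function(profile, catalog, set_name) {
  set <- if (identical(set_name, "mito_nuclear")) {
    catalog$mito_nuclear_genes
  } else if (set_name %in% names(catalog$named_sets)) {
    catalog$named_sets[[set_name]]
  } else stop("unknown gene set '", set_name, "'", call. = FALSE)
  bad <- intersect(set, catalog$mtdna_genes)
  if (length(bad))
    stop("set '", set_name, "' contains mtDNA gene(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  nuclear <- profile[!names(profile) %in% catalog$mtdna_genes]
  denom <- sum(nuclear)
  if (!is.finite(denom) || denom <= 0)
    stop("nuclear (non-mtDNA) total abundance must be positive",
         call. = FALSE)
  100 * sum(nuclear[names(nuclear) %in% set]) / denom
}

#' Tissue proliferation score
#'
#' Arithmetic mean of the abundances of the three proliferation marker
#' genes (MKI67, TOP2A, RRM2 by default, taken from the catalog's
#' `proliferation` set), in the profile's own TPM-like units. Proxy for
#' replicative activity, which dilutes mitochondria at cell division.
#'
#' @param profile named numeric per-gene abundances.
#' @param catalog a [gene_catalog()] with a `proliferation` named set.
#' @return scalar score (same units as the profile).
#' @export
proliferation_score <- function(profile, catalog) {
  genes <- catalog$named_sets[["proliferation"]]
  if (is.null(genes))
    stop("catalog has no 'proliferation' gene set", call. = FALSE)
  miss <- setdiff(genes, names(profile))
  if (length(miss))
    stop("proliferation gene(s) absent from profile: ",
         paste(miss, collapse = ", "), call. = FALSE)
  mean(profile[genes])
}

#' Build the per subject-tissue index table
#'
#' Computes, for every sample, mtDNA%, mito-nDNA%, one percentage column
#' per named nuclear set (`<set>_pct`), and the proliferation score, then
#' collapses to one row per (subject, tissue); a subject's repeated
#' samples of one tissue are averaged at the index level.
#'
#' @param mat validated expression matrix (genes x samples).
#' @param samples sample table annotating every column of `mat`.
#' @param catalog a [gene_catalog()].
#' @param sets named sets to report as percentages; defaults to all sets
#'   in the catalog except `proliferation`.
#' @return feature table with key columns `subject_id`, `tissue` and one
#'   column per index; tissue-to-class map kept in
#'   `attr(, "tissue_classes")`.
#' @export
build_index_table <- function(mat, samples, catalog,
                              sets = setdiff(names(catalog$named_sets),
                                             "proliferation")) {
  samples <- validate_sample_table(samples)
  unann <- setdiff(colnames(mat), samples$sample_id)
  if (length(unann))
    stop("sample(s) not annotated in sample table: ",
         paste(unann, collapse = ", "), call. = FALSE)
  samples <- samples[match(colnames(mat), samples$sample_id), , drop = FALSE]

  per_sample <- data.frame(
    subject_id = samples$subject_id,
    tissue = samples$tissue,
    mtdna_pct = apply(mat, 2L, mtdna_percent, catalog = catalog),
    mito_ndna_pct = apply(mat, 2L, nuclear_set_percent, catalog = catalog,
                          set_name = "mito_nuclear"),
    stringsAsFactors = FALSE, row.names = NULL)
  for (nm in sets)
    per_sample[[paste0(nm, "_pct")]] <-
      apply(mat, 2L, nuclear_set_percent, catalog = catalog, set_name = nm)
  if ("proliferation" %in% names(catalog$named_sets))
    per_sample$proliferation_score <-
      apply(mat, 2L, proliferation_score, catalog = catalog)

  out <- average_replicates(per_sample)
  cls <- unique(samples[, c("tissue", "tissue_class")])
  structure(out,
            tissue_classes = setNames(cls$tissue_class, cls$tissue))
}

#' Fold range of per-tissue means
#'
#' Ratio of the highest to the lowest tissue mean of an index, the
#' "x-fold" span of the tissue ranking.
#'
#' @param tissue_means named numeric vector of per-tissue means, all > 0.
#' @return max / min.
#' @export
fold_range <- function(tissue_means) {
  if (length(tissue_means) == 0L || any(!is.finite(tissue_means)) ||
      any(tissue_means <= 0))
    stop("tissue means must be positive and finite", call. = FALSE)
  max(tissue_means) / min(tissue_means)
}

#' Per-tissue means of a feature
#'
#' @param table feature table.
#' @param feature feature column name.
#' @return named numeric vector, tissue -> mean (missing cells dropped).
#' @export
tissue_means <- function(table, feature) {
  v <- tapply(table[[feature]], table$tissue,
              function(x) mean(x, na.rm = TRUE))
  setNames(as.numeric(v), names(v))
}
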