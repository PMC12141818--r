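#' Read a TPM-like expression table
#'
#' Accepts either a wide table (genes as rows, one column per sample, the
#' gene identifier in the first column) or a long table with columns
#' `gene_id`, `sample_id`, `value`. The dialect is auto-detected from the
#' header; the delimiter is inferred from the file extension (`.csv` =
#' comma, otherwise tab). Gzip-compressed files are accepted.
#'
#' @param path path to a TSV/CSV file, optionally gzipped.
#' @return a numeric matrix (genes x samples) with gene IDs as rownames
#'   and sample IDs as colnames, validated by [validate_expression_matrix()].
#' @export
read_expression_matrix <- function(path) {
  sep <- infer_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L || nrow(df) == 0L)
    stop("expression table at '", path, "' is empty or has fewer than 2 columns",
         call. = FALSE)
  if (identical(tolower(names(df)[1:3])[seq_len(min(3, ncol(df)))],
                c("gene_id", "sample_id", "value")) && ncol(df) == 3L) {
    wide <- long_to_wide(df)
  } else {
    genes <- as.character(df[[1L]])
    vals <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(vals))
      stop("non-numeric expression values in '", path, "'", call. = FALSE)
    rownames(vals) <- genes
    wide <- vals
  }
  validate_expression_matrix(wide)
}

long_to_wide <- function(df) {
  genes <- unique(df$gene_id)
  samples <- unique(df$sample_id)
  m <- matrix(0, length(genes), length(samples),
              dimnames = list(genes, samples))
  idx <- cbind(match(df$gene_id, genes), match(df$sample_id, samples))
  if (anyDuplicated(idx) > 0L)
    stop("duplicated (gene, sample) entry in long-format table", call. = FALSE)
  m[idx] <- df$value
  m
}

#' Validate an expression matrix
#'
#' Checks the invariants of a TPM-like table: unique gene and sample IDs,
#' no negative values, strictly positive per-sample totals.
#'
#' @param mat numeric matrix, genes x samples, dimnames set.
#' @return the matrix, invisibly unchanged, if valid; otherwise an error
#'   naming the offending gene or sample.
#' @export
validate_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression data must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix must carry gene rownames and sample colnames",
         call. = FALSE)
  dup <- rownames(mat)[duplicated(rownames(mat))]
  if (length(dup))
    stop("duplicated gene ID(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  dup <- colnames(mat)[duplicated(colnames(mat))]
  if (length(dup))
    stop("duplicated sample ID(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (anyNA(mat))
    stop("expression matrix contains missing values", call. = FALSE)
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative abundance for gene '", rownames(mat)[neg[1L, 1L]],
         "' in sample '", colnames(mat)[neg[1L, 2L]], "'", call. = FALSE)
  tot <- colSums(mat)
  if (any(tot <= 0))
    stop("sample '", colnames(mat)[which(tot <= 0)[1L]],
         "' has non-positive total abundance", call. = FALSE)
  mat
}

#' Write an expression matrix to disk
#'
#' Wide format: first column `gene_id`, then one column per sample.
#'
#' @param mat validated expression matrix.
#' @param path output path (`.csv` for comma, otherwise tab-delimited).
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = infer_sep(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

infer_sep <- function(path) {
  p <- sub("\\.gz$", "", path)
  if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
}

#' Read a sample metadata table
#'
#' Requires columns `sample_id`, `subject_id`, `tissue`, `tissue_class`;
#' an optional `rin` column holds the RNA integrity number.
#'
#' @param path TSV/CSV path.
#' @return a data.frame validated by [validate_sample_table()].
#' @export
read_sample_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = infer_sep(path),
                   stringsAsFactors = FALSE)
  validate_sample_table(df)
}

#' Validate sample metadata
#'
#' @param samples data.frame of per-sample annotations.
#' @return the data.frame (with an all-NA `rin` column added if absent).
#' @export
validate_sample_table <- function(samples) {
  req <- c("sample_id", "subject_id", "tissue", "tissue_class")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("sample table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in sample table", call. = FALSE)
  bad <- setdiff(unique(samples$tissue_class),
                 c("brain", "body", "cell_line"))
  if (length(bad))
    stop("unknown tissue_class value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cls <- unique(samples[, c("tissue", "tissue_class")])
  if (anyDuplicated(cls$tissue))
    stop("tissue mapped to more than one tissue_class", call. = FALSE)
  if (is.null(samples$rin)) samples$rin <- NA_real_
  samples
}

#' Read a gene catalog
#'
#' Two-column table (`gene_id`, `set_name`). Set names `mtdna` and
#' `mito_nuclear` populate the two primary gene classes; every other set
#' name becomes a named nuclear gene set. A gene may belong to several
#' sets, except that no gene may be both `mtdna` and `mito_nuclear`.
#'
#' @param path TSV/CSV path.
#' @return a `gene_catalog` list.
#' @export
read_gene_catalog <- function(path) {
  df <- read.table(path, header = TRUE, sep = infer_sep(path),
                   stringsAsFactors = FALSE)
  if (!all(c("gene_id", "set_name") %in% names(df)))
    stop("gene catalog needs columns gene_id, set_name", call. = FALSE)
  sets <- split(df$gene_id, df$set_name)
  gene_catalog(
    mtdna_genes = unique(sets[["mtdna"]]),
    mito_nuclear_genes = unique(sets[["mito_nuclear"]]),
    named_sets = lapply(sets[setdiff(names(sets),
                                     c("mtdna", "mito_nuclear"))], unique)
  )
}

#' Construct a gene catalog
#'
#' @param mtdna_genes character vector of mtDNA-encoded gene IDs.
#' @param mito_nuclear_genes nuclear-encoded mitochondrial gene IDs
#'   (Mitocarta-style inventory).
#' @param named_sets named list of additional nuclear gene sets (ISR,
#'   proliferation, single-regulator sets, pathway subsets, ...).
#' @return a list of class `gene_catalog`.
#' @export
gene_catalog <- function(mtdna_genes, mito_nuclear_genes,
                         named_sets = list()) {
  mtdna_genes <- as.character(mtdna_genes)
  mito_nuclear_genes <- as.character(mito_nuclear_genes)
  both <- intersect(mtdna_genes, mito_nuclear_genes)
  if (length(both))
    stop("gene(s) in both mtdna and mito_nuclear classes: ",
         paste(both, collapse = ", "), call. = FALSE)
  for (nm in names(named_sets)) {
    inmt <- intersect(named_sets[[nm]], mtdna_genes)
    if (length(inmt))
      stop("named set '", nm, "' contains mtDNA gene(s): ",
           paste(inmt, collapse = ", "), call. = FALSE)
  }
  structure(list(mtdna_genes = mtdna_genes,
                 mito_nuclear_genes = mito_nuclear_genes,
                 named_sets = named_sets),
            class = "gene_catalog")
}

#' Write a gene catalog as a two-column table
#'
#' @param catalog a `gene_catalog`.
#' @param path output TSV/CSV path.
#' @export
write_gene_catalog <- function(catalog, path) {
  rows <- rbind(
    data.frame(gene_id = catalog$mtdna_genes, set_name = "mtdna"),
    data.frame(gene_id = catalog$mito_nuclear_genes,
               set_name = "mito_nuclear"))
  for (nm in names(catalog$named_sets))
    rows <- rbind(rows, data.frame(gene_id = catalog$named_sets[[nm]],
                                   set_name = nm))
  write.table(rows, path, sep = infer_sep(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a per-subject-per-tissue feature table
#'
#' The common carrier for computed indices and for externally measured
#' features (enzymatic activities, mtDNA copy number, protein
#' percentages): one row per (subject, tissue), one column per feature,
#' missing cells allowed.
#'
#' @param path TSV/CSV path with columns `subject_id`, `tissue`, then
#'   features.
#' @return a data.frame.
#' @export
read_feature_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = infer_sep(path),
                   stringsAsFactors = FALSE)
  validate_feature_table(df)
}

validate_feature_table <- function(table, allow_replicates = FALSE) {
  if (!all(c("subject_id", "tissue") %in% names(table)))
    stop("feature table needs columns subject_id, tissue", call. = FALSE)
  if (!allow_replicates) {
    key <- paste(table$subject_id, table$tissue, sep = "\r")
    if (anyDuplicated(key))
      stop("more than one row per (subject, tissue); call ",
           "average_replicates() first", call. = FALSE)
  }
  table
}

#' Write a feature table
#'
#' @param table feature table data.frame.
#' @param path output TSV/CSV path.
#' @export
write_feature_table <- function(table, path) {
  write.table(table, path, sep = infer_sep(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Names of the feature columns of a feature table
#' @param table feature table.
#' @return character vector (everything except the row keys).
#' @export
feature_names <- function(table) {
  setdiff(names(table), c("subject_id", "tissue"))
}
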