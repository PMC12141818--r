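# Small in-code fixtures shared across test files.

# a 3-gene x 2-sample toy matrix with known column sums
toy_expression <- function() {
  m <- matrix(c(250000, 100000,
                650000, 800000,
                100000, 100000),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("MT-CO1", "NMIT0001", "OTH0001"),
                              c("s1", "s2")))
  m
}

toy_catalog <- function() {
  gene_catalog(mtdna_genes = "MT-CO1",
               mito_nuclear_genes = "NMIT0001",
               named_sets = list(other = "OTH0001"))
}

toy_samples <- function() {
  data.frame(sample_id = c("s1", "s2"),
             subject_id = c("A", "B"),
             tissue = c("heart", "heart"),
             tissue_class = "body",
             rin = c(7, 8),
             stringsAsFactors = FALSE)
}

# feature table with a planted availability pattern
feature_table_from_matrix <- function(avail, feature = "x", values = NULL) {
  idx <- which(avail, arr.ind = TRUE)
  df <- data.frame(subject_id = rownames(avail)[idx[, 1]],
                   tissue = colnames(avail)[idx[, 2]],
                   stringsAsFactors = FALSE)
  df[[feature]] <- if (is.null(values)) seq_len(nrow(df)) else values
  df
}

# brute-force reference for eligible_tissue_pairs (independent of the
# package's incidence-matrix implementation)
brute_eligible_pairs <- function(table, min_shared, tissue_fraction) {
  tissues <- sort(unique(table$tissue))
  shared <- function(a, b) {
    length(intersect(table$subject_id[table$tissue == a],
                     table$subject_id[table$tissue == b]))
  }
  retained <- tissues
  repeat {
    keep <- vapply(retained, function(a) {
      n_ok <- sum(vapply(setdiff(retained, a),
                         function(b) shared(a, b) >= min_shared, TRUE))
      n_ok > tissue_fraction * (length(retained) - 1)
    }, TRUE)
    if (all(keep)) break
    retained <- retained[keep]
  }
  out <- t(combn(tissues, 2))
  data.frame(tissue_a = out[, 1], tissue_b = out[, 2],
             n_shared = apply(out, 1, function(p) shared(p[1], p[2])),
             eligible = apply(out, 1, function(p)
               p[1] %in% retained && p[2] %in% retained &&
                 shared(p[1], p[2]) >= min_shared),
             stringsAsFactors = FALSE)
}

# a tiny 4-tissue panel used by clustering tests
four_tissue_panel <- function() {
  pan <- tissue_panel(n_brain = 1, n_body = 3, miss = 0)
  pan$tissue <- c("cortex", "muscle", "heart", "adipose")
  pan
}
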