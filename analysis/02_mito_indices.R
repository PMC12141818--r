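#!/usr/bin/env Rscript

# Stage 2 — per subject-tissue mitochondrial indices.
#
# Reads the simulated expression cohort from results/data/, applies the
# sample filters (RIN >= 5.5, no cell lines), computes mtDNA%,
# mito-nDNA%, the regulator and ISR percentages and the proliferation
# score for every subject-tissue combination, and reports the tissue
# ranking and its fold range.

suppressPackageStartupMessages(library(mitocoherence))

dat <- "results/data"
out <- "results"
expr <- read_expression_matrix(file.path(dat, "expression.tsv.gz"))
samples <- read_sample_table(file.path(dat, "samples.tsv"))
catalog <- read_gene_catalog(file.path(dat, "gene_catalog.tsv"))

kept <- apply_sample_filters(samples, rin_cutoff = 5.5)
message(sprintf("RIN filter: %d of %d samples retained",
                nrow(kept), nrow(samples)))
expr <- expr[, kept$sample_id]

tab <- build_index_table(expr, kept, catalog)
write_feature_table(tab, file.path(out, "index_table.tsv"))
message(sprintf("index table: %d subject-tissue rows, features: %s",
                nrow(tab), paste(feature_names(tab), collapse = ", ")))

for (feat in c("mtdna_pct", "mito_ndna_pct")) {
  tm <- sort(tissue_means(tab, feat), decreasing = TRUE)
  message(sprintf("%s: top tissue %s (%.1f%%), bottom %s (%.1f%%), %.1f-fold range",
                  feat, names(tm)[1], tm[1], names(tm)[length(tm)],
                  tm[length(tm)], fold_range(tm)))
  write.table(data.frame(tissue = names(tm), mean = tm),
              file.path(out, paste0("tissue_ranking_", feat, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
message("wrote ", out)
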