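#!/usr/bin/env Rscript

# Stage 3 — inter-tissue coherence structure.
#
# Asks the central question: do subjects with relatively high
# mitochondrial expression in one tissue have relatively high expression
# in their other tissues? Computes the pairwise Spearman structure of
# mtDNA% and mito-nDNA% over all eligible tissue pairs (>= 10 shared
# subjects, tissues pairing with > 50% of the others), stratifies pairs
# into brain-brain / body-body / brain-body, summarizes each class, and
# thresholds the structure into a coherence network (edges at r >= 0.2).
# The same machinery is then applied unchanged to the mouse-shaped
# enzymatic feature table (five features, 231 pairs each).

suppressPackageStartupMessages(library(mitocoherence))

out <- "results"
tab <- read_feature_table(file.path(out, "index_table.tsv"))
samples <- read_sample_table(file.path(out, "data", "samples.tsv"))
cls <- unique(samples[, c("tissue", "tissue_class")])
brain <- cls$tissue[cls$tissue_class == "brain"]

pairs <- eligible_tissue_pairs(tab, min_shared = 10, tissue_fraction = 0.5)
message(sprintf("eligible tissue pairs: %d of %d",
                sum(pairs$eligible), nrow(pairs)))

corrs <- pairwise_structure_multi(tab, pairs, brain_tissues = brain,
                                  features = c("mtdna_pct",
                                               "mito_ndna_pct"))
write.table(corrs, file.path(out, "correlations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

for (feat in c("mtdna_pct", "mito_ndna_pct")) {
  s <- summarize_coherence(corrs[corrs$feature == feat, ], alpha = 0.05)
  message(feat, " class medians:")
  print(s$summary[, c("pair_class", "n_pairs", "median_r", "pct_positive",
                      "pct_sig_positive")], digits = 2)
  write.table(s$summary, file.path(out, paste0("coherence_summary_",
                                               feat, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

tmc <- tissue_mean_coherence(corrs[corrs$feature == "mtdna_pct", ])
message(sprintf("most coherent tissue: %s (mean r = %.2f); least: %s (%.2f)",
                names(tmc)[1], tmc[1], names(tmc)[length(tmc)],
                tmc[length(tmc)]))

net <- build_network(corrs[corrs$feature == "mtdna_pct", ], threshold = 0.2)
write_network(net, graphml_path = file.path(out, "network_mtdna.graphml"),
              edges_path = file.path(out, "network_mtdna_edges.tsv"))
message(sprintf("coherence network: %d edges at r >= 0.2; max degree %s (%d)",
                nrow(net$edges), names(which.max(net$degree)),
                max(net$degree)))

# --- mouse-shaped enzymatic features, same machinery, no code change ---
enz <- read_feature_table(file.path(out, "data", "mouse_enzymes.tsv"))
mcls <- read.table(file.path(out, "data", "mouse_tissue_classes.tsv"),
                   header = TRUE, sep = "\t")
mbrain <- mcls$tissue[mcls$tissue_class == "brain"]
mpairs <- eligible_tissue_pairs(enz, min_shared = 10)
mco <- pairwise_structure_multi(enz, mpairs, brain_tissues = mbrain)
ms <- summarize_coherence(mco, alpha = 0.05)
message(sprintf("mouse-shaped cohort: %d pairwise comparisons (%d per feature)",
                nrow(mco), sum(mpairs$eligible)))
print(ms$summary[, c("pair_class", "n_pairs", "median_r", "pct_positive",
                     "pct_nonsig")], digits = 2)
write.table(mco, file.path(out, "mouse_correlations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ms$summary, file.path(out, "mouse_coherence_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ms$histogram, file.path(out, "mouse_coherence_histogram.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", out)
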