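#!/usr/bin/env Rscript

# Stage 1 — simulate the study cohorts.
#
# Two datasets drive the downstream analyses:
#   (a) a human-shaped multi-tissue expression cohort: 200 subjects,
#       12 brain + 10 body tissues, brain tissues loading 0.55 on a
#       shared brain factor, body tissues 0.30 on a body factor, the two
#       factors uncorrelated (no organism-wide trait); three investment
#       archetypes planted on four tissues with three archetype-linked
#       binary phenotypes; per-tissue missingness 15%, RIN drawn per
#       sample;
#   (b) a mouse-shaped enzymatic cohort: 27 animals, 17 brain regions +
#       5 peripheral tissues, five mitochondrial features (CI, CII, CIV,
#       CS, mtDNA density).
# Everything is written as plain TSV under results/data/ in the formats
# the package readers accept, together with the generator ground truth.

suppressPackageStartupMessages(library(mitocoherence))

seed <- 1234
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

panel <- tissue_panel(n_brain = 12, n_body = 10)
# regulator (PGC-1a) effects of either sign: positive in most body
# tissues, negative in a few, weakly positive in brain
panel$beta <- c(rep(0.15, 12), rep(0.5, 5), rep(-0.4, 3), rep(0, 2))
arch <- demo_archetypes(panel, high_a = "body_01", high_b = "brain_01")
cfg <- cohort_config(n_subjects = 200, tissues = panel, archetypes = arch,
                     seed = seed)
coh <- generate_cohort(cfg)

message(sprintf("cohort: %d genes x %d samples, %d subjects, %d tissues",
                nrow(coh$expression), ncol(coh$expression),
                cfg$n_subjects, nrow(panel)))
message(sprintf("archetype sizes: %s",
                paste(table(coh$truth$archetype), collapse = " / ")))

write_expression_matrix(coh$expression,
                        file.path(out, "expression.tsv.gz"))
write.table(coh$samples, file.path(out, "samples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_gene_catalog(coh$catalog, file.path(out, "gene_catalog.tsv"))
write.table(coh$clinical, file.path(out, "clinical.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- data.frame(subject_id = rownames(coh$truth$z),
                    archetype = coh$truth$archetype,
                    coh$truth$z, check.names = FALSE)
write.table(truth, file.path(out, "truth_subjects.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(panel, file.path(out, "truth_tissues.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

enz <- generate_enzymatic_cohort(seed = seed + 1)
write_feature_table(enz, file.path(out, "mouse_enzymes.tsv"))
cls <- attr(enz, "tissue_classes")
write.table(data.frame(tissue = names(cls), tissue_class = cls),
            file.path(out, "mouse_tissue_classes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("mouse-shaped cohort: %d rows x %d features",
                nrow(enz), length(feature_names(enz))))
message("wrote ", out)
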