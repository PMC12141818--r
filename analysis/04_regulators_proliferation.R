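#!/usr/bin/env Rscript

# Stage 4 — regulators and proliferation.
#
# Per tissue, correlates the nuclear-transcript percentage of PGC-1a
# (PPARGC1A), the four-gene ISR set, and the other biogenesis regulators
# (NRF1, NRF2, TFAM, POLG) with mito-nDNA% across subjects; compares the
# per-tissue coefficient profiles between regulators; and tests whether
# the within-tissue coupling of mtDNA% to mito-nDNA% increases with the
# tissue's proliferation score (the mitochondrial-dilution argument:
# dividing tissues must keep nuclear biogenesis tied to content).

suppressPackageStartupMessages(library(mitocoherence))

out <- "results"
tab <- read_feature_table(file.path(out, "index_table.tsv"))

regs <- c("PPARGC1A_pct", "ISR_pct", "NRF1_pct", "NRF2_pct", "TFAM_pct",
          "POLG_pct")
profiles <- lapply(regs, function(reg) {
  prof <- intra_tissue_association(tab, reg, "mito_ndna_pct", min_n = 10)
  write.table(prof, file.path(out, paste0("profile_", reg, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%-14s: r range [%.2f, %.2f], %d of %d tissues p < 0.05",
                  reg, min(prof$r), max(prof$r), sum(prof$p < 0.05),
                  nrow(prof)))
  prof
})
names(profiles) <- regs

cmp <- t(combn(regs, 2))
cmp_tab <- do.call(rbind, lapply(seq_len(nrow(cmp)), function(i) {
  cc <- compare_profiles(profiles[[cmp[i, 1]]], profiles[[cmp[i, 2]]])
  data.frame(profile_a = cmp[i, 1], profile_b = cmp[i, 2],
             r = cc$r, p = cc$p, n = cc$n)
}))
write.table(cmp_tab, file.path(out, "profile_comparisons.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("profile cross-comparisons: r in [%.2f, %.2f]",
                min(cmp_tab$r), max(cmp_tab$r)))

cp <- coupling_by_proliferation(tab, min_n = 10)
write.table(cp$per_tissue, file.path(out, "coupling_by_proliferation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf(
  "coupling (mtDNA%% ~ mito-nDNA%%) vs proliferation over %d tissues: meta r = %.2f, p = %.2g",
  cp$meta$n, cp$meta$r, cp$meta$p))
message("wrote ", out)
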