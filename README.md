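# mitocoherence

Do individuals with relatively high mitochondrial gene expression in one
tissue also rank high in their other tissues? `mitocoherence` is an R
package plus analysis workflow for that question — the *inter-tissue
coherence* of mitochondrial biology — aimed at anyone working with
multi-tissue, per-subject molecular data (bulk RNA-seq TPM tables,
enzymatic activity panels, mtDNA copy number, proteomics).

At its core are:

* **Transcript-based indices** per subject–tissue: mtDNA% (share of all
  transcripts of mitochondrial-genome origin, `100 Σ_{g∈M} x_g / Σ_g x_g`),
  mito-nDNA% (share of the *nuclear* transcriptome on nuclear-encoded
  mitochondrial genes, computed after removing all mtDNA transcripts),
  regulator and integrated-stress-response gene-set percentages, and a
  proliferation score (mean TPM of MKI67, TOP2A, RRM2).
* **Coherence structure**: for each eligible tissue pair (≥ 10 shared
  subjects; tissues must pair with > 50% of the others, iterated to a
  fixed point), the Spearman correlation of any feature across subjects,
  stratified into brain–brain / body–body / brain–body classes, with
  class summaries (median r, sign and significance percentages,
  fixed-bin histograms), per-tissue mean coherence, and a thresholded
  coherence network (edges at r ≥ 0.2).
* **Regulator and proliferation analyses**: per-tissue associations of
  PGC-1α%, ISR% and other regulators with mito-nDNA%; and the
  across-tissue meta-correlation of within-tissue mtDNA%↔mito-nDNA%
  coupling with tissue proliferation.
* **Subject subgroups**: z-scored log2 inter-tissue ratio features,
  seeded k-means (k-means++ initialization, best of 25 restarts), PCA
  variance, two-way type-II ANOVA with Hedges' g
  (J = 1 − 3/(4·df − 1)), and clinical-variable enrichment as z-scored
  prevalences.
* **A synthetic cohort generator** with a latent subject trait per
  tissue class: `logit(f) = logit(μ_t) + s_t(λ_t z + ε) + shift`, whose
  expected inter-tissue correlations are known in closed form
  (Pearson `λ_s λ_t / √((λ_s²+σ_s²)(λ_t²+σ_t²))`, Spearman
  `(6/π)·asin(ρ/2)`), so every pipeline stage has a recoverable target.

The methods vignette (`vignettes/multi-tissue-coherence.Rmd`) documents
the model, the parameter defaults and their rationale, and the
generator's scope.

## Worked example

```r
library(mitocoherence)

panel <- tissue_panel(n_brain = 12, n_body = 10)   # brain λ = 0.55, body λ = 0.30
coh   <- generate_cohort(cohort_config(n_subjects = 200, tissues = panel,
                                       seed = 1))
tab   <- build_index_table(coh$expression, coh$samples, coh$catalog)
pairs <- eligible_tissue_pairs(tab, min_shared = 10)
corrs <- pairwise_structure(tab, "mtdna_pct", pairs)
summarize_coherence(corrs, alpha = 0.05)$summary
```

```
   pair_class n_pairs median_r pct_positive pct_sig_positive
1 brain_brain      66    0.301          100             97.0
2   body_body      45    0.104           96             17.8
3  brain_body     120   -0.019           42              2.5
4         all     231    0.050           69             32.5
```

The 12 brain tissues share a latent factor with loading 0.55, so their
66 pairs concentrate around the analytic Spearman expectation
`(6/π)·asin(0.55²/2) = 0.290`; body tissues (loading 0.30) show weak
coherence; and brain–body pairs, whose class factors are uncorrelated
in this configuration, center on zero — the three-class signature the
coherence analysis is designed to expose.

## Analysis workflow

The numbered drivers under `analysis/` run the full study on simulated
cohorts and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R         # expression + mouse-shaped cohorts
Rscript analysis/02_mito_indices.R            # indices, tissue ranking, fold range
Rscript analysis/03_coherence_structure.R     # pair classes, summaries, network
Rscript analysis/04_regulators_proliferation.R
Rscript analysis/05_cluster_phenotypes.R      # k-means subgroups, ANOVA, clinical z
```

Each script narrates what it finds (retained samples, class medians,
network degree, meta-correlations, cluster agreement with the planted
archetypes) and every computation is a package function, so the same
steps run identically on user-supplied TSV inputs via `run_pipeline()`.

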