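#' Run the full multi-tissue coherence pipeline
#'
#' Orchestrates the stages over in-memory inputs: sample filtering,
#' index computation (skipped when a precomputed feature table is given,
#' e.g. mtDNA copy number or enzymatic activities), eligible-pair
#' enumeration, pairwise coherence structure with class stratification,
#' summary and network, regulator and proliferation analyses (when the
#' needed index columns exist), and ratio-feature clustering (when
#' requested). All tables are written as TSV under `out_dir` together
#' with a JSON manifest of resolved parameters and output checksums and
#' a plain-text log. Identical inputs and parameters produce identical
#' outputs.
#'
#' @param expression genes x samples matrix (with `samples` and
#'   `catalog`), or NULL when `feature_table` is supplied.
#' @param samples sample metadata table (required with `expression`).
#' @param catalog a [gene_catalog()] (required with `expression`).
#' @param feature_table precomputed feature table (skips the index
#'   stage); its `tissue_classes` attribute supplies pair classes.
#' @param clinical optional binary clinical table for the cluster stage.
#' @param out_dir output directory (created).
#' @param features feature columns to run the coherence stage on;
#'   default `"mito_ndna_pct"` in expression mode, all features in
#'   feature-table mode.
#' @param rin_cutoff,exclude_classes sample filters; defaults 5.5,
#'   `"cell_line"`.
#' @param min_shared,tissue_fraction pair eligibility; defaults 10, 0.5.
#' @param alpha significance level; default 0.05 (uncorrected).
#' @param threshold network edge threshold; default 0.2.
#' @param cluster NULL to skip, or a list with `feature`, `tissues`,
#'   `k` (default 3), `seed` (default 1), `n_restarts` (default 25).
#' @param regulators regulator index columns to profile against
#'   `mito_ndna_pct` (default those present among PPARGC1A_pct, ISR_pct,
#'   NRF1_pct, NRF2_pct, TFAM_pct, POLG_pct).
#' @param min_n per-tissue minimum for regulator/coupling stages.
#' @return (invisibly) a list of the in-memory stage results.
#' @export
run_pipeline <- function(expression = NULL, samples = NULL, catalog = NULL,
                         feature_table = NULL, clinical = NULL,
                         out_dir, features = NULL,
                         rin_cutoff = 5.5, exclude_classes = "cell_line",
                         min_shared = 10, tissue_fraction = 0.5,
                         alpha = 0.05, threshold = 0.2,
                         cluster = NULL, regulators = NULL, min_n = 10) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  if (is.null(expression) == is.null(feature_table))
    stop("supply exactly one of expression or feature_table", call. = FALSE)

  results <- list()
  if (!is.null(expression)) {
    if (is.null(samples) || is.null(catalog))
      stop("expression mode needs samples and catalog", call. = FALSE)
    samples <- apply_sample_filters(samples, rin_cutoff, exclude_classes)
    logf("sample filter: %d samples retained (RIN >= %s, classes != %s)",
         nrow(samples), rin_cutoff, paste(exclude_classes, collapse = ","))
    if (nrow(samples) == 0L) stop("no samples survive filtering",
                                  call. = FALSE)
    expression <- expression[, colnames(expression) %in% samples$sample_id,
                             drop = FALSE]
    table <- build_index_table(expression, samples, catalog)
    logf("index table: %d subject-tissue rows, %d features",
         nrow(table), length(feature_names(table)))
    write_feature_table(table, file.path(out_dir, "index_table.tsv"))
    if (is.null(features)) features <- "mito_ndna_pct"
  } else {
    table <- validate_feature_table(feature_table)
    if (is.null(features)) features <- feature_names(table)
    logf("feature table supplied: %d rows, features: %s",
         nrow(table), paste(features, collapse = ", "))
  }
  results$index_table <- table

  pairs <- eligible_tissue_pairs(table, min_shared, tissue_fraction)
  logf("eligible pairs: %d of %d (min_shared = %d, fraction = %s)",
       sum(pairs$eligible), nrow(pairs), min_shared, tissue_fraction)
  write.table(pairs, file.path(out_dir, "tissue_pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  results$pairs <- pairs

  cls <- attr(table, "tissue_classes")
  brain_tissues <- names(cls)[cls == "brain"]
  corrs <- pairwise_structure_multi(table, pairs,
                                    brain_tissues = brain_tissues,
                                    features = features)
  logf("coherence: %d pair correlations over %d feature(s)",
       nrow(corrs), length(features))
  write.table(corrs, file.path(out_dir, "correlations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  results$correlations <- corrs

  summ <- summarize_coherence(corrs, alpha)
  write.table(summ$summary, file.path(out_dir, "coherence_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(summ$histogram, file.path(out_dir, "coherence_histogram.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  results$summary <- summ

  tmc <- tissue_mean_coherence(corrs)
  write.table(data.frame(tissue = names(tmc), mean_r = tmc),
              file.path(out_dir, "tissue_mean_coherence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  results$tissue_mean_coherence <- tmc

  net <- build_network(corrs[corrs$feature == features[[1L]], ], threshold)
  write_network(net,
                graphml_path = file.path(out_dir, "network.graphml"),
                edges_path = file.path(out_dir, "network_edges.tsv"))
  results$network <- net
  logf("network: %d edges at r >= %s", nrow(net$edges), threshold)

  if (is.null(regulators))
    regulators <- intersect(
      c("PPARGC1A_pct", "ISR_pct", "NRF1_pct", "NRF2_pct",
        "TFAM_pct", "POLG_pct"),
      names(table))
  if ("mito_ndna_pct" %in% names(table) && length(regulators)) {
    results$regulator_profiles <- lapply(regulators, function(reg) {
      prof <- intra_tissue_association(table, reg, "mito_ndna_pct",
                                       min_n = min_n)
      write.table(prof,
                  file.path(out_dir, paste0("profile_", reg, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      prof
    })
    names(results$regulator_profiles) <- regulators
    logf("regulator profiles: %s", paste(regulators, collapse = ", "))
  }
  if (all(c("mtdna_pct", "mito_ndna_pct", "proliferation_score") %in%
          names(table))) {
    cp <- coupling_by_proliferation(table, min_n = min_n)
    write.table(cp$per_tissue,
                file.path(out_dir, "coupling_by_proliferation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$coupling <- cp
    logf("coupling vs proliferation: meta r = %.3f (p = %.3g, %d tissues)",
         cp$meta$r, cp$meta$p, cp$meta$n)
  }

  if (!is.null(cluster)) {
    feat <- cluster$feature %||% "mito_ndna_pct"
    k <- cluster$k %||% 3
    cl_seed <- cluster$seed %||% 1
    rf <- compute_ratio_features(table, feat, cluster$tissues)
    km <- kmeans_cluster(rf, k = k, seed = cl_seed,
                         n_restarts = cluster$n_restarts %||% 25)
    write.table(data.frame(subject_id = names(km$labels),
                           cluster = km$labels),
                file.path(out_dir, "cluster_assignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    pv <- pca_variance(rf)
    an <- cluster_anova(table, km$labels, cluster$tissues, feat)
    write.table(an$anova, file.path(out_dir, "cluster_anova.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(an$effect_sizes, file.path(out_dir, "cluster_effects.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$cluster <- list(ratio_features = rf, kmeans = km,
                            pca_variance = pv, anova = an)
    logf("clustering: k = %d, sizes %s, PC1+PC2 variance %.1f%%",
         k, paste(km$sizes, collapse = "/"), 100 * sum(pv[1:2]))
    if (!is.null(clinical) && ncol(clinical) > 1L) {
      ce <- clinical_enrichment(km$labels, clinical)
      write.table(data.frame(variable = rownames(ce$z), ce$z),
                  file.path(out_dir, "clinical_z.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      results$cluster$clinical <- ce
    }
  }

  manifest <- list(
    parameters = list(rin_cutoff = rin_cutoff,
                      exclude_classes = exclude_classes,
                      min_shared = min_shared,
                      tissue_fraction = tissue_fraction, alpha = alpha,
                      threshold = threshold, min_n = min_n,
                      features = features, cluster = cluster),
    outputs = as.list(tools::md5sum(
      list.files(out_dir, full.names = TRUE, pattern = "\\.(tsv|graphml)$")))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
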