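test_that("mtDNA% is the mtDNA share of all transcripts", {
  cat <- toy_catalog()
  prof <- c("MT-CO1" = 250000, "NMIT0001" = 650000, "OTH0001" = 100000)
  expect_equal(mtdna_percent(prof, cat), 25)

  # no mtDNA genes present
  expect_equal(mtdna_percent(prof[-1], cat), 0)
  expect_error(mtdna_percent(c(a = 0, b = 0), cat), "positive")

  # random 1000-gene profile against direct summation
  set.seed(3)
  genes <- sprintf("G%04d", 1:1000)
  mt <- sample(genes, 120)
  catalog <- gene_catalog(mt, setdiff(genes, mt)[1:200])
  p <- setNames(rexp(1000), genes)
  expect_equal(mtdna_percent(p, catalog), 100 * sum(p[mt]) / sum(p))
})

test_that("nuclear set percentages exclude all mtDNA transcripts", {
  cat <- toy_catalog()
  prof <- c("MT-CO1" = 500000, "NMIT0001" = 100000, "OTH0001" = 400000)
  expect_equal(nuclear_set_percent(prof, cat, "mito_nuclear"), 20)
  # a set covering every nuclear gene is 100%
  cat2 <- gene_catalog("MT-CO1", "NMIT0001",
                       named_sets = list(all_nuc = c("NMIT0001", "OTH0001")))
  expect_equal(nuclear_set_percent(prof, cat2, "all_nuc"), 100)
  # catalog error when a named set strays into the mtDNA class
  expect_error(gene_catalog("MT-CO1", "NMIT0001",
                            named_sets = list(bad = "MT-CO1")),
               "mtDNA")
  expect_error(nuclear_set_percent(prof, cat, "nope"), "unknown")

  # ISR set against the brute-force four-gene ratio
  set.seed(9)
  catalog <- default_gene_catalog()
  genes <- c(catalog$mtdna_genes, catalog$mito_nuclear_genes,
             unlist(catalog$named_sets), sprintf("OTH%04d", 1:50))
  genes <- unique(genes)
  p <- setNames(rexp(length(genes)), genes)
  nuc <- p[!names(p) %in% catalog$mtdna_genes]
  isr <- c("ATF4", "ATF5", "DDIT3", "GDF15")
  expect_equal(nuclear_set_percent(p, catalog, "ISR"),
               100 * sum(nuc[isr]) / sum(nuc))
})

test_that("proliferation score averages the three marker genes", {
  catalog <- default_gene_catalog()
  p <- c(MKI67 = 10, TOP2A = 20, RRM2 = 30, OTH0001 = 99)
  expect_equal(proliferation_score(p, catalog), 20)
  p0 <- c(MKI67 = 0, TOP2A = 0, RRM2 = 0)
  expect_equal(proliferation_score(p0, catalog), 0)
  expect_error(proliferation_score(p[-1], catalog), "MKI67")
  set.seed(2)
  p2 <- setNames(rexp(3), c("MKI67", "TOP2A", "RRM2"))
  expect_equal(proliferation_score(p2, catalog), mean(p2))
})

test_that("index table composes the per-sample operations per subject-tissue", {
  coh <- generate_cohort(cohort_config(
    n_subjects = 2, tissues = tissue_panel(n_brain = 1, n_body = 1,
                                           miss = 0), seed = 4))
  tab <- build_index_table(coh$expression, coh$samples, coh$catalog)
  expect_equal(nrow(tab), 4)
  for (i in seq_len(nrow(tab))) {
    sid <- paste(tab$subject_id[i], tab$tissue[i], sep = ".")
    prof <- coh$expression[, sid]
    expect_equal(tab$mtdna_pct[i], mtdna_percent(prof, coh$catalog))
    expect_equal(tab$mito_ndna_pct[i],
                 nuclear_set_percent(prof, coh$catalog, "mito_nuclear"))
    expect_equal(tab$proliferation_score[i],
                 proliferation_score(prof, coh$catalog))
  }

  # duplicate samples of one subject-tissue are averaged at the index level
  m <- cbind(coh$expression[, 1, drop = FALSE],
             coh$expression[, 2, drop = FALSE])
  colnames(m) <- c("dupA", "dupB")
  s <- coh$samples[1:2, ]
  s$sample_id <- c("dupA", "dupB")
  s$subject_id <- "X"; s$tissue <- "brain_01"; s$tissue_class <- "brain"
  tab2 <- build_index_table(m, s, coh$catalog)
  expect_equal(nrow(tab2), 1)
  expect_equal(tab2$mtdna_pct,
               mean(c(mtdna_percent(m[, 1], coh$catalog),
                      mtdna_percent(m[, 2], coh$catalog))))

  expect_error(build_index_table(m, s[1, ], coh$catalog), "not annotated")
})

test_that("tissue ranking by mean mtDNA% recovers the planted order", {
  pan <- tissue_panel(n_brain = 0, n_body = 6, miss = 0)
  pan$lambda <- 0; pan$sigma <- 1; pan$scale <- 0.15
  pan$mu <- c(0.05, 0.12, 0.2, 0.3, 0.45, 0.6)
  coh <- generate_cohort(cohort_config(n_subjects = 150, tissues = pan,
                                       seed = 8))
  tab <- build_index_table(coh$expression, coh$samples, coh$catalog)
  tm <- tissue_means(tab, "mtdna_pct")
  expect_identical(names(sort(tm)), pan$tissue[order(pan$mu)])
})

test_that("fold range is max over min of positive tissue means", {
  expect_equal(fold_range(c(a = 10, b = 20, c = 140)), 14)
  expect_equal(fold_range(c(a = 3, b = 3)), 1)
  expect_error(fold_range(c(a = 0, b = 1)), "positive")
  set.seed(6)
  v <- setNames(rexp(20) + 0.1, paste0("t", 1:20))
  expect_equal(fold_range(v), max(v) / min(v))
})

test_that("percentages respect conservation and scale invariance", {
  set.seed(12)
  catalog <- default_gene_catalog(n_mito_nuclear = 10, n_other = 0)
  genes <- unique(c(catalog$mtdna_genes, catalog$mito_nuclear_genes,
                    unlist(catalog$named_sets)))
  p <- setNames(rexp(length(genes)) + 0.01, genes)

  # a disjoint partition of the nuclear genes sums to 100
  nuc <- setdiff(genes, catalog$mtdna_genes)
  halves <- list(h1 = nuc[seq(1, length(nuc), 2)],
                 h2 = nuc[seq(2, length(nuc), 2)])
  cat2 <- gene_catalog(catalog$mtdna_genes, catalog$mito_nuclear_genes,
                       named_sets = halves)
  tot <- nuclear_set_percent(p, cat2, "h1") + nuclear_set_percent(p, cat2, "h2")
  expect_equal(tot, 100, tolerance = 1e-9)

  # mtDNA% plus the nuclear share of the total is 100
  nuc_share <- 100 * sum(p[nuc]) / sum(p)
  expect_equal(mtdna_percent(p, catalog) + nuc_share, 100, tolerance = 1e-9)

  # uniform rescaling leaves percentages unchanged, scales the score
  expect_equal(mtdna_percent(p * 7, catalog), mtdna_percent(p, catalog))
  expect_equal(nuclear_set_percent(p * 7, catalog, "ISR"),
               nuclear_set_percent(p, catalog, "ISR"))
  expect_equal(proliferation_score(p * 7, catalog),
               7 * proliferation_score(p, catalog))
})
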