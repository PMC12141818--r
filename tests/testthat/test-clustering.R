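test_that("ratio features are the z-scored log2 quotients of tissue pairs", {
  tab <- expand.grid(subject_id = c("A", "B", "C"),
                     tissue = c("t1", "t2", "t3", "t4"),
                     stringsAsFactors = FALSE)
  set.seed(51)
  tab$x <- rexp(nrow(tab)) + 0.5
  rf <- compute_ratio_features(tab, "x", c("t1", "t2", "t3", "t4"))
  expect_equal(ncol(rf$features), 6)
  expect_equal(nrow(rf$features), 3)
  # brute-force log2 quotient check before standardization
  w <- with(tab, tapply(x, list(subject_id, tissue), identity))
  for (cn in colnames(rf$raw)) {
    ab <- strsplit(cn, "/", fixed = TRUE)[[1]]
    expect_equal(rf$raw[, cn], log2(w[rownames(rf$raw), ab[1]] /
                                      w[rownames(rf$raw), ab[2]]))
  }
  # a subject with equal indices across tissues has all-zero raw ratios
  tab0 <- tab; tab0$x <- 3
  rf0 <- compute_ratio_features(tab0, "x", c("t1", "t2", "t3", "t4"))
  expect_true(all(rf0$raw == 0))
  expect_true(all(rf0$features == 0)) # zero-variance features pinned to 0

  # antisymmetry: swapping a pair's orientation negates the raw feature
  expect_equal(log2(w[, "t1"] / w[, "t2"]), -log2(w[, "t2"] / w[, "t1"]))

  # subjects with missing or non-positive values are dropped and logged
  tabm <- tab; tabm$x[tabm$subject_id == "B" & tabm$tissue == "t3"] <- NA
  rfm <- compute_ratio_features(tabm, "x", c("t1", "t2", "t3", "t4"))
  expect_false("B" %in% rownames(rfm$features))
  expect_equal(attr(rfm, "dropped"), "B")
})

test_that("seeded k-means recovers planted blobs and is deterministic", {
  set.seed(53)
  x <- rbind(matrix(rnorm(40 * 2, mean = 0), ncol = 2),
             matrix(rnorm(40 * 2, mean = 6), ncol = 2))
  rownames(x) <- sprintf("S%02d", 1:80)
  km <- kmeans_cluster(x, k = 2, seed = 5)
  truth <- rep(1:2, each = 40)
  expect_equal(cluster_agreement(km$labels, truth), 1)

  # bit-for-bit reproducibility and independence from the global RNG
  set.seed(999)
  km2 <- kmeans_cluster(x, k = 2, seed = 5)
  expect_identical(km, km2)

  # k = n gives singleton clusters with zero within-cluster scatter
  small <- x[1:6, ]
  kmn <- kmeans_cluster(small, k = 6, seed = 1)
  expect_equal(sort(kmn$sizes), rep(1L, 6))
  expect_equal(kmn$tot_withinss, 0)

  expect_error(kmeans_cluster(small, k = 1, seed = 1), "k must")
})

test_that("PCA variance fractions behave like covariance eigenvalues", {
  set.seed(57)
  # rank-1 data: first component carries everything
  u <- rnorm(50)
  x1 <- cbind(u, 2 * u, -u)
  expect_equal(pca_variance(x1)[1], 1)
  # fractions always sum to 1 and are non-increasing
  x <- matrix(rnorm(200 * 5), ncol = 5)
  v <- pca_variance(x)
  expect_equal(sum(v), 1)
  expect_true(all(diff(v) <= 1e-12))
  # isotropic noise spreads variance about evenly
  xi <- matrix(rnorm(4000 * 4), ncol = 4)
  expect_true(all(abs(pca_variance(xi) - 0.25) < 0.03))
})

test_that("Hedges' g applies the small-sample correction J = 1 - 3/(4 df - 1)", {
  # mean difference -2, pooled SD 1, df = 4, J = 1 - 3/15
  expect_equal(hedges_g(c(1, 2, 3), c(3, 4, 5)), -1.6)
  expect_equal(hedges_g(c(3, 4, 5), c(1, 2, 3)), 1.6)
  expect_true(is.na(hedges_g(c(2, 2), c(2, 2))))
  expect_error(hedges_g(1, 1:3), "at least 2")
})

test_that("two-way cluster ANOVA separates cluster, tissue and interaction", {
  set.seed(59)
  n_per <- 50
  make_tab <- function(interaction_shift) {
    d <- expand.grid(subject_id = sprintf("S%03d", 1:(2 * n_per)),
                     tissue = c("t1", "t2"), stringsAsFactors = FALSE)
    cl <- rep(rep(1:2, each = n_per), 2)
    d$mito_ndna_pct <- rnorm(nrow(d)) +
      interaction_shift * (cl == 2 & d$tissue == "t2")
    list(tab = d, labels = setNames(rep(rep(1:2, each = n_per), 1),
                                    sprintf("S%03d", 1:(2 * n_per))))
  }
  # no effect anywhere: cluster F small, g near 0
  null <- make_tab(0)
  a0 <- cluster_anova(null$tab, null$labels, c("t1", "t2"))
  expect_gt(a0$anova$p[a0$anova$term == "cluster"], 0.05)
  expect_true(all(abs(a0$effect_sizes$g) < 0.5))

  # planted 1-SD shift in one tissue only: interaction is significant
  alt <- make_tab(1)
  a1 <- cluster_anova(alt$tab, alt$labels, c("t1", "t2"))
  expect_lt(a1$anova$p[a1$anova$term == "cluster:tissue"], 0.05)
  g_t2 <- a1$effect_sizes$g[a1$effect_sizes$tissue == "t2"]
  expect_lt(g_t2, -0.5) # cluster 1 minus cluster 2

  # exact g for identical groups
  same <- data.frame(subject_id = rep(sprintf("S%02d", 1:4), 1),
                     tissue = "t1", mito_ndna_pct = c(1, 2, 1, 2))
  lab <- setNames(c(1, 1, 2, 2), sprintf("S%02d", 1:4))
  as <- cluster_anova(same, lab, "t1")
  expect_equal(as$effect_sizes$g, 0)
})

test_that("clinical z-scores use the population SD across clusters", {
  lab <- setNames(rep(1:3, each = 10), sprintf("S%02d", 1:30))
  clin <- data.frame(subject_id = sprintf("S%02d", 1:30),
                     flat = rep(1, 30),
                     graded = rep(c(0, NA, 1), each = 10))
  clin$graded[11:20] <- rep(c(0, 1), 5) # 50% in cluster 2
  ce <- clinical_enrichment(lab, clin)
  expect_equal(unname(ce$z["flat", ]), c(0, 0, 0))
  expect_equal(unname(ce$percent["graded", ]), c(0, 50, 100))
  expect_equal(unname(ce$z["graded", ]),
               c(-1.224745, 0, 1.224745), tolerance = 1e-6)

  # a variable entirely missing in one cluster is flagged undefined
  clin$gap <- clin$graded
  clin$gap[1:10] <- NA
  ce2 <- clinical_enrichment(lab, clin)
  expect_true(all(is.na(ce2$z["gap", ])))

  expect_error(clinical_enrichment(lab, transform(clin, bad = 1:30)),
               "not binary")
})

test_that("planted archetypes are recovered end-to-end", {
  pan <- four_tissue_panel()
  arch <- demo_archetypes(pan, high_a = "muscle", high_b = "cortex")
  coh <- generate_cohort(cohort_config(n_subjects = 120, tissues = pan,
                                       archetypes = arch, seed = 61))
  tab <- build_index_table(coh$expression, coh$samples, coh$catalog)
  rf <- compute_ratio_features(tab, "mito_ndna_pct", pan$tissue)
  km <- kmeans_cluster(rf, k = 3, seed = 2)
  truth <- setNames(coh$truth$archetype, rownames(coh$truth$z))
  expect_gt(cluster_agreement(km$labels, truth), 0.9)
  # planted sizes are recovered within 10%
  expect_true(all(abs(sort(km$sizes) - sort(table(truth))) <= 12))
  # the cluster factor separates the index values
  an <- cluster_anova(tab, km$labels, pan$tissue)
  expect_lt(an$anova$p[an$anova$term == "cluster:tissue"], 0.05)
})
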