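test_that("spearman matches the classic rank-difference formula and cor.test", {
  expect_equal(spearman_rp(1:3, 1:3)$r, 1)
  expect_equal(spearman_rp(1:3, 1:3)$p, 0)
  expect_equal(spearman_rp(1:3, 3:1)$r, -1)
  # n = 5 with sum of squared rank differences 4: r = 1 - 6*4/(5*24)
  expect_equal(spearman_rp(1:5, c(2, 1, 4, 3, 5))$r, 0.8)

  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- 0.4 * x + rnorm(n)
    if (i %% 2 == 0) { # introduce ties
      x <- round(x, 1); y <- round(y, 1)
    }
    got <- spearman_rp(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE))
    expect_equal(got$r, unname(ref$estimate))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("spearman is symmetric, monotone-invariant, and NA-aware", {
  set.seed(13)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(spearman_rp(x, y)$r, spearman_rp(y, x)$r)
  expect_equal(spearman_rp(exp(x), y)$r, spearman_rp(x, y)$r)
  expect_equal(spearman_rp(x, y^3 + 5)$r, spearman_rp(x, y)$r)

  x[c(2, 7)] <- NA
  ref <- spearman_rp(x[-c(2, 7)], y[-c(2, 7)])
  expect_equal(spearman_rp(x, y)$r, ref$r)
  expect_equal(spearman_rp(x, y)$n, 28)

  expect_false(spearman_rp(1:2, 2:1)$ok)
  expect_false(spearman_rp(c(1, 1, 1), 1:3)$ok)
})

test_that("pairwise structure yields one classified row per eligible pair", {
  avail <- matrix(TRUE, 30, 5, dimnames = list(sprintf("S%02d", 1:30),
                                               c("b1", "b2", "t1", "t2", "t3")))
  set.seed(17)
  tab <- feature_table_from_matrix(avail, values = rnorm(150))
  pe <- eligible_tissue_pairs(tab, min_shared = 10)
  co <- pairwise_structure(tab, "x", pe, brain_tissues = c("b1", "b2"))
  expect_equal(nrow(co), 10)
  expect_equal(sum(co$pair_class == "brain_brain"), 1)
  expect_equal(sum(co$pair_class == "brain_body"), 6)
  expect_equal(sum(co$pair_class == "body_body"), 3)
  expect_true(all(co$n == 30))
  expect_true(all(co$r >= -1 & co$r <= 1))

  # five features over the same pairs pool to 50 comparisons
  tab5 <- tab
  for (f in c("x2", "x3", "x4", "x5")) tab5[[f]] <- rnorm(150)
  multi <- pairwise_structure_multi(tab5, pe, brain_tissues = c("b1", "b2"))
  expect_equal(nrow(multi), 50)

  # a constant feature in one tissue is skipped, not fabricated
  tabc <- tab
  tabc$x[tabc$tissue == "t1"] <- 1
  coc <- pairwise_structure(tabc, "x", pe, brain_tissues = c("b1", "b2"))
  expect_equal(nrow(coc), 6)
  expect_length(attr(coc, "skipped"), 4)
})

test_that("coherence summaries report medians, sign and significance shares", {
  co <- data.frame(tissue_a = "a", tissue_b = c("b", "c", "d"),
                   feature = "x", r = c(0.2, 0.3, -0.1),
                   p = c(0.01, 0.2, 0.6), n = 20,
                   pair_class = "body_body")
  s <- summarize_coherence(co, alpha = 0.05)$summary
  bb <- s[s$pair_class == "body_body", ]
  expect_equal(bb$median_r, 0.2)
  expect_equal(bb$pct_positive, 200 / 3)
  expect_equal(bb$pct_sig_positive, 100 / 3)
  expect_equal(bb$pct_nonsig, 200 / 3)

  # an empty class is reported with count 0 and undefined statistics
  expect_equal(s[s$pair_class == "brain_brain", ]$n_pairs, 0)
  expect_true(is.na(s[s$pair_class == "brain_brain", ]$median_r))

  # everything significant-positive
  co2 <- transform(co, p = 0.001, r = abs(r))
  bb2 <- summarize_coherence(co2)$summary
  bb2 <- bb2[bb2$pair_class == "body_body", ]
  expect_equal(bb2$pct_sig_positive, 100)

  # histogram counts conserve the number of pairs, bins of width 0.1
  h <- summarize_coherence(co)$histogram
  hb <- h[h$pair_class == "body_body", ]
  expect_equal(sum(hb$count), 3)
  expect_equal(hb$bin_hi - hb$bin_lo, rep(0.1, 20))

  # permutation invariance
  s2 <- summarize_coherence(co[c(3, 1, 2), ])$summary
  expect_equal(s2, s)
})

test_that("per-tissue mean coherence equals the incident-edge mean", {
  co <- data.frame(tissue_a = c("a", "a"), tissue_b = c("b", "c"),
                   feature = "x", r = c(0.1, 0.3), p = 0.5, n = 10,
                   pair_class = "body_body")
  tm <- tissue_mean_coherence(co)
  expect_equal(tm[["a"]], 0.2)
  expect_equal(tm[["b"]], 0.1)

  single <- co[1, ]
  tm1 <- tissue_mean_coherence(single)
  expect_equal(unname(tm1[c("a", "b")]), c(0.1, 0.1))

  set.seed(23)
  tis <- paste0("t", 1:8)
  prs <- t(combn(tis, 2))
  rnd <- data.frame(tissue_a = prs[, 1], tissue_b = prs[, 2], feature = "x",
                    r = runif(nrow(prs), -1, 1), p = 0.5, n = 10,
                    pair_class = "body_body")
  tmr <- tissue_mean_coherence(rnd)
  for (t in tis) {
    ref <- mean(rnd$r[rnd$tissue_a == t | rnd$tissue_b == t])
    expect_equal(tmr[[t]], ref)
  }
})

test_that("the coherence network thresholds edges at r >= cutoff", {
  co <- data.frame(tissue_a = c("a", "a", "b"), tissue_b = c("b", "c", "c"),
                   feature = "x", r = c(0.25, 0.1, -0.4), p = 0.5, n = 10,
                   pair_class = "body_body")
  net <- build_network(co, threshold = 0.2)
  expect_equal(nrow(net$edges), 1)
  expect_equal(unname(net$degree[c("a", "b", "c")]), c(1, 1, 0))

  expect_equal(nrow(build_network(co, threshold = 0.99)$edges), 0)

  set.seed(29)
  tis <- paste0("t", 1:10)
  prs <- t(combn(tis, 2))
  rnd <- data.frame(tissue_a = prs[, 1], tissue_b = prs[, 2], feature = "x",
                    r = runif(nrow(prs), -1, 1), p = 0.5, n = 10,
                    pair_class = "body_body")
  net2 <- build_network(rnd, 0.2)
  expect_equal(nrow(net2$edges), sum(rnd$r >= 0.2))
  for (t in tis) {
    ref <- sum((rnd$tissue_a == t | rnd$tissue_b == t) & rnd$r >= 0.2)
    expect_equal(unname(net2$degree[t]), ref)
  }

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net2, graphml_path = gml)
  expect_true(file.exists(gml))
  reread <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(reread), nrow(net2$edges))
})
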