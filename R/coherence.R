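#' Spearman rank correlation with a t-approximation p-value
#'
#' Pairs with a missing value in either vector are dropped; mid-ranks
#' (average ranks) are used for ties; r is the Pearson correlation of the
#' ranks. The two-sided p-value uses the t approximation with n - 2
#' degrees of freedom; |r| = 1 gives p = 0.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p`, `n`, and `ok` (FALSE when n < 3 or a rank
#'   variance is zero, in which case the correlation is undefined and the
#'   pair should be skipped).
#' @export
spearman_rp <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L)
    return(list(r = NA_real_, p = NA_real_, n = n, ok = FALSE))
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, ok = FALSE))
  r <- cor(rx, ry)
  if (abs(r) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n, ok = TRUE)
}

#' Classify a tissue pair
#'
#' @param tissue_a,tissue_b tissue names.
#' @param brain_tissues character vector of brain tissues.
#' @return `"brain_brain"`, `"brain_body"`, or `"body_body"`.
#' @export
classify_pair <- function(tissue_a, tissue_b, brain_tissues) {
  nb <- (tissue_a %in% brain_tissues) + (tissue_b %in% brain_tissues)
  c("body_body", "brain_body", "brain_brain")[nb + 1L]
}

#' Pairwise inter-tissue correlation structure of a feature
#'
#' For each eligible tissue pair, correlates the feature across the
#' subjects measured in both tissues (Spearman), and classifies the pair
#' as brain-brain, brain-body, or body-body. Pairs whose correlation is
#' undefined (fewer than 3 complete subjects, zero rank variance) are
#' skipped and recorded in `attr(, "skipped")`.
#'
#' @param table feature table.
#' @param feature feature column to correlate.
#' @param pairs output of [eligible_tissue_pairs()] (its eligible rows
#'   are used), or any data.frame with `tissue_a`, `tissue_b`.
#' @param brain_tissues tissues of class brain; defaults to the
#'   `tissue_classes` attribute of `table` if present.
#' @return data.frame: `tissue_a`, `tissue_b`, `feature`, `r`, `p`, `n`,
#'   `pair_class`.
#' @export
pairwise_structure <- function(table, feature, pairs,
                               brain_tissues = NULL) {
  if (!feature %in% names(table))
    stop("feature '", feature, "' not in table", call. = FALSE)
  if (is.null(brain_tissues)) {
    cls <- attr(table, "tissue_classes")
    brain_tissues <- names(cls)[cls == "brain"]
  }
  if ("eligible" %in% names(pairs))
    pairs <- pairs[pairs$eligible, , drop = FALSE]
  wide <- feature_wide(table, feature)
  res <- vector("list", nrow(pairs))
  skipped <- character(0)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$tissue_a[i]; b <- pairs$tissue_b[i]
    s <- spearman_rp(wide[, a], wide[, b])
    if (!s$ok) {
      skipped <- c(skipped, paste(a, b, sep = " ~ "))
      next
    }
    res[[i]] <- data.frame(
      tissue_a = a, tissue_b = b, feature = feature,
      r = s$r, p = s$p, n = s$n,
      pair_class = classify_pair(a, b, brain_tissues),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(tissue_a = character(), tissue_b = character(),
                      feature = character(), r = numeric(), p = numeric(),
                      n = integer(), pair_class = character())
  rownames(out) <- NULL
  structure(out, skipped = skipped)
}

# subject x tissue wide matrix of one feature
feature_wide <- function(table, feature) {
  subjects <- unique(table$subject_id)
  tissues <- unique(table$tissue)
  m <- matrix(NA_real_, length(subjects), length(tissues),
              dimnames = list(subjects, tissues))
  m[cbind(match(table$subject_id, subjects),
          match(table$tissue, tissues))] <- table[[feature]]
  m
}

#' Correlation structure across several features
#'
#' Runs [pairwise_structure()] once per feature over the same eligible
#' pairs and pools the rows — the mouse enzymatic mode, where each
#' mitochondrial feature (CI, CII, CIV, CS, mtDNA density) contributes
#' one correlation per tissue pair.
#'
#' @inheritParams pairwise_structure
#' @param features feature columns; default all of them.
#' @return pooled long data.frame as in [pairwise_structure()].
#' @export
pairwise_structure_multi <- function(table, pairs, brain_tissues = NULL,
                                     features = feature_names(table)) {
  out <- lapply(features, pairwise_structure, table = table, pairs = pairs,
                brain_tissues = brain_tissues)
  do.call(rbind, out)
}

#' Summarize a coherence structure by pair class
#'
#' Per pair class (and pooled over all pairs, class `"all"`): median r,
#' pair count, percentage of positive / negative r, percentage
#' significant-positive / significant-negative at the uncorrected
#' two-sided level `alpha`, percentage not different from 0 (p >= alpha),
#' plus a histogram of r over fixed bins of width 0.1 on \[-1, 1\].
#'
#' @param corrs output of [pairwise_structure()] (any number of features).
#' @param alpha significance level; default 0.05, uncorrected.
#' @return list with `summary` (one row per class) and `histogram`
#'   (class, bin_lo, bin_hi, count).
#' @export
summarize_coherence <- function(corrs, alpha = 0.05) {
  if (nrow(corrs) == 0L)
    stop("no correlations to summarize", call. = FALSE)
  classes <- c("brain_brain", "body_body", "brain_body")
  groups <- c(setNames(lapply(classes, function(cl)
    corrs[corrs$pair_class == cl, , drop = FALSE]), classes),
    list(all = corrs))
  summ <- do.call(rbind, lapply(names(groups), function(cl) {
    g <- groups[[cl]]
    k <- nrow(g)
    if (k == 0L)
      return(data.frame(pair_class = cl, n_pairs = 0L, median_r = NA_real_,
                        pct_positive = NA_real_, pct_negative = NA_real_,
                        pct_sig_positive = NA_real_,
                        pct_sig_negative = NA_real_,
                        pct_nonsig = NA_real_))
    data.frame(
      pair_class = cl, n_pairs = k,
      median_r = median(g$r),
      pct_positive = 100 * mean(g$r > 0),
      pct_negative = 100 * mean(g$r < 0),
      pct_sig_positive = 100 * mean(g$r > 0 & g$p < alpha),
      pct_sig_negative = 100 * mean(g$r < 0 & g$p < alpha),
      pct_nonsig = 100 * mean(g$p >= alpha))
  }))
  edges <- seq(-1, 1, by = 0.1)
  hist_df <- do.call(rbind, lapply(names(groups), function(cl) {
    g <- groups[[cl]]
    counts <- if (nrow(g)) {
      tabulate(findInterval(g$r, edges, rightmost.closed = TRUE),
               nbins = length(edges) - 1L)
    } else integer(length(edges) - 1L)
    data.frame(pair_class = cl, bin_lo = edges[-length(edges)],
               bin_hi = edges[-1L], count = counts)
  }))
  list(summary = summ, histogram = hist_df)
}

#' Mean inter-tissue correlation of each tissue
#'
#' For each tissue, the arithmetic mean of r over all pairs that contain
#' it — how coherent that tissue is with the rest of the organism.
#'
#' @param corrs output of [pairwise_structure()].
#' @return named numeric vector, tissue -> mean r, sorted decreasing.
#' @export
tissue_mean_coherence <- function(corrs) {
  if (nrow(corrs) == 0L) stop("empty correlation table", call. = FALSE)
  long <- data.frame(tissue = c(corrs$tissue_a, corrs$tissue_b),
                     r = c(corrs$r, corrs$r))
  v <- tapply(long$r, long$tissue, mean)
  sort(setNames(as.numeric(v), names(v)), decreasing = TRUE)
}

#' Threshold the correlation structure into a coherence network
#'
#' Tissues are nodes; an edge joins each pair with r at or above the
#' threshold (default 0.2), weighted by r. Node degree counts incident
#' edges.
#'
#' @param corrs output of [pairwise_structure()] for one feature.
#' @param threshold edge threshold in (-1, 1); default 0.2.
#' @return list with `graph` (an igraph object), `edges` (data.frame),
#'   and `degree` (named integer vector over all tissues, including
#'   isolated ones).
#' @export
build_network <- function(corrs, threshold = 0.2) {
  stopifnot(threshold > -1, threshold < 1)
  tissues <- sort(unique(c(corrs$tissue_a, corrs$tissue_b)))
  keep <- corrs$r >= threshold
  edges <- corrs[keep, c("tissue_a", "tissue_b", "r"), drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$tissue_a, to = edges$tissue_b,
                   weight = edges$r),
    directed = FALSE,
    vertices = data.frame(name = tissues))
  list(graph = g, edges = edges,
       degree = igraph::degree(g)[tissues])
}

#' Export a coherence network as GraphML and an edge list
#'
#' @param network output of [build_network()].
#' @param graphml_path,edges_path output paths (either may be NULL).
#' @export
write_network <- function(network, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  if (!is.null(edges_path))
    write.table(network$edges, edges_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(network)
}
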