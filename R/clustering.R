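#' Inter-tissue log-ratio features
#'
#' For every subject with complete, strictly positive values of `feature`
#' across the selected tissues, computes one feature per unordered tissue
#' pair: `log2(index_a / index_b)` with a < b lexicographically, then
#' z-scores each feature across subjects (sample SD). Subjects with a
#' missing or non-positive index in any selected tissue are dropped and
#' listed in `attr(, "dropped")`.
#'
#' @param table index feature table.
#' @param feature feature column (e.g. `"mito_ndna_pct"`).
#' @param tissues at least two tissue names.
#' @return list with `features` (subjects x C(T,2) z-scored matrix),
#'   `raw` (same before z-scoring), `subjects`, `tissues`, `pairs`.
#' @export
compute_ratio_features <- function(table, feature, tissues) {
  if (length(tissues) < 2L)
    stop("need at least two tissues", call. = FALSE)
  wide <- feature_wide(table, feature)
  miss <- setdiff(tissues, colnames(wide))
  if (length(miss))
    stop("tissue(s) absent from table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  wide <- wide[, tissues, drop = FALSE]
  ok <- apply(wide, 1L, function(v) all(is.finite(v) & v > 0))
  dropped <- rownames(wide)[!ok]
  wide <- wide[ok, , drop = FALSE]
  if (nrow(wide) == 0L)
    stop("no subject has complete positive data across the selected tissues",
         call. = FALSE)
  prs <- combn(sort(tissues), 2L)
  raw <- matrix(NA_real_, nrow(wide), ncol(prs),
                dimnames = list(rownames(wide),
                                paste(prs[1L, ], prs[2L, ], sep = "/")))
  for (j in seq_len(ncol(prs)))
    raw[, j] <- log2(wide[, prs[1L, j]] / wide[, prs[2L, j]])
  z <- scale(raw)
  z[, attr(z, "scaled:scale") == 0] <- 0
  feats <- z[, , drop = FALSE]
  attributes(feats)[c("scaled:center", "scaled:scale")] <- NULL
  structure(list(features = feats, raw = raw,
                 subjects = rownames(wide), tissues = sort(tissues),
                 pairs = colnames(raw)),
            dropped = dropped)
}

#' Seeded k-means with k-means++ initialization and restarts
#'
#' Lloyd's algorithm on squared Euclidean distance, initialized by
#' k-means++ sampling; the best of `n_restarts` runs by total
#' within-cluster sum of squares is kept. A restart that produces an
#' empty cluster is re-seeded. Bit-for-bit reproducible for a given
#' `seed` and `n_restarts`.
#'
#' @param features numeric matrix (subjects x features) or the list
#'   returned by [compute_ratio_features()].
#' @param k number of clusters (2 <= k <= subjects); default 3.
#' @param seed integer RNG seed.
#' @param n_restarts independent initializations; default 25.
#' @return list with `labels` (named integer vector), `centers`,
#'   `tot_withinss`, `sizes`, `k`.
#' @export
kmeans_cluster <- function(features, k = 3, seed = 1, n_restarts = 25) {
  x <- if (is.list(features) && !is.null(features$features))
    features$features else as.matrix(features)
  n <- nrow(x)
  if (k < 2 || k > n)
    stop("k must satisfy 2 <= k <= number of subjects", call. = FALSE)
  stopifnot(n_restarts >= 1)
  best <- NULL
  with_preserved_seed(seed, {
    for (rep in seq_len(n_restarts)) {
      fit <- NULL
      for (attempt in 1:20) {
        centers <- kmeanspp_init(x, k)
        fit <- tryCatch(
          suppressWarnings(kmeans(x, centers = centers,
                                  algorithm = "Lloyd", iter.max = 100L)),
          error = function(e) NULL)
        if (!is.null(fit) && all(fit$size > 0L)) break
        fit <- NULL
      }
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss)
        best <- fit
    }
  })
  if (is.null(best))
    stop("k-means failed to produce a non-degenerate clustering",
         call. = FALSE)
  list(labels = setNames(as.integer(best$cluster), rownames(x)),
       centers = best$centers,
       tot_withinss = best$tot.withinss,
       sizes = as.integer(best$size), k = k)
}

# k-means++ center sampling (Arthur & Vassilvitskii style)
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums((x - rep(centers[1L, ], each = n))^2)
  for (j in 2:k) {
    if (all(d2 == 0)) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2 / sum(d2))
    }
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - rep(centers[j, ], each = n))^2))
  }
  centers
}

# run code with a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
  invisible(NULL)
}

#' Fractions of variance along principal components
#'
#' Eigenvalue fractions of the (column-centered) feature covariance,
#' in decreasing order; they sum to 1.
#'
#' @param features numeric matrix or [compute_ratio_features()] output.
#' @return numeric vector of variance fractions.
#' @export
pca_variance <- function(features) {
  x <- if (is.list(features) && !is.null(features$features))
    features$features else as.matrix(features)
  if (ncol(x) < 2L || nrow(x) < 3L)
    stop("need at least 2 features and 3 subjects", call. = FALSE)
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  if (sum(v) == 0) stop("zero total variance", call. = FALSE)
  v / sum(v)
}

#' Hedges' g standardized mean difference
#'
#' `g = J * (mean(x) - mean(y)) / s_pooled` with the small-sample bias
#' correction `J = 1 - 3 / (4 * df - 1)`, `df = n1 + n2 - 2`. Undefined
#' (NA) when the pooled variance is zero.
#'
#' @param x,y numeric vectors (the two groups).
#' @return scalar g.
#' @export
hedges_g <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  if (sp2 == 0) return(NA_real_)
  (1 - 3 / (4 * df - 1)) * (mean(x) - mean(y)) / sqrt(sp2)
}

#' Two-way ANOVA of an index across clusters and tissues
#'
#' Fixed-effects ANOVA of the index value on cluster, tissue and their
#' interaction (type II sums of squares), plus Hedges' g for each cluster
#' pair within each tissue.
#'
#' @param table index feature table.
#' @param labels named integer vector (subject -> cluster) from
#'   [kmeans_cluster()].
#' @param tissues tissues to include.
#' @param feature index column; default `"mito_ndna_pct"`.
#' @return list with `anova` (data.frame: term, sum_sq, df, F, p),
#'   `effect_sizes` (tissue, cluster_a, cluster_b, g), and `cell_means`
#'   (tissue x cluster means).
#' @export
cluster_anova <- function(table, labels, tissues,
                          feature = "mito_ndna_pct") {
  sub <- table[table$tissue %in% tissues &
                 table$subject_id %in% names(labels), , drop = FALSE]
  d <- data.frame(
    value = sub[[feature]],
    cluster = factor(labels[sub$subject_id]),
    tissue = factor(sub$tissue))
  d <- d[is.finite(d$value), , drop = FALSE]
  if (nlevels(droplevels(d$cluster)) < 2L)
    stop("need at least 2 clusters with data", call. = FALSE)
  fit <- if (nlevels(droplevels(d$tissue)) > 1L)
    lm(value ~ cluster * tissue, data = d) else lm(value ~ cluster, data = d)
  a2 <- car::Anova(fit, type = 2)
  anova_df <- data.frame(
    term = rownames(a2),
    sum_sq = a2[["Sum Sq"]],
    df = a2[["Df"]],
    F = a2[["F value"]],
    p = a2[["Pr(>F)"]],
    row.names = NULL)

  ks <- sort(unique(as.integer(as.character(d$cluster))))
  eff <- list()
  for (tis in levels(d$tissue)) {
    for (i in seq_along(ks)) for (j in seq_along(ks)) {
      if (i >= j) next
      xi <- d$value[d$tissue == tis & d$cluster == ks[i]]
      xj <- d$value[d$tissue == tis & d$cluster == ks[j]]
      if (length(xi) < 2L || length(xj) < 2L) next
      eff[[length(eff) + 1L]] <- data.frame(
        tissue = tis, cluster_a = ks[i], cluster_b = ks[j],
        g = hedges_g(xi, xj), stringsAsFactors = FALSE)
    }
  }
  cell <- tapply(d$value, list(d$tissue, d$cluster), mean)
  list(anova = anova_df,
       effect_sizes = do.call(rbind, eff),
       cell_means = cell)
}

#' Clinical-variable enrichment of clusters
#'
#' For each binary clinical variable, the percentage of positive subjects
#' per cluster (among non-missing), z-scored across the k cluster values
#' within each variable using the population (n-denominator) SD. A
#' variable with equal prevalence in all clusters gives all-zero z; a
#' variable entirely missing in some cluster gives NA for that cell.
#'
#' @param labels named integer vector, subject -> cluster.
#' @param clinical data.frame with `subject_id` and 0/1 (or NA) columns.
#' @return list with `percent` and `z` matrices (variable x cluster).
#' @export
clinical_enrichment <- function(labels, clinical) {
  if (!"subject_id" %in% names(clinical))
    stop("clinical table needs a subject_id column", call. = FALSE)
  vars <- setdiff(names(clinical), "subject_id")
  clinical <- clinical[clinical$subject_id %in% names(labels), , drop = FALSE]
  cl <- labels[clinical$subject_id]
  ks <- sort(unique(as.integer(labels)))
  pct <- matrix(NA_real_, length(vars), length(ks),
                dimnames = list(vars, paste0("cluster_", ks)))
  for (v in vars) {
    x <- clinical[[v]]
    bad <- stats::na.omit(unique(x[!x %in% c(0, 1)]))
    if (length(bad))
      stop("clinical variable '", v, "' is not binary", call. = FALSE)
    for (i in seq_along(ks)) {
      xi <- x[cl == ks[i]]
      xi <- xi[!is.na(xi)]
      if (length(xi)) pct[v, i] <- 100 * mean(xi)
    }
  }
  z <- t(apply(pct, 1L, function(row) {
    if (anyNA(row)) return(rep(NA_real_, length(row)))
    s <- sqrt(mean((row - mean(row))^2))
    if (s == 0) rep(0, length(row)) else (row - mean(row)) / s
  }))
  dimnames(z) <- dimnames(pct)
  list(percent = pct, z = z)
}

#' Best label agreement up to cluster permutation
#'
#' Fraction of subjects on which two labelings agree under the best
#' relabeling of one of them (all permutations are scanned; intended for
#' small k).
#'
#' @param labels,truth integer vectors (same order or both named).
#' @return agreement fraction in \[0, 1\].
#' @export
cluster_agreement <- function(labels, truth) {
  if (!is.null(names(labels)) && !is.null(names(truth)))
    truth <- truth[names(labels)]
  stopifnot(length(labels) == length(truth))
  ks <- sort(unique(as.integer(truth)))
  ls <- sort(unique(as.integer(labels)))
  if (length(ls) > 8L) stop("too many clusters to permute", call. = FALSE)
  perms <- permutations_of(ks)
  best <- 0
  for (p in perms) {
    relab <- p[match(as.integer(labels), ls)]
    best <- max(best, mean(relab == as.integer(truth), na.rm = TRUE))
  }
  best
}

permutations_of <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permutations_of(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}
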