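#' Per-tissue parameter panel for synthetic cohorts
#'
#' Builds the tissue table a [cohort_config()] consumes. Each tissue
#' carries: its class (`brain`/`body`), mean mtDNA transcript fraction
#' `mu`, mean nuclear-mito fraction `nu`, coherence loading `lambda` on
#' its class latent factor, residual noise SD `sigma` (default chosen so
#' the latent deviate has unit variance, `sigma = sqrt(1 - lambda^2)`),
#' logit-scale amplitude `scale` controlling biological spread,
#' proliferation parameter `prolif` in \[0, 1\] (drives both the
#' proliferation-gene level and the mtDNA-nuclear coupling),
#' regulator effect `beta` in \[-1, 1\], and per-subject missingness
#' probability `miss`.
#'
#' Defaults emulate the observed study conditions: brain tissues load
#' more strongly on their shared factor (lambda 0.55, expected
#' brain-brain Pearson ~0.30) than body tissues (lambda 0.30, expected
#' body-body Pearson ~0.09); brain mtDNA fractions are high (45-70% of
#' transcripts), body fractions span 5-40%; nuclear-mito fractions sit
#' near 5-12% of the nuclear transcriptome; body tissues span the
#' proliferation range while brain is post-mitotic.
#'
#' @param n_brain,n_body tissue counts per class.
#' @param brain_lambda,body_lambda class loadings.
#' @param sigma residual SD; default `sqrt(1 - lambda^2)` per tissue.
#' @param scale logit-scale amplitude; default 0.5.
#' @param miss missingness probability per subject-tissue; default 0.15.
#' @param beta regulator effect, recycled across tissues; default 0.
#' @return data.frame with one row per tissue.
#' @export
tissue_panel <- function(n_brain = 12, n_body = 10,
                         brain_lambda = 0.55, body_lambda = 0.30,
                         sigma = NULL, scale = 0.5, miss = 0.15,
                         beta = 0) {
  tissue <- c(sprintf("brain_%02d", seq_len(n_brain)),
              sprintf("body_%02d", seq_len(n_body)))
  cls <- rep(c("brain", "body"), c(n_brain, n_body))
  lambda <- rep(c(brain_lambda, body_lambda), c(n_brain, n_body))
  if (is.null(sigma)) sigma <- sqrt(1 - lambda^2)
  panel <- data.frame(
    tissue = tissue,
    tissue_class = cls,
    mu = c(seq(0.45, 0.70, length.out = max(n_brain, 2L))[seq_len(n_brain)],
           seq(0.05, 0.40, length.out = max(n_body, 2L))[seq_len(n_body)]),
    nu = c(rep(0.08, n_brain),
           seq(0.05, 0.12, length.out = max(n_body, 2L))[seq_len(n_body)]),
    lambda = lambda,
    sigma = rep(sigma, length.out = n_brain + n_body),
    scale = rep(scale, length.out = n_brain + n_body),
    prolif = c(rep(0.05, n_brain),
               seq(0.10, 0.90, length.out = max(n_body, 2L))[seq_len(n_body)]),
    beta = rep(beta, length.out = n_brain + n_body),
    miss = rep(miss, length.out = n_brain + n_body),
    stringsAsFactors = FALSE)
  rownames(panel) <- NULL
  panel
}

#' Archetype (cluster) specification for synthetic cohorts
#'
#' Defines k subject archetypes with mixing proportions, per-tissue
#' logit-scale shifts of mitochondrial investment, and per-archetype
#' probabilities of binary clinical phenotypes.
#'
#' @param shifts k x T numeric matrix; colnames are tissue names
#'   (tissues not listed get shift 0).
#' @param proportions length-k mixing proportions; default uniform.
#' @param phenotype_probs k x V matrix of Bernoulli probabilities with
#'   phenotype names as colnames; may be NULL.
#' @return list of class `archetype_spec`.
#' @export
archetype_spec <- function(shifts, proportions = NULL,
                           phenotype_probs = NULL) {
  shifts <- as.matrix(shifts)
  k <- nrow(shifts)
  if (is.null(proportions)) proportions <- rep(1 / k, k)
  stopifnot(length(proportions) == k, all(proportions > 0))
  if (!is.null(phenotype_probs)) {
    phenotype_probs <- as.matrix(phenotype_probs)
    stopifnot(nrow(phenotype_probs) == k,
              all(phenotype_probs >= 0 & phenotype_probs <= 1))
  }
  structure(list(k = k, shifts = shifts,
                 proportions = proportions / sum(proportions),
                 phenotype_probs = phenotype_probs),
            class = "archetype_spec")
}

#' Demo archetype specification with a planted ratio-feature separation
#'
#' Builds three investment archetypes over a tissue panel — one shifting
#' mitochondrial investment up in `high_a` and down in `high_b`
#' ("muscle-high"), one the reverse ("brain-high"), and one balanced —
#' with logit shifts sized so that, on the inter-tissue log-ratio
#' features, the centroid of each shifted archetype differs from the
#' balanced one by `separation` within-cluster SDs on each singly
#' affected ratio feature. Under the generator the within-cluster SD of
#' a log2-ratio feature is `sqrt(2) * scale * s_tot / log(2)` with
#' `s_tot = sqrt(lambda^2 + sigma^2)`, so the required logit shift is
#' `h = separation * sqrt(2) * scale * s_tot` applied with opposite
#' signs to the two focal tissues.
#'
#' @param panel tissue panel the archetypes act on.
#' @param high_a,high_b the two focal tissues (default the first body
#'   and the first brain tissue of the panel).
#' @param separation planted standardized separation; default 2.
#' @param phenotype_probs k x V Bernoulli probabilities; the default
#'   plants three phenotypes, each enriched in one archetype
#'   (0.7 vs 0.15).
#' @return an [archetype_spec()].
#' @export
demo_archetypes <- function(panel,
                            high_a = panel$tissue[panel$tissue_class ==
                                                    "body"][1L],
                            high_b = panel$tissue[panel$tissue_class ==
                                                    "brain"][1L],
                            separation = 2, phenotype_probs = NULL) {
  stopifnot(high_a %in% panel$tissue, high_b %in% panel$tissue)
  s_tot <- sqrt(panel$lambda^2 + panel$sigma^2)
  sc <- if (is.null(panel$scale)) rep(0.5, nrow(panel)) else panel$scale
  amp <- setNames(sc * s_tot, panel$tissue)
  h <- separation * sqrt(2) * mean(amp[c(high_a, high_b)])
  shifts <- matrix(0, 3, 2, dimnames = list(NULL, c(high_a, high_b)))
  shifts[1L, ] <- c(h, -h)
  shifts[2L, ] <- c(-h, h)
  if (is.null(phenotype_probs))
    phenotype_probs <- cbind(pheno_A = c(0.70, 0.15, 0.15),
                             pheno_B = c(0.15, 0.70, 0.15),
                             pheno_C = c(0.15, 0.15, 0.70))
  archetype_spec(shifts, phenotype_probs = phenotype_probs)
}

#' Synthetic cohort configuration
#'
#' @param n_subjects cohort size.
#' @param tissues a [tissue_panel()]-style data.frame.
#' @param n_mito_nuclear,n_other gene counts for the nuclear-mito and
#'   filler nuclear classes (13 mtDNA genes and the named regulator /
#'   ISR / proliferation genes are always present).
#' @param gene_sdlog log-normal dispersion of within-class gene weights.
#' @param factor_cor correlation between the brain and body latent
#'   factors; 1 collapses them to a single organism-wide trait, 0 makes
#'   brain-body expected correlations zero. Default 0.
#' @param regulator_scale logit amplitude of regulator/ISR fractions.
#' @param rin list(mean, sd, min, max) of the truncated-normal RIN draw.
#' @param archetypes an [archetype_spec()] or NULL (single archetype).
#' @param seed RNG seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 200, tissues = tissue_panel(),
                          n_mito_nuclear = 100, n_other = 300,
                          gene_sdlog = 1, factor_cor = 0,
                          regulator_scale = 0.5,
                          rin = list(mean = 7.2, sd = 1.1,
                                     min = 3, max = 10),
                          archetypes = NULL, seed = 1) {
  stopifnot(n_subjects >= 1,
            all(tissues$mu > 0 & tissues$mu < 1),
            all(tissues$nu > 0 & tissues$nu < 1),
            all(tissues$lambda >= 0 & tissues$lambda <= 1),
            all(tissues$lambda^2 + tissues$sigma^2 > 0),
            all(tissues$miss >= 0 & tissues$miss < 1),
            all(abs(tissues$beta) <= 1),
            factor_cor >= 0, factor_cor <= 1)
  if (anyDuplicated(tissues$tissue))
    stop("duplicated tissue name in panel", call. = FALSE)
  structure(list(n_subjects = n_subjects, tissues = tissues,
                 n_mito_nuclear = n_mito_nuclear, n_other = n_other,
                 gene_sdlog = gene_sdlog, factor_cor = factor_cor,
                 regulator_scale = regulator_scale, rin = rin,
                 archetypes = archetypes, seed = seed),
            class = "cohort_config")
}

# gene identities shared by all synthetic cohorts
MTDNA_GENES <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8",
                 "MT-ATP6", "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4",
                 "MT-ND5", "MT-ND6", "MT-CYB")
REGULATOR_GENES <- c("PPARGC1A", "NRF1", "NRF2", "TFAM", "POLG")
ISR_GENES <- c("ATF4", "ATF5", "DDIT3", "GDF15")
PROLIF_GENES <- c("MKI67", "TOP2A", "RRM2")

# baseline nuclear-fraction means of the special single genes / sets
REG_MU <- c(PPARGC1A = 2e-4, NRF1 = 1.5e-4, NRF2 = 2e-4,
            TFAM = 1.2e-4, POLG = 1e-4)
ISR_MU <- 6e-4
PROLIF_MU <- 2e-3   # multiplied by (0.02 + prolif) per tissue

#' Gene catalog of the synthetic cohorts
#'
#' 13 mtDNA genes, `n_mito_nuclear` nuclear-mito genes, the regulator /
#' ISR / proliferation marker genes, and `n_other` filler nuclear genes;
#' named sets `ISR`, `proliferation`, and one singleton set per
#' regulator.
#'
#' @param n_mito_nuclear,n_other class sizes.
#' @return a [gene_catalog()].
#' @export
default_gene_catalog <- function(n_mito_nuclear = 100, n_other = 300) {
  mito_nuc <- sprintf("NMIT%04d", seq_len(n_mito_nuclear))
  singles <- setNames(as.list(REGULATOR_GENES), REGULATOR_GENES)
  gene_catalog(
    mtdna_genes = MTDNA_GENES,
    mito_nuclear_genes = mito_nuc,
    named_sets = c(list(ISR = ISR_GENES, proliferation = PROLIF_GENES),
                   singles))
}

#' Expected inter-tissue correlation of two synthetic tissues
#'
#' Under the latent-trait model, the Pearson correlation of the two
#' tissues' (logit-scale) mitochondrial investments is
#' `rho = cross * lambda_s * lambda_t /
#'   sqrt((lambda_s^2 + sigma_s^2) * (lambda_t^2 + sigma_t^2))`,
#' where `cross` is the correlation of the two tissues' latent factors
#' (1 within a class or with a single shared trait). The corresponding
#' large-n Spearman expectation for a bivariate normal is
#' `(6 / pi) * asin(rho / 2)`; ranks are unchanged by the logistic
#' transform, so this holds for the fractions themselves.
#'
#' @param lambda_s,lambda_t loadings.
#' @param sigma_s,sigma_t residual SDs.
#' @param cross latent-factor correlation between the tissues' classes;
#'   default 1.
#' @return list with `pearson` and `spearman`.
#' @export
expected_pair_correlation <- function(lambda_s, lambda_t,
                                      sigma_s, sigma_t, cross = 1) {
  stopifnot(lambda_s^2 + sigma_s^2 > 0, lambda_t^2 + sigma_t^2 > 0)
  rho <- cross * lambda_s * lambda_t /
    sqrt((lambda_s^2 + sigma_s^2) * (lambda_t^2 + sigma_t^2))
  list(pearson = rho, spearman = (6 / pi) * asin(rho / 2))
}

# truncated-normal draw via inverse CDF (deterministic under the seed)
rtnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic multi-tissue expression cohort
#'
#' Implements the latent-trait coherence model. Per subject i a latent
#' factor is drawn for each tissue class (correlated `factor_cor` across
#' classes) together with an archetype; per subject-tissue the
#' mitochondrial investment is drawn on the log-odds scale,
#' `logit(f) = logit(mu_t) + scale_t * (lambda_t z + eps) + shift`,
#' `eps ~ N(0, sigma_t^2)`; the nuclear-mito fraction follows the same
#' form around `nu_t` with a Gaussian-copula coupling of strength
#' `prolif_t` to the mitochondrial deviate; the PGC-1a (PPARGC1A)
#' fraction couples with strength `beta_t` to the nuclear-mito deviate;
#' proliferation-gene levels scale with `prolif_t`; gene-level abundances
#' are log-normal within each class and rescaled so the class sums hit
#' the drawn fractions exactly and every sample totals 1e6 (TPM).
#' Tissues are dropped per subject with probability `miss`, RIN is drawn
#' per sample, and clinical binaries follow the archetype probabilities.
#'
#' @param config a [cohort_config()].
#' @return list with `expression` (genes x samples matrix), `samples`
#'   (sample table), `catalog`, `clinical` (data.frame), and `truth`
#'   (latent factors, archetypes, drawn fractions, presence mask,
#'   config).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  tis <- config$tissues
  n <- config$n_subjects
  subjects <- sprintf("S%04d", seq_len(n))
  classes <- unique(tis$tissue_class)

  # class latent factors with cross-class correlation factor_cor
  g <- rnorm(n)
  z <- sapply(classes, function(cl)
    sqrt(config$factor_cor) * g + sqrt(1 - config$factor_cor) * rnorm(n))
  z <- matrix(z, nrow = n, dimnames = list(subjects, classes))

  arch <- config$archetypes
  if (is.null(arch))
    arch <- archetype_spec(matrix(0, 1, 0), proportions = 1)
  # archetype counts follow the mixing proportions exactly (shuffled
  # assignment) so planted cluster sizes are part of the ground truth
  counts <- diff(round(cumsum(c(0, arch$proportions)) * n))
  archetype <- sample(rep.int(seq_len(arch$k), counts))

  catalog <- default_gene_catalog(config$n_mito_nuclear, config$n_other)
  other_genes <- sprintf("OTH%04d", seq_len(config$n_other))
  genes <- c(MTDNA_GENES, catalog$mito_nuclear_genes, REGULATOR_GENES,
             ISR_GENES, PROLIF_GENES, other_genes)
  base_meanlog <- setNames(rnorm(length(genes), 0, 1), genes)

  ntis <- nrow(tis)
  f_mat <- matrix(NA_real_, n, ntis, dimnames = list(subjects, tis$tissue))
  g_mat <- f_mat
  present <- matrix(FALSE, n, ntis, dimnames = dimnames(f_mat))

  expr_blocks <- list(); sample_blocks <- list()
  for (t in seq_len(ntis)) {
    lam <- tis$lambda[t]; sig <- tis$sigma[t]; sc <- tis$scale[t]
    s_tot <- sqrt(lam^2 + sig^2)
    d <- lam * z[, tis$tissue_class[t]] + rnorm(n, 0, sig)
    d_std <- d / s_tot
    shift <- shift_for(arch, archetype, tis$tissue[t])

    b_std <- tis$prolif[t] * d_std +
      sqrt(1 - tis$prolif[t]^2) * rnorm(n)
    r_std <- tis$beta[t] * b_std + sqrt(1 - tis$beta[t]^2) * rnorm(n)

    f <- plogis(qlogis(tis$mu[t]) + sc * d + shift)
    gfrac <- plogis(qlogis(tis$nu[t]) + sc * s_tot * b_std + shift)
    reg_frac <- sapply(REGULATOR_GENES, function(gene) {
      std <- if (gene == "PPARGC1A") r_std else rnorm(n)
      plogis(qlogis(REG_MU[[gene]]) + config$regulator_scale * std)
    })
    isr_frac <- plogis(qlogis(ISR_MU) + config$regulator_scale * rnorm(n))
    prol_frac <- plogis(qlogis(PROLIF_MU * (0.02 + tis$prolif[t])) +
                          0.3 * rnorm(n))

    special <- rowSums(reg_frac) + isr_frac + prol_frac
    if (any(gfrac + special >= 0.999))
      stop("infeasible nuclear fractions (sum >= 1) for tissue '",
           tis$tissue[t], "'", call. = FALSE)

    keep <- runif(n) >= tis$miss[t]
    if (!any(keep)) next
    f_mat[keep, t] <- f[keep]
    g_mat[keep, t] <- gfrac[keep]
    present[keep, t] <- TRUE

    m <- sum(keep)
    w <- matrix(rlnorm(length(genes) * m, meanlog = base_meanlog,
                       sdlog = config$gene_sdlog),
                nrow = length(genes),
                dimnames = list(genes, NULL))
    nuc_tot <- (1 - f[keep]) * 1e6
    block <- w
    block[MTDNA_GENES, ] <- scale_block(w[MTDNA_GENES, , drop = FALSE],
                                        f[keep] * 1e6)
    block[catalog$mito_nuclear_genes, ] <-
      scale_block(w[catalog$mito_nuclear_genes, , drop = FALSE],
                  gfrac[keep] * nuc_tot)
    for (j in seq_along(REGULATOR_GENES))
      block[REGULATOR_GENES[j], ] <- reg_frac[keep, j] * nuc_tot
    block[ISR_GENES, ] <- scale_block(w[ISR_GENES, , drop = FALSE],
                                      isr_frac[keep] * nuc_tot)
    block[PROLIF_GENES, ] <- scale_block(w[PROLIF_GENES, , drop = FALSE],
                                         prol_frac[keep] * nuc_tot)
    other_tot <- nuc_tot * (1 - gfrac[keep] - special[keep])
    block[other_genes, ] <- scale_block(w[other_genes, , drop = FALSE],
                                        other_tot)
    colnames(block) <- paste(subjects[keep], tis$tissue[t], sep = ".")
    expr_blocks[[t]] <- block
    sample_blocks[[t]] <- data.frame(
      sample_id = colnames(block),
      subject_id = subjects[keep],
      tissue = tis$tissue[t],
      tissue_class = tis$tissue_class[t],
      rin = rtnorm(m, config$rin$mean, config$rin$sd,
                   config$rin$min, config$rin$max),
      stringsAsFactors = FALSE)
  }

  clinical <- data.frame(subject_id = subjects, stringsAsFactors = FALSE)
  if (!is.null(arch$phenotype_probs)) {
    for (v in colnames(arch$phenotype_probs))
      clinical[[v]] <- rbinom(n, 1, arch$phenotype_probs[archetype, v])
  }

  list(
    expression = do.call(cbind, expr_blocks[!vapply(expr_blocks, is.null,
                                                    TRUE)]),
    samples = do.call(rbind, sample_blocks[!vapply(sample_blocks, is.null,
                                                   TRUE)]),
    catalog = catalog,
    clinical = clinical,
    truth = list(z = z, archetype = archetype, f = f_mat, g = g_mat,
                 present = present, config = config))
}

shift_for <- function(arch, archetype, tissue) {
  if (ncol(arch$shifts) == 0L || !(tissue %in% colnames(arch$shifts)))
    return(rep(0, length(archetype)))
  arch$shifts[archetype, tissue]
}

# rescale columns of a weight block so each column sums to `targets`
scale_block <- function(w, targets) {
  cs <- colSums(w)
  sweep(w, 2L, targets / cs, `*`)
}

#' Mouse-like tissue panel (17 brain regions, 5 peripheral tissues)
#'
#' Emulates the shape of a multi-region mouse biochemistry cohort:
#' brain regions load on a shared brain factor, peripheral tissues are
#' close to independent, and the two class factors are uncorrelated, so
#' that brain-brain coherence is moderate while brain-body and body-body
#' coherence are near zero.
#'
#' @param brain_lambda,body_lambda class loadings; defaults 0.55, 0.10.
#' @return tissue panel data.frame.
#' @export
mouse_tissue_panel <- function(brain_lambda = 0.55, body_lambda = 0.10) {
  brain <- c("Cereb", "NAc", "CA3", "PAG", "DGd", "DGv", "mPFC", "CPu",
             "M1", "VN", "Thal", "VTA", "mOFC", "Hypo", "Amyg", "V1", "SN")
  body <- c("Soleus", "AG", "WG", "Liver", "Heart")
  data.frame(
    tissue = c(brain, body),
    tissue_class = rep(c("brain", "body"), c(length(brain), length(body))),
    lambda = rep(c(brain_lambda, body_lambda),
                 c(length(brain), length(body))),
    sigma = sqrt(1 - rep(c(brain_lambda, body_lambda),
                         c(length(brain), length(body)))^2),
    miss = 0,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic enzymatic-activity feature table
#'
#' Same latent-trait machinery as [generate_cohort()] but producing a
#' (subject, tissue) x feature table directly — the shape of a mouse
#' multi-tissue biochemistry dataset with OxPhos complex activities
#' (CI, CII, CIV), citrate synthase (CS), and mtDNA density. Each
#' feature couples to the tissue's latent deviate with its own loading
#' weight, so per-feature inter-tissue correlations follow
#' `w_f^2 * lambda_s * lambda_t / sqrt((lambda_s^2 + sigma_s^2) *
#' (lambda_t^2 + sigma_t^2))` within a class. Values are log-normal
#' (positive, activity-like).
#'
#' @param n_subjects number of animals; default 27.
#' @param tissues a panel data.frame with `tissue`, `tissue_class`,
#'   `lambda`, `sigma`, `miss`; default [mouse_tissue_panel()].
#' @param feature_loadings named vector of per-feature loading weights
#'   in \[0, 1\].
#' @param scale log-scale amplitude; default 0.4.
#' @param factor_cor cross-class factor correlation; default 0.
#' @param seed RNG seed.
#' @return feature table (subject_id, tissue, one column per feature)
#'   with `tissue_classes` and `truth` attributes.
#' @export
generate_enzymatic_cohort <- function(n_subjects = 27,
                                      tissues = mouse_tissue_panel(),
                                      feature_loadings = c(
                                        CI = 1, CII = 0.9, CIV = 1,
                                        CS = 0.95, mtDNA_density = 0.85),
                                      scale = 0.4, factor_cor = 0,
                                      seed = 1) {
  stopifnot(all(tissues$lambda^2 + tissues$sigma^2 > 0),
            all(feature_loadings >= 0 & feature_loadings <= 1))
  set.seed(seed)
  subjects <- sprintf("M%03d", seq_len(n_subjects))
  classes <- unique(tissues$tissue_class)
  g <- rnorm(n_subjects)
  z <- matrix(sapply(classes, function(cl)
    sqrt(factor_cor) * g + sqrt(1 - factor_cor) * rnorm(n_subjects)),
    nrow = n_subjects, dimnames = list(subjects, classes))

  rows <- list()
  for (t in seq_len(nrow(tissues))) {
    lam <- tissues$lambda[t]; sig <- tissues$sigma[t]
    d_std <- (lam * z[, tissues$tissue_class[t]] +
                rnorm(n_subjects, 0, sig)) / sqrt(lam^2 + sig^2)
    keep <- runif(n_subjects) >= tissues$miss[t]
    if (!any(keep)) next
    vals <- sapply(names(feature_loadings), function(f) {
      w <- feature_loadings[[f]]
      exp(scale * (w * d_std + sqrt(1 - w^2) * rnorm(n_subjects)))
    })
    row <- data.frame(subject_id = subjects, tissue = tissues$tissue[t],
                      vals, stringsAsFactors = FALSE)
    rows[[t]] <- row[keep, , drop = FALSE]
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  structure(out,
            tissue_classes = setNames(tissues$tissue_class, tissues$tissue),
            truth = list(z = z, tissues = tissues,
                         feature_loadings = feature_loadings, seed = seed))
}
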