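# ---------------------------------------------------------------------------
# Sample, genotype and expression QC plus the transforms feeding the eQTL
# scan. Filter thresholds default to the study criteria: tumor purity >= 0.6;
# SNPs kept at INFO >= 0.5, MAF >= 5%, missing rate < 5% (after masking
# calls with posterior < 0.7), HWE exact p > 1e-6; lncRNAs kept when the
# 10th-percentile RPKM > 0 and the 90th-percentile RPKM > 0.1.
# ---------------------------------------------------------------------------

new_qc_report <- function(step, removed, retained) {
  data.frame(step = step, removed = removed, retained = retained,
             input = removed + retained, stringsAsFactors = FALSE)
}

#' Filter samples by tumor purity
#'
#' @param covariates A [covariate_table()].
#' @param threshold Minimum purity; samples with purity >= threshold are
#'   kept (the boundary is retained).
#' @return List with `samples` (kept ids) and `report` (QC count row).
#' @export
filter_samples_by_purity <- function(covariates, threshold = 0.6) {
  if (threshold < 0 || threshold > 1) {
    stop("purity threshold must lie in [0,1]")
  }
  pur <- covariates$purity
  if (anyNA(pur)) {
    stop("purity missing for sample(s): ",
         paste(covariates$samples[is.na(pur)], collapse = ", "))
  }
  keep <- pur >= threshold
  if (!any(keep)) stop("purity filter removed every sample")
  list(samples = covariates$samples[keep],
       report = new_qc_report("purity", sum(!keep), sum(keep)))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, sums the
#' probabilities of all heterozygote counts whose probability under HWE does
#' not exceed that of the observed table (Wigginton-style). Log-scale
#' recursion over heterozygote counts keeps it stable for large samples.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (AA = ref homozygote).
#' @return Exact p-value in (0, 1\].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotype")
  n_a <- 2 * n_aa + n_Aa              # minor-ish allele count
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_a, n_A)
  if (rare == 0) return(1.0)          # monomorphic
  # admissible heterozygote counts share the parity of the rare-allele count
  het0 <- rare %% 2
  hets <- seq(het0, rare, by = 2)
  # unnormalized log-probabilities: P(het) proportional to
  # n! / (nAA! nAa! naa!) * 2^het with nAA,naa determined by allele counts
  logp <- vapply(hets, function(h) {
    aa <- (rare - h) / 2
    AA <- (max(n_a, n_A) - h) / 2
    h * log(2) - lgamma(AA + 1) - lgamma(h + 1) - lgamma(aa + 1)
  }, 0)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- prob[match(n_Aa, hets)]
  sum(prob[prob <= obs + 1e-12])
}

#' Genotype QC
#'
#' Filters SNPs in the fixed order INFO -> posterior-masking -> missingness
#' -> MAF -> HWE. When per-call posteriors are available, calls below
#' `posterior_min` are set missing before the missing-rate filter; MAF is
#' computed on non-missing calls.
#'
#' @param gm A [genotype_matrix()].
#' @param info_min Minimum imputation INFO score (SNPs with no INFO pass).
#' @param maf_min Minimum minor allele frequency.
#' @param miss_max Maximum per-SNP missing rate (strictly below keeps).
#' @param hwe_min Minimum HWE exact p (strictly above keeps).
#' @param posterior_min Minimum per-call posterior (used when posteriors are
#'   present; otherwise the rule is skipped).
#' @return List with `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (per-filter counts).
#' @export
qc_genotypes <- function(gm, info_min = 0.5, maf_min = 0.05,
                         miss_max = 0.05, hwe_min = 1e-6,
                         posterior_min = 0.7) {
  reports <- list()
  # (i) INFO
  info <- gm$snps$info
  keep <- is.na(info) | info >= info_min
  reports$info <- new_qc_report("info", sum(!keep), sum(keep))
  gm <- subset_genotypes(gm, snps = which(keep))
  # posterior masking
  if (!is.null(gm$posterior)) {
    mask <- !is.na(gm$posterior) & gm$posterior < posterior_min
    gm$dosage[mask] <- NA
  }
  # (iii) missingness
  miss <- colMeans(is.na(gm$dosage))
  keep <- miss < miss_max
  reports$missing <- new_qc_report("missing", sum(!keep), sum(keep))
  gm <- subset_genotypes(gm, snps = which(keep))
  # (ii) MAF on non-missing calls
  keep <- !is.na(gm$snps$maf) & gm$snps$maf >= maf_min
  reports$maf <- new_qc_report("maf", sum(!keep), sum(keep))
  gm <- subset_genotypes(gm, snps = which(keep))
  # (iv) HWE exact
  if (ncol(gm$dosage) > 0) {
    hwe_p <- apply(gm$dosage, 2, function(g) {
      g <- g[!is.na(g)]
      hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
    })
    keep <- hwe_p > hwe_min
  } else keep <- logical(0)
  reports$hwe <- new_qc_report("hwe", sum(!keep), sum(keep))
  gm <- subset_genotypes(gm, snps = which(keep))
  if (ncol(gm$dosage) == 0) warning("no SNPs left after genotype QC")
  list(genotypes = gm, report = do.call(rbind, reports))
}

#' Filter lncRNAs by RPKM percentile rules
#'
#' Keeps a feature iff its 10th-percentile RPKM across samples is > 0 and
#' its 90th-percentile RPKM is > 0.1 (type-7 linear-interpolation sample
#' quantiles).
#'
#' @param em [expression_matrix()] at stage raw_rpkm.
#' @return List with `expression` (stage filtered) and `report`.
#' @export
filter_lncrna_expression <- function(em) {
  if (em$stage != "raw_rpkm") stop("expected stage raw_rpkm, got ", em$stage)
  q10 <- apply(em$values, 2, stats::quantile, probs = 0.1, names = FALSE)
  q90 <- apply(em$values, 2, stats::quantile, probs = 0.9, names = FALSE)
  keep <- q10 > 0 & q90 > 0.1
  out <- subset_expression(em, features = which(keep))
  out$stage <- "filtered"
  list(expression = out,
       report = new_qc_report("expression_percentile", sum(!keep),
                              sum(keep)))
}

#' Quantile-normalize an expression matrix across samples
#'
#' After normalization every sample's sorted expression vector equals the
#' across-sample mean of sorted vectors; ties within a sample receive the
#' mean of the reference values they span.
#'
#' @param em [expression_matrix()] with no missing values.
#' @return [expression_matrix()] at stage quantile_normalized.
#' @export
quantile_normalize <- function(em) {
  if (ncol(em$values) < 2) stop("need at least 2 features")
  if (anyNA(em$values)) stop("missing values not allowed")
  # limma expects genes x samples
  qn <- t(limma::normalizeQuantiles(t(em$values), ties = TRUE))
  dimnames(qn) <- dimnames(em$values)
  out <- em
  out$values <- qn
  out$stage <- "quantile_normalized"
  out
}

#' Rank-based inverse normal transform
#'
#' value_i = qnorm((rank_i - 3/8) / (n + 1/4)) with average ranks for ties
#' (Blom offset).
#'
#' @param x Numeric vector, length >= 3, not constant.
#' @return Transformed vector.
#' @export
inverse_normal_transform <- function(x) {
  if (length(x) < 3) stop("need length >= 3")
  if (length(unique(x)) == 1) stop("constant vector: all ranks tied")
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

#' Apply the inverse normal transform feature-wise
#'
#' @param em [expression_matrix()].
#' @return [expression_matrix()] at stage inverse_normal.
#' @export
inverse_normal_expression <- function(em) {
  out <- em
  out$values <- apply(em$values, 2, inverse_normal_transform)
  rownames(out$values) <- rownames(em$values)
  out$stage <- "inverse_normal"
  out
}

#' log2(RPKM + 1) transform
#'
#' @param em [expression_matrix()] with non-negative values.
#' @return [expression_matrix()] at stage log2.
#' @export
log2_rpkm <- function(em) {
  if (any(em$values < 0)) stop("negative expression value")
  out <- em
  out$values <- log2(em$values + 1)
  out$stage <- "log2"
  out
}

#' Estimate latent expression factors (PEER-style surrogate)
#'
#' Residualizes expression on the known covariates (intercept, age, sex)
#' and returns the top-k left singular vectors of the residual matrix —
#' a deterministic surrogate for PEER's latent confounders, validated by
#' planted-batch recovery in the test suite.
#'
#' @param em [expression_matrix()] at stage inverse_normal (no missing
#'   values).
#' @param k Number of factors (default 5).
#' @param covariates Optional [covariate_table()]; when given, age and sex
#'   are regressed out first.
#' @return Samples x k matrix of unit-norm factor columns.
#' @export
estimate_latent_factors <- function(em, k = 5, covariates = NULL) {
  E <- em$values
  if (anyNA(E)) stop("missing values not allowed")
  if (k >= min(dim(E))) stop("k must be < min(samples, features)")
  X <- cbind(intercept = rep(1, nrow(E)))
  if (!is.null(covariates)) {
    X <- cbind(X, age = covariates$age, sex = covariates$sex)
  }
  R <- stats::lm.fit(X, E)$residuals
  sv <- svd(R, nu = k, nv = 0)
  f <- sv$u
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(f[, j]))
    if (f[i, j] < 0) f[, j] <- -f[, j]
  }
  colnames(f) <- paste0("factor", seq_len(k))
  rownames(f) <- rownames(E)
  f
}

#' Discretize promoter methylation beta values
#'
#' Takes the median beta over a feature's promoter (TSS200/TSS1500) probes
#' per sample and maps it to an ordinal level: 0 if median < 0.2, 1 if
#' 0.2 <= median <= 0.6, 2 if median > 0.6.
#'
#' @param beta Samples x probes matrix of methylation beta values in \[0,1\].
#' @param probe_feature Character vector (length = ncol(beta)) giving the
#'   feature each promoter probe belongs to.
#' @param features Feature ids to report (default: unique probe features).
#' @return Samples x features matrix of levels in \{0,1,2\}; a feature with
#'   no probes gets NA with a warning.
#' @export
discretize_methylation <- function(beta, probe_feature, features = NULL) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0,1]")
  }
  if (is.null(features)) features <- unique(probe_feature)
  out <- matrix(NA_real_, nrow(beta), length(features),
                dimnames = list(rownames(beta), features))
  for (f in features) {
    idx <- which(probe_feature == f)
    if (!length(idx)) {
      warning("feature ", f, " has no promoter probes; level set NA")
      next
    }
    med <- apply(beta[, idx, drop = FALSE], 1, stats::median, na.rm = TRUE)
    out[, f] <- ifelse(med < 0.2, 0, ifelse(med <= 0.6, 1, 2))
  }
  out
}

#' Prefilter mRNAs for instrumental-variable analysis
#'
#' Keeps a gene iff the coefficient of variation of its counts is > 0.5,
#' the 30th percentile of log2(count+1) is > 0, and the 90th percentile of
#' log2(count+1) is > 5. Genes with mean count 0 (CV undefined) are dropped.
#'
#' @param em [expression_matrix()] at stage raw_count.
#' @return List with `expression` (kept genes), `keep` (named logical) and
#'   `report`.
#' @export
filter_mrna_for_iv <- function(em) {
  if (em$stage != "raw_count") stop("expected stage raw_count")
  counts <- em$values
  mu <- colMeans(counts)
  cv <- ifelse(mu > 0, apply(counts, 2, stats::sd) / mu, NA)
  lc <- log2(counts + 1)
  q30 <- apply(lc, 2, stats::quantile, probs = 0.3, names = FALSE)
  q90 <- apply(lc, 2, stats::quantile, probs = 0.9, names = FALSE)
  keep <- !is.na(cv) & cv > 0.5 & q30 > 0 & q90 > 5
  list(expression = subset_expression(em, features = which(keep)),
       keep = stats::setNames(keep, colnames(counts)),
       report = new_qc_report("mrna_iv_prefilter", sum(!keep), sum(keep)))
}
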