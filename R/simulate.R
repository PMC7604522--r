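# ---------------------------------------------------------------------------
# Synthetic cohort generator.
#
# Genotypes: per LD block, haplotypes come from a latent AR(1) Gaussian
# (Gaussian copula) thresholded at the allele-frequency quantile; summing two
# independent haplotypes per sample gives Hardy-Weinberg genotypes with a
# tunable adjacent-SNP r^2. Expression follows an additive linear model on
# the log2 scale (genotype + age + sex + latent factors + SCNA + methylation
# + Gaussian noise), mapped to RPKM via 2^latent - 1 floored at zero so the
# percentile filters see genuine zeros. mRNA is mediated by lncRNA; immune
# fractions are logistic-normal (softmax) with one lncRNA-driven cell type.
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Defaults describe the reference synthetic cohort used throughout the test
#' suite: 300 tumor samples, 500 SNPs in 10-SNP LD blocks (MAF 0.3, adjacent
#' haplotype r^2 0.5), 50 lncRNAs, 100 mRNAs and 5 immune cell types.
#'
#' @param n_samples Number of samples.
#' @param blocks data.frame with columns `n_snps`, `maf`, `r2` (one row per
#'   LD block), or NULL for `n_blocks` identical blocks.
#' @param n_blocks,snps_per_block,maf,r2 Used when `blocks` is NULL.
#' @param n_lncrna,n_mrna Feature counts.
#' @param cis_beta,trans_beta Effect of one alt allele on log2 expression for
#'   lncRNAs carrying a cis / trans eQTL.
#' @param frac_cis,frac_trans Fractions of lncRNAs given a true cis / trans
#'   eQTL.
#' @param frac_low Fraction of lncRNAs made low-expressed (10th-percentile
#'   RPKM 0) to exercise the expression filters.
#' @param mediation_alpha Effect of lncRNA (log2 scale) on mediated mRNA.
#' @param frac_mediated Fraction of mRNAs truly mediated by a lncRNA.
#' @param beta_age,beta_sex,beta_scna,beta_meth Covariate effects on log2
#'   expression.
#' @param sd_latent Standard deviation of the K=5 latent factor contribution.
#' @param noise_sd Residual standard deviation of log2 expression.
#' @param scna_geno_corr Correlation knob linking SCNA to the cis genotype
#'   (0 = somatic events independent of germline; >0 plants confounding).
#' @param purity_shape1,purity_shape2 Beta-distribution parameters of tumor
#'   purity.
#' @param n_cell_types Number of immune cell types.
#' @param immune_gamma Effect of the designated lncRNA on its target cell
#'   type's softmax linear predictor.
#' @param confounder_sd Standard deviation of the shared lncRNA/mRNA
#'   confounder used by the mediation model.
#' @param miss_rate Genotype missingness rate.
#' @param seed Integer seed; every simulate_* call is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300,
                       blocks = NULL,
                       n_blocks = 50, snps_per_block = 10,
                       maf = 0.3, r2 = 0.5,
                       n_lncrna = 50, n_mrna = 100,
                       cis_beta = 0.5, trans_beta = 0.5,
                       frac_cis = 0.5, frac_trans = 0.2,
                       frac_low = 0.2,
                       mediation_alpha = 1.5, frac_mediated = 0.05,
                       beta_age = 0.005, beta_sex = 0.1,
                       beta_scna = 0.5, beta_meth = 0.2,
                       sd_latent = 0.5, noise_sd = 1,
                       scna_geno_corr = 0,
                       purity_shape1 = 8, purity_shape2 = 2,
                       n_cell_types = 5, immune_gamma = 0.4,
                       confounder_sd = 1,
                       miss_rate = 0, seed = 1L) {
  if (is.null(blocks)) {
    blocks <- data.frame(n_snps = rep(snps_per_block, n_blocks),
                         maf = maf, r2 = r2)
  }
  stopifnot(n_samples >= 20)
  if (any(blocks$maf <= 0 | blocks$maf > 0.5)) {
    stop("block maf must lie in (0, 0.5]")
  }
  if (any(blocks$r2 < 0 | blocks$r2 >= 1)) {
    stop("block r2 must lie in [0, 1)")
  }
  cfg <- list(n_samples = n_samples, blocks = blocks,
              n_lncrna = n_lncrna, n_mrna = n_mrna,
              cis_beta = cis_beta, trans_beta = trans_beta,
              frac_cis = frac_cis, frac_trans = frac_trans,
              frac_low = frac_low,
              mediation_alpha = mediation_alpha,
              frac_mediated = frac_mediated,
              beta_age = beta_age, beta_sex = beta_sex,
              beta_scna = beta_scna, beta_meth = beta_meth,
              sd_latent = sd_latent, noise_sd = noise_sd,
              scna_geno_corr = scna_geno_corr,
              purity_shape1 = purity_shape1, purity_shape2 = purity_shape2,
              n_cell_types = n_cell_types, immune_gamma = immune_gamma,
              confounder_sd = confounder_sd,
              miss_rate = miss_rate, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Latent-Gaussian correlation giving a target haplotype (binary allele)
# correlation at allele frequency p. The binary correlation of two standard
# normals thresholded at z = qnorm(p) with latent correlation rho is
# (P11 - p^2) / (p (1 - p)) where P11 = P(Z1 < z, Z2 < z); solved by uniroot
# with P11 from one-dimensional quadrature.
solve_latent_rho <- function(p, target_r2) {
  if (target_r2 <= 0) return(0)
  r_bin <- sqrt(target_r2)
  z <- stats::qnorm(p)
  p11 <- function(rho) {
    f <- function(x) {
      stats::dnorm(x) * stats::pnorm((z - rho * x) / sqrt(1 - rho^2))
    }
    stats::integrate(f, -Inf, z, rel.tol = 1e-10)$value
  }
  target_p11 <- r_bin * p * (1 - p) + p^2
  stats::uniroot(function(rho) p11(rho) - target_p11,
                 lower = 1e-6, upper = 1 - 1e-6, tol = 1e-9)$root
}

#' Simulate genotypes in LD blocks
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()] with SNPs laid out block-by-block across
#'   autosomes (one block per 10 Mb slot, SNPs 2 kb apart).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  blocks <- config$blocks
  dosage_cols <- vector("list", nrow(blocks))
  meta <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    m <- blocks$n_snps[b]
    p <- blocks$maf[b]
    rho <- solve_latent_rho(p, blocks$r2[b])
    z <- stats::qnorm(p)
    hap <- function() {
      # AR(1) latent path per haplotype
      e <- matrix(stats::rnorm(n * m), n, m)
      lat <- matrix(0, n, m)
      lat[, 1] <- e[, 1]
      if (m > 1) {
        s <- sqrt(1 - rho^2)
        for (j in 2:m) lat[, j] <- rho * lat[, j - 1] + s * e[, j]
      }
      (lat < z) * 1L
    }
    dosage_cols[[b]] <- hap() + hap()
    chrom <- paste0("chr", ((b - 1) %% 22) + 1)
    slot <- (b - 1) %/% 22          # multiple blocks per chromosome
    pos <- slot * 10e6 + 1e6 + seq_len(m) * 2000
    meta[[b]] <- data.frame(
      snp_id = sprintf("snp_b%d_%d", b, seq_len(m)),
      chrom = chrom, pos = as.integer(pos),
      ref = "A", alt = "B",
      info = round(stats::runif(m, 0.6, 1), 3),
      stringsAsFactors = FALSE)
  }
  dosage <- do.call(cbind, dosage_cols)
  rownames(dosage) <- sprintf("S%03d", seq_len(n))
  if (config$miss_rate > 0) {
    miss <- matrix(stats::runif(length(dosage)) < config$miss_rate,
                   nrow(dosage))
    dosage[miss] <- NA
  }
  genotype_matrix(dosage, do.call(rbind, meta))
}

#' Simulate lncRNA expression, covariates and the eQTL truth table
#'
#' Designated cis SNPs sit within 1 Mb of their target lncRNA; trans SNPs
#' are drawn from other chromosomes. Latent log2 expression is the additive
#' model (genotype, age, sex, latent factors, SCNA, methylation, Gaussian
#' noise); RPKM = 2^latent - 1 floored at 0.
#'
#' @param genotypes A [genotype_matrix()] from [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @return List with `expression` (stage raw_rpkm), `covariates`
#'   ([covariate_table()] incl. per-feature SCNA and methylation), and
#'   `truth` (data.frame: snp_id, feature_id, mode, true_beta).
#' @export
simulate_expression <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_samples
  nl <- config$n_lncrna
  snps <- genotypes$snps
  dos <- genotypes$dosage
  dos_c <- impute_dosage(dos)

  # covariates
  age <- round(stats::rnorm(n, 60, 10))
  sex <- stats::rbinom(n, 1, 0.5)
  purity <- stats::rbeta(n, config$purity_shape1, config$purity_shape2)
  k <- 5
  L <- matrix(stats::rnorm(n * k), n, k)
  loadings <- matrix(stats::rnorm(k * nl, 0, config$sd_latent), k, nl)

  # assign each lncRNA a home SNP (spread over blocks) and place the feature
  # within the 1 Mb cis window of that SNP
  anchor <- as.integer(round(seq(1, nrow(snps), length.out = nl)))
  feat <- data.frame(
    feature_id = sprintf("LNC%03d", seq_len(nl)),
    chrom = snps$chrom[anchor],
    start = pmax(1L, snps$pos[anchor] + 50000L),
    stringsAsFactors = FALSE)
  feat$end <- feat$start + 999L
  feat$strand <- "+"
  feat$biotype <- "lncRNA"

  n_cis <- round(config$frac_cis * nl)
  n_trans <- round(config$frac_trans * nl)
  cis_idx <- seq_len(n_cis)
  trans_idx <- seq_len(n_trans)          # may overlap cis carriers
  low_idx <- if (config$frac_low > 0) {
    utils::tail(seq_len(nl), round(config$frac_low * nl))
  } else integer(0)

  # trans SNP for lncRNA j: first SNP on a different chromosome, offset by j
  other_chrom <- function(j) {
    cand <- which(snps$chrom != feat$chrom[j])
    if (!length(cand)) stop("need >= 2 chromosomes for trans effects")
    cand[1 + (j * 7) %% length(cand)]
  }

  scna <- matrix(stats::rnorm(n * nl, 0, 0.5), n, nl)
  meth <- matrix(sample(0:2, n * nl, replace = TRUE,
                        prob = c(0.25, 0.5, 0.25)), n, nl)
  truth <- list()
  latent <- matrix(0, n, nl)
  intercept <- ifelse(seq_len(nl) %in% low_idx, -1.5, 3)
  for (j in seq_len(nl)) {
    mu <- intercept[j] +
      config$beta_age * (age - 60) + config$beta_sex * sex +
      L %*% loadings[, j, drop = FALSE]
    if (j %in% cis_idx) {
      g <- dos_c[, anchor[j]]
      mu <- mu + config$cis_beta * g
      if (config$scna_geno_corr > 0) {
        scna[, j] <- config$scna_geno_corr * scale(g)[, 1] +
          stats::rnorm(n, 0, 0.5)
      }
      truth[[length(truth) + 1]] <- data.frame(
        snp_id = snps$snp_id[anchor[j]], feature_id = feat$feature_id[j],
        mode = "cis", true_beta = config$cis_beta)
    }
    if (j %in% trans_idx) {
      tj <- other_chrom(j)
      mu <- mu + config$trans_beta * dos_c[, tj]
      truth[[length(truth) + 1]] <- data.frame(
        snp_id = snps$snp_id[tj], feature_id = feat$feature_id[j],
        mode = "trans", true_beta = config$trans_beta)
    }
    mu <- mu + config$beta_scna * scna[, j] +
      config$beta_meth * (meth[, j] - 1)
    latent[, j] <- mu + stats::rnorm(n, 0, config$noise_sd)
  }
  rpkm <- pmax(2^latent - 1, 0)
  rownames(rpkm) <- rownames(dos)
  rownames(scna) <- rownames(dos)
  rownames(meth) <- rownames(dos)
  colnames(scna) <- feat$feature_id
  colnames(meth) <- feat$feature_id

  em <- expression_matrix(rpkm, feat, stage = "raw_rpkm")
  cov <- covariate_table(rownames(dos), age, sex, purity,
                         latent_factors = NULL, scna = scna,
                         methylation = meth)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(snp_id = character(), feature_id = character(),
               mode = character(), true_beta = numeric())
  list(expression = em, covariates = cov, truth = truth)
}

#' Simulate mediated mRNA expression and immune-cell fractions
#'
#' mRNA latent log2 expression = alpha * lncRNA(log2 RPKM) + shared
#' confounder + noise, mapped to counts via round(2^latent - 1). Immune
#' fractions are a softmax over per-cell-type linear predictors with one
#' cell type driven by a designated lncRNA, so rows sum to exactly 1.
#'
#' @param lncrna_expr lncRNA [expression_matrix()] (stage raw_rpkm).
#' @param config The [sim_config()].
#' @return List with `mrna` (stage raw_count), `fractions`
#'   ([immune_fraction_table()]), `truth_axes` (lncrna_id, mrna_id,
#'   true_alpha), `truth_immune` (lncrna_id, cell_type, true_gamma), and
#'   `confounder` (the shared confounder vector, for bias studies).
#' @export
simulate_downstream <- function(lncrna_expr, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- nrow(lncrna_expr$values)
  nm <- config$n_mrna
  x <- log2(lncrna_expr$values + 1)
  nl <- ncol(x)
  u <- stats::rnorm(n, 0, config$confounder_sd)  # shared confounder

  n_med <- max(1, round(config$frac_mediated * nm))
  med_mrna <- seq_len(n_med)
  med_lnc <- rep(seq_len(max(1, min(nl, n_med))), length.out = n_med)

  latent <- matrix(0, n, nm)
  truth_axes <- data.frame(lncrna_id = character(), mrna_id = character(),
                           true_alpha = numeric())
  for (j in seq_len(nm)) {
    mu <- 6 + 0.5 * u + stats::rnorm(n, 0, 1)
    if (j %in% med_mrna) {
      lj <- med_lnc[match(j, med_mrna)]
      xl <- x[, lj] - mean(x[, lj])
      mu <- mu + config$mediation_alpha * xl
      truth_axes <- rbind(truth_axes, data.frame(
        lncrna_id = colnames(x)[lj],
        mrna_id = sprintf("MRNA%03d", j),
        true_alpha = config$mediation_alpha))
    }
    latent[, j] <- mu
  }
  counts <- round(pmax(2^latent - 1, 0))
  rownames(counts) <- rownames(lncrna_expr$values)
  mfeat <- data.frame(
    feature_id = sprintf("MRNA%03d", seq_len(nm)),
    chrom = "chr99", start = seq_len(nm) * 10000L,
    stringsAsFactors = FALSE)
  mfeat$end <- mfeat$start + 999L
  mfeat$strand <- "+"
  mfeat$biotype <- "mRNA"
  mrna <- expression_matrix(counts, mfeat, stage = "raw_count")

  # immune fractions: softmax of per-cell-type predictors
  nc <- config$n_cell_types
  base <- seq(0.5, -0.5, length.out = nc)
  eta <- matrix(stats::rnorm(n * nc, 0, 0.3), n, nc)
  eta <- sweep(eta, 2, base, `+`)
  drv_lnc <- 1L                          # designated driver lncRNA
  drv_cell <- 1L
  xl <- x[, drv_lnc] - mean(x[, drv_lnc])
  eta[, drv_cell] <- eta[, drv_cell] + config$immune_gamma * xl
  frac <- exp(eta)
  frac <- frac / rowSums(frac)
  rownames(frac) <- rownames(counts)
  colnames(frac) <- sprintf("cell_type_%d", seq_len(nc))
  truth_immune <- data.frame(
    lncrna_id = colnames(x)[drv_lnc],
    cell_type = colnames(frac)[drv_cell],
    true_gamma = config$immune_gamma)

  list(mrna = mrna, fractions = immune_fraction_table(frac),
       truth_axes = truth_axes, truth_immune = truth_immune,
       confounder = u)
}

#' Simulate a complete cohort
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_expression()] and [simulate_downstream()].
#'
#' @param config A [sim_config()].
#' @return List with `genotypes`, `expression`, `covariates`, `mrna`,
#'   `fractions`, and `truth` (list of the three truth tables).
#' @export
simulate_cohort <- function(config = sim_config()) {
  gm <- simulate_genotypes(config)
  ex <- simulate_expression(gm, config)
  dn <- simulate_downstream(ex$expression, config)
  list(genotypes = gm, expression = ex$expression,
       covariates = ex$covariates,
       mrna = dn$mrna, fractions = dn$fractions,
       truth = list(eqtl = ex$truth, axes = dn$truth_axes,
                    immune = dn$truth_immune),
       confounder = dn$confounder)
}

# per-SNP mean imputation of missing dosages (matrix-scan convention)
impute_dosage <- function(dosage) {
  if (!anyNA(dosage)) return(dosage)
  mu <- colMeans(dosage, na.rm = TRUE)
  idx <- which(is.na(dosage), arr.ind = TRUE)
  dosage[idx] <- mu[idx[, 2]]
  dosage
}
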