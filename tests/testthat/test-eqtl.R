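test_that("cis/trans classification follows the 1 Mb window", {
  # feature chr1:2,000,000-2,001,000
  expect_equal(classify_pair("chr1", 1500000, "chr1", 2000000, 2001000),
               "cis")
  expect_equal(classify_pair("chr2", 1500000, "chr1", 2000000, 2001000),
               "trans")
  expect_equal(classify_pair("chr1", 3001001, "chr1", 2000000, 2001000),
               "trans")                        # 3,001,001 > 2,001,000 + 1e6
  expect_equal(classify_pair("chr1", 3001000, "chr1", 2000000, 2001000),
               "cis")                          # boundary inclusive
  expect_equal(classify_pair("chr1", 1000000, "chr1", 2000000, 2001000),
               "cis")                          # start - 1e6 boundary
  expect_error(classify_pair(NA, 1, "chr1", 1, 2), "chromosome")
})

test_that("noiseless association is recovered exactly", {
  n <- 30
  g <- rep(c(0, 1, 2), each = 10)
  y <- 0.5 * g
  gm <- genotype_matrix(matrix(g, n, dimnames = list(paste0("S", 1:n), NULL)),
                        data.frame(snp_id = "s", chrom = "chr1",
                                   pos = 1000L, ref = "A", alt = "B",
                                   info = NA_real_))
  em <- quick_em(matrix(y, n, 1, dimnames = list(paste0("S", 1:n), NULL)))
  rec <- scan_eqtl(gm, em, mode = "all")
  expect_equal(rec$beta, 0.5, tolerance = 1e-12)
  expect_lt(rec$p, 1e-200)
})

test_that("matrix fast path equals naive per-pair OLS", {
  co <- tiny_cohort(n_samples = 50, n_blocks = 4, snps_per_block = 5,
                    n_lncrna = 10, frac_low = 0, seed = 55)
  cov <- co$covariates
  cov$latent_factors <- estimate_latent_factors(co$em, k = 2,
                                                covariates = cov)
  rec <- scan_eqtl(co$gm, co$em, cov, mode = "all")
  expect_equal(nrow(co$gm$snps), 20)
  expect_equal(nrow(co$em$features), 10)
  for (i in seq_len(nrow(rec))) {
    df <- data.frame(y = co$em$values[, rec$feature_id[i]],
                     g = co$gm$dosage[, rec$snp_id[i]],
                     age = cov$age, sex = cov$sex,
                     f1 = cov$latent_factors[, 1],
                     f2 = cov$latent_factors[, 2])
    fit <- summary(lm(y ~ g + age + sex + f1 + f2, df))$coefficients["g", ]
    expect_lt(abs(rec$beta[i] - fit[1]), 1e-10)
    expect_lt(abs(rec$se[i] - fit[2]), 1e-10)
    expect_lt(abs(rec$p[i] - fit[4]), 1e-10)
  }
})

test_that("scan p-values are uniform under the null", {
  cfg <- sim_config(n_samples = 100, n_blocks = 20, snps_per_block = 5,
                    n_lncrna = 20, frac_cis = 0, frac_trans = 0,
                    frac_low = 0, sd_latent = 0, beta_scna = 0,
                    beta_meth = 0, beta_age = 0, beta_sex = 0, seed = 66)
  gm <- simulate_genotypes(cfg)
  ex <- simulate_expression(gm, cfg)
  emi <- inverse_normal_expression(
    quantile_normalize(filter_lncrna_expression(ex$expression)$expression))
  rec <- scan_eqtl(gm, emi, mode = "all")
  expect_gt(nrow(rec), 1500)
  expect_gt(ks.test(rec$p, "punif")$p.value, 0.01)
})

test_that("BH q-values match the hand computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "\\(0,1\\]")
  # significant-set monotonicity: lowering the cutoff never adds records
  set.seed(13)
  q <- bh_fdr(runif(100)^2)
  expect_true(all(which(q < 0.05) %in% which(q < 0.1)))
})

test_that("LD r2 is symmetric to allele flips and validates input", {
  set.seed(14)
  g <- rbinom(100, 2, 0.4)
  expect_equal(ld_r2(g, g), 1.0)
  expect_equal(ld_r2(g, 2 - g), 1.0)
  expect_error(ld_r2(g, rep(1, 100)), "monomorphic")
  g2 <- rbinom(2000, 2, 0.4)
  g3 <- rbinom(2000, 2, 0.4)
  expect_lt(ld_r2(g2, g3), 0.01)
})

test_that("greedy clumping matches a brute-force oracle", {
  set.seed(15)
  n <- 300
  # blocks of correlated SNPs at known positions
  cfg <- sim_config(n_samples = n,
                    blocks = data.frame(n_snps = rep(10, 3), maf = 0.3,
                                        r2 = 0.8), seed = 15)
  gm <- simulate_genotypes(cfg)
  idx <- seq_len(30)
  rec <- data.frame(snp_id = gm$snps$snp_id[idx],
                    chrom = gm$snps$chrom[idx], pos = gm$snps$pos[idx],
                    feature_id = "F", mode = "cis",
                    beta = 0.5, se = 0.1, t = 5,
                    p = runif(30, 1e-10, 1e-3), fdr = NA, n_samples = n)
  r2mat <- cor(gm$dosage[, idx])^2
  dimnames(r2mat) <- list(rec$snp_id, rec$snp_id)
  expected <- brute_clump(rec, r2mat)
  got <- clump(rec, gm)
  got_list <- setNames(lapply(got$members, sort), got$snp_id)
  expect_equal(got_list[order(names(got_list))],
               expected[order(names(expected))])
  # partition: every input SNP in exactly one clump
  expect_setequal(unlist(got$members), rec$snp_id)
  expect_equal(sum(got$n_members), 30)
  # tag p <= member p
  for (i in seq_len(nrow(got))) {
    expect_true(all(got$p[i] <= rec$p[match(got$members[[i]],
                                            rec$snp_id)] + 1e-15))
  }
})

test_that("clumping separates correlated SNPs beyond the distance gate", {
  n <- 100
  set.seed(16)
  g <- rbinom(n, 2, 0.4)
  dos <- cbind(g, g)            # r2 = 1
  rownames(dos) <- paste0("S", 1:n)
  gm <- genotype_matrix(dos, data.frame(
    snp_id = c("s1", "s2"), chrom = "chr1",
    pos = c(1000000L, 1600000L),   # 600 kb apart
    ref = "A", alt = "B", info = NA_real_))
  rec <- data.frame(snp_id = c("s1", "s2"), chrom = "chr1",
                    pos = c(1000000L, 1600000L), feature_id = "F",
                    mode = "cis", beta = 1, se = 0.1, t = 10,
                    p = c(1e-8, 1e-6), fdr = NA, n_samples = n)
  got <- clump(rec, gm)
  expect_equal(nrow(got), 2)
  # single record clumps to itself
  one <- clump(rec[1, ], gm)
  expect_equal(one$members[[1]], "s1")
})

test_that("multivariate revalidation nests the scan model", {
  co <- tiny_cohort(n_samples = 80, n_blocks = 4, n_lncrna = 8,
                    frac_low = 0, seed = 17)
  cis <- co$truth[co$truth$mode == "cis", ][1, ]
  # with no covariates beyond those of the scan design, the cis_G
  # coefficient equals the scan_eqtl output exactly
  cov0 <- co$covariates
  cov0$scna <- NULL
  cov0$methylation <- NULL
  v <- validate_multivariate(cis$feature_id, cis$snp_id, NULL,
                             co$gm, co$em, cov0)
  rec <- scan_eqtl(co$gm, co$em, cov0, mode = "all")
  rec <- rec[rec$snp_id == cis$snp_id & rec$feature_id == cis$feature_id, ]
  b <- v$coefficients[v$coefficients$term == "cis_G", ]
  expect_lt(abs(b$estimate - rec$beta), 1e-10)
  expect_lt(abs(b$se - rec$se), 1e-10)
})

test_that("collinear designs are rejected with the offending column named", {
  co <- tiny_cohort(n_samples = 60, n_blocks = 4, n_lncrna = 8,
                    frac_low = 0, seed = 18)
  cis <- co$truth[co$truth$mode == "cis", ][1, ]
  cov <- co$covariates
  # make SCNA identical to the cis genotype
  cov$scna[, cis$feature_id] <- co$gm$dosage[, cis$snp_id]
  expect_error(
    validate_multivariate(cis$feature_id, cis$snp_id, NULL, co$gm,
                          co$em, cov),
    "collinear")
})

test_that("the multivariate model removes planted SCNA confounding", {
  set.seed(19)
  reps <- 30
  bias1 <- bias2 <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_samples = 200, n_blocks = 4, n_lncrna = 4,
                      frac_cis = 1, frac_trans = 0, frac_low = 0,
                      sd_latent = 0, beta_meth = 0, beta_scna = 0.8,
                      scna_geno_corr = 0.8, noise_sd = 0.5,
                      seed = 1000 + r)
    gm <- simulate_genotypes(cfg)
    ex <- simulate_expression(gm, cfg)
    em <- log2_rpkm(ex$expression)   # keep the generative scale
    cis <- ex$truth[ex$truth$mode == "cis", ][1, ]
    rec <- scan_eqtl(gm, em, ex$covariates, mode = "all")
    rec <- rec[rec$snp_id == cis$snp_id &
                 rec$feature_id == cis$feature_id, ]
    v <- validate_multivariate(cis$feature_id, cis$snp_id, NULL, gm, em,
                               ex$covariates)
    b2 <- v$coefficients$estimate[v$coefficients$term == "cis_G"]
    bias1[r] <- rec$beta - cis$true_beta
    bias2[r] <- b2 - cis$true_beta
  }
  # genotype-correlated SCNA biases the marginal scan upward; adjusting
  # for SCNA removes most of it
  expect_gt(mean(bias1), 0.1)
  expect_lt(abs(mean(bias2)), 0.1)
  expect_true(wilcox.test(abs(bias1), abs(bias2), paired = TRUE,
                          alternative = "greater")$p.value < 0.01)
})
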