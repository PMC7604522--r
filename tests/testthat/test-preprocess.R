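test_that("purity filter keeps the boundary and validates input", {
  cov <- covariate_table(c("A", "B", "C"), age = c(50, 60, 70),
                         sex = c(0, 1, 0), purity = c(0.59, 0.60, 0.9))
  res <- filter_samples_by_purity(cov)
  expect_equal(res$samples, c("B", "C"))
  expect_equal(res$report$removed, 1)
  expect_equal(res$report$removed + res$report$retained, 3)

  cov2 <- covariate_table("A", 50, 0, 1.0)
  expect_equal(filter_samples_by_purity(cov2)$samples, "A")
  expect_error(filter_samples_by_purity(cov, threshold = 0.95),
               "every sample")
  cov3 <- covariate_table(c("A", "B"), c(50, 60), c(0, 1), c(NA, 0.8))
  expect_error(filter_samples_by_purity(cov3), "A")
})

test_that("HWE exact test matches brute-force enumeration for n <= 50", {
  for (n in c(5, 17, 50)) {
    for (naa in 0:min(n, 8)) {
      for (nAa in seq(0, n - naa, by = max(1, (n - naa) %/% 5))) {
        nAA <- n - naa - nAa
        expect_equal(hwe_exact_test(nAA, nAa, naa),
                     brute_hwe(nAA, nAa, naa), tolerance = 1e-12,
                     info = sprintf("counts %d/%d/%d", nAA, nAa, naa))
      }
    }
  }
  expect_equal(hwe_exact_test(25, 50, 25), 1.0)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  expect_equal(hwe_exact_test(100, 0, 0), 1.0)
  expect_error(hwe_exact_test(-1, 0, 5), ">= 0")
})

test_that("genotype QC applies INFO, missingness, MAF and HWE in order", {
  n <- 100
  set.seed(5)
  dos <- cbind(
    good = rbinom(n, 2, 0.3),
    low_info = rbinom(n, 2, 0.3),
    missing6 = rbinom(n, 2, 0.3),
    rare = rbinom(n, 2, 0.02),
    hwe_bad = c(rep(0, 50), rep(2, 50)))
  dos[1:6, "missing6"] <- NA            # 6% missing -> removed
  rownames(dos) <- paste0("S", 1:n)
  snps <- data.frame(snp_id = colnames(dos), chrom = "chr1",
                     pos = 1:5 * 1000L, ref = "A", alt = "B",
                     info = c(0.9, 0.4, 0.9, 0.9, 0.9))
  gm <- genotype_matrix(dos, snps)
  res <- qc_genotypes(gm)
  expect_equal(res$genotypes$snps$snp_id, "good")
  expect_equal(res$report$removed[res$report$step == "info"], 1)
  expect_equal(res$report$removed[res$report$step == "missing"], 1)
  expect_equal(res$report$removed[res$report$step == "maf"], 1)
  expect_equal(res$report$removed[res$report$step == "hwe"], 1)
  # conservation at every filter
  expect_true(all(res$report$removed + res$report$retained ==
                    res$report$input))
  # MAF from non-missing calls: dosages 0,1,2,2 -> 5/8 alt -> maf 3/8
  gm2 <- genotype_matrix(
    matrix(c(0, 1, 2, 2), 4, dimnames = list(paste0("S", 1:4), NULL)),
    data.frame(snp_id = "x", chrom = "chr1", pos = 1L, ref = "A",
               alt = "B", info = NA_real_))
  expect_equal(unname(gm2$snps$maf), 0.375)
  expect_equal(nrow(qc_genotypes(gm2)$genotypes$snps), 1)
})

test_that("call posteriors below 0.7 are masked before the missing filter", {
  n <- 40
  set.seed(6)
  dos <- matrix(rbinom(2 * n, 2, 0.4), n, 2,
                dimnames = list(paste0("S", 1:n), NULL))
  post <- matrix(1, n, 2)
  post[1:3, 2] <- 0.5                    # 7.5% low-posterior calls
  gm <- genotype_matrix(dos, data.frame(snp_id = c("a", "b"),
                                        chrom = "chr1", pos = c(1L, 2L),
                                        ref = "A", alt = "B",
                                        info = NA_real_),
                        posterior = post)
  res <- qc_genotypes(gm)
  expect_equal(res$genotypes$snps$snp_id, "a")
  expect_equal(res$report$removed[res$report$step == "missing"], 1)
})

test_that("lncRNA percentile filter implements both RPKM rules", {
  set.seed(7)
  n <- 50
  vals <- cbind(
    zeros30 = ifelse(runif(n) < 0.3, 0, rexp(n)),  # q10 = 0 -> out
    low = rep(0.05, n),                            # q90 <= 0.1 -> out
    keep = rep(1.0, n))
  rownames(vals) <- paste0("S", 1:n)
  em <- quick_em(vals, stage = "raw_rpkm")
  res <- filter_lncrna_expression(em)
  expect_equal(res$expression$features$feature_id, "keep")
  expect_equal(res$expression$stage, "filtered")
  expect_equal(res$report$removed, 2)
})

test_that("quantile normalization equalizes per-sample distributions", {
  em <- quick_em(rbind(S1 = c(1, 2, 3), S2 = c(10, 20, 30)))
  qn <- quantile_normalize(em)
  expect_equal(unname(qn$values["S1", ]), c(5.5, 11, 16.5))
  expect_equal(unname(qn$values["S2", ]), c(5.5, 11, 16.5))

  set.seed(8)
  em2 <- quick_em(matrix(rgamma(200, 2), 10, 20,
                         dimnames = list(paste0("S", 1:10), NULL)))
  qn2 <- quantile_normalize(em2)
  sorted <- apply(qn2$values, 1, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))

  expect_error(quantile_normalize(quick_em(matrix(1:4, 4, 1))),
               "2 features")
})

test_that("inverse normal transform uses Blom scores and is rank-based", {
  expect_equal(inverse_normal_transform(c(1, 2, 3)),
               c(-0.8694, 0, 0.8694), tolerance = 1e-4)
  set.seed(9)
  x <- rexp(31)
  expect_equal(inverse_normal_transform(x),
               inverse_normal_transform(log(x + 5)))  # monotone invariance
  expect_equal(mean(inverse_normal_transform(x)), 0, tolerance = 1e-12)
  expect_error(inverse_normal_transform(rep(2, 10)), "constant")
  expect_error(inverse_normal_transform(c(1, 2)), "length")
})

test_that("log2 transform is elementwise log2(x+1)", {
  em <- quick_em(rbind(S1 = c(0, 1, 3), S2 = c(7, 15, 31)))
  lg <- log2_rpkm(em)
  expect_equal(unname(lg$values["S1", ]), c(0, 1, 2))
  expect_equal(unname(lg$values["S2", ]), c(3, 4, 5))
  em$values[1, 1] <- -1
  expect_error(log2_rpkm(em), "negative")
})

test_that("latent factors recover a planted batch shift", {
  set.seed(10)
  n <- 60; p <- 40
  batch <- rep(c(0, 1), each = n / 2)
  E <- matrix(rnorm(n * p), n, p) + outer(batch, rnorm(p, 2, 0.2))
  rownames(E) <- paste0("S", 1:n)
  f <- estimate_latent_factors(quick_em(E, stage = "inverse_normal"), k = 3)
  expect_gt(abs(cor(f[, 1], batch)), 0.9)

  # iid noise: each factor explains roughly 1/min(n,p) of total variance
  E0 <- matrix(rnorm(n * p), n, p, dimnames = list(paste0("S", 1:n), NULL))
  f0 <- estimate_latent_factors(quick_em(E0, stage = "inverse_normal"),
                                k = 3)
  sv <- svd(scale(E0, scale = FALSE))$d^2
  # Marchenko-Pastur-style sanity bound: top share ~ (1+sqrt(p/n))^2 / p
  expect_lt(sv[1] / sum(sv), 4 / min(n, p))
  expect_error(estimate_latent_factors(quick_em(E), k = 40), "k must be")
})

test_that("promoter methylation discretizes at 0.2/0.6 with median pooling", {
  beta <- rbind(S1 = c(0.1, 0.1, 0.15, 0.7, 0.55),
                S2 = c(0.9, 0.85, 0.9, 0.6, 0.65))
  probes <- c("g1", "g1", "g1", "g2", "g2")
  lv <- discretize_methylation(beta, probes)
  expect_equal(unname(lv["S1", "g1"]), 0)   # median 0.1
  expect_equal(unname(lv["S2", "g1"]), 2)   # median 0.9
  expect_equal(unname(lv["S2", "g2"]), 2)   # median 0.625 > 0.6
  # boundary: median exactly 0.6 -> level 1
  expect_equal(unname(discretize_methylation(
    rbind(S1 = c(0.6, 0.6)), c("g", "g"))["S1", "g"]), 1)
  expect_warning(discretize_methylation(beta, probes,
                                        features = c("g1", "g2", "g3")),
                 "no promoter probes")
  expect_error(discretize_methylation(rbind(S1 = 1.2), "g"), "\\[0,1\\]")
})

test_that("mRNA IV prefilter applies CV and count-percentile rules", {
  n <- 50
  set.seed(12)
  counts <- cbind(
    constant = rep(100, n),                    # CV 0 -> out
    capped = c(rep(2, n - 5), rep(31, 5)),     # q90 log2(32)=5, not >5 -> out
    zeromean = rep(0, n),                      # CV undefined -> out
    good = round(rexp(n, 1 / 80)) + 3)         # heavy-tailed, q30>0
  rownames(counts) <- paste0("S", 1:n)
  em <- expression_matrix(counts,
                          data.frame(feature_id = colnames(counts),
                                     chrom = "chr9",
                                     start = 1:4 * 1000L,
                                     end = 1:4 * 1000L + 999L,
                                     strand = "+", biotype = "mRNA"),
                          stage = "raw_count")
  res <- filter_mrna_for_iv(em)
  expect_equal(res$expression$features$feature_id, "good")
  expect_equal(res$report$removed + res$report$retained, 4)
})
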