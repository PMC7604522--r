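test_that("fold enrichment follows the proportion-ratio definition", {
  # 2x2 [[10,90],[10,890]] -> fold = (10/100)/(10/900) = 9
  fe <- enrichment_result(10, 90, 10, 890)
  expect_equal(fe$fold, 9.0)
  expect_lt(fe$p, 0.001)
  # equal fractions -> fold 1
  expect_equal(enrichment_result(5, 45, 20, 180)$fold, 1.0)
  # flag-vector interface
  fe2 <- fold_enrichment(c(rep(TRUE, 10), rep(FALSE, 90)),
                         c(rep(TRUE, 10), rep(FALSE, 890)))
  expect_equal(fe2$fold, 9.0)
  expect_error(fold_enrichment(logical(0), TRUE), "non-empty")
})

test_that("set enrichment computes cross-product OR with Woolf CI", {
  universe <- paste0("L", 1:70)
  query <- universe[1:20]
  annotation <- universe[11:30]           # overlap 10 -> 2x2 [10,10;10,40]
  se <- set_enrichment(query, annotation, universe)
  expect_equal(c(se$a, se$b, se$c, se$d), c(10, 10, 10, 40))
  expect_equal(se$odds_ratio, 4.0)
  ci_width <- exp(qnorm(0.975) * sqrt(1 / 10 + 1 / 10 + 1 / 10 + 1 / 40))
  expect_equal(se$ci_high / se$odds_ratio, ci_width, tolerance = 1e-12)
  # depletion direction
  dep <- set_enrichment(universe[1:30], universe[31:70], universe)
  expect_lt(dep$odds_ratio, 1)
  expect_error(set_enrichment("a", "b", character(0)), "universe")
})

test_that("Fisher p matches brute-force hypergeometric enumeration", {
  set.seed(26)
  for (i in 1:25) {
    n_univ <- sample(20:200, 1)
    a <- sample(0:10, 1); b <- sample(0:15, 1); c <- sample(0:15, 1)
    d <- n_univ - a - b - c
    if (d < 0) next
    er <- enrichment_result(a, b, c, d)
    expect_equal(er$p, brute_fisher_p(a, b, c, d), tolerance = 1e-9,
                 info = sprintf("table %d %d %d %d", a, b, c, d))
  }
})

test_that("OR direction agrees with one-sided Fisher tests", {
  set.seed(27)
  for (i in 1:20) {
    tab <- matrix(sample(1:40, 4, replace = TRUE), 2)
    er <- enrichment_result(tab[1], tab[3], tab[2], tab[4])
    p_up <- fisher.test(matrix(c(tab[1], tab[3], tab[2], tab[4]), 2,
                               byrow = TRUE), alternative = "greater")$p.value
    p_dn <- fisher.test(matrix(c(tab[1], tab[3], tab[2], tab[4]), 2,
                               byrow = TRUE), alternative = "less")$p.value
    if (er$odds_ratio > 1) expect_lte(p_up, p_dn)
    if (er$odds_ratio < 1) expect_lte(p_dn, p_up)
  }
})

test_that("LD proxies respect the r2 and distance gates", {
  set.seed(28)
  n <- 400
  g1 <- rbinom(n, 2, 0.4)
  flip <- function(g, k) { i <- sample(n, k); g[i] <- rbinom(k, 2, 0.4); g }
  dos <- cbind(tag = g1,
               strong = flip(g1, 60),      # high r2, within window
               weak = flip(g1, 300),       # low r2
               far = g1)                   # r2 = 1 but 600 kb away
  rownames(dos) <- paste0("S", 1:n)
  gm <- genotype_matrix(dos, data.frame(
    snp_id = colnames(dos), chrom = "chr1",
    pos = c(1000000L, 1100000L, 1050000L, 1600000L),
    ref = "A", alt = "B", info = NA_real_))
  expect_gt(ld_r2(dos[, "tag"], dos[, "strong"]), 0.5)
  expect_lt(ld_r2(dos[, "tag"], dos[, "weak"]), 0.5)
  catalog <- data.frame(snp_id = c("tag", "absent"), chrom = "chr1",
                        pos = c(1000000L, 5L), trait = "cancer")
  expect_message(px <- build_ld_proxies(catalog, gm), "absent")
  expect_setequal(px$tag, c("tag", "strong"))

  ic <- gwas_intercept(c("strong", "weak", "far"), px)
  expect_equal(unname(ic$flag), c(TRUE, FALSE, FALSE))
  expect_equal(ic$percent, 100 / 3)
  expect_equal(gwas_intercept(c("a", "b"), list())$percent, 0)
  expect_equal(gwas_intercept("tag", px)$percent, 100)
})

test_that("peak overlap uses the half-open convention", {
  ps <- peak_set(data.frame(chrom = "chr1", start0 = 100L, end = 200L))
  # 1-based pos 101 is the 0-based point 100 (interval start): inside
  # 1-based pos 201 is the 0-based point 200 (interval end): outside
  res <- peak_overlap_enrichment(
    data.frame(chrom = "chr1", pos = c(101L, 201L)), ps,
    data.frame(chrom = "chr1", pos = c(150L, 500L)))
  expect_equal(c(res$a, res$b), c(1, 1))
  expect_equal(c(res$c, res$d), c(1, 1))
  # extreme table: all query inside, no background -> Haldane-corrected OR
  res2 <- peak_overlap_enrichment(
    data.frame(chrom = "chr1", pos = rep(150L, 5)), ps,
    data.frame(chrom = "chr1", pos = rep(500L, 5)))
  expect_true(res2$corrected)
  expect_true(is.finite(res2$odds_ratio))
  # empty peak set -> undefined, flagged
  empty <- peak_set(data.frame(chrom = character(), start0 = integer(),
                               end = integer()))
  res3 <- peak_overlap_enrichment(data.frame(chrom = "chr1", pos = 1L),
                                  empty,
                                  data.frame(chrom = "chr1", pos = 2L))
  expect_true(res3$undefined)
})

test_that("meta-analysis pools log odds ratios by inverse variance", {
  mk <- function(a, b, c, d) enrichment_result(a, b, c, d)
  # identical strata: pooled OR equals the stratum OR, I2 = 0
  same <- list(mk(10, 20, 5, 25), mk(10, 20, 5, 25))
  m <- meta_enrichment(same)
  expect_equal(m$or_fixed, same[[1]]$odds_ratio, tolerance = 1e-12)
  expect_equal(m$or_random, same[[1]]$odds_ratio, tolerance = 1e-12)
  expect_equal(m$I2, 0)
  # hand-computable case: log-ORs 0 and 1 with equal SE 0.5 -> FE pooled 0.5
  s1 <- structure(list(odds_ratio = 1, se_log_or = 0.5),
                  class = "enrichment_result")
  s2 <- structure(list(odds_ratio = exp(1), se_log_or = 0.5),
                  class = "enrichment_result")
  m2 <- meta_enrichment(list(s1, s2))
  expect_equal(m2$log_or_fixed, 0.5, tolerance = 1e-12)
  expect_error(meta_enrichment(list(s1)), "at least 2")
  bad <- structure(list(odds_ratio = 1, se_log_or = 0),
                   class = "enrichment_result")
  expect_error(meta_enrichment(list(s1, bad)), "zero SE")
})

test_that("meta-analysis agrees with metafor on random strata", {
  skip_if_not_installed("metafor")
  set.seed(29)
  strata <- lapply(1:4, function(i) {
    enrichment_result(sample(5:30, 1), sample(5:30, 1),
                      sample(5:30, 1), sample(5:30, 1))
  })
  m <- meta_enrichment(strata)
  yi <- sapply(strata, function(s) log(s$odds_ratio))
  vi <- sapply(strata, function(s) s$se_log_or^2)
  fe <- metafor::rma(yi, vi, method = "FE")
  re <- metafor::rma(yi, vi, method = "DL")
  expect_equal(m$log_or_fixed, as.numeric(fe$beta), tolerance = 1e-8)
  expect_equal(m$log_or_random, as.numeric(re$beta), tolerance = 1e-8)
  expect_equal(m$tau2, re$tau2, tolerance = 1e-8)
  expect_equal(m$Q, as.numeric(fe$QE), tolerance = 1e-8)
})
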