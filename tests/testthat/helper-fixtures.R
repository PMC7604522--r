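# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk except the published summary tables
# shipped in inst/extdata.

# small aligned cohort for scan-level tests
tiny_cohort <- function(n_samples = 50, n_blocks = 4, snps_per_block = 5,
                        n_lncrna = 10, seed = 101, ...) {
  cfg <- sim_config(n_samples = n_samples, n_blocks = n_blocks,
                    snps_per_block = snps_per_block, n_lncrna = n_lncrna,
                    seed = seed, ...)
  gm <- simulate_genotypes(cfg)
  ex <- simulate_expression(gm, cfg)
  emi <- inverse_normal_expression(
    quantile_normalize(filter_lncrna_expression(ex$expression)$expression))
  list(cfg = cfg, gm = gm, raw = ex$expression, em = emi,
       covariates = ex$covariates, truth = ex$truth)
}

# brute-force exact HWE test by full table enumeration (independent oracle)
brute_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa
  if (min(na, 2 * n - na) == 0) return(1.0)
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  pr <- sapply(hets, function(h) {
    aa <- (na - h) / 2
    AA <- n - h - aa
    exp(lgamma(n + 1) - lgamma(AA + 1) - lgamma(h + 1) - lgamma(aa + 1) +
          h * log(2) +
          lgamma(na + 1) + lgamma(2 * n - na + 1) - lgamma(2 * n + 1))
  })
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  sum(pr[pr <= obs + 1e-12])
}

# independent greedy clumping oracle working directly on an r2 matrix
brute_clump <- function(rec, r2mat, r2_min = 0.2, window_bp = 5e5) {
  ord <- order(rec$p, rec$chrom, rec$pos, rec$snp_id)
  rec <- rec[ord, , drop = FALSE]
  assigned <- rep(FALSE, nrow(rec))
  clumps <- list()
  while (!all(assigned)) {
    tag <- which(!assigned)[1]
    assigned[tag] <- TRUE
    members <- rec$snp_id[tag]
    for (i in which(!assigned)) {
      if (rec$chrom[i] == rec$chrom[tag] &&
          abs(rec$pos[i] - rec$pos[tag]) <= window_bp &&
          r2mat[rec$snp_id[tag], rec$snp_id[i]] >= r2_min) {
        assigned[i] <- TRUE
        members <- c(members, rec$snp_id[i])
      }
    }
    clumps[[rec$snp_id[tag]]] <- sort(members)
  }
  clumps
}

# two-sided Fisher p by hypergeometric enumeration (independent oracle)
brute_fisher_p <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; k <- a + b
  xs <- max(0, k - nn):min(k, m)
  pr <- dhyper(xs, m, nn, k)
  obs <- dhyper(a, m, nn, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# minimal expression matrix from a plain values matrix
quick_em <- function(values, stage = "filtered", chrom = "chr1") {
  p <- ncol(values)
  expression_matrix(
    values,
    data.frame(feature_id = colnames(values) %||%
                 paste0("F", seq_len(p)),
               chrom = chrom, start = seq_len(p) * 1000L,
               end = seq_len(p) * 1000L + 999L,
               strand = "+", biotype = "lncRNA"),
    stage = stage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
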