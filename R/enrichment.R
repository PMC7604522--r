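# ---------------------------------------------------------------------------
# GWAS risk-locus LD interception, Fisher-exact set / peak-overlap
# enrichment, fold enrichment, and inverse-variance meta-analysis across
# epigenetic markers.
# ---------------------------------------------------------------------------

#' Build an enrichment result from a 2x2 table
#'
#' Counts are laid out as a = query & annotated, b = query & not,
#' c = background & annotated, d = background & not. The odds ratio is the
#' sample cross-product ad/bc with a Woolf log-interval 95% CI; the Haldane
#' 0.5 continuity correction is applied to OR and CI only when a zero cell
#' occurs. p is the two-sided Fisher exact probability.
#'
#' @param a,b,c,d 2x2 counts.
#' @param set_name Label.
#' @param alternative Passed to [stats::fisher.test()].
#' @return List of class `enrichment_result` with `a..d`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p`, `fold` (proportion ratio), `corrected`
#'   (TRUE when Haldane correction was used).
#' @export
enrichment_result <- function(a, b, c, d, set_name = NA_character_,
                              alternative = "two.sided") {
  stopifnot(all(c(a, b, c, d) >= 0))
  tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  zero <- any(tab == 0)
  cc <- if (zero) 0.5 else 0
  or <- ((a + cc) * (d + cc)) / ((b + cc) * (c + cc))
  se_log <- sqrt(1 / (a + cc) + 1 / (b + cc) + 1 / (c + cc) + 1 / (d + cc))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se_log)
  fold <- if (c + d > 0 && c > 0) {
    (a / (a + b)) / (c / (c + d))
  } else Inf
  structure(list(set_name = set_name, a = a, b = b, c = c, d = d,
                 odds_ratio = or, se_log_or = se_log,
                 ci_low = ci[1], ci_high = ci[2], p = p, fold = fold,
                 corrected = zero),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result", if (!is.na(x$set_name)) paste0("[", x$set_name, "]"),
      "\n  2x2:", x$a, x$b, "/", x$c, x$d, "\n")
  cat(sprintf("  OR = %.3f (95%% CI %.3f-%.3f), fold = %.3f, p = %.3g\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$fold, x$p))
  invisible(x)
}

#' LD proxies of GWAS catalog SNPs
#'
#' For each catalog risk SNP present in the reference panel, returns the
#' SNPs within `window_bp` and with genotypic r^2 >= `r2_min` (the tag
#' itself included). Catalog SNPs absent from the panel are skipped with a
#' message.
#'
#' @param catalog A [read_gwas_catalog()] table.
#' @param gm Reference [genotype_matrix()].
#' @param r2_min LD threshold (default 0.5).
#' @param window_bp Distance limit (default 5e5).
#' @return Named list tag snp_id -> character vector of proxy snp_ids.
#' @export
build_ld_proxies <- function(catalog, gm, r2_min = 0.5, window_bp = 5e5) {
  present <- catalog$snp_id %in% gm$snps$snp_id
  if (any(!present)) {
    message("build_ld_proxies: ", sum(!present),
            " catalog SNPs absent from the reference panel; skipped")
  }
  tags <- unique(catalog$snp_id[present])
  snps <- gm$snps
  out <- list()
  for (tg in tags) {
    i <- match(tg, snps$snp_id)
    cand <- which(snps$chrom == snps$chrom[i] &
                    abs(snps$pos - snps$pos[i]) <= window_bp)
    gt <- gm$dosage[, i]
    keep <- vapply(cand, function(j) {
      if (j == i) return(TRUE)
      r2 <- tryCatch(ld_r2(gt, gm$dosage[, j]), error = function(e) 0)
      r2 >= r2_min
    }, TRUE)
    out[[tg]] <- snps$snp_id[cand[keep]]
  }
  out
}

#' Flag eQTLs intercepting GWAS risk loci
#'
#' @param eqtl_snps Character vector of eQTL snp_ids.
#' @param proxy_map Output of [build_ld_proxies()].
#' @return List with `flag` (named logical per eQTL) and `percent`
#'   (flagged share in percent).
#' @export
gwas_intercept <- function(eqtl_snps, proxy_map) {
  proxies <- unique(unlist(proxy_map, use.names = FALSE))
  flag <- stats::setNames(eqtl_snps %in% proxies, eqtl_snps)
  pct <- if (length(flag)) 100 * mean(flag) else 0
  list(flag = flag, percent = pct)
}

#' Fold enrichment of a flag between eQTLs and non-eQTLs
#'
#' fold = (flagged fraction among eQTLs) / (flagged fraction among
#' background SNPs), with the Fisher exact p on the 2x2 table. A zero
#' flagged fraction in the background yields fold = Inf (flagged in the
#' result; the OR side uses the Haldane correction).
#'
#' @param eqtl_flags Logical vector over eQTL SNPs.
#' @param background_flags Logical vector over background (non-eQTL) SNPs.
#' @return An [enrichment_result()] (set_name "gwas_fold").
#' @export
fold_enrichment <- function(eqtl_flags, background_flags) {
  if (!length(eqtl_flags) || !length(background_flags)) {
    stop("both groups must be non-empty")
  }
  enrichment_result(sum(eqtl_flags), sum(!eqtl_flags),
                    sum(background_flags), sum(!background_flags),
                    set_name = "gwas_fold")
}

#' Fisher-exact set enrichment
#'
#' Tests whether `query` is enriched for `annotation` within `universe`.
#'
#' @param query,annotation Character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible ids.
#' @param set_name Label.
#' @return An [enrichment_result()].
#' @export
set_enrichment <- function(query, annotation, universe,
                           set_name = NA_character_) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  annotation <- intersect(unique(annotation), universe)
  a <- length(intersect(query, annotation))
  b <- length(query) - a
  c <- length(annotation) - a
  d <- length(universe) - a - b - c
  enrichment_result(a, b, c, d, set_name = set_name)
}

#' Peak-overlap enrichment of SNP positions
#'
#' Membership of a position is inclusion of its 1-bp point in a half-open
#' peak interval (a SNP at the 0-based interval start is inside; at the
#' end coordinate it is outside).
#'
#' @param snp_pos data.frame with `chrom`, `pos` (1-based) for the query
#'   SNPs.
#' @param peaks A [peak_set()].
#' @param background_pos data.frame with `chrom`, `pos` for the background
#'   SNPs.
#' @return An [enrichment_result()] (set_name = the peak marker), or a
#'   result flagged `undefined` when the peak set is empty.
#' @export
peak_overlap_enrichment <- function(snp_pos, peaks, background_pos) {
  if (!nrow(peaks$intervals)) {
    out <- list(set_name = peaks$marker_name, undefined = TRUE)
    class(out) <- "enrichment_result"
    return(out)
  }
  inpeak <- function(df) {
    if (!nrow(df)) return(logical(0))
    gr <- GenomicRanges::GRanges(
      peaks$intervals$chrom,
      IRanges::IRanges(start = peaks$intervals$start0 + 1L,
                       end = peaks$intervals$end))
    q <- GenomicRanges::GRanges(df$chrom,
                                IRanges::IRanges(df$pos, df$pos))
    IRanges::overlapsAny(q, gr)
  }
  qf <- inpeak(snp_pos)
  bf <- inpeak(background_pos)
  enrichment_result(sum(qf), sum(!qf), sum(bf), sum(!bf),
                    set_name = peaks$marker_name)
}

#' Meta-analysis of enrichment across strata
#'
#' Pools per-stratum log odds ratios by inverse-variance weighting:
#' fixed-effect estimate, DerSimonian-Laird random-effects estimate,
#' Cochran Q and I^2. Random effects are reported as the default
#' (`odds_ratio` field).
#'
#' @param results List of [enrichment_result()] objects (>= 2) with finite
#'   log-OR and SE.
#' @return List of class `meta_enrichment`: `k`, `or_fixed`, `ci_fixed`,
#'   `or_random`, `ci_random`, `odds_ratio` (= random), `tau2`, `Q`,
#'   `I2`, `p_random`.
#' @export
meta_enrichment <- function(results) {
  if (length(results) < 2) stop("need at least 2 strata")
  yi <- vapply(results, function(r) log(r$odds_ratio), 0)
  sei <- vapply(results, function(r) r$se_log_or, 0)
  if (any(!is.finite(yi)) || any(!is.finite(sei))) {
    stop("stratum with non-finite log-OR or SE")
  }
  if (any(sei <= 0)) stop("stratum with zero SE")
  wi <- 1 / sei^2
  mu_f <- sum(wi * yi) / sum(wi)
  se_f <- sqrt(1 / sum(wi))
  Q <- sum(wi * (yi - mu_f)^2)
  k <- length(yi)
  tau2 <- max(0, (Q - (k - 1)) / (sum(wi) - sum(wi^2) / sum(wi)))
  wr <- 1 / (sei^2 + tau2)
  mu_r <- sum(wr * yi) / sum(wr)
  se_r <- sqrt(1 / sum(wr))
  z <- stats::qnorm(0.975)
  I2 <- if (Q > 0) max(0, 100 * (Q - (k - 1)) / Q) else 0
  structure(list(
    k = k,
    or_fixed = exp(mu_f), ci_fixed = exp(mu_f + c(-1, 1) * z * se_f),
    or_random = exp(mu_r), ci_random = exp(mu_r + c(-1, 1) * z * se_r),
    odds_ratio = exp(mu_r),
    log_or_fixed = mu_f, log_or_random = mu_r,
    se_fixed = se_f, se_random = se_r,
    tau2 = tau2, Q = Q, I2 = I2,
    p_random = 2 * stats::pnorm(abs(mu_r / se_r), lower.tail = FALSE)),
    class = "meta_enrichment")
}

#' @export
print.meta_enrichment <- function(x, ...) {
  cat("meta_enrichment over", x$k, "strata\n")
  cat(sprintf("  fixed:  OR = %.3f (%.3f-%.3f)\n", x$or_fixed,
              x$ci_fixed[1], x$ci_fixed[2]))
  cat(sprintf("  random: OR = %.3f (%.3f-%.3f), tau2 = %.4f\n",
              x$or_random, x$ci_random[1], x$ci_random[2], x$tau2))
  cat(sprintf("  Q = %.3f, I2 = %.1f%%\n", x$Q, x$I2))
  invisible(x)
}
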