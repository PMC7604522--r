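# ---------------------------------------------------------------------------
# Two-stage least-squares instrumental-variable estimation of
# eQTL -> lncRNA -> mRNA regulatory axes and eQTL -> lncRNA -> immune
# fraction effects, with weak-instrument diagnostics and the prefilters.
# ---------------------------------------------------------------------------

#' Spearman prefilter of lncRNA-mRNA candidate pairs
#'
#' @param lnc,mrna Aligned numeric vectors (n >= 10).
#' @param rho_min Threshold on |rho| (default 0.3; strictly above keeps).
#' @return List with `rho` and `keep`; constant input gives `keep = FALSE`
#'   with `rho = NA` and a warning.
#' @export
spearman_prefilter <- function(lnc, mrna, rho_min = 0.3) {
  stopifnot(length(lnc) == length(mrna), length(lnc) >= 10)
  if (stats::sd(lnc) == 0 || stats::sd(mrna) == 0) {
    warning("constant vector: Spearman rho undefined; pair dropped")
    return(list(rho = NA_real_, keep = FALSE))
  }
  rho <- stats::cor(lnc, mrna, method = "spearman")
  list(rho = rho, keep = abs(rho) > rho_min)
}

#' Two-stage least squares with a single genetic instrument
#'
#' Stage 1 regresses the exposure on the instrument (plus covariates) and
#' stage 2 regresses the outcome on the fitted exposure (plus covariates).
#' The reported SE is the 2SLS-consistent one: residuals are taken from
#' the structural equation y - X b (observed exposure, 2SLS coefficients),
#' not from the second-stage fit. For one instrument and no covariates the
#' estimate equals the Wald ratio cov(y, g) / cov(x, g).
#'
#' @param g Instrument dosage vector.
#' @param x Exposure vector.
#' @param y Outcome vector.
#' @param covariates Optional numeric matrix of exogenous covariates.
#' @return List of class `iv_result`: `beta_2sls`, `se`, `t`, `p`,
#'   `adj_r2` (structural fit), `first_stage_f`, `first_stage_p`, `n`,
#'   `weak_instrument` (F < 10), `ols_beta` (naive OLS of y on x for
#'   comparison).
#' @export
two_stage_least_squares <- function(g, x, y, covariates = NULL) {
  ok <- stats::complete.cases(g, x, y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & stats::complete.cases(covariates)
    covariates <- covariates[ok, , drop = FALSE]
  }
  g <- g[ok]; x <- x[ok]; y <- y[ok]
  n <- length(y)
  if (stats::var(g) == 0) stop("instrument is constant in sample")
  C <- cbind(intercept = rep(1, n), covariates)
  Z <- cbind(C, g = g)                      # instruments incl. exogenous
  X <- cbind(C, x = x)                      # structural regressors
  # first stage: x on instrument + covariates; partial F for g
  f1 <- stats::lm.fit(Z, x)
  rss1 <- sum(f1$residuals^2)
  rss0 <- sum(stats::lm.fit(C, x)$residuals^2)
  df1 <- n - ncol(Z)
  fstat <- if (rss1 > 0) (rss0 - rss1) / (rss1 / df1) else Inf
  fp <- stats::pf(fstat, 1, df1, lower.tail = FALSE)
  if (is.finite(fstat) && fstat < .Machine$double.eps) {
    warning("first-stage F is 0: instrument unrelated to exposure")
  }
  # second stage on fitted exposure
  xhat <- x - f1$residuals
  X2 <- cbind(C, x = xhat)
  fit2 <- stats::lm.fit(X2, y)
  b <- fit2$coefficients
  # 2SLS-consistent covariance: sigma^2 from structural residuals,
  # (X2'X2)^{-1} from the projected design
  u <- y - X %*% b
  df2 <- n - ncol(X2)
  sigma2 <- sum(u^2) / df2
  XtXinv <- chol2inv(chol(crossprod(X2)))
  se <- sqrt(diag(XtXinv) * sigma2)
  bx <- b[["x"]]
  sex <- se[ncol(X2)]
  tstat <- bx / sex
  pval <- 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum(u^2) / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df2
  ols <- stats::lm.fit(X, y)$coefficients[["x"]]
  structure(list(beta_2sls = bx, se = sex, t = tstat, p = pval,
                 r2 = r2, adj_r2 = adj_r2,
                 first_stage_f = fstat, first_stage_p = fp, n = n,
                 weak_instrument = is.finite(fstat) && fstat < 10,
                 ols_beta = ols),
            class = "iv_result")
}

#' @export
print.iv_result <- function(x, ...) {
  cat(sprintf("iv_result: beta = %.4f (se %.4f), p = %.3g, n = %d\n",
              x$beta_2sls, x$se, x$p, x$n))
  cat(sprintf("  first-stage F = %.2f%s, adj R2 = %.3f\n",
              x$first_stage_f,
              if (x$weak_instrument) " [weak instrument]" else "",
              x$adj_r2))
  invisible(x)
}

#' Estimate eQTL -> lncRNA -> mRNA regulatory axes
#'
#' For each clumped cis eQTL-lncRNA pair and each prefiltered mRNA, runs
#' single-instrument 2SLS (instrument = tag dosage, exposure = lncRNA,
#' outcome = log2(count+1) mRNA), pre-gated by the |Spearman| > 0.3 rule,
#' BH-corrects p across all tested axes, and reports axes with FDR and
#' adjusted-R2 below/above the gates.
#'
#' @param pairs data.frame with columns `snp_id`, `feature_id` (the clump
#'   tag and its lncRNA).
#' @param gm [genotype_matrix()].
#' @param lnc_em lncRNA [expression_matrix()]; the exposure scale is taken
#'   as log2(RPKM+1) when the stage is raw_rpkm, otherwise values are used
#'   as-is (e.g. inverse_normal).
#' @param mrna_em mRNA [expression_matrix()] at stage raw_count (will be
#'   prefiltered by [filter_mrna_for_iv()] unless `prefiltered = TRUE`).
#' @param covariates Optional [covariate_table()] (age, sex, latent
#'   factors enter both stages as exogenous covariates).
#' @param fdr_max,adj_r2_min Reporting gates (defaults 0.1 and 0.1).
#' @param rho_min Spearman prefilter threshold.
#' @param prefiltered Set TRUE when `mrna_em` already passed the count
#'   prefilter.
#' @return List with `axes` (passing records), `tested` (all tested axes
#'   with fdr), each a data.frame with instrument, exposure, outcome,
#'   beta, se, p, fdr, adj_r2, first_stage_f, n, weak_instrument.
#' @export
run_axes <- function(pairs, gm, lnc_em, mrna_em, covariates = NULL,
                     fdr_max = 0.1, adj_r2_min = 0.1, rho_min = 0.3,
                     prefiltered = FALSE) {
  if (!prefiltered) {
    mrna_em <- filter_mrna_for_iv(mrna_em)$expression
  }
  ids <- align_samples(rownames(gm$dosage), rownames(lnc_em$values),
                       rownames(mrna_em$values))
  lx <- lnc_em$values[ids, , drop = FALSE]
  if (lnc_em$stage %in% c("raw_rpkm", "filtered")) lx <- log2(lx + 1)
  my <- log2(mrna_em$values[ids, , drop = FALSE] + 1)
  G <- impute_dosage(gm$dosage[ids, , drop = FALSE])
  cm <- if (!is.null(covariates)) {
    cv <- subset_covariates(covariates, ids)
    covariate_design(cv, length(ids))[, -1, drop = FALSE]
  }
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    snp <- pairs$snp_id[i]; lnc <- pairs$feature_id[i]
    if (!(snp %in% colnames(G)) || !(lnc %in% colnames(lx))) next
    for (m in colnames(my)) {
      sp <- spearman_prefilter(lx[, lnc], my[, m], rho_min)
      if (!isTRUE(sp$keep)) next
      iv <- two_stage_least_squares(G[, snp], lx[, lnc], my[, m], cm)
      rows[[length(rows) + 1]] <- data.frame(
        instrument = snp, exposure = lnc, outcome = m,
        beta = iv$beta_2sls, se = iv$se, p = iv$p,
        adj_r2 = iv$adj_r2, first_stage_f = iv$first_stage_f,
        n = iv$n, weak_instrument = iv$weak_instrument,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    empty <- data.frame(instrument = character(), exposure = character(),
                        outcome = character(), beta = numeric(),
                        se = numeric(), p = numeric(), fdr = numeric(),
                        adj_r2 = numeric(), first_stage_f = numeric(),
                        n = integer(), weak_instrument = logical())
    return(list(axes = empty, tested = empty))
  }
  tested <- do.call(rbind, rows)
  tested$fdr <- bh_fdr(tested$p)
  tested <- tested[order(tested$p), ]
  rownames(tested) <- NULL
  axes <- tested[tested$fdr < fdr_max & tested$adj_r2 > adj_r2_min, ]
  rownames(axes) <- NULL
  list(axes = axes, tested = tested)
}

#' Estimate eQTL -> lncRNA -> immune-fraction effects
#'
#' For each significant eQTL-lncRNA pair and each immune cell type, runs
#' 2SLS with outcome log2(fraction + 1); keeps results with p < `p_max`
#' and model R^2 > `r2_min`. Cell types with all-zero fractions are
#' skipped.
#'
#' @param pairs data.frame with `snp_id`, `feature_id`.
#' @param gm [genotype_matrix()].
#' @param lnc_em lncRNA [expression_matrix()] (exposure, as in
#'   [run_axes()]).
#' @param fractions An [immune_fraction_table()].
#' @param covariates Optional [covariate_table()].
#' @param p_max,r2_min Reporting gates (defaults 0.05 and 0).
#' @return List with `hits` (passing records) and `tested`.
#' @export
run_immune <- function(pairs, gm, lnc_em, fractions, covariates = NULL,
                       p_max = 0.05, r2_min = 0) {
  ids <- align_samples(rownames(gm$dosage), rownames(lnc_em$values),
                       fractions$samples)
  lx <- lnc_em$values[ids, , drop = FALSE]
  if (lnc_em$stage %in% c("raw_rpkm", "filtered")) lx <- log2(lx + 1)
  fr <- fractions$fraction[match(ids, fractions$samples), , drop = FALSE]
  G <- impute_dosage(gm$dosage[ids, , drop = FALSE])
  cm <- if (!is.null(covariates)) {
    cv <- subset_covariates(covariates, ids)
    covariate_design(cv, length(ids))[, -1, drop = FALSE]
  }
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    snp <- pairs$snp_id[i]; lnc <- pairs$feature_id[i]
    if (!(snp %in% colnames(G)) || !(lnc %in% colnames(lx))) next
    for (ct in colnames(fr)) {
      if (all(fr[, ct] == 0)) {
        message("run_immune: cell type ", ct, " identically 0; skipped")
        next
      }
      y <- log2(fr[, ct] + 1)
      iv <- two_stage_least_squares(G[, snp], lx[, lnc], y, cm)
      rows[[length(rows) + 1]] <- data.frame(
        instrument = snp, exposure = lnc, outcome = ct,
        beta = iv$beta_2sls, se = iv$se, p = iv$p, r2 = iv$r2,
        adj_r2 = iv$adj_r2, first_stage_f = iv$first_stage_f,
        n = iv$n, weak_instrument = iv$weak_instrument,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    empty <- data.frame()
    return(list(hits = empty, tested = empty))
  }
  tested <- do.call(rbind, rows)
  rownames(tested) <- NULL
  hits <- tested[tested$p < p_max & tested$r2 > r2_min, ]
  rownames(hits) <- NULL
  list(hits = hits, tested = tested)
}
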