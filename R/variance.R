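# ---------------------------------------------------------------------------
# Sequential variance decomposition of expression, allelic effect-size
# summaries, and cross-cohort specificity bookkeeping.
# ---------------------------------------------------------------------------

#' Sequential variance partition of one feature's expression
#'
#' Adds factor groups to a nested OLS in the given order and reports the
#' increment in plain R^2 contributed by each group. Negative numerical
#' increments are floored at 0 (with the count of floored terms recorded);
#' the telescoping identity sum(increments) = full-model R^2 holds exactly
#' before flooring. Default order mirrors the expression model: age, sex,
#' latent factors, cis eQTL, trans eQTL, SCNA, methylation.
#'
#' @param y Numeric response (transformed expression of one feature).
#' @param factor_groups Named list of numeric vectors/matrices, in the
#'   order they should enter the model. NULL or zero-column entries are
#'   skipped.
#' @return List of class `variance_partition`: `increments` (named, floored
#'   at 0), `residual`, `full_r2`, `n_floored`.
#' @export
sequential_variance_partition <- function(y, factor_groups) {
  factor_groups <- Filter(function(g) {
    !is.null(g) && (is.null(dim(g)) || ncol(g) > 0)
  }, factor_groups)
  n <- length(y)
  p_total <- sum(vapply(factor_groups, function(g)
    if (is.null(dim(g))) 1L else ncol(g), 0L)) + 1L
  if (n <= p_total) stop("n must exceed the total parameter count")
  X <- matrix(1, n, 1)
  tss <- sum((y - mean(y))^2)
  r2 <- function(X) {
    fit <- stats::lm.fit(X, y)
    1 - sum(fit$residuals^2) / tss
  }
  prev <- 0
  inc <- numeric(length(factor_groups))
  names(inc) <- names(factor_groups)
  for (k in seq_along(factor_groups)) {
    X <- cbind(X, factor_groups[[k]])
    cur <- r2(X)
    inc[k] <- cur - prev
    prev <- cur
  }
  n_floored <- sum(inc < 0)
  inc_floored <- pmax(inc, 0)
  structure(list(increments = inc_floored, raw_increments = inc,
                 residual = 1 - prev, full_r2 = prev,
                 n_floored = n_floored),
            class = "variance_partition")
}

#' Variance partition for every feature of a cohort
#'
#' Builds, per feature, the factor groups in the fixed order (age, sex,
#' latent factors, cis tag genotype, trans tag genotype, SCNA,
#' methylation) and averages the per-feature floored increments.
#'
#' @param em Transformed [expression_matrix()].
#' @param covariates [covariate_table()].
#' @param cis_tags Named character vector feature_id -> cis tag snp_id.
#' @param trans_tags Named character vector feature_id -> trans tag snp_id.
#' @param gm [genotype_matrix()].
#' @return List with `per_feature` (data.frame of increments) and
#'   `average` (named mean shares including residual).
#' @export
variance_partition_cohort <- function(em, covariates, cis_tags,
                                      trans_tags = NULL, gm) {
  ids <- align_samples(rownames(em$values), covariates$samples,
                       rownames(gm$dosage))
  feats <- intersect(names(cis_tags), em$features$feature_id)
  rows <- list()
  for (f in feats) {
    y <- em$values[ids, f]
    cidx <- match(ids, covariates$samples)
    groups <- list(
      age = covariates$age[cidx],
      sex = covariates$sex[cidx],
      latent_factors = covariates$latent_factors[cidx, , drop = FALSE],
      cis_eqtl = impute_dosage(gm$dosage[ids, cis_tags[[f]], drop = FALSE]),
      trans_eqtl = if (!is.null(trans_tags) && f %in% names(trans_tags))
        impute_dosage(gm$dosage[ids, trans_tags[[f]], drop = FALSE]),
      scna = if (!is.null(covariates$scna)) covariates$scna[cidx, f],
      methylation = if (!is.null(covariates$methylation))
        covariates$methylation[cidx, f])
    vp <- sequential_variance_partition(y, groups)
    # fixed column set: groups absent for this feature contribute 0
    full <- c(age = 0, sex = 0, latent_factors = 0, cis_eqtl = 0,
              trans_eqtl = 0, scna = 0, methylation = 0)
    full[names(vp$increments)] <- vp$increments
    shares <- c(full, residual = vp$residual)
    rows[[f]] <- data.frame(feature_id = f, t(shares),
                            stringsAsFactors = FALSE)
  }
  per_feature <- do.call(rbind, rows)
  rownames(per_feature) <- NULL
  avg <- colMeans(per_feature[, -1, drop = FALSE])
  list(per_feature = per_feature, average = avg)
}

#' Summary of absolute allelic effect sizes
#'
#' Distribution of |beta| over clump-tag eSNPs (one record per clump).
#'
#' @param records data.frame of tag records with a `beta` column.
#' @return List with `n`, `mean_abs_beta`, `quantiles` (0, 25, 50, 75,
#'   100%), and `histogram` (counts over 0.1-wide |beta| bins).
#' @export
allelic_effect_summary <- function(records) {
  if (!nrow(records)) {
    return(list(n = 0L, mean_abs_beta = NA_real_, quantiles = NULL,
                histogram = NULL))
  }
  ab <- abs(records$beta)
  breaks <- seq(0, ceiling(max(ab) / 0.1) * 0.1, by = 0.1)
  h <- hist(ab, breaks = breaks, plot = FALSE)
  list(n = length(ab), mean_abs_beta = mean(ab),
       quantiles = stats::quantile(ab, c(0, 0.25, 0.5, 0.75, 1)),
       histogram = data.frame(bin_low = h$breaks[-length(h$breaks)],
                              bin_high = h$breaks[-1], count = h$counts))
}

#' Cross-cohort specificity of entities
#'
#' Counts, for each entity (eQTL or elncRNA id), the number of cohorts in
#' which it occurs, and summarizes the fraction specific to exactly one
#' cohort and the fraction occurring in more than `k` cohorts.
#'
#' @param cohort_sets Named list of character vectors (entity ids per
#'   cohort).
#' @param k Threshold for the "shared" fraction (default 8, i.e. entities
#'   present in more than 8 cohorts).
#' @return List with `counts` (entity, n_cohorts), `n_unique`,
#'   `frac_specific`, `frac_shared_gt_k`, and `per_cohort` percentages of
#'   each cohort's entities that are cohort-specific.
#' @export
cross_cohort_specificity <- function(cohort_sets, k = 8) {
  if (!length(cohort_sets)) stop("need at least one cohort")
  all_ids <- unlist(cohort_sets, use.names = FALSE)
  tab <- table(unlist(lapply(cohort_sets, unique)))
  counts <- data.frame(entity = names(tab), n_cohorts = as.integer(tab),
                       stringsAsFactors = FALSE)
  n_unique <- nrow(counts)
  specific <- counts$entity[counts$n_cohorts == 1]
  per_cohort <- vapply(cohort_sets, function(s) {
    if (!length(s)) return(NA_real_)
    100 * mean(unique(s) %in% specific)
  }, 0)
  list(counts = counts, n_unique = n_unique,
       frac_specific = mean(counts$n_cohorts == 1),
       frac_shared_gt_k = mean(counts$n_cohorts > k),
       per_cohort = per_cohort)
}

#' Percentage share, reported the way summary tables print it
#'
#' @param numerator,denominator Counts.
#' @param digits Decimal places (default 2).
#' @return 100 * numerator / denominator, rounded.
#' @export
percent_share <- function(numerator, denominator, digits = 2) {
  round(100 * numerator / denominator, digits)
}

#' Cohort summary table bookkeeping
#'
#' Given a per-cohort count table (columns: cohort, n_lncrna, cis_pair,
#' cis_eqtl, cis_elncrna, trans_pair, trans_eqtl, trans_elncrna), appends
#' the derived percentage columns used in cohort summaries: the share of
#' filtered lncRNAs that are cis-/trans-elncRNAs.
#'
#' @param counts data.frame as above.
#' @return The input with `pct_cis_elncrna` and `pct_trans_elncrna` added.
#' @export
cohort_summary_percentages <- function(counts) {
  req <- c("cohort", "n_lncrna", "cis_elncrna", "trans_elncrna")
  if (!all(req %in% names(counts))) {
    stop("counts must have columns: ", paste(req, collapse = ", "))
  }
  counts$pct_cis_elncrna <- percent_share(counts$cis_elncrna,
                                          counts$n_lncrna)
  counts$pct_trans_elncrna <- percent_share(counts$trans_elncrna,
                                            counts$n_lncrna)
  counts
}
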