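# ---------------------------------------------------------------------------
# Pipeline orchestration: config handling and the staged run that chains
# QC -> normalization -> scanning -> clumping -> revalidation -> variance ->
# enrichment -> MR, writing one TSV per stage plus a JSON run manifest.
# ---------------------------------------------------------------------------

#' Default pipeline configuration
#'
#' All thresholds default to the study criteria and can be overridden by a
#' YAML file or by the `...` arguments.
#'
#' @param ... Named overrides of any default.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = TRUE,          # generate a synthetic cohort (see sim)
    sim = list(),             # overrides for sim_config()
    inputs = NULL,            # named list of file paths when simulate=FALSE
    purity_min = 0.6,
    info_min = 0.5, maf_min = 0.05, miss_max = 0.05, hwe_min = 1e-6,
    posterior_min = 0.7,
    peer_k = 5,
    cis_window = 1e6,
    cis_fdr = 0.1, trans_p = 1e-7,
    clump_r2 = 0.2, clump_bp = 5e5,
    gwas_r2 = 0.5, gwas_bp = 5e5,
    axes_fdr = 0.1, axes_adj_r2 = 0.1, spearman_min = 0.3,
    immune_p = 0.05, immune_r2 = 0)
  over <- list(...)
  cfg[names(over)] <- over
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file of key: value pairs (same keys as
#'   [pipeline_config()]).
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

validate_config <- function(cfg) {
  if (cfg$purity_min < 0 || cfg$purity_min > 1) {
    stop("purity_min must lie in [0,1]")
  }
  if (cfg$maf_min < 0 || cfg$maf_min > 0.5) stop("maf_min must be in [0,0.5]")
  if (cfg$cis_fdr <= 0 || cfg$cis_fdr > 1) stop("cis_fdr must be in (0,1]")
  if (cfg$clump_r2 < 0 || cfg$clump_r2 > 1) stop("clump_r2 must be in [0,1]")
  if (!cfg$simulate) {
    req <- c("genotypes", "expression", "annotation", "covariates")
    miss <- setdiff(req, names(cfg$inputs))
    if (length(miss)) stop("inputs missing: ", paste(miss, collapse = ", "))
    absent <- !vapply(unlist(cfg$inputs), file.exists, TRUE)
    if (any(absent)) {
      stop("input file(s) not found: ",
           paste(unlist(cfg$inputs)[absent], collapse = ", "))
    }
  }
  invisible(cfg)
}

write_stage <- function(df, outdir, name) {
  path <- file.path(outdir, paste0(name, ".tsv"))
  if (is.null(df) || !nrow(df)) {
    df <- data.frame(empty = logical(0))
  }
  df <- as.data.frame(lapply(df, function(col) {
    if (is.list(col)) vapply(col, paste, "", collapse = ",") else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Chains every stage on a synthetic or file-based cohort and writes one
#' TSV per stage (qc_report, eqtl_cis, eqtl_trans, clumped, validated,
#' variance, gwas_overlap, enrichment, iv_axes, iv_immune) plus
#' manifest.json into `outdir`. Deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  # ---- inputs -------------------------------------------------------------
  if (isTRUE(config$simulate)) {
    scfg <- do.call(sim_config, c(config$sim, list(seed = seed)))
    cohort <- simulate_cohort(scfg)
  } else {
    inp <- config$inputs
    gm <- read_genotypes(inp$genotypes)
    em <- read_expression(inp$expression, inp$annotation)
    ct <- utils::read.delim(inp$covariates, stringsAsFactors = FALSE)
    cohort <- list(
      genotypes = gm, expression = em,
      covariates = covariate_table(ct$sample_id, ct$age, ct$sex, ct$purity),
      mrna = if (!is.null(inp$mrna))
        read_expression(inp$mrna, inp$mrna_annotation, stage = "raw_count"),
      fractions = if (!is.null(inp$fractions))
        read_immune_fractions(inp$fractions),
      truth = NULL)
  }

  # ---- sample QC ----------------------------------------------------------
  pur <- filter_samples_by_purity(cohort$covariates, config$purity_min)
  ids <- pur$samples
  gm <- subset_genotypes(cohort$genotypes, samples = ids)
  em <- subset_expression(cohort$expression, samples = ids)
  cov <- subset_covariates(cohort$covariates, ids)

  # ---- genotype QC --------------------------------------------------------
  gq <- qc_genotypes(gm, config$info_min, config$maf_min, config$miss_max,
                     config$hwe_min, config$posterior_min)
  gm <- gq$genotypes

  # ---- expression filtering and transforms --------------------------------
  ef <- filter_lncrna_expression(em)
  em_qn <- quantile_normalize(ef$expression)
  em_int <- inverse_normal_expression(em_qn)
  qc_report <- rbind(pur$report, gq$report, ef$report)
  write_stage(qc_report, outdir, "qc_report")

  # ---- latent factors -----------------------------------------------------
  lf <- estimate_latent_factors(em_int, k = config$peer_k, covariates = cov)
  cov$latent_factors <- lf

  # ---- eQTL scan ----------------------------------------------------------
  scan <- scan_eqtl(gm, em_int, cov, mode = "all",
                    cis_window = config$cis_window)
  cis <- scan[scan$mode == "cis", ]
  trans <- scan[scan$mode == "trans", ]
  cis_sig <- cis[!is.na(cis$fdr) & cis$fdr < config$cis_fdr, ]
  trans_sig <- trans[trans$p < config$trans_p, ]
  write_stage(cis_sig, outdir, "eqtl_cis")
  write_stage(trans_sig, outdir, "eqtl_trans")

  # ---- clumping -----------------------------------------------------------
  clumped <- rbind(
    if (nrow(cis_sig)) clump(cis_sig, gm, config$clump_r2, config$clump_bp),
    if (nrow(trans_sig)) clump(trans_sig, gm, config$clump_r2,
                               config$clump_bp))
  write_stage(clumped, outdir, "clumped")

  # ---- multivariate revalidation -----------------------------------------
  validated <- list()
  if (!is.null(clumped) && nrow(clumped)) {
    cis_tags <- clumped[clumped$mode == "cis", ]
    trans_tags <- clumped[clumped$mode == "trans", ]
    for (f in unique(cis_tags$feature_id)) {
      ct_f <- cis_tags[cis_tags$feature_id == f, ]
      tt_f <- trans_tags[trans_tags$feature_id == f, ]
      v <- tryCatch(
        validate_multivariate(
          f, cis_tag = ct_f$snp_id[1],
          trans_tag = if (nrow(tt_f)) tt_f$snp_id[1],
          gm = gm, em = em_int, covariates = cov),
        error = function(e) NULL)
      if (is.null(v)) next
      cf <- v$coefficients
      validated[[f]] <- data.frame(
        feature_id = f, cis_tag = v$cis_tag,
        trans_tag = if (!is.null(v$trans_tag)) v$trans_tag else NA,
        term = cf$term, estimate = cf$estimate, se = cf$se, p = cf$p,
        model_r2 = v$model_r2, n = v$n, stringsAsFactors = FALSE)
    }
  }
  validated <- if (length(validated)) do.call(rbind, validated)
  write_stage(validated, outdir, "validated")

  # ---- variance partition -------------------------------------------------
  variance <- NULL
  if (!is.null(clumped) && nrow(clumped)) {
    ctag <- clumped[clumped$mode == "cis", ]
    ctag <- ctag[!duplicated(ctag$feature_id), ]
    ttag <- clumped[clumped$mode == "trans", ]
    ttag <- ttag[!duplicated(ttag$feature_id), ]
    if (nrow(ctag)) {
      vp <- variance_partition_cohort(
        em_int, cov,
        cis_tags = stats::setNames(ctag$snp_id, ctag$feature_id),
        trans_tags = if (nrow(ttag))
          stats::setNames(ttag$snp_id, ttag$feature_id),
        gm = gm)
      variance <- vp$per_feature
    }
  }
  write_stage(variance, outdir, "variance")

  # ---- GWAS interception & enrichment ------------------------------------
  # In simulate mode a synthetic risk-SNP catalog and lncRNA annotation set
  # are drawn from the cohort itself (deterministically) so the enrichment
  # stages always have inputs.
  set.seed(seed + 10L)
  if (isTRUE(config$simulate)) {
    eligible <- gm$snps
    n_risk <- min(10, nrow(eligible))
    risk_idx <- sample(nrow(eligible), n_risk)
    catalog <- data.frame(snp_id = eligible$snp_id[risk_idx],
                          chrom = eligible$chrom[risk_idx],
                          pos = eligible$pos[risk_idx],
                          trait = "synthetic_cancer",
                          stringsAsFactors = FALSE)
    class(catalog) <- c("gwas_catalog", "data.frame")
    ann_set <- sample(em$features$feature_id,
                      max(1, round(0.3 * nrow(em$features))))
  } else {
    catalog <- if (!is.null(config$inputs$gwas_catalog))
      read_gwas_catalog(config$inputs$gwas_catalog)
    ann_set <- if (!is.null(config$inputs$annotation_set))
      utils::read.delim(config$inputs$annotation_set,
                        stringsAsFactors = FALSE)[[1]]
  }
  gwas_overlap <- NULL
  enrich_rows <- list()
  if (!is.null(catalog) && nrow(clumped %||% data.frame())) {
    proxies <- build_ld_proxies(catalog, gm, config$gwas_r2, config$gwas_bp)
    eqtl_ids <- unique(clumped$snp_id)
    ic <- gwas_intercept(eqtl_ids, proxies)
    gwas_overlap <- data.frame(snp_id = names(ic$flag),
                               gwas_related = unname(ic$flag),
                               stringsAsFactors = FALSE)
    bg <- setdiff(gm$snps$snp_id, unique(scan$snp_id[
      (!is.na(scan$fdr) & scan$fdr < config$cis_fdr) |
        scan$p < config$trans_p]))
    if (length(bg)) {
      bg_flag <- gwas_intercept(bg, proxies)$flag
      fe <- fold_enrichment(ic$flag, bg_flag)
      enrich_rows$gwas <- data.frame(
        test = "gwas_fold", set_name = "gwas_risk_loci",
        a = fe$a, b = fe$b, c = fe$c, d = fe$d,
        odds_ratio = fe$odds_ratio, ci_low = fe$ci_low,
        ci_high = fe$ci_high, fold = fe$fold, p = fe$p,
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(ann_set) && !is.null(clumped) && nrow(clumped)) {
    universe <- em$features$feature_id
    for (md in unique(clumped$mode)) {
      q <- unique(clumped$feature_id[clumped$mode == md])
      se <- set_enrichment(q, ann_set, universe,
                           set_name = paste0(md, "_elncrna"))
      enrich_rows[[md]] <- data.frame(
        test = "set_enrichment", set_name = se$set_name,
        a = se$a, b = se$b, c = se$c, d = se$d,
        odds_ratio = se$odds_ratio, ci_low = se$ci_low,
        ci_high = se$ci_high, fold = se$fold, p = se$p,
        stringsAsFactors = FALSE)
    }
  }
  write_stage(gwas_overlap, outdir, "gwas_overlap")
  write_stage(if (length(enrich_rows)) do.call(rbind, enrich_rows),
              outdir, "enrichment")

  # ---- MR -----------------------------------------------------------------
  iv_axes <- NULL
  iv_immune <- NULL
  if (!is.null(cohort$mrna) && !is.null(clumped) && nrow(clumped)) {
    cis_pairs <- clumped[clumped$mode == "cis", c("snp_id", "feature_id")]
    cis_pairs <- cis_pairs[!duplicated(cis_pairs$feature_id), ]
    if (nrow(cis_pairs)) {
      lnc_log2 <- log2_rpkm(subset_expression(
        ef$expression, samples = rownames(em_int$values)))
      ax <- run_axes(cis_pairs, gm, lnc_log2,
                     subset_expression(cohort$mrna, samples = ids),
                     covariates = cov,
                     fdr_max = config$axes_fdr,
                     adj_r2_min = config$axes_adj_r2,
                     rho_min = config$spearman_min)
      iv_axes <- ax$tested
      if (!is.null(cohort$fractions)) {
        sig_pairs <- unique(ax$axes[, c("instrument", "exposure")])
        names(sig_pairs) <- c("snp_id", "feature_id")
        if (!nrow(sig_pairs)) sig_pairs <- cis_pairs[1, , drop = FALSE]
        im <- run_immune(sig_pairs, gm, lnc_log2, cohort$fractions,
                         covariates = cov, p_max = config$immune_p,
                         r2_min = config$immune_r2)
        iv_immune <- im$tested
      }
    }
  }
  write_stage(iv_axes, outdir, "iv_axes")
  write_stage(iv_immune, outdir, "iv_immune")

  # ---- manifest -----------------------------------------------------------
  manifest <- list(
    package = "lnceqtl",
    version = as.character(utils::packageVersion("lnceqtl")),
    seed = seed,
    thresholds = config[c("purity_min", "info_min", "maf_min", "miss_max",
                          "hwe_min", "posterior_min", "peer_k",
                          "cis_window", "cis_fdr", "trans_p", "clump_r2",
                          "clump_bp", "gwas_r2", "gwas_bp", "axes_fdr",
                          "axes_adj_r2", "spearman_min", "immune_p")],
    n_samples = length(ids),
    n_snps_post_qc = nrow(gm$snps),
    n_lncrna_post_filter = nrow(ef$expression$features),
    n_cis_significant = nrow(cis_sig),
    n_trans_significant = nrow(trans_sig),
    n_clumps = if (!is.null(clumped)) nrow(clumped) else 0L,
    n_axes_tested = if (!is.null(iv_axes)) nrow(iv_axes) else 0L)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(outdir, "manifest.json"))
  invisible(list(
    qc_report = qc_report, genotypes = gm, expression = em_int,
    covariates = cov, scan = scan, cis_sig = cis_sig,
    trans_sig = trans_sig, clumped = clumped, validated = validated,
    variance = variance, gwas_overlap = gwas_overlap,
    enrichment = if (length(enrich_rows)) do.call(rbind, enrich_rows),
    iv_axes = iv_axes, iv_immune = iv_immune, manifest = manifest,
    truth = cohort$truth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
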