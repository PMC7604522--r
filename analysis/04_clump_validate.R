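#!/usr/bin/env Rscript
# LD clumping of the significant records (r2 = 0.2, 500 kb) and the second
# multivariate round per elncRNA, adjusting the clump tags for age, sex,
# latent factors, SCNA and promoter methylation.

source(file.path("analysis", "_common.R"))

co <- load_cohort()
gm <- read_genotypes(file.path(RESULTS, "genotypes_qc.tsv"), format = "tsv")
em <- read_expression(file.path(RESULTS, "lncrna_inverse_normal.tsv"),
                      file.path(COHORT_DIR, "lncrna_annotation.tsv"))
em$stage <- "inverse_normal"
lf <- read.delim(file.path(RESULTS, "latent_factors.tsv"), row.names = 1,
                 check.names = FALSE)
cov <- lnceqtl:::subset_covariates(co$covariates, rownames(em$values))
cov$latent_factors <- as.matrix(lf)
cis_sig <- read.delim(file.path(RESULTS, "eqtl_cis.tsv"))
trans_sig <- read.delim(file.path(RESULTS, "eqtl_trans.tsv"))

clumped <- rbind(
  if (nrow(cis_sig)) clump(cis_sig, gm),
  if (nrow(trans_sig) && "snp_id" %in% names(trans_sig))
    clump(trans_sig, gm))
write_tsv(clumped, "clumped.tsv")

rows <- list()
cis_tags <- clumped[clumped$mode == "cis", ]
trans_tags <- clumped[clumped$mode == "trans", ]
for (f in unique(cis_tags$feature_id)) {
  ct <- cis_tags[cis_tags$feature_id == f, ]
  tt <- trans_tags[trans_tags$feature_id == f, ]
  v <- tryCatch(
    validate_multivariate(f, ct$snp_id[1],
                          if (nrow(tt)) tt$snp_id[1],
                          gm = gm, em = em, covariates = cov),
    error = function(e) NULL)
  if (is.null(v)) next
  cf <- v$coefficients
  rows[[f]] <- data.frame(feature_id = f, cis_tag = v$cis_tag,
                          term = cf$term, estimate = cf$estimate,
                          se = cf$se, p = cf$p, model_r2 = v$model_r2,
                          n = v$n)
}
validated <- do.call(rbind, rows)
write_tsv(validated, "validated.tsv")

cis_b <- validated[validated$term == "cis_G", ]
cat(sprintf("clumps: %d cis, %d trans (from %d + %d records)\n",
            nrow(cis_tags), nrow(trans_tags), nrow(cis_sig),
            nrow(trans_sig)))
cat(sprintf(
  "multivariate round: %d elncRNAs refit; cis tag significant (p<0.05) in %d\n",
  length(unique(validated$feature_id)), sum(cis_b$p < 0.05)))
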