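#!/usr/bin/env Rscript
# Sequential variance decomposition of elncRNA expression (age, sex,
# latent factors, cis tag, trans tag, SCNA, methylation), allelic
# effect-size summaries over clump tags, and the percentage bookkeeping
# for the published per-cohort summary table.

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
clumped <- read.delim(file.path(RESULTS, "clumped.tsv"))

ctag <- clumped[clumped$mode == "cis", ]
ctag <- ctag[!duplicated(ctag$feature_id), ]
ttag <- clumped[clumped$mode == "trans", ]
ttag <- ttag[!duplicated(ttag$feature_id), ]

vp <- variance_partition_cohort(
  em, cov, cis_tags = setNames(ctag$snp_id, ctag$feature_id),
  trans_tags = if (nrow(ttag)) setNames(ttag$snp_id, ttag$feature_id),
  gm = gm)
write_tsv(vp$per_feature, "variance_partition.tsv")
avg <- round(100 * vp$average, 2)
write_tsv(data.frame(factor = names(avg), mean_pct_variance = unname(avg)),
          "variance_average.tsv")

eff <- allelic_effect_summary(ctag)
write_tsv(eff$histogram, "effect_size_histogram.tsv")

counts <- read.delim(system.file("extdata", "published_cohort_summary.tsv",
                                 package = "lnceqtl"))
write_tsv(cohort_summary_percentages(counts), "published_summary_pct.tsv")

cat("average variance shares (% of total), elncRNAs with a cis tag:\n")
print(avg)
cat(sprintf("mean |beta| over %d cis tags: %.3f\n", eff$n,
            eff$mean_abs_beta))
cat(sprintf(
  "published table check: THCA cis-elncRNA share %.2f%%, STAD %.2f%%\n",
  cohort_summary_percentages(counts)$pct_cis_elncrna[counts$cohort == "THCA"],
  cohort_summary_percentages(counts)$pct_cis_elncrna[counts$cohort == "STAD"]))
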