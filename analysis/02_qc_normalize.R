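#!/usr/bin/env Rscript
# Sample, genotype and expression QC, then the transform chain used for
# association scanning: percentile filter -> quantile normalization ->
# rank-based inverse normal transform, plus latent-factor estimation.

source(file.path("analysis", "_common.R"))

co <- load_cohort()

pur <- filter_samples_by_purity(co$covariates, threshold = 0.6)
ids <- pur$samples
gm <- lnceqtl:::subset_genotypes(co$genotypes, samples = ids)
em <- lnceqtl:::subset_expression(co$expression, samples = ids)
cov <- lnceqtl:::subset_covariates(co$covariates, ids)

gq <- qc_genotypes(gm)
ef <- filter_lncrna_expression(em)
em_int <- inverse_normal_expression(quantile_normalize(ef$expression))

lf <- estimate_latent_factors(em_int, k = 5, covariates = cov)

qc <- rbind(pur$report, gq$report, ef$report)
write_tsv(qc, "qc_report.tsv")
write_expression(em_int, file.path(RESULTS, "lncrna_inverse_normal.tsv"))
write_genotypes(gq$genotypes, file.path(RESULTS, "genotypes_qc.tsv"))
write.table(data.frame(sample_id = rownames(lf), lf, check.names = FALSE),
            file.path(RESULTS, "latent_factors.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("purity filter: removed %d of %d samples (threshold 0.6)\n",
            pur$report$removed, pur$report$input))
cat(sprintf("genotype QC: %d of %d SNPs retained\n",
            nrow(gq$genotypes$snps), nrow(gm$snps)))
cat(sprintf("expression filter: %d of %d lncRNAs retained\n",
            ef$report$retained, ef$report$input))
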