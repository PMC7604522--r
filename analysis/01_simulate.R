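#!/usr/bin/env Rscript
# Generate the reference synthetic cohort and write every fixture in the
# formats the pipeline readers consume, together with the ground-truth
# effect tables used for parameter-recovery checks downstream.

source(file.path("analysis", "_common.R"))

cfg <- cohort_config()
co <- simulate_cohort(cfg)

write_genotypes(co$genotypes, file.path(COHORT_DIR, "genotypes.tsv"))
write_expression(co$expression,
                 file.path(COHORT_DIR, "lncrna_rpkm.tsv"),
                 file.path(COHORT_DIR, "lncrna_annotation.tsv"))
write_expression(co$mrna,
                 file.path(COHORT_DIR, "mrna_counts.tsv"),
                 file.path(COHORT_DIR, "mrna_annotation.tsv"))
write.table(data.frame(sample_id = co$covariates$samples,
                       age = co$covariates$age, sex = co$covariates$sex,
                       purity = round(co$covariates$purity, 6)),
            file.path(COHORT_DIR, "covariates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = rownames(co$covariates$scna),
                       co$covariates$scna, check.names = FALSE),
            file.path(COHORT_DIR, "scna.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = rownames(co$covariates$methylation),
                       co$covariates$methylation, check.names = FALSE),
            file.path(COHORT_DIR, "methylation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_immune_fractions(co$fractions,
                       file.path(COHORT_DIR, "immune_fractions.tsv"))
write.table(co$truth$eqtl, file.path(COHORT_DIR, "truth_eqtl.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(co$truth$axes, file.path(COHORT_DIR, "truth_axes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(co$truth$immune, file.path(COHORT_DIR, "truth_immune.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "cohort: %d samples, %d SNPs, %d lncRNAs (%d with true cis eQTL, %d with true trans eQTL), %d mRNAs (%d mediated), %d immune cell types\n",
  cfg$n_samples, nrow(co$genotypes$snps), cfg$n_lncrna,
  sum(co$truth$eqtl$mode == "cis"), sum(co$truth$eqtl$mode == "trans"),
  cfg$n_mrna, nrow(co$truth$axes), cfg$n_cell_types))
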