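# Shared settings for the numbered analysis scripts. Every script sources
# this file, so the whole workflow is reproducible from one seed.

library(lnceqtl)

SEED <- 20201019L
RESULTS <- file.path("results")
COHORT_DIR <- file.path(RESULTS, "cohort")

dir.create(COHORT_DIR, showWarnings = FALSE, recursive = TRUE)

cohort_config <- function() {
  # reference synthetic cohort: 300 samples, 500 SNPs in 10-SNP LD blocks,
  # 50 lncRNAs, 100 mRNAs, 5 immune cell types
  sim_config(seed = SEED)
}

# read back the fixture files written by 01_simulate.R
load_cohort <- function() {
  gm <- read_genotypes(file.path(COHORT_DIR, "genotypes.tsv"),
                       format = "tsv")
  em <- read_expression(file.path(COHORT_DIR, "lncrna_rpkm.tsv"),
                        file.path(COHORT_DIR, "lncrna_annotation.tsv"))
  mrna <- read_expression(file.path(COHORT_DIR, "mrna_counts.tsv"),
                          file.path(COHORT_DIR, "mrna_annotation.tsv"),
                          stage = "raw_count")
  cv <- read.delim(file.path(COHORT_DIR, "covariates.tsv"))
  scna <- as.matrix(read.delim(file.path(COHORT_DIR, "scna.tsv"),
                               row.names = 1, check.names = FALSE))
  meth <- as.matrix(read.delim(file.path(COHORT_DIR, "methylation.tsv"),
                               row.names = 1, check.names = FALSE))
  cov <- covariate_table(cv$sample_id, cv$age, cv$sex, cv$purity,
                         scna = scna, methylation = meth)
  fractions <- read_immune_fractions(
    file.path(COHORT_DIR, "immune_fractions.tsv"))
  truth <- list(
    eqtl = read.delim(file.path(COHORT_DIR, "truth_eqtl.tsv")),
    axes = read.delim(file.path(COHORT_DIR, "truth_axes.tsv")),
    immune = read.delim(file.path(COHORT_DIR, "truth_immune.tsv")))
  list(genotypes = gm, expression = em, mrna = mrna, covariates = cov,
       fractions = fractions, truth = truth)
}

write_tsv <- function(df, name) {
  path <- file.path(RESULTS, name)
  df <- as.data.frame(lapply(df, function(col) {
    if (is.list(col)) vapply(col, paste, "", collapse = ",") else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
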