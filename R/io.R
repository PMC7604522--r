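# ---------------------------------------------------------------------------
# Containers. Lightweight S3: a cohort here is a handful of aligned matrices
# with metadata, for which data.frame + matrix are the natural carriers.
# Coordinates are 1-based inclusive internally (VCF/GTF convention); BED is
# converted at the boundary (see read_bed).
# ---------------------------------------------------------------------------

#' Construct a genotype matrix
#'
#' Bundles an additive-dosage matrix (samples x SNPs, values 0/1/2 or NA)
#' with per-SNP metadata. Dosage is the count of alternate alleles; the
#' alternate allele is the effect allele for all reported coefficients.
#'
#' @param dosage Numeric matrix, samples in rows, SNPs in columns. Row names
#'   are sample ids, column names SNP ids. Values must be in \{0, 1, 2, NA\}.
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`, and optionally `info` (imputation INFO score in \[0,1\]).
#' @param posterior Optional matrix of per-call posterior probabilities with
#'   the same shape as `dosage`.
#' @return An object of class `genotype_matrix` with elements `dosage`,
#'   `snps` (with a computed `maf` column), `samples`, and `posterior`.
#' @export
genotype_matrix <- function(dosage, snps, posterior = NULL) {
  stopifnot(is.matrix(dosage), is.data.frame(snps))
  req <- c("snp_id", "chrom", "pos")
  if (!all(req %in% names(snps))) {
    stop("snps must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(snps$snp_id)) {
    stop("duplicate snp_id: ",
         paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  }
  if (ncol(dosage) != nrow(snps)) {
    stop("dosage has ", ncol(dosage), " columns but snps has ",
         nrow(snps), " rows")
  }
  if (any(snps$pos < 1)) stop("SNP positions must be >= 1")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  if (!is.null(posterior)) {
    stopifnot(all(dim(posterior) == dim(dosage)))
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  }
  colnames(dosage) <- snps$snp_id
  snps$maf <- compute_maf(dosage)
  structure(
    list(dosage = dosage, snps = snps, samples = rownames(dosage),
         posterior = posterior),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$snps), "SNPs\n")
  cat("  chromosomes:", paste(unique(x$snps$chrom), collapse = " "), "\n")
  cat("  missing calls:", sum(is.na(x$dosage)), "\n")
  invisible(x)
}

# MAF per SNP from non-missing dosages; folded so maf <= 0.5.
compute_maf <- function(dosage) {
  af <- colMeans(dosage, na.rm = TRUE) / 2
  af[is.nan(af)] <- NA_real_
  pmin(af, 1 - af)
}

#' Construct an expression matrix
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param features data.frame with columns `feature_id`, `chrom`, `start`,
#'   `end` (1-based inclusive), `strand`, `biotype` (lncRNA or mRNA).
#' @param stage Processing stage label, one of `raw_rpkm`, `raw_count`,
#'   `filtered`, `quantile_normalized`, `inverse_normal`, `log2`.
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, features,
                              stage = c("raw_rpkm", "raw_count", "filtered",
                                        "quantile_normalized",
                                        "inverse_normal", "log2")) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(values), is.data.frame(features))
  req <- c("feature_id", "chrom", "start", "end")
  if (!all(req %in% names(features))) {
    stop("features must have columns: ", paste(req, collapse = ", "))
  }
  if (ncol(values) != nrow(features)) {
    stop("values has ", ncol(values), " columns but features has ",
         nrow(features), " rows")
  }
  if (any(features$start > features$end)) stop("feature start > end")
  if (stage != "raw_rpkm" && stage != "raw_count" && anyNA(values)) {
    stop("missing values not allowed at stage ", stage)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  }
  colnames(values) <- features$feature_id
  structure(
    list(values = values, features = features, samples = rownames(values),
         stage = stage),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", length(x$samples), "samples x",
      nrow(x$features), "features; stage =", x$stage, "\n")
  invisible(x)
}

#' Construct a covariate table
#'
#' Holds the per-sample covariates of the expression model: age, sex, tumor
#' purity, latent expression factors, and per-feature somatic copy-number
#' scores and discretized promoter-methylation levels.
#'
#' @param samples Character vector of sample ids.
#' @param age Numeric vector (years).
#' @param sex Integer vector coded 0/1.
#' @param purity Numeric vector in \[0,1\].
#' @param latent_factors Optional samples x K matrix of latent covariates.
#' @param scna Optional samples x features matrix of copy-number scores.
#' @param methylation Optional samples x features matrix of ordinal
#'   methylation levels in \{0,1,2\} (NA = no promoter probes).
#' @return Object of class `covariate_table`.
#' @export
covariate_table <- function(samples, age, sex, purity,
                            latent_factors = NULL, scna = NULL,
                            methylation = NULL) {
  n <- length(samples)
  stopifnot(length(age) == n, length(sex) == n, length(purity) == n)
  if (!all(sex %in% c(0, 1))) stop("sex must be coded 0/1")
  ok_pur <- is.na(purity) | (purity >= 0 & purity <= 1)
  if (!all(ok_pur)) stop("purity must lie in [0,1]")
  if (!is.null(latent_factors)) {
    latent_factors <- as.matrix(latent_factors)
    stopifnot(nrow(latent_factors) == n)
  }
  if (!is.null(methylation)) {
    mv <- methylation[!is.na(methylation)]
    if (!all(mv %in% c(0, 1, 2))) stop("methylation levels must be 0/1/2")
  }
  structure(
    list(samples = samples, age = age, sex = sex, purity = purity,
         latent_factors = latent_factors, scna = scna,
         methylation = methylation),
    class = "covariate_table"
  )
}

#' Construct an immune-cell fraction table
#'
#' @param fraction Samples x cell-types matrix of fractions in \[0,1\];
#'   each row must sum to at most 1 (plus numerical slack).
#' @return Object of class `immune_fraction_table`.
#' @export
immune_fraction_table <- function(fraction) {
  stopifnot(is.matrix(fraction))
  if (any(fraction < 0 | fraction > 1)) stop("fractions must lie in [0,1]")
  rs <- rowSums(fraction)
  if (any(rs > 1 + 1e-6)) stop("immune fractions in a sample sum to > 1")
  structure(
    list(samples = rownames(fraction), cell_types = colnames(fraction),
         fraction = fraction),
    class = "immune_fraction_table"
  )
}

# ---------------------------------------------------------------------------
# Readers / writers
# ---------------------------------------------------------------------------

#' Read genotypes from VCF or dosage TSV
#'
#' VCF records are converted to additive alt-allele dosage from the GT field
#' (`./.` becomes NA); multi-allelic records are skipped with a message.
#' The TSV layout is the one `write_genotypes()` emits: metadata columns
#' `snp_id chrom pos ref alt info` followed by one column per sample.
#'
#' @param path File path.
#' @param format `"vcf"` or `"tsv"`; default inferred from the extension.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    message("read_genotypes: skipping ", sum(multi), " multi-allelic records")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # allele count: number of "1" alleles in the GT string; "." -> NA
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || grepl("\\.", g)) return(NA_real_)
    sum(strsplit(g, "[/|]")[[1]] == "1")
  })
  info <- rep(NA_real_, nrow(fix))
  m <- regmatches(fix$INFO, regexpr("(?<=\\bINFO=)[0-9.eE+-]+",
                                    fix$INFO, perl = TRUE))
  if (length(m)) {
    has <- grepl("\\bINFO=", fix$INFO)
    info[has] <- as.numeric(m)
  }
  ids <- fix$ID
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fix$CHROM[blank], ":", fix$POS[blank])
  if (anyDuplicated(ids)) stop("duplicate snp_id in VCF")
  snps <- data.frame(snp_id = ids, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                     info = info, stringsAsFactors = FALSE)
  genotype_matrix(t(dos), snps)
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta_cols <- c("snp_id", "chrom", "pos", "ref", "alt", "info")
  have <- intersect(meta_cols, names(tab))
  if (!all(c("snp_id", "chrom", "pos") %in% have)) {
    stop("genotype TSV must have snp_id, chrom, pos columns")
  }
  sample_cols <- setdiff(names(tab), meta_cols)
  dos <- t(as.matrix(tab[, sample_cols, drop = FALSE]))
  if (!is.numeric(dos)) stop("non-numeric dosage cell in ", path)
  rownames(dos) <- sample_cols
  snps <- tab[, have, drop = FALSE]
  if (!"ref" %in% have) snps$ref <- "A"
  if (!"alt" %in% have) snps$alt <- "B"
  if (!"info" %in% have) snps$info <- NA_real_
  genotype_matrix(dos, snps)
}

#' Write genotypes as a dosage TSV
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @export
write_genotypes <- function(gm, path) {
  tab <- cbind(gm$snps[, c("snp_id", "chrom", "pos", "ref", "alt", "info")],
               as.data.frame(t(gm$dosage), check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix with its feature annotation
#'
#' The matrix TSV has feature ids in the first column and one column per
#' sample. The annotation TSV has columns `feature_id chrom start end strand
#' biotype`. Features absent from the annotation are dropped with a message.
#'
#' @param path Expression matrix TSV.
#' @param annotation_path Feature annotation TSV.
#' @param stage Stage label for the result (`raw_rpkm` or `raw_count`).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, annotation_path,
                            stage = c("raw_rpkm", "raw_count")) {
  stage <- match.arg(stage)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ann <- utils::read.delim(annotation_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression cell in ", path)
  keep <- ids %in% ann$feature_id
  if (any(!keep)) {
    message("read_expression: dropping ", sum(!keep),
            " features without annotation")
  }
  vals <- vals[keep, , drop = FALSE]
  ids <- ids[keep]
  ann <- ann[match(ids, ann$feature_id), , drop = FALSE]
  expression_matrix(t(vals), ann, stage = stage)
}

#' Write an expression matrix (and optionally its annotation) as TSV
#'
#' @param em An [expression_matrix()].
#' @param path Output path for the matrix.
#' @param annotation_path Optional output path for the feature annotation.
#' @export
write_expression <- function(em, path, annotation_path = NULL) {
  tab <- data.frame(feature_id = em$features$feature_id,
                    t(em$values), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path)) {
    utils::write.table(em$features, annotation_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a BED3+ file into a merged peak set
#'
#' BED intervals are 0-based half-open on disk; they are validated in that
#' convention, merged (book-ended/overlapping intervals union), and stored
#' half-open as (`start0`, `end`).
#'
#' @param path BED file path.
#' @param marker_name,cell_line Labels carried on the result.
#' @return Object of class `peak_set` with a data.frame `intervals`
#'   (`chrom`, `start0`, `end`).
#' @export
read_bed <- function(path, marker_name = NA_character_,
                     cell_line = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(peak_set(data.frame(chrom = character(), start0 = integer(),
                               end = integer()),
                    marker_name, cell_line))
  }
  parts <- strsplit(lines, "\t| +")
  ncols <- vapply(parts, length, 0L)
  if (any(ncols < 3)) {
    stop("BED line ", which(ncols < 3)[1], " has fewer than 3 columns")
  }
  chrom <- vapply(parts, `[[`, "", 1)
  start0 <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3)))
  if (anyNA(start0) || anyNA(end)) {
    stop("BED line ", which(is.na(start0) | is.na(end))[1],
         ": non-integer coordinates")
  }
  bad <- end <= start0
  if (any(bad)) stop("BED line ", which(bad)[1], ": end <= start")
  peak_set(data.frame(chrom = chrom, start0 = start0, end = end,
                      stringsAsFactors = FALSE),
           marker_name, cell_line)
}

#' Construct a peak set (merging overlapping intervals)
#'
#' @param intervals data.frame with `chrom`, `start0` (0-based), `end`
#'   (exclusive).
#' @param marker_name,cell_line Labels.
#' @export
peak_set <- function(intervals, marker_name = NA_character_,
                     cell_line = NA_character_) {
  stopifnot(all(c("chrom", "start0", "end") %in% names(intervals)))
  if (nrow(intervals)) {
    gr <- GenomicRanges::GRanges(
      intervals$chrom,
      IRanges::IRanges(start = intervals$start0 + 1L, end = intervals$end))
    gr <- GenomicRanges::reduce(gr)
    intervals <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start0 = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE)
  }
  structure(list(marker_name = marker_name, cell_line = cell_line,
                 intervals = intervals),
            class = "peak_set")
}

#' Read a GWAS-catalog style risk-SNP table
#'
#' @param path TSV with columns `snp_id`, `chrom`, `pos`, `trait`.
#' @return data.frame of class `gwas_catalog`.
#' @export
read_gwas_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("snp_id", "chrom", "pos", "trait")
  if (!all(req %in% names(tab))) {
    stop("GWAS catalog must have columns: ", paste(req, collapse = ", "))
  }
  if (any(tab$pos < 1)) stop("catalog positions must be 1-based")
  if (any(is.na(tab$trait) | !nzchar(tab$trait))) {
    stop("empty trait in catalog")
  }
  class(tab) <- c("gwas_catalog", "data.frame")
  tab
}

#' Read an immune-cell fraction table
#'
#' @param path TSV with sample ids in the first column, one column per cell
#'   type, fractions in \[0,1\].
#' @return An [immune_fraction_table()].
#' @export
read_immune_fractions <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  immune_fraction_table(m)
}

#' Write an immune-cell fraction table
#' @param ift An [immune_fraction_table()].
#' @param path Output path.
#' @export
write_immune_fractions <- function(ift, path) {
  tab <- data.frame(sample_id = ift$samples, ift$fraction,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Intersect sample ids across containers, preserving the first one's order.
# Used by every stage so all matrices are aligned on the same samples.
align_samples <- function(...) {
  lists <- list(...)
  ids <- Reduce(intersect, lists)
  if (!length(ids)) stop("no samples in common across inputs")
  if (length(ids) < max(lengths(lists))) {
    message("sample alignment: ", length(ids), " samples in common (inputs: ",
            paste(lengths(lists), collapse = ", "), ")")
  }
  ids
}

# Subset helpers keeping classes intact
subset_genotypes <- function(gm, samples = NULL, snps = NULL) {
  d <- gm$dosage
  post <- gm$posterior
  meta <- gm$snps
  if (!is.null(samples)) {
    d <- d[samples, , drop = FALSE]
    if (!is.null(post)) post <- post[samples, , drop = FALSE]
  }
  if (!is.null(snps)) {
    idx <- if (is.character(snps)) match(snps, meta$snp_id) else snps
    d <- d[, idx, drop = FALSE]
    if (!is.null(post)) post <- post[, idx, drop = FALSE]
    meta <- meta[idx, , drop = FALSE]
  }
  meta$maf <- NULL
  genotype_matrix(d, meta, post)
}

subset_expression <- function(em, samples = NULL, features = NULL) {
  v <- em$values
  meta <- em$features
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(features)) {
    idx <- if (is.character(features)) match(features, meta$feature_id)
           else features
    v <- v[, idx, drop = FALSE]
    meta <- meta[idx, , drop = FALSE]
  }
  expression_matrix(v, meta, stage = em$stage)
}

subset_covariates <- function(cov, samples) {
  idx <- match(samples, cov$samples)
  covariate_table(
    samples = cov$samples[idx], age = cov$age[idx], sex = cov$sex[idx],
    purity = cov$purity[idx],
    latent_factors = if (!is.null(cov$latent_factors))
      cov$latent_factors[idx, , drop = FALSE],
    scna = if (!is.null(cov$scna)) cov$scna[idx, , drop = FALSE],
    methylation = if (!is.null(cov$methylation))
      cov$methylation[idx, , drop = FALSE])
}
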