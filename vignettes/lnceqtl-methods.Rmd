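---
title: "Methods: lncRNA eQTL mapping and instrumental-variable analysis"
author: "lnceqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA eQTL mapping and instrumental-variable analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models the package implements,
the design of the synthetic cohort that every stage is validated on, the
numerical conventions, and the limitations a user should keep in mind.

## The two-round association model

Tumor lncRNA expression is treated as a quantitative trait. In the first
round, each SNP–transcript pair is fit by ordinary least squares on the
inverse-normal transformed expression:

$$y_i = \beta_0 + \beta_1 G_i + \beta_2 A_i + \beta_3 S_i +
\sum_k \gamma_k F_{ik} + \varepsilon_i,$$

where $G_i \in \{0,1,2\}$ is the alternate-allele dosage, $A_i$ age,
$S_i$ sex, and $F_{ik}$ the latent expression factors. A pair is *cis*
when the SNP lies within 1 Mb of either end of the transcript on the same
chromosome, *trans* otherwise (equivalently: outside the roughly 2-Mb
window around the gene, or on another chromosome). Cis pairs are gated at
Benjamini–Hochberg FDR < 0.1 computed over all tested cis pairs in the
cohort; trans pairs use the fixed gate $P < 10^{-7}$, since the trans
test count makes an FDR estimate unstable. The FDR scope (per mode,
within one cohort) is a design choice; it is the natural unit at which
the two gates are defined.

The scan uses the Frisch–Waugh fast path: dosage and expression are both
residualized on the covariate design once, and each pair reduces to a
simple regression of residuals. This is algebraically *identical* to the
per-pair OLS — coefficient, SE and p — and the test suite asserts the
equality to 1e-10 against `lm()`.

Significant SNPs are collapsed into haplotype blocks by greedy clumping:
the most significant unassigned SNP becomes a tag and absorbs every
unassigned SNP within 500 kb with genotypic $r^2 \ge 0.2$. Ties on p are
broken lexicographically by (chromosome, position, SNP id) so results are
deterministic; reference implementations of this algorithm leave tie
order to floating-point sort, which is not reproducible across platforms.

In the second round each elncRNA is refit once with its cis tag, its most
significant trans tag (when one exists), age, sex, latent factors, its
somatic copy-number score and its discretized promoter methylation level.
Methylation enters as the ordinal level 0/1/2 obtained by cutting the
median beta over promoter (TSS200/TSS1500) probes at 0.2 and 0.6; medians
exactly at a cutoff go to the middle level. This second model is what
separates a germline effect from somatic confounding: the test suite
plants SCNA that is correlated with genotype and verifies that the
marginal scan is biased while the multivariate refit recovers the true
coefficient.

## Latent factors

The latent covariates play the role PEER factors play in expression
pipelines: absorbing batch and other broad technical/biological
variation. They are computed by residualizing the transformed expression
matrix on the known covariates (intercept, age, sex) and taking the top
$k = 5$ left singular vectors of the residual matrix, with a
deterministic sign convention. Five factors is the pipeline default. The
factors are validated behaviorally: a planted two-group batch shift is
recovered by the first factor with point-biserial $|r| > 0.9$, and on
pure noise no factor captures more than a Marchenko–Pastur-scale share of
variance. This surrogate is linear and non-Bayesian; it will not
reproduce PEER's automatic relevance determination, but for the scan it
serves the same purpose (removing broad variance components) and its
effect on eQTL recovery is exercised directly in the tests.

## Preprocessing conventions

* Purity: samples with tumor purity $\ge 0.6$ are kept (boundary kept).
* Genotype QC order: INFO $\ge 0.5$ → posterior masking (calls below 0.7
  set missing, when per-call posteriors exist; without posteriors the
  rule is skipped, since there is nothing defensible to apply it to) →
  missing rate $< 5\%$ → MAF $\ge 5\%$ on non-missing calls → exact HWE
  $p > 10^{-6}$.
* The HWE test is the exact conditional test (enumeration of heterozygote
  counts given allele counts, summing probabilities at or below the
  observed table), computed on a log scale. A chi-square approximation
  would be unreliable at the $10^{-6}$ cutoff, which lives deep in the
  tail. The implementation is checked against full enumeration for
  $n \le 50$.
* Expression filter: a lncRNA is kept iff its 10th-percentile RPKM is
  $> 0$ **and** its 90th-percentile RPKM is $> 0.1$ (linear-interpolation
  sample quantiles). The two published phrasings (exclude-then-retain)
  only compose consistently as a conjunction.
* Quantile normalization equalizes the per-sample distributions (ties
  receive the mean of the reference values they span); the inverse normal
  transform uses Blom scores, $\Phi^{-1}((r_i - 3/8)/(n + 1/4))$, with
  average ranks on ties. No offset is canonical; Blom is the common
  default in eQTL practice and any offset choice is rank-preserving.
* Missing dosages are mean-imputed per SNP for the matrix scan (the
  standard matrix-eQTL convention); the second-round refits instead drop
  incomplete samples, since they are per-feature and can afford it.

## Variance partition

Per elncRNA, factor groups enter a nested OLS in the fixed order age,
sex, latent factors, cis tag, trans tag, SCNA, methylation, and each
group is credited with its increment in plain $R^2$. The increments
telescope exactly to the full-model $R^2$ (asserted to 1e-9); tiny
negative increments that can arise numerically are floored at zero and
counted. Sequential $R^2$ is order-dependent; the order is configurable
but defaults to the one above, which mirrors the model hierarchy
(demographics → latent structure → germline → somatic). Cohort averages
are means of per-feature floored increments.

## Enrichment statistics

All enrichment tests reduce to a 2×2 table. The p-value is the two-sided
Fisher exact probability; the reported odds ratio is the sample
cross-product $ad/bc$ with a Woolf log-interval 95% CI, applying the
Haldane 0.5 correction only when a zero cell occurs. The "fold"
statistic — the ratio of flagged proportions — is reported alongside the
OR for every test, because the two are distinct magnitudes and published
summaries use both without always saying which. The background for the
GWAS fold enrichment defaults to all QC-passing SNPs that were tested but
not significant; this is configurable, as no canonical background exists.

Peak overlap uses the half-open BED convention: a SNP at a peak's 0-based
start is inside, a SNP at its end coordinate is outside. Marker-level
results are pooled by inverse-variance meta-analysis; both the
fixed-effect and the DerSimonian–Laird random-effects estimates are
computed (with Cochran Q and $I^2$), and random effects are reported by
default since ChIP-seq strata from different cell lines are heterogeneous
by construction. The closed-form pooling is cross-checked against
`metafor::rma` in the tests.

## Instrumental-variable analysis

For a candidate axis (tag eSNP → elncRNA → mRNA), two-stage least
squares uses the tag dosage as the single instrument: stage 1 fits the
exposure on instrument plus exogenous covariates, stage 2 fits the
outcome on the fitted exposure plus covariates. The SE is the
2SLS-consistent one (residuals from the structural equation, not the
second stage), homoskedastic by default, matching standard IV-regression
defaults. With one instrument and no covariates the estimator reduces to
the Wald ratio $\mathrm{cov}(y,g)/\mathrm{cov}(x,g)$ — asserted to 1e-10
in the tests. First-stage partial F below 10 flags a weak instrument;
flagged rows are reported, not dropped, since dropping would silently
bias the reported landscape toward strong instruments.

Candidate mRNAs pass three prefilters before any IV fit: count CV > 0.5,
30th percentile of log2(count+1) > 0, 90th percentile > 5, and
|Spearman rho| > 0.3 with the exposure. Axes are reported at BH-FDR < 0.1
(across all tested axes in the run) and structural-equation adjusted
$R^2 > 0.1$; immune-fraction outcomes use log2(fraction + 1), gates
p < 0.05 and $R^2 > 0$.

Two scale decisions were genuinely open. The exposure enters 2SLS on the
log2(RPKM+1) scale by default (inverse-normal available via argument):
on that scale the mediation coefficient is a fold-change effect and is
directly comparable to the generator's planted value. And the adjusted
$R^2$ gate is taken from the structural-equation fit, which is the
quantity that measures how much of the outcome the axis explains.
Immune-cell fractions are analyzed per cell type despite being
compositional; a positive effect on one cell type forces negative shares
elsewhere, so per-type results should be read jointly, not independently.

## The synthetic cohort

The generator produces the exact statistical structure the models assume,
with ground-truth tables for parameter recovery:

* **Genotypes.** Per LD block, haplotypes are latent AR(1) Gaussians
  thresholded at the allele-frequency quantile (Gaussian copula); the
  latent autocorrelation is solved numerically so adjacent haplotypes hit
  a target allele-level $r^2$. Two independent haplotypes per sample sum
  to the dosage, so Hardy–Weinberg holds by construction. Only MAF, LD
  and HWE matter to the methods under test, so no coalescent machinery is
  used, and no attempt is made to mimic real allele-frequency spectra or
  LD maps.
* **Expression.** Latent log2 expression is the additive model (genotype,
  age, sex, latent factors, SCNA, methylation, Gaussian noise);
  RPKM $= 2^{\text{latent}} - 1$ floored at zero. The floor gives the
  percentile filters genuine zeros to act on, and a configurable fraction
  of lncRNAs is made low-expressed for the same reason. Gaussian noise on
  the log scale is an assumption — the pipeline's inverse-normal
  transform makes the scan insensitive to it.
* **Downstream.** Mediated mRNAs load on their lncRNA (log2 scale) plus a
  shared confounder and noise, exponentiated to counts. Immune fractions
  are a softmax over per-cell-type linear predictors (logistic-normal),
  one driven by a designated lncRNA — rows sum to one exactly, and a
  single cell-type effect is directly parameterizable, which a Dirichlet
  would not allow.
* **Defaults.** 300 samples, 50 blocks of 10 SNPs (MAF 0.3, adjacent
  $r^2$ 0.5), 50 lncRNAs (half with a true cis eQTL at $\beta = 0.5$,
  20% with a trans eQTL, 20% low-expressed), 100 mRNAs (5% mediated at
  $\alpha = 1.5$), 5 immune cell types, purity Beta(8, 2), noise sd 1.
  SCNA is independent of genotype by default — somatic events are not
  germline-determined — and the genotype-correlated SCNA used to study
  confounding is an explicit switch (`scna_geno_corr`).

What passing tests on this cohort do show: the estimators recover the
effects they target under the model's own assumptions, the null
calibration is correct, and confounding is removed where the design says
it should be. What they do not show: robustness to real-data features the
generator omits — population structure, non-Gaussian expression noise,
realistic LD, copy-number segmentation artifacts, cell-type mixture in
bulk expression.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive internally; BED input is converted at
  the boundary. Strand is carried but ignored for windowing.
* Dosage is the alternate-allele count; the alternate allele is the
  effect allele of every reported $\beta$.
* p-values are floored at the smallest positive double so downstream
  (0,1] contracts hold under extreme signals.
* Zero-variance SNPs after imputation are skipped with a log message;
  features with no admissible cis SNP yield empty record sets, not
  errors; a feature with no promoter probes loses its methylation term
  with a warning; constant vectors are rejected by the inverse-normal
  transform and the Spearman prefilter.
* Problem sizes in the test suite (replicate counts, cohort sizes) follow
  the validation design: 10,000 pairs for null calibration of the scan,
  1,000 replicates for IV p-uniformity and CI coverage, 50 replicates at
  n = 500 for effect recovery — large enough that the Monte-Carlo error
  of each check is small relative to its assertion band.

## Known limitations

* The latent-factor surrogate is linear SVD, not PEER's ARD model.
* Single-instrument 2SLS only; no pleiotropy-robust estimators (Egger,
  weighted median) and no colocalization.
* No conditional/stepwise secondary-signal analysis within a clump.
* Immune-fraction compositionality is not modeled in the per-type IV.
* The published-table bookkeeping reproduces printed percentage
  arithmetic; it does not (and cannot) re-derive the underlying cohort
  counts from raw data.
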