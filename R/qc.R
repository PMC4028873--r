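#' Quality-control thresholds
#'
#' Defaults are the standard array/genotyping QC settings this pipeline is
#' built around: methylation samples need a probe detection call rate of at
#' least 90% and a mean intensity of at least half the experiment-wide mean
#' and at least 2,000 units; data points with detection p > 0.001 are set
#' to missing; PCA outliers beyond 2.5 SD from the origin in the PC1/PC2
#' plane are dropped; SNPs need call rate >= 95%, MAF >= 0.05, and a
#' Hardy-Weinberg exact p >= 1e-5; samples with > 5% missing genotype
#' calls are dropped.
#'
#' @param sample_detection_callrate_min minimum per-sample detection call rate.
#' @param detection_p_max detection p-value above which a point is masked.
#' @param intensity_rel_min minimum intensity relative to the sample mean.
#' @param intensity_abs_min minimum absolute intensity (arbitrary units).
#' @param pca_sd_cut PC1/PC2 distance cutoff in SDs.
#' @param snp_callrate_min minimum per-SNP call rate.
#' @param maf_min minimum minor allele frequency (exclusion is strict `<`).
#' @param hwe_p_min minimum Hardy-Weinberg exact-test p-value.
#' @param sample_missing_max maximum per-sample genotype missingness.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_detection_callrate_min = 0.90,
                          detection_p_max = 0.001,
                          intensity_rel_min = 0.50,
                          intensity_abs_min = 2000,
                          pca_sd_cut = 2.5,
                          snp_callrate_min = 0.95,
                          maf_min = 0.05,
                          hwe_p_min = 0.00001,
                          sample_missing_max = 0.05) {
  thr <- list(sample_detection_callrate_min = sample_detection_callrate_min,
              detection_p_max = detection_p_max,
              intensity_rel_min = intensity_rel_min,
              intensity_abs_min = intensity_abs_min,
              pca_sd_cut = pca_sd_cut,
              snp_callrate_min = snp_callrate_min,
              maf_min = maf_min, hwe_p_min = hwe_p_min,
              sample_missing_max = sample_missing_max)
  stopifnot(all(vapply(thr, function(x) is.numeric(x) && length(x) == 1 && x >= 0, logical(1))))
  class(thr) <- "qc_thresholds"
  thr
}

#' Methylation sample QC and detection-p masking
#'
#' Removes samples whose probe detection call rate (fraction of probes with
#' detection p at or below `detection_p_max`) is below the minimum, or
#' whose mean intensity fails either the relative or the absolute rule.
#' After sample exclusion, every remaining data point with detection
#' p-value above the threshold is set to missing.
#'
#' @param m a [methylation_matrix()] with detection p-values and intensity.
#' @param thr a [qc_thresholds()].
#' @return A list: `methylation` (filtered, masked) and `qc_log` records.
#' @export
methylation_sample_qc <- function(m, thr = qc_thresholds()) {
  stopifnot(inherits(m, "methylation_matrix"))
  det <- m$detection_p
  callrate <- rowMeans(det <= thr$detection_p_max | is.na(det))
  inten <- m$intensity
  rel_ok <- is.na(inten) | inten >= thr$intensity_rel_min * mean(inten, na.rm = TRUE)
  abs_ok <- is.na(inten) | inten >= thr$intensity_abs_min
  drop_call <- callrate < thr$sample_detection_callrate_min
  drop_int <- !(rel_ok & abs_ok)
  drop <- drop_call | drop_int
  if (all(drop)) stop("methylation sample QC excluded every sample")
  log <- rbind(
    qc_log_record("methylation_sample_qc", "sample",
                  rownames(det)[drop_call], "detection call rate < minimum"),
    qc_log_record("methylation_sample_qc", "sample",
                  rownames(det)[drop_int & !drop_call], "low mean intensity")
  )
  keep <- !drop
  beta <- m$beta[keep, , drop = FALSE]
  det <- det[keep, , drop = FALSE]
  beta[!is.na(det) & det > thr$detection_p_max] <- NA_real_
  list(methylation = methylation_matrix(beta, det, m$intensity[keep]),
       qc_log = log)
}

#' PCA-based outlier sample removal
#'
#' Single pass: beta-values are mean-imputed per CpG (for the decomposition
#' only) and centered; a sample is removed when its Euclidean distance from
#' the origin in the (PC1, PC2) score plane exceeds `pca_sd_cut` standard
#' deviations, where one standard deviation is the natural scale of the
#' zero-mean score cloud, `sqrt(sd(PC1)^2 + sd(PC2)^2)` (the root mean
#' square distance). Under this rule a clean cohort loses essentially no
#' samples, while a globally shifted array sits far outside the cut.
#'
#' @param m a [methylation_matrix()] with at least 3 samples.
#' @param thr a [qc_thresholds()].
#' @return A list: `methylation` (filtered), `excluded` sample IDs, and
#'   `qc_log` records.
#' @export
pca_outlier_removal <- function(m, thr = qc_thresholds()) {
  stopifnot(inherits(m, "methylation_matrix"))
  beta <- m$beta
  if (nrow(beta) < 3) stop("PCA outlier removal needs at least 3 samples")
  for (j in seq_len(ncol(beta))) {
    miss <- is.na(beta[, j])
    if (any(miss)) beta[miss, j] <- mean(beta[, j], na.rm = TRUE)
  }
  beta[is.na(beta)] <- 0  # CpGs missing in all samples carry no signal
  pc <- stats::prcomp(beta, center = TRUE, scale. = FALSE, rank. = 2)
  sc <- pc$x
  d <- sqrt(sc[, 1]^2 + if (ncol(sc) >= 2) sc[, 2]^2 else 0)
  cut <- thr$pca_sd_cut * sqrt(mean(d^2))
  drop <- if (is.na(cut) || cut == 0) rep(FALSE, length(d)) else d > cut
  excluded <- rownames(m$beta)[drop]
  keep <- !drop
  list(
    methylation = methylation_matrix(m$beta[keep, , drop = FALSE],
                                     m$detection_p[keep, , drop = FALSE],
                                     m$intensity[keep]),
    excluded = excluded,
    qc_log = qc_log_record("pca_outlier_removal", "sample", excluded,
                           sprintf("PC1/PC2 distance > %.1f SD", thr$pca_sd_cut))
  )
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the sum of probabilities of all heterozygote counts no more likely than
#' the observed one (two-sided by probability ordering).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype observation required")
  nA <- 2L * n_AA + n_Aa
  rare <- min(nA, 2L * n - nA)
  if (rare == 0L) return(1)
  h <- seq(rare %% 2L, rare, by = 2L)
  lp <- lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((2 * n - nA - h) / 2) + h * log(2) +
    lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  lp <- lp - logsumexp(lp)  # guard against rounding in the closed form
  p_obs <- lp[match(n_Aa, h)]
  min(1, sum(exp(lp[lp <= p_obs + 1e-9])))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' SNP and genotype-sample QC
#'
#' Order of operations: (1) drop samples with genotype missingness above
#' `sample_missing_max`; (2) drop SNPs with call rate below
#' `snp_callrate_min`; (3) drop SNPs with Hardy-Weinberg exact p below
#' `hwe_p_min`; (4) drop SNPs with MAF below `maf_min` (strict `<`, so a
#' SNP at exactly the threshold is retained). MAF and HWE are computed on
#' the retained sample set.
#'
#' @param g a [genotype_matrix()].
#' @param thr a [qc_thresholds()].
#' @return A list: `genotypes` (filtered) and `qc_log` records.
#' @export
snp_qc <- function(g, thr = qc_thresholds()) {
  if (!nrow(g) || !ncol(g)) stop("empty genotype matrix")
  log <- empty_qc_log()

  miss_sample <- rowMeans(is.na(g))
  drop_s <- miss_sample > thr$sample_missing_max
  log <- rbind(log, qc_log_record("snp_qc", "sample", rownames(g)[drop_s],
                                  sprintf("genotype missingness > %g", thr$sample_missing_max)))
  g <- g[!drop_s, , drop = FALSE]
  if (!nrow(g)) stop("SNP QC excluded every sample")

  callrate <- colMeans(!is.na(g))
  drop_cr <- callrate < thr$snp_callrate_min
  log <- rbind(log, qc_log_record("snp_qc", "snp", colnames(g)[drop_cr],
                                  sprintf("call rate < %g", thr$snp_callrate_min)))
  g <- g[, !drop_cr, drop = FALSE]

  if (ncol(g)) {
    hwe_p <- vapply(seq_len(ncol(g)), function(j) {
      x <- g[, j]
      hwe_exact_test(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                     sum(x == 0, na.rm = TRUE))
    }, numeric(1))
    drop_hwe <- hwe_p < thr$hwe_p_min
    log <- rbind(log, qc_log_record("snp_qc", "snp", colnames(g)[drop_hwe],
                                    sprintf("HWE exact p < %g", thr$hwe_p_min)))
    g <- g[, !drop_hwe, drop = FALSE]
  }

  if (ncol(g)) {
    f <- colMeans(g, na.rm = TRUE) / 2
    maf <- pmin(f, 1 - f)
    drop_maf <- maf < thr$maf_min
    log <- rbind(log, qc_log_record("snp_qc", "snp", colnames(g)[drop_maf],
                                    sprintf("MAF < %g", thr$maf_min)))
    g <- g[, !drop_maf, drop = FALSE]
  }

  if (!ncol(g)) stop("SNP QC excluded every SNP")
  list(genotypes = g, qc_log = log)
}

#' Exclude CpG probes containing known variants
#'
#' A CpG is excluded iff any variant position falls within its probe
#' interval (1-based, inclusive on both ends); such probes yield technical
#' artifacts rather than genuine SNP-methylation associations.
#'
#' @param cpg_ann a [cpg_annotation()].
#' @param variants a [snp_annotation()] (or any data.frame with `chrom`
#'   and `pos`) of variants to screen against.
#' @return Character vector of retained CpG IDs.
#' @export
exclude_probes_with_snps <- function(cpg_ann, variants) {
  retained <- logical(nrow(cpg_ann))
  for (ch in unique(cpg_ann$chrom)) {
    ci <- which(cpg_ann$chrom == ch)
    vp <- sort(variants$pos[variants$chrom == ch])
    if (!length(vp)) {
      retained[ci] <- TRUE
      next
    }
    n_inside <- findInterval(cpg_ann$probe_end[ci], vp) -
      findInterval(cpg_ann$probe_start[ci] - 1L, vp)
    retained[ci] <- n_inside == 0L
  }
  cpg_ann$cpg_id[retained]
}

#' Apply the full QC cascade to a cohort
#'
#' Runs methylation sample QC, PCA outlier removal, SNP/sample genotype QC,
#' and probe-SNP exclusion (against the cohort's own SNP annotation), then
#' restricts all components to the surviving common sample set. Every
#' exclusion is appended to the cohort's `qc_log`.
#'
#' @param ds a [cohort_dataset()].
#' @param thr a [qc_thresholds()].
#' @return The filtered [cohort_dataset()].
#' @export
apply_qc <- function(ds, thr = qc_thresholds()) {
  stopifnot(inherits(ds, "cohort_dataset"))
  log <- ds$qc_log

  mq <- methylation_sample_qc(ds$methylation, thr)
  log <- rbind(log, mq$qc_log)
  pq <- pca_outlier_removal(mq$methylation, thr)
  log <- rbind(log, pq$qc_log)
  meth <- pq$methylation

  # SNP statistics (call rate, HWE, MAF) are computed on the samples that
  # survive methylation QC - the set the association tests will use
  geno <- ds$genotypes[intersect(rownames(meth$beta), rownames(ds$genotypes)), ,
                       drop = FALSE]
  gq <- snp_qc(geno, thr)
  log <- rbind(log, gq$qc_log)
  geno <- gq$genotypes

  keep_cpg <- exclude_probes_with_snps(ds$cpg_ann, ds$snp_ann)
  dropped_cpg <- setdiff(ds$cpg_ann$cpg_id, keep_cpg)
  log <- rbind(log, qc_log_record("exclude_probes_with_snps", "cpg", dropped_cpg,
                                  "variant within probe interval"))
  meth <- methylation_matrix(meth$beta[, keep_cpg, drop = FALSE],
                             meth$detection_p[, keep_cpg, drop = FALSE],
                             meth$intensity)

  samples <- intersect(rownames(meth$beta), rownames(geno))
  if (!length(samples)) stop("no samples survive QC in cohort ", ds$name)
  meth <- methylation_matrix(meth$beta[samples, , drop = FALSE],
                             meth$detection_p[samples, , drop = FALSE],
                             meth$intensity[samples])
  geno <- genotype_matrix(geno[samples, , drop = FALSE])
  covs <- ds$covariates
  if (!is.null(covs)) {
    covs <- covs[match(samples, covs$sample_id), , drop = FALSE]
    class(covs) <- c("covariate_table", "data.frame")
  }
  cohort_dataset(ds$name, geno,
                 ds$snp_ann[ds$snp_ann$snp_id %in% colnames(geno), , drop = FALSE],
                 meth,
                 ds$cpg_ann[ds$cpg_ann$cpg_id %in% keep_cpg, , drop = FALSE],
                 covariates = covs, qc_log = log)
}
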