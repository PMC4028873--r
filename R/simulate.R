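#' Configure the multi-cohort simulator
#'
#' Defaults emulate the structure of a seven-cohort meQTL study: two
#' African-American-like cohorts (adult peripheral blood and cord blood)
#' with short LD blocks, a Caucasian-like cord-blood cohort, and four brain
#' cohorts from a common Caucasian-like population with hybridization
#' batches and occasional array outliers. Sample sizes default to the study
#' sizes (90, 87, 87, 111, 125, 105, 106); feature counts default to a desk
#' scale that still yields several hundred cis pairs per cohort.
#'
#' @param n_cohorts number of cohorts.
#' @param cohort_names cohort labels.
#' @param n_samples per-cohort sample sizes (recycled to `n_cohorts`).
#' @param n_snps,n_cpgs number of SNPs / CpG probes (shared positions).
#' @param chrom_length simulated chromosome length in bp.
#' @param maf_lo,maf_hi per-cohort bounds of the uniform per-SNP minor
#'   allele frequency, in (0, 0.5].
#' @param ld_block_len per-cohort LD block length in SNPs; haplotypes are
#'   correlated within a block and independent across blocks.
#' @param ld_rho within-block haplotype copy probability per SNP step;
#'   adjacent-SNP correlation decays roughly as `ld_rho^distance`.
#' @param n_planted number of planted cis SNP-CpG effects.
#' @param effect_size planted additive effect, delta-beta per REF allele.
#' @param effect_sharing optional 0/1 matrix (`n_planted` x `n_cohorts`):
#'   which cohorts carry each planted effect. Default: half the effects are
#'   shared by all cohorts, the rest by random subsets.
#' @param noise_sd per-sample logit-scale methylation noise SD.
#' @param baseline_logit_sd SD of CpG baseline levels on the logit scale.
#' @param batch_effect_sd beta-scale SD of per-batch, per-CpG offsets.
#' @param n_batches per-cohort number of hybridization batches.
#' @param outlier_fraction per-cohort fraction of samples given a large
#'   global methylation shift (detectable on PC1/PC2).
#' @param outlier_shift beta-scale size of the outlier shift.
#' @param detection_fail_rate fraction of data points with detection
#'   p-value above the 0.001 QC threshold.
#' @param genotype_missing_rate fraction of missing genotype calls.
#' @param seed integer seed; fully determines all simulator output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 7,
                       cohort_names = c("PB", "CBA", "CBB", "FCTX", "TCTX", "CRBLM", "PONS")[seq_len(n_cohorts)],
                       n_samples = c(90, 87, 87, 111, 125, 105, 106)[seq_len(n_cohorts)],
                       n_snps = 240, n_cpgs = 80, chrom_length = 4e6,
                       maf_lo = 0.05, maf_hi = 0.5,
                       ld_block_len = c(5, 5, 15, 15, 15, 15, 15)[seq_len(n_cohorts)],
                       ld_rho = 0.9,
                       n_planted = 15, effect_size = 0.1,
                       effect_sharing = NULL,
                       noise_sd = 0.3, baseline_logit_sd = 1.5,
                       batch_effect_sd = 0.02,
                       n_batches = c(1, 1, 1, 2, 2, 2, 2)[seq_len(n_cohorts)],
                       outlier_fraction = c(0, 0, 0, 0.02, 0.02, 0.02, 0.02)[seq_len(n_cohorts)],
                       outlier_shift = 0.3,
                       detection_fail_rate = 0.01,
                       genotype_missing_rate = 0.01,
                       seed = 1L) {
  cfg <- list(
    n_cohorts = as.integer(n_cohorts),
    cohort_names = as.character(cohort_names),
    n_samples = as.integer(rep_len(n_samples, n_cohorts)),
    n_snps = as.integer(n_snps), n_cpgs = as.integer(n_cpgs),
    chrom_length = as.integer(chrom_length),
    maf_lo = rep_len(maf_lo, n_cohorts), maf_hi = rep_len(maf_hi, n_cohorts),
    ld_block_len = as.integer(rep_len(ld_block_len, n_cohorts)),
    ld_rho = ld_rho,
    n_planted = as.integer(n_planted), effect_size = effect_size,
    effect_sharing = effect_sharing,
    noise_sd = noise_sd, baseline_logit_sd = baseline_logit_sd,
    batch_effect_sd = batch_effect_sd,
    n_batches = as.integer(rep_len(n_batches, n_cohorts)),
    outlier_fraction = rep_len(outlier_fraction, n_cohorts),
    outlier_shift = outlier_shift,
    detection_fail_rate = detection_fail_rate,
    genotype_missing_rate = genotype_missing_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_cohorts >= 1, cfg$n_snps >= 1, cfg$n_cpgs >= 1,
            length(cfg$cohort_names) == cfg$n_cohorts)
  if (any(cfg$maf_lo <= 0 | cfg$maf_lo > cfg$maf_hi | cfg$maf_hi > 0.5)) {
    stop("require 0 < maf_lo <= maf_hi <= 0.5 for every cohort")
  }
  if (any(cfg$n_snps < cfg$ld_block_len)) stop("n_snps < ld_block_len")
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (cfg$effect_size < 0 || cfg$effect_size > 0.3) {
    stop("effect_size must be in [0, 0.3] so planted beta stays inside (0, 1)")
  }
  if (!is.null(cfg$effect_sharing)) {
    es <- as.matrix(cfg$effect_sharing)
    if (!identical(dim(es), c(cfg$n_planted, cfg$n_cohorts))) {
      stop("effect_sharing must be an n_planted x n_cohorts matrix")
    }
    if (!all(es %in% c(0, 1))) stop("effect_sharing entries must be 0/1")
  }
  invisible(cfg)
}

# deterministic stream seeds: one global seed fans out to independent
# per-stage / per-cohort seeds, all below 2^31
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(tag)) h <- (h * 131 + v) %% 2147483629
  as.integer(h)
}

# shared SNP/CpG annotations: identical positions in every cohort
sim_annotations <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "annotation"))
  snp_pos <- sort(sample.int(cfg$chrom_length - 60L, cfg$n_snps))
  cpg_pos <- sort(sample.int(cfg$chrom_length - 60L, cfg$n_cpgs))
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, cfg$n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
  list(
    snp_ann = snp_annotation(sprintf("rs%06d", seq_len(cfg$n_snps)), "chr1",
                             snp_pos, ref, alt),
    cpg_ann = cpg_annotation(sprintf("cg%06d", seq_len(cfg$n_cpgs)), "chr1",
                             cpg_pos + 25L, cpg_pos, cpg_pos + 49L)
  )
}

#' Simulate one cohort's genotypes
#'
#' Haplotypes follow a latent-uniform copy chain: within an LD block each
#' haplotype either copies its previous latent value (probability `ld_rho`)
#' or draws afresh, and the allele at SNP j is the indicator that the
#' latent value falls below that SNP's frequency. Marginal per-SNP
#' frequencies are exact, genotypes are sums of two independent haplotypes
#' (so Hardy-Weinberg holds marginally), and adjacent-SNP r-squared decays
#' with distance inside a block and vanishes across block boundaries.
#'
#' @param cfg a [sim_config()].
#' @param cohort cohort index in `1..n_cohorts`.
#' @return A list with `genotypes` and `snp_ann` as in [read_genotypes()],
#'   plus a `maf` attribute on the matrix (the drawn per-SNP frequencies).
#' @export
simulate_genotypes <- function(cfg, cohort) {
  validate_sim_config(cfg)
  stopifnot(cohort >= 1, cohort <= cfg$n_cohorts)
  ann <- sim_annotations(cfg)
  set.seed(derive_seed(cfg$seed, "geno", cohort))
  n <- cfg$n_samples[cohort]
  m <- cfg$n_snps
  blk <- cfg$ld_block_len[cohort]
  # allele frequencies are anchored per LD block with small per-SNP jitter:
  # appreciable r^2 between linked SNPs requires closely matched
  # frequencies, so independent per-SNP draws would give blocks in name
  # only. With maf_lo == maf_hi every SNP gets exactly that frequency.
  block_id <- (seq_len(m) - 1L) %/% blk
  anchor <- stats::runif(max(block_id) + 1L, cfg$maf_lo[cohort], cfg$maf_hi[cohort])
  maf <- pmin(pmax(anchor[block_id + 1L] + stats::runif(m, -0.02, 0.02),
                   cfg$maf_lo[cohort]), cfg$maf_hi[cohort])
  nh <- 2L * n
  fresh <- matrix(stats::runif(nh * m), nh, m)
  keep <- matrix(stats::runif(nh * m) < cfg$ld_rho, nh, m)
  keep[, ((seq_len(m) - 1L) %% blk) == 0L] <- FALSE  # block boundaries restart
  u <- fresh
  for (j in seq_len(m)[-1]) {
    u[, j] <- ifelse(keep[, j], u[, j - 1L], fresh[, j])
  }
  alt_alleles <- sweep(u, 2, maf, `<`)  # minor allele = ALT
  alt_dose <- alt_alleles[seq_len(n), ] + alt_alleles[n + seq_len(n), ]
  ref_count <- 2L - alt_dose
  if (cfg$genotype_missing_rate > 0) {
    ref_count[stats::runif(n * m) < cfg$genotype_missing_rate] <- NA_integer_
  }
  samples <- sprintf("%s_s%03d", cfg$cohort_names[cohort], seq_len(n))
  g <- genotype_matrix(ref_count, samples = samples, snps = ann$snp_ann$snp_id)
  attr(g, "maf") <- stats::setNames(maf, ann$snp_ann$snp_id)
  list(genotypes = g, snp_ann = ann$snp_ann)
}

# planted pairs and per-cohort sharing flags, deterministic in cfg$seed
sim_truth <- function(cfg) {
  ann <- sim_annotations(cfg)
  set.seed(derive_seed(cfg$seed, "truth"))
  snp <- ann$snp_ann
  cpg <- ann$cpg_ann
  # candidate SNPs: within 50 kb of the CpG but outside its probe interval
  cand <- lapply(seq_len(nrow(cpg)), function(i) {
    ok <- snp$chrom == cpg$chrom[i] & abs(snp$pos - cpg$pos[i]) <= 50000L &
      !(snp$pos >= cpg$probe_start[i] & snp$pos <= cpg$probe_end[i])
    which(ok)
  })
  eligible <- which(lengths(cand) > 0)
  if (length(eligible) < cfg$n_planted) {
    stop("not enough CpGs with a SNP within 50 kb to plant ", cfg$n_planted, " effects")
  }
  cpg_idx <- sort(sample(eligible, cfg$n_planted))
  snp_idx <- vapply(cand[cpg_idx], function(k) k[sample.int(length(k), 1)], integer(1))
  sign <- sample(c(-1, 1), cfg$n_planted, replace = TRUE)
  sharing <- cfg$effect_sharing
  if (is.null(sharing)) {
    n_shared <- ceiling(cfg$n_planted / 2)
    sharing <- rbind(
      matrix(1, n_shared, cfg$n_cohorts),
      matrix(stats::rbinom((cfg$n_planted - n_shared) * cfg$n_cohorts, 1, 0.5),
             cfg$n_planted - n_shared, cfg$n_cohorts)
    )
    empty <- rowSums(sharing) == 0
    sharing[empty, sample.int(cfg$n_cohorts, sum(empty), replace = TRUE)] <- 1
  }
  sharing <- as.matrix(sharing)
  dimnames(sharing) <- list(NULL, cfg$cohort_names)
  structure(
    list(pairs = data.frame(snp_id = snp$snp_id[snp_idx],
                            cpg_id = cpg$cpg_id[cpg_idx],
                            sign = sign, stringsAsFactors = FALSE),
         sharing = sharing),
    class = "sim_truth"
  )
}

#' Simulate one cohort's methylation matrix
#'
#' Each CpG has a logit-normal baseline (a shared component plus a cohort
#' shift); per-sample noise is normal on the logit scale, which yields the
#' heteroskedastic beta-value spread seen on arrays. Planted effects add
#' `sign * effect_size * (REF allele count)` on the beta scale; batch
#' offsets and outlier shifts are added afterwards and the result is
#' clamped to `[0.01, 0.99]`. Planted CpGs have mid-range baselines
#' (beta in `[0.3, 0.6]`) so clamping does not attenuate planted slopes.
#'
#' @param cfg a [sim_config()].
#' @param genotypes the cohort's [genotype_matrix()].
#' @param truth a truth object from [simulate_study()] (planted pairs).
#' @param cohort cohort index.
#' @return A [methylation_matrix()] with attributes `batch` (per-sample
#'   batch factor) and `outliers` (shifted sample IDs).
#' @export
simulate_methylation <- function(cfg, genotypes, truth, cohort) {
  validate_sim_config(cfg)
  ann <- sim_annotations(cfg)
  if (!all(truth$pairs$snp_id %in% colnames(genotypes))) {
    stop("truth refers to SNPs absent from the genotype matrix")
  }
  n <- nrow(genotypes)
  m <- cfg$n_cpgs
  planted_col <- match(truth$pairs$cpg_id, ann$cpg_ann$cpg_id)

  # shared baselines (identical across cohorts)
  set.seed(derive_seed(cfg$seed, "baseline"))
  base_logit <- stats::rnorm(m, 0, cfg$baseline_logit_sd)
  base_logit[planted_col] <- stats::qlogis(stats::runif(cfg$n_planted, 0.3, 0.6))

  set.seed(derive_seed(cfg$seed, "meth", cohort))
  cohort_shift <- stats::rnorm(m, 0, 0.3)
  cohort_shift[planted_col] <- 0
  logit <- matrix(base_logit + cohort_shift, n, m, byrow = TRUE) +
    matrix(stats::rnorm(n * m, 0, cfg$noise_sd), n, m)
  beta <- stats::plogis(logit)

  for (i in seq_len(nrow(truth$pairs))) {
    if (truth$sharing[i, cohort] == 1) {
      g <- genotypes[, truth$pairs$snp_id[i]]
      g[is.na(g)] <- 0
      beta[, planted_col[i]] <- beta[, planted_col[i]] +
        truth$pairs$sign[i] * cfg$effect_size * g
    }
  }

  nb <- cfg$n_batches[cohort]
  batch <- factor(rep_len(seq_len(nb), n))
  if (nb > 1 && cfg$batch_effect_sd > 0) {
    offs <- matrix(stats::rnorm(nb * m, 0, cfg$batch_effect_sd), nb, m)
    beta <- beta + offs[as.integer(batch), ]
  }

  n_out <- round(cfg$outlier_fraction[cohort] * n)
  out_idx <- if (n_out > 0) sample.int(n, n_out) else integer(0)
  if (n_out > 0) beta[out_idx, ] <- beta[out_idx, ] + cfg$outlier_shift

  beta <- pmin(pmax(beta, 0.01), 0.99)

  det <- matrix(stats::runif(n * m, 0, 5e-4), n, m)
  if (cfg$detection_fail_rate > 0) {
    fail <- stats::runif(n * m) < cfg$detection_fail_rate
    det[fail] <- stats::runif(sum(fail), 0.0011, 0.2)
  }
  intensity <- stats::rnorm(n, 5000, 300)

  samples <- rownames(genotypes)
  dimnames(beta) <- dimnames(det) <- list(samples, ann$cpg_ann$cpg_id)
  mm <- methylation_matrix(beta, det, stats::setNames(intensity, samples))
  attr(mm, "batch") <- stats::setNames(batch, samples)
  attr(mm, "outliers") <- samples[out_idx]
  mm
}

#' Simulate a full multi-cohort study
#'
#' All cohorts share SNP/CpG positions but differ in allele frequencies,
#' LD block length, baseline methylation, batches/outliers, and in which
#' planted effects they carry (`effect_sharing`). Ground truth is returned
#' so recovery can be scored.
#'
#' @param cfg a [sim_config()].
#' @return A list with `cohorts` (list of [cohort_dataset()]) and `truth`
#'   (planted pairs with per-cohort sharing flags and signs).
#' @export
simulate_study <- function(cfg) {
  validate_sim_config(cfg)
  truth <- sim_truth(cfg)
  cohorts <- lapply(seq_len(cfg$n_cohorts), function(k) {
    gen <- simulate_genotypes(cfg, k)
    meth <- simulate_methylation(cfg, gen$genotypes, truth, k)
    ann <- sim_annotations(cfg)
    batch <- attr(meth, "batch")
    covs <- NULL
    if (nlevels(batch) > 1) {
      args <- list(sample_id = rownames(gen$genotypes))
      for (b in levels(batch)[-1]) {
        args[[paste0("batch", b)]] <- as.numeric(batch == b)
      }
      covs <- do.call(covariate_table, args)
    }
    cohort_dataset(cfg$cohort_names[k], gen$genotypes, gen$snp_ann,
                   meth, ann$cpg_ann, covariates = covs)
  })
  names(cohorts) <- cfg$cohort_names
  list(cohorts = cohorts, truth = truth)
}
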