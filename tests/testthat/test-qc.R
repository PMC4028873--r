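test_that("methylation sample QC applies call-rate and intensity rules", {
  m <- tiny_methylation(n = 10, m = 20, seed = 41)
  # sample 1: only 85% of probes detected -> excluded
  m$detection_p[1, 1:3] <- 0.5
  # sample 2: intensity below the 2,000-unit floor -> excluded
  m$intensity[2] <- 1900
  # sample 3: above the absolute floor but below half the experiment-wide
  # mean of ~4390 -> excluded by the relative rule
  m$intensity[3] <- 2000
  # sample 4: one masked data point but retained
  m$detection_p[4, 7] <- 0.01
  out <- methylation_sample_qc(m)
  kept <- rownames(out$methylation$beta)
  expect_false(any(c("s01", "s02", "s03") %in% kept))
  expect_true("s04" %in% kept)
  expect_true(is.na(out$methylation$beta["s04", 7]))
  expect_equal(sum(!is.na(out$methylation$beta["s04", ])), 19L)
  expect_setequal(out$qc_log$item_id, c("s01", "s02", "s03"))

  # clean matrix: nothing excluded, nothing masked
  clean <- methylation_sample_qc(tiny_methylation(n = 6, m = 8, det = 0))
  expect_equal(nrow(clean$methylation$beta), 6L)
  expect_false(anyNA(clean$methylation$beta))
  expect_equal(nrow(clean$qc_log), 0L)
})

test_that("PCA outlier removal flags planted shifts and respects the boundary", {
  # identical samples: no outliers, no error
  beta <- matrix(0.5, 10, 8,
                 dimnames = list(sprintf("s%02d", 1:10), sprintf("cg%03d", 1:8)))
  expect_length(pca_outlier_removal(methylation_matrix(beta))$excluded, 0)

  # one sample shifted ~10 SD on PC1 among 50
  m <- tiny_methylation(n = 50, m = 30, seed = 43)
  m$beta[17, ] <- pmin(m$beta[17, ] + 0.45, 0.99)
  out <- pca_outlier_removal(m)
  expect_identical(out$excluded, "s17")

  # max distance below the 2.5 SD cut: nothing excluded
  m2 <- tiny_methylation(n = 30, m = 20, seed = 44)
  sc <- prcomp(m2$beta)$x[, 1:2]
  d <- sqrt(rowSums(sc^2))
  expect_lt(max(d) / sqrt(mean(d^2)), 2.5)  # fixture sits inside the boundary
  expect_length(pca_outlier_removal(m2)$excluded, 0)

  expect_error(pca_outlier_removal(tiny_methylation(n = 2, m = 5)), "3 samples")
})

test_that("HWE exact test matches direct enumeration", {
  expect_equal(hwe_exact_test(50, 0, 0), 1)         # monomorphic
  expect_equal(hwe_exact_test(25, 50, 25), hwe_enum_oracle(25, 50, 25))
  expect_equal(hwe_exact_test(0, 100, 0), hwe_enum_oracle(0, 100, 0),
               tolerance = 1e-9)
  expect_lt(hwe_exact_test(0, 100, 0), 1e-5)
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")

  set.seed(47)
  for (rep in 1:50) {
    counts <- as.vector(rmultinom(1, sample(5:80, 1), runif(3)))
    expect_equal(hwe_exact_test(counts[1], counts[2], counts[3]),
                 hwe_enum_oracle(counts[1], counts[2], counts[3]),
                 tolerance = 1e-9)
  }
})

test_that("SNP QC applies missingness, call-rate, HWE, and MAF filters in order", {
  set.seed(53)
  n <- 100
  # enough well-behaved SNPs that a single missing call keeps per-sample
  # missingness under the 5% sample filter
  good <- matrix(sample(0:2, n * 24, TRUE, prob = c(.25, .5, .25)), n, 24,
                 dimnames = list(NULL, sprintf("good%02d", 1:24)))
  vals <- cbind(
    good,
    maf_low = c(rep(1L, 4), rep(2L, n - 4)),              # MAF 0.02 -> dropped
    maf_edge = c(rep(1L, 10), rep(2L, n - 10)),           # MAF exactly 0.05 -> kept
    hwe_bad = rep(1L, n),                                 # all het -> HWE p << 1e-5
    low_call = c(rep(NA_integer_, 6), sample(0:2, n - 6, TRUE))  # 94% call rate
  )
  g <- genotype_matrix(vals, samples = sprintf("s%03d", 1:n),
                       snps = colnames(vals))
  out <- snp_qc(g)
  expect_true("maf_edge" %in% colnames(out$genotypes))
  expect_false(any(c("maf_low", "hwe_bad", "low_call") %in% colnames(out$genotypes)))
  reasons <- setNames(out$qc_log$reason, out$qc_log$item_id)
  expect_match(reasons[["maf_low"]], "MAF")
  expect_match(reasons[["hwe_bad"]], "HWE")
  expect_match(reasons[["low_call"]], "call rate")

  # sample with > 5% missing genotypes is dropped before SNP filters
  vals2 <- matrix(sample(0:2, 20 * 30, TRUE), 20, 30)
  vals2[1, 1:3] <- NA  # 10% missing
  g2 <- genotype_matrix(vals2, sprintf("s%02d", 1:20), sprintf("rs%03d", 1:30))
  out2 <- snp_qc(g2, qc_thresholds(maf_min = 0))
  expect_false("s01" %in% rownames(out2$genotypes))
})

test_that("QC filters are idempotent and the log reconciles counts", {
  set.seed(59)
  study <- simulate_study(sim_config(n_cohorts = 1, cohort_names = "A",
                                     n_samples = 60, n_snps = 50, n_cpgs = 20,
                                     ld_block_len = 5, n_planted = 2,
                                     outlier_fraction = 0.05, seed = 61))
  ds <- study$cohorts[[1]]
  once <- apply_qc(ds)
  twice <- apply_qc(once)
  expect_identical(dim(once$genotypes), dim(twice$genotypes))
  expect_identical(colnames(once$methylation$beta), colnames(twice$methylation$beta))
  expect_equal(nrow(twice$qc_log), nrow(once$qc_log))  # nothing new to exclude

  # every removed sample/SNP/CpG is accounted for in the log
  log <- once$qc_log
  lost_snps <- setdiff(colnames(ds$genotypes), colnames(once$genotypes))
  expect_setequal(lost_snps, log$item_id[log$item_type == "snp"])
  lost_cpgs <- setdiff(colnames(ds$methylation$beta), colnames(once$methylation$beta))
  expect_setequal(lost_cpgs, log$item_id[log$item_type == "cpg"])
  lost_samples <- setdiff(rownames(ds$methylation$beta), rownames(once$methylation$beta))
  expect_true(all(lost_samples %in% log$item_id[log$item_type == "sample"]))
})

test_that("probes containing variants are excluded, inclusively at both ends", {
  cpg <- cpg_annotation(c("cg1", "cg2", "cg3"), "chr1",
                        c(100L, 300L, 500L), c(80L, 280L, 480L), c(129L, 329L, 529L))
  snp_at_start <- snp_annotation("rs1", "chr1", 80L, "A", "G")
  expect_false("cg1" %in% exclude_probes_with_snps(cpg, snp_at_start))
  snp_past_end <- snp_annotation("rs2", "chr1", 330L, "A", "G")
  expect_true("cg2" %in% exclude_probes_with_snps(cpg, snp_past_end))
  other_chrom <- snp_annotation("rs3", "chr9", 500L, "A", "G")
  expect_true("cg3" %in% exclude_probes_with_snps(cpg, other_chrom))

  # random instance against the all-pairs brute force
  set.seed(67)
  cpg_r <- cpg_annotation(sprintf("cg%03d", 1:100),
                          sample(c("chr1", "chr2"), 100, TRUE),
                          p <- sample.int(50000, 100), p - 25L, p + 24L)
  var_r <- snp_annotation(sprintf("rs%03d", 1:200),
                          sample(c("chr1", "chr2"), 200, TRUE),
                          sample.int(50000, 200), "A", "G")
  brute <- cpg_r$cpg_id[!vapply(seq_len(100), function(i) {
    any(var_r$chrom == cpg_r$chrom[i] &
          var_r$pos >= cpg_r$probe_start[i] & var_r$pos <= cpg_r$probe_end[i])
  }, logical(1))]
  expect_identical(exclude_probes_with_snps(cpg_r, var_r), brute)
})
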