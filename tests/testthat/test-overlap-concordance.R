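test_that("published seven-cohort overlap percents are reproduced from counts", {
  pub <- published_overlap_counts()
  ot <- overlap_table_from_counts(pub$counts, pub$shared, pub$universe)
  rep_mat <- render_overlap_report(ot)
  # four printed cells are internally inconsistent with the printed counts
  # (off by 0.1 or a digit slip); the remaining 38 must reproduce exactly
  discrepant <- rbind(c("TCTX", "PB"), c("FCTX", "TCTX"),
                      c("TCTX", "PONS"), c("PONS", "CB A"))
  n_checked <- 0
  for (i in pub$cohorts) {
    for (j in pub$cohorts) {
      if (i == j || any(discrepant[, 1] == i & discrepant[, 2] == j)) next
      expect_equal(rep_mat[i, j],
                   sprintf("%d (%.1f)", pub$shared[i, j], pub$percent_printed[i, j]),
                   label = paste("cell", i, j))
      n_checked <- n_checked + 1
    }
  }
  expect_equal(n_checked, 38)
  # spot examples: percent pair depends on which cohort is the baseline
  expect_equal(ot$percent["CB A", "PB"], 100 * 319 / 724)   # renders 44.1
  expect_equal(ot$percent["PB", "CB A"], 100 * 319 / 629)   # renders 50.7
  expect_equal(rep_mat["PB", "CB A"], "319 (50.7)")
})

test_that("overlap_table computes shared counts, percents, and Fisher tails", {
  keys <- sprintf("rs%02d:cg%02d", 1:30, rep(1:6, each = 5))
  a <- mock_scan(keys, sig_keys = keys[1:10])
  b <- mock_scan(keys, sig_keys = keys[6:15])
  ot <- overlap_table(list(A = a, B = b))
  expect_equal(unname(ot$meqtl_counts), c(10L, 10L))
  expect_equal(ot$shared["A", "B"], 5L)
  expect_equal(ot$percent["A", "B"], 50)
  expect_equal(ot$universe_size, 30L)
  expect_equal(ot$shared, t(ot$shared))

  # identical significant sets: 100% both directions, shared = count
  ot2 <- overlap_table(list(A = a, B = a))
  expect_equal(ot2$percent["A", "B"], 100)
  expect_equal(ot2$percent["B", "A"], 100)
  expect_equal(ot2$shared["A", "B"], 10L)

  # mismatched universes are refused
  expect_error(overlap_table(list(A = a, B = mock_scan(keys[1:20], keys[1]))),
               "mismatched")
})

test_that("fisher_exact_log10 matches enumeration and the stats oracle", {
  expect_equal(10^fisher_exact_log10(3, 1, 1, 3), fisher_enum_oracle(3, 1, 1, 3))
  # a at its expectation under independent margins: upper tail >= 0.5
  expect_gte(10^fisher_exact_log10(25, 25, 25, 25), 0.5)
  expect_error(fisher_exact_log10(-1, 1, 1, 1), "non-negative")

  set.seed(103)
  for (rep in 1:30) {
    cells <- as.vector(rmultinom(1, sample(10:200, 1), runif(4, 0.05, 1)))
    ours <- fisher_exact_log10(cells[1], cells[2], cells[3], cells[4])
    ft <- fisher.test(matrix(cells, 2, byrow = TRUE), alternative = "greater")
    expect_equal(10^ours, ft$p.value, tolerance = 1e-9)
  }
})

test_that("sign concordance matches exhaustive sign-vector enumeration", {
  # all 2^7 sign vectors once: every per-cohort positive proportion is 1/2
  k <- 7
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  cs <- sign_concordance(signs, m = 6)
  expect_equal(cs$p_i, setNames(rep(0.5, k), colnames(signs)))
  expect_equal(cs$expected_all_same, 2 * 0.5^7)          # 0.015625
  expect_equal(cs$observed_all_same, 2 / 128)
  expect_equal(cs$expected_atleast_m, 16 / 128)          # (2 + 14)/128
  expect_equal(cs$observed_atleast_m, 16 / 128)

  # all t-statistics positive: agreement is certain
  cs1 <- sign_concordance(matrix(abs(rnorm(30)) + 0.1, 10, 3), m = 3)
  expect_equal(cs1$expected_all_same, 1)
  expect_equal(cs1$observed_all_same, 1)

  # heterogeneous p_i: Poisson-binomial tail equals 2^k enumeration
  set.seed(107)
  for (k in c(3, 5, 8, 10)) {
    p <- runif(k, 0.2, 0.8)
    pmf <- poisson_binomial_pmf(p)
    vecs <- as.matrix(expand.grid(rep(list(0:1), k)))
    probs <- apply(vecs, 1, function(v) prod(ifelse(v == 1, p, 1 - p)))
    expect_equal(pmf, vapply(0:k, function(s) sum(probs[rowSums(vecs) == s]),
                             numeric(1)), tolerance = 1e-12)
    m <- sample.int(k, 1)
    expected_enum <- sum(probs[pmax(rowSums(vecs), k - rowSums(vecs)) >= m])
    tmat <- matrix(rnorm(40 * k), 40, k)
    tmat[tmat == 0] <- 1
    cs_k <- sign_concordance(tmat, m = m)
    pmf_k <- poisson_binomial_pmf(cs_k$p_i)
    probs_k <- apply(vecs, 1, function(v) prod(ifelse(v == 1, cs_k$p_i, 1 - cs_k$p_i)))
    expect_equal(cs_k$expected_atleast_m,
                 sum(probs_k[pmax(rowSums(vecs), k - rowSums(vecs)) >= m]),
                 tolerance = 1e-12)
  }

  expect_error(sign_concordance(matrix(1, 5, 3), m = 4), "exceed")
  # rows with zero t-statistics are dropped, not signed
  tz <- rbind(c(1, 1), c(0, 2), c(-1, -3))
  csz <- sign_concordance(tz, m = 2)
  expect_equal(csz$n_pairs, 2L)
  expect_equal(csz$n_dropped_zero_or_missing, 1L)
})

test_that("expected all-same-sign has the closed form p^k + (1-p)^k", {
  set.seed(109)
  k <- 7
  for (p in c(0.3, 0.456, 0.493, 0.7)) {
    # sign matrix whose columns each contain exactly 1000*p positive entries
    n <- 1000
    tmat <- vapply(seq_len(k), function(j) {
      sample(c(rep(1, round(n * p)), rep(-1, n - round(n * p))))
    }, numeric(n)) * abs(rnorm(n * k) + 3)
    cs <- sign_concordance(tmat, m = k - 1)
    expect_equal(unname(cs$p_i), rep(p, k))
    expect_equal(cs$expected_all_same, p^k + (1 - p)^k, tolerance = 1e-12)
  }
})

test_that("ld_prune removes correlated SNPs and keeps independent ones", {
  set.seed(113)
  # mutually independent SNPs with n large enough that sampling noise
  # cannot push any pairwise r2 over the threshold
  g_ind <- genotype_matrix(matrix(rbinom(800 * 15, 2, 0.4), 800, 15),
                           sprintf("s%03d", 1:800), sprintf("rs%03d", 1:15))
  expect_equal(ld_prune(g_ind, r2_max = 0.05), colnames(g_ind))

  # duplicated SNP column: exactly one of the pair survives
  g_dup <- cbind(unclass(g_ind), dup = unclass(g_ind)[, 3])
  g_dup <- genotype_matrix(g_dup, rownames(g_ind), colnames(g_dup))
  kept <- ld_prune(g_dup)
  expect_true(xor("rs003" %in% kept, "dup" %in% kept))

  # LD-blocked simulation: all retained within-window pairs have r2 <= 0.05
  cfg <- sim_config(n_cohorts = 1, cohort_names = "A", n_samples = 150,
                    n_snps = 100, n_cpgs = 2, ld_block_len = 10,
                    n_planted = 0, genotype_missing_rate = 0,
                    outlier_fraction = 0, n_batches = 1, seed = 127)
  sim <- simulate_genotypes(cfg, 1)
  kept2 <- ld_prune(sim$genotypes, sim$snp_ann, window = 50, r2_max = 0.05, step = 5)
  expect_lt(length(kept2), 100)
  idx <- match(kept2, colnames(sim$genotypes))
  for (w in seq(1, length(idx) - 1)) {
    span <- idx[idx >= idx[w] & idx < idx[w] + 50]
    if (length(span) < 2) next
    r2 <- cor(unclass(sim$genotypes)[, span, drop = FALSE])^2
    expect_true(all(r2[upper.tri(r2)] <= 0.05 + 1e-12))
  }
})

test_that("t-statistic clustering is deterministic and groups identical cohorts", {
  set.seed(131)
  base <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  tmat <- cbind(base, A2 = base[, "A"])
  cl <- cluster_tstats(tmat)
  # the duplicated pair merges first at height 0
  expect_equal(cl$cohort_hclust$height[1], 0)
  first <- sort(-cl$cohort_hclust$merge[1, ])
  expect_setequal(colnames(tmat)[first], c("A", "A2"))

  # permuting rows leaves the cohort tree unchanged
  cl2 <- cluster_tstats(tmat[sample(nrow(tmat)), ])
  expect_equal(cl2$cohort_hclust$height, cl$cohort_hclust$height)
  expect_equal(cl2$cohort_order, cl$cohort_order)

  expect_error(cluster_tstats(matrix(1, 5, 1)), "2 cohorts")
})

test_that("cohorts cluster by allele-frequency regime", {
  # two low-MAF and two high-MAF cohorts sharing all planted effects:
  # power differences make same-regime t-statistics most similar
  hits <- 0
  for (seed in 1:6) {
    cfg <- sim_config(n_cohorts = 4, cohort_names = c("L1", "L2", "H1", "H2"),
                      n_samples = 80, n_snps = 60, n_cpgs = 20,
                      chrom_length = 1e6, ld_block_len = 5,
                      maf_lo = c(0.05, 0.05, 0.35, 0.35),
                      maf_hi = c(0.12, 0.12, 0.5, 0.5),
                      n_planted = 8, effect_size = 0.1,
                      effect_sharing = matrix(1, 8, 4),
                      outlier_fraction = 0, n_batches = 1,
                      detection_fail_rate = 0, seed = seed)
    st <- simulate_study(cfg)
    scans <- lapply(st$cohorts, scan_cohort, min_df = 30)
    common <- restrict_to_common_pairs(scans)
    tmat <- sapply(common, function(r) r$t)
    any_sig <- Reduce(`|`, lapply(common, function(r) r$significant))
    cl <- cluster_tstats(tmat[any_sig, , drop = FALSE])
    merges <- cl$cohort_hclust$merge
    leaf <- function(x) colnames(tmat)[-x]
    first2 <- apply(merges, 1, function(r) all(r < 0))
    pairs <- lapply(which(first2), function(i) sort(leaf(merges[i, ])))
    regime <- function(nm) substr(nm, 1, 1)
    if (any(vapply(pairs, function(p) regime(p[1]) == regime(p[2]), logical(1)))) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 5)
})

test_that("subject partitioning separates shared effects from shared subjects", {
  cfg <- sim_config(n_cohorts = 2, cohort_names = c("T1", "T2"),
                    n_samples = 100, n_snps = 80, n_cpgs = 30,
                    chrom_length = 1e6, ld_block_len = 4, n_planted = 8,
                    effect_size = 0.12, effect_sharing = matrix(1, 8, 2),
                    genotype_missing_rate = 0, outlier_fraction = 0,
                    n_batches = 1, detection_fail_rate = 0, seed = 137)
  st <- simulate_study(cfg)
  gen <- st$cohorts[[1]]$genotypes
  ann <- st$cohorts[[1]]
  # two tissues over the SAME subjects: same genotypes, independent noise
  meth_a <- simulate_methylation(cfg, gen, st$truth, 1)
  meth_b <- simulate_methylation(cfg, gen, st$truth, 2)
  ds_a <- cohort_dataset("T1", gen, ann$snp_ann, meth_a, ann$cpg_ann)
  ds_b <- cohort_dataset("T2", gen, ann$snp_ann, meth_b, ann$cpg_ann)

  po <- partition_overlap(ds_a, ds_b, seed = 7)
  expect_setequal(po$subjects,
                  c("same_subjects", "disjoint_subjects", "same_tissue_disjoint"))
  disj <- po[po$subjects == "disjoint_subjects", ]
  # shared planted effects: cross-tissue overlap in disjoint halves is
  # far beyond chance
  expect_true(all(disj$fisher_log10p < log10(0.05)))
  expect_true(all(disj$shared > 0))

  # disjoint planted effects: cross-tissue shared counts look like chance
  sharing <- rbind(matrix(c(1, 0), 4, 2, byrow = TRUE),
                   matrix(c(0, 1), 4, 2, byrow = TRUE))
  cfg2 <- sim_config(n_cohorts = 2, cohort_names = c("T1", "T2"),
                     n_samples = 100, n_snps = 80, n_cpgs = 30,
                     chrom_length = 1e6, ld_block_len = 4, n_planted = 8,
                     effect_size = 0.12, effect_sharing = sharing,
                     genotype_missing_rate = 0, outlier_fraction = 0,
                     n_batches = 1, detection_fail_rate = 0, seed = 139)
  st2 <- simulate_study(cfg2)
  gen2 <- st2$cohorts[[1]]$genotypes
  meth_a2 <- simulate_methylation(cfg2, gen2, st2$truth, 1)
  meth_b2 <- simulate_methylation(cfg2, gen2, st2$truth, 2)
  ds_a2 <- cohort_dataset("T1", gen2, st2$cohorts[[1]]$snp_ann, meth_a2,
                          st2$cohorts[[1]]$cpg_ann)
  ds_b2 <- cohort_dataset("T2", gen2, st2$cohorts[[1]]$snp_ann, meth_b2,
                          st2$cohorts[[1]]$cpg_ann)
  po2 <- partition_overlap(ds_a2, ds_b2, seed = 7)
  disj2 <- po2[po2$subjects == "disjoint_subjects", ]
  for (r in seq_len(nrow(disj2))) {
    row <- disj2[r, ]
    lo <- qhyper(0.025, row$n_i, row$universe - row$n_i, row$n_j)
    hi <- qhyper(0.975, row$n_i, row$universe - row$n_i, row$n_j)
    # planted pairs sit in LD neighborhoods, so allow the band's edges
    expect_gte(row$shared, lo)
    expect_lte(row$shared, hi + 2)
  }
  # too few common subjects is an error
  few <- rownames(ds_a$genotypes)[1:4]
  ds_small <- cohort_dataset("T1s",
                             genotype_matrix(ds_a$genotypes[few, , drop = FALSE]),
                             ds_a$snp_ann,
                             methylation_matrix(ds_a$methylation$beta[few, , drop = FALSE],
                                                ds_a$methylation$detection_p[few, , drop = FALSE],
                                                ds_a$methylation$intensity[few]),
                             ds_a$cpg_ann)
  expect_error(partition_overlap(ds_small, ds_b), "8 common subjects")
})
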