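#' Restrict scan results to the pairs tested in every cohort
#'
#' Cross-cohort comparisons are only meaningful over SNP-CpG combinations
#' that produced a test in all cohorts; this helper intersects the tested
#' (`status == "ok"`) pair sets and subsets each result table to it.
#'
#' @param results_by_cohort named list of [scan_cohort()] results.
#' @return The list with each element restricted to the common universe,
#'   in a common row order.
#' @export
restrict_to_common_pairs <- function(results_by_cohort) {
  stopifnot(length(results_by_cohort) >= 2)
  keys <- lapply(results_by_cohort, function(r) {
    paste(r$snp_id, r$cpg_id, sep = "\r")[r$status == "ok"]
  })
  common <- Reduce(intersect, keys)
  lapply(results_by_cohort, function(r) {
    key <- paste(r$snp_id, r$cpg_id, sep = "\r")
    r <- r[match(common, key), , drop = FALSE]
    rownames(r) <- NULL
    r
  })
}

#' Pairwise cross-cohort meQTL overlap table
#'
#' For every ordered cohort pair (i, j): the number of significant pairs
#' shared, the percent overlap with the column cohort's meQTL count as the
#' denominator (`percent[i, j] = 100 * shared[i, j] / counts[j]`), and a
#' one-sided Fisher exact log10 p-value for independence of meQTL status,
#' computed from the 2x2 table {both, i-only, j-only, neither} over the
#' common tested universe.
#'
#' @param results_by_cohort named list of [scan_cohort()] results over an
#'   identical (snp_id, cpg_id) universe (see [restrict_to_common_pairs()]).
#' @param universe_size number of pairs tested in every cohort; defaults
#'   to the common universe's size.
#' @return A list of class `overlap_table`.
#' @export
overlap_table <- function(results_by_cohort, universe_size = NULL) {
  k <- length(results_by_cohort)
  stopifnot(k >= 2)
  cohorts <- names(results_by_cohort)
  if (is.null(cohorts)) cohorts <- paste0("cohort", seq_len(k))
  keys <- lapply(results_by_cohort, function(r) paste(r$snp_id, r$cpg_id, sep = "\r"))
  for (i in seq_len(k)[-1]) {
    if (!identical(sort(keys[[i]]), sort(keys[[1]]))) {
      stop("cohorts have mismatched SNP-CpG universes; ",
           "restrict to common tested pairs first")
    }
  }
  if (is.null(universe_size)) universe_size <- length(unique(keys[[1]]))
  sig_sets <- lapply(seq_len(k), function(i) {
    keys[[i]][results_by_cohort[[i]]$significant %in% TRUE]
  })
  counts <- lengths(sig_sets)
  shared <- matrix(0L, k, k, dimnames = list(cohorts, cohorts))
  percent <- fisher <- matrix(NA_real_, k, k, dimnames = list(cohorts, cohorts))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      both <- length(intersect(sig_sets[[i]], sig_sets[[j]]))
      shared[i, j] <- both
      percent[i, j] <- 100 * both / counts[j]
      fisher[i, j] <- fisher_exact_log10(
        both, counts[i] - both, counts[j] - both,
        universe_size - counts[i] - counts[j] + both
      )
    }
  }
  structure(
    list(cohorts = cohorts, meqtl_counts = stats::setNames(counts, cohorts),
         shared = shared, percent = percent, fisher_log10p = fisher,
         universe_size = universe_size),
    class = "overlap_table"
  )
}

#' Build an overlap table from published counts
#'
#' Reconstructs an [overlap_table()] from per-cohort meQTL counts and a
#' pairwise shared-count matrix (the form in which cross-cohort overlap is
#' usually published), recomputing percents and Fisher log10 p-values.
#'
#' @param meqtl_counts named integer vector of per-cohort meQTL counts.
#' @param shared integer matrix of pairwise shared counts (diagonal ignored).
#' @param universe_size number of SNP-CpG combinations tested in every
#'   cohort (the Fisher 2x2 total).
#' @return A list of class `overlap_table`.
#' @export
overlap_table_from_counts <- function(meqtl_counts, shared, universe_size) {
  k <- length(meqtl_counts)
  cohorts <- names(meqtl_counts)
  shared <- as.matrix(shared)
  stopifnot(identical(dim(shared), c(k, k)))
  percent <- fisher <- matrix(NA_real_, k, k, dimnames = list(cohorts, cohorts))
  sh <- matrix(0L, k, k, dimnames = list(cohorts, cohorts))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      if (shared[i, j] > min(meqtl_counts[i], meqtl_counts[j])) {
        stop("shared count exceeds a cohort's meQTL count")
      }
      sh[i, j] <- as.integer(shared[i, j])
      percent[i, j] <- 100 * shared[i, j] / meqtl_counts[j]
      fisher[i, j] <- fisher_exact_log10(
        sh[i, j], meqtl_counts[i] - sh[i, j], meqtl_counts[j] - sh[i, j],
        universe_size - meqtl_counts[i] - meqtl_counts[j] + sh[i, j]
      )
    }
  }
  structure(
    list(cohorts = cohorts, meqtl_counts = meqtl_counts, shared = sh,
         percent = percent, fisher_log10p = fisher,
         universe_size = universe_size),
    class = "overlap_table"
  )
}

#' One-sided Fisher exact test, log10 scale
#'
#' Hypergeometric upper-tail probability `P(X >= a)` for the 2x2 table
#' `(a, b, c, d)` with fixed margins (the enrichment direction), computed
#' by log-sum-exp over log-scale hypergeometric mass so that p-values far
#' below the double-precision underflow limit (1e-308) remain
#' representable.
#'
#' @param a,b,c,d non-negative cell counts: `a` = both, `b` = first only,
#'   `c` = second only, `d` = neither.
#' @return log10 of the one-sided p-value.
#' @export
fisher_exact_log10 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)) || any(!is.finite(cells))) {
    stop("cell counts must be finite non-negative integers")
  }
  hi <- min(a + b, a + c)
  x <- a:hi
  lp <- stats::dhyper(x, m = a + b, n = c + d, k = a + c, log = TRUE)
  logsumexp(lp) / log(10)
}

#' Poisson-binomial probability mass function
#'
#' Distribution of the number of successes among independent Bernoulli
#' trials with unequal probabilities, by direct convolution.
#'
#' @param p vector of success probabilities.
#' @return numeric vector of length `length(p) + 1`; entry `s + 1` is
#'   `P(S = s)`.
#' @export
poisson_binomial_pmf <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  v <- 1
  for (pi in p) v <- c(v * (1 - pi), 0) + c(0, v * pi)
  v
}

#' Cross-cohort sign concordance of association t-statistics
#'
#' For pairs tested in several cohorts, compares the observed proportion
#' whose t-statistics agree in sign across all (or at least `m`) cohorts
#' with the chance expectation. With `p_i` the proportion of positive
#' t-statistics in cohort i, the all-same expectation is
#' `prod(p_i) + prod(1 - p_i)`; the at-least-m expectation is the
#' Poisson-binomial tail `P(S >= m) + P(S <= k - m) - P(m <= S <= k - m)`
#' (the last term removes double counting when both tails can hold, i.e.
#' when `m <= k/2`). Rows containing zero (signless) or missing
#' t-statistics are dropped. Observed vs expected proportions are compared
#' with one-sided binomial tests on the log10 scale.
#'
#' @param tstats numeric matrix, pairs x cohorts, typically restricted to
#'   pairs significant in at least one cohort.
#' @param m minimum number of agreeing cohorts for the "at least m"
#'   summary (default `k - 1`); must not exceed the number of cohorts.
#' @return A list of class `concordance_summary`.
#' @export
sign_concordance <- function(tstats, m = ncol(tstats) - 1L) {
  tstats <- as.matrix(tstats)
  k <- ncol(tstats)
  if (m > k) stop("m cannot exceed the number of cohorts")
  drop <- apply(tstats, 1, function(r) anyNA(r) || any(r == 0))
  n_dropped <- sum(drop)
  tstats <- tstats[!drop, , drop = FALSE]
  if (!nrow(tstats)) stop("no rows with complete, signed t-statistics")
  pos <- tstats > 0
  p_i <- colMeans(pos)
  n_pos <- rowSums(pos)
  n_pairs <- nrow(tstats)

  observed_all_same <- mean(n_pos == k | n_pos == 0)
  expected_all_same <- prod(p_i) + prod(1 - p_i)

  pmf <- poisson_binomial_pmf(p_i)
  tail_ge <- function(s) sum(pmf[(s + 1):(k + 1)])
  tail_le <- function(s) sum(pmf[1:(s + 1)])
  expected_atleast_m <- tail_ge(m) + tail_le(k - m) -
    if (m <= k - m) sum(pmf[(m + 1):(k - m + 1)]) else 0
  observed_atleast_m <- mean(pmax(n_pos, k - n_pos) >= m)

  binom_log10 <- function(obs_prop, exp_prop) {
    x <- round(obs_prop * n_pairs)
    stats::pbinom(x - 1, n_pairs, min(exp_prop, 1), lower.tail = FALSE,
                  log.p = TRUE) / log(10)
  }
  structure(
    list(k = k, n_pairs = n_pairs, n_dropped_zero_or_missing = n_dropped,
         p_i = p_i, m = m,
         observed_all_same = observed_all_same,
         expected_all_same = expected_all_same,
         observed_atleast_m = observed_atleast_m,
         expected_atleast_m = expected_atleast_m,
         binomial_log10p = c(
           all_same = binom_log10(observed_all_same, expected_all_same),
           atleast_m = binom_log10(observed_atleast_m, expected_atleast_m)
         )),
    class = "concordance_summary"
  )
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("<concordance_summary> k =", x$k, "cohorts,", x$n_pairs, "pairs\n")
  cat(sprintf("  all same sign:      observed %.3f, expected by chance %.4f (log10 p = %.1f)\n",
              x$observed_all_same, x$expected_all_same, x$binomial_log10p["all_same"]))
  cat(sprintf("  same sign in >= %d: observed %.3f, expected by chance %.4f (log10 p = %.1f)\n",
              x$m, x$observed_atleast_m, x$expected_atleast_m,
              x$binomial_log10p["atleast_m"]))
  invisible(x)
}

#' Prune SNPs to a roughly independent set by pairwise r-squared
#'
#' Sliding windows of `window` consecutive position-sorted SNPs, advanced
#' by `step` SNPs; within each window, for every pair of retained SNPs
#' whose genotype correlation satisfies `r^2 > r2_max`, the later SNP (by
#' position, then ID) is removed. Deterministic.
#'
#' @param g a [genotype_matrix()] with SNP columns sorted by position (use
#'   `snp_ann` to have them sorted for you).
#' @param snp_ann optional [snp_annotation()]; when given, columns are
#'   processed in position order.
#' @param window window size in SNPs (default 50).
#' @param r2_max maximum allowed squared correlation (default 0.05).
#' @param step window slide in SNPs (default 5).
#' @return Character vector of retained SNP IDs.
#' @export
ld_prune <- function(g, snp_ann = NULL, window = 50L, r2_max = 0.05, step = 5L) {
  ids <- colnames(g)
  if (!is.null(snp_ann)) {
    ord <- match(ids, snp_ann$snp_id)
    if (anyNA(ord)) stop("annotation is missing SNPs present in the matrix")
    ids <- ids[order(snp_ann$pos[ord], ids, method = "radix")]
    g <- g[, ids, drop = FALSE]
  }
  m <- length(ids)
  keep <- rep(TRUE, m)
  if (m < 2) return(ids)
  starts <- if (m <= window) 1L else unique(c(seq(1L, m - window, by = step), m - window + 1L))
  for (ws in starts) {
    idx <- seq(ws, min(ws + window - 1L, m))
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    r <- suppressWarnings(stats::cor(g[, idx, drop = FALSE],
                                     use = "pairwise.complete.obs"))
    r2 <- r^2
    for (i in seq_along(idx)[-length(idx)]) {
      if (!keep[idx[i]]) next
      for (j in seq((i + 1), length(idx))) {
        if (!keep[idx[j]]) next
        if (!is.na(r2[i, j]) && r2[i, j] > r2_max) keep[idx[j]] <- FALSE
      }
    }
  }
  ids[keep]
}

#' Hierarchically cluster association t-statistics
#'
#' Agglomerative clustering (Euclidean distance, average linkage) of both
#' cohorts (columns) and SNP-CpG pairs (rows); missing t-statistics are
#' set to 0. Intended for matrices restricted to pairs significant in at
#' least one cohort.
#'
#' @param tstats numeric matrix, pairs x cohorts, with >= 2 cohorts.
#' @return A list of class `tstat_clustering`: `cohort_hclust`,
#'   `pair_hclust` (NULL when fewer than 2 rows), `cohort_order`,
#'   `pair_order`.
#' @export
cluster_tstats <- function(tstats) {
  tstats <- as.matrix(tstats)
  if (ncol(tstats) < 2) stop("clustering needs at least 2 cohorts")
  tstats[is.na(tstats)] <- 0
  ch <- stats::hclust(stats::dist(t(tstats)), method = "average")
  ph <- if (nrow(tstats) >= 2) {
    stats::hclust(stats::dist(tstats), method = "average")
  } else NULL
  structure(
    list(cohort_hclust = ch, pair_hclust = ph,
         cohort_order = colnames(tstats)[ch$order],
         pair_order = if (is.null(ph)) seq_len(nrow(tstats)) else ph$order),
    class = "tstat_clustering"
  )
}

#' Subject-partitioned cross-tissue overlap
#'
#' Splits the common subjects of two tissue datasets at random into two
#' non-overlapping halves, scans each tissue in each half, and reports
#' meQTL overlap for same-subject comparisons (tissue 1 vs tissue 2 within
#' a half) and disjoint-subject comparisons (tissue 1 in one half vs
#' tissue 2 in the other, and each tissue against itself across halves).
#' Separates genuine cross-tissue sharing from artifacts of sampling both
#' tissues from the same individuals.
#'
#' @param ds_a,ds_b two [cohort_dataset()]s over a common subject set.
#' @param seed integer seed for the random partition.
#' @param window_bp,min_df,scale,alpha passed to [scan_cohort()].
#' @return data.frame with one row per comparison: the two scans compared,
#'   whether their subject sets overlap, meQTL counts, shared count,
#'   percent overlap in both directions, and Fisher log10 p.
#' @export
partition_overlap <- function(ds_a, ds_b, seed = 1L, window_bp = 50000L,
                              min_df = 10, scale = "beta", alpha = 0.05) {
  subjects <- intersect(rownames(ds_a$methylation$beta), rownames(ds_b$methylation$beta))
  if (length(subjects) < 8) stop("subject partitioning needs at least 8 common subjects")
  set.seed(derive_seed(seed, "partition"))
  perm <- sample(subjects)
  half <- list(A = sort(perm[seq_len(length(perm) %/% 2)]),
               B = sort(perm[(length(perm) %/% 2 + 1):length(perm)]))
  scans <- list()
  for (tissue in c("a", "b")) {
    ds <- if (tissue == "a") ds_a else ds_b
    for (h in c("A", "B")) {
      scans[[paste0(tissue, h)]] <- scan_cohort(
        subset_cohort_samples(ds, half[[h]]),
        window_bp = window_bp, min_df = min_df, scale = scale, alpha = alpha
      )
    }
  }
  comparisons <- list(
    c("aA", "bA", "same_subjects"), c("aB", "bB", "same_subjects"),
    c("aA", "bB", "disjoint_subjects"), c("aB", "bA", "disjoint_subjects"),
    c("aA", "aB", "same_tissue_disjoint"), c("bA", "bB", "same_tissue_disjoint")
  )
  rows <- lapply(comparisons, function(cmp) {
    pair <- restrict_to_common_pairs(scans[cmp[1:2]])
    ot <- overlap_table(pair)
    data.frame(
      scan_i = cmp[1], scan_j = cmp[2], subjects = cmp[3],
      universe = ot$universe_size,
      n_i = ot$meqtl_counts[1], n_j = ot$meqtl_counts[2],
      shared = ot$shared[1, 2],
      pct_of_i = ot$percent[2, 1], pct_of_j = ot$percent[1, 2],
      fisher_log10p = ot$fisher_log10p[1, 2],
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, rows)
}

# restrict a cohort dataset to a subject subset (used by partition_overlap)
subset_cohort_samples <- function(ds, samples) {
  stopifnot(all(samples %in% rownames(ds$genotypes)))
  covs <- ds$covariates
  if (!is.null(covs)) {
    covs <- covs[match(samples, covs$sample_id), , drop = FALSE]
    class(covs) <- c("covariate_table", "data.frame")
  }
  cohort_dataset(
    ds$name, genotype_matrix(ds$genotypes[samples, , drop = FALSE]),
    ds$snp_ann,
    methylation_matrix(ds$methylation$beta[samples, , drop = FALSE],
                       ds$methylation$detection_p[samples, , drop = FALSE],
                       ds$methylation$intensity[samples]),
    ds$cpg_ann, covariates = covs, qc_log = ds$qc_log
  )
}
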