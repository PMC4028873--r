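# Small in-code fixtures shared across test files.

# deterministic tiny genotype matrix (no missing values unless asked)
tiny_genotypes <- function(n = 20, m = 5, seed = 1, missing = 0) {
  set.seed(seed)
  vals <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (missing > 0) vals[sample(length(vals), missing)] <- NA
  genotype_matrix(vals, samples = sprintf("s%02d", seq_len(n)),
                  snps = sprintf("rs%03d", seq_len(m)))
}

tiny_snp_ann <- function(m = 5, pos = seq(1000, by = 10000, length.out = m)) {
  snp_annotation(sprintf("rs%03d", seq_len(m)), "chr1", pos,
                 rep("A", m), rep("G", m))
}

tiny_cpg_ann <- function(m = 3, pos = seq(5000, by = 20000, length.out = m)) {
  cpg_annotation(sprintf("cg%03d", seq_len(m)), "chr1", pos,
                 pos - 25L, pos + 24L)
}

tiny_methylation <- function(n = 20, m = 3, seed = 2, det = 0) {
  set.seed(seed)
  beta <- matrix(runif(n * m, 0.2, 0.8), n, m,
                 dimnames = list(sprintf("s%02d", seq_len(n)),
                                 sprintf("cg%03d", seq_len(m))))
  detp <- matrix(det, n, m, dimnames = dimnames(beta))
  methylation_matrix(beta, detp,
                     setNames(rep(5000, n), rownames(beta)))
}

tiny_cohort <- function(n = 40, seed = 3) {
  g <- tiny_genotypes(n = n, m = 5, seed = seed)
  meth <- tiny_methylation(n = n, m = 3, seed = seed + 1)
  cohort_dataset("toy", g, tiny_snp_ann(5), meth, tiny_cpg_ann(3))
}

# independent OLS slope/t oracle via the normal equations
ols_oracle <- function(y, g, Z = NULL) {
  cc <- stats::complete.cases(cbind(y, g, Z))
  y <- y[cc]; g <- g[cc]
  D <- cbind(1, g)
  if (!is.null(Z)) D <- cbind(D, as.matrix(Z)[cc, , drop = FALSE])
  xtx <- crossprod(D)
  beta <- solve(xtx, crossprod(D, y))
  res <- y - D %*% beta
  df <- length(y) - ncol(D)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(xtx)) * sigma2)
  b2 <- unname(beta[2]); s2 <- unname(se[2])
  list(beta_hat = b2, t = b2 / s2, df = df,
       p = 2 * stats::pt(-abs(b2 / s2), df))
}

# exact HWE p-value by direct enumeration with choose() (independent of
# the lgamma-based implementation)
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  rare <- min(nA, 2 * n - nA)
  if (rare == 0) return(1)
  h <- seq(rare %% 2, rare, by = 2)
  pr <- vapply(h, function(het) {
    naa <- (nA - het) / 2
    2^het * choose(n, het) * choose(n - het, naa) / choose(2 * n, nA)
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, h)]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# hypergeometric upper tail by direct enumeration with choose()
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  x <- a:min(r1, c1)
  sum(choose(r1, x) * choose(N - r1, c1 - x)) / choose(N, c1)
}

# printed overlap counts from a seven-cohort blood/brain meQTL study
# (peripheral blood, two cord-blood cohorts, four brain regions)
published_overlap_counts <- function() {
  cohorts <- c("PB", "CB A", "CB B", "FCTX", "TCTX", "CRBLM", "PONS")
  counts <- setNames(c(724L, 629L, 2055L, 2853L, 3029L, 2802L, 2150L), cohorts)
  shared <- matrix(NA_integer_, 7, 7, dimnames = list(cohorts, cohorts))
  shared["PB", ]    <- c(NA, 319, 366, 254, 234, 185, 203)
  shared["CB A", ]  <- c(319, NA, 437, 205, 196, 165, 211)
  shared["CB B", ]  <- c(366, 437, NA, 650, 649, 517, 587)
  shared["FCTX", ]  <- c(254, 205, 650, NA, 2046, 1078, 1414)
  shared["TCTX", ]  <- c(234, 196, 649, 2046, NA, 1091, 1480)
  shared["CRBLM", ] <- c(185, 165, 517, 1078, 1091, NA, 1004)
  shared["PONS", ]  <- c(203, 211, 587, 1414, 1480, 1004, NA)
  diag(shared) <- 0L
  percent <- matrix(NA_real_, 7, 7, dimnames = list(cohorts, cohorts))
  percent["PB", ]    <- c(NA, 50.7, 17.8, 8.9, 7.7, 6.6, 9.4)
  percent["CB A", ]  <- c(44.1, NA, 21.3, 7.2, 6.5, 5.9, 9.8)
  percent["CB B", ]  <- c(50.6, 69.5, NA, 22.8, 21.4, 18.5, 27.3)
  percent["FCTX", ]  <- c(35.1, 32.6, 31.6, NA, 67.6, 38.5, 65.8)
  percent["TCTX", ]  <- c(33.3, 31.2, 31.6, 71.7, NA, 38.9, 68.9)
  percent["CRBLM", ] <- c(25.6, 26.2, 25.2, 37.8, 36.0, NA, 46.7)
  percent["PONS", ]  <- c(28.0, 33.6, 28.6, 49.6, 48.9, 35.8, NA)
  list(cohorts = cohorts, counts = counts, shared = shared,
       percent_printed = percent, universe = 529224L)
}

# minimal scan-result data.frame used by overlap tests
mock_scan <- function(keys, sig_keys, t = NULL) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(
    snp_id = vapply(parts, `[`, "", 1),
    cpg_id = vapply(parts, `[`, "", 2),
    distance_bp = 0L,
    beta_hat = 0.1, t = if (is.null(t)) 1 else t, df = 40L,
    p = 0.5, p_holm = ifelse(keys %in% sig_keys, 0.01, 1),
    significant = keys %in% sig_keys,
    n_used = 42L, status = "ok", stringsAsFactors = FALSE
  )
}
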