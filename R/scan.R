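#' Enumerate cis SNP-CpG pairs
#'
#' All same-chromosome pairs whose positions differ by at most `window_bp`
#' (inclusive). Output order is deterministic: lexicographic by
#' (`cpg_id`, `snp_id`).
#'
#' @param snp_ann a [snp_annotation()].
#' @param cpg_ann a [cpg_annotation()].
#' @param window_bp cis window in bp (default 50,000).
#' @return data.frame with `snp_id`, `cpg_id`, `distance_bp`.
#' @export
build_cis_pairs <- function(snp_ann, cpg_ann, window_bp = 50000L) {
  out <- vector("list", nrow(cpg_ann))
  for (ch in unique(cpg_ann$chrom)) {
    si <- which(snp_ann$chrom == ch)
    if (!length(si)) next
    ord <- si[order(snp_ann$pos[si])]
    spos <- snp_ann$pos[ord]
    for (i in which(cpg_ann$chrom == ch)) {
      lo <- findInterval(cpg_ann$pos[i] - window_bp - 1L, spos) + 1L
      hi <- findInterval(cpg_ann$pos[i] + window_bp, spos)
      if (hi < lo) next
      hits <- ord[lo:hi]
      out[[i]] <- data.frame(
        snp_id = snp_ann$snp_id[hits],
        cpg_id = cpg_ann$cpg_id[i],
        distance_bp = abs(snp_ann$pos[hits] - cpg_ann$pos[i]),
        stringsAsFactors = FALSE
      )
    }
  }
  pairs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(pairs)) {
    return(data.frame(snp_id = character(), cpg_id = character(),
                      distance_bp = integer(), stringsAsFactors = FALSE))
  }
  pairs <- pairs[order(pairs$cpg_id, pairs$snp_id, method = "radix"), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Logit (base-2) transform of beta-values
#'
#' `M = log2(beta / (1 - beta))` after clamping beta to
#' `[1e-6, 1 - 1e-6]`, so boundary values stay finite.
#'
#' @param beta beta-values in `[0, 1]` (vector or matrix).
#' @return M-values.
#' @export
beta_to_m <- function(beta) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) stop("beta-values must lie in [0, 1]")
  b <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  log2(b / (1 - b))
}

#' Holm (step-down Bonferroni) adjustment
#'
#' @param pvalues numeric p-values in `[0, 1]` (no missing values).
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(pvalues, method = "holm")
}

#' Test one SNP-CpG pair by linear regression
#'
#' Ordinary least squares of the methylation response on an intercept, the
#' REF-allele count, and any covariate columns, using complete cases only.
#' Pairs whose residual degrees of freedom would fall below `min_df` are
#' returned as filtered-out markers rather than tests, as are pairs that
#' are monomorphic among complete cases. Covariate columns that are
#' constant among complete cases are dropped (they change neither the
#' slope nor the residual df); exactly collinear covariates are an error.
#' A constant response yields `beta_hat = 0, t = 0, p = 1` by the 0/0 -> 0
#' convention.
#'
#' @param beta_values per-sample methylation values (proportions).
#' @param alleles per-sample REF-allele counts (0/1/2, `NA` allowed).
#' @param covariates optional numeric matrix of covariates (same samples).
#' @param min_df minimum residual degrees of freedom (default 30).
#' @param scale `"beta"` fits proportions directly; `"mvalue"` transforms
#'   the response with [beta_to_m()] first.
#' @return A list: `status` (`"ok"`, `"low_df"`, or `"monomorphic"`),
#'   `beta_hat`, `t`, `df`, `p`, `n_used`.
#' @export
fit_pair <- function(beta_values, alleles, covariates = NULL, min_df = 30,
                     scale = c("beta", "mvalue")) {
  scale <- match.arg(scale)
  y <- as.numeric(beta_values)
  g <- as.numeric(alleles)
  if (length(y) != length(g)) stop("response and allele vectors differ in length")
  Z <- covariates
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (nrow(Z) != length(y)) stop("covariate rows must match the sample count")
  }
  cc <- !is.na(y) & !is.na(g)
  if (!is.null(Z)) cc <- cc & !apply(is.na(Z), 1, any)
  n_used <- sum(cc)
  filtered <- function(status) list(status = status, beta_hat = NA_real_,
                                    t = NA_real_, df = NA_integer_,
                                    p = NA_real_, n_used = n_used)
  y <- y[cc]; g <- g[cc]
  if (!is.null(Z)) {
    Z <- Z[cc, , drop = FALSE]
    keep <- apply(Z, 2, function(z) stats::var(z) > 0)
    Z <- Z[, keep, drop = FALSE]
    if (!ncol(Z)) Z <- NULL
  }
  df <- n_used - (2L + if (is.null(Z)) 0L else ncol(Z))
  if (df < min_df) return(filtered("low_df"))
  if (n_used < 3 || stats::var(g) == 0) return(filtered("monomorphic"))
  if (scale == "mvalue") y <- beta_to_m(y)
  if (stats::var(y) == 0) {
    # constant response: slope and residual SE are both 0; 0/0 -> 0 convention
    return(list(status = "ok", beta_hat = 0, t = 0, df = as.integer(df),
                p = 1, n_used = n_used))
  }

  D <- cbind(1, g, Z)
  fit <- .lm.fit(D, y)
  if (fit$rank < ncol(D)) stop("covariates are exactly collinear with the model")
  coefs <- numeric(ncol(D))
  coefs[fit$pivot] <- fit$coefficients
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  R <- qr.R(structure(list(qr = fit$qr, qraux = fit$qraux, rank = fit$rank),
                      class = "qr"))
  xtx_inv <- chol2inv(R)
  var_diag <- numeric(ncol(D))
  var_diag[fit$pivot] <- diag(xtx_inv)
  beta_hat <- coefs[2]
  se <- sqrt(sigma2 * var_diag[2])
  if (se == 0) {
    if (beta_hat == 0) {
      tval <- 0; p <- 1  # constant response: 0/0 -> 0 convention
    } else {
      tval <- sign(beta_hat) * Inf; p <- 0
    }
  } else {
    tval <- beta_hat / se
    p <- 2 * stats::pt(-abs(tval), df)
  }
  list(status = "ok", beta_hat = beta_hat, t = tval, df = as.integer(df),
       p = p, n_used = n_used)
}

#' Scan a cohort for cis meQTLs
#'
#' Fits every cis pair with [fit_pair()] and Holm-adjusts the p-values over
#' exactly the set of pairs that produced a test (pairs filtered out by the
#' df rule or monomorphism do not count toward the correction). A pair is
#' flagged significant when its Holm-adjusted p is below `alpha`.
#'
#' @param ds a QC'd [cohort_dataset()].
#' @param window_bp cis window in bp.
#' @param min_df minimum residual degrees of freedom.
#' @param scale response scale, `"beta"` or `"mvalue"`.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with one row per cis pair: `snp_id`, `cpg_id`,
#'   `distance_bp`, `beta_hat`, `t`, `df`, `p`, `p_holm`, `significant`,
#'   `n_used`, `status`. Untested pairs carry their filter reason in
#'   `status` and `NA` statistics.
#' @export
scan_cohort <- function(ds, window_bp = 50000L, min_df = 30, scale = c("beta", "mvalue"),
                        alpha = 0.05) {
  scale <- match.arg(scale)
  stopifnot(inherits(ds, "cohort_dataset"))
  pairs <- build_cis_pairs(ds$snp_ann, ds$cpg_ann, window_bp)
  if (!nrow(pairs)) stop("no cis pairs within ", window_bp, " bp in cohort ", ds$name)
  samples <- rownames(ds$methylation$beta)
  G <- ds$genotypes[samples, , drop = FALSE]
  B <- ds$methylation$beta
  Z <- covariate_design(ds$covariates, samples)
  si <- match(pairs$snp_id, colnames(G))
  ci <- match(pairs$cpg_id, colnames(B))

  n <- nrow(pairs)
  beta_hat <- tval <- p <- rep(NA_real_, n)
  df <- n_used <- rep(NA_integer_, n)
  status <- character(n)
  for (k in seq_len(n)) {
    f <- fit_pair(B[, ci[k]], G[, si[k]], covariates = Z,
                  min_df = min_df, scale = scale)
    status[k] <- f$status
    n_used[k] <- f$n_used
    if (f$status == "ok") {
      beta_hat[k] <- f$beta_hat; tval[k] <- f$t
      df[k] <- f$df; p[k] <- f$p
    }
  }
  ok <- status == "ok"
  if (!any(ok)) stop("no testable pairs in cohort ", ds$name)
  p_holm <- rep(NA_real_, n)
  p_holm[ok] <- holm_adjust(p[ok])
  res <- data.frame(
    snp_id = pairs$snp_id, cpg_id = pairs$cpg_id,
    distance_bp = pairs$distance_bp,
    beta_hat = beta_hat, t = tval, df = df, p = p, p_holm = p_holm,
    significant = !is.na(p_holm) & p_holm < alpha,
    n_used = n_used, status = status, stringsAsFactors = FALSE
  )
  attr(res, "cohort") <- ds$name
  attr(res, "scale") <- scale
  res
}
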