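#' Bin SNPs by minor allele frequency
#'
#' Bin index is `floor(MAF / width)` (0-based), so with the default width
#' of 0.025 a MAF of 0.05 falls in bin 2, interval `[0.05, 0.075)`. A MAF
#' of exactly 0.5 is assigned to the top bin.
#'
#' @param maf named numeric vector of MAFs in `(0, 0.5]` (names = SNP IDs).
#' @param width bin width (default 0.025).
#' @return Named list mapping bin index (as character) to SNP IDs.
#' @export
bin_by_maf <- function(maf, width = 0.025) {
  if (is.null(names(maf))) stop("maf must be named by SNP ID")
  if (any(is.na(maf) | maf <= 0 | maf > 0.5)) stop("MAF values must lie in (0, 0.5]")
  top <- ceiling(0.5 / width) - 1L
  bin <- pmin(floor(maf / width + 1e-9), top)
  split(names(maf), bin)
}

#' Draw a MAF-matched random SNP set
#'
#' Samples, without replacement and independently within each MAF bin,
#' exactly as many SNPs from the universe as the meQTL set contains in
#' that bin. The meQTL SNPs themselves remain part of the sampling
#' universe. Uses R's RNG stream; seed via `set.seed()` upstream.
#'
#' @param meqtls character vector of meQTL SNP IDs (subset of the universe
#'   unless `meqtl_maf` supplies their MAFs directly).
#' @param universe named numeric vector of MAFs over all analyzed SNPs.
#' @param width MAF bin width (default 0.025).
#' @param meqtl_maf optional named MAF vector for the meQTL set itself;
#'   defaults to looking the meQTLs up in `universe`.
#' @return Character vector of sampled SNP IDs, `length(meqtls)` of them,
#'   with per-bin counts matching the meQTL set exactly.
#' @export
sample_matched_set <- function(meqtls, universe, width = 0.025,
                               meqtl_maf = NULL) {
  if (is.null(meqtl_maf)) {
    if (!all(meqtls %in% names(universe))) {
      stop("meQTL SNPs missing from the universe: ",
           paste(utils::head(setdiff(meqtls, names(universe))), collapse = ", "))
    }
    meqtl_maf <- universe[meqtls]
  } else if (!all(meqtls %in% names(meqtl_maf))) {
    stop("meqtl_maf does not cover every meQTL SNP")
  }
  bins_univ <- bin_by_maf(universe, width)
  counts <- table(names(bin_to_index(meqtl_maf[meqtls], width)))
  out <- character(0)
  for (b in names(counts)) {
    avail <- bins_univ[[b]]
    nb <- counts[[b]]
    if (is.null(avail) || length(avail) < nb) {
      stop("insufficient SNPs in MAF bin ", b, ": need ", nb,
           ", have ", length(avail))
    }
    out <- c(out, avail[sample.int(length(avail), nb)])
  }
  out
}

bin_to_index <- function(maf, width = 0.025) {
  top <- ceiling(0.5 / width) - 1L
  stats::setNames(names(maf), pmin(floor(maf / width + 1e-9), top))
}

#' MAF-matched empirical enrichment test
#'
#' Tests whether a set of meQTL SNPs overlaps a target SNP set (GWAS top
#' hits, miRNA binding-site SNPs, published meQTL/eQTL lists) more than
#' expected by chance. The null distribution is built by repeatedly
#' drawing MAF-matched random sets of the same size from the analyzed
#' universe; the empirical p-value is the proportion of random sets whose
#' overlap with the target is at least the observed overlap. With zero
#' exceedances the result is reported as the bound `p < 1/n_resamples`; a
#' `(x + 1) / (n + 1)` corrected value is also returned for downstream
#' use.
#'
#' @param meqtls character meQTL SNP IDs (must be in the universe).
#' @param target character target SNP IDs; overlap is computed against
#'   `target` intersected with the universe.
#' @param universe named numeric MAF vector over all analyzed SNPs.
#' @param n_resamples number of random sets (default 10,000; 1,000 is
#'   typical for small target panels).
#' @param seed optional integer seed.
#' @param width MAF bin width (default 0.025).
#' @return A list of class `enrichment_result`.
#' @export
enrichment_test <- function(meqtls, target, universe, n_resamples = 10000L,
                            seed = NULL, width = 0.025) {
  if (n_resamples < 1) stop("n_resamples must be at least 1")
  if (!all(meqtls %in% names(universe))) stop("meqtls must be a subset of the universe")
  if (!is.null(seed)) set.seed(seed)
  target <- intersect(target, names(universe))
  observed <- length(intersect(meqtls, target))

  # pre-index each bin once; a resample is then one sample.int per bin
  bins_univ <- bin_by_maf(universe, width)
  is_target <- lapply(bins_univ, function(ids) ids %in% target)
  need <- table(names(bin_to_index(universe[meqtls], width)))
  bins <- names(need)
  sizes <- lengths(bins_univ)[bins]
  nulls <- integer(n_resamples)
  for (r in seq_len(n_resamples)) {
    tot <- 0L
    for (i in seq_along(bins)) {
      tot <- tot + sum(is_target[[bins[i]]][sample.int(sizes[i], need[[i]])])
    }
    nulls[r] <- tot
  }
  exceed <- sum(nulls >= observed)
  empirical_p <- exceed / n_resamples
  structure(
    list(observed_overlap = observed, n_meqtls = length(meqtls),
         n_target_in_universe = length(target), n_resamples = n_resamples,
         null_mean = mean(nulls), null_sd = stats::sd(nulls),
         null_max = max(nulls),
         empirical_p = empirical_p,
         empirical_p_corrected = (exceed + 1) / (n_resamples + 1),
         reported_as = if (exceed == 0) {
           sprintf("p < %.4g", 1 / n_resamples)
         } else {
           sprintf("p = %.4g", empirical_p)
         }),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result>\n")
  cat(sprintf("  observed overlap: %d of %d meQTLs (target in universe: %d)\n",
              x$observed_overlap, x$n_meqtls, x$n_target_in_universe))
  cat(sprintf("  MAF-matched null (%d draws): mean %.2f, SD %.2f, max %d\n",
              x$n_resamples, x$null_mean, x$null_sd, x$null_max))
  cat("  ", x$reported_as, "\n", sep = "")
  invisible(x)
}
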