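#' Construct a SNP annotation table
#'
#' One row per SNP with 1-based forward-strand coordinates and REF/ALT
#' alleles. Dosages throughout the package count REF alleles (0, 1, 2).
#'
#' @param snp_id character, unique SNP identifiers (e.g. rsIDs).
#' @param chrom character chromosome names.
#' @param pos integer 1-based positions (bp).
#' @param ref_allele,alt_allele single-character alleles in A/C/G/T.
#' @return A `data.frame` of class `snp_annotation`.
#' @export
snp_annotation <- function(snp_id, chrom, pos, ref_allele, alt_allele) {
  ann <- data.frame(
    snp_id = as.character(snp_id), chrom = as.character(chrom),
    pos = as.integer(pos), ref_allele = as.character(ref_allele),
    alt_allele = as.character(alt_allele), stringsAsFactors = FALSE
  )
  validate_snp_annotation(ann)
  class(ann) <- c("snp_annotation", "data.frame")
  ann
}

validate_snp_annotation <- function(ann) {
  stopifnot(all(c("snp_id", "chrom", "pos", "ref_allele", "alt_allele") %in% names(ann)))
  if (anyDuplicated(ann$snp_id)) {
    stop("duplicate snp_id in annotation: ",
         paste(unique(ann$snp_id[duplicated(ann$snp_id)]), collapse = ", "))
  }
  if (any(ann$pos < 1L)) stop("SNP positions must be >= 1 (1-based)")
  ok <- grepl("^[ACGT]+$", ann$ref_allele) & grepl("^[ACGT]+$", ann$alt_allele)
  if (!all(ok)) stop("alleles must be non-empty strings over {A,C,G,T}")
  invisible(ann)
}

#' Construct a CpG probe annotation table
#'
#' One row per CpG with the interrogated position and the probe's genomic
#' footprint (1-based, inclusive on both ends). The probe interval is what
#' the probe-SNP exclusion filter screens against.
#'
#' @param cpg_id character, unique CpG identifiers.
#' @param chrom character chromosome names.
#' @param pos integer 1-based CpG positions (bp).
#' @param probe_start,probe_end integer probe interval, must contain `pos`.
#' @return A `data.frame` of class `cpg_annotation`.
#' @export
cpg_annotation <- function(cpg_id, chrom, pos, probe_start, probe_end) {
  ann <- data.frame(
    cpg_id = as.character(cpg_id), chrom = as.character(chrom),
    pos = as.integer(pos), probe_start = as.integer(probe_start),
    probe_end = as.integer(probe_end), stringsAsFactors = FALSE
  )
  validate_cpg_annotation(ann)
  class(ann) <- c("cpg_annotation", "data.frame")
  ann
}

validate_cpg_annotation <- function(ann) {
  stopifnot(all(c("cpg_id", "chrom", "pos", "probe_start", "probe_end") %in% names(ann)))
  if (anyDuplicated(ann$cpg_id)) stop("duplicate cpg_id in annotation")
  if (any(ann$probe_end < ann$probe_start)) stop("probe_end must be >= probe_start")
  if (any(ann$pos < ann$probe_start | ann$pos > ann$probe_end)) {
    stop("probe interval must contain the CpG position")
  }
  invisible(ann)
}

#' Construct a genotype matrix
#'
#' Allele counts are the number of REF alleles per the SNP annotation, so a
#' sample homozygous for REF carries 2. Missing calls are `NA`; downstream
#' association tests are complete-case per SNP-CpG pair.
#'
#' @param values numeric matrix, samples in rows, SNPs in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param samples,snps row/column identifiers.
#' @return An integer matrix of class `genotype_matrix` with dimnames.
#' @export
genotype_matrix <- function(values, samples = rownames(values), snps = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(samples) || is.null(snps)) stop("sample and SNP IDs are required")
  if (nrow(values) != length(samples) || ncol(values) != length(snps)) {
    stop("genotype matrix dimensions do not match ID lists")
  }
  bad <- !(values %in% c(0, 1, 2) | is.na(values))
  if (any(bad)) stop("genotype values must be in {0, 1, 2} or missing")
  storage.mode(values) <- "integer"
  dimnames(values) <- list(as.character(samples), as.character(snps))
  class(values) <- c("genotype_matrix", class(matrix()))
  values
}

#' Construct a methylation matrix
#'
#' Beta-values are methylated/(methylated + unmethylated) signal in `[0, 1]`.
#' Detection p-values carry the array's per-data-point quality statistic;
#' values above the QC threshold are later masked to missing. `intensity` is
#' the per-sample mean total signal used by the intensity QC rules.
#'
#' @param beta numeric matrix, samples x CpGs, in `[0, 1]` or `NA`.
#' @param detection_p numeric matrix, same shape, in `[0, 1]` or `NA`.
#' @param intensity named numeric vector, one mean total signal per sample.
#' @return A list of class `methylation_matrix`.
#' @export
methylation_matrix <- function(beta, detection_p = NULL, intensity = NULL) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("beta matrix requires sample rownames and CpG colnames")
  }
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) stop("beta-values must lie in [0, 1]")
  if (is.null(detection_p)) {
    detection_p <- matrix(0, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  }
  detection_p <- as.matrix(detection_p)
  if (!identical(dim(detection_p), dim(beta))) stop("detection_p shape must match beta")
  if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE)) {
    stop("detection p-values must lie in [0, 1]")
  }
  dimnames(detection_p) <- dimnames(beta)
  if (is.null(intensity)) {
    intensity <- stats::setNames(rep(NA_real_, nrow(beta)), rownames(beta))
  }
  if (is.null(names(intensity))) names(intensity) <- rownames(beta)
  if (!setequal(names(intensity), rownames(beta))) {
    stop("intensity must be named by the beta matrix samples")
  }
  structure(
    list(beta = beta, detection_p = detection_p,
         intensity = intensity[rownames(beta)]),
    class = "methylation_matrix"
  )
}

#' Construct a covariate table
#'
#' Numeric design columns (e.g. batch indicator coding) entered alongside
#' the allele count in every association model. Categorical batches should
#' be pre-expanded to 0/1 indicator columns.
#'
#' @param sample_id character sample identifiers.
#' @param ... named numeric vectors, one per covariate.
#' @return A `data.frame` of class `covariate_table`.
#' @export
covariate_table <- function(sample_id, ...) {
  covs <- list(...)
  if (length(covs) && (is.null(names(covs)) || any(names(covs) == ""))) {
    stop("covariate columns must be named")
  }
  tab <- data.frame(sample_id = as.character(sample_id), stringsAsFactors = FALSE)
  for (nm in names(covs)) {
    v <- covs[[nm]]
    if (!is.numeric(v)) stop("covariate '", nm, "' must be numeric")
    if (length(v) != nrow(tab)) stop("covariate '", nm, "' length mismatch")
    tab[[nm]] <- v
  }
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in covariate table")
  class(tab) <- c("covariate_table", "data.frame")
  tab
}

#' Assemble one cohort's dataset
#'
#' Binds genotypes, methylation, annotations, and covariates for a cohort
#' and enforces ID consistency between all components. The `qc_log` records
#' every exclusion applied so input and output counts reconcile.
#'
#' @param name cohort label.
#' @param genotypes a [genotype_matrix()].
#' @param snp_ann a [snp_annotation()] covering the genotype columns.
#' @param methylation a [methylation_matrix()].
#' @param cpg_ann a [cpg_annotation()] covering the beta columns.
#' @param covariates a [covariate_table()] over the same samples, or `NULL`.
#' @param qc_log a data.frame of applied-filter records (may be empty).
#' @return A list of class `cohort_dataset`.
#' @export
cohort_dataset <- function(name, genotypes, snp_ann, methylation, cpg_ann,
                           covariates = NULL, qc_log = empty_qc_log()) {
  if (!inherits(methylation, "methylation_matrix")) stop("methylation must be a methylation_matrix")
  samples_g <- rownames(genotypes)
  samples_m <- rownames(methylation$beta)
  if (!setequal(samples_g, samples_m)) {
    stop("cohort '", name, "': genotype and methylation sample sets differ")
  }
  if (!setequal(colnames(genotypes), snp_ann$snp_id)) {
    stop("cohort '", name, "': genotype columns and SNP annotation differ")
  }
  if (!setequal(colnames(methylation$beta), cpg_ann$cpg_id)) {
    stop("cohort '", name, "': methylation columns and CpG annotation differ")
  }
  if (!is.null(covariates) && !setequal(covariates$sample_id, samples_g)) {
    stop("cohort '", name, "': covariate samples and cohort samples differ")
  }
  structure(
    list(name = name, genotypes = genotypes, snp_ann = snp_ann,
         methylation = methylation, cpg_ann = cpg_ann,
         covariates = covariates, qc_log = qc_log),
    class = "cohort_dataset"
  )
}

empty_qc_log <- function() {
  data.frame(stage = character(), item_type = character(),
             item_id = character(), reason = character(),
             stringsAsFactors = FALSE)
}

qc_log_record <- function(stage, item_type, item_id, reason) {
  if (!length(item_id)) return(empty_qc_log())
  data.frame(stage = stage, item_type = item_type,
             item_id = as.character(item_id), reason = reason,
             stringsAsFactors = FALSE)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset> ", x$name, "\n", sep = "")
  cat("  samples:  ", nrow(x$genotypes), "\n", sep = "")
  cat("  SNPs:     ", ncol(x$genotypes), "\n", sep = "")
  cat("  CpGs:     ", ncol(x$methylation$beta), "\n", sep = "")
  ncov <- if (is.null(x$covariates)) 0L else ncol(x$covariates) - 1L
  cat("  covariates: ", ncov, "; QC exclusions logged: ", nrow(x$qc_log), "\n", sep = "")
  invisible(x)
}

# covariate design matrix (samples x covariates) aligned to given sample order
covariate_design <- function(covariates, samples) {
  if (is.null(covariates) || ncol(covariates) <= 1L) return(NULL)
  idx <- match(samples, covariates$sample_id)
  if (anyNA(idx)) stop("covariate table is missing samples: ",
                       paste(samples[is.na(idx)], collapse = ", "))
  m <- as.matrix(covariates[idx, setdiff(names(covariates), "sample_id"), drop = FALSE])
  rownames(m) <- samples
  m
}
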