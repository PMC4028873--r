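#' Read a genotype matrix and SNP annotation
#'
#' Supports VCF 4.x (GT genotypes only, parsed with \pkg{vcfR}) and a
#' tabular dosage format with one row per SNP (`snp_id`, `chrom`, `pos`,
#' `ref_allele`, `alt_allele`, then one column per sample holding REF-allele
#' counts). For VCF, the REF-allele count of a call is `2 - (# ALT alleles
#' in GT)`, so `0/0 -> 2`, `0/1 -> 1`, `1/1 -> 0`; `./.` stays missing.
#'
#' @param path input file.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return A list with elements `genotypes` ([genotype_matrix()]) and
#'   `snp_ann` ([snp_annotation()]).
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_dosage(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  if (anyDuplicated(ids)) stop("duplicate snp_id in VCF: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  counts <- matrix(vapply(gt, gt_to_ref_count, integer(1)),
                   nrow = nrow(gt), dimnames = dimnames(gt))
  ann <- snp_annotation(ids, fix[, "CHROM"], as.integer(fix[, "POS"]),
                        fix[, "REF"], fix[, "ALT"])
  list(genotypes = genotype_matrix(t(counts), samples = colnames(gt), snps = ids),
       snp_ann = ann)
}

gt_to_ref_count <- function(gt) {
  if (is.na(gt) || gt %in% c("./.", ".|.", ".")) return(NA_integer_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (length(alleles) != 2L || !all(alleles %in% c("0", "1"))) {
    stop("malformed GT value: '", gt, "'")
  }
  2L - sum(alleles == "1")
}

read_genotypes_dosage <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  ann_cols <- c("snp_id", "chrom", "pos", "ref_allele", "alt_allele")
  if (!all(ann_cols %in% names(tab))) {
    stop("dosage TSV must start with columns: ", paste(ann_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$snp_id)) stop("duplicate snp_id in dosage file")
  samples <- setdiff(names(tab), ann_cols)
  if (!length(samples)) stop("dosage TSV has no sample columns")
  vals <- t(as.matrix(tab[, samples, drop = FALSE]))
  ann <- snp_annotation(tab$snp_id, tab$chrom, tab$pos, tab$ref_allele, tab$alt_allele)
  list(genotypes = genotype_matrix(vals, samples = samples, snps = tab$snp_id),
       snp_ann = ann)
}

#' Write genotypes to VCF or dosage TSV
#'
#' The VCF writer emits a minimal plain-text VCF 4.2 with GT-only genotype
#' fields; REF-allele counts are translated back so that
#' `read_genotypes()` round-trips the matrix exactly.
#'
#' @param genotypes a [genotype_matrix()].
#' @param snp_ann the matching [snp_annotation()].
#' @param path output file.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @export
write_genotypes <- function(genotypes, snp_ann, path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  idx <- match(colnames(genotypes), snp_ann$snp_id)
  if (anyNA(idx)) stop("annotation is missing SNPs present in the matrix")
  ann <- snp_ann[idx, , drop = FALSE]
  if (format == "dosage_tsv") {
    out <- data.frame(ann[, c("snp_id", "chrom", "pos", "ref_allele", "alt_allele")],
                      t(unclass(genotypes)), check.names = FALSE,
                      stringsAsFactors = FALSE)
    data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
    return(invisible(path))
  }
  gt_code <- c(`2` = "0/0", `1` = "0/1", `0` = "1/1")
  body <- vapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(ann$chrom[j], ann$pos[j], ann$snp_id[j], ann$ref_allele[j],
            ann$alt_allele[j], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a methylation matrix and CpG annotation
#'
#' Tabular format with one row per CpG: `cpg_id`, `chrom`, `pos`,
#' `probe_start`, `probe_end`, then paired `beta.<sample>` and
#' `det.<sample>` columns. Per-sample mean total intensities are carried in
#' `##intensity <sample> <value>` header lines.
#'
#' @param path input file written by [write_methylation()].
#' @return A list with elements `methylation` ([methylation_matrix()]) and
#'   `cpg_ann` ([cpg_annotation()]).
#' @export
read_methylation <- function(path) {
  if (!file.exists(path)) stop("methylation file not found: ", path)
  lines <- readLines(path)
  meta <- grep("^##", lines)
  intensity <- NULL
  if (length(meta)) {
    fields <- strsplit(sub("^##", "", lines[meta]), "\t", fixed = TRUE)
    ok <- vapply(fields, function(f) length(f) == 3L && f[1] == "intensity", logical(1))
    if (!all(ok)) stop("unrecognized metadata line in methylation file")
    intensity <- stats::setNames(as.numeric(vapply(fields, `[`, "", 3)),
                                 vapply(fields, `[`, "", 2))
  }
  tab <- data.table::fread(text = lines[setdiff(seq_along(lines), meta)],
                           sep = "\t", header = TRUE, data.table = FALSE)
  ann_cols <- c("cpg_id", "chrom", "pos", "probe_start", "probe_end")
  if (!all(ann_cols %in% names(tab))) {
    stop("methylation TSV must start with columns: ", paste(ann_cols, collapse = ", "))
  }
  rest <- setdiff(names(tab), ann_cols)
  is_beta <- grepl("^beta\\.", rest)
  is_det <- grepl("^det\\.", rest)
  if (any(!is_beta & !is_det)) {
    stop("unknown column(s) in methylation file: ",
         paste(rest[!is_beta & !is_det], collapse = ", "))
  }
  samples <- sub("^beta\\.", "", rest[is_beta])
  if (!setequal(samples, sub("^det\\.", "", rest[is_det]))) {
    stop("beta.* and det.* sample sets differ")
  }
  beta <- t(as.matrix(tab[, paste0("beta.", samples), drop = FALSE]))
  det <- t(as.matrix(tab[, paste0("det.", samples), drop = FALSE]))
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) stop("beta-value outside [0, 1]")
  rownames(beta) <- rownames(det) <- samples
  colnames(beta) <- colnames(det) <- tab$cpg_id
  ann <- cpg_annotation(tab$cpg_id, tab$chrom, tab$pos, tab$probe_start, tab$probe_end)
  list(methylation = methylation_matrix(beta, det, intensity), cpg_ann = ann)
}

#' Write a methylation matrix with its annotation
#'
#' @param methylation a [methylation_matrix()].
#' @param cpg_ann the matching [cpg_annotation()].
#' @param path output file.
#' @export
write_methylation <- function(methylation, cpg_ann, path) {
  idx <- match(colnames(methylation$beta), cpg_ann$cpg_id)
  if (anyNA(idx)) stop("annotation is missing CpGs present in the matrix")
  ann <- cpg_ann[idx, , drop = FALSE]
  samples <- rownames(methylation$beta)
  beta <- t(methylation$beta)
  det <- t(methylation$detection_p)
  colnames(beta) <- paste0("beta.", samples)
  colnames(det) <- paste0("det.", samples)
  out <- data.frame(ann[, c("cpg_id", "chrom", "pos", "probe_start", "probe_end")],
                    fmt10(beta), fmt10(det), check.names = FALSE,
                    stringsAsFactors = FALSE)
  inten <- methylation$intensity
  writeLines(sprintf("##intensity\t%s\t%s", names(inten), fmt10(inten)), path)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA",
                     append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Write meQTL scan results to TSV
#'
#' Rows are sorted lexicographically by (`snp_id`, `cpg_id`) so output is
#' deterministic regardless of input order; all floats are serialized with
#' 10 significant digits.
#'
#' @param results a data.frame of scan results (see [scan_cohort()]); only
#'   tested pairs (status `"ok"`) are written.
#' @param path output file.
#' @export
write_results <- function(results, path) {
  cols <- c("snp_id", "cpg_id", "distance_bp", "beta_hat", "t", "df", "p",
            "p_holm", "significant")
  if (!is.null(results$status)) results <- results[results$status == "ok", , drop = FALSE]
  if (!all(cols %in% names(results))) {
    stop("results must contain columns: ", paste(cols, collapse = ", "))
  }
  results <- results[order(results$snp_id, results$cpg_id, method = "radix"),
                     cols, drop = FALSE]
  out <- results
  for (nm in c("beta_hat", "t", "p", "p_holm")) out[[nm]] <- fmt10(results[[nm]])
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a results TSV written by [write_results()]
#' @param path input file.
#' @return data.frame of results.
#' @export
read_results <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                    colClasses = list(character = c("snp_id", "cpg_id")))
}

#' Read a plain-text SNP ID list (one ID per line)
#' @param path input file; blank lines and `#` comments are skipped.
#' @return character vector of SNP IDs.
#' @export
read_snp_set <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

# 10-significant-digit serialization used by all writers
fmt10 <- function(x) {
  if (is.matrix(x)) {
    structure(apply(x, 2, fmt10), dim = dim(x), dimnames = dimnames(x))
  } else {
    ifelse(is.na(x), NA_character_, sprintf("%.10g", x))
  }
}
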