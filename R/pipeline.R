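#' Assemble a pipeline run configuration
#'
#' One object drives the full simulate -> QC -> scan -> overlap ->
#' concordance -> enrichment pipeline. A single global seed
#' deterministically derives per-stage seeds (via an internal hash of
#' `seed` and the stage name), so stages can be rerun independently with
#' identical results.
#'
#' @param sim a [sim_config()]; its seed is overridden by the derived
#'   simulate-stage seed.
#' @param qc a [qc_thresholds()].
#' @param window_bp cis window in bp.
#' @param min_df minimum residual degrees of freedom per test.
#' @param scale `"beta"` or `"mvalue"` response scale.
#' @param alpha family-wise significance level.
#' @param concordance_m "at least m cohorts" threshold for the sign
#'   concordance summary (default: all but one cohort).
#' @param enrichment list with `n_resamples` and optional `target` (a
#'   plain-text SNP ID file, one per line). Without a target file the
#'   planted truth SNPs are used, turning the stage into a recovery check.
#' @param seed global integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), qc = qc_thresholds(),
                       window_bp = 50000L, min_df = 30,
                       scale = c("beta", "mvalue"), alpha = 0.05,
                       concordance_m = sim$n_cohorts - 1L,
                       enrichment = list(n_resamples = 1000L, target = NULL),
                       seed = 1L) {
  scale <- match.arg(scale)
  stopifnot(inherits(sim, "sim_config"), inherits(qc, "qc_thresholds"),
            window_bp > 0, min_df >= 0, alpha > 0, alpha < 1,
            concordance_m >= 1, concordance_m <= sim$n_cohorts,
            is.numeric(seed), length(seed) == 1)
  if (is.null(enrichment$n_resamples)) enrichment$n_resamples <- 1000L
  structure(
    list(sim = sim, qc = qc, window_bp = as.integer(window_bp),
         min_df = min_df, scale = scale, alpha = alpha,
         concordance_m = as.integer(concordance_m),
         enrichment = enrichment, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `seed`, `window_bp`, `min_df`, `scale`,
#' `alpha`, `concordance_m`, and the sections `sim:`, `qc:`, and
#' `enrichment:` whose entries are passed to [sim_config()],
#' [qc_thresholds()], and the enrichment stage respectively. Unknown keys
#' are an error so typos do not silently fall back to defaults.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("sim", "qc", "enrichment", "seed", "window_bp", "min_df",
             "scale", "alpha", "concordance_m")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- raw[setdiff(names(raw), c("sim", "qc", "enrichment"))]
  if (!is.null(raw$sim)) {
    sim_args <- raw$sim
    for (nm in c("effect_sharing")) {
      if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- do.call(rbind, sim_args[[nm]])
    }
    args$sim <- do.call(sim_config, sim_args)
  }
  if (!is.null(raw$qc)) args$qc <- do.call(qc_thresholds, raw$qc)
  if (!is.null(raw$enrichment)) args$enrichment <- raw$enrichment
  do.call(run_config, args)
}

#' Write a pipeline configuration to YAML
#' @param cfg a [run_config()].
#' @param path output YAML file.
#' @export
write_run_config <- function(cfg, path) {
  out <- list(
    seed = cfg$seed, window_bp = cfg$window_bp, min_df = cfg$min_df,
    scale = cfg$scale, alpha = cfg$alpha, concordance_m = cfg$concordance_m,
    sim = unclass(cfg$sim), qc = unclass(cfg$qc), enrichment = cfg$enrichment
  )
  if (!is.null(out$sim$effect_sharing)) {
    out$sim$effect_sharing <- apply(out$sim$effect_sharing, 1, as.list)
  }
  out$sim <- Filter(Negate(is.null), out$sim)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Render an overlap table as printable "n (pct)" cells
#'
#' Cells are `"SHARED (PCT)"` with the percent to one decimal, rounding
#' half away from zero; the diagonal is `"-"`.
#'
#' @param table an [overlap_table()].
#' @return Character matrix (cohorts x cohorts) with dimnames.
#' @export
render_overlap_report <- function(table) {
  stopifnot(inherits(table, "overlap_table"))
  k <- length(table$cohorts)
  out <- matrix("-", k, k, dimnames = list(table$cohorts, table$cohorts))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      out[i, j] <- sprintf("%d (%s)", table$shared[i, j],
                           fmt_pct1(table$percent[i, j]))
    }
  }
  out
}

# one-decimal percent, rounding half away from zero
fmt_pct1 <- function(x) {
  sprintf("%.1f", sign(x) * floor(abs(x) * 10 + 0.5 + 1e-9) / 10)
}

#' @export
print.overlap_table <- function(x, ...) {
  cat("<overlap_table> universe:", x$universe_size, "SNP-CpG pairs\n")
  rep_mat <- render_overlap_report(x)
  tab <- cbind(`# meQTLs` = as.character(x$meqtl_counts), rep_mat)
  print(tab, quote = FALSE)
  invisible(x)
}

#' Run the full pipeline on a synthetic study
#'
#' Simulates the configured multi-cohort study, applies QC, scans every
#' cohort for cis meQTLs, and computes cross-cohort overlap, sign
#' concordance, and MAF-matched enrichment. All inputs and outputs are
#' written under `out_dir` together with a machine-readable manifest
#' (stage seeds, record counts, file checksums). Any stage error aborts
#' the run naming the stage.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results
#'   (`study`, `qc`, `scans`, `overlap`, `concordance`, `enrichment`,
#'   `manifest`).
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "data"), showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, stages = list())
  run_stage <- function(name, expr) {
    msg_stage <- function(...) message("[", name, "] ", ...)
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    msg_stage("done")
    res
  }

  # 1. simulate
  sim_cfg <- cfg$sim
  sim_cfg$seed <- derive_seed(cfg$seed, "simulate")
  study <- run_stage("simulate", simulate_study(sim_cfg))
  manifest$stages$simulate <- list(seed = sim_cfg$seed,
                                   cohorts = length(study$cohorts),
                                   planted = nrow(study$truth$pairs))
  for (ds in study$cohorts) {
    write_genotypes(ds$genotypes, ds$snp_ann,
                    file.path(out_dir, "data", paste0(ds$name, ".vcf")), "vcf")
    write_methylation(ds$methylation, ds$cpg_ann,
                      file.path(out_dir, "data", paste0(ds$name, ".methylation.tsv")))
  }
  truth_tab <- data.frame(study$truth$pairs, study$truth$sharing,
                          check.names = FALSE)
  data.table::fwrite(truth_tab, file.path(out_dir, "data", "truth.tsv"), sep = "\t")

  # 2. qc
  qcd <- run_stage("qc", lapply(study$cohorts, apply_qc, thr = cfg$qc))
  qc_log <- do.call(rbind, lapply(qcd, function(ds) {
    if (!nrow(ds$qc_log)) return(NULL)
    data.frame(cohort = ds$name, ds$qc_log, stringsAsFactors = FALSE)
  }))
  if (is.null(qc_log)) qc_log <- data.frame(cohort = character(), empty_qc_log())
  data.table::fwrite(qc_log, file.path(out_dir, "qc_log.tsv"), sep = "\t")
  manifest$stages$qc <- list(exclusions = nrow(qc_log))

  # 3. scan
  scans <- run_stage("scan", lapply(qcd, scan_cohort, window_bp = cfg$window_bp,
                                    min_df = cfg$min_df, scale = cfg$scale,
                                    alpha = cfg$alpha))
  for (nm in names(scans)) {
    write_results(scans[[nm]], file.path(out_dir, paste0("results_", nm, ".tsv")))
  }
  manifest$stages$scan <- list(
    tested = vapply(scans, function(r) sum(r$status == "ok"), integer(1)),
    significant = vapply(scans, function(r) sum(r$significant), integer(1))
  )

  # 4. overlap
  common <- run_stage("overlap", restrict_to_common_pairs(scans))
  ot <- overlap_table(common)
  rep_mat <- render_overlap_report(ot)
  writeLines(c(
    paste0("universe\t", ot$universe_size),
    paste(c("cohort", "n_meqtls", colnames(rep_mat)), collapse = "\t"),
    vapply(seq_along(ot$cohorts), function(i) {
      paste(c(ot$cohorts[i], ot$meqtl_counts[i], rep_mat[i, ]), collapse = "\t")
    }, character(1))
  ), file.path(out_dir, "overlap_report.tsv"))
  overlap_long <- do.call(rbind, lapply(seq_along(ot$cohorts), function(i) {
    do.call(rbind, lapply(seq_along(ot$cohorts), function(j) {
      if (i == j) return(NULL)
      data.frame(cohort_i = ot$cohorts[i], cohort_j = ot$cohorts[j],
                 shared = ot$shared[i, j], percent = ot$percent[i, j],
                 fisher_log10p = ot$fisher_log10p[i, j], stringsAsFactors = FALSE)
    }))
  }))
  data.table::fwrite(overlap_long, file.path(out_dir, "overlap.tsv"), sep = "\t")
  manifest$stages$overlap <- list(universe = ot$universe_size)

  # 5. concordance (+ t-statistic clustering over the same rows)
  conc <- run_stage("concordance", {
    tmat <- sapply(common, function(r) r$t)
    any_sig <- Reduce(`|`, lapply(common, function(r) r$significant))
    tmat <- tmat[any_sig, , drop = FALSE]
    if (!nrow(tmat)) stop("no pair significant in any cohort")
    list(summary = sign_concordance(tmat, m = cfg$concordance_m),
         clustering = cluster_tstats(tmat))
  })
  cs <- conc$summary
  data.table::fwrite(data.frame(
    k = cs$k, n_pairs = cs$n_pairs, m = cs$m,
    observed_all_same = cs$observed_all_same,
    expected_all_same = cs$expected_all_same,
    observed_atleast_m = cs$observed_atleast_m,
    expected_atleast_m = cs$expected_atleast_m,
    binom_log10p_all_same = cs$binomial_log10p[["all_same"]],
    binom_log10p_atleast_m = cs$binomial_log10p[["atleast_m"]]
  ), file.path(out_dir, "concordance.tsv"), sep = "\t")
  writeLines(conc$clustering$cohort_order,
             file.path(out_dir, "cluster_cohort_order.txt"))
  manifest$stages$concordance <- list(pairs = cs$n_pairs)

  # 6. enrichment
  target <- if (!is.null(cfg$enrichment$target)) {
    read_snp_set(cfg$enrichment$target)
  } else {
    unique(study$truth$pairs$snp_id)
  }
  enr <- run_stage("enrichment", {
    rows <- lapply(names(scans), function(nm) {
      r <- scans[[nm]]
      tested_snps <- unique(r$snp_id[r$status == "ok"])
      g <- qcd[[nm]]$genotypes[, tested_snps, drop = FALSE]
      f <- colMeans(g, na.rm = TRUE) / 2
      universe <- pmin(f, 1 - f)
      meqtls <- unique(r$snp_id[r$significant])
      if (!length(meqtls)) {
        return(data.frame(cohort = nm, n_meqtls = 0L, observed = NA_integer_,
                          null_mean = NA_real_, empirical_p = NA_real_,
                          reported_as = "no meQTLs", stringsAsFactors = FALSE))
      }
      et <- enrichment_test(meqtls, target, universe,
                            n_resamples = cfg$enrichment$n_resamples,
                            seed = derive_seed(cfg$seed, "enrichment", nm))
      data.frame(cohort = nm, n_meqtls = length(meqtls),
                 observed = et$observed_overlap, null_mean = et$null_mean,
                 empirical_p = et$empirical_p, reported_as = et$reported_as,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  data.table::fwrite(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t")
  manifest$stages$enrichment <- list(cohorts = nrow(enr))

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest$files <- as.list(tools::md5sum(files))
  names(manifest$files) <- sub(paste0("^", out_dir, "/?"), "", names(manifest$files))
  manifest$completed_stages <- names(manifest$stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(study = study, qc = qcd, scans = scans, overlap = ot,
                 concordance = conc, enrichment = enr, manifest = manifest))
}
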