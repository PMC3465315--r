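# End-to-end pipeline: expression QC -> genotype QC -> cis/trans scans ->
# multiple-testing correction, with a stage-count log and machine-readable
# summary. Every threshold in effect is recorded so a run is auditable.

#' Pipeline configuration
#'
#' Collects input paths and every tunable threshold with its canonical
#' default: probe detectability fraction 0.5 and flag fraction 0.75, MAF QC
#' floor 0.01 and analysis floor 0.10, Hardy-Weinberg p 0.001, differential
#' missingness p 1e-4, replication p 0.05, cis window 250 kb, family-wise
#' alpha 0.05, Meff variance threshold 0.995, outlier-array MAD multiplier
#' 3.
#'
#' @param genotypes_ped,genotypes_map,snp_metadata,expression,samples,probe_bed
#'   Input file paths (see the readers in this package for formats).
#' @param flags Optional flag sidecar TSV path; when `NULL`, all probes are
#'   treated as detectable and unflagged.
#' @param out_dir Output directory for result files.
#' @param detect_frac,flag_frac Probe filter fractions.
#' @param maf_qc,maf_analysis,hwe_p,missing_p,replication_p eSNP selection
#'   thresholds (see [esnp_thresholds()]).
#' @param window_bp Cis window flank in bp.
#' @param alpha Family-wise significance level.
#' @param variance_threshold Meff variance-explained threshold `C`.
#' @param outlier_k MAD multiplier for [detect_outlier_arrays()].
#' @param skip_outlier_filter Disable the outlier-array screen.
#' @param hwe_samples `"all"` or `"controls"`.
#' @param verbose Emit per-stage messages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genotypes_ped, genotypes_map, snp_metadata,
                            expression, samples, probe_bed, flags = NULL,
                            out_dir = "esnp-results", detect_frac = 0.5,
                            flag_frac = 0.75, maf_qc = 0.01,
                            maf_analysis = 0.10, hwe_p = 0.001,
                            missing_p = 1e-4, replication_p = 0.05,
                            window_bp = 250000, alpha = 0.05,
                            variance_threshold = 0.995, outlier_k = 3,
                            skip_outlier_filter = FALSE,
                            hwe_samples = "all", verbose = TRUE) {
  cfg <- list(genotypes_ped = genotypes_ped, genotypes_map = genotypes_map,
              snp_metadata = snp_metadata, expression = expression,
              samples = samples, probe_bed = probe_bed, flags = flags,
              out_dir = out_dir, detect_frac = detect_frac,
              flag_frac = flag_frac, maf_qc = maf_qc,
              maf_analysis = maf_analysis, hwe_p = hwe_p,
              missing_p = missing_p, replication_p = replication_p,
              window_bp = window_bp, alpha = alpha,
              variance_threshold = variance_threshold,
              outlier_k = outlier_k,
              skip_outlier_filter = isTRUE(skip_outlier_filter),
              hwe_samples = match.arg(hwe_samples, c("all", "controls")),
              verbose = isTRUE(verbose))
  for (nm in c("detect_frac", "flag_frac", "maf_qc", "maf_analysis",
               "hwe_p", "missing_p", "replication_p", "alpha"))
    if (!.is_prob(cfg[[nm]])) .stopf("%s must be in [0, 1]", nm)
  if (!.is_count(cfg$window_bp)) .stopf("window_bp must be >= 0")
  if (cfg$variance_threshold <= 0 || cfg$variance_threshold > 1)
    .stopf("variance_threshold must be in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative input paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (nm in c("genotypes_ped", "genotypes_map", "snp_metadata",
               "expression", "samples", "probe_bed", "flags")) {
    if (!is.null(y[[nm]]) && !grepl("^(/|[A-Za-z]:)", y[[nm]]))
      y[[nm]] <- file.path(base, y[[nm]])
  }
  do.call(pipeline_config, y)
}

#' Run the full eSNP pipeline
#'
#' Stages: read inputs; outlier-array screen (optional); probe filtering,
#' replicate collapse and quantile normalization; eSNP selection; cis-window
#' construction and cis scan; trans scan; effective-test multiple-testing
#' correction and significance annotation. Writes `cis_results.tsv`,
#' `trans_results.tsv`, `snp_filter_report.tsv`, `correction.json`,
#' `summary.json` and `run_log.txt` to `out_dir`, and returns the same
#' objects invisibly. Reruns with identical inputs are bit-identical (the
#' pipeline itself draws no random numbers).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `summary` (stage counts and thresholds),
#'   `correction` (a [correction_summary()]), `cis`, `trans`,
#'   `snp_report`, `expression` (normalized matrix), `samples`, and
#'   `genotypes` (retained SNPs).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (config$verbose) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # --- input stage ----------------------------------------------------------
  inp <- stage("read_inputs", {
    geno <- read_genotypes(config$genotypes_ped, config$genotypes_map,
                           config$snp_metadata)
    expr <- read_expression_tsv(config$expression)
    samples <- read_sample_tsv(config$samples)
    probes <- read_probe_bed(config$probe_bed)
    list(geno = geno, expr = expr, samples = samples, probes = probes)
  })
  say("inputs: %d samples, %d SNPs, %d probes (raw)",
      nrow(inp$samples), ncol(inp$geno$dosages), nrow(inp$expr))
  say("thresholds: detect>%.2f flag>%.2f maf_qc>=%.2g hwe>=%.3g miss>=%.2g repl<%.2g maf>=%.2g window=%dbp alpha=%.2g C=%.3f",
      config$detect_frac, config$flag_frac, config$maf_qc, config$hwe_p,
      config$missing_p, config$replication_p, config$maf_analysis,
      config$window_bp, config$alpha, config$variance_threshold)

  # --- expression QC --------------------------------------------------------
  eq <- stage("expression_qc", {
    expr <- inp$expr
    samples <- inp$samples
    outliers <- character(0)
    if (!config$skip_outlier_filter) {
      outliers <- detect_outlier_arrays(log2(pmax(expr, .Machine$double.eps)),
                                        k = config$outlier_k)
      if (length(outliers)) {
        expr <- expr[, !colnames(expr) %in% outliers, drop = FALSE]
        samples <- samples[!samples$sample_id %in% outliers, , drop = FALSE]
      }
    }
    fl <- if (!is.null(config$flags))
      read_flags_tsv(config$flags, rownames(expr), colnames(expr))
    else list(flags = NULL, detectable = NULL)
    grp <- samples$status[match(colnames(expr), samples$sample_id)]
    raw <- raw_expression(expr, flags = fl$flags,
                          detectable = fl$detectable, sample_group = grp)
    keep <- filter_probes(raw, config$detect_frac, config$flag_frac)
    vals <- expr[rownames(expr) %in% keep, , drop = FALSE]
    vals <- collapse_replicates(vals)
    norm <- quantile_normalize_log2(vals)
    list(norm = norm, samples = samples, outliers = outliers,
         n_raw = nrow(inp$expr), n_kept = length(keep))
  })
  say("outlier arrays removed: %d (%s); samples %d -> %d",
      length(eq$outliers),
      if (length(eq$outliers)) paste(eq$outliers, collapse = ",") else "none",
      nrow(inp$samples), nrow(eq$samples))
  say("probes: %d raw -> %d after filters -> %d after replicate collapse",
      eq$n_raw, eq$n_kept, nrow(eq$norm))

  # --- genotype QC ----------------------------------------------------------
  gq <- stage("genotype_qc", {
    geno <- inp$geno
    keep <- rownames(geno$dosages) %in% eq$samples$sample_id
    geno$dosages <- geno$dosages[keep, , drop = FALSE]
    sel <- select_esnps(
      geno, eq$samples$status[match(rownames(geno$dosages),
                                    eq$samples$sample_id)],
      thresholds = esnp_thresholds(config$maf_qc, config$hwe_p,
                                   config$missing_p, config$replication_p,
                                   config$maf_analysis),
      hwe_samples = config$hwe_samples)
    sel
  })
  say("SNPs: %d input -> %d retained (%s)",
      nrow(gq$report), ncol(gq$genotypes$dosages),
      paste(sprintf("%s=%d", names(table(gq$report$status)),
                    table(gq$report$status)), collapse = ", "))

  # --- scans ----------------------------------------------------------------
  sc <- stage("scans", {
    windows <- build_locus_windows(gq$genotypes$snps, config$window_bp)
    cis <- run_cis_scan(gq$genotypes, eq$norm, eq$samples, inp$probes,
                        window_bp = config$window_bp, windows = windows)
    trans <- run_trans_scan(gq$genotypes, eq$norm, eq$samples)
    list(windows = windows, cis = cis, trans = trans)
  })
  say("cis scan: %d SNP-probe pairs over %d loci; trans scan: %d pairs",
      nrow(sc$cis), nrow(sc$windows), nrow(sc$trans))

  # --- multiple-testing correction -----------------------------------------
  corr <- stage("correction", {
    loci <- sc$windows$locus
    meff <- setNames(integer(length(loci)), loci)
    nprob <- setNames(integer(length(loci)), loci)
    annotated <- inp$probes[inp$probes$probe_id %in% rownames(eq$norm), ]
    for (i in seq_along(loci)) {
      sid <- gq$genotypes$snps$id[gq$genotypes$snps$locus == loci[i]]
      meff[i] <- simple_m(
        genotype_correlation_matrix(
          gq$genotypes$dosages[, sid, drop = FALSE]),
        C = config$variance_threshold)
      nprob[i] <- sum(.probes_in_window(annotated, sc$windows[i, ]))
    }
    cis_probes <- unique(sc$cis$probe)
    r2 <- if (length(cis_probes) >= 2)
      mean_outcome_r2(eq$norm[cis_probes, , drop = FALSE]) else 0
    correction_summary(meff, nprob, r2, n_probes_total = nrow(eq$norm),
                       alpha = config$alpha,
                       variance_threshold = config$variance_threshold)
  })
  say("Meff per locus: %s; effective cis tests M = %d; mean outcome R^2 = %.4f",
      paste(sprintf("%s=%d", names(corr$per_locus_meff),
                    corr$per_locus_meff), collapse = ", "),
      corr$effective_cis_tests, corr$mean_outcome_r2)
  say("alpha_cis = %.4g, alpha_trans = %.4g", corr$alpha_cis,
      corr$alpha_trans)

  cis <- sc$cis
  trans <- sc$trans
  cis$significant <- !is.na(cis$p_2df) & !is.na(corr$alpha_cis) &
    cis$p_2df < corr$alpha_cis
  trans$significant <- !is.na(trans$p_2df) & trans$p_2df < corr$alpha_trans
  say("significant pairs: %d cis, %d trans",
      sum(cis$significant), sum(trans$significant))

  # --- outputs --------------------------------------------------------------
  summary <- list(
    n_samples_input = nrow(inp$samples),
    n_samples_used = nrow(eq$samples),
    outlier_arrays = eq$outliers,
    n_probes_raw = eq$n_raw,
    n_probes_filtered = eq$n_kept,
    n_probes_analyzed = nrow(eq$norm),
    n_snps_input = nrow(gq$report),
    n_snps_retained = ncol(gq$genotypes$dosages),
    snp_filter_counts = as.list(table(gq$report$status)),
    n_cis_pairs = nrow(cis),
    n_trans_pairs = nrow(trans),
    per_locus_meff = as.list(corr$per_locus_meff),
    probes_per_locus = as.list(corr$probes_per_locus),
    meff_total_snps = corr$meff_total_snps,
    effective_cis_tests = corr$effective_cis_tests,
    mean_outcome_r2 = corr$mean_outcome_r2,
    alpha_cis = corr$alpha_cis,
    alpha_trans = corr$alpha_trans,
    n_significant_cis = sum(cis$significant),
    n_significant_trans = sum(trans$significant),
    thresholds = config[c("detect_frac", "flag_frac", "maf_qc",
                          "maf_analysis", "hwe_p", "missing_p",
                          "replication_p", "window_bp", "alpha",
                          "variance_threshold", "outlier_k",
                          "skip_outlier_filter", "hwe_samples")])
  stage("write_outputs", {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(cis, file.path(config$out_dir, "cis_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(trans, file.path(config$out_dir, "trans_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(gq$report,
                file.path(config$out_dir, "snp_filter_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    corr_out <- unclass(corr)[c(
      "per_locus_meff", "probes_per_locus", "meff_total_snps",
      "effective_cis_tests", "mean_outcome_r2", "alpha",
      "variance_threshold", "alpha_cis", "alpha_trans", "n_probes_total")]
    corr_out$per_locus_meff <- as.list(corr_out$per_locus_meff)
    corr_out$probes_per_locus <- as.list(corr_out$probes_per_locus)
    jsonlite::write_json(corr_out,
                         file.path(config$out_dir, "correction.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  })
  invisible(list(summary = summary, correction = corr, cis = cis,
                 trans = trans, snp_report = gq$report,
                 expression = eq$norm, samples = eq$samples,
                 genotypes = gq$genotypes, windows = sc$windows))
}
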