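# The 2-df joint test of genotype and genotype-by-status interaction, with
# stratified per-group effect estimates, locus window construction, and the
# cis/trans scan engines.
#
# With ~25 samples per group, minor-allele homozygotes are rare, so genotype
# enters all models dominant-coded (0 = no minor allele, 1 = at least one).
# The 2-df statistic compares, by nested-model F-test,
#   full:    y ~ X + D + X:D + RIN + PMI + age
#   reduced: y ~     D       + RIN + PMI + age
# so it is jointly sensitive to a genotype effect and to a difference in
# that effect between cases and controls. The F form (not asymptotic chi2)
# is used because n ~ 50 makes the finite-sample correction material.

#' Dominant-model genotype coding
#'
#' @param dosage Minor-allele dosages in `{0, 1, 2, NA}`.
#' @return Vector in `{0, 1, NA}`: 1 when at least one minor allele is
#'   carried.
#' @export
dominant_code <- function(dosage) {
  if (!all(dosage %in% c(0, 1, 2) | is.na(dosage)))
    .stopf("dosages must lie in {0, 1, 2, NA}")
  pmin(dosage, 1)
}

.check_status <- function(status) {
  status <- as.character(status)
  if (!all(status %in% c("case", "control")))
    .stopf("status entries must be 'case' or 'control'")
  status
}

.covar_matrix <- function(covariates, n) {
  cv <- as.matrix(as.data.frame(covariates))
  if (nrow(cv) != n) .stopf("covariates must have one row per sample")
  if (!is.numeric(cv)) .stopf("covariates must be numeric")
  cv
}

# Relative tolerance under which a residual sum of squares is treated as an
# exact fit (perfect, noiseless signal).
.EXACT_TOL <- 1e-10

#' Fit the 2-df joint genotype / genotype-by-status test for one probe
#'
#' Ordinary least squares on the full model (intercept, dominant genotype
#' `X`, status `D`, interaction `X:D`, covariates) and the reduced model
#' without `X` and `X:D`;
#' `F = ((RSS_reduced - RSS_full) / 2) / (RSS_full / (n - 7))` with p from
#' the upper tail of `F(2, n - 7)`. Samples missing the genotype, the
#' response or any covariate are dropped (complete-case per pair). A design
#' that is rank deficient in the used samples (e.g. genotype constant, or
#' constant within one stratum in a way that aliases the interaction) is
#' flagged `degenerate` with no p-value; a perfect fit (`RSS_full` at
#' rounding error) is flagged `exact_fit` with `p = 0`.
#'
#' @param y Numeric response (log2 expression), one value per sample.
#' @param dosage Minor-allele dosages in `{0, 1, 2, NA}`.
#' @param status `"case"`/`"control"` per sample.
#' @param covariates Data frame or matrix of numeric covariates (RIN, PMI,
#'   age at death in the canonical model).
#' @return List with `n_used`, `f_stat`, `p_2df`, `rss_full`,
#'   `rss_reduced`, `df_resid` and `flags` (character, `""` when clean).
#' @export
fit_2df <- function(y, dosage, status, covariates) {
  status <- .check_status(status)
  n_all <- length(y)
  cv <- .covar_matrix(covariates, n_all)
  x <- dominant_code(dosage)
  keep <- !is.na(y) & !is.na(x) & complete.cases(cv)
  n <- sum(keep)
  p_full <- 4L + ncol(cv)
  if (n <= p_full)
    .stopf("too few samples: %d used, full model has %d parameters",
           n, p_full)
  xk <- x[keep]
  dk <- as.integer(status[keep] == "case")
  Ck <- cv[keep, , drop = FALSE]
  Xf <- cbind(1, xk, dk, xk * dk, Ck)
  Xr <- cbind(1, dk, Ck)
  qf <- qr(Xf)
  flags <- character(0)
  if (var(xk) == 0 || qf$rank < ncol(Xf)) {
    return(list(n_used = n, f_stat = NA_real_, p_2df = NA_real_,
                rss_full = NA_real_, rss_reduced = NA_real_,
                df_resid = n - p_full, flags = "degenerate"))
  }
  yk <- y[keep]
  rss_f <- sum(qr.resid(qf, yk)^2)
  rss_r <- sum(qr.resid(qr(Xr), yk)^2)
  df2 <- n - p_full
  tss <- sum((yk - mean(yk))^2)
  if (rss_f < .EXACT_TOL * max(tss, .Machine$double.eps)) {
    return(list(n_used = n, f_stat = Inf, p_2df = 0, rss_full = rss_f,
                rss_reduced = rss_r, df_resid = df2, flags = "exact_fit"))
  }
  f <- ((rss_r - rss_f) / 2) / (rss_f / df2)
  list(n_used = n, f_stat = f, p_2df = pf(f, 2, df2, lower.tail = FALSE),
       rss_full = rss_f, rss_reduced = rss_r, df_resid = df2, flags = "")
}

#' Marginal 1-df genotype test (no interaction)
#'
#' The conventional single-df alternative to [fit_2df()]: OLS of expression
#' on dominant genotype, status and covariates, with a two-sided t-test on
#' the genotype coefficient. Provided for power comparisons — when an
#' effect is opposite in cases and controls the marginal genotype effect
#' cancels and this test loses the signal the joint test retains.
#'
#' @inheritParams fit_2df
#' @return List with `n_used`, `beta`, `se`, `p` and `flags`.
#' @export
fit_marginal <- function(y, dosage, status, covariates) {
  status <- .check_status(status)
  n_all <- length(y)
  cv <- .covar_matrix(covariates, n_all)
  x <- dominant_code(dosage)
  keep <- !is.na(y) & !is.na(x) & complete.cases(cv)
  n <- sum(keep)
  p_par <- 3L + ncol(cv)
  if (n <= p_par) .stopf("too few samples for the marginal model")
  xk <- x[keep]
  dk <- as.integer(status[keep] == "case")
  X <- cbind(1, xk, dk, cv[keep, , drop = FALSE])
  qx <- qr(X)
  if (var(xk) == 0 || qx$rank < ncol(X))
    return(list(n_used = n, beta = NA_real_, se = NA_real_, p = NA_real_,
                flags = "degenerate"))
  yk <- y[keep]
  beta <- qr.coef(qx, yk)
  rss <- sum(qr.resid(qx, yk)^2)
  df <- n - ncol(X)
  xtx_inv <- solve(crossprod(X))[2, 2]
  se <- sqrt(rss / df * xtx_inv)
  tstat <- unname(beta[2]) / se
  list(n_used = n, beta = unname(beta[2]), se = se,
       p = 2 * pt(-abs(tstat), df), flags = "")
}

#' Stratified within-group genotype effect
#'
#' OLS of expression on dominant genotype plus all covariates within one
#' group's samples; returns the genotype coefficient and its two-sided
#' t-test p-value. The covariates are retained even within group, mirroring
#' the adjusted joint model.
#'
#' @param y Numeric response for the group's samples.
#' @param dosage Minor-allele dosages for the same samples.
#' @param covariates Covariate data frame/matrix for the same samples.
#' @return List with `n_used`, `beta`, `se`, `p` and `flags`
#'   (`"x_constant"` when the genotype does not vary within the group).
#' @export
stratified_effects <- function(y, dosage, covariates) {
  n_all <- length(y)
  cv <- .covar_matrix(covariates, n_all)
  x <- dominant_code(dosage)
  keep <- !is.na(y) & !is.na(x) & complete.cases(cv)
  n <- sum(keep)
  if (n <= 5) .stopf("group too small (%d samples) for the stratified model", n)
  xk <- x[keep]
  if (var(xk) == 0)
    return(list(n_used = n, beta = NA_real_, se = NA_real_, p = NA_real_,
                flags = "x_constant"))
  X <- cbind(1, xk, cv[keep, , drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X))
    return(list(n_used = n, beta = NA_real_, se = NA_real_, p = NA_real_,
                flags = "degenerate"))
  yk <- y[keep]
  beta <- qr.coef(qx, yk)
  rss <- sum(qr.resid(qx, yk)^2)
  df <- n - ncol(X)
  tss <- sum((yk - mean(yk))^2)
  if (rss < .EXACT_TOL * max(tss, .Machine$double.eps))
    return(list(n_used = n, beta = unname(beta[2]), se = 0, p = 0,
                flags = "exact_fit"))
  se <- sqrt(rss / df * solve(crossprod(X))[2, 2])
  tstat <- unname(beta[2]) / se
  list(n_used = n, beta = unname(beta[2]), se = se,
       p = 2 * pt(-abs(tstat), df), flags = "")
}

#' Cis windows around each locus's SNP span
#'
#' Per locus, the window is `[min position - window_bp,
#' max position + window_bp]` (1-based, clipped at 1); every probe
#' overlapping the window is tested against every SNP of the locus, so each
#' probe meets the full LD block.
#'
#' @param snps Data frame with columns `locus`, `chromosome`, `position`.
#' @param window_bp Flank size in bp (default 250000; >= 0).
#' @return Data frame with columns `locus`, `chromosome`, `window_start`,
#'   `window_end`.
#' @export
build_locus_windows <- function(snps, window_bp = 250000) {
  if (!.is_count(window_bp)) .stopf("window_bp must be a nonnegative integer")
  loci <- unique(snps$locus)
  rows <- lapply(loci, function(lc) {
    s <- snps[snps$locus == lc, ]
    chr <- unique(.norm_chrom(s$chromosome))
    if (length(chr) != 1L)
      .stopf("locus '%s' spans multiple chromosomes (%s)", lc,
             paste(chr, collapse = ", "))
    data.frame(locus = lc, chromosome = chr,
               window_start = max(1, min(s$position) - window_bp),
               window_end = max(s$position) + window_bp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Probe-in-window membership under the package's half-open overlap
# convention: probe intervals and windows are both treated as half-open
# [start, end), so a probe overlaps iff start < window_end and
# end > window_start. A probe ending exactly at window_start is excluded.
.probes_in_window <- function(probes, window) {
  same <- .norm_chrom(probes$chromosome) == window$chromosome
  same & probes$start < window$window_end &
    probes$end > window$window_start
}

# Scan one SNP against a matrix of probes sharing its complete-case mask.
# Y: probes x samples; returns one row per probe.
.scan_snp <- function(snp_id, dosage, Y, status, cv, scan_type) {
  probes <- rownames(Y)
  np <- length(probes)
  na_row <- function(flag) data.frame(
    snp = snp_id, probe = probes, scan_type = scan_type,
    n_used = sum(!is.na(dosage)), f_stat = NA_real_, p_2df = NA_real_,
    beta_case = NA_real_, p_case = NA_real_, beta_control = NA_real_,
    p_control = NA_real_, flags = flag, stringsAsFactors = FALSE)
  x <- dominant_code(dosage)
  keep <- !is.na(x)
  n <- sum(keep)
  p_full <- 4L + ncol(cv)
  if (n <= p_full) return(na_row("too_few_samples"))
  xk <- x[keep]
  dk <- as.integer(status[keep] == "case")
  Ck <- cv[keep, , drop = FALSE]
  Yt <- t(Y[, keep, drop = FALSE])            # samples x probes
  Xf <- cbind(1, xk, dk, xk * dk, Ck)
  qf <- qr(Xf)
  if (var(xk) == 0 || qf$rank < ncol(Xf)) return(na_row("degenerate"))
  rss_f <- colSums(qr.resid(qf, Yt)^2)
  rss_r <- colSums(qr.resid(qr(cbind(1, dk, Ck)), Yt)^2)
  df2 <- n - p_full
  tss <- colSums(sweep(Yt, 2, colMeans(Yt))^2)
  exact <- rss_f < .EXACT_TOL * pmax(tss, .Machine$double.eps)
  f <- ((rss_r - rss_f) / 2) / (rss_f / df2)
  p <- pf(f, 2, df2, lower.tail = FALSE)
  f[exact] <- Inf
  p[exact] <- 0
  flags <- ifelse(exact, "exact_fit", "")
  strat <- lapply(c(case = 1L, control = 0L), function(g) {
    idx <- dk == g
    ng <- sum(idx)
    empty <- list(beta = rep(NA_real_, np), p = rep(NA_real_, np))
    if (ng <= 5) return(c(empty, flag = "small_group"))
    xg <- xk[idx]
    if (var(xg) == 0) return(c(empty, flag = "x_constant"))
    Xg <- cbind(1, xg, Ck[idx, , drop = FALSE])
    qg <- qr(Xg)
    if (qg$rank < ncol(Xg)) return(c(empty, flag = "degenerate_group"))
    Yg <- Yt[idx, , drop = FALSE]
    beta <- qr.coef(qg, Yg)[2, ]
    rss <- colSums(qr.resid(qg, Yg)^2)
    dfg <- ng - ncol(Xg)
    tssg <- colSums(sweep(Yg, 2, colMeans(Yg))^2)
    exg <- rss < .EXACT_TOL * pmax(tssg, .Machine$double.eps)
    se <- sqrt(rss / dfg * solve(crossprod(Xg))[2, 2])
    pg <- 2 * pt(-abs(beta / se), dfg)
    pg[exg] <- 0
    list(beta = unname(beta), p = pg, flag = "")
  })
  add_flag <- function(fl, extra, grp)
    ifelse(nzchar(extra), paste0(fl, ifelse(nzchar(fl), ";", ""),
                                 grp, ":", extra), fl)
  flags <- add_flag(flags, strat$case$flag, "case")
  flags <- add_flag(flags, strat$control$flag, "control")
  data.frame(snp = snp_id, probe = probes, scan_type = scan_type,
             n_used = n, f_stat = f, p_2df = p,
             beta_case = strat$case$beta, p_case = strat$case$p,
             beta_control = strat$control$beta, p_control = strat$control$p,
             flags = flags, stringsAsFactors = FALSE)
}

# align expression columns and dosage rows to the sample table
.align_inputs <- function(genotypes, expression, samples) {
  ids <- as.character(samples$sample_id)
  if (anyDuplicated(ids)) .stopf("duplicate sample ids in sample table")
  if (!all(ids %in% rownames(genotypes$dosages)))
    .stopf("sample axis mismatch: samples absent from the genotype matrix")
  if (!all(ids %in% colnames(expression)))
    .stopf("sample axis mismatch: samples absent from the expression matrix")
  list(dosages = genotypes$dosages[ids, , drop = FALSE],
       expression = expression[, ids, drop = FALSE],
       status = .check_status(samples$status),
       covariates = .covar_matrix(
         samples[, c("rin", "pmi", "age_at_death")], length(ids)))
}

.empty_results <- function() {
  data.frame(snp = character(), probe = character(), scan_type = character(),
             n_used = integer(), f_stat = numeric(), p_2df = numeric(),
             beta_case = numeric(), p_case = numeric(),
             beta_control = numeric(), p_control = numeric(),
             flags = character(), stringsAsFactors = FALSE)
}

#' Cis scan: locus SNPs against probes inside the locus window
#'
#' Tests every (SNP, probe) pair where the probe's annotated interval
#' overlaps the SNP's locus window on the same chromosome, using
#' [fit_2df()]-equivalent joint tests plus stratified effects; the pair
#' count is the sum over loci of `n_snps * n_probes_in_window`. Probes
#' present in the expression matrix but absent from the annotation are
#' skipped with a warning.
#'
#' @param genotypes A `genotype_matrix` (typically the output of
#'   [select_esnps()]).
#' @param expression Probes x samples matrix of normalized log2 expression.
#' @param samples Sample table with `sample_id`, `status`, `rin`, `pmi`,
#'   `age_at_death`.
#' @param probes Probe annotation data frame (`probe_id`, `chromosome`,
#'   `start`, `end`; 0-based half-open), e.g. from [read_probe_bed()].
#' @param window_bp Cis window flank in bp (default 250000).
#' @param windows Optional precomputed [build_locus_windows()] result.
#' @return Data frame of association results, one row per tested pair, with
#'   columns `snp`, `probe`, `scan_type`, `n_used`, `f_stat`, `p_2df`,
#'   `beta_case`, `p_case`, `beta_control`, `p_control`, `flags`.
#' @export
run_cis_scan <- function(genotypes, expression, samples, probes,
                         window_bp = 250000, windows = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  al <- .align_inputs(genotypes, expression, samples)
  unannot <- setdiff(rownames(expression), probes$probe_id)
  if (length(unannot))
    .warnf("%d expression probes lack annotation and are skipped from the cis scan",
           length(unannot))
  if (is.null(windows))
    windows <- build_locus_windows(genotypes$snps, window_bp)
  probes <- probes[probes$probe_id %in% rownames(expression), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    pid <- probes$probe_id[.probes_in_window(probes, w)]
    if (!length(pid)) next
    Y <- al$expression[pid, , drop = FALSE]
    sid <- genotypes$snps$id[genotypes$snps$locus == w$locus]
    for (s in sid)
      out[[length(out) + 1L]] <-
        .scan_snp(s, al$dosages[, s], Y, al$status, al$covariates, "cis")
  }
  if (!length(out)) return(.empty_results())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Trans scan: every SNP against every probe
#'
#' Transcriptome-wide scan over all retained probes; cis pairs are included
#' (labelled by `scan_type`), matching a secondary-hypothesis analysis run
#' on the whole array.
#'
#' @inheritParams run_cis_scan
#' @return Data frame of association results (see [run_cis_scan()]).
#' @export
run_trans_scan <- function(genotypes, expression, samples) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (ncol(genotypes$dosages) == 0L) {
    .warnf("no SNPs to scan; returning empty result")
    return(.empty_results())
  }
  al <- .align_inputs(genotypes, expression, samples)
  out <- lapply(colnames(al$dosages), function(s)
    .scan_snp(s, al$dosages[, s], al$expression, al$status, al$covariates,
              "trans"))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
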