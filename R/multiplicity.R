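# Effective-number-of-tests estimation and the two adjusted significance
# thresholds: a correlation-adjusted Bonferroni cutoff for the cis scan and
# a plain Bonferroni cutoff on effective SNPs x probes for the trans scan.

#' Pairwise Pearson correlation of SNP dosages at one locus
#'
#' Correlations are computed on raw dosages (0/1/2), pairwise-complete over
#' non-missing samples — LD is a property of alleles, so the dominant
#' recode used by the association model is deliberately not applied here.
#'
#' @param dosages Samples x SNPs matrix of dosages in `{0, 1, 2, NA}`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
genotype_correlation_matrix <- function(dosages) {
  dosages <- as.matrix(dosages)
  v <- apply(dosages, 2, var, na.rm = TRUE)
  if (any(zero <- !is.finite(v) | v == 0)) {
    nm <- colnames(dosages)[zero]
    if (is.null(nm)) nm <- which(zero)
    .stopf("SNP(s) with zero variance: %s", paste(nm, collapse = ", "))
  }
  r <- cor(dosages, use = "pairwise.complete.obs")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Effective number of independent tests from eigenvalues
#'
#' Eigenvalue-based Meff: the smallest number `k` such that the `k` largest
#' eigenvalues of the correlation matrix explain at least a fraction `C` of
#' the total variance. Perfectly correlated SNPs collapse to one effective
#' test; independent SNPs count fully.
#'
#' @param corr_matrix Symmetric correlation matrix; eigenvalues in
#'   `[-1e-8, 0)` are clipped to 0, more negative values are an error.
#' @param C Variance-explained threshold in `(0, 1]` (default 0.995, the
#'   conventional choice for this estimator).
#' @return Integer Meff, `1 <= Meff <= nrow(corr_matrix)`.
#' @export
simple_m <- function(corr_matrix, C = 0.995) {
  corr_matrix <- as.matrix(corr_matrix)
  if (!nrow(corr_matrix)) .stopf("empty correlation matrix")
  if (nrow(corr_matrix) != ncol(corr_matrix) ||
      max(abs(corr_matrix - t(corr_matrix))) > 1e-8)
    .stopf("correlation matrix must be symmetric")
  if (!is.numeric(C) || length(C) != 1L || C <= 0 || C > 1)
    .stopf("C must be in (0, 1]")
  ev <- eigen(corr_matrix, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8))
    .stopf("correlation matrix is not positive semi-definite (min eigenvalue %g)",
           min(ev))
  ev <- pmax(ev, 0)
  frac <- cumsum(ev) / sum(ev)
  as.integer(which(frac >= C - 1e-12)[1])
}

#' Effective number of cis tests
#'
#' `M = sum over loci of Meff(locus) * n_probes(locus window)`: the number
#' of probes tested at a locus multiplied by the locus's effective number
#' of independent SNPs, summed across loci.
#'
#' @param per_locus_meff Named integer vector of per-locus Meff.
#' @param probes_per_locus Named integer vector of probe counts per locus
#'   window; names must match `per_locus_meff`.
#' @return Integer total effective test count.
#' @export
effective_cis_tests <- function(per_locus_meff, probes_per_locus) {
  if (is.null(names(per_locus_meff)) || is.null(names(probes_per_locus)) ||
      !setequal(names(per_locus_meff), names(probes_per_locus)))
    .stopf("per_locus_meff and probes_per_locus must share locus names")
  probes_per_locus <- probes_per_locus[names(per_locus_meff)]
  if (any(probes_per_locus == 0))
    message(sprintf("locus with zero probes in window contributes 0: %s",
                    paste(names(probes_per_locus)[probes_per_locus == 0],
                          collapse = ", ")))
  as.integer(sum(per_locus_meff * probes_per_locus))
}

#' Mean squared pairwise correlation of outcome probes
#'
#' Mean over all unordered probe pairs of the squared Pearson correlation
#' of expression across samples; the single-number summary of outcome
#' correlation used by [sankoh_adjusted_alpha()].
#'
#' @param expression Probes x samples matrix (>= 2 probes).
#' @return Mean squared correlation in `[0, 1]`.
#' @export
mean_outcome_r2 <- function(expression) {
  expression <- as.matrix(expression)
  m <- nrow(expression)
  if (m < 2) .stopf("need at least 2 probes")
  r <- cor(t(expression))
  (sum(r^2) - m) / (m * (m - 1))
}

#' Correlation-adjusted Bonferroni threshold for correlated outcomes
#'
#' `alpha_adj = alpha / M^(1 - r2bar)`: plain Bonferroni when the outcomes
#' are uncorrelated (`r2bar = 0`), no correction at all when they are
#' perfectly correlated (`r2bar = 1`), and in between never more
#' conservative than Bonferroni. An alternative Sidak-style form
#' `1 - (1 - alpha)^(1 / M^(1 - r2bar))` is available; the divide form is
#' the default.
#'
#' @param alpha Family-wise level (default 0.05).
#' @param M Number of (effective) tests, >= 1.
#' @param r2bar Mean squared pairwise correlation of the outcomes, in
#'   `[0, 1]`.
#' @param form `"divide"` (default) or `"sidak"`.
#' @return Adjusted per-test alpha.
#' @export
sankoh_adjusted_alpha <- function(alpha = 0.05, M, r2bar,
                                  form = c("divide", "sidak")) {
  form <- match.arg(form)
  if (!.is_prob(alpha) || alpha <= 0) .stopf("alpha must be in (0, 1]")
  if (!is.numeric(M) || length(M) != 1L || M < 1) .stopf("M must be >= 1")
  if (!.is_prob(r2bar)) .stopf("r2bar must be in [0, 1]")
  meff <- M^(1 - r2bar)
  switch(form,
         divide = alpha / meff,
         sidak  = 1 - (1 - alpha)^(1 / meff))
}

#' Bonferroni threshold for the trans scan
#'
#' `alpha_trans = alpha / (meff_total_snps * n_probes)`: the effective
#' number of independent SNPs multiplied by the total number of probes on
#' the array.
#'
#' @param alpha Family-wise level (default 0.05).
#' @param meff_total_snps Effective number of independent SNPs (>= 1).
#' @param n_probes Total probe count (>= 1).
#' @return Adjusted per-test alpha.
#' @export
trans_adjusted_alpha <- function(alpha = 0.05, meff_total_snps, n_probes) {
  if (!.is_prob(alpha) || alpha <= 0) .stopf("alpha must be in (0, 1]")
  if (!is.numeric(meff_total_snps) || meff_total_snps < 1)
    .stopf("meff_total_snps must be >= 1")
  if (!is.numeric(n_probes) || n_probes < 1) .stopf("n_probes must be >= 1")
  alpha / (meff_total_snps * n_probes)
}

#' Assemble a multiple-testing correction summary
#'
#' @param per_locus_meff Named per-locus Meff vector.
#' @param probes_per_locus Named per-locus probe counts.
#' @param mean_r2 Mean squared outcome correlation from [mean_outcome_r2()].
#' @param n_probes_total Total probes entering the trans scan.
#' @param alpha Family-wise level.
#' @param variance_threshold Meff variance-explained threshold `C`.
#' @return A `correction_summary` list with per-locus Meff, the summed
#'   effective SNP count, effective cis test count, both adjusted alphas and
#'   the inputs.
#' @export
correction_summary <- function(per_locus_meff, probes_per_locus, mean_r2,
                               n_probes_total, alpha = 0.05,
                               variance_threshold = 0.995) {
  M <- effective_cis_tests(per_locus_meff, probes_per_locus)
  meff_total <- as.integer(sum(per_locus_meff))
  # no probes in any window: the cis family is empty, its threshold undefined
  alpha_cis <- if (M >= 1) sankoh_adjusted_alpha(alpha, M, mean_r2)
               else NA_real_
  structure(list(
    per_locus_meff = per_locus_meff,
    probes_per_locus = probes_per_locus[names(per_locus_meff)],
    meff_total_snps = meff_total,
    effective_cis_tests = M,
    mean_outcome_r2 = mean_r2,
    alpha = alpha,
    variance_threshold = variance_threshold,
    alpha_cis = alpha_cis,
    alpha_trans = trans_adjusted_alpha(alpha, meff_total, n_probes_total),
    n_probes_total = n_probes_total),
    class = "correction_summary")
}

#' @export
print.correction_summary <- function(x, ...) {
  cat("Multiple-testing correction summary\n")
  cat(sprintf("  per-locus Meff: %s\n",
              paste(sprintf("%s=%d", names(x$per_locus_meff),
                            x$per_locus_meff), collapse = ", ")))
  cat(sprintf("  effective SNPs (sum Meff): %d\n", x$meff_total_snps))
  cat(sprintf("  effective cis tests M: %d\n", x$effective_cis_tests))
  cat(sprintf("  mean outcome R^2: %.4f\n", x$mean_outcome_r2))
  cat(sprintf("  alpha_cis = %.3g, alpha_trans = %.3g (alpha = %g)\n",
              x$alpha_cis, x$alpha_trans, x$alpha))
  invisible(x)
}
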