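# SNP-level QC and eSNP selection: MAF, Hardy-Weinberg exact test,
# differential missingness by case/control status, external replication and
# direction-of-effect filters, and the analysis-sample MAF floor.

#' Minor allele frequency of one SNP
#'
#' Computed as `sum(dosages) / (2 * non-missing count)`; if the counted
#' allele turns out to be the major one (frequency > 0.5) the reported
#' frequency is re-polarized to `1 - p`, so the return value is always the
#' frequency of the rarer allele.
#'
#' @param dosages Numeric vector of allele counts in `{0, 1, 2, NA}`.
#' @return Frequency in `[0, 0.5]`.
#' @export
minor_allele_frequency <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) .stopf("all genotype calls are missing")
  if (!all(d %in% c(0, 1, 2))) .stopf("dosages must lie in {0, 1, 2, NA}")
  p <- sum(d) / (2 * length(d))
  min(p, 1 - p)
}

#' Re-polarize SNPs whose counted allele is the major one
#'
#' Any SNP with allele frequency > 0.5 has its dosages recoded as
#' `2 - dosage` and its minor/major allele labels swapped (when present in
#' the metadata), so dosages always count the minor allele. Applying the
#' operation twice returns the input.
#'
#' @param genotypes A `genotype_matrix`.
#' @return A `genotype_matrix` with all allele frequencies <= 0.5.
#' @export
repolarize_genotypes <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosages
  p <- colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
  flip <- p > 0.5
  if (any(flip)) {
    d[, flip] <- 2L - d[, flip]
    genotypes$dosages <- d
    if (all(c("minor_allele", "major_allele") %in% names(genotypes$snps))) {
      mn <- genotypes$snps$minor_allele[flip]
      genotypes$snps$minor_allele[flip] <- genotypes$snps$major_allele[flip]
      genotypes$snps$major_allele[flip] <- mn
    }
  }
  genotypes
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test: all heterozygote counts consistent with the
#' observed allele counts are enumerated, each assigned its probability
#' under the Hardy-Weinberg null (random union of gametes; a hypergeometric
#' distribution over heterozygote counts), and the p-value is the sum of
#' probabilities not exceeding that of the observed configuration.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (major homozygote, heterozygote,
#'   minor homozygote); nonnegative, total >= 1.
#' @return Exact p-value in `(0, 1]`; monomorphic SNPs return 1 (no test
#'   possible, conventionally non-significant).
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (!.is_count(n_AA) || !.is_count(n_Aa) || !.is_count(n_aa))
    .stopf("genotype counts must be nonnegative integers")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) .stopf("total genotype count must be >= 1")
  na <- 2 * n_aa + n_Aa                  # count of the 'a' allele
  na <- min(na, 2 * n - na)              # work with the rarer allele
  if (na == 0) return(1.0)               # monomorphic
  hets <- seq(na %% 2, na, by = 2)       # feasible heterozygote counts
  # log P(n_Aa = h | allele counts) up to a shared constant:
  # n! / (nAA! h! naa!) * 2^h
  logp <- vapply(hets, function(h) {
    hom_a <- (na - h) / 2
    hom_A <- n - h - hom_a
    lgamma(n + 1) - lgamma(hom_A + 1) - lgamma(h + 1) - lgamma(hom_a + 1) +
      h * log(2)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]         # het count is polarity-invariant
  if (is.na(p_obs)) .stopf("inconsistent genotype counts")
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Differential missingness test (case/control)
#'
#' Fisher's exact test on the 2x2 table of missing-call counts by
#' case/control status. SNPs with no missing calls return 1.
#'
#' @param missing Logical vector, `TRUE` where the genotype call is missing.
#' @param status Character/factor of `"case"`/`"control"`, same length.
#' @return Two-sided exact p-value.
#' @export
differential_missingness_test <- function(missing, status) {
  if (length(missing) != length(status))
    .stopf("missing and status must have equal length")
  status <- as.character(status)
  if (!all(status %in% c("case", "control")))
    .stopf("status entries must be 'case' or 'control'")
  if (!any(missing)) return(1.0)
  tab <- table(factor(missing, c(TRUE, FALSE)),
               factor(status, c("case", "control")))
  fisher.test(tab)$p.value
}

#' Default eSNP selection thresholds
#'
#' @param maf_qc Genotyping-QC MAF floor (default 0.01).
#' @param hwe_p Hardy-Weinberg exact p floor (default 0.001).
#' @param missing_p Differential-missingness p floor (default 1e-4).
#' @param replication_p Replication p ceiling (default 0.05; strict `<`).
#' @param maf_analysis Analysis-sample MAF floor (default 0.10), guarding
#'   against inflated type-I error with quantitative traits at small n.
#' @return Named list of thresholds.
#' @export
esnp_thresholds <- function(maf_qc = 0.01, hwe_p = 0.001, missing_p = 1e-4,
                            replication_p = 0.05, maf_analysis = 0.10) {
  th <- list(maf_qc = maf_qc, hwe_p = hwe_p, missing_p = missing_p,
             replication_p = replication_p, maf_analysis = maf_analysis)
  for (nm in names(th))
    if (!.is_prob(th[[nm]])) .stopf("threshold %s must be in [0, 1]", nm)
  th
}

#' Select analysis eSNPs
#'
#' Applies the QC and selection filters in order, recording for each SNP the
#' first filter it failed: minimum MAF (`maf_qc`), Hardy-Weinberg exact test
#' (on all samples by default, switchable to controls only), differential
#' missingness by status, external replication (`replication_p` strictly
#' below threshold *and* direction of effect matching the discovery sign),
#' and finally the analysis-sample MAF floor (`maf_analysis`). Dosages are
#' re-polarized first so every filter sees minor-allele counts. Requires
#' metadata columns `replication_p`, `risk_or`, `discovery_direction`.
#'
#' @param genotypes A `genotype_matrix`.
#' @param status Character/factor of `"case"`/`"control"` per sample.
#' @param thresholds A list from [esnp_thresholds()].
#' @param hwe_samples `"all"` (default) or `"controls"`: which samples enter
#'   the Hardy-Weinberg test.
#' @return List with `genotypes` (the filtered, re-polarized
#'   `genotype_matrix`) and `report` (one row per input SNP: id, locus, the
#'   computed statistics, and `status` = `"retained"` or the first failed
#'   filter, one of `"maf_qc"`, `"hwe"`, `"missingness"`, `"replication"`,
#'   `"maf_analysis"`).
#' @export
select_esnps <- function(genotypes, status, thresholds = esnp_thresholds(),
                         hwe_samples = c("all", "controls")) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  hwe_samples <- match.arg(hwe_samples)
  status <- as.character(status)
  if (length(status) != nrow(genotypes$dosages))
    .stopf("status must have one entry per sample")
  req <- c("replication_p", "risk_or", "discovery_direction")
  if (!all(req %in% names(genotypes$snps)))
    .stopf("snps metadata must contain %s", paste(req, collapse = ", "))
  genotypes <- repolarize_genotypes(genotypes)
  d <- genotypes$dosages
  meta <- genotypes$snps
  hwe_rows <- if (hwe_samples == "all") rep(TRUE, nrow(d))
              else status == "control"
  m <- ncol(d)
  maf <- hwe_p <- miss_p <- numeric(m)
  dirmatch <- logical(m)
  state <- character(m)
  for (j in seq_len(m)) {
    dj <- d[, j]
    maf[j] <- minor_allele_frequency(dj)
    dh <- dj[hwe_rows & !is.na(dj)]
    hwe_p[j] <- hwe_exact_test(sum(dh == 0), sum(dh == 1), sum(dh == 2))
    miss_p[j] <- differential_missingness_test(is.na(dj), status)
    dirmatch[j] <- sign(log(meta$risk_or[j])) == meta$discovery_direction[j]
    state[j] <-
      if (maf[j] < thresholds$maf_qc) "maf_qc"
      else if (hwe_p[j] < thresholds$hwe_p) "hwe"
      else if (miss_p[j] < thresholds$missing_p) "missingness"
      else if (!(meta$replication_p[j] < thresholds$replication_p) ||
               !dirmatch[j]) "replication"
      else if (maf[j] < thresholds$maf_analysis) "maf_analysis"
      else "retained"
  }
  report <- data.frame(id = meta$id, locus = meta$locus, maf = maf,
                       hwe_p = hwe_p, missingness_p = miss_p,
                       replication_p = meta$replication_p,
                       direction_match = dirmatch, status = state,
                       stringsAsFactors = FALSE)
  keep <- state == "retained"
  if (!any(keep)) .warnf("no SNPs passed eSNP selection")
  out <- genotype_matrix(d[, keep, drop = FALSE],
                         meta[keep, , drop = FALSE])
  list(genotypes = out, report = report)
}
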