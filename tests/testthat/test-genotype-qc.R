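test_that("minor allele frequency counts and re-polarizes correctly", {
  expect_equal(minor_allele_frequency(c(0, 0, 1, 1, 2)), 0.4)
  expect_equal(minor_allele_frequency(rep(0, 5)), 0)
  expect_equal(minor_allele_frequency(c(2, 2, 2, 1)), 1 / 8)
  expect_equal(minor_allele_frequency(c(0, NA, 1)), 0.25)
  expect_error(minor_allele_frequency(c(NA, NA)), "missing")
  expect_error(minor_allele_frequency(c(0, 3)), "dosages")
})

test_that("re-polarization flips major-allele counting and is stable", {
  d <- cbind(a = c(0L, 1L, 0L, 0L), b = c(2L, 2L, 2L, 1L))
  g <- make_geno(d)
  r1 <- repolarize_genotypes(g)
  expect_identical(r1$dosages[, "a"], g$dosages[, "a"])     # already minor
  expect_identical(unname(r1$dosages[, "b"]), c(0L, 0L, 0L, 1L))
  expect_identical(r1$snps$minor_allele, c("G", "A"))       # labels swapped
  expect_identical(repolarize_genotypes(r1), r1)            # stable
  # flipping back by hand recovers the input dosages
  r1$dosages[, "b"] <- 2L - r1$dosages[, "b"]
  expect_identical(r1$dosages, g$dosages)
})

test_that("Hardy-Weinberg exact test matches hand enumeration and the oracle", {
  expect_equal(hwe_exact_test(0, 2, 0), 1.0)
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(hwe_exact_test(5, 0, 0), 1.0)      # monomorphic
  expect_gt(hwe_exact_test(2500, 5000, 2500), 0.99)
  expect_error(hwe_exact_test(0, 0, 0), "total")
  expect_error(hwe_exact_test(-1, 1, 1), "nonnegative")
  # exhaustive agreement with the factorial-enumeration oracle, n <= 20
  for (n in 1:20)
    for (aa in 0:n)
      for (ab in 0:(n - aa)) {
        got <- hwe_exact_test(n - aa - ab, ab, aa)
        expect_equal(got, oracle_hwe(n - aa - ab, ab, aa),
                     tolerance = 1e-12,
                     label = sprintf("hwe(%d,%d,%d)", n - aa - ab, ab, aa))
      }
})

test_that("differential missingness is an exact 2x2 test with the right null behavior", {
  status <- rep(c("case", "control"), each = 10)
  missing <- c(rep(TRUE, 5), rep(FALSE, 15))
  # oracle: dhyper enumeration of the [[5,5],[0,10]] missing-by-status table
  expect_equal(differential_missingness_test(missing, status),
               oracle_fisher(matrix(c(5, 5, 0, 10), 2, byrow = TRUE)),
               tolerance = 1e-12)
  expect_equal(differential_missingness_test(rep(FALSE, 20), status), 1.0)
  # super-uniform under independence: exact tests satisfy P(p <= a) <= a
  set.seed(61)
  ps <- replicate(500, {
    miss <- runif(20) < 0.2
    differential_missingness_test(miss, status)
  })
  for (a in c(0.05, 0.2))
    expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / 500))
})

test_that("eSNP selection applies filters in order and reports first failure", {
  n_case <- 26; n_ctrl <- 24
  status <- rep(c("case", "control"), c(n_case, n_ctrl))
  good <- function() rep(c(0L, 1L, 2L), c(25, 21, 4))  # MAF .29, in HWE
  cols <- list(); meta_p <- c(); meta_or <- c(); meta_dir <- c()
  add <- function(k, col, p = 0.01, or = 1.2, dir = 1) {
    for (i in seq_len(k)) {
      cols[[length(cols) + 1]] <<- col
      meta_p <<- c(meta_p, p); meta_or <<- c(meta_or, or)
      meta_dir <<- c(meta_dir, dir)
    }
  }
  add(67, good())                                    # retained
  add(8, rep(0L, 50))                                # maf_qc (monomorphic)
  add(7, rep(c(0L, 2L), each = 25))                  # hwe: no heterozygotes
  miss_col <- c(rep(NA, 13), rep(0L, 9), rep(1L, 4), # missingness: 13 NAs,
                rep(c(0L, 1L, 2L), c(14, 8, 2)))     # all in cases
  add(6, miss_col)
  add(4, good(), p = 0.5)                            # replication p
  add(4, good(), or = 1.2, dir = -1)                 # direction mismatch
  add(4, rep(c(0L, 1L), c(45, 5)))                   # maf_analysis (MAF .05)
  d <- do.call(cbind, cols)
  g <- make_geno(d)
  g$snps$replication_p <- meta_p
  g$snps$risk_or <- meta_or
  g$snps$discovery_direction <- meta_dir
  sel <- select_esnps(g, status)
  expect_equal(ncol(sel$genotypes$dosages), 67)
  counts <- table(sel$report$status)
  expect_equal(as.integer(counts[c("retained", "maf_qc", "hwe",
                                   "missingness", "replication",
                                   "maf_analysis")]),
               c(67L, 8L, 7L, 6L, 8L, 4L))
  # single-SNP spot checks of the first-failed-filter logic
  expect_equal(sel$report$status[68], "maf_qc")
  expect_equal(sel$report$status[c(89, 93)], c("replication", "replication"))
  # replication threshold is strict: p = 0.06 fails, direction must match
  g2 <- make_geno(cbind(s1 = good()), replication_p = 0.06)
  expect_warning(sel2 <- select_esnps(g2, status), "no SNPs")
  expect_equal(sel2$report$status, "replication")
  # order invariance
  set.seed(7)
  perm <- sample(ncol(g$dosages))
  gp <- genotype_matrix(g$dosages[, perm, drop = FALSE], g$snps[perm, ])
  selp <- select_esnps(gp, status)
  expect_setequal(selp$genotypes$snps$id, sel$genotypes$snps$id)
  # empty result warns rather than errors
  g3 <- make_geno(cbind(s1 = rep(0L, 50)))
  expect_warning(select_esnps(g3, status), "no SNPs")
})
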