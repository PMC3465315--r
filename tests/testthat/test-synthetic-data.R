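test_that("spec constructors validate their invariants", {
  expect_error(locus_spec("L", "1", 0, 100), "n_snps")
  expect_error(locus_spec("L", "1", 2, 100, maf_range = c(0.1, 0.6)),
               "maf_range")
  expect_error(locus_spec("L", "1", 2, 100, ld_rho = 1), "ld_rho")
  expect_error(planted_effect("s", "p", 1, -1, "shared"), "inconsistent")
  expect_error(planted_effect("s", "p", 0, 0.5, "case_only"), "inconsistent")
  expect_silent(planted_effect("s", "p", -0.5, 0.4, "opposite"))
  expect_error(
    small_spec(effects = list(planted_effect("nope", "trans_0001", 1, 1,
                                             "shared"))),
    "unknown snp_id")
})

test_that("genotype simulation is deterministic with bounded dosages and laid-out metadata", {
  spec <- default_simulation_spec(seed = 7)
  g1 <- simulate_genotypes(spec)
  g2 <- simulate_genotypes(spec)
  expect_identical(g1, g2)
  expect_true(all(g1$dosages %in% 0:2))
  expect_identical(colnames(g1$dosages), spec_snp_ids(spec))
  expect_equal(ncol(g1$dosages), 67)
  mapt <- g1$snps[g1$snps$locus == "MAPT", ]
  expect_equal(mapt$position, 43900000 + (0:23) * 15000)
  expect_error(simulate_genotypes(small_spec(n_cases = 1, n_controls = 0)),
               "at least 2 samples")
})

test_that("LD follows ld_rho: independence at 0, near-perfect LD near 1", {
  big <- function(rho, nsnp) small_spec(
    n_cases = 1000, n_controls = 1000,
    loci = list(locus_spec("L", "1", nsnp, 1000000,
                           maf_range = c(0.3, 0.3), ld_rho = rho)),
    n_probes = 1, cis_probes_per_locus = 0, seed = 11)
  g0 <- simulate_genotypes(big(0, 5))
  r2 <- cor(g0$dosages)^2
  expect_lt(mean(r2[upper.tri(r2)]), 0.05)

  g9 <- simulate_genotypes(big(0.999, 2))
  expect_gt(cor(g9$dosages)[1, 2]^2, 0.9)
  # oracle: direct haplotype-pair simulation with the same latent model
  set.seed(99)
  z1 <- rnorm(4000)
  z2 <- 0.999 * z1 + sqrt(1 - 0.999^2) * rnorm(4000)
  h1 <- z1 < qnorm(0.3)
  h2 <- z2 < qnorm(0.3)
  d1 <- h1[1:2000] + h1[2001:4000]
  d2 <- h2[1:2000] + h2[2001:4000]
  expect_gt(cor(d1, d2)^2, 0.9)
})

test_that("simulated covariates follow the group-specific distributions", {
  spec <- small_spec(n_cases = 10000, n_controls = 10000, seed = 3)
  s <- simulate_covariates(spec)
  expect_identical(s, simulate_covariates(spec))
  ca <- s[s$status == "case", ]
  co <- s[s$status == "control", ]
  # age is untruncated: sample mean within 3 SE of the nominal group mean
  expect_lt(abs(mean(ca$age_at_death) - 77.31), 3 * 8.14 / 100)
  expect_lt(abs(mean(co$age_at_death) - 75.67), 3 * 11.73 / 100)
  # PMI is truncated at 0: compare to the closed-form truncated-normal mean
  tmean <- function(mu, sg) mu + sg * dnorm(-mu / sg) / (1 - pnorm(-mu / sg))
  expect_lt(abs(mean(ca$pmi) - tmean(6.57, 6.98)), 3 * sd(ca$pmi) / 100)
  expect_lt(abs(mean(co$pmi) - tmean(13.26, 10.86)), 3 * sd(co$pmi) / 100)
  # RIN truncation to [1, 10] is negligible at these parameters
  expect_lt(abs(mean(ca$rin) - 7.37), 3 * 0.89 / 100)
  expect_true(all(s$pmi >= 0))
  expect_true(all(s$rin >= 1 & s$rin <= 10))
})

test_that("degenerate covariate settings collapse as documented", {
  cp <- list(case = list(age = c(70, 0), pmi = c(5, 0), rin = c(7, 0)),
             control = list(age = c(60, 0), pmi = c(8, 0), rin = c(6, 0)))
  s <- simulate_covariates(small_spec(n_cases = 4, n_controls = 3,
                                      covariate_params = cp))
  expect_equal(unique(s$age_at_death[s$status == "case"]), 70)
  expect_equal(unique(s$pmi[s$status == "control"]), 8)
  only_cases <- simulate_covariates(small_spec(n_cases = 5, n_controls = 0))
  expect_equal(nrow(only_cases), 5)
  expect_true(all(only_cases$status == "case"))
})

test_that("expression model: null correlations, noiseless recovery, equicorrelation level", {
  loci <- list(locus_spec("L", "1", 2, 1000000))
  # no planted effects, independent probes: correlations center on zero
  sp <- small_spec(loci = loci, n_probes = 100, noise_sd = 1, probe_cor = 0,
                   seed = 5)
  g <- simulate_genotypes(sp)
  s <- simulate_covariates(sp)
  E <- simulate_expression(sp, g, s)
  expect_identical(E, simulate_expression(sp, g, s))
  r <- cor(t(E))
  expect_lt(abs(mean(r[upper.tri(r)])), 0.05)

  # planted shared effect, zero noise: stratified fits recover beta exactly
  sp0 <- small_spec(loci = loci, n_probes = 10, noise_sd = 0,
                    effects = list(planted_effect("L_snp01", "cis_L_1",
                                                  1, 1, "shared")),
                    seed = 6)
  g0 <- simulate_genotypes(sp0)
  s0 <- simulate_covariates(sp0)
  E0 <- simulate_expression(sp0, g0, s0)
  for (grp in c("case", "control")) {
    idx <- s0$status == grp
    fit <- stratified_effects(E0["cis_L_1", idx],
                              g0$dosages[idx, "L_snp01"],
                              covars_of(s0[idx, ]))
    expect_equal(fit$beta, 1, tolerance = 1e-8)
  }

  # factor-model equicorrelation: mean pairwise r^2 near the closed form
  sp2 <- small_spec(loci = loci, n_probes = 100, noise_sd = 1,
                    probe_cor = 0.11, seed = 8)
  E2 <- simulate_expression(sp2, simulate_genotypes(sp2),
                            simulate_covariates(sp2))
  r2 <- cor(t(E2))^2
  n <- ncol(E2)
  rho <- 0.11
  expected <- rho^2 + (1 - rho^2)^2 / (n - 1)
  expect_lt(abs(mean(r2[upper.tri(r2)]) - expected), 0.015)

  # dimension mismatch names the offending axis
  s_bad <- s0[1:10, ]
  expect_error(simulate_expression(sp0, g0, s_bad), "sample axis")
})

test_that("write_dataset round-trips losslessly through the readers", {
  sp <- small_spec(
    loci = list(locus_spec("A", "1", 3, 1000000),
                locus_spec("B", "2", 3, 2000000)),
    n_probes = 10, cis_probes_per_locus = 2, n_cases = 6, n_controls = 6,
    noise_sd = 0.5, seed = 10)
  d <- withr::local_tempdir()
  out <- write_dataset(sp, d)
  # 2 loci x 3 SNPs -> 6 MAP rows
  expect_length(readLines(out$map), 6)
  g <- read_genotypes(out$ped, out$map, out$snps)
  expect_identical(g$dosages, out$genotypes$dosages)
  expect_equal(g$snps, out$genotypes$snps)
  e <- read_expression_tsv(out$expression)
  expect_equal(e, 2^out$expression_log2, tolerance = 1e-12)
  s <- read_sample_tsv(out$samples)
  expect_equal(s, out$sample_table, tolerance = 1e-12)
  b <- read_probe_bed(out$probes)
  expect_equal(b, out$probe_annotations)
  # rewriting from the same spec is byte-identical
  d2 <- withr::local_tempdir()
  out2 <- write_dataset(sp, d2)
  expect_identical(readLines(out$ped), readLines(out2$ped))
  expect_identical(readLines(out$expression), readLines(out2$expression))
})

test_that("empty planted-effect list yields a header-only effects table", {
  sp <- small_spec(seed = 12)
  d <- withr::local_tempdir()
  out <- write_dataset(sp, d)
  eff <- read.delim(out$effects)
  expect_equal(nrow(eff), 0)
  expect_named(eff, c("snp_id", "probe_id", "beta_case", "beta_control",
                      "mode"))
})
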