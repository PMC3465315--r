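test_that("dominant coding maps dosages as defined", {
  expect_equal(dominant_code(c(0, 1, 2)), c(0, 1, 1))
  expect_equal(dominant_code(rep(0, 4)), rep(0, 4))
  expect_equal(dominant_code(c(1, NA, 2)), c(1, NA, 1))
  expect_error(dominant_code(c(0, 3)), "dosages")
})

test_that("2-df F statistic matches the normal-equations oracle on random designs", {
  set.seed(101)
  for (rep in 1:100) {
    n <- 12
    status <- rep(c("case", "control"), each = 6)
    d <- draw_dosage(n, status, maf = 0.4)
    cv <- data.frame(rin = rnorm(n, 7, 1), pmi = rnorm(n, 10, 4),
                     age = rnorm(n, 75, 8))
    y <- rnorm(n)
    fit <- fit_2df(y, d, status, cv)
    orc <- oracle_f_2df(y, pmin(d, 1), as.integer(status == "case"), cv)
    expect_equal(fit$f_stat, orc$f, tolerance = 1e-10)
    expect_equal(fit$p_2df, orc$p, tolerance = 1e-10)
  }
})

test_that("2-df test handles degenerate and exact-fit designs", {
  n <- 50
  status <- rep(c("case", "control"), c(26, 24))
  set.seed(11)
  cv <- data.frame(rin = rnorm(n, 7, 1), pmi = rnorm(n, 10, 4),
                   age = rnorm(n, 75, 8))
  d <- draw_dosage(n, status)
  # exact noiseless genotype signal
  fit <- fit_2df(2 * pmin(d, 1), d, status, cv)
  expect_equal(fit$p_2df, 0)
  expect_equal(fit$flags, "exact_fit")
  # constant genotype: flagged, no p-value
  fit0 <- fit_2df(rnorm(n), rep(0, n), status, cv)
  expect_equal(fit0$flags, "degenerate")
  expect_true(is.na(fit0$p_2df))
  # too few samples errors
  expect_error(fit_2df(rnorm(7), rep(c(0, 1), c(3, 4)), status[1:7],
                       cv[1:7, ]), "too few samples")
  # missing genotypes drop samples (complete-case)
  d2 <- d; d2[1:5] <- NA
  expect_equal(fit_2df(rnorm(n), d2, status, cv)$n_used, 45)
})

test_that("2-df p-values are uniform under the null (pure covariate signal)", {
  set.seed(202)
  n <- 50
  status <- rep(c("case", "control"), c(26, 24))
  ps <- replicate(1000, {
    cv <- data.frame(rin = rnorm(n, 7, 1), pmi = rnorm(n, 10, 4),
                     age = rnorm(n, 75, 8))
    y <- 0.15 * cv$rin - 0.01 * cv$pmi - 0.005 * cv$age + rnorm(n, sd = 0.3)
    fit_2df(y, draw_dosage(n, status), status, cv)$p_2df
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("stratified effects recover planted group-specific signs and magnitudes", {
  set.seed(303)
  n_case <- 26; n_ctrl <- 24
  status <- rep(c("case", "control"), c(n_case, n_ctrl))
  hits <- replicate(200, {
    d <- draw_dosage(n_case + n_ctrl, status)
    cv <- data.frame(rin = rnorm(50, 7, 1), pmi = rnorm(50, 10, 4),
                     age = rnorm(50, 75, 8))
    b <- ifelse(status == "case", 0.5, -0.5)
    y <- b * pmin(d, 1) + rnorm(50, sd = 0.05)
    fc <- stratified_effects(y[status == "case"], d[status == "case"],
                             cv[status == "case", ])
    fk <- stratified_effects(y[status == "control"], d[status == "control"],
                             cv[status == "control", ])
    fc$beta > 0 && fk$beta < 0
  })
  expect_gte(mean(hits), 0.95)
  # noiseless shared effect is recovered exactly in both strata
  d <- draw_dosage(50, status)
  cv <- data.frame(rin = rnorm(50, 7, 1), pmi = rnorm(50, 10, 4),
                   age = rnorm(50, 75, 8))
  y <- 1.0 * pmin(d, 1)
  for (grp in c("case", "control")) {
    idx <- status == grp
    expect_equal(stratified_effects(y[idx], d[idx], cv[idx, ])$beta, 1,
                 tolerance = 1e-8)
  }
  expect_error(stratified_effects(y[1:5], d[1:5], cv[1:5, ]), "too small")
  expect_equal(stratified_effects(y[1:10], rep(1, 10), cv[1:10, ])$flags,
               "x_constant")
})

test_that("joint test outpowers the marginal test for opposite-direction effects", {
  set.seed(404)
  n <- 50
  status <- rep(c("case", "control"), c(26, 24))
  for (b in c(0.3, 0.5, 0.8)) {
    res <- replicate(200, {
      d <- draw_dosage(n, status)
      cv <- data.frame(rin = rnorm(n, 7, 1), pmi = rnorm(n, 10, 4),
                       age = rnorm(n, 75, 8))
      eff <- ifelse(status == "case", b, -b)
      y <- eff * pmin(d, 1) + rnorm(n, sd = 0.5)
      c(p2 = fit_2df(y, d, status, cv)$p_2df,
        p1 = fit_marginal(y, d, status, cv)$p)
    })
    expect_gt(mean(res["p2", ] < 0.05), mean(res["p1", ] < 0.05))
  }
})

test_that("statistics are invariant to sample permutation and covariate rescaling", {
  set.seed(505)
  n <- 50
  status <- rep(c("case", "control"), c(26, 24))
  d <- draw_dosage(n, status)
  cv <- data.frame(rin = rnorm(n, 7, 1), pmi = rnorm(n, 10, 4),
                   age = rnorm(n, 75, 8))
  y <- 0.4 * pmin(d, 1) + rnorm(n, sd = 0.4)
  base <- fit_2df(y, d, status, cv)
  perm <- sample(n)
  permfit <- fit_2df(y[perm], d[perm], status[perm], cv[perm, ])
  expect_equal(permfit$f_stat, base$f_stat, tolerance = 1e-12)
  cv2 <- data.frame(rin = 10 * cv$rin - 3, pmi = cv$pmi / 7 + 2,
                    age = -2 * cv$age)
  expect_equal(fit_2df(y, d, status, cv2)$f_stat, base$f_stat,
               tolerance = 1e-10)
})

test_that("locus windows use the SNP span plus the flank, clipped at 1", {
  snps <- data.frame(locus = "L", chromosome = "4",
                     position = c(1000000, 1100000))
  w <- build_locus_windows(snps)
  expect_equal(c(w$window_start, w$window_end), c(750000, 1350000))
  w1 <- build_locus_windows(data.frame(locus = "S", chromosome = "1",
                                       position = 5000000))
  expect_equal(c(w1$window_start, w1$window_end), c(4750000, 5250000))
  wc <- build_locus_windows(data.frame(locus = "E", chromosome = "1",
                                       position = 100000))
  expect_equal(wc$window_start, 1)
  bad <- data.frame(locus = "X", chromosome = c("1", "2"),
                    position = c(1, 2))
  expect_error(build_locus_windows(bad), "chromosomes")
})

cis_fixture <- function(probe_rows) {
  samples <- make_samples(seed = 21)
  set.seed(22)
  d <- sapply(1:2, function(i) draw_dosage(50, samples$status))
  g <- make_geno(d, chromosome = "4",
                 positions = c(1000000L, 1100000L))
  probes <- do.call(rbind, probe_rows)
  E <- matrix(rnorm(nrow(probes) * 50, 8, 1), nrow(probes), 50,
              dimnames = list(probes$probe_id, samples$sample_id))
  list(g = g, samples = samples, probes = probes, E = E)
}

test_that("cis scan pairs every locus SNP with every window probe under the overlap rule", {
  mk <- function(id, chrom, start, end)
    data.frame(probe_id = id, chromosome = chrom, start = start, end = end,
               stringsAsFactors = FALSE)
  # window is [750000, 1350000]; half-open overlap convention
  fx <- cis_fixture(list(
    mk("in1", "4", 800000, 800060),
    mk("in2", "4", 1349999, 1350059),    # start < window_end: included
    mk("in3", "4", 700000, 750001),      # end > window_start: included
    mk("edge_out", "4", 650000, 750000), # end == window_start: excluded
    mk("wrong_chr", "5", 800000, 800060)))
  res <- run_cis_scan(fx$g, fx$E, fx$samples, fx$probes)
  expect_equal(nrow(res), 2 * 3)          # 2 SNPs x 3 in-window probes
  expect_setequal(unique(res$probe), c("in1", "in2", "in3"))
  expect_true(all(res$scan_type == "cis"))
  expect_true(all(c("f_stat", "p_2df", "beta_case", "p_control") %in%
                  names(res)))
  # probes missing from the annotation are skipped with a warning
  expect_warning(
    run_cis_scan(fx$g, rbind(fx$E, orphan = rnorm(50)), fx$samples,
                 fx$probes),
    "lack annotation")
})

test_that("trans scan covers all pairs and recovers a planted case-only effect", {
  fx <- cis_fixture(list(
    data.frame(probe_id = sprintf("p%02d", 1:10), chromosome = "9",
               start = (1:10) * 100000, end = (1:10) * 100000 + 60,
               stringsAsFactors = FALSE)))
  m3 <- fx$g$dosages[, c(1, 2, 1)]              # 3 SNPs
  colnames(m3) <- NULL
  g3 <- make_geno(m3)
  res <- run_trans_scan(g3, fx$E, fx$samples)
  expect_equal(nrow(res), 30)
  expect_true(all(res$scan_type == "trans"))

  empty <- make_geno(matrix(integer(0), 50, 0,
                            dimnames = list(fx$samples$sample_id, NULL)))
  expect_warning(res0 <- run_trans_scan(empty, fx$E, fx$samples), "no SNPs")
  expect_equal(nrow(res0), 0)

  # planted case-only trans effect is the top-ranked pair in >= 90% of reps
  set.seed(606)
  samples <- make_samples(seed = 23)
  top_hit <- replicate(100, {
    d <- sapply(1:5, function(i) draw_dosage(50, samples$status))
    g <- make_geno(d)
    E <- matrix(rnorm(40 * 50, 8, 0.3), 40, 50,
                dimnames = list(sprintf("pr%02d", 1:40),
                                samples$sample_id))
    b <- ifelse(samples$status == "case", 0.9, 0)
    E["pr07", ] <- E["pr07", ] + b * pmin(d[, 3], 1)
    res <- run_trans_scan(g, E, samples)
    top <- res[which.min(res$p_2df), ]
    top$snp == "snp03" && top$probe == "pr07"
  })
  expect_gte(mean(top_hit), 0.9)
})
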