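# Synthetic genotype / covariate / expression generator.
#
# The generator emulates the statistical structure the association analysis
# assumes: LD-blocked genotypes at a handful of risk loci, group-specific
# covariate distributions, and probe expression driven by covariates plus
# planted eQTLs that may be shared between groups, specific to one group, or
# opposite in direction. It writes the same text formats the pipeline reads.

#' Describe one simulated risk locus
#'
#' @param name Locus label (e.g. `"SNCA"`).
#' @param chromosome Chromosome label; a leading `"chr"` prefix is ignored.
#' @param n_snps Number of SNPs in the LD block (>= 1).
#' @param base_position 1-based bp position of the first SNP.
#' @param snp_spacing Distance in bp between adjacent SNPs.
#' @param maf_range Length-2 vector: per-SNP minor allele frequencies are
#'   drawn uniformly from this interval; must satisfy
#'   `0 < low <= high < 0.5`.
#' @param ld_rho AR(1) autocorrelation of the latent Gaussian used to induce
#'   LD between adjacent SNPs, in `[0, 1)`. Zero gives independent SNPs;
#'   values near 1 give near-perfect LD.
#' @return A `locus_spec` object.
#' @export
locus_spec <- function(name, chromosome, n_snps, base_position,
                       snp_spacing = 5000, maf_range = c(0.2, 0.45),
                       ld_rho = 0.8) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    .stopf("locus name must be a non-empty string")
  if (!.is_count(n_snps) || n_snps < 1) .stopf("n_snps must be >= 1")
  if (!.is_count(base_position) || base_position < 1)
    .stopf("base_position must be a positive integer")
  if (!.is_count(snp_spacing) || snp_spacing < 1)
    .stopf("snp_spacing must be a positive integer")
  if (length(maf_range) != 2L || !is.numeric(maf_range) ||
      maf_range[1] <= 0 || maf_range[2] >= 0.5 || maf_range[1] > maf_range[2])
    .stopf("maf_range must satisfy 0 < low <= high < 0.5")
  if (!is.numeric(ld_rho) || length(ld_rho) != 1L || ld_rho < 0 || ld_rho >= 1)
    .stopf("ld_rho must be in [0, 1)")
  structure(
    list(name = name, chromosome = .norm_chrom(chromosome),
         n_snps = as.integer(n_snps),
         base_position = as.integer(base_position),
         snp_spacing = as.integer(snp_spacing),
         maf_range = as.numeric(maf_range), ld_rho = as.numeric(ld_rho)),
    class = "locus_spec")
}

#' Describe one planted eQTL
#'
#' @param snp_id,probe_id Identifiers that must exist in the simulated
#'   genotype and expression data.
#' @param beta_case,beta_control Expression effect (log2 units per
#'   dominant-coded genotype) in cases and controls.
#' @param mode One of `"shared"`, `"case_only"`, `"control_only"`,
#'   `"opposite"`; checked for consistency with the sign/zero pattern of the
#'   two betas.
#' @return A `planted_effect` object.
#' @export
planted_effect <- function(snp_id, probe_id, beta_case, beta_control, mode) {
  mode <- match.arg(mode, c("shared", "case_only", "control_only", "opposite"))
  ok <- switch(mode,
    shared       = beta_case != 0 && beta_control != 0 &&
                   sign(beta_case) == sign(beta_control),
    case_only    = beta_case != 0 && beta_control == 0,
    control_only = beta_case == 0 && beta_control != 0,
    opposite     = beta_case != 0 && beta_control != 0 &&
                   sign(beta_case) != sign(beta_control))
  if (!ok)
    .stopf("mode '%s' is inconsistent with betas (%g, %g)",
           mode, beta_case, beta_control)
  structure(list(snp_id = snp_id, probe_id = probe_id,
                 beta_case = as.numeric(beta_case),
                 beta_control = as.numeric(beta_control), mode = mode),
            class = "planted_effect")
}

#' Full specification of a simulated case/control eSNP dataset
#'
#' @param n_cases,n_controls Sample sizes per group (total >= 2).
#' @param loci List of [locus_spec()] objects.
#' @param n_probes Total number of expression probes, including the
#'   `cis_probes_per_locus * length(loci)` probes placed inside the cis
#'   windows.
#' @param probe_cor Common pairwise correlation of the probe noise
#'   (single-factor equicorrelation model), in `[0, 1)`.
#' @param covariate_params Per-group `mean`/`sd` for age at death, PMI and
#'   RIN: a list with elements `case` and `control`, each a list of length-2
#'   numeric vectors `age`, `pmi`, `rin`.
#' @param covariate_betas Named numeric vector with elements `rin`, `pmi`,
#'   `age`: additive effects of the covariates on every probe (log2 units per
#'   covariate unit).
#' @param effects List of [planted_effect()] objects.
#' @param noise_sd Residual standard deviation on the log2 scale.
#' @param seed Integer seed; expanded internally into independent per-stage
#'   substreams so each stage is reproducible on its own.
#' @param cis_probes_per_locus Number of probes placed inside each locus
#'   window.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(n_cases, n_controls, loci, n_probes,
                            probe_cor = 0, covariate_params = NULL,
                            covariate_betas = c(rin = 0, pmi = 0, age = 0),
                            effects = list(), noise_sd = 1, seed = 1,
                            cis_probes_per_locus = 8) {
  if (!.is_count(n_cases) || !.is_count(n_controls))
    .stopf("n_cases and n_controls must be nonnegative integers")
  if (!is.list(loci) || !length(loci) ||
      !all(vapply(loci, inherits, logical(1), "locus_spec")))
    .stopf("loci must be a non-empty list of locus_spec objects")
  if (anyDuplicated(vapply(loci, `[[`, character(1), "name")))
    .stopf("locus names must be unique")
  if (!.is_count(n_probes) || n_probes < 1) .stopf("n_probes must be >= 1")
  if (!is.numeric(probe_cor) || probe_cor < 0 || probe_cor >= 1)
    .stopf("probe_cor must be in [0, 1)")
  if (!is.numeric(noise_sd) || noise_sd < 0) .stopf("noise_sd must be >= 0")
  if (!.is_count(cis_probes_per_locus))
    .stopf("cis_probes_per_locus must be a nonnegative integer")
  if (n_probes < cis_probes_per_locus * length(loci))
    .stopf("n_probes must cover the %d cis probes",
           cis_probes_per_locus * length(loci))
  if (is.null(covariate_params)) covariate_params <- .default_covariate_params()
  for (grp in c("case", "control")) {
    cp <- covariate_params[[grp]]
    if (is.null(cp) || !all(c("age", "pmi", "rin") %in% names(cp)))
      .stopf("covariate_params$%s must contain age, pmi and rin", grp)
    for (v in c("age", "pmi", "rin"))
      if (length(cp[[v]]) != 2L || cp[[v]][2] < 0)
        .stopf("covariate_params$%s$%s must be c(mean, sd) with sd >= 0",
               grp, v)
  }
  if (!all(c("rin", "pmi", "age") %in% names(covariate_betas)))
    .stopf("covariate_betas must be named with rin, pmi, age")
  if (!all(vapply(effects, inherits, logical(1), "planted_effect")))
    .stopf("effects must be a list of planted_effect objects")
  spec <- structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         loci = loci, n_probes = as.integer(n_probes),
         probe_cor = as.numeric(probe_cor),
         covariate_params = covariate_params,
         covariate_betas = covariate_betas[c("rin", "pmi", "age")],
         effects = effects, noise_sd = as.numeric(noise_sd),
         seed = as.integer(seed),
         cis_probes_per_locus = as.integer(cis_probes_per_locus)),
    class = "simulation_spec")
  sid <- spec_snp_ids(spec)
  pid <- spec_probe_ids(spec)
  for (e in effects) {
    if (!e$snp_id %in% sid)
      .stopf("planted effect references unknown snp_id '%s'", e$snp_id)
    if (!e$probe_id %in% pid)
      .stopf("planted effect references unknown probe_id '%s'", e$probe_id)
  }
  spec
}

# Brain-bank covariate distributions of the emulated cohort (per-group
# mean/sd for age at death [years], PMI [hours], RIN).
.default_covariate_params <- function() {
  list(case    = list(age = c(77.31, 8.14), pmi = c(6.57, 6.98),
                      rin = c(7.37, 0.89)),
       control = list(age = c(75.67, 11.73), pmi = c(13.26, 10.86),
                      rin = c(7.37, 0.86)))
}

#' Default simulated study: 5 risk loci, 67 SNPs, 26 cases / 24 controls
#'
#' The default dataset mirrors the structure of a postmortem-cortex eSNP
#' study of Parkinson disease risk loci: five LD blocks (SNCA and GAK on
#' chromosome 4, HLA on 6, MAPT on 17, RIT2 on 18) totalling 67 SNPs,
#' 26 case and 24 control samples with group-specific covariate
#' distributions, 1000 probes of which 8 per locus lie inside the cis
#' windows, and five planted eQTLs covering the shared, opposite-direction,
#' case-only and control-only patterns.
#'
#' @param seed Integer seed.
#' @return A [simulation_spec()].
#' @export
default_simulation_spec <- function(seed = 1) {
  loci <- list(
    locus_spec("SNCA", "4", 20, 90600000, snp_spacing = 10000, ld_rho = 0.85),
    locus_spec("GAK",  "4", 10,   900000, snp_spacing = 8000,  ld_rho = 0.80),
    locus_spec("HLA",  "6",  8, 32380000, snp_spacing = 12000, ld_rho = 0.70),
    locus_spec("MAPT", "17", 24, 43900000, snp_spacing = 15000, ld_rho = 0.90),
    locus_spec("RIT2", "18", 5, 40300000, snp_spacing = 10000, ld_rho = 0.60))
  effects <- list(
    planted_effect("HLA_snp02",  "cis_HLA_1",  1.06,  1.28, "shared"),
    planted_effect("MAPT_snp04", "cis_MAPT_1", 1.35,  1.38, "shared"),
    planted_effect("MAPT_snp08", "cis_MAPT_2", -0.56, 0.39, "opposite"),
    planted_effect("SNCA_snp03", "trans_0001", 0.86,  0.00, "case_only"),
    planted_effect("RIT2_snp01", "trans_0002", 0.00, -1.45, "control_only"))
  simulation_spec(
    n_cases = 26, n_controls = 24, loci = loci, n_probes = 1000,
    probe_cor = 0.11,
    covariate_betas = c(rin = 0.15, pmi = -0.01, age = -0.005),
    effects = effects, noise_sd = 0.3, seed = seed)
}

#' SNP and probe identifier universes of a simulation spec
#'
#' SNP ids are `<locus>_snp<k>`; probe ids are `cis_<locus>_<j>` for probes
#' placed inside locus windows and `trans_<k>` for the remainder.
#'
#' @param spec A [simulation_spec()].
#' @return Character vector of identifiers.
#' @export
spec_snp_ids <- function(spec) {
  unlist(lapply(spec$loci, function(l)
    sprintf("%s_snp%02d", l$name, seq_len(l$n_snps))), use.names = FALSE)
}

#' @rdname spec_snp_ids
#' @export
spec_probe_ids <- function(spec) {
  cis <- unlist(lapply(spec$loci, function(l)
    sprintf("cis_%s_%d", l$name, seq_len(spec$cis_probes_per_locus))),
    use.names = FALSE)
  n_trans <- spec$n_probes - length(cis)
  c(cis, sprintf("trans_%04d", seq_len(n_trans)))
}

.spec_sample_ids <- function(spec) {
  c(sprintf("case_%02d", seq_len(spec$n_cases)),
    sprintf("ctrl_%02d", seq_len(spec$n_controls)))
}

# One global seed expanded into per-stage substreams, so e.g. regenerating
# covariates does not perturb the genotype stream. Kept below 2^31 - 1.
.stage_seed <- function(seed, stage) {
  as.integer((abs(as.double(seed)) * 48271 + stage * 1013904223) %% 2147483647)
}

#' Simulate LD-blocked minor-allele dosages
#'
#' Each locus is generated from a latent AR(1) Gaussian per haplotype: for
#' SNP k with target minor allele frequency `q_k`, the haplotype carries the
#' minor allele when its latent value falls below `qnorm(q_k)`; the two
#' haplotypes of an individual are independent and summed into a dosage in
#' `{0, 1, 2}`. Adjacent-SNP LD increases monotonically with `ld_rho`.
#' Per-SNP metadata (position, locus, minor/major allele, external
#' replication p-value, risk odds ratio and discovery direction of effect)
#' is attached; simulated SNPs replicate the external association by
#' construction, mirroring a pre-selected risk-SNP panel.
#'
#' @param spec A [simulation_spec()].
#' @return A `genotype_matrix`: list with `dosages` (samples x SNPs integer
#'   matrix) and `snps` (data frame of per-SNP metadata).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_cases + spec$n_controls
  if (n < 2) .stopf("need at least 2 samples (n_cases + n_controls >= 2)")
  set.seed(.stage_seed(spec$seed, 1L))
  ids <- .spec_sample_ids(spec)
  dos <- NULL
  meta <- vector("list", length(spec$loci))
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(spec$loci)) {
    l <- spec$loci[[i]]
    m <- l$n_snps
    mafs <- runif(m, l$maf_range[1], l$maf_range[2])
    thr <- qnorm(mafs)
    hap <- function() {
      z <- matrix(rnorm(n * m), n, m)
      if (m > 1L && l$ld_rho > 0) {
        s <- sqrt(1 - l$ld_rho^2)
        for (k in 2:m) z[, k] <- l$ld_rho * z[, k - 1] + s * z[, k]
      }
      t(t(z) < thr) + 0L
    }
    d <- hap() + hap()
    colnames(d) <- sprintf("%s_snp%02d", l$name, seq_len(m))
    dos <- cbind(dos, d)
    alleles <- vapply(seq_len(m), function(k) sample(bases, 2), character(2))
    direction <- sample(c(-1L, 1L), m, replace = TRUE)
    meta[[i]] <- data.frame(
      id = colnames(d), chromosome = l$chromosome,
      position = l$base_position + (seq_len(m) - 1L) * l$snp_spacing,
      minor_allele = alleles[1, ], major_allele = alleles[2, ],
      locus = l$name,
      replication_p = runif(m, 0.001, 0.049),
      risk_or = exp(direction * runif(m, 0.1, 0.3)),
      discovery_direction = direction,
      stringsAsFactors = FALSE)
  }
  rownames(dos) <- ids
  genotype_matrix(dos, do.call(rbind, meta))
}

#' Construct a genotype matrix container
#'
#' @param dosages Samples x SNPs matrix of minor-allele dosages in
#'   `{0, 1, 2, NA}`, with sample ids as row names and SNP ids as column
#'   names.
#' @param snps Data frame of per-SNP metadata with at least columns `id`,
#'   `chromosome`, `position`, `locus`; rows aligned to the columns of
#'   `dosages`.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosages, snps) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)) ||
      (ncol(dosages) > 0L && is.null(colnames(dosages))))
    .stopf("dosages must have sample row names and SNP column names")
  if (ncol(dosages) == 0L && is.null(colnames(dosages)))
    colnames(dosages) <- character(0)
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) .stopf("dosages must lie in {0, 1, 2, NA}")
  req <- c("id", "chromosome", "position", "locus")
  if (!all(req %in% names(snps)))
    .stopf("snps metadata must contain columns %s", paste(req, collapse = ", "))
  cn <- colnames(dosages)
  if (is.null(cn)) cn <- character(0)
  if (!identical(as.character(snps$id), cn))
    .stopf("snps$id must match the dosage column names, in order")
  snps$chromosome <- .norm_chrom(snps$chromosome)
  rownames(snps) <- NULL
  structure(list(dosages = dosages, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%d loci)\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$snps$locus))))
  invisible(x)
}

# truncated normal via inverse-CDF; sd = 0 collapses to the mean
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Simulate the per-sample covariate table
#'
#' Age at death is Normal per group; PMI is Normal truncated at 0 hours; RIN
#' is Normal truncated to the instrument range `[1, 10]`. Truncation shifts
#' the realized PMI mean above the nominal group mean when the nominal sd is
#' large relative to the mean (see the methods vignette).
#'
#' @param spec A [simulation_spec()].
#' @return A data frame (`sample_table`) with columns `sample_id`, `status`
#'   (`"case"`/`"control"`), `age_at_death`, `pmi`, `rin`.
#' @export
simulate_covariates <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(.stage_seed(spec$seed, 2L))
  out <- lapply(c(case = "case", control = "control"), function(grp) {
    ng <- if (grp == "case") spec$n_cases else spec$n_controls
    cp <- spec$covariate_params[[grp]]
    data.frame(
      status = rep(grp, ng),
      age_at_death = rnorm(ng, cp$age[1], cp$age[2]),
      pmi = .rtruncnorm(ng, cp$pmi[1], cp$pmi[2], lower = 0),
      rin = .rtruncnorm(ng, cp$rin[1], cp$rin[2], lower = 1, upper = 10),
      stringsAsFactors = FALSE)
  })
  tab <- rbind(out$case, out$control)
  tab <- cbind(sample_id = .spec_sample_ids(spec), tab)
  rownames(tab) <- NULL
  tab
}

#' Simulate probe expression with covariate effects and planted eQTLs
#'
#' Probe values are built on the log2 scale as
#' `intercept + covariate effects + planted effect * dominant(genotype) +`
#' correlated Gaussian noise. The noise follows a single-factor
#' equicorrelation model: every pair of probes has correlation `probe_cor`.
#' Planted effects use `beta_case` for case samples and `beta_control` for
#' controls.
#'
#' @param spec A [simulation_spec()].
#' @param genotypes A `genotype_matrix` from [simulate_genotypes()].
#' @param samples A sample table from [simulate_covariates()].
#' @return Probes x samples numeric matrix on the log2 scale.
#' @export
simulate_expression <- function(spec, genotypes, samples) {
  stopifnot(inherits(spec, "simulation_spec"),
            inherits(genotypes, "genotype_matrix"))
  n <- nrow(samples)
  if (nrow(genotypes$dosages) != n)
    .stopf("sample axis mismatch: genotypes have %d samples, table has %d",
           nrow(genotypes$dosages), n)
  if (!identical(rownames(genotypes$dosages), as.character(samples$sample_id)))
    .stopf("sample axis mismatch: genotype row names differ from sample_id")
  set.seed(.stage_seed(spec$seed, 3L))
  p <- spec$n_probes
  pid <- spec_probe_ids(spec)
  intercept <- runif(p, 6, 12)          # baseline log2 intensity per probe
  cb <- spec$covariate_betas
  cov_eff <- cb[["rin"]] * samples$rin + cb[["pmi"]] * samples$pmi +
    cb[["age"]] * samples$age_at_death
  E <- matrix(intercept, p, n) + matrix(cov_eff, p, n, byrow = TRUE)
  rho <- spec$probe_cor
  f <- rnorm(n)                         # factor shared by all probes
  eps <- sqrt(rho) * matrix(f, p, n, byrow = TRUE) +
    sqrt(1 - rho) * matrix(rnorm(p * n), p, n)
  E <- E + spec$noise_sd * eps
  dimnames(E) <- list(pid, samples$sample_id)
  for (e in spec$effects) {
    x <- dominant_code(genotypes$dosages[, e$snp_id])
    b <- ifelse(samples$status == "case", e$beta_case, e$beta_control)
    E[e$probe_id, ] <- E[e$probe_id, ] + b * x
  }
  E
}

#' Deterministic probe genomic annotations for a simulation spec
#'
#' The `cis_probes_per_locus` probes of each locus are spread evenly across
#' the SNP span extended by 100 kb on each side (safely inside the default
#' 250 kb cis window); the remaining probes are placed far from every locus,
#' cycling over chromosomes 1-22. Probes are 60 bp (one array feature).
#'
#' @param spec A [simulation_spec()].
#' @return Data frame with columns `probe_id`, `chromosome`, `start`, `end`
#'   (0-based half-open, the package's internal convention).
#' @export
probe_annotations <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  cis <- lapply(spec$loci, function(l) {
    if (spec$cis_probes_per_locus == 0L) return(NULL)
    lo <- l$base_position
    hi <- l$base_position + (l$n_snps - 1L) * l$snp_spacing
    starts <- round(seq(max(0, lo - 100000), hi + 100000,
                        length.out = spec$cis_probes_per_locus))
    data.frame(
      probe_id = sprintf("cis_%s_%d", l$name,
                         seq_len(spec$cis_probes_per_locus)),
      chromosome = l$chromosome, start = starts, end = starts + 60L,
      stringsAsFactors = FALSE)
  })
  n_trans <- spec$n_probes - spec$cis_probes_per_locus * length(spec$loci)
  trans <- if (n_trans > 0) {
    k <- seq_len(n_trans)
    data.frame(probe_id = sprintf("trans_%04d", k),
               chromosome = as.character((k - 1L) %% 22L + 1L),
               start = 5000000L + 10000L * k,
               end = 5000000L + 10000L * k + 60L,
               stringsAsFactors = FALSE)
  }
  ann <- rbind(do.call(rbind, cis), trans)
  rownames(ann) <- NULL
  ann
}

#' Write a complete simulated dataset in the pipeline's input formats
#'
#' Generates genotypes, covariates and expression from `spec` and writes
#' PED/MAP genotypes, SNP metadata TSV, raw expression TSV (intensities,
#' `2^log2value`), sample TSV, probe BED and a planted-effects TSV (header
#' only when no effects are planted). All files round-trip losslessly
#' through the package readers.
#'
#' @param spec A [simulation_spec()].
#' @param outdir Output directory, created if needed.
#' @return Invisibly, a named list of file paths plus the in-memory objects
#'   (`genotypes`, `samples`, `expression`, `probes`).
#' @export
write_dataset <- function(spec, outdir) {
  stopifnot(inherits(spec, "simulation_spec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) .stopf("cannot create output directory '%s'", outdir)
  g <- simulate_genotypes(spec)
  s <- simulate_covariates(spec)
  e <- simulate_expression(spec, g, s)
  ann <- probe_annotations(spec)
  paths <- list(
    ped = file.path(outdir, "genotypes.ped"),
    map = file.path(outdir, "genotypes.map"),
    snps = file.path(outdir, "snps.tsv"),
    expression = file.path(outdir, "expression.tsv"),
    samples = file.path(outdir, "samples.tsv"),
    probes = file.path(outdir, "probes.bed"),
    effects = file.path(outdir, "effects.tsv"))
  write_ped_map(g, s, paths$ped, paths$map)
  write_snp_metadata(g$snps, paths$snps)
  write_expression_tsv(2^e, paths$expression)
  write_sample_tsv(s, paths$samples)
  write_probe_bed(ann, paths$probes)
  eff <- if (length(spec$effects)) {
    do.call(rbind, lapply(spec$effects, function(x)
      data.frame(snp_id = x$snp_id, probe_id = x$probe_id,
                 beta_case = x$beta_case, beta_control = x$beta_control,
                 mode = x$mode, stringsAsFactors = FALSE)))
  } else {
    data.frame(snp_id = character(), probe_id = character(),
               beta_case = numeric(), beta_control = numeric(),
               mode = character(), stringsAsFactors = FALSE)
  }
  write.table(eff, paths$effects, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paths, list(genotypes = g, sample_table = s,
                          expression_log2 = e, probe_annotations = ann)))
}
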