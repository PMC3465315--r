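# Programmatic fixtures shared across test files.

# covariate table for n_case + n_control samples
make_samples <- function(n_case = 26, n_control = 24, seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    status = rep(c("case", "control"), c(n_case, n_control)),
    age_at_death = rnorm(n, 76, 9),
    pmi = abs(rnorm(n, 10, 6)),
    rin = pmin(pmax(rnorm(n, 7.4, 0.9), 1), 10),
    stringsAsFactors = FALSE)
}

covars_of <- function(samples) samples[, c("rin", "pmi", "age_at_death")]

# genotype_matrix around a plain dosage matrix, with metadata defaults
make_geno <- function(dosages, locus = "L1", chromosome = "1",
                      positions = NULL, replication_p = 0.01, risk_or = 1.2,
                      discovery_direction = 1) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (is.null(colnames(dosages)) && m > 0)
    colnames(dosages) <- sprintf("snp%02d", seq_len(m))
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("s%03d", seq_len(nrow(dosages)))
  if (m == 0)
    return(genotype_matrix(dosages, data.frame(
      id = character(), chromosome = character(), position = integer(),
      minor_allele = character(), major_allele = character(),
      locus = character(), replication_p = numeric(), risk_or = numeric(),
      discovery_direction = integer(), stringsAsFactors = FALSE)))
  snps <- data.frame(
    id = colnames(dosages),
    chromosome = rep_len(chromosome, m),
    position = positions %||% (1000000L + seq_len(m) * 5000L),
    minor_allele = "G", major_allele = "A",
    locus = rep_len(locus, m),
    replication_p = rep_len(replication_p, m),
    risk_or = rep_len(risk_or, m),
    discovery_direction = rep_len(discovery_direction, m),
    stringsAsFactors = FALSE)
  genotype_matrix(dosages, snps)
}

# a polymorphic dominant-coded-friendly dosage vector (resampled until both
# strata vary, so the interaction design has full rank)
draw_dosage <- function(n, status, maf = 0.3) {
  repeat {
    d <- rbinom(n, 2, maf)
    x <- pmin(d, 1)
    if (var(x[status == "case"]) > 0 && var(x[status == "control"]) > 0)
      return(d)
  }
}

# four-probe filter fixture: A fails detectability in both groups, B only in
# controls, C is flagged on every array, D is clean
toy_raw <- function() {
  vals <- matrix(100, 4, 4,
                 dimnames = list(c("A", "B", "C", "D"),
                                 c("c1", "c2", "k1", "k2")))
  grp <- c("case", "case", "control", "control")
  det <- matrix(TRUE, 4, 4, dimnames = dimnames(vals))
  det["A", ] <- FALSE
  det["B", c("k1", "k2")] <- FALSE
  fl <- matrix(FALSE, 4, 4, dimnames = dimnames(vals))
  fl["C", ] <- TRUE
  raw_expression(vals, flags = list(popn_outlier = fl), detectable = det,
                 sample_group = grp)
}

# small simulation spec builder used by several files
small_spec <- function(..., loci = list(locus_spec("L", "1", 2, 1000000)),
                       n_probes = 10, cis_probes_per_locus = 1,
                       n_cases = 26, n_controls = 24, seed = 1) {
  simulation_spec(n_cases = n_cases, n_controls = n_controls, loci = loci,
                  n_probes = n_probes,
                  cis_probes_per_locus = cis_probes_per_locus, seed = seed,
                  ...)
}
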