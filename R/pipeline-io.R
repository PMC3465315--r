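# Readers and writers for the pipeline's text formats: PLINK-style PED/MAP
# genotypes, SNP metadata TSV, expression TSV (probes x samples, '.' for
# missing), sample covariate TSV, per-probe-per-array flag sidecar TSV, and
# probe BED. MAP/metadata positions are 1-based; BED is 0-based half-open
# and kept that way internally.

#' Read PLINK-style text genotypes into a genotype matrix
#'
#' Alleles are converted to minor-allele dosages using the `minor_allele` /
#' `major_allele` columns of the SNP metadata; `"0 0"` becomes a missing
#' call. PED columns are FID, IID, PAT, MAT, SEX, PHENO followed by two
#' allele columns per SNP; MAP columns are chromosome, id, cM, bp.
#'
#' @param ped_path,map_path,metadata_path Paths to the PED, MAP and SNP
#'   metadata TSV files (the latter from [write_snp_metadata()], with
#'   columns `id`, `minor_allele`, `major_allele`, `locus`,
#'   `replication_p`, `risk_or`, `discovery_direction`).
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(ped_path, map_path, metadata_path) {
  map <- read.delim(map_path, header = FALSE, colClasses = "character")
  if (ncol(map) != 4L) .stopf("MAP file must have 4 columns")
  names(map) <- c("chromosome", "id", "cm", "position")
  map$position <- as.integer(map$position)
  if (anyDuplicated(map$id))
    .stopf("duplicate SNP id in MAP: %s", map$id[duplicated(map$id)][1])
  meta <- read_snp_metadata(metadata_path)
  missing_meta <- setdiff(map$id, meta$id)
  if (length(missing_meta))
    .stopf("SNPs absent from metadata: %s",
           paste(utils::head(missing_meta, 3), collapse = ", "))
  meta <- meta[match(map$id, meta$id), ]
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n_snps <- nrow(map)
  ids <- character(length(lines))
  dos <- matrix(NA_integer_, length(lines), n_snps,
                dimnames = list(NULL, map$id))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * n_snps)
      .stopf("PED line %d has %d fields, expected %d (PED/MAP mismatch)",
             i, length(f), 6L + 2L * n_snps)
    ids[i] <- f[2]
    a1 <- f[seq(7L, by = 2L, length.out = n_snps)]
    a2 <- f[seq(8L, by = 2L, length.out = n_snps)]
    for (j in seq_len(n_snps)) {
      alleles <- c(a1[j], a2[j])
      if (all(alleles == "0")) next            # missing call
      valid <- c(meta$minor_allele[j], meta$major_allele[j])
      if (!all(alleles %in% valid))
        .stopf("PED line %d, SNP %s: allele '%s' not in {%s, 0}",
               i, map$id[j], setdiff(alleles, valid)[1],
               paste(valid, collapse = ", "))
      dos[i, j] <- sum(alleles == meta$minor_allele[j])
    }
  }
  if (anyDuplicated(ids))
    .stopf("duplicate sample id in PED at line %d",
           which(duplicated(ids))[1])
  rownames(dos) <- ids
  snps <- data.frame(id = map$id, chromosome = .norm_chrom(map$chromosome),
                     position = map$position,
                     minor_allele = meta$minor_allele,
                     major_allele = meta$major_allele, locus = meta$locus,
                     replication_p = meta$replication_p,
                     risk_or = meta$risk_or,
                     discovery_direction = meta$discovery_direction,
                     stringsAsFactors = FALSE)
  genotype_matrix(dos, snps)
}

#' Write a genotype matrix as PED/MAP
#'
#' @param genotypes A `genotype_matrix` whose metadata includes
#'   `minor_allele` and `major_allele`.
#' @param samples Sample table supplying case/control status for the PED
#'   phenotype column (1 = control, 2 = case); sex is written as 1
#'   (all-male cohort emulated by the generator).
#' @param ped_path,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(genotypes, samples, ped_path, map_path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  s <- genotypes$snps
  if (!all(c("minor_allele", "major_allele") %in% names(s)))
    .stopf("metadata must include minor_allele and major_allele")
  map <- data.frame(s$chromosome, s$id, 0, s$position)
  write.table(map, map_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ids <- rownames(genotypes$dosages)
  if (!identical(as.character(samples$sample_id), ids))
    .stopf("sample table must align with genotype rows")
  pheno <- ifelse(samples$status == "case", 2L, 1L)
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    d <- genotypes$dosages[i, ]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, s$minor_allele,
                                       s$major_allele))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2, s$minor_allele,
                                       s$major_allele))
    writeLines(paste(c(ids[i], ids[i], "0", "0", "1", pheno[i],
                       as.vector(rbind(a1, a2))), collapse = " "), con)
  }
  invisible(c(ped = ped_path, map = map_path))
}

#' Read and write the SNP metadata TSV
#'
#' Columns: `id`, `minor_allele`, `major_allele`, `locus`, `replication_p`
#' (replication-sample association p-value), `risk_or` (discovery odds
#' ratio), `discovery_direction` (sign of the discovery effect).
#'
#' @param path File path.
#' @return `read_snp_metadata()`: a data frame; `write_snp_metadata()`: the
#'   path, invisibly.
#' @export
read_snp_metadata <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c(id = "character"))
  req <- c("id", "minor_allele", "major_allele", "locus", "replication_p",
           "risk_or", "discovery_direction")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    .stopf("SNP metadata lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(meta$replication_p <= 0 | meta$replication_p > 1))
    .stopf("replication_p must lie in (0, 1]")
  if (any(meta$risk_or <= 0)) .stopf("risk_or must be > 0")
  meta
}

#' @param snps SNP metadata data frame.
#' @rdname read_snp_metadata
#' @export
write_snp_metadata <- function(snps, path) {
  cols <- c("id", "minor_allele", "major_allele", "locus", "replication_p",
            "risk_or", "discovery_direction")
  write.table(snps[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read and write the expression TSV
#'
#' First column `probe_id`, remaining columns one per sample; missing
#' values are written as `"."`. Probe ids may repeat (replicate probes).
#'
#' @param path File path.
#' @return `read_expression_tsv()`: numeric matrix with probe row names and
#'   sample column names.
#' @export
read_expression_tsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE,
                    colClasses = "character")
  if (names(tab)[1] != "probe_id")
    .stopf("expression TSV must start with a probe_id column")
  ids <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  m[m == "."] <- NA
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' @param values Probes x samples matrix.
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(values, path) {
  m <- format(values, digits = 15, trim = TRUE, scientific = FALSE)
  m[is.na(values)] <- "."
  tab <- cbind(probe_id = rownames(values), as.data.frame(m))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write the sample covariate TSV
#'
#' Columns: `sample_id`, `status` (`case`/`control`), `age_at_death`
#' (years), `pmi` (hours), `rin`.
#'
#' @param path File path.
#' @return `read_sample_tsv()`: the sample table data frame.
#' @export
read_sample_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(sample_id = "character"))
  req <- c("sample_id", "status", "age_at_death", "pmi", "rin")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    .stopf("sample TSV lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample_id)) .stopf("duplicate sample ids")
  if (any(is.na(tab$status)) || !all(tab$status %in% c("case", "control")))
    .stopf("status must be 'case' or 'control' with no missing values")
  tab
}

#' @param samples Sample table data frame.
#' @rdname read_sample_tsv
#' @export
write_sample_tsv <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write the flag sidecar TSV
#'
#' Long format with columns `probe`, `sample`, `flag`, `value` (0/1); only
#' nonzero entries need be present. `read_flags_tsv()` expands the table
#' into the list-of-logical-matrices layout [raw_expression()] expects.
#'
#' @param path File path.
#' @param probe_ids,sample_ids Row/column universe for the expanded
#'   matrices.
#' @return `read_flags_tsv()`: list with elements `flags` (named list of
#'   logical matrices) and `detectable` (logical matrix; `TRUE` unless a
#'   `not_detectable` entry is present).
#' @export
read_flags_tsv <- function(path, probe_ids, sample_ids) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(probe = "character",
                                   sample = "character"))
  req <- c("probe", "sample", "flag", "value")
  if (!all(req %in% names(tab)))
    .stopf("flag TSV must have columns %s", paste(req, collapse = ", "))
  known <- c(.FLAG_NAMES, "not_detectable")
  if (!all(tab$flag %in% known))
    .stopf("unknown flag name(s): %s",
           paste(unique(setdiff(tab$flag, known)), collapse = ", "))
  blank <- matrix(FALSE, length(probe_ids), length(sample_ids),
                  dimnames = list(probe_ids, sample_ids))
  flags <- setNames(rep(list(blank), length(.FLAG_NAMES)), .FLAG_NAMES)
  detectable <- !blank
  for (i in seq_len(nrow(tab))) {
    if (!tab$probe[i] %in% probe_ids || !tab$sample[i] %in% sample_ids)
      .stopf("flag row %d references unknown probe/sample", i)
    on <- tab$value[i] != 0
    if (tab$flag[i] == "not_detectable")
      detectable[tab$probe[i], tab$sample[i]] <- !on
    else
      flags[[tab$flag[i]]][tab$probe[i], tab$sample[i]] <- on
  }
  list(flags = flags, detectable = detectable)
}

#' @param raw A [raw_expression()] object whose nonzero flag /
#'   non-detectable entries are serialized.
#' @rdname read_flags_tsv
#' @export
write_flags_tsv <- function(raw, path) {
  stopifnot(inherits(raw, "raw_expression"))
  rows <- list()
  emit <- function(mat, nm) {
    w <- which(mat, arr.ind = TRUE)
    if (!nrow(w)) return(NULL)
    data.frame(probe = rownames(mat)[w[, 1]],
               sample = colnames(mat)[w[, 2]],
               flag = nm, value = 1L, stringsAsFactors = FALSE)
  }
  for (nm in names(raw$flags))
    rows[[length(rows) + 1L]] <- emit(raw$flags[[nm]], nm)
  rows[[length(rows) + 1L]] <- emit(!raw$detectable, "not_detectable")
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(probe = character(), sample = character(),
                      flag = character(), value = integer())
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read probe annotations from BED
#'
#' BED's 0-based half-open coordinates are honored and kept as the internal
#' convention; the name column is the probe id; strand, if present, is
#' ignored (eQTL windows are strand-agnostic).
#'
#' @param path BED file path (>= 4 columns: chrom, start, end, name).
#' @return Data frame with columns `probe_id`, `chromosome`, `start`,
#'   `end`.
#' @export
read_probe_bed <- function(path) {
  tab <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 4L)
    .stopf("BED must have at least 4 columns (chrom, start, end, name)")
  start <- as.integer(tab[[2]])
  end <- as.integer(tab[[3]])
  bad <- which(!(start < end))
  if (length(bad))
    .stopf("BED line %d: start >= end", bad[1])
  name <- tab[[4]]
  if (any(is.na(name) | !nzchar(name)))
    .stopf("BED line %d: missing name field",
           which(is.na(name) | !nzchar(name))[1])
  if (anyDuplicated(name))
    .stopf("duplicate probe id in BED: %s", name[duplicated(name)][1])
  data.frame(probe_id = name, chromosome = .norm_chrom(tab[[1]]),
             start = start, end = end, stringsAsFactors = FALSE)
}

#' @param probes Probe annotation data frame (`probe_id`, `chromosome`,
#'   `start`, `end`, 0-based half-open).
#' @rdname read_probe_bed
#' @export
write_probe_bed <- function(probes, path) {
  write.table(probes[, c("chromosome", "start", "end", "probe_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
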