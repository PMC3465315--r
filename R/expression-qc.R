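# Probe-level QC for one-color microarray expression:
# detectability/flag filtering, replicate collapse, quantile normalization,
# and a simple correlation-distance screen for outlier arrays.

.FLAG_NAMES <- c("well_above_bg", "saturated", "popn_outlier",
                 "nonunif_outlier")

#' Bundle raw expression intensities with their QC masks
#'
#' @param values Probes x samples matrix of nonnegative intensities, with
#'   probe ids as row names and sample ids as column names.
#' @param flags Named list of logical matrices (same shape as `values`), one
#'   per feature-extraction flag in
#'   `c("well_above_bg", "saturated", "popn_outlier", "nonunif_outlier")`;
#'   `TRUE` means the exclusion condition holds for that probe on that array
#'   (for `well_above_bg`, that the signal is *not* well above background).
#'   Missing flags default to all-`FALSE`.
#' @param detectable Logical matrix, `TRUE` where the probe's value lies
#'   within the detectable spike-in range on that array. Defaults to
#'   all-`TRUE`. Supplied as data because the spike-in control probes
#'   themselves are platform-specific and out of scope.
#' @param sample_group Character/factor of `"case"`/`"control"` per array.
#' @return A `raw_expression` object.
#' @export
raw_expression <- function(values, flags = NULL, detectable = NULL,
                           sample_group) {
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) .stopf("intensities must be >= 0")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("values must have probe row names and sample column names")
  if (length(sample_group) != ncol(values))
    .stopf("sample_group must have one entry per array")
  sample_group <- as.character(sample_group)
  if (!all(sample_group %in% c("case", "control")))
    .stopf("sample_group entries must be 'case' or 'control'")
  blank <- matrix(FALSE, nrow(values), ncol(values),
                  dimnames = dimnames(values))
  fl <- setNames(rep(list(blank), length(.FLAG_NAMES)), .FLAG_NAMES)
  for (nm in names(flags)) {
    if (!nm %in% .FLAG_NAMES)
      .stopf("unknown flag '%s' (expected one of %s)", nm,
             paste(.FLAG_NAMES, collapse = ", "))
    f <- as.matrix(flags[[nm]])
    if (!identical(dim(f), dim(values)))
      .stopf("flag '%s' must have the same shape as values", nm)
    storage.mode(f) <- "logical"
    dimnames(f) <- dimnames(values)
    fl[[nm]] <- f
  }
  if (is.null(detectable)) detectable <- !blank
  detectable <- as.matrix(detectable)
  if (!identical(dim(detectable), dim(values)))
    .stopf("detectable must have the same shape as values")
  storage.mode(detectable) <- "logical"
  dimnames(detectable) <- dimnames(values)
  structure(list(values = values, flags = fl, detectable = detectable,
                 sample_group = sample_group),
            class = "raw_expression")
}

#' Filter probes on detectability and feature flags
#'
#' A probe is removed iff (a) its fraction of non-detectable arrays exceeds
#' `detect_frac` in the control arrays *and* in the case arrays, or (b) any
#' single feature flag fires in more than `flag_frac` of all arrays. Both
#' comparisons are strict (`>`), so e.g. `flag_frac = 1` disables the flag
#' rule. The detectability rule is two-sided by design: a probe reliably
#' detected in one group is kept even if undetectable in the other, since a
#' group-restricted transcript is itself of interest.
#'
#' @param raw A [raw_expression()] object; both groups must be present.
#' @param detect_frac,flag_frac Fraction thresholds (defaults 0.5 and 0.75).
#' @return Character vector of retained probe ids, in input order.
#' @export
filter_probes <- function(raw, detect_frac = 0.5, flag_frac = 0.75) {
  stopifnot(inherits(raw, "raw_expression"))
  if (!.is_prob(detect_frac) || !.is_prob(flag_frac))
    .stopf("detect_frac and flag_frac must be fractions in [0, 1]")
  is_case <- raw$sample_group == "case"
  if (sum(is_case) == 0L || sum(!is_case) == 0L)
    .stopf("both case and control arrays are required")
  nondet <- !raw$detectable
  frac_case <- rowMeans(nondet[, is_case, drop = FALSE])
  frac_ctrl <- rowMeans(nondet[, !is_case, drop = FALSE])
  drop_detect <- frac_case > detect_frac & frac_ctrl > detect_frac
  drop_flag <- Reduce(`|`, lapply(raw$flags, function(f)
    rowMeans(f) > flag_frac))
  rownames(raw$values)[!(drop_detect | drop_flag)]
}

#' Collapse replicate probes by per-sample median
#'
#' Rows sharing a probe id are replaced by their column-wise median; probe
#' order follows the first occurrence of each id.
#'
#' @param values Probes x samples numeric matrix.
#' @param probe_ids Character vector of probe ids, one per row (may contain
#'   duplicates). Defaults to `rownames(values)`.
#' @return Matrix with unique probe ids as row names.
#' @export
collapse_replicates <- function(values, probe_ids = rownames(values)) {
  values <- as.matrix(values)
  if (length(probe_ids) != nrow(values))
    .stopf("probe_ids must have one entry per row")
  if (!anyDuplicated(probe_ids)) {
    rownames(values) <- probe_ids
    return(values)
  }
  uid <- unique(probe_ids)
  out <- matrix(NA_real_, length(uid), ncol(values),
                dimnames = list(uid, colnames(values)))
  dup <- unique(probe_ids[duplicated(probe_ids)])
  single <- setdiff(uid, dup)
  out[single, ] <- values[match(single, probe_ids), , drop = FALSE]
  for (id in dup)
    out[id, ] <- apply(values[probe_ids == id, , drop = FALSE], 2, median)
  out
}

#' Quantile normalize across arrays, then log2 transform
#'
#' Classic quantile normalization: each column's sorted values are replaced
#' by the row-wise mean of all columns' sorted values, assigned back by
#' rank. Tied values within a column receive the mean of the normalized
#' values at the tied ranks. The result is log2 transformed, so every
#' column shares an identical empirical distribution on the log2 scale.
#'
#' @param values Probes x samples matrix of strictly positive intensities.
#' @return Matrix of the same shape, quantile normalized and log2
#'   transformed.
#' @export
quantile_normalize_log2 <- function(values) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values <= 0))
    .stopf("all intensities must be positive and finite before log2")
  ref <- rowMeans(apply(values, 2, sort))
  out <- apply(values, 2, function(x) {
    v <- numeric(length(x))
    v[order(x)] <- ref
    ave(v, x)                       # ties -> mean over the tied ranks
  })
  dimnames(out) <- dimnames(values)
  log2(out)
}

#' Flag outlier arrays by mean inter-array correlation distance
#'
#' For each array, the mean distance to all other arrays is computed as
#' `1 - Pearson r` of the (typically log2) intensity columns; arrays whose
#' mean distance exceeds `median + k * mad` are flagged. This is a single
#' documented heuristic standing in for a full array-quality report, and can
#' be disabled in the pipeline.
#'
#' @param values Probes x samples matrix (log2 scale recommended); at least
#'   3 arrays.
#' @param k Multiplier on the MAD (default 3); `Inf` disables flagging.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
detect_outlier_arrays <- function(values, k = 3) {
  values <- as.matrix(values)
  if (ncol(values) < 3) .stopf("need at least 3 arrays")
  if (!is.numeric(k) || length(k) != 1L || k < 0)
    .stopf("k must be a nonnegative number")
  if (!is.finite(k)) return(character(0))
  r <- cor(values)
  d <- (rowSums(1 - r)) / (ncol(values) - 1)   # diag contributes 0
  cutoff <- median(d) + k * mad(d)
  colnames(values)[d > cutoff]
}
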