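---
title: "Methods: case/control-aware eSNP mapping"
author: "esnpscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case/control-aware eSNP mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esnpscan)
```

## The association model

`esnpscan` tests disease-risk SNPs as expression QTLs in a small
case/control cohort. The response for each test is one probe's quantile
normalized, log2 expression across samples; the predictor of interest is a
dominant-coded genotype $X \in \{0, 1\}$ (any copy of the minor allele).
Dominant coding is the right choice at these sample sizes: with roughly 25
samples per group, minor-allele homozygotes are too rare for an additive or
genotypic model to be stable, and collapsing them with heterozygotes avoids
leverage points that inflate type-I error for quantitative traits.

The central statistic is a 2-degree-of-freedom joint test. The full model

$$y = \beta_0 + \beta_1 X + \beta_2 D + \beta_3 XD
      + \beta_4\,\mathrm{RIN} + \beta_5\,\mathrm{PMI}
      + \beta_6\,\mathrm{age} + \varepsilon$$

is compared with the reduced model lacking $X$ and $XD$ by a nested-model
F-test with 2 numerator and $n - 7$ denominator degrees of freedom. The
joint test is simultaneously sensitive to an overall genotype effect and to
a difference in that effect between cases ($D = 1$) and controls, so
disease-specific and opposite-direction eQTLs — which a marginal
genotype-only test averages toward zero — remain detectable.
`fit_marginal()` implements that 1-df marginal test precisely so the power
ordering can be measured rather than asserted; the acceptance suite
compares the two on planted opposite-direction effects.

Two modelling choices deserve a note:

* **F rather than asymptotic $\chi^2$.** At $n \approx 50$ the
  finite-sample F reference differs materially from $\chi^2_2/2$; the F
  form is exact under Gaussian errors and conservative-leaning otherwise.
* **Ordinary least squares throughout.** Fits use QR decompositions of the
  explicit design matrices; for scans, one QR per SNP serves every probe
  simultaneously (the response enters only through matrix products), which
  is what keeps a 67,000-pair trans scan to seconds.

Stratified effect estimates refit $y \sim X + \mathrm{RIN} + \mathrm{PMI} +
\mathrm{age}$ within each group, retaining all covariates so the per-group
estimates are adjusted exactly as the joint model is. Groups of five or
fewer samples are refused (the model has five parameters).

Missing data are handled per pair, complete-case: samples missing the
genotype, the response or any covariate are dropped for that test, and
`n_used` is reported per result row. Designs that lose rank in the used
samples (genotype constant overall, or constant within a stratum in a way
that aliases the interaction) are flagged `degenerate` with no p-value
rather than silently dropped. A residual sum of squares below $10^{-10}$ of
the total sum of squares is treated as an exact fit: the p-value is
reported as 0 with an `exact_fit` flag, which arises only in noiseless
synthetic data.

## Covariates

RIN (RNA integrity number, 1–10), PMI (postmortem interval, hours) and age
at death (years) are the adjustment set. These are the standard technical
and demographic confounders of postmortem expression: degraded RNA and long
intervals globally depress measured intensity, and both can differ
systematically between cases and controls (the generator's defaults give
controls a PMI roughly twice that of cases for exactly this reason). Tissue
pH is deliberately absent: it is nearly collinear with RIN, and including
both destabilizes a 7-parameter model at $n = 50$. Sex is not modelled —
the emulated cohort is single-sex.

## Probe-level QC

`filter_probes()` removes a probe iff

* its fraction of non-detectable arrays exceeds `detect_frac` (default
  0.5) in the control arrays *and* in the case arrays, or
* any single feature flag (not well above background, saturated,
  population outlier, non-uniformity outlier) fires in more than
  `flag_frac` (default 0.75) of all arrays.

Both comparisons are strict inequalities, read literally from the
"more than 50% / more than 75%" convention, so `flag_frac = 1` disables
the flag rule. The two-group AND in the detectability rule is intentional:
a transcript reliably detected only in one group is itself a potential
disease signal. Each flag is tested separately ("any of the flags"), not
pooled. The detectable mask is supplied as data rather than derived from
spike-in control probes, which are platform-specific and out of scope.

Replicate probes are collapsed to their per-sample median; quantile
normalization then forces every array onto the common distribution (each
column's sorted values are replaced by the row-wise mean of all columns'
sorted values), with ties receiving the mean of the normalized values at
the tied ranks, and the result is log2 transformed.

Outlier arrays are screened by a single documented heuristic — an array is
flagged when its mean correlation distance ($1 - r$) to all other arrays
exceeds the median plus `k` MADs (default $k = 3$, `mad()` with its usual
consistency constant) — standing in for a full array-quality report. It is
a deliberately blunt instrument, can flag borderline arrays in clean data,
and can be disabled (`skip_outlier_filter`). The pipeline applies it before
probe filtering, mirroring the usual processing order.

## SNP-level QC and eSNP selection

`select_esnps()` applies, in order, recording the first failed filter per
SNP:

1. MAF ≥ 0.01 (genotyping quality floor);
2. Hardy–Weinberg exact p ≥ 0.001;
3. case/control differential-missingness (Fisher exact) p ≥ 10⁻⁴;
4. external replication p < 0.05 **and** direction of effect matching the
   discovery sign (encoded as $\mathrm{sign}(\log \mathrm{OR}) =$
   discovery direction);
5. MAF ≥ 0.10 in the analysis samples, guarding against the type-I
   inflation small-sample quantitative-trait tests suffer at low MAF.

The Hardy–Weinberg test is the full exact enumeration over heterozygote
counts consistent with the observed allele counts, summing null
probabilities not exceeding the observed configuration's; monomorphic SNPs
return p = 1. It is computed on all samples by default (switchable to
controls only) — a choice, not a given, since HWE can be distorted in cases
by true association. Differential missingness is tested only against
case/control status; a missingness-by-flanking-genotype test needs
neighboring-SNP haplotype data the pipeline does not model and is
deliberately omitted. Dosages are re-polarized (recoded $2 - d$ with allele
labels swapped) whenever the counted allele turns out to be the major one,
so every downstream step sees minor-allele counts. The 10% analysis-MAF
floor uses all analysis samples rather than a group-wise criterion.

## Scans and windows

Cis windows span each locus's SNP positions extended by `window_bp`
(default 250,000 bp, clipped at 1) on each side, so every probe in a window
is tested against the locus's entire LD block. Probe intervals come from
BED (0-based half-open) and stay in that convention internally; a probe
overlaps a window iff `start < window_end` and `end > window_start`, so a
probe ending exactly at the window start is excluded — an explicit,
testable edge convention. Membership uses the full annotated interval, not
a midpoint. The trans scan tests every retained SNP against every retained
probe; cis pairs are labelled, not removed, so the trans family is the full
transcriptome-wide set.

## Multiple-testing correction

The correction recognizes that neither the SNPs (LD) nor the probes
(co-expression) are independent.

* **Per-locus effective SNPs.** Meff is the smallest $k$ such that the $k$
  largest eigenvalues of the locus's dosage correlation matrix explain at
  least `variance_threshold` (default $C = 0.995$, the conventional value
  for this estimator; exposed as configuration) of total variance.
  Correlations are computed on raw 0/1/2 dosages, pairwise-complete — LD is
  a property of alleles, so the dominant recode is not applied here.
  Eigenvalues in $[-10^{-8}, 0)$ are clipped to zero; anything more
  negative is rejected as a non-PSD input.
* **Effective cis tests.** $M = \sum_{\mathrm{locus}} \mathrm{Meff} \times
  n_{\mathrm{probes~in~window}}$. A locus with no probes in its window
  contributes zero (logged); if every locus is empty the cis threshold is
  undefined and reported as `NA`.
* **Cis threshold.** $\alpha_{cis} = \alpha / M^{1 - \bar r^2}$, where
  $\bar r^2$ is the mean squared pairwise correlation of the probes that
  entered the cis scan. This correlation-adjusted Bonferroni form
  interpolates between plain Bonferroni ($\bar r^2 = 0$) and no correction
  ($\bar r^2 = 1$) and is never more conservative than Bonferroni. A
  Šidák-style variant $1 - (1-\alpha)^{1/M^{1-\bar r^2}}$ is provided; the
  divide form is the default because it is the form under which the
  published threshold $6.7\times10^{-5}$ is recovered exactly from
  $M = 1698$ and $\bar r^2 = 0.11$.
* **Trans threshold.** Plain Bonferroni over effective SNPs times all
  probes: $\alpha_{trans} = \alpha / (\sum \mathrm{Meff} \times
  n_{\mathrm{probes}})$. Summing the per-locus Meff for the SNP side is an
  assumption (a single global eigen-analysis is the alternative) and is
  consistent with the per-locus computation used for cis.

## The synthetic-data generator

No real brain genotype or expression data ship with the package; the
generator defines the study conditions instead, and its defaults are fixed
once:

* **Cohort**: 26 cases, 24 controls. Age $\sim N(77.31, 8.14^2)$ /
  $N(75.67, 11.73^2)$ (case/control, years); PMI $\sim N(6.57, 6.98^2)$ /
  $N(13.26, 10.86^2)$ truncated at 0 hours; RIN $\sim N(7.37, 0.89^2)$ /
  $N(7.37, 0.86^2)$ truncated to $[1, 10]$. Truncation is a physical
  plausibility constraint; note it shifts the realized PMI mean above the
  nominal parameter (by about +2.2 h for cases), which the tests account
  for via the closed-form truncated-normal mean.
* **Genotypes**: five LD blocks — SNCA (20 SNPs) and GAK (10) on
  chromosome 4, HLA (8) on 6, MAPT (24) on 17, RIT2 (5) on 18; 67 SNPs in
  all. Each locus uses a latent AR(1) Gaussian per haplotype: SNP $k$'s
  haplotype carries the minor allele when its latent value falls below the
  MAF quantile, and the two haplotypes sum to the dosage. `ld_rho`
  (defaults 0.6–0.9 per locus) controls adjacent-SNP LD monotonically;
  per-SNP MAFs are drawn from $U(0.2, 0.45)$ so the empirical analysis-MAF
  floor of 0.10 is comfortably cleared at $n = 50$. Simulated SNP metadata
  replicates the external association by construction (replication p
  $\sim U(0.001, 0.049)$, direction matching), emulating a pre-selected
  risk-SNP panel.
* **Expression**: 1000 probes, 8 per locus placed inside the cis windows,
  the rest far from every locus. Probe value = intercept
  ($U(6, 12)$ log2 units) + covariate effects (defaults
  $0.15/\mathrm{RIN}$, $-0.01/\mathrm{h}$, $-0.005/\mathrm{yr}$) + planted
  effect × dominant genotype + noise. Noise follows a single-factor
  equicorrelation model with common correlation `probe_cor` (default 0.11,
  reusing the published mean-$R^2$ summary as the correlation parameter)
  and standard deviation `noise_sd` (default 0.3 log2 units, a typical
  residual scale for array data after covariate adjustment).
* **Planted eQTLs**: five defaults spanning all modes — shared cis
  (1.06/1.28 and 1.35/1.38), opposite cis (−0.56/+0.39), case-only trans
  (0.86/0) and control-only trans (0/−1.45) — magnitudes chosen to match
  the range reported in small-cohort eSNP studies.
* **Reproducibility**: one spec-level seed, expanded into fixed per-stage
  substreams so regenerating one stage never perturbs another; identical
  spec and seed give byte-identical output files.

What the generator does **not** emulate: haplotype inversions (the MAPT
H1/H2 structure), array-intensity-level artifacts (the written intensities
are simply $2^{\log_2}$ values with all-clean QC masks), probe sequence
effects (SNPs under probes), population structure, and realistic
missingness (none is generated by default). Passing tests on this data
therefore demonstrate the statistical machinery — calibration, power
ordering, effect recovery, threshold computation — not robustness to those
real-data pathologies.

One interaction worth knowing: the equicorrelated noise factor acts like an
array-level intensity shift, and quantile normalization removes exactly
that kind of shift. The mean outcome $\bar r^2$ measured after the
pipeline's normalization is therefore close to the null level
$1/(n-1)$ rather than to `probe_cor`; the factor-model level is visible
only on the un-normalized simulated matrix. This is the correct behavior of
both components, not a defect of either.

## Problem sizes and numerical tolerances

The test and acceptance suites size their simulations to be decisive yet
quick: 1000 null replicates for type-I calibration (binomial SE ≈ 0.007
around 0.05), 500 replicates for power and bias comparisons, 100 random
designs for oracle agreement at $10^{-10}$, exhaustive Hardy–Weinberg
enumeration for all configurations up to 20 individuals at $10^{-12}$, and
20 seeded end-to-end pipeline runs (each about three seconds) for planted
effect recovery. Quantile normalization is checked to $10^{-12}$ column
agreement; file round-trips to $10^{-12}$ relative on expression values and
bitwise on dosages.

## Known limitations

* Linear fixed-effects models only: no mixed models, surrogate-variable or
  latent-factor expression correction, and no conditional (multi-SNP)
  analysis.
* The outlier-array heuristic is intentionally simple and not a
  reimplementation of full array-quality diagnostics.
* The exact tests (Hardy–Weinberg, Fisher missingness) are conservative at
  these sample sizes, as exact conditional tests are; their p-values are
  super-uniform, not uniform.
* Binary PLINK (BED/BIM/FAM) and VCF genotype input are extension points,
  not implemented; text PED/MAP only.
* With both scans run on the same data, cis pairs appear in the trans
  family too; they are labelled by `scan_type`, and downstream users who
  want disjoint families should filter on that label.
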