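---
title: "Mapping cis-meQTLs across cohorts: models, quality control, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cis-meQTLs across cohorts: models, quality control, and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismeqtl)
```

## The scientific problem

A methylation quantitative trait locus (meQTL) is a SNP whose genotype
associates with DNA methylation at a nearby CpG site. Because genotype is
constant across tissues while methylation is highly tissue- and
age-specific, meQTLs are a natural probe of how much of inter-individual
methylation variation is sequence-driven — and of whether an accessible
tissue (blood) can stand in for an inaccessible one (brain). This package
implements the full analysis chain used for that kind of multi-cohort
comparison: per-cohort quality control, cis association scanning with
family-wise error control, cross-cohort overlap and sign-concordance
statistics, and frequency-matched enrichment tests, together with a
synthetic multi-cohort generator so that every stage can be exercised,
calibrated, and stress-tested without access to restricted genotype data.

## The association model

For each CpG site and each SNP within 50 kb (inclusive; the window is
configurable), the methylation level is regressed on the REF-allele count
under an additive model:

\[
\beta_{ij} = \mu + b \cdot g_{ij} + \gamma^\top z_i + \varepsilon_{ij},
\qquad g_{ij} \in \{0, 1, 2\},
\]

where \(\beta_{ij}\) is the methylation proportion (beta-value) of sample
\(i\) at CpG \(j\), \(g_{ij}\) the allele count, and \(z_i\) optional
covariates (batch indicators). Fitting is ordinary least squares on
complete cases per pair; the slope's two-sided p-value comes from the
Student-t distribution with \(n - 2 - (\text{number of covariates})\)
degrees of freedom. Pairs with residual degrees of freedom below 30
(i.e. fewer than 32 complete observations in the simple model) are not
tested at all — small complete-case subsets otherwise produce inflated
test statistics. Within a cohort, a Holm (step-down Bonferroni)
correction is applied over exactly the set of pairs that produced a test,
and a pair is called an meQTL when the adjusted p-value is below 0.05.
Holm controls the family-wise error rate at 5% for independent tests and
is conservative under the positive dependence that linkage disequilibrium
(LD) induces.

Two modelling conventions worth making explicit:

* **Response scale.** Beta-values are bounded and heteroskedastic;
  M-values (`beta_to_m()`, the base-2 logit with clamping at
  \(10^{-6}\)) are closer to homoskedastic. Both scales are supported
  (`scan_cohort(..., scale = "mvalue")`); on strongly associated pairs the
  two sets of t-statistics are nearly identical (the acceptance suite
  checks Pearson r > 0.95), so the beta scale — directly interpretable as
  methylation-proportion change per allele — is the default.
* **Degenerate fits.** A pair that is monomorphic among complete cases is
  filtered (reported, not tested). A constant response is reported as
  slope 0, t = 0, p = 1 (the 0/0 → 0 convention). Covariate columns that
  are constant among complete cases are dropped — they change neither the
  slope nor the degrees of freedom — while exactly collinear covariates
  raise an error rather than silently aliasing.

## Quality control

`apply_qc()` runs the standard array/genotyping cascade and logs every
exclusion:

1. **Methylation samples**: drop samples with probe detection call rate
   below 90% or mean total intensity below 2,000 units or below half the
   experiment-wide mean; then set data points with detection p > 0.001 to
   missing (`methylation_sample_qc()`).
2. **PCA outliers**: one pass of `pca_outlier_removal()` — samples whose
   PC1/PC2 distance from the origin exceeds 2.5 standard deviations are
   dropped. One "standard deviation away from the origin" is the scale of
   the zero-mean score cloud, \(\sqrt{\mathrm{sd}(PC1)^2 +
   \mathrm{sd}(PC2)^2}\) (the root-mean-square distance). The
   alternative reading — 2.5 times the standard deviation *of the
   distance itself* — is incoherent as an outlier rule: distances from
   the origin have a large mean relative to their SD (Rayleigh-like), so
   that cut would discard roughly a quarter of perfectly clean samples.
   Under the RMS rule a clean cohort loses essentially nothing while a
   globally shifted array sits far outside the cut.
3. **SNPs and genotyped samples** (`snp_qc()`), in a fixed, logged order,
   computed on the samples that survive methylation QC: drop samples with
   more than 5% missing genotypes; then SNPs with call rate < 95%; then
   SNPs failing the Hardy-Weinberg exact test at p < 1e-5; then SNPs with
   minor allele frequency below 0.05 (strict inequality: a SNP at exactly
   0.05 is retained). The order matters because MAF and HWE depend on the
   retained sample set; computing them on the final analysis set also
   makes the cascade idempotent.
4. **Probe-SNP exclusion** (`exclude_probes_with_snps()`): any CpG whose
   probe interval (1-based, inclusive ends) contains a known variant is
   removed — such probes report genotype, not methylation.

The Hardy-Weinberg test is the exact conditional test: given the allele
counts, the p-value sums the probabilities of all heterozygote counts no
more likely than the observed one. It is implemented in log space and
verified against full enumeration for every table with up to 50 samples.

## Cross-cohort statistics

**Overlap tables.** Comparisons are restricted to SNP-CpG combinations
tested in every cohort (`restrict_to_common_pairs()`). For each cohort
pair, `overlap_table()` reports the shared significant-pair count, the
percent overlap with the *column* cohort's meQTL count as denominator
(so the matrix is asymmetric: 319 shared hits are 50.7% of a 629-meQTL
cohort but 44.1% of a 724-meQTL one), and a one-sided Fisher exact test
of independence from the 2×2 table {both, i-only, j-only, neither}.
The Fisher tail is computed by log-sum-exp over log-scale hypergeometric
mass (`fisher_exact_log10()`), so p-values far below the double-precision
underflow limit — routine at these universe sizes — remain exactly
representable on the log10 scale. `render_overlap_report()` formats cells
as `"shared (percent)"` with one decimal, rounding half away from zero.

**Sign concordance.** For pairs significant in at least one cohort,
`sign_concordance()` compares the observed proportion of pairs whose
t-statistics share a sign across all \(k\) cohorts with the chance
expectation \(\prod_i p_i + \prod_i (1 - p_i)\), where \(p_i\) is cohort
i's proportion of positive t-statistics. For agreement in at least
\(m\) cohorts the chance expectation is a Poisson-binomial tail,
\(P(S \ge m) + P(S \le k - m) - P(m \le S \le k - m)\) (the subtraction
removes double counting when \(m \le k/2\)); the pmf is computed by
direct convolution and verified against exhaustive \(2^k\) sign-vector
enumeration. Pairs containing zero (signless) or missing t-statistics are
dropped and counted. Observed-vs-expected comparisons use one-sided
binomial tests on the log10 scale.

**Subject-partitioned overlap.** When two tissues are sampled from the
same individuals, their meQTL overlap conflates shared biology with
shared subjects. `partition_overlap()` splits the common subjects into
two random halves, scans each tissue in each half, and contrasts
same-subject with disjoint-subject cross-tissue overlap.

**LD pruning and clustering.** `ld_prune()` implements the standard
sliding-window pairwise-r² pruning (windows of 50 SNPs, step 5, removing
the later SNP of any pair with r² > 0.05 — deliberately aggressive, to
yield a roughly independent SNP set for sensitivity analyses). The
window is in SNPs, the common idiom, although window sizes for such
pruning are sometimes quoted in base pairs; both the window and step are
arguments. `cluster_tstats()` hierarchically clusters cohorts and pairs
(Euclidean distance, average linkage — fixed for determinism; missing t
set to 0) to expose ancestry- and tissue-driven structure.

**Enrichment.** `enrichment_test()` asks whether an meQTL SNP set
overlaps an external target list (GWAS top hits, miRNA binding-site
SNPs, published meQTL/eQTL catalogues) more than frequency-matched
chance. SNPs are binned by MAF in intervals of 0.025 (bin =
floor(MAF/0.025), MAF 0.5 assigned to the top bin); each resample draws,
without replacement and per bin, as many universe SNPs as the meQTL set
has in that bin (the meQTL SNPs stay in the sampling universe). The
empirical p-value is the proportion of resamples with overlap at least
the observed; with zero exceedances it is reported as the bound
`p < 1/n_resamples`, and a `(x+1)/(n+1)` corrected value is also
returned. Defaults: 10,000 resamples for large catalogues, 1,000 for
small panels.

## The synthetic multi-cohort generator

`simulate_study()` generates the structure the analysis assumes, with
ground truth for recovery scoring. Defaults emulate a seven-cohort
blood/brain design: two African-American-like cohorts (adult peripheral
blood, cord blood) with short LD blocks (5 SNPs), a Caucasian-like
cord-blood cohort and four brain cohorts with longer blocks (15 SNPs),
sample sizes 90/87/87/111/125/105/106, brain cohorts with 2
hybridization batches and 2% outlier arrays. Feature counts default to a
desk scale (240 SNPs, 80 CpGs on a 4 Mb chromosome, ~400–500 cis pairs
per cohort) so a full pipeline run takes seconds; all counts are
configurable.

* **Genotypes.** Haplotypes follow a latent-uniform copy chain: within an
  LD block each haplotype copies its previous latent value with
  probability `ld_rho` (default 0.9) or draws afresh, and the allele at a
  SNP is the indicator that the latent value falls below that SNP's
  frequency. Marginal frequencies are exact, genotypes are sums of two
  independent haplotypes (so Hardy-Weinberg holds exactly in
  expectation), and r² decays geometrically within blocks and vanishes
  across block boundaries. Allele frequencies are anchored per block
  (uniform over the cohort's MAF range) with ±0.02 per-SNP jitter:
  appreciable r² between two loci mathematically requires closely matched
  frequencies, so independent per-SNP frequencies would produce LD blocks
  in name only — and, downstream, association tests so close to
  independent that Holm's correlated-test conservativeness disappears.
  A coalescent simulator would add realism (recombination hotspots,
  frequency spectra) that none of the tested statistics depend on.
* **Methylation.** Each CpG has a logit-normal baseline (SD 1.5 on the
  logit scale — wide enough to cover near-boundary CpGs, whose
  heteroskedasticity is exactly what makes beta-value regression
  interesting) plus a cohort shift; per-sample noise is normal on the
  logit scale (default SD 0.3, which maps to a beta-scale spread of a few
  percentage points at mid-range CpGs). Planted effects add
  `sign × effect_size × (allele count)` on the beta scale (default Δβ =
  0.1 per allele, a strong but routinely reported meQTL effect);
  planted CpGs get mid-range baselines (β in [0.3, 0.6]) so the [0.01,
  0.99] clamp never attenuates a planted slope. Batch offsets (SD 0.02)
  and outlier shifts (+0.3 globally, which lands 10+ SDs out on PC1) are
  added before clamping. Detection p-values exceed the 0.001 threshold at
  rate 1% by default; genotype calls are missing at rate 1%.
* **Sharing.** `effect_sharing` (planted pairs × cohorts, 0/1) controls
  which cohorts carry each effect; by default half the effects are
  universal and the rest hit random cohort subsets, mimicking the mix of
  ubiquitous and tissue-/ancestry-specific meQTLs.

What the generator does *not* emulate — probe chemistry, cell-type
mixture, bimodal genome-wide beta distributions, genuine haplotype
reference structure — bounds what passing tests show: they validate the
statistical machinery under the model's assumptions, not array physics.

## Calibration results the test suite establishes

The package's acceptance tests recompute, at fixed seeds and desk scale:

* published seven-cohort overlap percents from their count matrix (the
  rendering convention reproduces 38 of the 42 printed cells exactly;
  the remaining four disagree with their own printed counts by 0.1, or
  1.0 in one apparent digit slip, under any denominator convention —
  the recomputed values are the arithmetically consistent ones);
* the log-space Fisher tail against exhaustive enumeration for all 2×2
  tables with total ≤ 60 (to 1e-9 in log10 p), and log10 p < −308 on a
  published blood/cord-blood 2×2 over a 529,224-pair universe;
* chance sign-concordance: for k = 7 and per-cohort positive proportions
  in [.456, .493] the all-same expectation stays within [0.0157, 0.0182]
  (bracketing the canonical 1.67%), and Poisson-binomial tails equal
  2^k enumeration for k ≤ 10;
* family-wise error: with no planted effects (2,000 cis pairs, n = 90),
  at least 95 of 100 simulation seeds yield zero Holm-significant pairs;
* recovery: 200 planted effects of Δβ = 0.1 at n = 100 are estimated
  with mean slope within ±15% and detected (Holm) in well over half the
  pairs;
* enrichment calibration: under a null meQTL set the empirical p-value
  is uniform (fraction ≤ 0.05 inside the exact binomial band over 200
  replicates of 1,000 resamples).

`scripts/acceptance.R` re-runs the same computations from the installed
package and writes the resulting numbers as JSON.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout; BED-style inputs are
  converted on read. Dosages count REF alleles, with forward-strand
  orientation asserted at load.
* The cis window is inclusive at exactly 50,000 bp.
* Missing genotypes stay missing (complete-case per pair); no dosage
  imputation. Hard calls {0,1,2} only — the QC regime this pipeline
  mirrors excluded low-confidence imputed genotypes rather than carrying
  fractional dosages.
* Holm is applied per cohort over performed tests only.
* All file output serializes floats with 10 significant digits; result
  rows are sorted by (snp_id, cpg_id) so reruns are byte-identical.
* One global seed drives a run; per-stage seeds are derived by hashing
  the seed with the stage name, so any stage can be rerun independently.
* Batch covariates use 0/1 indicator coding (first batch as reference).

## Known limitations

* No cell-type composition correction; heterogeneous tissues blur
  cohort comparisons in real data.
* The enrichment null matches allele frequency but not LD structure;
  clumped or LD-aware matching would be stricter.
* Beta-scale OLS p-values at extreme tails rely on approximate normality
  of bounded residuals; the M-value option exists precisely because that
  approximation can thin out near boundary CpGs.
* Trans (distal) effects, fractional dosages, and permutation-based
  per-CpG nulls are out of scope.
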