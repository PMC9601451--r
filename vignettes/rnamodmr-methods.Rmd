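---
title: "Methods and design of rnamodmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of rnamodmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`rnamodmr` chains the summary-statistic analyses used to ask whether
RNA-modification-related SNPs (RNAm-SNPs) explain GWAS signals: catalogue
annotation, resampling enrichment, QTL linking, instrument construction,
two-sample Mendelian randomization (MR), SMR/HEIDI integration of eQTL
and GWAS data, and gene-set over-representation. This vignette is the
package's own account of the statistics it implements, the knobs that
matter, and the choices made where the design was genuinely open.

## The statistical setting

Everything operates on *summary statistics*: per SNP, an effect size
`beta` per copy of the effect allele, its standard error, a p-value, the
alleles and (optionally) the effect-allele frequency. Two-sample MR
assumes the exposure associations (here: plasma protein or expression
levels) and outcome associations (here: a trait such as bone mineral
density) come from independent samples of the same population, and that
instruments are valid — associated with the exposure, not associated
with confounders, and affecting the outcome only through the exposure.
The estimators differ in how much of the third assumption they relax:
IVW requires it for every instrument, the weighted median for half the
instrument weight, MR-Egger only requires pleiotropy to be independent
of instrument strength (InSIDE), and MR-PRESSO detects and removes
individual violators.

## Annotation and tallies

Annotation is an inner join on rsid between a validated GWAS table and
the RNAm catalogue. A SNP can carry several modification types; it
contributes one row per type to the per-type summary (matching
per-type tabulations of such catalogues) but is counted once in overall
classification tallies — both counts are reported. Every gate in the
package is a *strict* inequality (`p < 5e-8`, not `<=`), consistent with
the conventional "p < 5.0 × 10⁻⁸" phrasing of genome-wide significance.

Percentages in printed summaries use half-away-from-zero rounding
(`round_half_up`), two decimals in per-type tables and one decimal in
cohort tallies, matching how such tables are conventionally printed;
base R's `round()` is round-half-even and disagrees at exact halves.
Every summary re-derives its percentages from its own counts before
returning (an internal consistency check that aborts on mismatch).

"Locus" has no universal definition; the package uses single-linkage
chaining — consecutive significant SNPs on a chromosome at most
`window_kb` (default 1,000 kb) apart join one locus — because it is
reproducible, order-independent, and equals the transitive closure of
the pairwise-distance relation (tested against a brute-force closure).
The lead SNP is the smallest p-value, ties broken by smaller position.

## Permutation enrichment

The enrichment question: among SNPs carrying an RNAm flag, is the
genome-wide-significant fraction higher than chance? Each of `B`
replicates samples, without replacement, as many non-flagged SNPs as
there are flagged ones and records the significant fraction; "a set of"
SNPs implies distinct SNPs, hence sampling without replacement. No
MAF/LD matching of sampled SNPs is attempted — plain random sampling is
the stated design, and a matching hook would change the null being
tested. Both empirical p-values are reported: the raw fraction
`#{null ≥ observed}/B` (which can be exactly 0) and the +1-corrected
`(1 + #{null ≥ observed})/(1 + B)`. The corrected value is the headline
because a permutation p of exactly zero is statistically improper — the
smallest honestly attainable value is `1/(B+1)`. The exact binomial
complement (`p_binomial`) uses the non-flagged significant rate as the
success probability; it has resolution below `1/(B+1)` but assumes
independence across SNPs, which LD violates, so it is a complement, not
a replacement.

## Instruments

* **Selection**: exposure `p < p_instrument` (default 5 × 10⁻⁴, the
  conventional relaxed threshold for protein QTL instruments).
* **Harmonization**: matching allele pairs are kept; swapped pairs flip
  the outcome beta's sign and complement its frequency; strand
  complements are resolved the same way. Palindromic SNPs (A/T, C/G)
  cannot be oriented by allele labels. The default drops only
  *frequency-ambiguous* palindromes — eaf within 0.5 ± 0.08 in either
  study, or missing — and orients the rest by frequency concordance
  (same side of 0.5 → kept, opposite sides → flipped). A strict mode
  drops every palindrome for users who prefer the conservative
  convention. The 0.08 band is the common default of harmonization
  tools; it is configurable.
* **Clumping**: greedy by ascending p (ties: position, then rsid, for
  bit-reproducibility), removing SNPs within `window_kb` (default
  10,000 kb) of a kept SNP with `r² ≥ r2_threshold` (default 0.001).
  Distance is measured between SNP positions. SNP pairs missing from
  the LD panel count as r² = 0 with a warning — the permissive default
  mirrors common clumping-tool behaviour when a panel lacks a variant;
  the alternative (dropping such SNPs) would silently discard signal.

## The MR estimators

With ratio estimates `theta_j = beta_Yj / beta_Xj` and weights
`w_j = beta_Xj² / se_Yj²` (first-order weights, ignoring `se_Xj`):

* **IVW** is the weighted mean of `theta_j`, identically the slope of
  the zero-intercept weighted regression of `beta_Y` on `beta_X` with
  weights `1/se_Yj²`. The default is multiplicative random effects: the
  fixed-effect SE is inflated by `max(1, sqrt(Q/(n-1)))` with Cochran's
  `Q`, floored at 1 so under-dispersion never shrinks the SE, and the
  test uses a t reference on `n − 1` df. This matches mainstream MR
  practice and is conservative; a fixed-effect flag is available.
* **MR-Egger** frees the intercept; instruments are first oriented so
  every `beta_Xj > 0` (the estimate is invariant to allele coding only
  after this step). SEs use the same multiplicative inflation with
  `n − 2` df. Constraining the intercept to zero reproduces IVW exactly
  with the same weights — kept as a test mode and verified in the suite.
* **Weighted median**: order `theta_j`, form standardized cumulative
  weights `s_j = (Σ_{i≤j} w_i − w_j/2)/Σw`, and interpolate `theta` at
  `s = 0.5`. The SE is the SD of the estimator over `n_boot` parametric
  bootstrap draws of `(beta_X, beta_Y)` under their SEs, with a fixed
  seed. First-order ratio SEs (`se_Yj/|beta_Xj|`) define the weights;
  a second-order option exists behind a flag.
* **MR-PRESSO**: the observed residual sum of squares around
  leave-one-out IVW fits is compared with `n_sim` parametric
  simulations (global test); per-SNP squared residuals are compared
  with their simulated distributions and Bonferroni-adjusted (outlier
  test, flag at adjusted p < 0.05); the percent change of the IVW
  estimate after removing flagged SNPs is compared against removing
  random same-size subsets drawn without replacement (distortion
  test). Empirical p-values carry the +1 correction, with raw
  fractions emitted alongside for comparison with the original
  software, which reports raw fractions. With no outliers the
  distortion test is skipped and the corrected estimate equals the
  all-SNP estimate; if *every* SNP is flagged the corrected estimate is
  undefined and the result is flagged rather than silently degraded.

## SMR and HEIDI

The SMR statistic at the top cis-eQTL SNP combines the two Wald
z-scores: `T_SMR = z₁²z₂²/(z₁²+z₂²)`, chi-square with 1 df, with effect
`b_xy = beta_GWAS/beta_eQTL` and `se_bxy = |b_xy|/sqrt(T_SMR)` (so the
Wald chi-square of `b_xy` equals `T_SMR`). `T_SMR ≤ min(z₁², z₂²)`
always — the test is driven by the weaker of the two signals.

HEIDI asks whether all SNPs in the region imply the same `b_xy` as the
top SNP, which distinguishes one shared causal variant (pleiotropy)
from distinct variants in LD (linkage). Defaults follow the published
conventions of the SMR tooling run "with default parameters":
eligibility requires `|z_eQTL| ≥ 3.16` (≈ p < 1.6 × 10⁻³; weaker eQTL
SNPs make the ratio `b_xy` too unstable for the first-order expansion),
r² to the top SNP within [0.05, 0.9] (high-r² SNPs duplicate the top
signal, low-r² SNPs carry no information about it), and at most 20 SNPs
ranked by eQTL significance. Differences `d_i = b_xy(i) − b_xy(top)`
are standardized by first-order error propagation with
`cov(beta_i, beta_j) = r_ij · se_i · se_j` within each study (the two
studies independent), and `T_HEIDI = Σ z_d²` follows a correlated
chi-square mixture under the null. The default p-value matches the
first two moments of the eigenvalue mixture (Satterthwaite scale and
df) — cheap and accurate where the 0.05 gate operates (p ≳ 10⁻⁴); a
Monte-Carlo mode simulating the multivariate-normal z-differences is
retained as oracle and fallback, and the suite checks the two agree to
±0.03. Fewer than 3 eligible SNPs yields a missing p with reason
`insufficient_snps` rather than a fabricated value. The cis region for
the scan is ±1,000 kb of the target TSS, the same window as QTL
linking.

## Over-representation analysis

Per set, the hypergeometric upper tail `P(X ≥ k)` for an overlap of `k`
between an `n`-gene query and a `K`-gene set in an `N`-gene universe —
identically the one-sided Fisher exact test (verified against
`fisher.test` over fuzzed small instances). The default universe is the
union of all collection genes; an explicit universe overrides it, since
the appropriate background (all genes vs the measured set) is an
analysis decision, not a package one. Benjamini–Hochberg q-values are
the default correction; the EASE variant (replace `k` by `k − 1` in the
tail, a conservative modification used by some annotation servers) is
available behind a flag.

## The synthetic-data generator

The generator exists so every downstream stage has parameter-recovery
tests against a known truth. Genotypes: per LD block, two
latent-Gaussian haplotypes per individual follow an AR(1) process with
lag-1 correlation `rho`; dosage is the count of haplotypes below the
MAF quantile. This gives direct, reproducible control of LD decay
(latent lag-k correlation exactly `rho^k`) without coalescent
machinery. Phenotypes follow the structural model `X = Gγ + ε_x` with
`γ` rescaled so the genetic component's sample variance equals
`heritability_x` exactly, and `Y = βX + Gα + ε_y`, where a configurable
fraction of causal SNPs receive direct (horizontally pleiotropic)
effects `α_j ~ N(0, alpha_scale²)`. Summary statistics are *exact*
per-SNP OLS on the simulated individuals, not an analytic shortcut —
this makes the null z-score calibration property literally true and is
what the Kolmogorov–Smirnov tests in the suite verify. The RNAm
catalogue flags each SNP with probability `rnam_base_rate`, multiplied
by `rnam_enrichment` at causal SNPs (capped at 1), with categorical
attributes drawn from an m⁶A-dominated distribution mirroring the
composition of public RNAm catalogues.

Defaults describe the reference scenario used throughout the tests:
50,000 individuals, 50 blocks, AR(1) `rho = 0.8`, MAF uniform on
[0.05, 0.5], 50 causal SNPs spread across blocks (so default
instruments are quasi-independent), 30% exposure heritability, true
causal effect 0.1, no pleiotropy, flag base rate 5% enriched 5-fold.
The fixed bundle seed is 20221018.

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: realistic MAF spectra and LD structure
(blocks are homogeneous AR(1), real LD is not), population
stratification and relatedness, winner's-curse-free exposure panels
(instrument selection and estimation share one simulated sample, which
real two-sample designs avoid; the small attenuation this causes is
visible in the worked example), imputation uncertainty, sex
chromosomes, and allele-frequency mismatch between studies.

## Numerical choices and degenerate inputs

* Input p-values of exactly 0 are clamped to 1e-300 with a warning
  (printed tables sometimes contain "0"); p-values implying a z-score
  more than a factor of 10 from `beta/se` warn but do not reject.
* Rows with non-positive SEs, identical or non-ACGT alleles, or
  p outside (0, 1] are rejected with row-numbered diagnostics;
  accepted + rejected always equals the input row count.
* All stochastic routines take an explicit seed and restore the
  caller's RNG state; generators are byte-identical under a fixed
  (config, seed) pair, and the pipeline writes its seed into the run
  manifest.
* Ties in clumping order and locus leads are broken deterministically
  (position, then rsid).
* Monomorphic simulated SNPs (possible at small n) are dropped from
  summary tables with a warning rather than emitting infinite SEs.
* A single instrument degrades IVW to the ratio estimate with
  `se = se_Y/|beta_X|`; Egger and the weighted median refuse fewer than
  3 instruments, MR-PRESSO fewer than 4.

## Problem sizes used by the test suite

Simulation-backed properties run at sizes chosen to give stable
verdicts on one CPU: IVW recovery and CI coverage over 200 seeds at the
reference conditions (n = 50,000, 50 single-SNP blocks); Egger
intercept type-I error over 500 summary-level draws of 50 instruments
(the summary-level null is the correct reference for a
summary-statistic estimator and avoids redundant genotype simulation);
enrichment calibration over 200 seeds on a 5,000-SNP universe with 400
flags, power over 100 seeds on a 10,000-SNP universe; SMR/HEIDI
positive-control and linkage scenarios over 100 seeds at n = 50,000
with single 12-SNP blocks; MR-PRESSO outlier detection over 100 planted
seeds and global-p calibration over 200 null seeds. The whole suite
completes in a few minutes.

## Known limitations

* HEIDI's Satterthwaite p matches two moments of the mixture; extreme
  tail p-values (far below the 0.05 gate) are approximate — use the
  Monte-Carlo mode where the tail matters.
* The binomial enrichment p treats SNPs as independent; LD makes it
  anti-conservative, which is why the permutation p is the headline.
* First-order IVW/median weights ignore exposure-side error; with weak
  instruments this understates uncertainty (no F-statistic filter is
  provided, mirroring the implemented analysis plan).
* The LD panel API computes pairwise correlations on demand from
  dosages; for very large panels a precomputed correlation table is the
  intended input.
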