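---
title: "Differential methylation and epigenetic biomarkers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential methylation and epigenetic biomarkers: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(methfield)
```

This vignette is the package's account of the statistics it implements, the
assumptions behind them, and the choices made where the design was genuinely
open. The motivating setting is a methylation-array study of hereditary
colorectal tumors (Lynch syndrome and FAP) with paired normal mucosa, where
the questions are differential methylation at three granularities, a panel of
per-sample epigenetic biomarkers, DNA methylation age, and the expression
consequences of promoter methylation.

## Scales: β and M

A probe's β value is the methylated fraction of signal, in [0,1] — the
interpretable scale. Testing happens on M = log2(β/(1−β)), which is closer
to homoskedastic across the β range. β is clipped to [ε, 1−ε] with ε = 10⁻⁶
(configurable) before the logit so M stays finite; the two transforms are
mutual inverses to better than 10⁻¹² inside the clip region. Effect sizes
for *calling* (Δβ) are deliberately left on the β scale, as differences of
covariate-unadjusted group means, because a fixed Δβ threshold has the same
biological meaning at every baseline.

## Probe filtering

Probes are excluded in a fixed order, each removal attributed to the first
criterion it fails: detection failure (detection P ≥ 0.01 in one or more
samples), cross-reactive probes, sex-chromosome probes, non-CpG probes,
SNP-masked probes. The detection rule deserves a note: the convention in
array pipelines is that a probe is *well* detected when its detection P is
small, so the removal criterion is detection P **at or above** the threshold
in any sample. The threshold (0.01) and the one-bad-sample rule are the
standard array defaults.

Quantile normalization here is the plain across-sample variant: every column
is mapped onto the mean of the order statistics, ties receiving the mean of
their target quantiles (delegated to `limma::normalizeQuantiles`). This is a
simplification of probe-type-stratified array normalization and is intended
for normal-vs-normal comparisons where no global shift is expected; the
package otherwise consumes already-normalized β as input, since raw IDAT
processing is out of scope.

## Per-probe model and empirical-Bayes moderation

Each probe's M-values are regressed on a common design: intercept, tumor
indicator, centered age, and a binary colon-location indicator (proximal vs
distal). Age and location are included because both are known methylation
confounders in colon mucosa; a covariate that is constant in the included
samples is dropped with a warning rather than producing a singular fit. The
model is unpaired even though tumors have paired normals — the quoted
covariate model of the motivating design is unpaired, and the pairing
information remains available in the sample sheet for score-level paired
analyses.

Variance moderation follows the standard empirical-Bayes formulation:
residual variances s² with d degrees of freedom are assumed to follow a
scaled inverse-χ² prior with parameters (d₀, s₀²), estimated by moment
matching of log s² — the excess variance of log s² beyond trigamma(d/2)
determines d₀ through trigamma inversion (Newton iteration, tolerance 10⁻⁸,
at most 50 steps), and s₀² follows from the mean. Three conventions:

* d₀ estimates above 10⁶ are reported as infinite; with infinite d₀ the
  posterior variance is s₀² for every probe, s₀² is the mean observed
  variance, and the t reference is normal. (The mean — not geometric mean —
  matches the behavior of the reference implementation in limma, which the
  test suite uses as an independent cross-check.)
* d₀ = 0 reproduces the ordinary t exactly; this limiting case is asserted
  to 10⁻¹⁰.
* Probes with zero residual variance take s² = s₀² before the t computation
  and are flagged, so a constant probe cannot produce an infinite statistic.

A probe is a DMP when the BH-adjusted P (over all tested probes) is below
0.01 **and** |Δβ| strictly exceeds the contrast's threshold — 0.10 for
low-grade and normal-normal contrasts, 0.15 for high-grade and carcinoma
contrasts, where tolerating only larger effects compensates the stronger
signal. The strict inequality follows the verbal rule ("greater than") of
the motivating design. A raw-P variant (`use_raw_p`) exists for
low-signal comparisons where no probe survives adjustment.

## Regions

Region calling is a transparent seed-and-merge scheme sharing the proximity
scale of kernel-based DMR tools: seed probes (raw P < 0.01) on one
chromosome merge while consecutive seeds are at most λ = 1000 bp apart;
clusters with at least 2 seeds become candidates; member p-values are
combined by the signed Stouffer method (z weighted by effect sign, so
opposing directions cancel); BH runs over candidates; regions are kept at
adjusted P < 0.05 and |mean Δβ| > 0.10 (0.08 in the sensitivity variant).
The kernel tool's C = 2 scaling parameter has no analogue in the merge
scheme and is deliberately unused. Exact parity with kernel-smoothed region
boundaries is a non-goal; the accuracy surface is planted-region recovery
(positional Jaccard ≥ 0.8), which the acceptance suite measures.

## Promoter enrichment

Promoter sets (gene → promoter-region probes) are tested against the probe
list ranked by M-value log2 fold change, all tested probes included (the
alternative — only significant DMPs — is available by subsetting the input,
but ranking all probes preserves information about near-threshold probes).
The statistic is the weighted Kolmogorov–Smirnov running sum with weight
|score| and exponent 1; ES is the extremum, the leading edge is the member
probes at or before it (at or after, for negative ES). The null permutes
probe labels — random same-size sets from the ranked list — rather than
phenotypes, matching rank-list enrichment practice; each gene's permutation
stream is seeded from the global seed plus a hash of the gene name, so
results are independent of evaluation order. NES divides ES by the mean
|null ES| of matching sign; the permutation p uses the add-one rule and BH
runs across genes. Sets need ≥ 5 CpGs present in the ranked list (≥ 3 in
the sensitivity variant used for weak-signal cohorts). Ties in the ranking
are broken by probe id, making every downstream quantity deterministic.

## Biomarker scores

* **LINE-1 index**: mean β over probes flagged as mapping to evolutionarily
  young LINE-1 elements. The flag is a manifest input — the genomic
  intersection with repeat annotations is out of scope — so the index is
  defined relative to the supplied list.
* **Hypermethylation index**: mean β over probes hypermethylated in *every*
  tumor-vs-normal contrast of a family, restricted to CpG-island probes with
  at least one promoter-proximal region (5′UTR/TSS200/TSS1500/1stExon).
  The intersection is monotone non-increasing in the number of contrasts.
* **CIMP**: positive iff ≥ 3 of 5 panel-gene statuses are hypermethylated.
  The five statuses are inputs; which genes constitute the panel is a
  wet-lab choice outside the package.
* **MSI**: MSI iff at least one of BAT25/BAT26 is unstable, MSS iff both
  stable; missing markers yield an absent call, not an error.
* **TMB**: mutations / 6.4 Mb (the targeted panel's footprint);
  hypermutated iff strictly above 10/Mb, so a count of exactly 64 on 6.4 Mb
  is not hypermutated.

Group comparisons use Kruskal–Wallis across groups and pairwise Wilcoxon
rank-sum with BH over the pair family; inter-score relations use Spearman
correlation. These primitives delegate to the base-R implementations; the
only hand-written piece is the exact permutation p for Spearman at n < 10,
where the base exact path refuses ties (mid-ranks are used throughout).
Wilcoxon is exact (enumeration) when both samples have ≤ 8 observations and
no ties, otherwise the tie-corrected normal approximation with continuity
correction; a fully tied comparison returns p = 1 by convention.

## DNA methylation age

The clock is a linear predictor over clock-probe β values passed through
the piecewise age transform F(age) = log((age+1)/(A+1)) for age ≤ A and
(age−A)/(A+1) above, with adult age A = 20 — logarithmic in development,
linear in adulthood, F(A) = 0, and invertible to 10⁻⁹ over [0, 120].
Published coefficients load from a two-column CSV with an `(Intercept)`
row; none are bundled, so the package builds offline and all tests use
synthetic clocks. Missing clock probes follow the "warn" policy by default
(drop the term, warn; error below 50% coverage), matching common clock-tool
behavior; "strict" and "impute β = 0.5" variants exist for audits.

## The synthetic cohort

The generator is first-class, tested code: it emulates the *structure* of
the motivating study so that every analysis layer can be scored against a
registry of planted truths.

* Eight groups at the study's sample sizes (16/32/21/7/5 LS unaffected
  normal/normal/low-grade/high-grade/carcinoma; 31/25/1 FAP
  normal/adenoma/carcinoma), with group-specific age distributions and the
  study's location pattern (FAP distal; LS mostly proximal). Tumors are
  paired to normals of the same synthetic patient (shared age and location).
* Baseline β per probe is bimodal by CGI class (islands low, open sea
  high); within-group noise is Beta-distributed with concentration 50
  (sd ≈ 0.05 near β = 0.5), a typical array-scale dispersion.
* Planted effects are applied on the logit scale and back-transformed, so
  the configured Δβ is exact at the baseline and β never leaves [0,1]:
  hypermethylation (Δβ = 0.2, the middle of the per-probe effect range the
  motivating study reports) on whole Island-promoter clusters,
  hypomethylation on scattered open-sea probes, and a −0.3 logit LINE-1
  shift in tumors. Each tumor sample carries a severity multiplier
  U(0.6, 1.4) scaling all its planted effects — this single latent variable
  is what makes the LINE-1 / hypermethylation / TMB correlations emerge
  with the study's signs, and drives the steep MSI-severity coupling.
* Mutation counts (generated for the LS arm only, as in the motivating
  study's targeted sequencing) follow round(a + b·H + noise) with b > 0 on
  the hypermethylation level H, clamped at zero; the defaults place the
  hypermutation boundary at mid-severity so the simulated hypermutated
  fraction (~0.6) and burden range (0 to ~39/Mb) match the study's, and the
  positive TMB-hypermethylation / negative TMB-LINE-1 correlations emerge.
* The clock has 353 probes (the size of the published multi-tissue clock)
  with small per-probe age loadings (|u| ≤ 0.06) and weights scaled so the
  linear predictor equals F(age) exactly at zero noise; small individual
  coefficients are what keep predictions stable when probes are dropped.
  The predictor noise default (sd 0.3 in transformed-age units) is
  calibrated so the expected DNAm-age concordance matches the strongest
  correlation the motivating study reports in normal colon (Spearman
  R ≈ 0.94); the closed form is Pearson = √(v/(v+σ²)) with
  v = var(F(age)) ≈ 0.68 for ages uniform on 20–80.
* Expression is 8 + slope·(centered mean promoter M) + noise for the 40
  coupled genes (slope −3, noise sd 0.5) and pure noise elsewhere.
* One global seed feeds a fixed, append-only sequence of per-stage
  substreams (manifest, baselines, planting, sample sheet, β, clock,
  expression, detection, mutations), so adding a later feature never
  perturbs earlier draws and identical seeds give identical bytes.

What the generator does **not** emulate: batch and chip effects, cell-type
composition, probe-type (Infinium I/II) chemistry differences, spatial
autocorrelation beyond the planted clusters, and the heavy-tailed
inter-individual variation of real mucosa. Passing recovery tests therefore
demonstrates the estimators' correctness and calibration under the planted
model, not robustness to those real-data artifacts.

## Statistical conventions

* Two-sided Fisher tests use the probability-mass definition (sum of table
  probabilities not exceeding the observed, with 10⁻⁷ relative tolerance),
  the convention of standard statistical environments. The r×c test
  enumerates fixed-margin tables up to a grand total of 200 and offers a
  seeded Monte-Carlo estimate, flagged approximate, beyond it.
* The 2×2 chi-square applies the Yates continuity correction by default —
  the printed p-value this package reproduces (0.008 from the
  hypo/hypermethylated DMP counts) is the corrected statistic — with a flag
  to disable.
* BH adjustment is the standard step-up, applied once per family (all
  tested probes; all candidate regions; all tested promoter sets; all
  pairwise group comparisons; all tested features in the expression
  integration).
* Stouffer combination clips p = 0 to 10⁻³⁰⁰ with a warning and computes
  Φ⁻¹ through the upper tail to stay finite near zero.

## Problem sizes in the test and acceptance suites

The suites run on synthetic data scaled for a laptop-class single core:
2,000 probes and 15-vs-15 samples for the null-calibration (20 replicate
seeds) and power runs; 5,000 probes for variance-prior recovery; a single
planted 10-probe cluster per seed (20 seeds) for region recovery; 200
features at 18-vs-18 samples for the integration layer; the full analysis
workflow under `analysis/` uses 20,000 probes and the study's 138 samples.
These sizes keep every suite comfortably reproducible while leaving the
statistical behavior (calibration within binomial error, recovery rates)
indistinguishable from larger runs.

## Known limitations

* Δβ thresholds interact with the unpaired model: with strong paired
  structure a paired or blocked model would gain power; the package exposes
  the pairing in the sample sheet but does not fit it.
* The region caller's boundaries are seed-probe spans; a kernel smoother
  would extend regions into flanking sub-threshold probes.
* The permutation null for promoter enrichment conditions on the observed
  ranking; inter-probe correlation within a promoter is preserved in the
  observed statistic but not in the null, which can make p-values mildly
  anti-conservative for tightly correlated sets — the planted-recovery and
  null-calibration tests bound this in practice.
* Fisher r×c enumeration is exponential in the margins; the 200-total limit
  is deliberate, with Monte-Carlo beyond.
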