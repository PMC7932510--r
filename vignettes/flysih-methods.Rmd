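---
title: "Methods: starvation-induced hyperactivity phenotyping, mixed-model GWAS and splicing analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: starvation-induced hyperactivity phenotyping, mixed-model GWAS and splicing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flysih)
```

# Overview

`flysih` implements the computational chain of a quantitative-genetic
screen of starvation-induced hyperactivity (SIH) in an inbred *Drosophila*
panel such as the DGRP: reading TriKinetics DAM2 beam-break files,
computing the Delta Activity (DA) phenotype and the starvation-resistance
(SR) index, estimating broad-sense heritability and trait correlations,
running a covariate-adjusted linear mixed-model association scan with
variant site classification, and analysing starvation-responsive
differential expression and intron-usage (PSI) changes. A synthetic-data
module generates every input, so the whole chain is testable without any
external data. This vignette documents the models, the estimators, the
generator design, the numerical choices, and the known limitations.

# The locomotor assay and the SIH phenotype

Flies are monitored one per tube in DAM2 monitors, 32 channels per
monitor, with beam breaks accumulated in 30-minute bins. The assay runs
60 hours from lights-off (bin 0 starts at 18:00 on the setup day), i.e.
120 bins covering three nights and two days. Bins are half-open,
left-anchored at lights-off; raw readings at any cadence dividing 30
minutes are summed into bins, and a bin with an incomplete set of raw
readings is dropped and flagged rather than zero-filled, because silent
zero-filling would masquerade as death in the SR index.

For each fly the five 12-hour window totals are computed
(N1 = bins 0–23, D1 = 24–47, N2 = 48–71, D2 = 72–95, N3 = 96–119).
Food-condition and starved flies are different animals, so the "activity
difference between the two conditions" is implemented as each starved
fly's window total minus the *strain mean* of the food-condition flies'
totals for that window; this preserves the per-fly DA (and its 8-fly SEM)
while being well defined. The fly's DA is the **signed maximum** of the
five window differences — the trait is hyperactivity, so a negative
extreme (hypoactivity) is deliberately not selected. The strain phenotype
is the mean ± SEM over its starved flies (default 8 per condition per
strain).

The SR index is inferred from the activity record alone: a starved fly's
death bin is one past its last bin with any beam cross; a fly still
crossing in the final bin is a survivor. The strain SR is the largest
death bin among its flies, or 121 when any fly survives — an integer on
the 0–121 scale at 30-minute granularity, because activity is only
observed per bin. "Baseline activity" (used for the DA-vs-baseline
correlation) is the strain mean of food-condition flies' total counts over
all 120 bins; the underlying screen did not define the term, so this
choice is exposed as a documented knob rather than buried.

**A property of the max-of-five estimator worth knowing.** Because DA is
the maximum of five noisy window differences, it carries a positive
selection bias of roughly $E[\max_5 \mathcal N(0,1)] \approx 1.16$ times
the window-noise SD (about +25 counts under the default generator noise,
under 8% of a 500-count effect). The bias is near-constant across strains
with similar noise, so it barely affects heritability or correlations,
but a strain with a true DA of zero will not average to zero. The null
recovery test therefore checks the window-wise differences (which are
unbiased), not the maximum.

# Heritability and correlation estimators

Broad-sense heritability uses the classical one-way random-effects
method-of-moments decomposition: $\hat\sigma^2_E$ is the within-line mean
square, $\hat\sigma^2_G = (MS_{between} - MS_{within})/n_0$ with
$n_0 = (N - \sum_i n_i^2/N)/(k-1)$ the unbalanced-design effective
replicate count, and $H^2 = \sigma^2_G/(\sigma^2_G + \sigma^2_E)$.
A negative among-line component is truncated to zero and flagged. REML
would be the modern choice, but the method-of-moments estimator is the
one that corresponds to the published ANOVA table and $H^2$ formula, and
at 198 lines x 8 flies the two are practically indistinguishable.
`heritability_from_summaries()` recovers exactly the same estimate from a
published-style table of per-line mean/SEM/n, using
$SS_{within,i} = (n_i - 1)\, n_i\, \mathrm{sem}_i^2$.

Correlations are plain Pearson tests (two-sided t on $n-2$ df);
segregation ratios use the chi-squared goodness-of-fit test without
continuity correction.

# The mixed-model association scan

Line phenotypes are first adjusted by OLS on an intercept plus Wolbachia
infection status and five inversion genotypes (numeric dosage coding);
the scan uses the residuals. Genotypes of fully inbred lines are coded as
the 0/1 minor-allele indicator (dosage 0/2 is equivalent up to scale for
homozygous lines). Variants with MAF $\le$ 0.05 are excluded (strict
inequality, matching "larger than 0.05").

The genomic relationship matrix is $K = ZZ^\top/m$ over standardized
genotypes $z = (g - p)/\sqrt{p(1-p)}$, with per-variant mean imputation
of missing calls and monomorphic variants skipped. The polygenic null
model $\mathrm{Var}(y) = \sigma^2_g K + \sigma^2_e I$ is fitted by REML
with intercept-only fixed effects, using one eigendecomposition of $K$
and a one-dimensional profile of the restricted likelihood in
$\delta = \sigma^2_e/\sigma^2_g$: a coarse grid on
$\log_{10}\delta \in [-6, 6]$ (step 0.2) brackets the optimum and
`optimize()` refines it to $10^{-6}$; tests verify agreement with a
2000-point grid oracle to $10^{-3}$ in log-likelihood. A numerically
identity $K$ makes the split unidentifiable; the fit then returns the
total variance with a degeneracy flag.

The scan itself is P3D/EMMAX-style by default: variance components are
frozen at the null estimates and each marker is tested by generalized
least squares of $y$ on an intercept and the minor-allele indicator under
$\hat V$. After rotating by the eigenvectors and whitening, this is an
ordinary two-column regression per marker, vectorized across markers.
The residual scale is re-estimated per marker and the Wald statistic is
referred to $t_{n-2}$, so with $\hat\sigma^2_g = 0$ the scan reduces
*exactly* to single-marker OLS — a reduction the tests assert at
$10^{-10}$. An `exact` mode re-fits the REML per marker (with the marker
in the fixed effects); on well-behaved panels the two agree within a
factor of two in p-value, asserted at the 198-line scale. Significance
uses the nominal $P < 10^{-5}$ threshold with no genomic control or
multiple-testing correction, matching the screening convention for this
panel; `lambda_gc()` is provided for QQ diagnostics.

Reported effects are the GLS coefficient of the minor allele. Whether the
upstream pipeline's printed "effect" was a GLS beta or a raw minor-major
mean difference is not documented; the GLS beta is the default and the
raw difference is recoverable from the genotype and phenotype tables.

# Variant site classification

Site classes are assigned from a GFF3 subset (gene/mRNA/exon/CDS) plus a
reference FASTA, with precedence CDS > UTR > Intron >
Upstream/Downstream > Intergenic. Flanks extend up to 1000 bp from the
transcript span, strand-aware ("less than 1 kb" is implemented as
$\le$ 1000 with the boundary documented and tested). For coding SNPs the
minor allele is substituted into the codon (reading frame concatenated
across CDS segments, reverse-complemented on the minus strand) and
translated with the standard code; equal amino acids give Synonymous,
anything else — including any indel in CDS — NonSynonymous. A variant
whose stated reference allele contradicts the reference base is an error,
not a silent reclassification. Gene nomination returns the owning gene
for genic classes, the nearest gene within 1 kb for flanks (equidistant
ties all reported, ascending id), and `n/a` for intergenic records. The
reported three-way distribution groups {Intron}, {Intergenic, Upstream,
Downstream} and {Synonymous, NonSynonymous}, rounded to 0.1%.

# Differential splicing

Intron junctions (0-based half-open, BED convention) sharing a start or
end coordinate on the same chromosome and strand are connected; clusters
are connected components, determinized by coordinate sort. Introns below
0.1% of their cluster's reads are pruned and clusters below 30 reads (or
with a single intron) dropped, iterating to a fixed point. PSI of an
intron in a condition is its pooled count share of the cluster total, so
PSIs sum to one per cluster per condition, and
$\Delta\mathrm{PSI} = \mathrm{PSI}_{starved} - \mathrm{PSI}_{food}$.

The per-cluster test models each sample's counts as Dirichlet-multinomial
with proportions $\pi$ and concentration $c$ ($\alpha = c\pi$), and
compares condition-specific versus shared proportions by likelihood
ratio on $K-1$ degrees of freedom. Two numerical choices matter:

* the concentration is estimated by maximum likelihood **under the null
  only** and held fixed in the condition-specific fit. Re-estimating it
  jointly in the alternative makes the LRT anticonservative at 4-vs-4
  samples (measured type-I error 0.105 at nominal 0.05 on
  Dirichlet-multinomial nulls with $\rho = 0.02$); with the
  concentration profiled out under the null the measured type-I error is
  0.056. The cost is mild conservatism under strong alternatives, where
  the null fit absorbs part of the shift into overdispersion;
* when the null concentration estimate diverges (log-concentration at
  its bound, i.e. no detectable overdispersion) the test falls back to a
  multinomial G-test on pooled condition totals, which matches the
  chi-squared reference on large counts. Both paths are also exposed
  directly via `method = "dm"` / `"g"`.

This is deliberately simpler than LeafCutter's per-junction GLM;
reproducing that machinery is out of scope, and the simplification is
the reason published cluster *counts* are not comparable, only
proportions. Cluster significance is Benjamini–Hochberg FDR < 0.05
across clusters; each significant cluster is classed by its maximum
$|\Delta\mathrm{PSI}|$: below-threshold ($\le 0.10$), small
($0.10 < |\Delta\mathrm{PSI}| < 0.25$), intermediate
($0.25 \le |\Delta\mathrm{PSI}| \le 0.50$), large ($> 0.50$) — the
boundaries sit exactly where the reported class definitions put them,
inclusive on the intermediate side.

# Differential expression

Size factors are DESeq-style median-of-ratios against the geometric-mean
pseudo-reference (genes with any zero excluded; total-count fallback with
a warning when no reference gene exists). Per gene, an NB dispersion is
estimated by moments on normalized counts within conditions, truncated at
zero, and shrunk halfway (log scale) toward a lowess mean–dispersion
trend; the condition effect is then Wald-tested in an NB log-link GLM
with size-factor offsets (Poisson GLM when the shrunk dispersion is
below $10^{-4}$, which also makes the small-dispersion limit exact). The
reported log2 fold change (starvation vs food) uses normalized condition
means with a prior count of 0.5 — raw, not shrunk; which flavour the
original screen gated on is undocumented, so the simpler one is used.
Calls require FDR < 0.05 *and* linear fold change $\ge 2$ (i.e.
$|\log_2 FC| \ge 1$). This NB Wald test is a documented stand-in for the
original pipeline's DE engine, whose internals are not published; for
that reason published DE gene counts are not comparison targets.

# What the generators emulate

All generators are seed-deterministic (identical seeds give
byte-identical outputs) and write planted-truth tables sufficient to
score every downstream stage.

**Activity.** The circadian baseline is a low trough plus two Gaussian
bumps at lights-off and lights-on (the bimodal day–night profile);
per-bin counts are negative binomial (dispersion 0.05) around the
strain-scaled profile. Starved flies add a persistent uplift spread
uniformly over bins (a ramp shape is available behind a flag, since the
time course of hyperactivity onset is not quantified anywhere); the
per-fly uplift is gamma-distributed with mean equal to the strain DA.
Defaults encode the screen's conditions: 198 strains, 8 flies per
condition, 120 bins, a lognormal-quantile strain DA spectrum anchored at
93.61 and 2101.91 at the extreme order-statistic positions, heritability
0.38, DA–SR correlation −0.231 and DA–baseline correlation 0.046.

Three calibration details keep the *recomputed* statistics on target
rather than merely the planted ones:

* the anchors describe *observed* strain means, which include estimation
  noise; the generator plants the deconvolved spectrum (deviations
  shrunk by $\sqrt{1/(1 + (1-h^2)/(8 h^2))}$) so the pipeline's observed
  spectrum reproduces the anchors in expectation rather than
  overshooting its maximum;
* the per-fly gamma variance realizes the target within-line variance
  $\sigma^2_G (1-h^2)/h^2$ after subtracting the window-count noise, and
  is capped at $\delta_s^2/2$ per strain (gamma shape $\ge 2$) with the
  mean variance rescaled to target — uncapped, low-DA strains would get
  absurdly skewed fly distributions and a heavy-tailed within-line mean
  square;
* target correlations are planted through a Gaussian copula whose latent
  correlation is corrected for marginal-shape attenuation (the exact
  first Hermite coefficient, computed from the marginals) and then
  refined by a fixed-point iteration against an analytic predictor of
  the *observed* correlation. The predictor includes DA estimation noise
  and the max-of-$k$-windows bias: strains that die early have fewer
  live windows, which couples the DA estimate to SR and would otherwise
  attenuate the recomputed correlation by a further ~25%. All of this is
  closed-form at generation time; nothing is tuned against test output.

Deaths are planted per strain so the latest death bin realizes the SR
index exactly (one beam cross is guaranteed in the final active bin to
keep the planted death identifiable; a survivor realizes 121); other
flies die within 15 h before the strain's last death. `sr = NA` plants a
death-free strain, and a `death_time` column forces a single last-active
bin, which the unit tests use for boundary cases.

**Genotype panel.** Independent variants (no LD) with MAF uniform on
(0.05, 0.5), homozygous 0/1 lines, Wolbachia and five inversion
covariates with configurable effects, optional causal variants, a
polygenic draw with covariance proportional to the realized GRM, an iid
line deviation, and per-fly errors scaled so the expected broad-sense
heritability hits the target. Linkage structure is deliberately out of
scope, so LD-aware power properties of the scan are not claimed.

**Junctions.** Each cluster's per-sample counts are Dirichlet-multinomial
around condition proportions ($\rho = 0$ gives multinomial). The default
set emulates the splicing screen's outcome scale: 359 shifted two-intron
clusters whose planted maximum $|\Delta\mathrm{PSI}|$ magnitudes fall
290/67/2 into the small/intermediate/large bins (the reported
80.8/18.7/0.5% proportions), 100 null clusters, and one 10-intron
cluster with planted shifts topped by −12% and +6% (the syncrip-like
alternative-terminus cluster). The default overdispersion is
$\rho = 0.005$ at depth 2000 — biological replicates of an isogenic
stock are only modestly overdispersed — giving a per-intron
$\Delta\mathrm{PSI}$ SE near 0.02, so a few percent of clusters migrate
across the 0.10/0.25/0.50 boundaries upon re-estimation; recovered class
percentages are therefore compared with ±6/±6/±3 point bands.

**Expression.** NB counts with lognormal baseline means, shared
dispersion, per-sample depth factors, and planted symmetric log2 fold
changes in a configurable subset of genes.

What the generators do **not** emulate: linkage disequilibrium, real
genome coordinates, shared junctions between genes, batch structure,
library-size trends in dispersion, and fly-to-fly circadian phase
variation. Passing tests therefore demonstrate that the estimators
recover what they claim under the stated stochastic models — not that
the pipeline is robust to every artefact of real recordings.

# Problem sizes and tolerances used by the tests

The test suite runs the full study-scale conditions where they are cheap
(198 strains x 16 flies x 120 bins; 460 junction clusters; 5000-variant
null scans) and scales replicate counts to keep the whole suite under a
minute: 200 replicate panels for heritability recovery (±0.03 band on
the mean), 100 replicates for causal-variant ranking, 2000 clusters/genes
for the splicing and DE calibration checks. Tolerances reflect each
statistic's sampling variance under those conditions: ±0.05 for a single
heritability estimate, ±0.10 for correlations estimated over 198 strains,
±20% for the maximum strain DA (a single extreme order statistic with
~10% sampling SD), exact equality for desk-scale arithmetic, and
$10^{-10}$/$10^{-3}$ for the GLS and REML oracle agreements.

# Known limitations

* The DA estimator's positive selection bias (above) is inherent to the
  published max-of-five definition; comparisons of absolute DA between
  designs with different noise levels should use the window differences.
* The splicing test is conservative under strong alternatives because
  the null-profiled concentration absorbs part of the shift; published
  cluster counts additionally depend on unpublished clustering filters,
  so only class proportions are reproduced.
* The DE module is a clean-room NB Wald pipeline, not a re-derivation of
  the original engine; gene counts from the original screen are not
  reproducible from summary data and are not targeted.
* The segregation-ratio p-value printed in the original analysis
  (0.7223) is not reproduced by a standard goodness-of-fit test against
  1:2 expectations (closed form gives ≈ 0.708); the expected
  probabilities actually used there are unstated, so the package asserts
  the closed-form value.
* `exact` scan mode re-fits one REML per marker and is quadratic in
  panel size; it is intended for verification, not genome-scale scans.
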