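---
title: "Methods: pool-seq sweep scans, pooled FST, and dose-response in poolsweep"
author: "poolsweep maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pool-seq sweep scans, pooled FST, and dose-response in poolsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsweep)
```

# The problem

Pooled sequencing (Pool-seq) estimates population allele frequencies by
sequencing DNA pooled from many individuals. With pools of 100 diploids
(200 chromosomes) per population, per-site read counts carry enough
information to scan a genome for the footprint of a hard selective sweep —
a long run of windows with near-zero nucleotide diversity — and to measure
differentiation between populations that differ in a selected trait such
as insecticide resistance. `poolsweep` implements that scan end to end:
sync-format allele counts in; windowed diversity statistics, delineated
sweep regions, pairwise FST, PCA outlier SNPs, coding-consequence calls,
and probit LC50 estimates out. A seeded generator produces synthetic
datasets with the same structure, so every stage is testable against a
known truth.

# Diversity statistics

## Coverage subsampling

All diversity statistics are computed on reads subsampled to a uniform
target coverage (default 50). Sites below the target are dropped as
insufficient; sites above a maximum (default 100) are excluded as
suspected copy-number artifacts; the rest receive a multivariate
hypergeometric draw of exactly `target_coverage` reads without
replacement. Uniform coverage makes the sample size of every retained
site identical, which is what makes the classic forms of the statistics
below well defined.

## Per-site and windowed statistics

For a site at uniform coverage $c$ with allele frequencies $f_a$
(alleles supported by fewer than `min_count` reads are zeroed and $c$
recomputed),

$$\hat\pi = \frac{c}{c-1}\Big(1 - \sum_a f_a^2\Big),$$

which equals the mean pairwise difference among the $c$ reads (the test
suite verifies this exhaustively against brute-force pair counting for
all count vectors with $c \le 20$). Per nonoverlapping window (default
5 kb): $\pi$ is the sum of site values over covered positions divided by
the number of covered positions (not the raw window length;
`covered_frac` is reported so either convention can be reconstructed);
Watterson's $\theta_W = S / (a_1 \, n_{\text{cov}})$ with $S$ the number
of segregating sites and $a_1 = \sum_{i=1}^{c-1} 1/i$; and Tajima's
$D = (\sum_{\text{sites}}\hat\pi - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}$
with the standard constants evaluated at $n = c$. A window is valid when
at least `min_covered_fraction` (default 0.6) of its positions reached
target coverage. Gene-wise $\pi$ repeats the same computation over the
union of a gene model's CDS intervals, and a gene is usable only when its
mean raw coverage exceeds 50.

Using the classic Tajima's D with $n = c$ rather than a
pooled-data-corrected variant is a deliberate simplification: after
subsampling, the read sample is a fixed-size sample, and the generator's
read model (below) makes it a true chromosome sample. The `min_count`
default of 2 exists to suppress sequencing error; on error-free data it
would strip true singletons and bias D upward, so neutral calibration
runs use `min_count = 1` with `error_rate = 0`.

# The synthetic-data generator

The source study is empirical and specifies no generative model, so every
distributional choice here is a documented stand-in.

* **Background polymorphism.** Each site is polymorphic with probability
  `theta` (default 0.10, chosen so that expected per-site $\pi$ —
  `theta` times the neutral-SFS mean heterozygosity at $2N = 200$,
  0.1694 — matches the ~0.0175 genome-wide diversity of a susceptible
  population). The derived-allele count among the pool's 200 chromosomes
  follows the neutral site frequency spectrum, $P(i) \propto 1/i$.
* **Drift between populations.** Per-population frequencies are Beta
  perturbations of the ancestral frequency with concentration `nu`
  (default 200; FST between replicate pools is roughly $1/(1+\nu)$).
  `drift_concentration = Inf` disables the perturbation; the neutral
  Tajima's D calibration uses it, because drift legitimately distorts
  each population's marginal SFS (population structure shifts D — a real
  effect, not an estimator defect).
* **Read sampling.** Depth is Poisson (default mean 82, the study's raw
  coverage — subsampling then targets 50; a mean of 50 would leave half
  of all sites below target and invalidate every window). Reads cover
  *distinct template chromosomes*: up to $2n$ reads are drawn without
  replacement from the pool (hypergeometric), and only depth beyond $2n$
  resamples binomially. This emulates a pipeline that removes PCR/optical
  duplicates. Sampling reads with replacement instead would shrink the
  effective sample size and bias classic Tajima's D by about +0.17 (we
  measured this directly); with the distinct-template model the neutral
  mean D is statistically indistinguishable from 0, while read fractions
  still converge to pool fractions as depth grows. Each read is miscalled
  to a uniform other base with probability `error_rate` (default 1e-3).
* **The sweep.** Inside the shared core (default 100 kb of a 1-Mb
  genome), polymorphic sites survive with probability
  `diversity_reduction` ($\varepsilon$; 0 = complete sweep); inside the
  extension only the designated resistant population is thinned.
  Survivors are redrawn as singleton-like recent mutations (derived
  copies 1–2 of $2n$): after a sweep, variation re-accumulates as rare
  new mutations, which is exactly what drives Tajima's D strongly
  negative inside the swept region.
* **Special SNPs.** A fixed nonsynonymous SNP sits inside a generated
  plus-strand gene whose codon context (CTT, Leu) is written into the
  FASTA at codon 934, so the screen labels the canonical L934F
  knock-down-resistance change; 20 outlier SNPs flank the sweep with a
  large frequency shift in the resistant population.

A green test on this generator establishes that the estimators recover a
*stated* world; it does not establish robustness to features the
generator lacks — linkage and haplotype structure, coalescent
correlations between sites, mapping artifacts, indels, or base-quality
variation.

# Sweep delineation

Candidate sweeps are maximal runs of consecutive valid windows with
$\pi$ below `pi_threshold` (default 0.002, the shading convention used in
the study's gene-wise tables; the original delineation was partly by
eye, so the threshold is exposed). Up to `max_gap_windows` (default 1)
interior windows at or above threshold are tolerated, because real
window statistics are noisy. Each region reports the flanking contrast
(mean $\pi$ of up to 10 windows each side). Regions are intersected
across populations into a shared core plus per-population extensions.
Distribution tails of Tajima's D use type-7 interpolated quantiles with
ties included in the tail, and the mean's confidence interval is a
percentile bootstrap (default 10,000 replicates at level 0.90).

One caveat discovered while testing: when sweep windows exceed 1% of all
windows, the bottom-1% cutoff of the all-window D distribution lies
*inside* the sweep's own distribution, so "mean sweep D below the
all-window cutoff" is unsatisfiable by construction. The meaningful
statements — asserted by the tests — are that the bottom-1% tail windows
all lie inside the sweep and that mean sweep D falls below the bottom-1%
cutoff of the neutral background.

# Pairwise FST

Two estimators are reported side by side, and their disagreement is
informative rather than an error:

* **Classical (heterozygosity-based).**
  $F_{ST} = (\pi_t - \pi_w)/\pi_t$ with $\pi_w$ the mean of the two
  pools' site $\hat\pi$ and $\pi_t$ the site $\hat\pi$ of the summed
  counts. Because the $c/(c-1)$ correction differs between $c$ and $2c$,
  identical pools give a slightly negative value (−0.0102 at a 30/20
  split) — negative values are effectively zero. With two demes this
  estimator converges to $(F/2)/(1 - F/2)$, a model-determined offset
  that deeper sampling does not remove.
* **ANOVA (identity-probability, pool-size corrected).** Within-pool
  read-pair identity $Q_1^{\text{reads}} = \sum_a y_a(y_a-1)/(c(c-1))$
  is corrected to chromosome-pair identity through the $1/n_{\text{hap}}$
  probability that two reads hit the same chromosome:
  $Q_1 = (Q_1^{\text{reads}} - 1/n_{\text{hap}})/(1 - 1/n_{\text{hap}})$;
  between pools $Q_2 = \sum_a y_{Aa} y_{Ba}/(c_A c_B)$; then
  $F_{ST} = (Q_1 - Q_2)/(1 - Q_2)$. The multilocus value is the ratio of
  summed numerators over summed denominators, never a mean of per-SNP
  ratios (which would be biased and ordering-sensitive). On
  moment-matched island-model simulations the multilocus estimate is
  within 0.01 of truth across $F \in \{0, 0.05, 0.1, 0.2\}$.

Outlier SNPs are those at or above the empirical 99% quantile of per-SNP
FST; the genome summary is recomputed excluding the sweep region directly
from the stored per-SNP numerator/denominator components, so a region
containing no SNPs leaves the value exactly unchanged.

# PCA outlier scan

Per-SNP minor-allele frequencies (global top-two alleles, renormalized)
form a pools × SNPs matrix. Columns are centered (optionally scaled);
the first K principal-component score vectors come from the SVD; each
SNP's z-vector is its standardized regression coefficients on those
scores, with residual df $n - 1 - K$. Mahalanobis
$d^2 = z^\top \Sigma^{-1} z$ uses the covariance of z estimated from all
SNPs, and $p$-values are the upper chi-squared tail with K df;
Benjamini–Hochberg gives q-values. A genomic-inflation-factor rescaling
and a robust covariance are available but off by default, following the
literal chi-squared-with-K-df procedure.

Two properties matter in practice. First, with $n = K + 1$ pools (the
3-pool, K = 2 design) the regression fit is exact and no residual
variance exists; the scan falls back to raw coefficients (whose scale
the Mahalanobis covariance absorbs) and warns that it is weakly powered.
Second, the chi-squared calibration presumes *genuine structure* that
the K components capture, with null SNPs drifting along it. Under a
completely structureless null the estimated PCs chase sampling noise and
the smallest p-values are anticonservative at any pool count — we
measured false-rejection probabilities of 0.12–0.7 under BH at q = 0.05.
The calibration tests therefore simulate pools on a continuous 2-D
ancestry gradient that every SNP follows (frequency-effect sd 0.06 per
component, 100 pools), under which the Kolmogorov–Smirnov uniformity
check and the BH false-discovery property both hold; the outlier-recovery
tests use a two-group axis with a 0.4 frequency shift among 24 pools.
These worlds were fixed by design-stage power analysis before the
acceptance tests were frozen.

# Variant screening

Segregating variants (a non-reference allele passing `min_count` summed
over pools) are located in gene models, the codon is rebuilt from the
spliced CDS (minus-strand genes via reverse complement), and the
substitution is translated with the standard genetic code; the label is
RefAA + 1-based codon index + AltAA (e.g. L934F). The test suite checks
all 61 sense codons × 3 positions × 3 substitutions on both strands
against Biostrings translation. "Conservative" means BLOSUM62 score
strictly positive: the Leu/Phe pair scores exactly 0 and the canonical
kdr change is a *non*conservative substitution, so a ≥ 0 rule would
misclassify the motivating example. Sites with reference base N are
excluded from consequence calls; sites overlapping several gene models
are reported once per model.

# Dose-response analysis

Mortality is modeled as $\Phi^{-1}(p) = \alpha + \beta \log_{10}(d)$,
fitted by maximum likelihood (binomial GLM, probit link; log10 dose is
the toxicology convention). $LC_{50} = 10^{-\alpha/\beta}$. The 95% CI
comes from Fieller's theorem on $-\alpha/\beta$; when the residual
deviance exceeds the chi-squared 0.95 quantile, the variance is inflated
by Finney's heterogeneity factor (deviance/df) and a t quantile replaces
z — both the corrected and uncorrected intervals are reported, since
common toxicology software is inconsistent about applying the
correction.
Complete separation (all-0% or all-100% mortality) has no finite MLE and
errors; a non-positive slope warns and suppresses the CI. Two
populations differ significantly when their 95% CIs are disjoint; the
ratio of LC50s is the resistance ratio. No control-mortality (Abbott)
correction is applied by default; an `abbott` argument exists. At the
emulated assay design (5 doses × 3 replicates × 20 larvae), recovery
simulations show LC50 median bias under 1% and CI coverage 93–96% across
$LC_{50} \in \{0.4, 7, 24, 260\}$ ppm.

# Pipeline

`run_all()` chains simulate → diversity → sweep → fst → pca → screen →
probit from one config. A single global seed expands into fixed
per-stage seeds, every parameter is logged, and all outputs are listed
in a manifest with md5 checksums — identical config + seed reproduces
identical checksums, which is itself an acceptance criterion. The
`poolsweep` CLI exposes each stage as a subcommand with a plain-text
`key = value` config.

# Known limitations

* Sites are independent in the generator: no linkage, haplotype
  structure, or coalescent correlation, hence no power statements about
  haplotype-based statistics.
* Classic Tajima's D (not a pooled-data-corrected variant), valid here
  because of subsampling plus the distinct-template read model; on real
  data with heavy read duplication it would be biased positive.
* The classical FST estimator is reported as defined (with its two-deme
  offset); comparisons across studies should use the ANOVA estimator.
* The PCA scan is weakly powered with 3 pools and K = 2; it runs, but
  its p-values should not be taken at face value in that regime.
* Base-quality filtering is out of scope: counts are assumed
  quality-filtered upstream.
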