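---
title: "Statistical methods behind magpop"
author: "magpop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind magpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magpop)
```

magpop analyses the population genomics of a eukaryotic
metagenome-assembled genome (MAG) observed through pooled metagenomic read
recruitment: each sampling station/depth contributes one *pool* of reads,
and the data at a locus are per-pool nucleotide counts, not genotypes. This
vignette explains the models and estimators, the tunable parameters, what
the synthetic-data generator does and does not emulate, and the numerical
choices that a maintainer would otherwise have to reverse-engineer.

## Read-recruitment quality control

Before any statistic, a sample must prove that its recruited reads come
from the target genome. The cascade applies, in order:

1. **Identity pre-filter** at 80% per-read identity (identity = 100 ×
   matches / alignment length, gap columns counted in the denominator).
2. **Mean vertical coverage ≥ 4×** and **coverage breadth ≥ 80%**, both
   computed over *all* reference positions, zeros included. Averaging over
   covered positions only would reward patchy recruitment; the conservative
   definition is used.
3. **Identity filter at 97%** on the survivors.
4. **Unimodality of the coverage profile.** Non-specific recruitment (e.g.
   via conserved rRNA loci or hypervariable regions) shows up as a second
   mode in the depth distribution. We operationalise what is often a visual
   inspection as Hartigan's dip statistic on the nonzero depths with a
   bootstrap p-value (uniform reference, the standard calibration). The
   sample passes when `p >= 0.05`.

The order of stages follows the filtering description the thresholds come
from: coverage is assessed after the 80% stage and before the 97% stage;
`qc_thresholds(coverage_after_final = TRUE)` flips this, since the source
protocol does not pin it down.

**The dip statistic is implemented from scratch** (no R implementation is
among this package's dependencies): the iterative greatest-convex-minorant
/ least-concave-majorant algorithm, validated in the test suite against an
independent brute-force oracle that finds, by bisection and quadratic
programming, the smallest tube width admitting a nondecreasing
convex-then-concave CDF through the ECDF constraints. Depth counts are
discrete; tied data are jittered by half the smallest positive gap so the
continuous uniform reference applies. Bootstrap resolution defaults to
`n_boot = 200` (p-value grid of 1/201, ample for a 0.05 threshold), and
dips are computed on at most 5,000 subsampled values to bound cost.

## SNV calling and the variant landscape

A site is a single-nucleotide variant (SNV) when the pooled minor-allele
count is at least 2 and every pool's depth lies in `[4, 200]`
(min-covered-fraction-1 semantics: a site out of window in *any* admitted
pool is excluded genome-wide). Only the top non-reference allele is kept as
the alternate (ties broken in the fixed order A < C < G < T); residual
alleles are a representation choice, matching the downstream B-allele
frequency (BAF) matrix. SNV density is reported per *covered* position, not
per genome length, so assembly gaps do not dilute it.

Context classification assigns each variant to exactly one of coding, UTR,
intron, intergenic, with precedence coding > UTR > intron on overlap.
Effects substitute the alternate base into its codon (reverse-complementing
on the minus strand), translate with the standard genetic code, and report
silent / missense / nonsense; stop-loss changes are folded into missense
because only three effect classes are reported.

## Fixation indices

Two frequency-based estimators are exposed:

* **Pairwise, per locus** (`locus_fst`): with pool frequencies $p_1, p_2$
  and $\bar p = (p_1+p_2)/2$,
  $$F_{ST} = \frac{H_T - H_S}{H_T},\qquad
    H_T = 2\bar p(1-\bar p),\quad
    H_S = \tfrac12\left(2p_1(1-p_1) + 2p_2(1-p_2)\right),$$
  defined as 0 when $H_T=0$. Monomorphic (non-informative) loci are
  *suppressed*, not counted as zeros, and pairwise matrices aggregate loci
  by the **median**. A pool-size/read-depth corrected variant
  (`estimator = "corrected"`, default pool size 500) is available for
  comparison with classical pool-seq tooling; it is not the default because
  the frequency-based form is the one the pairwise contract specifies.

* **Multi-population, per locus** (`multipop_fst`): with $n$ pools,
  $\hat F = s^2 / (\bar p(1-\bar p) + s^2/n)$ where $s^2$ is the unbiased
  between-pool variance. Under the island model the ratio of expectations
  equals the inbreeding coefficient for any $n \ge 2$ — the naive
  $(H_T-H_S)/H_T$ form is biased downward by a factor of roughly
  $(n-1)/(n-F)$ — so this corrected form is used wherever a per-locus
  statistic must be compared to its generating parameter: the
  Lewontin-Krakauer scan and the differentiation-recovery checks.

Median pairwise FST is the package's proxy for genomic differentiation;
`differentiation_class` applies the guideline bands (< 0.05 low, 0.05-0.15
moderate to high, ≥ 0.15 great). Region-level matrices average the median
pairwise values of all sample pairs spanning two regions. The
population-wide per-locus FST distribution is itself dip-tested: a
multimodal distribution suggests the reference recruited more than one
species.

## Selection scans

**Lewontin-Krakauer.** $LK_l = (n-1)\,F_l/\bar F$ with $\bar F$ the *mean*
per-locus FST (the classical definition; the alternative median normaliser
is not used). Under neutral drift of a single species $LK \sim \chi^2_{n-1}$,
giving p-values and Benjamini-Hochberg q-values; candidates at `q < 0.15`.

**PCA/Mahalanobis outlier scan.** Loci with across-pool minor allele
frequency below 0.05 (computed on the mean BAF) are dropped; loci are
centred and scaled by $\sqrt{\bar p(1-\bar p)}$; the pools-by-loci matrix
is decomposed by SVD, each locus receives its score vector on the top $K$
axes, and a robust Mahalanobis distance (minimum covariance determinant, so
that outlier loci do not inflate their own null) is divided by the genomic
inflation factor (observed median over the $\chi^2_K$ median) before
$\chi^2_K$ p-values and BH q-values. $K$ defaults to $n-1$: with the 3-9
pools typical of MAG recruitment there is no room for scree-based
selection, and the planted-outlier simulations show full power and a
negligible false-flag rate at this default. Selection scans derive their
BAF matrix without the per-pool depth window
(`baf_matrix(..., per_pool_window = FALSE)`): locus admission inside the
scan is governed by its own MAF filter, and the depth window — a
variant-calling and FST concern — would otherwise discard strongly
differentiated loci at overdispersed depths.

**Aberrant pools.** Before scanning, pools whose principal-component scores
sit more than 6 median-absolute-deviations from the median on any retained
axis are flagged so the caller can exclude them and re-run (the
false-positive-inflation guard). Only axes carrying at least an average
share (1/n) of the variance are inspected: with a handful of pools the
trailing axes are noise and over-flag.

## Isolation by environment

Environmental preprocessing drops ammonium, sums nitrate and nitrite into
one variable, and z-scores everything with the *population* standard
deviation (so three evenly spaced values map to ±1.2247, 0). Collinearity
is reported — pairwise Spearman correlations flagged at `p < 0.01`,
variance inflation factors flagged at ≥ 10 — but flagged variables are
retained, since nutrient variables with known biological relevance should
not be silently removed.

**Variance partitioning.** The response is the vectorised upper triangle of
the median pairwise-FST matrix, one observation per sample pair. Each
variable's Euclidean distance matrix over samples is turned into a
covariance kernel over the *pair* observations: Gower double-centring of
the squared pairwise-distance differences, which collapses algebraically to
the centred outer product of the distance vector (a rank-one kernel per
variable). Kernels are scaled to trace $m$ (the identity's trace over $m$
pairs) so each estimated component is directly a per-observation variance
and shares are comparable. Components for all kernels plus the identity
residual are estimated by EM-REML with non-negativity clipping;
convergence is declared on the restricted log-likelihood (relative change
below 1e-6), because a component crawling toward the zero boundary changes
the parameters forever but the likelihood not at all; components below
1e-6 of the total are pinned to zero. When there are fewer than 6 pairs, or
at least as many components as observations (both common with 3-4 pools
and a full variable set), REML is unidentifiable and a Haseman-Elston-style
method-of-moments fit (least squares of the centred outer product of the
response on the kernels) is used instead; the `method` field records which
route ran. The reported `fixed_share` is the share of the total mean square
attributable to the fitted intercept, kept distinct from the residual
component. A residual share above 30% triggers a weak-identification
warning — with ≤ 10 pairs and ≥ 5 kernels the model cannot do better, and
the warning surfaces that honestly.

**Mantel verification.** For each variable, the Pearson correlation of
lower triangles with a one-sided permutation p-value,
$p = (1 + \#\{r_{perm} \ge r_{obs}\})/(n_{perm}+1)$, 9,999 permutations by
default, bit-reproducible given the seed. The test suite cross-checks the
statistic against an independent implementation.

## The synthetic-data generator

`simulate_metapopulation` draws, per locus, an ancestral frequency uniform
on `ancestral_maf_range` (default 0.1-0.9: segregating mid-frequency loci,
the regime in which a MAF-filtered pool-seq panel lives), then per-pool
frequencies from the Balding-Nichols Beta parameterisation with inbreeding
coefficient `fst_target`; depths are negative-binomial
(`coverage_dispersion` is the inverse size, Poisson in the limit 0, default
0.2 ≈ the depth CV of uneven metagenome recruitment) and counts binomial.
Defaults — 4 pools, 5,000 loci, 100× depth, `fst_target = 0.05` — are the
conditions under which the estimator-recovery, null-calibration and power
properties are stated.

*Planted outliers* redraw at the elevated `fst_selected` until the realized
frequency vector is actually polymorphic (mean BAF ≥ 0.05) and
differentiated (realized multi-pool FST ≥ `fst_selected`/2, at most 50
redraws): a "selected" locus that happened to draw near-identical
frequencies in every pool would be an incoherent truth label for a power
analysis.

*Environmental linkage.* Under iid Balding-Nichols draws the pools are
exchangeable, so the pairwise genetic distance matrix has no
low-dimensional structure an environmental gradient could track — the
realized distances are sampling noise around a constant. When `env_link`
is requested, pool frequencies are therefore drawn through a Gaussian
copula whose inter-pool correlation decays along a latent gradient
(`exp(-d/0.5)`); the Beta marginals, and hence every per-pool property, are
unchanged. Linked variables are then built from the one-dimensional
classical-MDS embedding of the realized genetic distance matrix mixed with
independent noise, the mixing angle grid-searched (181 points over
[0, π/2]) so the realized squared-environmental-distance vs
genetic-distance correlation equals the requested fraction; the realized
value is recorded in `truth$env_fractions_realized`. At fractions near 0.8
the one-dimensional embedding occasionally caps the achievable correlation
slightly below target; the realized value is the honest truth label.

What the generator does **not** emulate: sequencing error and base-quality
structure, indels, multi-allelic sites, linkage between loci, reference
bias, or a real demographic history — pools are a statistical island model,
not *Chaetoceros* biology. Passing tests therefore demonstrate estimator
and scan correctness under the stated statistical model, not robustness to
every artefact of real metagenomes.

`simulate_annotation` builds a toy multi-contig genome (genes with UTRs,
1-3 CDS exons, introns, both strands, intergenic gaps) and draws mutations
by enumerating, for every coding position, the effect class of each of the
three possible substitutions — so effect labels are planted exactly, and
the requested transition:transversion ratio (default 1.5) and
context composition (default 50% coding / 30% intergenic / 15% UTR / 5%
intron, echoing the composition typically observed for such genomes) are
realized up to multinomial sampling.

## Problem sizes and determinism

The shipped test-suite and acceptance computations use 4-8 pools, 2,000 to
20,000 loci, 50-replicate recovery grids and 1,000-trial permutation
calibrations — sizes at which every stated tolerance band is comfortably
resolved while a full run stays in the minutes range. All randomness flows
through explicit seeds (`local_seed` restores the caller's RNG state), and
re-running any pipeline configuration with the same seed reproduces
byte-identical artefacts.

## Known limitations

* The pairwise FST estimator is the uncorrected frequency form by
  contract; between-pair comparisons at very different depths should use
  `estimator = "corrected"`.
* The LK test assumes a shared drift history across loci; its null is
  calibrated here under the island model only.
* With rank-one environmental kernels, collinear variables alias: the sum
  of their shares is stable but the split between them is arbitrary (the
  duplicated-kernel test pins exactly this behaviour).
* Mantel tests on autocorrelated environmental variables can be
  anticonservative; they are a verification layer, not the primary
  inference.
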