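---
title: "Haplotype-block diversity, differentiation and nucleus selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-block diversity, differentiation and nucleus selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapdiv)
```

# Why haplotype blocks

Commercial SNP arrays are ascertained in cosmopolitan breeds, so
single-SNP diversity statistics systematically understate the diversity
of unselected local populations relative to the breeds the array was
designed on.  Short phased haplotypes largely escape this bias: even if
the individual SNPs are common everywhere, the *combinations* they form
over a few tens of kilobases differ between populations, and a window of
four SNPs defines up to 16 distinguishable alleles.  `hapdiv` therefore
converts a filtered SNP panel into non-overlapping 4-SNP blocks and runs
the classical multi-allelic toolbox on the block alleles.

## Block construction

Blocks are built by a greedy left-to-right scan within each chromosome:
a run of consecutive SNPs is extended while the gap to the next SNP is
below `max_gap` (default 50 kb); each time the run accumulates
`block_size` (default 4) SNPs a block is emitted and the run restarts; a
gap at or above the threshold resets the run; leftover runs shorter than
four SNPs are discarded.  The source material does not specify the
partition algorithm; the greedy scan is deterministic, maximizes the
number of blocks under the gap rule, and automatically bounds every
block span below `3 * max_gap` = 150 kb.  Variable-size blocks are
deliberately not produced — four SNPs per block is treated as exact.
Monomorphic blocks stay in the denominator of the mean-alleles-per-block
statistic `mA = nA / B`; `B` is always the realized block count.

Haplotype strings are mapped to dense integer codes per block in order
of first appearance across the combined sample (animal order, first then
second haplotype).  A missing genotype at any member SNP flags the whole
block genotype of that animal as absent; the animal is excluded from
that block's counts only.

# Quality control

SNPs are retained when (i) the call rate over the combined sample is at
least 95 %, (ii) the pooled minor-allele frequency is at least 0.025,
and (iii) the within-breed Hardy–Weinberg conditional exact test is not
rejected at `P < 0.01` in any breed with at least 10 genotyped animals.
Three choices here were genuinely open and are our own: the exact test
(rather than a chi-square) because array QC with modest within-breed
samples is exactly the regime where the chi-square approximation fails;
the *any-breed* aggregation rule because it is conservative; and the
10-animal floor because exact tests on a handful of genotypes carry no
information and would veto SNPs on noise.  Call rate is computed over
the combined sample, the standard array-QC convention.

# Diversity statistics

All statistics run on per-block allele-count tables (`tally_alleles`).

* **Allele classes.**  A block allele observed in exactly one breed is
  private (`npA`); in exactly two breeds, rare (`nrA`) and credited to
  *both* carriers (the pooled row therefore counts each distinct rare
  allele once, i.e. half the per-breed sum); in all breeds, common
  (`ncA`).  This "rare" definition is aimed at introgression: an allele
  private to a donor breed that has leaked into one recipient becomes
  rare in both.
* **Heterozygosity.**  `H_O` is the fraction of genotyped animals whose
  two block alleles differ, averaged over blocks.  `H_E` is Nei's
  unbiased estimator `(2n/(2n-1))(1 - Σ p̂²)` per block and breed,
  averaged over blocks.  `H_O[SNP]` is the per-animal fraction of
  heterozygous SNP genotypes averaged within breed — kept as a contrast
  column precisely because its disagreement with the block statistics is
  the ascertainment-bias signal.
* **Allelic richness.**  Hypergeometric rarefaction to a standardized
  depth of `g` gene copies; by default `g` is the smallest positive
  (block, breed) gene-copy total, i.e. standardization to the smallest
  sample, and is reported alongside the table.  At full depth the
  estimator equals the observed allele count exactly (this identity is a
  test).
* **F-statistics.**  Weir–Cockerham variance components per allele per
  block, summed over alleles and blocks.  The test suite checks the
  implementation against an independent ANOVA mean-square formulation to
  1e-10.
* **Pairwise G_ST and D_EST.**  Per block and breed pair, `H_S` is the
  unweighted mean of the two unbiased within-breed gene diversities and
  `H_T` the unbiased diversity of the unweighted mean allele frequencies
  with the Nei–Chesser small-sample correction
  (`H_T = 1 - Σ p̄² + H_S/(4 Ñ)`, `Ñ` the harmonic-mean sample size).
  Unweighted averaging is our choice: breed samples are very unequal and
  weighting would let the larger sample dominate a two-breed contrast.
  Jost's per-block `D = 2 (H_T - H_S)/(1 - H_S)` is combined across
  blocks by the variance-corrected harmonic mean
  `D_EST = Ā³/(Ā² + s²)` with `Ā`, `s²` the mean and variance of the
  per-block values.  Per-block `D ≤ 0` values are *retained* (no
  truncation, which would bias the multilocus estimate upward); blocks
  with `H_S = 1` (undefined `D`) are excluded.  The algebraic form
  `Ā³/(Ā² + s²)` is used because the naive harmonic mean is undefined
  whenever any block has `D ≤ 0`.
* **Estimator bias at identity.**  Applied to two *identical* finite
  samples the corrected estimators return a small negative value of
  order `1/n`, not exactly zero; values are reported as computed, never
  clamped.

# Distances and the 2D ordination

Nei's `D_A(x, y) = 1 - L⁻¹ Σ_blocks Σ_i √(x_i y_i)` between breeds and
the shared-allele distance `D_PS = -ln(PS)` between individuals, where
`PS` is the mean over commonly typed blocks of the multiset intersection
of the two block genotypes divided by two (A/A vs A/B shares one; A/A vs
A/A shares two).  The sign of the logarithm is a deliberate correction
of the source's printed `ln(PS)`, which is non-positive and cannot serve
as a distance.  Pairs sharing nothing get an infinite sentinel, replaced
on export by 1.1 times the largest finite entry (logged).  Neither
distance satisfies the triangle inequality in general; none of the
downstream uses require it.  Matrices export as square PHYLIP and NEXUS
`DISTANCES` blocks for tree/network software; network construction
itself is out of scope.

The 2D ordination starts from classical multidimensional scaling
(`stats::cmdscale`; axis signs fixed so each axis's largest-magnitude
coordinate is positive, making the start deterministic) and is refined
by a great-deluge search: the objective is the Pearson correlation
between the condensed input distances and the condensed 2D Euclidean
distances; one uniformly chosen individual is perturbed per iteration by
centred Gaussian noise; a move is accepted iff the objective does not
fall below the water level, which starts at the initial objective and
rises by `rain_speed × (best - level)` after every acceptance.  The
concrete schedule (defaults `step_sigma` = 10 % of the coordinate
spread, halved after 500 consecutive rejections; `rain_speed = 0.02`;
`max_iter = 2e5`) is our own: the cited heuristic is described only in
outline, so the scheme was chosen for determinism under a seed and a
guaranteed monotone best-objective sequence.  Pearson (not rank)
correlation is the objective, matching the least-squares character of
the PCoA start.  A literal reading of "stop when the level reaches the
best objective" would terminate before the first move (they start
equal), so the stop fires only after at least one acceptance, or when
the adaptive step has collapsed below 1e-14.

# Genomic relationships

With genotype dosage `x ∈ {0, 1, 2}` and pooled-sample frequency `p` per
SNP, off-diagonals are `mean[(x_i - 2p)(x_j - 2p)/(2p(1-p))]` and the
diagonal is `1 + mean[(x² - (1+2p)x + 2p²)/(2p(1-p))]`, i.e. one plus an
inbreeding estimate.  Per-SNP standardization (not a global VanRaden
denominator) matches the IBS-to-IBD reconciliation this estimator comes
from.  Frequencies come from the combined sample because no per-breed
reference is available in the intended use; a consequence — reproduced
in simulation — is that average relationships among a focal breed's
animals are slightly negative.  Monomorphic SNPs are excluded; pairs are
averaged over SNPs genotyped in both animals.

# Supervised admixture and nucleus selection

The admixture estimator is deliberately *supervised*: reference breed
allele frequencies are estimated from labelled reference animals,
clamped into `[0.001, 0.999]`, and each query animal's ancestry vector
`q` maximizes `Σ_snps [x log(Σ_k q_k f_k) + (2-x) log(Σ_k q_k(1-f_k))]`
over the simplex by EM from a uniform start (tolerance `1e-6` on the
update, cap 1000 iterations, last iterate returned with a flag on
non-convergence).  Unsupervised likelihood clustering and
cross-validated choice of K are out of scope; the recovery use-case
knows its candidate source breeds.  If the references are
indistinguishable at every SNP the likelihood is flat; the function
warns and flags the result rather than returning an arbitrary point
silently.  In simulations, recovery of a pure animal to `q ≥ 0.95`
needs reference panels of roughly 50 animals per breed (the emulated
survey's breed sample sizes); smaller references leave a few percent of
mass on the wrong component through frequency-sampling noise.

Nucleus selection is staged and deterministic.  Stage 1 excludes
animals whose pedigree foreign fraction exceeds 12.5 % (pedigree breed
composition: founders are 100 % their labelled breed, others the
average of their parents; an unknown parent counts as a purebred focal
founder and flags the animal `pedigree_incomplete`, mirroring herd-book
practice while keeping the bias visible).  Stage 2 repeatedly takes the
worst remaining pair above the 0.25 relationship threshold and drops
one member: an inbred one (self-relationship > 1.05) if exactly one
qualifies, otherwise the member with the higher mean relationship to
the remaining focal animals, ties broken by id.  Stage 3 excludes
animals whose mean relationship to any reference breed exceeds that
breed's mean plus 2 SD; the baseline is the distribution over *all*
focal animals, the least ambiguous reading of "2 SD above average".
Every exclusion is logged with its stage and numbers.  Lowering the
relationship threshold can only shrink the nucleus (tested).  For the
evidence correlations, type classes are coded focal = 0, semi = 1,
source = 2 — an ordinal coding choice of ours — and constant columns
yield `NA`, not zero.

# The synthetic generator

`simulate_panel()` emulates a medium-density array survey of ~15 breeds
with unequal sample sizes (defaults: 15 breeds, the survey's sample
sizes, 29 autosomes × 1,534 SNPs ≈ 44.5 k SNPs at 56.4 kb mean
exponential spacing).  Consecutive 4-SNP groups form generator blocks;
each block has a pool of six distinct founder haplotypes (a pool size
chosen once because it yields `mA` in the empirically observed 5–9
range) whose ancestral frequencies are Dirichlet(1); each breed's pool
frequencies are drawn with Dirichlet concentration `π (1-F)/F`, the
multi-allelic analogue of the Balding–Nichols beta construction, with a
default drift `F = 0.1` per breed — a typical between-breed divergence
for European cattle.  Blocks are in linkage equilibrium with one
another, by design: the downstream estimators treat blocks as
independent multi-allelic loci, and inter-block LD is explicitly not
modelled.  Admixed focal animals draw each block haplotype's breed of
origin i.i.d. with probability `q` from the source breed; the default
admixture spec plants a 6 : 12 : 12 split of the focal sample at
`q = 0.0625, 0.25, 0.5`, mirroring the documented structure of the
emulated population (a few low-grade and two dozen substantially
admixed animals out of 76).  Pedigrees have three strata: purebred
focal founders, known-pedigree admixed animals (F1 structures at
`q ≥ 0.5`, backcross structures at `q = 0.25`), and no-pedigree animals
recorded as purebred (the low-grade admixed group plus every fourth
purebred).  Type classes follow true focal ancestry (pure ≥ 7/8, semi
≥ 1/2, else source type) and are misrecorded with probability 0.1;
genotypes are masked at rate 0.02 after the unmasked truth is stored.

What the generator does *not* emulate: coalescent site-frequency
spectra, recombination maps, inter-block LD, X chromosomes, genotyping
batch effects.  Passing tests therefore demonstrate estimator
correctness and recovery under the stated drift model, not performance
on every feature of real array data — in particular, real blocks are
autocorrelated along chromosomes, so effective numbers of independent
loci are smaller than block counts.

# Numerical choices and problem sizes

Rarefaction uses `lchoose` differences (exact up to floating point);
the HWE test enumerates heterozygote counts in log space; the EM
clamps reference frequencies to avoid infinite log-likelihoods; the
deluge updates the correlation through running sums (O(n) per move).
Test and acceptance runs use scaled-down panels — hundreds of SNPs to a
few thousand, 2–5 breeds, 10–20 replicates — sizes at which every
Monte-Carlo check has comfortable margins while the whole suite runs in
minutes; the estimators themselves are vectorized and handle
survey-scale data (tens of thousands of SNPs, hundreds of animals).

# Known limitations

Input haplotypes must be pre-phased (phasing and imputation are out of
scope); the HWE aggregation rule and the pairwise-averaging convention
are documented choices where the source material is silent; `D_PS`
pairs with no shared alleles are representable only through the export
sentinel; and the great-deluge schedule is one member of a family of
threshold-accepting searches — different schedules reach slightly
different local optima, which is why the seed and the start/final
correlations are part of the result object.
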