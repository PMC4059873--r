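---
title: "Methods: sliding-window bin maps and QTL scans for low-coverage F2 populations"
author: "BinMapQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding-window bin maps and QTL scans for low-coverage F2 populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BinMapQTL)
```

# The setting

An F2 intercross between two inbred parents segregates AA : AB : BB at
1 : 2 : 1 at every locus. Low-coverage genotyping-by-sequencing observes
each individual at a sparse random subset of the parental SNP catalogue —
at ~0.04× coverage roughly one site per 130 kb per individual — and at a
heterozygous site a single read reports one of the two parental alleles at
random. Per-site genotypes are therefore unusable; the analysis instead
pools information along the chromosome, exploiting that an F2 genome is a
mosaic of a handful of long parental segments (a few crossovers per
chromosome).

This vignette describes each stage of the pipeline, its assumptions, the
tunable parameters, and the numerical and design choices that were open.

# Window calling and genotype blocks

Per individual and chromosome, the observed allele calls (A = allele of
the first parent, B = second parent) are scanned in sliding windows of
`window = 18` SNPs advancing by `step = 2`. A window with
`homMin = 15` or more alleles from one parent is called homozygous for
that parent; anything below the cutoff is heterozygous. These defaults are
the standard operating point for maize-scale GBS data: under the
single-read model a heterozygous window has Binomial(18, ½) parental
counts, so 15-of-18 mislabels a heterozygous window homozygous with
probability ~0.75%, while a homozygous window needs four or more of
18 calls wrong to be mislabelled — negligible at a 1% allele error rate.
The cutoff must satisfy `homMin > window/2` so the homozygous calls cannot
overlap; an exact A/B tie is heterozygous. If a chromosome has fewer than
18 observed SNPs a single window over all `k` of them is called with the
cutoff rescaled to `ceiling(15/18 * k)`, preserving the 83% homozygosity
ratio.

Maximal runs of identically-called windows become genotype blocks.
Because consecutive windows share 16 of 18 SNPs, a single extreme stretch
of calls flips up to `window/step = 9` consecutive windows; a dissenting
run shorter than 9 windows flanked by two runs of one identical call is
therefore absorbed (`smooth = TRUE`), suppressing error-driven spurious
double crossovers. The cost is that genuine segments spanning less than
one full window of observed SNPs (~2.3 Mb at study-like density) are
invisible; `smooth = FALSE` disables the absorption.

## Breakpoint localization

The recombination breakpoint between two adjacent blocks lies somewhere in
the transition zone spanned by the two boundary windows. Two rules are
provided:

* `refine = FALSE`: the midpoint between the last observed SNP of the left
  run's final window and the first observed SNP of the right run's first
  window.
* `refine = TRUE` (default): the split of the transition-zone SNPs that
  maximizes the emission likelihood of the two flanking genotypes, with
  emission model P(B | AA) = e, P(B | AB) = ½, P(B | BB) = 1 − e for
  allele error rate e; the breakpoint is the midpoint of the two SNPs
  straddling the optimal split.

The refinement is the default because the midpoint rule is biased towards
the heterozygous side of a transition: the homozygous call persists ~6–8
SNPs into a heterozygous segment before the fourth B allele arrives, so at
one observed SNP per 130 kb the midpoint lands several hundred kb from the
truth on average (simulation places its median error near 375 kb, versus
~45 kb for the likelihood changepoint; the package's recovery tests bound
the refined median error at 150 kb). On clean, dense data the two rules
coincide. Breakpoint positions are conventions of the *estimate*; a
position exactly at a block boundary belongs to the right block.

# Bin construction

Chromosomes are cut into grid intervals of `gridUnit = 100000` bp
(half-open, 0-based internally; all exported tables are 1-based
inclusive). A grid interval is *recombinant* if at least one individual's
inferred breakpoint falls in it — the interval containing base `b − 1` for
a breakpoint at `b`, so a breakpoint at an exact grid boundary stays at a
bin edge. Maximal runs of non-recombinant intervals merge into bins;
recombinant intervals stand alone. After construction no individual
recombines strictly inside a multi-interval bin, so each bin is a single
marker for the whole population.

An individual's genotype in a bin is the genotype of the block covering
the larger share of the bin; an exact tie gives NA. How the
breakpoint-carrying individual's boundary bin should be coded is
genuinely underdetermined; larger-share is the neutral choice and affects
only the one individual recombining in that bin.

Crossovers per individual are counted from the bin genotype sequence
(NA skipped): transitions AA↔AB and AB↔BB weigh 1, AA↔BB weighs 2, since
the latter requires a crossover in both gametes between the two markers.

## Marker filtering

Bins are removed when (in order of precedence):

1. **distorted** — χ² against 1 : 2 : 1 (2 df, no continuity correction,
   expected (¼, ½, ¼)·n over non-NA calls) has *P* < `pCut = 1e-10`;
2. **two-genotype** — only two genotype classes are present;
3. **monomorphic** — one class, or a minor-class frequency below
   `monoFreq = 0.01` (the "nearly monomorphic" cutoff is not fixed by any
   reference; 1% is configurable).

Filtering is idempotent, and the full decision trail (counts, χ², *P*,
reason) is kept in the segregation report.

# Genetic map estimation

The recombination fraction r between each pair of physically adjacent bin
markers is the F2 two-point maximum-likelihood estimate, computed by EM:
joint genotype class probabilities derive from two independent gametes
each recombinant with probability r; the double-heterozygote class mixes
the 0- and 2-recombinant configurations with weights (1−r)² and r²
(normalized); the E-step assigns each class its expected recombinant
gametes and the M-step sets r to expected recombinant gametes over 2n.
Iteration stops at |Δr| < 1e-8; the estimate is clamped to
[0, `rMax = 0.4999`] so the Haldane transform stays finite, and its
standard error comes from the numerically differentiated observed
information. Pairwise-complete individuals only are used.

Map distance is Haldane's d = −50 ln(1 − 2r) cM, cumulated within
chromosomes from 0 at the first marker. Two design points deviate from a
full multipoint treatment deliberately:

* **Two-point instead of multipoint EM.** Bin genotypes are near-complete
  (missingness is confined to tied boundary bins), and with complete data
  the multipoint likelihood factorizes over adjacent intervals, making the
  two estimators coincide; the two-point version is simpler and O(markers).
* **No interference.** Haldane's function matches the simulator's Poisson
  meiosis; Kosambi-style interference modelling is out of scope, and
  physical marker order is taken as given throughout.

# QTL scanning

Traits are regressed marker by marker on x_a ∈ {+1 (AA), 0, −1 (BB)} and
x_d ∈ {1 (AB), 0}, giving LOD = (n/2) log₁₀(RSS₀/RSS₁) against the
intercept-only fit on the same individuals; at a fully genotyped marker
this equals Haley–Knott regression and, with all three classes present,
the saturated group-means likelihood ratio (the package's tests exploit
the latter as an independent oracle). Individuals with a missing genotype
at the scanned marker are dropped there — with near-complete bins there is
nothing to impute. Positions between markers are not scanned; with ~0.2 cM
bin spacing the loss of resolution is below the interval width of any
detectable QTL. The sign convention is a > 0 when the first parent's
allele increases the trait. A binary trait (e.g. a 0/1 colour score) is
scanned with the same linear-model LOD by default, as a normal-model scan
would; `glm`-based logistic scanning is deliberately not the default so
thresholds remain comparable across traits.

**Permutation threshold.** The trait is permuted over individuals
`nPerm = 1000` times; each permutation records the genome-wide maximum
LOD, and the threshold is the order statistic
`ceiling((1 − alpha) * nPerm)` (the 950th of 1000 sorted maxima at
`alpha = 0.05`). Thresholds are computed per trait, since missingness
patterns differ. For a single 2-df test the threshold converges to
χ²₂(0.95)/(2 ln 10) ≈ 1.30; on a dense ~1,400 cM F2 map with n ≈ 700 it
sits near 4 (both are verified in the acceptance tests). Permutations run
through a vectorized group-sums engine that is algebraically identical to
the marker regression; the equivalence is itself under test.

**Support intervals and effects.** The 1.5-LOD support interval is the
maximal contiguous marker run containing the peak with LOD ≥ peak − 1.5
(ties for the peak take the leftmost and are flagged); its endpoints are
reported as the physical bounds of the terminal bins and their cM
positions. Effects at a marker are a = (μ_AA − μ_BB)/2,
d = μ_AB − (μ_AA + μ_BB)/2, and R² (%) = 100·(1 − RSS₁/RSS₀).

**Multiple QTL.** `scanMulti` approximates multiple-QTL mapping by forward
cofactor selection: accept the genome-wide peak if it reaches the
threshold, add its additive/dominance codings as covariates, rescan,
repeat (up to `maxQtl = 10`). Accepted QTL are re-profiled with the other
QTL as cofactors for their conditional LOD and interval; effects come from
the joint model, and each QTL's R² is its drop-one loss of explained sum
of squares over the total. A minimum-separation guard
(`minSeparationCM = 15`, or 10 Mb without a map) excludes candidate peaks
tightly linked to an already-accepted QTL: after conditioning on a strong
locus, sporadic bin-genotype miscalls at neighbouring bins leave formally
significant residual signal that is an artefact of genotyping error, not a
second locus. The guard's cost is that genuinely linked QTL closer than
the separation cannot be resolved — consistent with the resolution any
F2 of this size can support.

# The synthetic-population generator

`simulateF2` draws, per gamete and chromosome, a Poisson number of
crossovers with mean equal to the chromosome length in Morgans and uniform
crossover positions (no interference — matching Haldane), and forms each
F2 from two independent F1 gametes. `makeParentalSNPs` places catalogue
SNPs uniformly at density 1/1770 bp. `observeAlleles` observes each site
independently with rate 1770/130300 ≈ 0.0136 (one observed SNP per
~130.3 kb per individual, the ~0.04× operating point), emits the parental
allele at homozygous sites and a fair coin at heterozygous sites (single
read), then flips the call with `errorRate = 0.01`. `simulatePhenotypes`
adds per-locus a·x_a + d·x_d to Gaussian noise and scores an optional
dominant binary locus as 1 iff at least one dominant allele is carried
(expected 3 : 1).

What the generator does *not* emulate — and what passing tests therefore
do not certify about real data: restriction-site-driven, spatially
clustered site recovery (observation here is i.i.d. per site); depth
variation and multi-read sites; reference-alignment artefacts and
segregation distortion of biological origin (simulated markers are fair,
so the distortion filter is exercised only by constructed fixtures);
crossover interference; and linked or epistatic trait architectures beyond
additive + dominance.

All stochastic functions require an explicit `seed` and restore the
caller's RNG state, so library use is reproducible and side-effect-free.

# Problem sizes used in validation

The package's own validation (test suite and acceptance script) uses these
scales, chosen to keep the per-base-pair statistics of the real setting
while remaining desk-sized:

* **Threshold and null calibration:** n = 700 complete genotypes,
  10 chromosomes × 140 cM at 1 marker/cM (the study's map dimensions),
  1000 permutations; 500 replicate null scans for the false-positive rate.
* **Recovery from raw observations:** n = 708, genome 2 × 100 Mb at
  0.68 cM/Mb, SNP catalogue 1/1.77 kb, observation rate 1/130.3 kb,
  1% error. Chromosomes of 100 Mb keep the ~2.3 Mb window span small
  relative to chromosome length, as in a real maize genome; on short desk
  chromosomes the method's intrinsic blindness to terminal segments
  shorter than one window dominates the map-length error.
* **Interval coverage:** 100 replicates of a single QTL with a = −2.1,
  d = −0.2, σ = 5.8 (R² ≈ 6.2%) at n = 708 — the size of a
  mid-sized tassel-architecture QTL.

# Known limitations

* Breakpoints are point estimates without confidence intervals; a hidden
  Markov model over sites would provide posteriors but is out of scope.
* Terminal chromosome segments spanning fewer than ~13 observed SNPs are
  undetectable, slightly deflating map length (visible on short
  chromosomes).
* The two-point map inherits any residual bin-genotype errors as a small
  upward bias in adjacent-pair r; smoothing keeps this below a few
  percent of total map length at the default operating point.
* Forward cofactor selection is greedy; it does not revisit accepted QTL
  and cannot separate loci closer than the separation guard.
* The linear-model LOD for binary traits is a working approximation; for
  strongly unbalanced binary traits the logistic option is preferable.
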