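# BinMapQTL

Bin-map construction and QTL mapping for large, ultra-low-coverage F2
populations.

## The problem

Genotyping-by-sequencing (GBS) makes it cheap to genotype hundreds of F2
plants, but at ~0.04× coverage each individual is observed at only a sparse,
mostly non-overlapping subset of the parental SNPs — roughly one observed
SNP per 130 kb — and each heterozygous site is seen through a single read
that shows one parental allele at random. No single site can be genotyped
reliably; the information lives in runs of neighbouring sites.

`BinMapQTL` implements the standard sliding-window strategy for this
setting, end to end:

1. **Window calling.** Per individual, observed parental-allele calls
   (A = first parent, B = second parent) are scanned in windows of 18 SNPs
   advancing by 2. A window with ≥ 15 alleles from one parent is called
   homozygous for that parent; anything less is heterozygous.
2. **Blocks and breakpoints.** Runs of identically-called windows merge
   into genotype blocks; the boundary between adjacent blocks is a
   recombination breakpoint, localized by a maximum-likelihood changepoint
   within the transition zone (an SNP-midpoint rule is available as
   `refine = FALSE`).
3. **Bin map.** Chromosomes are cut into 100-kb grid intervals;
   consecutive intervals in which *no* individual recombines are joined
   into bins. Each bin is one marker genotyped across the population
   (AA/AB/BB/NA) — a `BinMap` object extending
   `RangedSummarizedExperiment`.
4. **Filtering.** Bins distorted from the F2 expectation 1:2:1
   (χ², 2 df, *P* < 10⁻¹⁰), with fewer than three genotype classes, or
   nearly monomorphic are removed.
5. **Genetic map.** Recombination fractions *r* between adjacent bins are
   estimated by two-point EM for an F2 intercross and converted to map
   distance with Haldane's function, *d* = −50 ln(1 − 2*r*) cM.
6. **QTL scan.** Marker regression of each trait on the additive
   (*x_a* = +1/0/−1) and dominance (*x_d* = 1 for AB) codings gives
   LOD = (*n*/2) log₁₀(RSS₀/RSS₁); genome-wide significance comes from
   1000 phenotype permutations (5% order statistic of the max-LOD
   distribution); each QTL gets a 1.5-LOD support interval, additive and
   dominance effects (*a* = (μ_AA − μ_BB)/2, *d* = μ_AB − midpoint) and
   R² (%). A forward-cofactor scan approximates multiple-QTL mapping.

A synthetic-population module (`simulateF2`, `observeAlleles`,
`simulatePhenotypes`) generates F2 genomes by interference-free Poisson
meiosis with full ground truth, emulating the sparse single-read GBS
observation process, so every stage can be validated against known
parameters.

## Worked example

A desk-scale run: 150 F2 individuals on a 4 × 5 Mb genome with study-like
SNP density (1/1.77 kb), observation rate (1/130.3 kb per individual) and
1% allele error; one additive/dominant quantitative locus on chr2 and a
dominant monogenic binary locus (e.g. a colour trait) on chr3.

```r
library(BinMapQTL)
cfg <- pipelineConfig(
  genome = deskGenome(4, 5e6),
  nIndividuals = 150,
  mapLengthPerBp = 7e-8,        # 35 cM per chromosome
  nPerm = 200,
  qtl = qtlSimSpec(
    loci = data.frame(chrom = "chr2", pos = 2.5e6, a = 2, d = 0.3),
    sigma = 1.5,
    binaryLocus = list(chrom = "chr3", pos = 2e6, dominant = "A")),
  seed = 42)
res <- runPipeline(cfg, "demo_run")
```

The run log prints, among other stages:

```
bins: 131 built, 131 kept; mean length 152.7 kb, median 100 kb, 94.7% < 0.5 Mb
crossovers per individual: mean 0.98, median 1, range 0-3
genetic map: 49.5 cM total
trait trait: max LOD 18.14, permutation threshold 2.69
trait binary: max LOD 88.61, permutation threshold 2.66
QTL detected: 2
```

and the QTL table recovers both simulated loci:

```r
res$qtl[, c("trait", "bin_id", "chrom", "pos_bp", "LOD",
            "additive", "dominance", "r2_pct")]
#>    trait  bin_id chrom  pos_bp  LOD additive dominance r2_pct
#> 1  trait Bin2_17  chr2 2250000 18.1    1.902   -0.0369   42.7
#> 2 binary Bin3_13  chr3 2050000 88.6    0.488    0.4737   93.4
```

The quantitative locus (true *a* = 2 at chr2:2.5 Mb) is found two bins
from its true position with *a* ≈ 1.9; the binary locus maps to the bin
containing its causal position with a LOD in the 80s and *a* ≈ *d* ≈ 0.5,
the signature of complete dominance on a 0/1 trait. Every stage is also
written to `demo_run/` as commented TSV (`binmap.tsv`, `genetic_map.tsv`,
`qtl_table.tsv`, ...), and a second run with the same seed reproduces the
files byte for byte.

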