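# ccmosaic

Genome characterization for Collaborative Cross (CC) mouse strains: how
much residual heterozygosity is left in a nominally inbred strain, which
founder haplotypes its genome is built from, and which strain-private
deletions its reads reveal.

The CC is a panel of recombinant inbred mouse strains, each bred from
eight inbred founders (A/J, C57BL/6J, 129S1/SvImJ, NOD/ShiLtJ, NZO/HlLtJ,
CAST/EiJ, PWK/PhJ, WSB/EiJ) through a two-generation outcrossing funnel
followed by many generations of brother–sister mating. Inbreeding is
never quite finished: in regions of *residual heterozygosity* two founder
haplotypes still segregate. `ccmosaic` implements the computational
pipeline used to characterize such strains, with a synthetic breeding
simulator providing ground truth for every stage:

- **simdata** — CC funnel breeding with Poisson recombination,
  genotyping-array emission (configurable error/H/N rates), and shotgun
  read simulation with implanted deletions. The expected heterozygosity
  after *g* generations of sib mating follows the exact recurrence
  H_g = H_{g-1}/2 + H_{g-2}/4 (decay factor (1+√5)/4 ≈ 0.809), which the
  simulator reproduces.
- **hetscan** — trio-based residual-heterozygosity estimation: markers
  biallelic and informative among the founders are retained; a marker is
  evidence of heterozygosity when any of a strain's three genotyped mice
  carries an H call or the calls are discordant; evidence clusters are
  combined and their spans summed against the assayed genome.
- **haprecon** — founder-haplotype reconstruction over the 36 diplotype
  states (8 inbred + 28 founder pairs) by a scaled forward–backward HMM,
  linear-interpolation imputation across platforms, obligate-ancestor
  (MRCA) merging with redistribution of conflicting inbred maxima onto
  heterozygous states, male-X 8-state handling, and posterior
  segmentation into a chromosome mosaic.
- **delscan** — strain-private homozygous deletion discovery: an exact
  k-mer read index (the msBWT query contract: how many reads contain a
  45-mer in either orientation, and which), 45-mer/15-bp reference
  tiling with a ≥3-read presence threshold, candidate intervals
  >500 bp in non-repetitive sequence, and breakpoint resolution by
  majority-vote consensus extension of the flanking reads with
  edit-distance adjudication of simple polymorphisms.
- **popstats** — founder haplotype frequencies (heterozygous segments
  contribute ½ to each founder), per-locus population frequencies, and a
  circular-rotation permutation test for enrichment of wild-derived
  haplotypes (CAST/EiJ, PWK/PhJ, WSB/EiJ) in heterozygous regions.

The published characterization tables for the six most recently released
strains (CC078–CC083) ship as plain-text data and feed the summary
routines.

## Worked example

```r
library(ccmosaic)

## a founder panel, one 100 kb chromosome, 2,000 markers
p <- simulateFounderPanel(1, 1e5, 2000, seed = 41, withSequences = FALSE)

## breed one CC strain: funnel + 10 generations of sib mating
g <- simulateCCStrain(p, ccPedigree(c(3,1,4,8,2,6,5,7), 10, seed = 12))
realizedHetFraction(g)
#> [1] 0.41218

## genotype it (0.5% call error), reconstruct the founder mosaic
calls <- emitArrayGenotypes(g, p, errorRate = 0.005, seed = 13)
track <- forwardBackward(calls, p@markers, p@markerAlleles,
                         hmmParams(epsilon = 0.005))
mosaic <- mosaicFromTrack(track)
head(founderFrequencies(mosaic), 3)
#>         A/J    C57BL/6J 129S1/SvImJ
#>   0.1109106   0.1111462   0.1204615

## trio heterozygosity estimate vs. the simulator's truth
est <- estimateHetFraction(cbind(calls, calls, calls), p@markers,
                           p@markerAlleles)
est$fraction
#> [1] 0.3948902
```

This particular breeding realization is an unusually heterozygous one —
41% of its genome still segregates after 10 generations of sib mating
(the expectation is `expectedHeterozygosity(10)` ≈ 0.114, but single
realizations scatter widely, exactly as real CC strains do). The
reconstruction track assigns each marker a probability vector over the
36 diplotype states; `founderFrequencies` integrates the mosaic into
per-founder genome shares, and the trio estimate (0.395) tracks the
simulated truth (0.412) to within two percentage points.

Deletion discovery runs off reads rather than array calls:

```r
set.seed(1)
tmpl <- paste(sample(c("A", "C", "G", "T"), 1e5, replace = TRUE),
              collapse = "")
rds <- simulateReads(tmpl, 150, 10, 0.002, seed = 1,
                     deletions = data.frame(start = 12001, end = 14000))
idx <- buildKmerIndex(rds)
scanDeletions(tmpl, idx)[, c("tileStart", "tileEnd", "resolvedStart",
                             "resolvedEnd", "sizeKb", "spanningReads")]
#>   tileStart tileEnd resolvedStart resolvedEnd sizeKb spanningReads
#> 1     11971   13996         12001       14000  2.025            11
```

The implanted 2 kb deletion is recovered with base-exact breakpoints
from depth-10 reads with 0.2% base errors; `sizeKb` follows the
tile-coordinate bookkeeping convention (last minus first absent 45-mer
start, divided by 1,000).

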