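---
title: "Methods: haplotype mosaics, residual heterozygosity and private deletions in the Collaborative Cross"
author: "ccmosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype mosaics, residual heterozygosity and private deletions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `ccmosaic`. The package characterizes Collaborative Cross (CC)
strain genomes at three levels — residual heterozygosity from
genotyping-array trios, founder-haplotype mosaics from a 36-state HMM,
and strain-private homozygous deletions from short reads — and couples
every stage to a breeding simulator with known ground truth.

## The breeding simulator

`simulateCCStrain` runs the CC design literally: four founder-pair
crosses (G1), two four-way crosses (G2), one eight-way cross producing
the G2:F1 sibling pair, then `nInbreedingGenerations` of brother–sister
mating. Founders enter the funnel as (AB×CD)×(EF×GH) in the pedigree's
permutation order.

**Recombination.** Each meiosis draws a Poisson number of crossovers
with no interference and no sex-specific map, at an expected 1 crossover
per 100 kb of synthetic chromosome (scaled linearly with length;
`crossoversPer100kb` exposes the rate). A synthetic 100 kb chromosome
therefore behaves, in segment statistics, like a scaled-down 100 Mb
chromosome at ~1 cM/Mb. This is the simplest model with the right
segment-length behaviour; nothing downstream depends on interference.

**Heterozygosity decay.** At funnel-informative loci the two G2:F1
haplotypes descend from disjoint founder quartets, so heterozygosity
starts at 1 and decays under sib mating by the classical recurrence
H_g = H_{g-1}/2 + H_{g-2}/4 with H_0 = 1, H_1 = 3/4 (asymptotic factor
(1+√5)/4 ≈ 0.809 per generation). `expectedHeterozygosity` iterates this
recurrence exactly; the test suite verifies the Monte-Carlo mean of the
simulator against it within 3 standard errors at g ∈ {2, 5, 10} with
2,000 replicates each.

**Sex chromosomes.** Chromosomes may be tagged X: males carry a single
X haplotype, transmitted mother-to-son; funnel-position effects on X
inheritance are ignored (sufficient for exercising the male-X code
paths downstream). The realized heterozygous fraction is computed over
diploid chromosomes only.

**Markers.** `simulateFounderPanel` draws, per marker, a reference and
an alternate base and a random carrier subset of 1–7 founders, so every
marker is biallelic and informative among the founders by construction.
Sequences are the shared random background with alternate alleles
substituted into carriers; per-founder background divergence beyond the
markers is deliberately absent, since downstream marker analyses see
only the allele table and read analyses use explicit templates.

**Array emission.** At zero noise a marker's call is the unordered
allele pair implied by the two founder haplotypes — the shared allele
when both haplotypes carry the same base (including heterozygous founder
pairs whose alleles coincide at that marker), H when they differ, the
single allele on hemizygous male X. Corruption is applied per marker
from one uniform draw: a random wrong call from the marker's vocabulary
with `errorRate`, H with `hMiscallRate` (homozygous calls only), N with
`nRate`.

**Reads.** `simulateReads` excises implanted deletions from the
template, then draws `round(depth × templateLength / readLength)` reads
uniformly from both strands with per-base substitution errors. A finite
template means windows within one read length of the ends are reachable
by few start positions; analyses of simulated data should treat template
edges accordingly.

**Reproducibility.** All seeded simulators snapshot and restore the
caller's RNG stream. This matters for Monte-Carlo loops: if a simulator
left the global stream positioned by its own `set.seed`, seeds drawn
between calls would form a deterministic orbit rather than independent
draws — an effect we observed as a multi-standard-error bias in decay
estimates before the change.

## Residual heterozygosity from trios

A strain is genotyped in three recent mice. Markers are first filtered
against the founders: biallelic, informative (both alleles present), no
H or N calls in any founder replicate, concordant across replicates, and
founder alleles must perfectly predict observed F1 hybrid genotypes
(`selectInformativeMarkers` reports per-filter drop counts).

At each retained marker the trio provides evidence of residual
heterozygosity when any call is H or the non-N calls disagree. N is
missing data: a marker with at least one non-N call is assayed, an
all-N marker drops out of both numerator and denominator.

Maximal runs of evidence markers form clusters (`clusterEvidence`). A
cluster's span runs from its first to its last evidence marker — never
extended into flanking homozygous markers, which keeps the estimate
conservative. A singleton's span is the chromosome's rounded mean
inter-marker spacing, capped at the gaps to its flanking assayed
markers; the cap keeps the estimator monotone (an additional H call can
then never shrink the total span) and prevents singletons in locally
dense marker regions from claiming more span than their neighbourhood.

**Cluster combination.** Inside a genuinely heterozygous region only
the markers that separate the two segregating founders show H; markers
where the two founders share an allele are silent, and with random
biallelic markers roughly half are silent for any given pair. Raw runs
therefore fragment, and summed raw-run spans recover only ~40% of true
heterozygous length. `combineClusters` implements the combination step:
two adjacent clusters merge when at least one founder pair is discordant
at every evidence marker and concordant at every silent assayed marker
across the combined span — the signature a single segregating pair
produces at zero noise. Merging across a truly homozygous gap would
require a founder pair concordant at every one of its markers, whose
probability decays geometrically with gap marker count. With this step
the zero-noise estimator is asymptotically exact; at 5,000 markers per
100 kb its mean absolute error against simulator truth is below 0.005
(the suite asserts < 0.03 over 20 seeds).

The fraction is summed cluster span over the assayed span (first to last
assayed retained marker per chromosome): unassayed telomeric sequence
carries no evidence either way and is excluded from the denominator.
Real-data percentages in published tables need not be reproduced exactly
by these conventions; the published per-strain values ship as data
(`ccNewStrainHet`) and feed `summarizeHetEstimates` unchanged.

Sample-to-strain matching (`matchSampleToStrain`) uses pairwise
concordance (matching non-N calls over comparable calls), reports ties
rather than resolving them, and flags best matches below 0.9.

## 36-state haplotype reconstruction

States are the 8 inbred founder states followed by the 28 unordered
founder pairs in lexicographic order. The published parameterization of
the original reconstruction HMM is not printed anywhere we can follow,
so the package defines its own faithful-in-structure model; posterior
files for real strains are not expected to match the public files
numerically.

**Emission.** Under state {f, g} the expected call is the shared founder
allele if the two founders agree at the marker, H otherwise. The
observed call equals the expected one with probability 1 − ε, with ε
split uniformly over the other members of the marker's call vocabulary
(its two alleles and H — so ε/2 each). N is uninformative and emits 1
everywhere. ε defaults to 0.005, a typical array error scale; values an
order of magnitude either way change posteriors little because evidence
accumulates over many markers.

**Transitions.** Each haplotype independently switches founder with
probability r = 1 − exp(−ρ d) over d bp, uniformly onto the other 7
founders; the ordered two-haplotype product is folded onto unordered
pairs. Note the d→∞ limit of this stated model is r = 1 (switch with
certainty, uniformly among the *others*), not the uniform stationary
distribution — the test suite checks rows against brute-force
two-haplotype enumeration rather than a stationary heuristic. ρ defaults
to 1e-4 per bp, calibrated so expected founder switches per simulated
100 kb chromosome match the crossover accumulation of a funnel plus
~10 sib-mating generations; posterior decoding is robust to this choice
within an order of magnitude.

**Algorithm.** Scaled forward–backward per chromosome; each posterior
row sums to 1. All-N input returns the prior at every marker with a
warning, per the interface contract. On reduced state spaces (3 founders,
≤4 markers) the posteriors equal exhaustive path enumeration to 1e-10.

**Imputation.** Probabilities at target positions are elementwise linear
interpolations of the flanking dense markers, renormalized. Outside the
dense range interpolation is undefined, so targets take the nearest end
marker's vector — the least-assumption extension.

**MRCA merging.** At each marker the maximum-probability state of every
obligate ancestor is found (ties break to the lowest canonical index,
for determinism). If two or more ancestors have inbred maxima on
different founders, each such ancestor's inbred-maximum mass is added
onto the heterozygous states pairing its founder with the other
conflicting founders — split equally when there are several, the
deterministic reading of the two-founder worked example — and its inbred
entry zeroed. Then the elementwise maximum across ancestors is taken and
normalized. Merging a vector with itself is the identity; a three-way
inbred conflict puts support exactly on the three pairwise heterozygous
states. Male-X 8-state tracks are expanded to 36 states with zero
heterozygous mass before merging; a merged strain track may legitimately
carry X heterozygosity when female ancestors disagree.

**Mosaic extraction.** Per-marker argmax states are merged into runs;
segment boundaries sit at the midpoint between flanking markers of
different argmax; segments whose mean posterior falls below
`minPosterior` (default 0.5) are flagged uncertain. On simulated strains
(2,000 markers/100 kb, ε = 0.005 data noise) marker-level diplotype
recovery exceeds 0.95 and zero-noise boundary error is of the order of
the marker spacing.

## Deletion discovery

The multi-string BWT of the original pipeline is used only through two
queries — how many reads contain a 45-mer in either orientation, and
which reads — so the package replaces it with an exact canonical k-mer
index (`buildKmerIndex`, data.table-backed). k-mers containing N never
match; counts are distinct-read counts; orientation symmetry
count(q) = count(revcomp(q)) holds by construction and is property-tested
against naive substring search.

The reference is tiled with 45-mers every 15 bp. A tile is *present*
with at least 3 supporting reads — the threshold that absorbs sequencing
error and index hopping — and *repetitive* when its 45-mer occurs more
than once in the reference on either strand. Maximal absent runs are
candidates when their tile span (last minus first absent 45-mer start)
exceeds 500 bp and fewer than half their tiles are repetitive. Reported
sizes follow the tile bookkeeping convention `(tileEnd − tileStart)/1000`
kb.

**Breakpoint resolution.** From the last present tile left of the run, a
majority-vote consensus is extended inward, re-anchoring on its terminal
45-mer in ≤30-base steps. Two failure modes of low-coverage consensus
building are handled explicitly: when no read extends past the anchor
(an erroneous base voted into the consensus, or a read-end error) the
consensus is trimmed back base-by-base so a cleaner anchor can recruit
reads that out-vote the error; when the 45-mer anchor itself finds no
reads (a local coverage gap) a 31-base anchor searched directly in the
read set recruits reads starting inside the window. The reference jump J
is then estimated from exact 30-base probes spread over a 120-base tail
band of the consensus — one erroneous consensus base cannot intersect
every probe — and never at or before the first consensus/reference
divergence, where a probe would trivially match the flank. J at most the
polymorphism threshold (edit distance ≤ 5 per 45–60 base window; the
value is a package choice, exposed as `polymorphismEditMax`) closes the
gap as a simple polymorphism; a larger J is a deletion. The junction is
placed at the leftmost minimizer of prefix-mismatches-versus-flank plus
suffix-mismatches-versus-jumped-reference, which is robust to isolated
consensus errors and resolves micro-homology to the leftmost equivalent
placement. Across 120 implanted events (600 bp to 20 kb, depth 10, 0.2%
base error) recall is 1.0 with 0 bp breakpoint error.

**Classification.** A call is homozygous when every non-repetitive
interior tile is below the presence threshold (a 1:1 deleted/intact read
mixture keeps interior tiles present and produces no candidate at all);
junction support is the read count of the 45-mer straddling the novel
junction; a deletion is not strain-unique when a comparison read index
also lacks the same interior tiles; the haplotype label is the mosaic
founder pair overlapping the interval.

## Population statistics

Founder frequencies integrate the mosaic: homozygous segments count
fully, heterozygous segments contribute half their length to each
founder, so each strain's eight frequencies sum to 1. Per-locus
population frequencies are means of diploid dosage (1, ½, 0) across
strains.

The wild-derived enrichment test asks whether CAST/EiJ, PWK/PhJ and
WSB/EiJ haplotypes are over-represented inside heterozygous regions (a
non-domesticus subset {CAST, PWK} is available via
`ccWildFounders(domesticusExcluded = TRUE)`). The statistic is total
wild dosage-length inside the heterozygous intervals summed over
strains. No test is specified for the published result, so the package
uses the least-assumption null: each strain's heterozygous intervals are
circularly rotated per chromosome by independent uniform offsets,
preserving interval count, lengths and chromosome structure;
p = (1 + #{null ≥ observed})/(1 + permutations). Type-I error is near
nominal on null simulations (0.045 at nominal 0.05 over 200 replicates)
and forced alternatives reach the 1/(n+1) floor.

## Scale of the validation suite

Tests and the acceptance script run on synthetic genomes of one or two
100 kb chromosomes with 2,000–5,000 markers, read depth 10, and 1,000 to
2,000 Monte-Carlo replicates per decay point — sizes chosen so each
statistical check retains 3-standard-error resolution while the whole
suite completes in minutes. The generator emulates funnel breeding,
array noise and shotgun reads with implanted deletions; it does not
emulate platform-specific intensity clustering, realistic genetic maps,
selection against incompatible haplotypes, or repeat-rich genome
structure beyond explicit tandem-repeat fixtures. Passing tests
demonstrate the pipeline's correctness under these conditions, not that
real-data percentages (which depend on the real marker content and
breeding history) are reproduced; quantities that require the real
genotype and sequence archives are deliberately out of the suite's
reach and are represented instead by the published per-strain tables
shipped as data.
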