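#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowRanges
#' @importFrom data.table data.table setkey
#' @importFrom stats setNames runif rpois rbinom
#' @importFrom utils combn read.csv write.csv adist
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' FounderPanel: synthetic CC founder genomes and marker alleles
#'
#' Container for a synthetic panel of the eight inbred CC founder genomes:
#' per-chromosome nucleotide sequences for each founder, and a biallelic,
#' informative marker set with the allele carried by each founder.
#'
#' @slot founderIds Character vector of 8 founder names (canonical order).
#' @slot sequences Named list (one element per chromosome) of
#'   \link[Biostrings]{DNAStringSet} objects with one sequence per founder,
#'   or `NULL` when the panel was built without sequences.
#' @slot markers A \link[GenomicRanges]{GRanges} of marker positions with
#'   metadata column `markerId`.
#' @slot markerAlleles Character matrix (markers x 8 founders) of alleles.
#' @slot chromLengths Named numeric vector of chromosome lengths (bp).
#' @slot chromType Named character vector, `"autosome"` or `"X"`.
#' @exportClass FounderPanel
setClass("FounderPanel",
  representation(founderIds = "character", sequences = "listOrNULL",
                 markers = "GRanges", markerAlleles = "matrix",
                 chromLengths = "numeric", chromType = "character"))

setValidity("FounderPanel", function(object) {
  msg <- character()
  if (length(object@founderIds) != ncol(object@markerAlleles))
    msg <- c(msg, "markerAlleles must have one column per founder")
  if (length(object@markers) != nrow(object@markerAlleles))
    msg <- c(msg, "one allele row per marker required")
  if (nrow(object@markerAlleles)) {
    nall <- apply(object@markerAlleles, 1L, function(a) length(unique(a)))
    if (any(nall != 2L))
      msg <- c(msg, "every marker must be biallelic and informative")
    if (any(object@markerAlleles %in% c("H", "N")))
      msg <- c(msg, "founder alleles may not contain H or N")
  }
  if (length(msg)) msg else TRUE
})

#' CCPedigree: a CC funnel breeding design
#'
#' Describes one CC funnel: the order in which the 8 founders enter the
#' two generations of outcrossing, and the number of subsequent generations
#' of brother-sister mating.
#'
#' @slot funnelOrder Integer permutation of 1:8 (positions in the funnel
#'   (AB x CD) x (EF x GH)).
#' @slot nInbreedingGenerations Integer >= 0.
#' @slot seed Integer seed controlling meiosis randomness.
#' @exportClass CCPedigree
setClass("CCPedigree",
  representation(funnelOrder = "integer", nInbreedingGenerations = "integer",
                 seed = "integer"))

setValidity("CCPedigree", function(object) {
  msg <- character()
  if (!identical(sort(object@funnelOrder), 1:8))
    msg <- c(msg, "funnelOrder must be a permutation of 1:8")
  if (object@nInbreedingGenerations < 0L)
    msg <- c(msg, "nInbreedingGenerations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a CCPedigree
#'
#' @param funnelOrder Permutation of 1:8 assigning founders to funnel slots.
#' @param nInbreedingGenerations Generations of sib mating after the G2:F1.
#' @param seed Integer seed for the breeding simulation.
#' @return A [CCPedigree-class] object.
#' @examples
#' ccPedigree(1:8, 10, seed = 1)
#' @export
ccPedigree <- function(funnelOrder = 1:8, nInbreedingGenerations = 0L,
                       seed = 1L) {
  new("CCPedigree", funnelOrder = as.integer(funnelOrder),
      nInbreedingGenerations = as.integer(nInbreedingGenerations),
      seed = as.integer(seed))
}

#' StrainGenome: a realized diploid founder mosaic
#'
#' Ground-truth genome of one simulated CC individual: for every chromosome
#' the one (male X) or two haplotypes, each an ordered run of founder
#' segments in 1-based inclusive coordinates.
#'
#' @slot haplotypes Named list per chromosome; each element a list of one
#'   or two `data.frame(start, end, founder)` segment tables.
#' @slot chromLengths Named numeric chromosome lengths.
#' @slot chromType Named character, `"autosome"` or `"X"`.
#' @slot sex `"female"` or `"male"`.
#' @slot realizedHetFraction Fraction of the diploid assayed genome where
#'   the two haplotypes carry different founders.
#' @exportClass StrainGenome
setClass("StrainGenome",
  representation(haplotypes = "list", chromLengths = "numeric",
                 chromType = "character", sex = "character",
                 realizedHetFraction = "numeric"))

setValidity("StrainGenome", function(object) {
  msg <- character()
  for (chrom in names(object@haplotypes)) {
    L <- object@chromLengths[[chrom]]
    haps <- object@haplotypes[[chrom]]
    isX <- identical(object@chromType[[chrom]], "X")
    nExp <- if (isX && object@sex == "male") 1L else 2L
    if (length(haps) != nExp)
      msg <- c(msg, sprintf("chromosome %s: expected %d haplotype(s)",
                            chrom, nExp))
    for (h in haps) {
      if (h$start[1L] != 1 || h$end[length(h$end)] != L ||
          (nrow(h) > 1L && any(h$start[-1L] != h$end[-nrow(h)] + 1)))
        msg <- c(msg, sprintf("chromosome %s: segments must tile 1..%d",
                              chrom, L))
    }
  }
  if (!object@sex %in% c("female", "male"))
    msg <- c(msg, "sex must be 'female' or 'male'")
  if (length(msg)) msg else TRUE
})

#' GenotypeMatrix of categorical array calls
#'
#' Markers-by-samples matrix of genotype calls over the closed vocabulary
#' A/C/G/T (homozygous), H (heterozygous) and N (missing), carried as a
#' \link[SummarizedExperiment]{RangedSummarizedExperiment} whose row ranges
#' hold the marker map (chromosome, 1-based position, `markerId`).
#'
#' @exportClass CCGenotypes
setClass("CCGenotypes",
         contains = "RangedSummarizedExperiment")

setValidity("CCGenotypes", function(object) {
  msg <- character()
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'calls' is required")
  else {
    calls <- SummarizedExperiment::assay(object, "calls")
    bad <- !(calls %in% .CALL_LEVELS)
    if (any(bad))
      msg <- c(msg, sprintf("invalid call token(s): %s",
                            paste(unique(calls[bad]), collapse = ", ")))
  }
  ids <- S4Vectors::mcols(SummarizedExperiment::rowRanges(object))$markerId
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "unique markerId required for every marker")
  if (length(msg)) msg else TRUE
})

#' Construct a CCGenotypes object
#'
#' @param calls Character matrix (markers x samples) over A/C/G/T/H/N.
#' @param markers `GRanges` of marker positions with metadata column
#'   `markerId`, parallel to the rows of `calls`.
#' @return A [CCGenotypes-class] object.
#' @export
CCGenotypes <- function(calls, markers) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = as.matrix(calls)), rowRanges = markers)
  new("CCGenotypes", se)
}

#' Extract the call matrix from a CCGenotypes object
#' @param x A [CCGenotypes-class] object.
#' @return Character matrix of calls.
#' @export
genotypeCalls <- function(x) SummarizedExperiment::assay(x, "calls")

#' Extract the marker map from a CCGenotypes object
#' @param x A [CCGenotypes-class] or [StateProbTrack-class] object.
#' @return `GRanges` of marker positions.
#' @export
markerMap <- function(x) {
  if (is(x, "StateProbTrack")) x@markers
  else SummarizedExperiment::rowRanges(x)
}

#' StateProbTrack: per-marker founder diplotype probabilities
#'
#' Posterior (or merged) probability vectors over the canonical diplotype
#' state space at each marker of one sample or strain.
#'
#' @slot probs Numeric matrix, markers x states; every row sums to 1.
#' @slot markers `GRanges` of marker positions with `markerId`.
#' @slot states Character vector of state codes (canonical order).
#' @slot sampleId Sample or strain identifier.
#' @slot chromKind `"autosome"`, `"femaleX"` or `"maleX"` (8-state space).
#' @exportClass StateProbTrack
setClass("StateProbTrack",
  representation(probs = "matrix", markers = "GRanges", states = "character",
                 sampleId = "character", chromKind = "character"))

setValidity("StateProbTrack", function(object) {
  msg <- character()
  if (nrow(object@probs) != length(object@markers))
    msg <- c(msg, "one probability row per marker required")
  if (ncol(object@probs) != length(object@states))
    msg <- c(msg, "one probability column per state required")
  if (nrow(object@probs)) {
    s <- rowSums(object@probs)
    if (any(abs(s - 1) > 1e-9))
      msg <- c(msg, "every probability row must sum to 1 (tol 1e-9)")
    if (any(object@probs < -1e-12))
      msg <- c(msg, "probabilities must be nonnegative")
  }
  if (!object@chromKind %in% c("autosome", "femaleX", "maleX"))
    msg <- c(msg, "chromKind must be autosome, femaleX or maleX")
  if (length(msg)) msg else TRUE
})

#' Construct a StateProbTrack
#'
#' @param probs Numeric matrix markers x states; rows must sum to 1.
#' @param markers `GRanges` of marker positions with `markerId`.
#' @param states State codes in canonical order.
#' @param sampleId Sample or strain id.
#' @param chromKind `"autosome"`, `"femaleX"` or `"maleX"`.
#' @return A [StateProbTrack-class] object.
#' @export
StateProbTrack <- function(probs, markers, states = diplotypeStates(),
                           sampleId = "sample", chromKind = "autosome") {
  colnames(probs) <- states
  new("StateProbTrack", probs = probs, markers = markers, states = states,
      sampleId = sampleId, chromKind = chromKind)
}

#' Probability matrix of a StateProbTrack
#' @param x A [StateProbTrack-class] object.
#' @return Numeric matrix markers x states.
#' @export
stateProbs <- function(x) x@probs

#' KmerIndex: an exact k-mer read index
#'
#' Answers the two read-set queries used throughout deletion discovery:
#' how many reads contain a given k-mer in either orientation, and which
#' reads those are. This is an exact, in-memory stand-in for a multi-string
#' BWT of the read set, honoring the same query contract.
#'
#' @slot k k-mer length (45 throughout the deletion pipeline).
#' @slot counts `data.table` keyed by canonical k-mer with the count of
#'   distinct reads containing it in either orientation.
#' @slot membership `data.table` keyed by canonical k-mer mapping to read
#'   indices.
#' @slot reads Character vector of the indexed reads.
#' @slot readLength Common read length.
#' @slot nSkipped Number of reads shorter than k that were skipped.
#' @exportClass KmerIndex
setClass("KmerIndex",
  representation(k = "integer", counts = "ANY", membership = "ANY",
                 reads = "character", readLength = "integer",
                 nSkipped = "integer"))

#' @describeIn FounderPanel-class Compact display.
#' @param object The object to display.
#' @export
setMethod("show", "FounderPanel", function(object) {
  cat(sprintf("FounderPanel: %d founders, %d chromosome(s), %d markers%s\n",
              length(object@founderIds), length(object@chromLengths),
              length(object@markers),
              if (is.null(object@sequences)) " (no sequences)" else ""))
})

#' @export
setMethod("show", "CCPedigree", function(object) {
  cat(sprintf("CCPedigree: funnel [%s], %d inbreeding generation(s), seed %d\n",
              paste(object@funnelOrder, collapse = " "),
              object@nInbreedingGenerations, object@seed))
})

#' @export
setMethod("show", "StrainGenome", function(object) {
  cat(sprintf(
    "StrainGenome (%s): %d chromosome(s), realized het fraction %.4f\n",
    object@sex, length(object@haplotypes), object@realizedHetFraction))
})

#' @export
setMethod("show", "StateProbTrack", function(object) {
  cat(sprintf("StateProbTrack '%s' (%s): %d markers x %d states\n",
              object@sampleId, object@chromKind, nrow(object@probs),
              ncol(object@probs)))
})

#' @export
setMethod("show", "KmerIndex", function(object) {
  cat(sprintf("KmerIndex: k = %d, %d reads (%d skipped), %d distinct k-mers\n",
              object@k, length(object@reads), object@nSkipped,
              nrow(object@counts)))
})

#' Realized heterozygous fraction of a simulated genome
#' @param x A [StrainGenome-class] object.
#' @return Fraction in [0, 1].
#' @export
realizedHetFraction <- function(x) x@realizedHetFraction
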