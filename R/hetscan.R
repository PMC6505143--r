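## Residual heterozygosity from genotype trios.
##
## A strain is genotyped in three recent mice; at markers that are
## biallelic and informative among the CC founders, one or more H calls or
## discordant calls among the trio are evidence that more than one founder
## haplotype still segregates there. Clusters of evidence markers are
## combined and their spans summed against the assayed genome span.

#' Select markers informative for residual-heterozygosity scanning
#'
#' Applies the five founder-based filters: markers must be (1) biallelic
#' among the founders, (2) informative (both alleles present), (3) free of
#' H and N calls in every founder replicate, (4) concordant across founder
#' replicates, and (5) such that founder genotypes perfectly predict the
#' observed F1 hybrid genotypes.
#'
#' @param founderGenotypes A [CCGenotypes-class] of founder samples
#'   (>= 1 replicate per founder).
#' @param founderOf Named character vector mapping each founder sample id
#'   to its founder name.
#' @param f1Genotypes Optional [CCGenotypes-class] of F1 hybrid samples.
#' @param f1Parents Named list mapping each F1 sample id to its two
#'   parental founder names.
#' @return A list with `markers` (`GRanges` of retained markers),
#'   `alleles` (retained-markers x 8 founder allele matrix), `keep`
#'   (logical over input markers) and `dropCounts` (named integer vector of
#'   per-filter drops, applied sequentially).
#' @export
selectInformativeMarkers <- function(founderGenotypes, founderOf,
                                     f1Genotypes = NULL, f1Parents = NULL) {
  calls <- genotypeCalls(founderGenotypes)
  mk <- markerMap(founderGenotypes)
  founders <- ccFounders()
  if (!all(founderOf %in% founders))
    stop("founderOf must map sample ids to the 8 CC founder names")
  n <- nrow(calls)
  alive <- rep(TRUE, n)
  drops <- c(hn = 0L, replicates = 0L, biallelic = 0L, informative = 0L,
             f1 = 0L)

  ## (3) H/N in any founder replicate
  hasHN <- rowSums(calls == "H" | calls == "N") > 0L
  drops["hn"] <- sum(alive & hasHN); alive <- alive & !hasHN
  ## (4) replicate concordance within founder
  disc <- rep(FALSE, n)
  for (f in unique(founderOf)) {
    cols <- which(founderOf[colnames(calls)] == f)
    if (length(cols) > 1L) {
      sub <- calls[, cols, drop = FALSE]
      disc <- disc | apply(sub, 1L, function(r) length(unique(r)) > 1L)
    }
  }
  drops["replicates"] <- sum(alive & disc); alive <- alive & !disc
  ## consensus founder allele matrix (first replicate per founder)
  firstCol <- vapply(unname(founders), function(f)
    which(founderOf[colnames(calls)] == f)[1L], 1L)
  if (any(is.na(firstCol)))
    stop("founder genotypes must include every founder")
  alleles <- calls[, firstCol, drop = FALSE]
  colnames(alleles) <- unname(founders)
  ## (1) biallelic, (2) informative
  nAll <- apply(alleles, 1L, function(a)
    length(unique(a[!a %in% c("H", "N")])))
  tooMany <- nAll > 2L
  drops["biallelic"] <- sum(alive & tooMany); alive <- alive & !tooMany
  mono <- nAll < 2L
  drops["informative"] <- sum(alive & mono); alive <- alive & !mono
  ## (5) founders predict F1s
  if (!is.null(f1Genotypes)) {
    f1calls <- genotypeCalls(f1Genotypes)
    bad <- rep(FALSE, n)
    for (s in colnames(f1calls)) {
      par <- f1Parents[[s]]
      a1 <- alleles[, par[1L]]; a2 <- alleles[, par[2L]]
      expected <- ifelse(a1 == a2, a1, "H")
      bad <- bad | (f1calls[, s] != expected)
    }
    drops["f1"] <- sum(alive & bad); alive <- alive & !bad
  }
  list(markers = mk[alive], alleles = alleles[alive, , drop = FALSE],
       keep = alive, dropCounts = drops)
}

#' Trio evidence of residual heterozygosity at one marker
#'
#' A marker is evidence of residual heterozygosity when any of the three
#' samples carries an H call, or when the non-N calls are not all
#' identical. N is treated as missing: markers where all three calls are N
#' are not assayed for the trio and return `NA`.
#'
#' @param calls Character vector of exactly 3 calls (A/C/G/T/H/N).
#' @return `TRUE`, `FALSE`, or `NA` (all-N, excluded from the assayed set).
#' @examples
#' trioMarkerEvidence(c("A", "A", "A"))  # FALSE
#' trioMarkerEvidence(c("A", "H", "A"))  # TRUE
#' trioMarkerEvidence(c("A", "A", "G"))  # TRUE
#' trioMarkerEvidence(c("A", "N", "A"))  # FALSE
#' @export
trioMarkerEvidence <- function(calls) {
  if (length(calls) != 3L) stop("a trio has exactly 3 calls")
  if (!all(calls %in% .CALL_LEVELS)) stop("invalid call token")
  nonN <- calls[calls != "N"]
  if (!length(nonN)) return(NA)
  any(nonN == "H") || length(unique(nonN)) > 1L
}

## Vectorized trio evidence over a markers x 3 call matrix.
.trioEvidence <- function(calls) {
  stopifnot(ncol(calls) == 3L)
  isN <- calls == "N"
  allN <- rowSums(isN) == 3L
  anyH <- rowSums(calls == "H" & !isN) > 0L
  ## discordance among non-N calls
  first <- apply(calls, 1L, function(r) r[r != "N"][1L])
  disc <- rowSums(calls != first & !isN) > 0L
  out <- anyH | disc
  out[allN] <- NA
  out
}

#' Combine evidence flags into clusters of residual heterozygosity
#'
#' Maximal runs of flagged markers — with no intervening unflagged assayed
#' marker — form one cluster per run. A cluster's span is the distance from
#' its first to its last flagged marker (inclusive); a singleton cluster is
#' assigned the rounded mean inter-marker spacing of its chromosome,
#' capped at the gaps to its flanking assayed markers so that a singleton
#' never claims more span than joining a neighboring run would. Markers
#' with `NA` flags (all-N trios) are not assayed and neither flag nor
#' break runs.
#'
#' @param flags Logical vector of evidence flags (NA = not assayed),
#'   parallel to `markers`.
#' @param markers `GRanges` of the retained markers.
#' @return `data.frame(chromosome, start, end, nMarkers, spanBp)`; one row
#'   per cluster, ordered along the genome.
#' @export
clusterEvidence <- function(flags, markers) {
  stopifnot(length(flags) == length(markers))
  chrom <- as.character(GenomicRanges::seqnames(markers))
  pos <- GenomicRanges::start(markers)
  out <- list()
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn & !is.na(flags))
    if (!length(idx)) next
    p <- pos[idx]; f <- flags[idx]
    spacing <- if (length(p) > 1L) round(mean(diff(p))) else 1
    r <- rle(f)
    endsAt <- cumsum(r$lengths)
    startsAt <- endsAt - r$lengths + 1L
    for (k in which(r$values)) {
      i1 <- startsAt[k]; i2 <- endsAt[k]
      span <- if (i1 == i2) .singletonSpan(p, i1, spacing)
              else p[i2] - p[i1] + 1
      out[[length(out) + 1L]] <-
        data.frame(chromosome = cn, start = p[i1], end = p[i2],
                   nMarkers = i2 - i1 + 1L, spanBp = span)
    }
  }
  if (!length(out))
    return(data.frame(chromosome = character(), start = integer(),
                      end = integer(), nMarkers = integer(),
                      spanBp = numeric()))
  do.call(rbind, out)
}

## Singleton-cluster span: mean spacing capped at the flanking gaps.
.singletonSpan <- function(p, i, spacing) {
  gaps <- c(if (i > 1L) p[i] - p[i - 1L],
            if (i < length(p)) p[i + 1L] - p[i])
  if (!length(gaps)) return(spacing)
  min(spacing, min(gaps))
}

## Which of the 28 founder pairs are discordant (carry different alleles)
## at each marker. Returns markers x 28 logical matrix.
.pairDiscordance <- function(alleles) {
  pr <- utils::combn(ncol(alleles), 2L)
  D <- alleles[, pr[1L, ], drop = FALSE] != alleles[, pr[2L, ], drop = FALSE]
  D
}

#' Combine adjacent evidence clusters segregating the same founder pair
#'
#' Two adjacent clusters on a chromosome are combined when at least one
#' founder pair is discordant at every flagged marker and concordant at
#' every unflagged assayed marker across the combined span — the pattern a
#' single segregating founder pair would produce at zero noise, since
#' markers that do not separate the segregating pair are silent inside a
#' heterozygous region. Combination is repeated until no further merge is
#' possible.
#'
#' @param clusters Output of [clusterEvidence()].
#' @param flags,markers As passed to [clusterEvidence()].
#' @param alleles Founder allele matrix for the same markers (from
#'   [selectInformativeMarkers()]).
#' @return A cluster `data.frame` in the same format, with spans recomputed
#'   over the combined runs.
#' @export
combineClusters <- function(clusters, flags, markers, alleles) {
  if (nrow(clusters) < 2L) return(clusters)
  chrom <- as.character(GenomicRanges::seqnames(markers))
  pos <- GenomicRanges::start(markers)
  D <- .pairDiscordance(alleles)
  out <- list()
  for (cn in unique(clusters$chromosome)) {
    cl <- clusters[clusters$chromosome == cn, , drop = FALSE]
    idx <- which(chrom == cn & !is.na(flags))
    p <- pos[idx]; f <- flags[idx]; Dc <- D[idx, , drop = FALSE]
    spacing <- if (length(p) > 1L) round(mean(diff(p))) else 1
    ## cluster bounds as indices into the assayed markers of this chrom
    i1 <- match(cl$start, p); i2 <- match(cl$end, p)
    ## single left-to-right pass: the merge condition only gains
    ## constraints as ranges grow, so a failed merge never succeeds later
    k <- 1L
    while (k < length(i1)) {
      rng <- i1[k]:i2[k + 1L]
      ok <- any(colSums(Dc[rng, , drop = FALSE] != f[rng]) == 0L)
      if (ok) {
        i2[k] <- i2[k + 1L]
        i1 <- i1[-(k + 1L)]; i2 <- i2[-(k + 1L)]
      } else k <- k + 1L
    }
    nm <- vapply(seq_along(i1), function(k) sum(f[i1[k]:i2[k]]), 1L)
    span <- ifelse(i1 == i2,
                   vapply(i1, .singletonSpan, 1, p = p,
                          spacing = spacing),
                   p[i2] - p[i1] + 1)
    out[[length(out) + 1L]] <-
      data.frame(chromosome = cn, start = p[i1], end = p[i2],
                 nMarkers = nm, spanBp = span)
  }
  do.call(rbind, out)
}

#' Estimate the residual-heterozygosity fraction of a strain trio
#'
#' Computes trio evidence flags at the retained markers, combines evidence
#' clusters, and estimates the heterozygous fraction as the summed cluster
#' span divided by the assayed genome span (per chromosome, the distance
#' from the first to the last assayed retained marker). This is
#' conservative: clusters never extend beyond their outermost evidence
#' markers.
#'
#' @param trioCalls Character matrix (retained markers x 3 samples), or a
#'   [CCGenotypes-class] restricted to the retained markers with 3 samples.
#' @param markers `GRanges` of the retained markers (ignored when
#'   `trioCalls` is a `CCGenotypes`).
#' @param alleles Optional founder allele matrix enabling the
#'   pair-consistency cluster combination step ([combineClusters()]).
#' @return A list with `fraction`, `clusters`, `spanBp` (summed cluster
#'   span), `assayedBp` and `nClusters`.
#' @export
estimateHetFraction <- function(trioCalls, markers = NULL, alleles = NULL) {
  if (is(trioCalls, "CCGenotypes")) {
    markers <- markerMap(trioCalls)
    trioCalls <- genotypeCalls(trioCalls)
  }
  if (is.null(markers) || !length(markers))
    stop("no retained markers: heterozygosity estimate undefined")
  flags <- .trioEvidence(trioCalls)
  cl <- clusterEvidence(flags, markers)
  if (!is.null(alleles) && nrow(cl))
    cl <- combineClusters(cl, flags, markers, alleles)
  chrom <- as.character(GenomicRanges::seqnames(markers))
  pos <- GenomicRanges::start(markers)
  assayed <- 0
  for (cn in unique(chrom)) {
    p <- pos[chrom == cn & !is.na(flags)]
    if (length(p)) assayed <- assayed + (max(p) - min(p) + 1)
  }
  if (assayed == 0)
    stop("no assayed markers: heterozygosity estimate undefined")
  spanBp <- sum(cl$spanBp)
  list(fraction = spanBp / assayed, clusters = cl, spanBp = spanBp,
       assayedBp = assayed, nClusters = nrow(cl))
}

#' Summarize per-strain heterozygosity estimates
#'
#' @param percentages Numeric vector of per-strain heterozygosity values
#'   (percent or fraction scale).
#' @return A list with `n`, `mean`, `min` and `max`.
#' @examples
#' summarizeHetEstimates(c(10, 20, 30))$mean
#' @export
summarizeHetEstimates <- function(percentages) {
  if (!length(percentages)) stop("no estimates to summarize")
  list(n = length(percentages), mean = mean(percentages),
       min = min(percentages), max = max(percentages))
}

#' Genotype concordance between two samples
#'
#' Fraction of matching calls among markers where both samples have a
#' non-N call.
#'
#' @param callsA,callsB Character vectors of calls on a shared marker set.
#' @return Fraction in [0, 1].
#' @export
concordance <- function(callsA, callsB) {
  stopifnot(length(callsA) == length(callsB))
  use <- callsA != "N" & callsB != "N"
  if (!any(use)) stop("no comparable markers: concordance undefined")
  mean(callsA[use] == callsB[use])
}

#' Match a sample to its strain by genotype concordance
#'
#' Compares a sample's calls against a reference panel of per-strain call
#' vectors and reports the best-matching strain. Ties are reported, not
#' silently resolved; a best concordance below `warnThreshold` is flagged.
#'
#' @param sampleCalls Character vector of calls.
#' @param referencePanel Character matrix (markers x strains).
#' @param warnThreshold Concordance below which the match is flagged.
#' @return A list with `best` (character vector: >1 on ties), `table`
#'   (named concordances, decreasing) and `lowConfidence`.
#' @export
matchSampleToStrain <- function(sampleCalls, referencePanel,
                                warnThreshold = 0.9) {
  if (is.null(dim(referencePanel)) || ncol(referencePanel) == 0L)
    stop("empty reference panel")
  conc <- vapply(seq_len(ncol(referencePanel)), function(j)
    concordance(sampleCalls, referencePanel[, j]), 1)
  names(conc) <- colnames(referencePanel)
  best <- names(conc)[conc == max(conc)]
  list(best = best, table = sort(conc, decreasing = TRUE),
       lowConfidence = max(conc) < warnThreshold)
}
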