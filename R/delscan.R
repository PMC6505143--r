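## Strain-private homozygous deletion discovery.
##
## The read set is indexed by canonical 45-mer; the reference is tiled
## with overlapping 45-mers shifted by 15 bp; maximal runs of absent tiles
## in non-repetitive sequence are candidate deletions; breakpoints are
## resolved by majority-vote consensus extension of the flanking reads
## into the missing interval, adjudicating simple polymorphisms by edit
## distance to the reference.

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.canonical <- function(x) {
  pmin(x, .revcomp(x))
}

#' Build an exact k-mer read index
#'
#' Indexes every k-mer of every read (canonicalized over orientation) so
#' that [kmerCount()] reports, for any query, the number of reads
#' containing it or its reverse complement as a substring, and
#' [kmerReads()] retrieves those reads. k-mers containing N are never
#' indexed and never match. Reads shorter than k are skipped with a
#' message.
#'
#' @param reads Character vector or `DNAStringSet`.
#' @param k k-mer length (45 throughout the deletion pipeline).
#' @return A [KmerIndex-class] object.
#' @export
buildKmerIndex <- function(reads, k = 45L) {
  reads <- as.character(reads)
  short <- nchar(reads) < k
  if (any(short))
    message(sum(short), " read(s) shorter than k skipped")
  keep <- which(!short)
  rl <- nchar(reads[keep])
  nk <- rl - k + 1L
  readId <- rep(keep, nk)
  offs <- sequence(nk)
  km <- substring(reads[readId], offs, offs + k - 1L)
  hasN <- grepl("N", km, fixed = TRUE)
  if (any(hasN)) {
    km <- km[!hasN]; readId <- readId[!hasN]
  }
  canon <- .canonical(km)
  dt <- data.table::data.table(kmer = canon, read = readId)
  dt <- unique(dt)
  data.table::setkey(dt, kmer)
  counts <- dt[, list(count = .N), by = "kmer"]
  data.table::setkey(counts, kmer)
  new("KmerIndex", k = as.integer(k), counts = counts, membership = dt,
      reads = reads,
      readLength = as.integer(max(nchar(reads), 0L)),
      nSkipped = sum(short))
}

#' Count reads containing a k-mer in either orientation
#'
#' @param index A [KmerIndex-class] object.
#' @param kmers Character vector of queries of length `k`.
#' @return Integer vector of read counts (0 for queries containing N).
#' @export
kmerCount <- function(index, kmers) {
  stopifnot(all(nchar(kmers) == index@k))
  out <- integer(length(kmers))
  ok <- !grepl("N", kmers, fixed = TRUE)
  if (any(ok)) {
    canon <- .canonical(kmers[ok])
    m <- index@counts[data.table::data.table(kmer = canon), on = "kmer"]
    out[ok] <- ifelse(is.na(m$count), 0L, m$count)
  }
  out
}

#' Retrieve the reads containing a k-mer
#'
#' Reads are returned oriented so that the query appears in forward
#' orientation in every returned read.
#'
#' @param index A [KmerIndex-class] object.
#' @param kmer A single query of length `k`.
#' @return Character vector of (re-oriented) reads; empty when absent.
#' @export
kmerReads <- function(index, kmer) {
  stopifnot(length(kmer) == 1L, nchar(kmer) == index@k)
  if (grepl("N", kmer, fixed = TRUE)) return(character())
  canon <- .canonical(kmer)
  ids <- index@membership[data.table::data.table(kmer = canon),
                          on = "kmer", nomatch = NULL]$read
  if (!length(ids)) return(character())
  rd <- index@reads[ids]
  fwd <- grepl(kmer, rd, fixed = TRUE)
  if (!all(fwd)) rd[!fwd] <- .revcomp(rd[!fwd])
  rd
}

#' Tile a reference with overlapping 45-mers and record read support
#'
#' Queries the read index with reference 45-mers starting every 15 bp
#' (positions 1, 16, 31, ...; the last window that fits is included) and
#' archives the counts as the tiling data matrix. A tile is present when
#' its read count reaches `presenceThreshold`; a tile is repetitive when
#' its 45-mer occurs more than once in the reference (either strand).
#'
#' @param reference Reference sequence (character or `DNAString`).
#' @param index A [KmerIndex-class] of the sample's reads.
#' @param presenceThreshold Minimum read count accepted as evidence of a
#'   45-mer's presence (default 3, mitigating sequencing error and index
#'   hopping).
#' @param shift Tile shift in bp (default 15).
#' @return `data.frame(start, count, present, repetitive)` with one row
#'   per tile, 1-based start coordinates.
#' @export
tileReference <- function(reference, index, presenceThreshold = 3L,
                          shift = 15L) {
  refc <- as.character(reference)
  k <- index@k
  L <- nchar(refc)
  if (L < k) stop("reference shorter than k")
  starts <- seq.int(1L, L - k + 1L, by = shift)
  tiles <- substring(refc, starts, starts + k - 1L)
  cnt <- kmerCount(index, tiles)
  ## reference-internal multiplicity over all positions, either strand
  allStarts <- seq_len(L - k + 1L)
  refKmers <- .canonical(substring(refc, allStarts, allStarts + k - 1L))
  mult <- table(refKmers)
  rep_ <- as.integer(mult[.canonical(tiles)]) > 1L
  data.frame(start = starts, count = cnt,
             present = cnt >= presenceThreshold,
             repetitive = rep_)
}

#' Find candidate missing intervals in a tile matrix
#'
#' Maximal runs of absent tiles become deletion candidates when the tile
#' span (last absent 45-mer start minus first) exceeds `minSizeBp` and
#' fewer than half of the run's tiles are repetitive.
#'
#' @param tiles Output of [tileReference()].
#' @param minSizeBp Minimum tile span (default 500).
#' @return `data.frame(tileStart, tileEnd, nTiles, repFraction, spanBp)`;
#'   `tileStart`/`tileEnd` are the first/last absent 45-mer starts.
#' @export
findMissingIntervals <- function(tiles, minSizeBp = 500L) {
  r <- rle(!tiles$present)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    i1 <- starts[k]; i2 <- ends[k]
    span <- tiles$start[i2] - tiles$start[i1]
    repFrac <- mean(tiles$repetitive[i1:i2])
    if (span > minSizeBp && repFrac < 0.5)
      out[[length(out) + 1L]] <-
        data.frame(tileStart = tiles$start[i1], tileEnd = tiles$start[i2],
                   nTiles = i2 - i1 + 1L, repFraction = repFrac,
                   spanBp = span)
  }
  if (!length(out))
    return(data.frame(tileStart = integer(), tileEnd = integer(),
                      nTiles = integer(), repFraction = numeric(),
                      spanBp = numeric()))
  do.call(rbind, out)
}

## Read suffixes extending past the end of `cons`. Anchored on the
## terminal index k-mer; when that fails (coverage gap, or an erroneous
## base voted into the consensus), falls back to a shorter 31-base
## anchor searched directly in the read set, which also recruits reads
## whose alignment starts inside the anchored window.
.suffixesAt <- function(index, cons) {
  k <- index@k
  nc <- nchar(cons)
  term <- substring(cons, nc - k + 1L, nc)
  rd <- kmerReads(index, term)
  if (length(rd)) {
    at <- regexpr(term, rd, fixed = TRUE)
    sfx <- substring(rd, at + k)
    sfx <- sfx[nchar(sfx) > 0L]
    if (length(sfx)) return(sfx)
  }
  k2 <- 31L
  term2 <- substring(cons, nc - k2 + 1L, nc)
  fwd <- index@reads[grepl(term2, index@reads, fixed = TRUE)]
  bwd <- index@reads[grepl(.revcomp(term2), index@reads, fixed = TRUE)]
  rd <- c(fwd, .revcomp(bwd))
  rd <- rd[grepl(term2, rd, fixed = TRUE)]
  if (!length(rd)) return(character())
  at <- regexpr(term2, rd, fixed = TRUE)
  sfx <- substring(rd, at + k2)
  sfx[nchar(sfx) > 0L]
}

## Majority-vote consensus extension to the right of a seed k-mer.
## Re-anchors on the terminal k-mer every `step` bases.
.extendRight <- function(index, seed, maxLen, step = 30L, minReads = 1L) {
  cons <- seed
  target <- nchar(seed) + maxLen
  best <- nchar(cons)
  trims <- 0L
  while (nchar(cons) < target) {
    sfx <- .suffixesAt(index, cons)
    if (length(sfx) < minReads) {
      ## no read extends past the anchor (read-end error or erroneous
      ## consensus base): trim back so a cleaner anchor can recruit
      ## extending reads and out-vote the error
      if (trims < 60L && nchar(cons) > nchar(seed) + 1L) {
        cons <- substring(cons, 1L, nchar(cons) - 1L)
        trims <- trims + 1L
        next
      }
      break
    }
    w <- min(step, max(nchar(sfx)))
    chunk <- character(0)
    for (j in seq_len(w)) {
      col <- substring(sfx, j, j)
      col <- col[col != ""]
      if (!length(col)) break
      tab <- sort(table(col), decreasing = TRUE)
      chunk <- c(chunk, names(tab)[1L])
    }
    if (!length(chunk)) break
    cons <- paste0(cons, paste(chunk, collapse = ""))
    if (nchar(cons) <= best) break   # no net progress: stop
    best <- nchar(cons)
  }
  cons
}

#' Resolve the breakpoints of a candidate missing interval
#'
#' Starting from the last present tile to the left of the interval, the
#' reads containing that boundary 45-mer are retrieved and a majority-vote
#' consensus is extended into the missing interval in steps of at most
#' 45-60 bases. At the first consensus/reference divergence the consensus
#' continuation is realigned to the reference downstream: a realignment
#' that skips more than `polymorphismEditMax` reference bases is called a
#' deletion with base-precise breakpoints (micro-homology placed
#' leftmost); a small shift consistent with a simple polymorphism closes
#' the gap; otherwise the interval is unresolved.
#'
#' @param candidate One row of [findMissingIntervals()] output.
#' @param index A [KmerIndex-class] of the sample's reads.
#' @param reference Reference sequence (character or `DNAString`).
#' @param tiles Tile matrix from [tileReference()] (for flank lookup).
#' @param window Consensus window length range used per extension step.
#' @param polymorphismEditMax Maximum per-window edit distance (and
#'   realignment shift) still consistent with a simple polymorphism.
#' @return A list: `outcome` (`"deletion"`, `"closed_polymorphism"` or
#'   `"unresolved"`), `resolvedStart`, `resolvedEnd` (1-based inclusive
#'   deleted interval; NA unless a deletion), `consensus`, `editDistance`,
#'   and `junctionKmer` (the 45-mer straddling the novel junction, for
#'   deletions).
#' @export
resolveBreakpoints <- function(candidate, index, reference, tiles,
                               window = c(45L, 60L),
                               polymorphismEditMax = 5L) {
  refc <- as.character(reference)
  k <- index@k
  present <- tiles$start[tiles$present]
  lp <- present[present < candidate$tileStart]
  if (!length(lp))
    return(list(outcome = "unresolved", resolvedStart = NA_integer_,
                resolvedEnd = NA_integer_, consensus = "",
                editDistance = NA_integer_, junctionKmer = NA_character_,
                note = "no present tile left of interval"))
  lp <- max(lp)
  seed <- substring(refc, lp, lp + k - 1L)
  if (kmerCount(index, seed) == 0L)
    return(list(outcome = "unresolved", resolvedStart = NA_integer_,
                resolvedEnd = NA_integer_, consensus = "",
                editDistance = NA_integer_, junctionKmer = NA_character_,
                note = "no reads contain the boundary 45-mer"))
  maxLen <- (candidate$tileStart + k - lp) + max(window) + 120L
  cons <- .extendRight(index, seed, maxLen, step = max(window) - k + 15L)
  ext <- substring(cons, k + 1L)
  if (!nchar(ext))
    return(list(outcome = "unresolved", resolvedStart = NA_integer_,
                resolvedEnd = NA_integer_, consensus = cons,
                editDistance = NA_integer_, junctionKmer = NA_character_,
                note = "consensus could not be extended"))
  refCont <- substring(refc, lp + k)
  nc <- min(nchar(ext), nchar(refCont))
  extV <- strsplit(substring(ext, 1L, nc), "")[[1L]]
  refV <- strsplit(substring(refCont, 1L, nc), "")[[1L]]
  d <- which(extV != refV)[1L]
  if (is.na(d))
    return(list(outcome = "closed_polymorphism",
                resolvedStart = NA_integer_, resolvedEnd = NA_integer_,
                consensus = cons, editDistance = 0L,
                junctionKmer = NA_character_,
                note = "consensus matches reference across the interval"))
  ## per-window edit distance of the diverging consensus vs reference
  sDiv <- lp + k + d - 1L
  wlen <- min(max(window), nchar(ext) - d + 1L)
  ed <- as.integer(utils::adist(substring(ext, d, d + wlen - 1L),
                                substring(refc, sDiv, sDiv + wlen - 1L)))
  ## estimate the reference jump J from exact tail probes of the
  ## consensus (several offsets, so an isolated consensus error in one
  ## probe does not block realignment)
  ncons <- nchar(cons)
  ## tail probes can map as far as tileEnd + k + the extension length
  searchEnd <- min(nchar(refc), candidate$tileEnd + k + ncons)
  region <- substring(refc, lp, searchEnd)
  J <- NA_integer_
  ## probes spread over a wide tail band, so that one erroneous
  ## consensus base cannot intersect every probe
  for (off in seq.int(0L, 120L, by = 3L)) {
    cpos <- ncons - 29L - off
    ## never probe at or before the first divergence: a pre-divergence
    ## probe matches the flank at jump 0 and would mask a deletion
    if (cpos <= k || cpos < k + d) break
    probe <- substring(cons, cpos, cpos + 29L)
    hit <- regexpr(probe, region, fixed = TRUE)
    if (hit > 0L) {
      J <- (lp + as.integer(hit) - 1L) - (lp + cpos - 1L)
      break
    }
  }
  if (is.na(J) || J < 0L)
    return(list(outcome = "unresolved", resolvedStart = NA_integer_,
                resolvedEnd = NA_integer_, consensus = cons,
                editDistance = ed, junctionKmer = NA_character_,
                note = "consensus did not realign to the reference"))
  if (J <= polymorphismEditMax)
    return(list(outcome = "closed_polymorphism",
                resolvedStart = NA_integer_, resolvedEnd = NA_integer_,
                consensus = cons, editDistance = ed,
                junctionKmer = NA_character_,
                note = sprintf("realigned with shift %d", J)))
  ## junction placement: leftmost minimizer of prefix mismatches against
  ## the flank reference plus suffix mismatches against the jumped
  ## reference (robust to isolated consensus errors; micro-homology
  ## resolves to the leftmost equivalent placement)
  consV <- strsplit(cons, "")[[1L]]
  nUse <- min(ncons, nchar(refc) - lp - J + 1L)
  consV <- consV[seq_len(nUse)]
  aV <- strsplit(substring(refc, lp, lp + nUse - 1L), "")[[1L]]
  bV <- strsplit(substring(refc, lp + J, lp + J + nUse - 1L), "")[[1L]]
  mA <- consV != aV
  mB <- consV != bV
  pref <- c(0L, cumsum(mA))          # mismatches in cons[1..t-1] vs flank
  suffB <- sum(mB) - c(0L, cumsum(mB))  # mismatches in cons[t..] vs jump
  t0 <- which.min(pref + suffB)      # first (leftmost) minimizer
  s <- lp + t0 - 1L
  e <- s + J - 1L
  jk <- paste0(substring(refc, s - 22L, s - 1L),
               substring(refc, e + 1L, e + 23L))
  list(outcome = "deletion", resolvedStart = s, resolvedEnd = e,
       consensus = cons, editDistance = ed, junctionKmer = jk)
}

#' Classify a resolved deletion call
#'
#' Determines zygosity (homozygous when every non-repetitive interior tile
#' falls below the presence threshold), counts reads spanning the novel
#' junction, tests strain uniqueness against comparison read indexes
#' (a deletion is not unique when a comparison sample also lacks the same
#' interior tiles), and attaches the founder haplotype overlapping the
#' interval from the strain's mosaic.
#'
#' @param candidate One row of [findMissingIntervals()] output.
#' @param resolution Result of [resolveBreakpoints()] for that candidate.
#' @param tiles Tile matrix of the focal sample.
#' @param index Focal sample [KmerIndex-class].
#' @param reference Reference sequence.
#' @param comparisonIndices Named list of [KmerIndex-class] objects for
#'   other strains (may be empty).
#' @param mosaic Optional strain mosaic (`GRanges` with `founder1`,
#'   `founder2`) for haplotype labeling; the candidate is assumed to lie
#'   on the mosaic's chromosome.
#' @param chromosome Chromosome label of the scanned reference.
#' @param presenceThreshold Tile presence threshold (default 3).
#' @return One-row `data.frame` with Table-3-style columns: `chromosome`,
#'   `tileStart`, `tileEnd`, `resolvedStart`, `resolvedEnd`, `sizeKb`,
#'   `spanningReads`, `zygosity`, `uniqueToStrain`, `haplotype`.
#' @export
classifyCall <- function(candidate, resolution, tiles, index, reference,
                         comparisonIndices = list(), mosaic = NULL,
                         chromosome = "chr1", presenceThreshold = 3L) {
  refc <- as.character(reference)
  interior <- tiles$start >= candidate$tileStart &
              tiles$start <= candidate$tileEnd & !tiles$repetitive
  homozygous <- all(tiles$count[interior] < presenceThreshold)
  spanning <- if (!is.na(resolution$junctionKmer) &&
                  nchar(resolution$junctionKmer) == index@k)
    kmerCount(index, resolution$junctionKmer) else NA_integer_
  unique_ <- TRUE
  if (length(comparisonIndices)) {
    intTiles <- substring(refc, tiles$start[interior],
                          tiles$start[interior] + index@k - 1L)
    for (ci in comparisonIndices) {
      cnt <- kmerCount(ci, intTiles)
      if (all(cnt < presenceThreshold)) { unique_ <- FALSE; break }
    }
  }
  hap <- NA_character_
  if (!is.null(mosaic) && !is.na(resolution$resolvedStart)) {
    ov <- mosaic[GenomicRanges::start(mosaic) <= resolution$resolvedEnd &
                 GenomicRanges::end(mosaic) >= resolution$resolvedStart]
    if (length(ov)) {
      f1 <- S4Vectors::mcols(ov)$founder1[1L]
      f2 <- S4Vectors::mcols(ov)$founder2[1L]
      hap <- if (f1 == f2) f1 else paste(f1, f2, sep = "/")
    }
  }
  data.frame(chromosome = chromosome,
             tileStart = candidate$tileStart, tileEnd = candidate$tileEnd,
             resolvedStart = resolution$resolvedStart,
             resolvedEnd = resolution$resolvedEnd,
             sizeKb = deletionSizeKb(candidate$tileStart,
                                     candidate$tileEnd),
             spanningReads = spanning,
             zygosity = if (homozygous) "homozygous" else "ambiguous",
             uniqueToStrain = unique_, haplotype = hap)
}

#' Deletion size from tile coordinates
#'
#' Size in kb computed from the first and last absent 45-mer start
#' positions, `(tileEnd - tileStart) / 1000` — the bookkeeping convention
#' used for reported deletion sizes.
#'
#' @param tileStart,tileEnd First and last absent 45-mer starts (1-based).
#' @return Size in kb.
#' @examples
#' deletionSizeKb(11600371, 11620171)  # 19.8
#' @export
deletionSizeKb <- function(tileStart, tileEnd) {
  (tileEnd - tileStart) / 1000
}

#' Scan a reference and read set for strain-private homozygous deletions
#'
#' Convenience pipeline: build the tile matrix, find candidate missing
#' intervals, resolve breakpoints, and classify every candidate that
#' resolves as a deletion.
#'
#' @param reference Reference sequence.
#' @param index [KmerIndex-class] of the focal sample's reads.
#' @param comparisonIndices Named list of comparison indexes.
#' @param mosaic Optional strain mosaic for haplotype labels.
#' @param chromosome Chromosome label.
#' @param presenceThreshold,minSizeBp,polymorphismEditMax Tuning knobs as
#'   in the stage functions.
#' @return `data.frame` of deletion calls (possibly empty), plus the tile
#'   matrix and candidates as attributes `"tiles"` and `"candidates"`.
#' @export
scanDeletions <- function(reference, index, comparisonIndices = list(),
                          mosaic = NULL, chromosome = "chr1",
                          presenceThreshold = 3L, minSizeBp = 500L,
                          polymorphismEditMax = 5L) {
  tiles <- tileReference(reference, index, presenceThreshold)
  cand <- findMissingIntervals(tiles, minSizeBp)
  calls <- list()
  for (i in seq_len(nrow(cand))) {
    res <- resolveBreakpoints(cand[i, ], index, reference, tiles,
                              polymorphismEditMax = polymorphismEditMax)
    if (res$outcome == "deletion") {
      cc <- classifyCall(cand[i, ], res, tiles, index, reference,
                         comparisonIndices, mosaic, chromosome,
                         presenceThreshold)
      if (cc$zygosity == "homozygous")
        calls[[length(calls) + 1L]] <- cc
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chromosome = character(), tileStart = integer(),
               tileEnd = integer(), resolvedStart = integer(),
               resolvedEnd = integer(), sizeKb = numeric(),
               spanningReads = integer(), zygosity = character(),
               uniqueToStrain = logical(), haplotype = character())
  attr(out, "tiles") <- tiles
  attr(out, "candidates") <- cand
  out
}
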