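## Synthetic CC data: founder panel, funnel breeding, array calls, reads.
##
## Internal genome representation (hot path for the Monte-Carlo breeding
## loops): a haplotype is data.frame(start, end, founder) tiling 1..L;
## an individual is list(sex=, chrom=list(<chrom>=list(h1[, h2]))).

#' Simulate a synthetic CC founder panel
#'
#' Builds eight synthetic inbred founder genomes carrying a set of
#' biallelic markers that are informative among the founders (both alleles
#' present). Founder sequences are a shared random background with the
#' marker alternate allele substituted into each carrier founder.
#'
#' @param nChromosomes Number of chromosomes (>= 1).
#' @param chromLengthBp Length of every chromosome in bp (>= 1000).
#' @param nMarkersPerChrom Number of markers per chromosome (>= 2).
#' @param seed Integer seed; identical seeds give identical panels.
#' @param includeX Make the last chromosome an X chromosome.
#' @param withSequences Generate founder nucleotide sequences (needed only
#'   for read simulation); marker-level work does not require them.
#' @return A [FounderPanel-class] object.
#' @examples
#' p <- simulateFounderPanel(1, 10000, 10, seed = 1, withSequences = FALSE)
#' p
#' @export
simulateFounderPanel <- function(nChromosomes = 1L, chromLengthBp = 1e5,
                                 nMarkersPerChrom = 100L, seed = 1L,
                                 includeX = FALSE, withSequences = TRUE) {
  if (nChromosomes < 1L || chromLengthBp < 1000 || nMarkersPerChrom < 2L)
    stop("need nChromosomes >= 1, chromLengthBp >= 1000, ",
         "nMarkersPerChrom >= 2")
  rng <- .snapshotRng(); on.exit(.restoreRng(rng))
  set.seed(as.integer(seed))
  founders <- ccFounders()
  chroms <- paste0("chr", seq_len(nChromosomes))
  chromType <- rep("autosome", nChromosomes)
  if (includeX) {
    chroms[nChromosomes] <- "chrX"
    chromType[nChromosomes] <- "X"
  }
  names(chromType) <- chroms
  chromLengths <- stats::setNames(rep(chromLengthBp, nChromosomes), chroms)

  bases <- c("A", "C", "G", "T")
  seqs <- if (withSequences) stats::setNames(vector("list", nChromosomes),
                                             chroms) else NULL
  markerChrom <- character(0); markerPos <- integer(0)
  alleleRows <- vector("list", nChromosomes)

  for (ci in seq_len(nChromosomes)) {
    L <- chromLengthBp
    pos <- sort(sample.int(L, nMarkersPerChrom))
    ref <- sample(bases, nMarkersPerChrom, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    ## carriers: random nonempty proper subset of the 8 founders
    nCarrier <- sample(1:7, nMarkersPerChrom, replace = TRUE)
    alle <- matrix(rep(ref, 8L), ncol = 8L)
    for (mi in seq_len(nMarkersPerChrom)) {
      carriers <- sample.int(8L, nCarrier[mi])
      alle[mi, carriers] <- alt[mi]
    }
    colnames(alle) <- unname(founders)
    alleleRows[[ci]] <- alle
    markerChrom <- c(markerChrom, rep(chroms[ci], nMarkersPerChrom))
    markerPos <- c(markerPos, pos)
    if (withSequences) {
      anc <- sample(bases, L, replace = TRUE)
      fseq <- vapply(seq_len(8L), function(f) {
        s <- anc
        s[pos] <- alle[, f]
        paste(s, collapse = "")
      }, "")
      seqs[[chroms[ci]]] <- Biostrings::DNAStringSet(
        stats::setNames(fseq, unname(founders)))
    }
  }
  alleles <- do.call(rbind, alleleRows)
  markers <- GenomicRanges::GRanges(markerChrom,
                                    IRanges::IRanges(markerPos, markerPos))
  S4Vectors::mcols(markers)$markerId <-
    sprintf("m%05d", seq_along(markers))
  new("FounderPanel", founderIds = unname(founders), sequences = seqs,
      markers = markers, markerAlleles = alleles,
      chromLengths = chromLengths, chromType = chromType)
}

## ---- meiosis machinery (plain data.frames for speed) ----

.pureHap <- function(founder, L) {
  data.frame(start = 1, end = L, founder = founder)
}

## One gamete from a diploid pair of haplotypes; Poisson crossovers with
## no interference, expected count scaled linearly with length.
.gamete <- function(h1, h2, L, crossoversPer100kb = 1) {
  nco <- stats::rpois(1L, crossoversPer100kb * L / 1e5)
  src <- sample.int(2L, 1L)
  if (nco == 0L) return(if (src == 1L) h1 else h2)
  cuts <- sort(sample.int(L - 1L, min(nco, L - 1L)))
  bounds <- c(0, cuts, L)
  haps <- list(h1, h2)
  pieces <- vector("list", length(bounds) - 1L)
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i] + 1; b <- bounds[i + 1L]
    h <- haps[[src]]
    keep <- h$end >= a & h$start <= b
    seg <- h[keep, , drop = FALSE]
    seg$start[1L] <- a
    seg$end[nrow(seg)] <- b
    pieces[[i]] <- seg
    src <- 3L - src
  }
  g <- do.call(rbind, pieces)
  ## merge adjacent same-founder runs
  same <- c(FALSE, g$founder[-1L] == g$founder[-nrow(g)])
  if (any(same)) {
    keep <- which(!same)
    g <- data.frame(start = g$start[keep],
                    end = g$end[c(keep[-1L] - 1L, nrow(g))],
                    founder = g$founder[keep])
  }
  rownames(g) <- NULL
  g
}

## Offspring of mom (female) x dad (male).
.offspring <- function(mom, dad, sex, chromLengths, chromType,
                       crossoversPer100kb = 1) {
  chrom <- stats::setNames(vector("list", length(chromLengths)),
                           names(chromLengths))
  for (cn in names(chromLengths)) {
    L <- chromLengths[[cn]]
    if (identical(chromType[[cn]], "X")) {
      momX <- mom$chrom[[cn]]
      gm <- if (length(momX) == 2L)
        .gamete(momX[[1L]], momX[[2L]], L, crossoversPer100kb)
      else momX[[1L]]
      chrom[[cn]] <- if (sex == "female") list(gm, dad$chrom[[cn]][[1L]])
                     else list(gm)
    } else {
      m <- mom$chrom[[cn]]; d <- dad$chrom[[cn]]
      chrom[[cn]] <- list(.gamete(m[[1L]], m[[2L]], L, crossoversPer100kb),
                          .gamete(d[[1L]], d[[2L]], L, crossoversPer100kb))
    }
  }
  list(sex = sex, chrom = chrom)
}

.founderIndividual <- function(founder, sex, chromLengths, chromType) {
  chrom <- stats::setNames(vector("list", length(chromLengths)),
                           names(chromLengths))
  for (cn in names(chromLengths)) {
    L <- chromLengths[[cn]]
    one <- identical(chromType[[cn]], "X") && sex == "male"
    chrom[[cn]] <- if (one) list(.pureHap(founder, L))
                   else list(.pureHap(founder, L), .pureHap(founder, L))
  }
  list(sex = sex, chrom = chrom)
}

## Heterozygous intervals (start, end) between two haplotypes.
.hetIntervals <- function(h1, h2) {
  cuts <- sort(unique(c(h1$start, h2$start)))
  f1 <- h1$founder[findInterval(cuts, h1$start)]
  f2 <- h2$founder[findInterval(cuts, h2$start)]
  het <- f1 != f2
  ends <- c(cuts[-1L] - 1, h1$end[nrow(h1)])
  data.frame(start = cuts[het], end = ends[het])
}

.individualHetFraction <- function(ind, chromLengths, chromType) {
  num <- 0; den <- 0
  for (cn in names(chromLengths)) {
    haps <- ind$chrom[[cn]]
    if (length(haps) != 2L) next  # male X: hemizygous, not assayed diploid
    hi <- .hetIntervals(haps[[1L]], haps[[2L]])
    num <- num + sum(hi$end - hi$start + 1)
    den <- den + chromLengths[[cn]]
  }
  if (den == 0) 0 else num / den
}

#' Simulate one CC strain genome through a breeding funnel
#'
#' Runs the CC breeding design: two generations of outcrossing combining
#' the eight founders as (AB x CD) x (EF x GH) in the pedigree's funnel
#' order, then the requested number of generations of brother-sister
#' mating. Crossovers per meiosis are Poisson with no interference, with
#' an expected 1 crossover per 100 kb of chromosome by default (scaled
#' linearly with length).
#'
#' @param panel A [FounderPanel-class], or a named numeric vector of
#'   chromosome lengths (with optional `chromType` attribute) when no
#'   marker/sequence content is needed.
#' @param pedigree A [CCPedigree-class] from [ccPedigree()].
#' @param sex Sex of the sampled individual.
#' @param crossoversPer100kb Expected crossovers per meiosis per 100 kb.
#' @return A [StrainGenome-class] with the realized diploid mosaic and its
#'   realized heterozygous fraction.
#' @examples
#' g <- simulateCCStrain(c(chr1 = 1e5), ccPedigree(1:8, 10, seed = 3))
#' realizedHetFraction(g)
#' @export
simulateCCStrain <- function(panel, pedigree, sex = c("female", "male"),
                             crossoversPer100kb = 1) {
  sex <- match.arg(sex)
  stopifnot(is(pedigree, "CCPedigree"))
  if (is(panel, "FounderPanel")) {
    chromLengths <- panel@chromLengths
    chromType <- panel@chromType
  } else {
    chromLengths <- panel
    chromType <- attr(panel, "chromType")
    if (is.null(chromType))
      chromType <- stats::setNames(rep("autosome", length(panel)),
                                   names(panel))
  }
  rng <- .snapshotRng(); on.exit(.restoreRng(rng))
  set.seed(pedigree@seed)
  fo <- pedigree@funnelOrder
  mk <- function(f, s) .founderIndividual(f, s, chromLengths, chromType)
  cross <- function(mom, dad, sex)
    .offspring(mom, dad, sex, chromLengths, chromType, crossoversPer100kb)
  ## G1: four F1s; dams female, sires male
  ab <- cross(mk(fo[1L], "female"), mk(fo[2L], "male"), "female")
  cd <- cross(mk(fo[3L], "female"), mk(fo[4L], "male"), "male")
  ef <- cross(mk(fo[5L], "female"), mk(fo[6L], "male"), "female")
  gh <- cross(mk(fo[7L], "female"), mk(fo[8L], "male"), "male")
  ## G2
  dam <- cross(ab, cd, "female")
  sire <- cross(ef, gh, "male")
  ## G2:F1 sibling pair, then sib mating
  sis <- cross(dam, sire, "female")
  bro <- cross(dam, sire, "male")
  g <- pedigree@nInbreedingGenerations
  if (g > 0L) {
    for (i in seq_len(g)) {
      newSis <- cross(sis, bro, "female")
      newBro <- cross(sis, bro, "male")
      sis <- newSis; bro <- newBro
    }
  }
  ind <- if (sex == "female") sis else bro
  new("StrainGenome", haplotypes = ind$chrom, chromLengths = chromLengths,
      chromType = chromType, sex = sex,
      realizedHetFraction = .individualHetFraction(ind, chromLengths,
                                                   chromType))
}

#' Expected heterozygosity under brother-sister mating
#'
#' Exact expected fraction of the genome still heterozygous after `g`
#' generations of full-sib mating, starting from the CC G2:F1 (whose two
#' haplotypes descend from disjoint founder quartets, so H = 1 at g = 0).
#' Computed by iterating the classical recurrence
#' H_t = H_{t-1}/2 + H_{t-2}/4 (asymptotic decay (1+sqrt(5))/4 per
#' generation).
#'
#' @param g Vector of generation counts (>= 0).
#' @return Expected heterozygous fraction for each element of `g`.
#' @examples
#' expectedHeterozygosity(0:5)
#' @export
expectedHeterozygosity <- function(g) {
  gmax <- max(g)
  H <- numeric(gmax + 1L)
  H[1L] <- 1
  if (gmax >= 1L) H[2L] <- 3 / 4
  if (gmax >= 2L) for (t in 2L:gmax)
    H[t + 1L] <- H[t] / 2 + H[t - 1L] / 4
  H[g + 1L]
}

#' True heterozygous intervals of a simulated genome
#'
#' @param genome A [StrainGenome-class] object.
#' @return `GRanges` of intervals where the two haplotypes carry different
#'   founders (diploid chromosomes only).
#' @export
trueHetIntervals <- function(genome) {
  out <- list()
  for (cn in names(genome@haplotypes)) {
    haps <- genome@haplotypes[[cn]]
    if (length(haps) != 2L) next
    hi <- .hetIntervals(haps[[1L]], haps[[2L]])
    if (nrow(hi))
      out[[cn]] <- GenomicRanges::GRanges(cn, IRanges::IRanges(hi$start,
                                                               hi$end))
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  do.call(c, unname(out))
}

#' Mosaic segments of a simulated genome as GRanges
#'
#' @param genome A [StrainGenome-class] object.
#' @param founders Founder names used to label segments.
#' @return `GRanges` tiling each diploid chromosome with metadata columns
#'   `founder1` and `founder2` (unordered; equal when homozygous).
#' @export
trueMosaic <- function(genome, founders = ccFounders()) {
  out <- list()
  for (cn in names(genome@haplotypes)) {
    haps <- genome@haplotypes[[cn]]
    if (length(haps) != 2L) next
    h1 <- haps[[1L]]; h2 <- haps[[2L]]
    cuts <- sort(unique(c(h1$start, h2$start)))
    f1 <- h1$founder[findInterval(cuts, h1$start)]
    f2 <- h2$founder[findInterval(cuts, h2$start)]
    ends <- c(cuts[-1L] - 1, h1$end[nrow(h1)])
    lo <- pmin(f1, f2); hi <- pmax(f1, f2)
    gr <- GenomicRanges::GRanges(cn, IRanges::IRanges(cuts, ends))
    S4Vectors::mcols(gr)$founder1 <- unname(founders[lo])
    S4Vectors::mcols(gr)$founder2 <- unname(founders[hi])
    out[[cn]] <- gr
  }
  do.call(c, unname(out))
}

#' Founder at given marker positions on each haplotype
#' @keywords internal
.foundersAtMarkers <- function(genome, markers) {
  chrom <- as.character(GenomicRanges::seqnames(markers))
  pos <- GenomicRanges::start(markers)
  n <- length(markers)
  f1 <- integer(n); f2 <- integer(n)
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    haps <- genome@haplotypes[[cn]]
    if (is.null(haps)) stop("genome has no chromosome ", cn)
    h1 <- haps[[1L]]
    f1[idx] <- h1$founder[findInterval(pos[idx], h1$start)]
    if (length(haps) == 2L) {
      h2 <- haps[[2L]]
      f2[idx] <- h2$founder[findInterval(pos[idx], h2$start)]
    } else f2[idx] <- f1[idx]
  }
  cbind(f1, f2)
}

#' Emit array genotype calls for a simulated genome
#'
#' Produces one genotype-array sample column for a simulated genome at the
#' panel's markers. At zero noise the call is the unordered allele pair
#' implied by the two founder haplotypes: the shared allele when both
#' haplotypes carry the same allele, H when the two alleles differ
#' (hemizygous male X markers report the single allele). Calls are then
#' corrupted to a random wrong call with probability `errorRate`, to H with
#' `hMiscallRate` (homozygous calls only), and to N with `nRate`.
#'
#' @param genome A [StrainGenome-class] object.
#' @param panel The [FounderPanel-class] the genome was bred from.
#' @param errorRate,hMiscallRate,nRate Corruption probabilities in [0, 1],
#'   summing to at most 1.
#' @param seed Optional integer seed for the corruption draws.
#' @return Character vector of calls, one per panel marker.
#' @export
emitArrayGenotypes <- function(genome, panel, errorRate = 0,
                               hMiscallRate = 0, nRate = 0, seed = NULL) {
  rates <- c(errorRate, hMiscallRate, nRate)
  if (any(rates < 0) || any(rates > 1) || sum(rates) > 1)
    stop("corruption rates must lie in [0,1] and sum to at most 1")
  if (!is.null(seed)) {
    rng <- .snapshotRng(); on.exit(.restoreRng(rng))
    set.seed(as.integer(seed))
  }
  ff <- .foundersAtMarkers(genome, panel@markers)
  n <- nrow(ff)
  a1 <- panel@markerAlleles[cbind(seq_len(n), ff[, 1L])]
  a2 <- panel@markerAlleles[cbind(seq_len(n), ff[, 2L])]
  calls <- ifelse(a1 == a2, a1, "H")
  if (sum(rates) > 0) {
    u <- stats::runif(n)
    wrong <- u < errorRate
    toH <- !wrong & u < errorRate + hMiscallRate & calls != "H"
    toN <- u >= errorRate + hMiscallRate & u < sum(rates)
    if (any(wrong)) {
      calls[wrong] <- vapply(which(wrong), function(i) {
        vocab <- unique(c(panel@markerAlleles[i, ], "H"))
        sample(setdiff(vocab, calls[i]), 1L)
      }, "")
    }
    calls[toH] <- "H"
    calls[toN] <- "N"
  }
  calls
}

#' Simulate shotgun reads from a template sequence
#'
#' Draws fixed-length reads uniformly from both strands of a template.
#' Any implanted deletions are excised from the template before sampling,
#' so no read carries sequence interior to a deletion. The number of reads
#' is `round(depth * templateLength / readLength)` where the template
#' length is measured after excision.
#'
#' @param sequence Template sequence (character or `DNAString`).
#' @param readLength Read length (>= 45).
#' @param depth Target mean coverage.
#' @param errorRate Per-base substitution probability.
#' @param seed Optional integer seed.
#' @param deletions `data.frame(start, end)` of non-overlapping 1-based
#'   inclusive intervals to excise, or `NULL`.
#' @return A `DNAStringSet` of reads; the excised template is attached in
#'   `metadata(x)$template`.
#' @export
simulateReads <- function(sequence, readLength = 150L, depth = 10,
                          errorRate = 0, seed = NULL, deletions = NULL) {
  if (readLength < 45L) stop("readLength must be >= 45")
  seqc <- as.character(sequence)
  L0 <- nchar(seqc)
  if (!is.null(deletions) && nrow(deletions)) {
    d <- deletions[order(deletions$start), , drop = FALSE]
    if (any(d$start < 1) || any(d$end > L0) || any(d$end < d$start))
      stop("deletions must lie within the sequence")
    if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)]))
      stop("deletions must be non-overlapping")
    keepFrom <- c(1, d$end + 1)
    keepTo <- c(d$start - 1, L0)
    parts <- substring(seqc, keepFrom, keepTo)
    seqc <- paste(parts, collapse = "")
  }
  if (!is.null(seed)) {
    rng <- .snapshotRng(); on.exit(.restoreRng(rng))
    set.seed(as.integer(seed))
  }
  L <- nchar(seqc)
  nReads <- round(depth * L / readLength)
  starts <- sample.int(L - readLength + 1L, nReads, replace = TRUE)
  reads <- substring(seqc, starts, starts + readLength - 1L)
  minus <- stats::runif(nReads) < 0.5
  if (any(minus))
    reads[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[minus])))
  if (errorRate > 0) {
    nb <- nReads * readLength
    nErr <- stats::rbinom(1L, nb, errorRate)
    if (nErr > 0L) {
      at <- sample.int(nb, nErr)
      ri <- (at - 1L) %/% readLength + 1L
      pi <- (at - 1L) %% readLength + 1L
      for (j in seq_len(nErr)) {
        old <- substr(reads[ri[j]], pi[j], pi[j])
        new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        substr(reads[ri[j]], pi[j], pi[j]) <- new
      }
    }
  }
  out <- Biostrings::DNAStringSet(reads)
  S4Vectors::metadata(out) <- list(template = seqc, depth = depth,
                                   errorRate = errorRate,
                                   readLength = readLength)
  out
}
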