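## Founder-contribution accounting and wild-derived enrichment.
##
## A strain's diploid mosaic attributes each genomic interval to an
## unordered founder pair; heterozygous intervals contribute half their
## length to each founder.

.mosaicFounders <- function(mosaic) {
  f1 <- S4Vectors::mcols(mosaic)$founder1
  f2 <- S4Vectors::mcols(mosaic)$founder2
  if (is.null(f1) || is.null(f2))
    stop("mosaic must carry founder1/founder2 metadata columns")
  list(f1 = f1, f2 = f2)
}

#' Founder haplotype frequencies of one strain
#'
#' Fraction of the diploid assayed genome attributed to each founder:
#' homozygous segments count fully, heterozygous segments contribute half
#' their length to each of the two founders.
#'
#' @param mosaic `GRanges` mosaic with `founder1`/`founder2` metadata
#'   (from [mosaicFromTrack()] or [trueMosaic()]).
#' @param founders Founder names defining the output order.
#' @return Named numeric 8-vector summing to 1.
#' @export
founderFrequencies <- function(mosaic, founders = ccFounders()) {
  if (!length(mosaic)) stop("empty mosaic")
  ff <- .mosaicFounders(mosaic)
  w <- GenomicRanges::width(mosaic)
  out <- stats::setNames(numeric(length(founders)), unname(founders))
  for (i in seq_along(mosaic)) {
    if (ff$f1[i] == ff$f2[i]) out[ff$f1[i]] <- out[ff$f1[i]] + w[i]
    else {
      out[ff$f1[i]] <- out[ff$f1[i]] + w[i] / 2
      out[ff$f2[i]] <- out[ff$f2[i]] + w[i] / 2
    }
  }
  out / sum(w)
}

#' Tabulate founder frequencies across strains
#'
#' @param freqList Named list of per-strain frequency vectors from
#'   [founderFrequencies()].
#' @return `data.frame` with one row per strain plus an `"Average"` row.
#' @export
founderFrequencyTable <- function(freqList) {
  m <- do.call(rbind, freqList)
  df <- as.data.frame(m)
  df <- rbind(df, Average = colMeans(m))
  df
}

#' Per-locus founder frequencies across a population
#'
#' At each grid position, a founder's frequency is the mean over strains
#' of its diploid dosage (1 homozygous, 1/2 heterozygous, 0 absent).
#'
#' @param mosaics Named list of strain mosaics (`GRanges`).
#' @param gridPositions Numeric positions on `chromosome`.
#' @param chromosome Chromosome to evaluate.
#' @param founders Founder names defining the output columns.
#' @return Matrix positions x founders; rows sum to 1.
#' @export
populationLocusFrequency <- function(mosaics, gridPositions,
                                     chromosome = "chr1",
                                     founders = ccFounders()) {
  stopifnot(length(mosaics) >= 1L)
  fr <- matrix(0, length(gridPositions), length(founders),
               dimnames = list(NULL, unname(founders)))
  used <- 0L
  for (mos in mosaics) {
    mos <- mos[as.character(GenomicRanges::seqnames(mos)) == chromosome]
    if (!length(mos)) next
    inRange <- gridPositions >= min(GenomicRanges::start(mos)) &
               gridPositions <= max(GenomicRanges::end(mos))
    if (!all(inRange))
      warning("grid position(s) outside assayed span excluded")
    idx <- findInterval(gridPositions, GenomicRanges::start(mos))
    ff <- .mosaicFounders(mos)
    for (j in which(inRange)) {
      s <- idx[j]
      fr[j, ff$f1[s]] <- fr[j, ff$f1[s]] + 0.5
      fr[j, ff$f2[s]] <- fr[j, ff$f2[s]] + 0.5
    }
    used <- used + 1L
  }
  fr / used
}

## Per-strain, per-chromosome wild-dosage step function and its cumulative
## integral, for fast interval queries under circular rotation.
.wildCumulative <- function(mosaic, wildSet, chromosome) {
  mos <- mosaic[as.character(GenomicRanges::seqnames(mosaic)) ==
                chromosome]
  if (!length(mos)) return(NULL)
  ff <- .mosaicFounders(mos)
  dose <- (ff$f1 %in% wildSet) / 2 + (ff$f2 %in% wildSet) / 2
  starts <- GenomicRanges::start(mos)
  ends <- GenomicRanges::end(mos)
  L <- max(ends)
  ## G(x) = integral of dosage over (0, x], x in 0..L
  brk <- c(starts - 1, L)
  cum <- c(0, cumsum(dose * (ends - starts + 1)))
  list(brk = brk, cum = cum, dose = dose, L = L, total = cum[length(cum)])
}

.wildIntegral <- function(wc, x) {
  ## integral of dosage over (0, x], clipped to [0, L]
  x <- pmin(pmax(x, 0), wc$L)
  i <- findInterval(x, wc$brk)
  wc$cum[i] + wc$dose[pmin(i, length(wc$dose))] * (x - wc$brk[i])
}

.wildCircular <- function(wc, x) {
  ## integral over the circularized genome up to coordinate x >= 0
  floor(x / wc$L) * wc$total + .wildIntegral(wc, x %% wc$L)
}

#' Permutation test for wild-derived enrichment in heterozygous regions
#'
#' Tests whether wild-derived founder haplotypes are over-represented
#' inside regions of residual heterozygosity. The statistic is the total
#' wild-derived dosage-length inside the heterozygous intervals summed
#' over strains; the null distribution is built by circularly rotating
#' each strain's heterozygous intervals per chromosome by independent
#' uniform offsets, preserving interval number, lengths and chromosome
#' structure. p = (1 + #(null >= observed)) / (1 + nPermutations).
#'
#' @param mosaics Named list of strain mosaics (`GRanges`).
#' @param hetIntervals Named list (same names) of `GRanges` heterozygous
#'   intervals per strain.
#' @param wildSet Founder names counted as wild-derived.
#' @param nPermutations Number of rotations (>= 999 recommended).
#' @param seed Optional integer seed.
#' @return A list with `observed`, `expected` (genome-wide wild fraction
#'   times total het length), `p`, `nPermutations` and `seed`.
#' @export
wildEnrichmentTest <- function(mosaics, hetIntervals,
                               wildSet = ccWildFounders(),
                               nPermutations = 999L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  strains <- names(mosaics)
  nHet <- sum(vapply(hetIntervals, length, 1L))
  if (nHet == 0L) stop("no heterozygous intervals: test undefined")
  obs <- 0; null <- numeric(nPermutations)
  expTotal <- 0
  for (s in strains) {
    mos <- mosaics[[s]]
    het <- hetIntervals[[s]]
    for (cn in unique(as.character(GenomicRanges::seqnames(mos)))) {
      wc <- .wildCumulative(mos, wildSet, cn)
      h <- het[as.character(GenomicRanges::seqnames(het)) == cn]
      if (is.null(wc) || !length(h)) next
      a <- GenomicRanges::start(h) - 1   # continuous [a, b]
      b <- GenomicRanges::end(h)
      obs <- obs + sum(.wildIntegral(wc, b) - .wildIntegral(wc, a))
      expTotal <- expTotal + sum(b - a) * wc$total / wc$L
      off <- stats::runif(nPermutations, 0, wc$L)
      for (ii in seq_along(a)) {
        null <- null + .wildCircular(wc, b[ii] + off) -
                       .wildCircular(wc, a[ii] + off)
      }
    }
  }
  p <- (1 + sum(null >= obs)) / (1 + nPermutations)
  list(observed = obs, expected = expTotal, p = p,
       nPermutations = nPermutations, seed = seed)
}

#' Founder representation and uncovered regions across a population
#'
#' For every grid position and founder, counts the strains carrying at
#' least one haplotype of that founder (dosage >= 1/2), and reports the
#' maximal runs of grid positions where a founder has no carrier at all.
#'
#' @param mosaics Named list of strain mosaics (`GRanges`).
#' @param gridPositions Numeric positions on `chromosome`.
#' @param chromosome Chromosome to evaluate.
#' @param founders Founder names.
#' @return A list with `carriers` (positions x founders integer matrix)
#'   and `uncovered` (`data.frame(founder, start, end)` of zero-carrier
#'   runs in grid coordinates).
#' @export
minFounderRepresentation <- function(mosaics, gridPositions,
                                     chromosome = "chr1",
                                     founders = ccFounders()) {
  stopifnot(length(mosaics) >= 1L)
  carriers <- matrix(0L, length(gridPositions), length(founders),
                     dimnames = list(NULL, unname(founders)))
  for (mos in mosaics) {
    mos <- mos[as.character(GenomicRanges::seqnames(mos)) == chromosome]
    if (!length(mos)) next
    idx <- findInterval(gridPositions, GenomicRanges::start(mos))
    ok <- idx >= 1L & gridPositions <= max(GenomicRanges::end(mos))
    ff <- .mosaicFounders(mos)
    for (j in which(ok)) {
      s <- idx[j]
      carriers[j, ff$f1[s]] <- carriers[j, ff$f1[s]] + 1L
      if (ff$f2[s] != ff$f1[s])
        carriers[j, ff$f2[s]] <- carriers[j, ff$f2[s]] + 1L
    }
  }
  unc <- list()
  for (f in unname(founders)) {
    zero <- carriers[, f] == 0L
    r <- rle(zero)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values))
      unc[[length(unc) + 1L]] <-
        data.frame(founder = f, start = gridPositions[starts[k]],
                   end = gridPositions[ends[k]])
  }
  uncovered <- if (length(unc)) do.call(rbind, unc) else
    data.frame(founder = character(), start = numeric(), end = numeric())
  list(carriers = carriers, uncovered = uncovered)
}
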