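## 36-state founder diplotype reconstruction.
##
## Emission model: under state {f, g} the expected array call is the shared
## founder allele when the two founders carry the same allele, H otherwise;
## the observed call equals the expected one with probability 1 - epsilon,
## the remaining epsilon split uniformly over the other members of the
## marker's call vocabulary (the two alleles and H). N is uninformative.
## Transitions factorize per haplotype: each haplotype switches founder
## with probability r = 1 - exp(-rho * d), uniformly to the 7 others.

#' HMM parameters for haplotype reconstruction
#'
#' @param epsilon Per-call genotyping error rate, in (0, 0.5).
#' @param rho Recombination-scale parameter: expected founder switches per
#'   bp per haplotype. The default (1e-4) is calibrated so that expected
#'   switch counts match the crossover accumulation of a simulated 100 kb
#'   chromosome bred through the CC funnel and ~10 generations of sib
#'   mating.
#' @param prior Prior over states (default uniform).
#' @return A list of validated parameters.
#' @export
hmmParams <- function(epsilon = 0.005, rho = 1e-4, prior = NULL) {
  if (epsilon <= 0 || epsilon >= 0.5) stop("epsilon must be in (0, 0.5)")
  if (rho <= 0) stop("rho must be > 0")
  list(epsilon = epsilon, rho = rho, prior = prior)
}

#' Emission probability of an array call under a diplotype state
#'
#' @param call Observed call (allele, `"H"` or `"N"`).
#' @param state State code, e.g. `"AA"` or `"AB"`.
#' @param founderAlleles Named character vector of the allele carried by
#'   each founder code at this marker.
#' @param epsilon Genotyping error rate.
#' @return Emission probability; 1 for `"N"` (uninformative).
#' @examples
#' emissionProbability("A", "AA", c(A = "A", B = "G"), 0.01)  # 0.99
#' @export
emissionProbability <- function(call, state, founderAlleles,
                                epsilon = 0.005) {
  if (call == "N") return(1)
  f <- substr(state, 1L, 1L); g <- substr(state, 2L, 2L)
  a1 <- founderAlleles[[f]]; a2 <- founderAlleles[[g]]
  expected <- if (a1 == a2) a1 else "H"
  vocab <- unique(c(founderAlleles, "H"))
  if (!call %in% vocab) return(epsilon / (length(vocab) - 1L))
  if (call == expected) 1 - epsilon else epsilon / (length(vocab) - 1L)
}

## Emission matrix: markers x states. alleles is markers x nFounders.
.emissionMatrix <- function(calls, alleles, epsilon, nFounders = 8L) {
  pairs <- .statePairs(nFounders)
  nS <- nrow(pairs)
  n <- length(calls)
  a1 <- alleles[, pairs[, 1L], drop = FALSE]
  a2 <- alleles[, pairs[, 2L], drop = FALSE]
  expected <- ifelse(a1 == a2, a1, "H")       # markers x states
  nVocab <- apply(alleles, 1L, function(a) length(unique(a))) + 1L
  E <- matrix(0, n, nS)
  hit <- expected == calls
  E[hit] <- 1 - epsilon
  E[!hit] <- (epsilon / (nVocab - 1L))[row(E)[!hit]]
  E[calls == "N", ] <- 1
  E
}

#' Diplotype transition matrix between two markers
#'
#' Factorized per-haplotype model: over distance `d` each haplotype
#' switches founder with probability `r = 1 - exp(-rho * d)`, uniformly to
#' the other founders; the two haplotypes are independent and the ordered
#' product is mapped onto unordered founder pairs.
#'
#' @param distanceBp Distance in bp (>= 0).
#' @param rho Switch-rate parameter per bp.
#' @param nFounders Number of founders (8 for the CC).
#' @return Stochastic matrix over the diplotype states.
#' @export
transitionMatrix <- function(distanceBp, rho, nFounders = 8L) {
  r <- 1 - exp(-rho * distanceBp)
  S <- matrix(r / (nFounders - 1L), nFounders, nFounders)
  diag(S) <- 1 - r
  pairs <- .statePairs(nFounders)
  nS <- nrow(pairs)
  a1 <- pairs[, 1L]; a2 <- pairs[, 2L]
  ## T[s, t] = S[a1,b1] S[a2,b2] + (b1 != b2) S[a1,b2] S[a2,b1]
  T1 <- S[a1, a1, drop = FALSE] * S[a2, a2, drop = FALSE]
  T2 <- S[a1, a2, drop = FALSE] * S[a2, a1, drop = FALSE]
  het <- a1 != a2
  Tm <- T1
  Tm[, het] <- T1[, het] + T2[, het]
  dimnames(Tm) <- NULL
  Tm
}

#' Forward-backward founder-state posterior probabilities
#'
#' Runs a numerically stabilized (per-position scaled) forward-backward
#' pass over the diplotype state space and returns the posterior marginals
#' at every marker. Chromosomes are processed independently. For male X
#' chromosomes the 8-state inbred-only space is used.
#'
#' @param calls Character vector of calls, one per marker.
#' @param markers `GRanges` of marker positions (with `markerId`).
#' @param founderAlleles Character matrix (markers x 8) of founder alleles.
#' @param params Parameter list from [hmmParams()].
#' @param chromKind `"autosome"`, `"femaleX"` or `"maleX"`.
#' @param sampleId Sample id recorded in the track.
#' @param founderCodes Founder code letters (reduced spaces supported).
#' @return A [StateProbTrack-class] of posterior marginals.
#' @export
forwardBackward <- function(calls, markers, founderAlleles,
                            params = hmmParams(),
                            chromKind = c("autosome", "femaleX", "maleX"),
                            sampleId = "sample",
                            founderCodes = names(ccFounders())) {
  chromKind <- match.arg(chromKind)
  if (!length(calls)) stop("at least one marker required")
  stopifnot(length(calls) == length(markers),
            nrow(founderAlleles) == length(markers))
  nF <- length(founderCodes)
  maleX <- chromKind == "maleX"
  states <- if (maleX) paste0(founderCodes, founderCodes)
            else diplotypeStates(founderCodes)
  nS <- length(states)
  prior <- params$prior
  if (is.null(prior)) prior <- rep(1 / nS, nS)
  if (all(calls == "N")) {
    warning("all calls are N; returning the prior at every marker")
    return(StateProbTrack(matrix(prior, length(calls), nS, byrow = TRUE),
                          markers, states = states, sampleId = sampleId,
                          chromKind = chromKind))
  }

  chrom <- as.character(GenomicRanges::seqnames(markers))
  pos <- GenomicRanges::start(markers)
  post <- matrix(0, length(calls), nS)
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    E <- if (maleX)
      .maleXEmission(calls[idx], founderAlleles[idx, , drop = FALSE],
                     params$epsilon)
    else .emissionMatrix(calls[idx], founderAlleles[idx, , drop = FALSE],
                         params$epsilon, nF)
    n <- length(idx)
    d <- diff(pos[idx])
    f <- matrix(0, n, nS); b <- matrix(0, n, nS)
    x <- prior * E[1L, ]
    f[1L, ] <- x / sum(x)
    if (n > 1L) for (t in 2L:n) {
      Tm <- .transition(d[t - 1L], params$rho, nF, maleX)
      x <- as.vector(f[t - 1L, ] %*% Tm) * E[t, ]
      f[t, ] <- x / sum(x)
    }
    b[n, ] <- 1
    if (n > 1L) for (t in (n - 1L):1L) {
      Tm <- .transition(d[t], params$rho, nF, maleX)
      x <- as.vector(Tm %*% (b[t + 1L, ] * E[t + 1L, ]))
      b[t, ] <- x / sum(x)
    }
    p <- f * b
    post[idx, ] <- p / rowSums(p)
  }
  StateProbTrack(post, markers, states = states, sampleId = sampleId,
                 chromKind = chromKind)
}

.transition <- function(d, rho, nFounders, maleX) {
  if (maleX) {
    r <- 1 - exp(-rho * d)
    S <- matrix(r / (nFounders - 1L), nFounders, nFounders)
    diag(S) <- 1 - r
    S
  } else transitionMatrix(d, rho, nFounders)
}

## Male X emission over the 8 inbred states: expected call is the founder
## allele; H is a wrong call.
.maleXEmission <- function(calls, alleles, epsilon) {
  n <- length(calls)
  nVocab <- apply(alleles, 1L, function(a) length(unique(a))) + 1L
  E <- matrix(0, n, ncol(alleles))
  hit <- alleles == calls
  E[hit] <- 1 - epsilon
  E[!hit] <- (epsilon / (nVocab - 1L))[row(E)[!hit]]
  E[calls == "N", ] <- 1
  E
}

#' Impute a probability track at new marker positions
#'
#' Elementwise linear interpolation of the state probabilities between the
#' flanking markers of a denser track, renormalized per position. Targets
#' outside the dense range take the nearest end marker's vector.
#'
#' @param track A [StateProbTrack-class] (single chromosome, sorted).
#' @param targetPositions Sorted numeric positions on the same chromosome.
#' @return A [StateProbTrack-class] at the target positions.
#' @export
imputeProbabilities <- function(track, targetPositions) {
  if (!length(track@markers)) stop("empty dense track")
  pos <- GenomicRanges::start(track@markers)
  chrom <- unique(as.character(GenomicRanges::seqnames(track@markers)))
  if (length(chrom) != 1L)
    stop("imputation operates on one chromosome at a time")
  P <- track@probs
  tp <- pmin(pmax(targetPositions, pos[1L]), pos[length(pos)])
  lo <- findInterval(tp, pos)
  hi <- pmin(lo + 1L, length(pos))
  w <- ifelse(pos[hi] == pos[lo], 0,
              (tp - pos[lo]) / (pos[hi] - pos[lo]))
  out <- (1 - w) * P[lo, , drop = FALSE] + w * P[hi, , drop = FALSE]
  out <- out / rowSums(out)
  mk <- GenomicRanges::GRanges(chrom, IRanges::IRanges(targetPositions,
                                                       targetPositions))
  S4Vectors::mcols(mk)$markerId <- sprintf("t%05d",
                                           seq_along(targetPositions))
  StateProbTrack(out, mk, states = track@states, sampleId = track@sampleId,
                 chromKind = track@chromKind)
}

#' Merge obligate-ancestor state vectors at one marker
#'
#' Implements the MRCA combination rule. At a marker, each obligate
#' ancestor contributes its state vector: (1) the maximum-probability state
#' of each ancestor is found; (2) when two or more ancestors have inbred
#' maxima on different founders, each such ancestor's inbred-maximum
#' probability is redistributed (added) onto the heterozygous states
#' pairing its founder with the other conflicting founders (split equally
#' when more than one), and the inbred entry set to 0; (3) the elementwise
#' maximum across ancestors is taken and (4) normalized.
#'
#' @param vectors Numeric matrix (ancestors x states), each row a
#'   normalized probability vector, or a list of such vectors.
#' @param founderCodes Founder letter codes of the state space.
#' @return Named numeric merged probability vector over the states.
#' @export
mergeAncestors <- function(vectors, founderCodes = names(ccFounders())) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  if (is.null(dim(vectors)) || nrow(vectors) == 0L)
    stop("at least one ancestor vector required")
  nF <- length(founderCodes)
  states <- diplotypeStates(founderCodes)
  stopifnot(ncol(vectors) == length(states))
  pairs <- .statePairs(nF)
  V <- vectors
  arg <- max.col(V, ties.method = "first")   # lowest index on ties
  inbred <- arg <= nF
  confl <- unique(arg[inbred])
  if (length(confl) >= 2L) {
    for (i in which(inbred)) {
      f <- arg[i]
      others <- setdiff(confl, f)
      share <- V[i, f] / length(others)
      for (g in others) {
        s <- .stateIndexOf(f, g, nF)
        V[i, s] <- V[i, s] + share
      }
      V[i, f] <- 0
    }
  }
  m <- apply(V, 2L, max)
  m <- m / sum(m)
  names(m) <- states
  m
}

#' Merge per-marker tracks of obligate ancestors into a strain track
#'
#' Applies [mergeAncestors()] marker by marker across a set of ancestor
#' tracks defined on the same markers. Male-X 8-state tracks must first be
#' expanded with [expandMaleX()].
#'
#' @param tracks List of [StateProbTrack-class] objects on identical
#'   markers and state space.
#' @param sampleId Strain id for the merged track.
#' @return A [StateProbTrack-class] of merged, normalized probabilities.
#' @export
mergeAncestorTracks <- function(tracks, sampleId = "strain") {
  stopifnot(length(tracks) >= 1L)
  n <- nrow(tracks[[1L]]@probs)
  states <- tracks[[1L]]@states
  codes <- unique(substr(states, 1L, 1L))
  out <- matrix(0, n, length(states))
  for (i in seq_len(n)) {
    M <- do.call(rbind, lapply(tracks, function(t) t@probs[i, ]))
    out[i, ] <- mergeAncestors(M, founderCodes = codes)
  }
  StateProbTrack(out, tracks[[1L]]@markers, states = states,
                 sampleId = sampleId,
                 chromKind = tracks[[1L]]@chromKind)
}

#' Expand a male-X 8-state vector to the 36-state space
#'
#' Inbred-state probabilities are copied and all heterozygous states get
#' probability 0, preserving the total.
#'
#' @param x Numeric 8-vector (one marker) or a male-X
#'   [StateProbTrack-class].
#' @param founderCodes Founder letter codes.
#' @return A 36-vector, or a 36-state [StateProbTrack-class].
#' @export
expandMaleX <- function(x, founderCodes = names(ccFounders())) {
  nF <- length(founderCodes)
  states <- diplotypeStates(founderCodes)
  if (is(x, "StateProbTrack")) {
    out <- matrix(0, nrow(x@probs), length(states))
    out[, seq_len(nF)] <- x@probs
    return(StateProbTrack(out, x@markers, states = states,
                          sampleId = x@sampleId, chromKind = "maleX"))
  }
  stopifnot(length(x) == nF)
  v <- numeric(length(states))
  v[seq_len(nF)] <- x
  names(v) <- states
  v
}

#' Segment a probability track into a haplotype mosaic
#'
#' Takes the per-marker maximum-posterior state (ties broken toward the
#' lowest canonical state index), merges consecutive markers with equal
#' argmax into segments, and places segment boundaries at the midpoint
#' between flanking markers of different argmax. Segments whose mean
#' posterior falls below `minPosterior` are flagged uncertain.
#'
#' @param track A [StateProbTrack-class] object.
#' @param minPosterior Mean-posterior threshold for confident segments.
#' @param founders Founder names used for segment labels.
#' @return `GRanges` of segments with metadata `state`, `founder1`,
#'   `founder2`, `meanPosterior`, `uncertain`.
#' @export
mosaicFromTrack <- function(track, minPosterior = 0.5,
                            founders = ccFounders()) {
  P <- track@probs
  chrom <- as.character(GenomicRanges::seqnames(track@markers))
  pos <- GenomicRanges::start(track@markers)
  arg <- max.col(P, ties.method = "first")
  segs <- list()
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    a <- arg[idx]; p <- pos[idx]
    r <- rle(a)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    bnd <- floor((p[ends[-length(ends)]] + p[starts[-1L]]) / 2)
    segStart <- c(p[1L], bnd + 1L)
    segEnd <- c(bnd, p[length(p)])
    mp <- vapply(seq_along(r$values), function(k) {
      rows <- idx[starts[k]:ends[k]]
      mean(P[cbind(rows, r$values[k])])
    }, 1)
    st <- track@states[r$values]
    gr <- GenomicRanges::GRanges(cn, IRanges::IRanges(segStart, segEnd))
    S4Vectors::mcols(gr)$state <- st
    codes <- names(founders)
    f1 <- match(substr(st, 1L, 1L), codes)
    f2 <- match(substr(st, 2L, 2L), codes)
    S4Vectors::mcols(gr)$founder1 <- unname(founders[f1])
    S4Vectors::mcols(gr)$founder2 <- unname(founders[f2])
    S4Vectors::mcols(gr)$meanPosterior <- mp
    S4Vectors::mcols(gr)$uncertain <- mp < minPosterior
    segs[[length(segs) + 1L]] <- gr
  }
  do.call(c, segs)
}
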