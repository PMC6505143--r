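## Independent oracles and small fixture builders used across the suite.

## Reverse complement, written independently of the package internals.
rcOracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(strsplit(x, ""), function(ch)
    paste(rev(unname(comp[ch])), collapse = ""), "")
}

## Naive read-count oracle: number of reads containing q or its reverse
## complement as a plain substring.
naiveKmerCount <- function(reads, q) {
  sum(grepl(q, reads, fixed = TRUE) |
      grepl(rcOracle(q), reads, fixed = TRUE))
}

## Brute-force posterior marginals by exhaustive path enumeration over a
## reduced founder space. Written from the model definition, independent
## of the forward-backward implementation: per-haplotype switch
## probability r = 1 - exp(-rho d) spread uniformly over the other
## founders; emission 1 - eps for the expected call, eps split over the
## other two members of the call vocabulary; N emits 1.
bruteForcePosterior <- function(calls, pos, alleles, eps, rho, nF) {
  pairs <- rbind(cbind(seq_len(nF), seq_len(nF)),
                 if (nF > 1) t(utils::combn(nF, 2)))
  nS <- nrow(pairs)
  emit <- function(t, s) {
    if (calls[t] == "N") return(1)
    a <- alleles[t, pairs[s, 1]]; b <- alleles[t, pairs[s, 2]]
    expected <- if (a == b) a else "H"
    vocab <- unique(c(alleles[t, ], "H"))
    if (calls[t] == expected) 1 - eps else eps / (length(vocab) - 1)
  }
  hapTrans <- function(f1, f2, d) {
    r <- 1 - exp(-rho * d)
    if (f1 == f2) 1 - r else r / (nF - 1)
  }
  trans <- function(s, t, d) {
    a <- pairs[s, ]; b <- pairs[t, ]
    p <- hapTrans(a[1], b[1], d) * hapTrans(a[2], b[2], d)
    if (b[1] != b[2])
      p <- p + hapTrans(a[1], b[2], d) * hapTrans(a[2], b[1], d)
    p
  }
  n <- length(calls)
  paths <- as.matrix(expand.grid(rep(list(seq_len(nS)), n)))
  w <- apply(paths, 1, function(path) {
    p <- (1 / nS) * emit(1, path[1])
    if (n > 1) for (t in 2:n)
      p <- p * trans(path[t - 1], path[t], pos[t] - pos[t - 1]) *
        emit(t, path[t])
    p
  })
  post <- matrix(0, n, nS)
  for (t in seq_len(n))
    post[t, ] <- vapply(seq_len(nS), function(s)
      sum(w[paths[, t] == s]), 1)
  post / rowSums(post)
}

## Random sequence fixture.
randomSeq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Tiny GRanges marker map on one chromosome.
markerFixture <- function(pos, chrom = "chr1") {
  gr <- GenomicRanges::GRanges(rep(chrom, length(pos)),
                               IRanges::IRanges(pos, pos))
  S4Vectors::mcols(gr)$markerId <- sprintf("m%04d", seq_along(pos))
  gr
}

## A 36-vector with named entries set and the rest zero.
stateVector <- function(...) {
  v <- setNames(numeric(36), diplotypeStates())
  args <- c(...)
  v[names(args)] <- args
  v
}
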