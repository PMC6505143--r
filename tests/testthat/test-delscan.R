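test_that("k-mer index honors the read-count query contract", {
  r1 <- randomSeq(150, seed = 101)
  idx1 <- buildKmerIndex(r1)
  q <- substring(r1, 1, 45)
  expect_identical(kmerCount(idx1, q), 1L)
  expect_identical(kmerCount(idx1, rcOracle(q)), 1L)
  ## exhaustive equivalence with naive substring search
  set.seed(103)
  tmpl <- randomSeq(20000)
  reads <- as.character(simulateReads(tmpl, 100, 2.5, 0.01, seed = 104))
  expect_length(reads, 500L)
  idx <- buildKmerIndex(reads)
  starts <- sample.int(20000 - 44, 150)
  queries <- c(substring(tmpl, starts, starts + 44),
               vapply(1:50, function(i)
                 randomSeq(45), ""))
  got <- kmerCount(idx, queries)
  want <- vapply(queries, naiveKmerCount, 1L, reads = reads)
  expect_identical(got, unname(want))
  ## orientation symmetry on every tested query
  expect_identical(kmerCount(idx, rcOracle(queries)), got)
  ## short reads skipped with a message; N k-mers never match
  expect_message(idxs <- buildKmerIndex(c(reads[1], "ACGT")), "skipped")
  expect_identical(idxs@nSkipped, 1L)
  nq <- paste0(substring(reads[1], 1, 44), "N")
  expect_identical(kmerCount(idx, nq), 0L)
})

test_that("k-mer read retrieval returns the reads, query-oriented", {
  reads <- c(randomSeq(100, seed = 111), randomSeq(100))
  idx <- buildKmerIndex(reads)
  q <- substring(reads[2], 30, 74)
  got <- kmerReads(idx, q)
  expect_true(all(grepl(q, got, fixed = TRUE)))
  expect_identical(sort(unique(c(got, rcOracle(got)))[
    unique(c(got, rcOracle(got))) %in% reads]), sort(reads[2]))
  expect_identical(kmerReads(idx, rcOracle(q)),
                   rcOracle(got))
})

test_that("reference tiling follows the 15 bp shift rule and threshold", {
  ref105 <- randomSeq(105, seed = 121)
  idx <- buildKmerIndex(randomSeq(150))
  tiles <- tileReference(ref105, idx)
  expect_identical(tiles$start, c(1L, 16L, 31L, 46L, 61L))
  ## a tile covered by exactly 2 reads is absent; 3 reads present
  ref <- randomSeq(300, seed = 123)
  tile1 <- substring(ref, 1, 45)
  reads2 <- c(substring(ref, 1, 150), substring(ref, 1, 150))
  t2 <- tileReference(ref, buildKmerIndex(reads2))
  expect_false(t2$present[1])
  t3 <- tileReference(ref, buildKmerIndex(c(reads2, reads2[1])))
  expect_true(t3$present[1])
  ## error-free full-depth reads: all non-repetitive tiles present
  tmpl <- randomSeq(20000, seed = 125)
  rds <- simulateReads(tmpl, 150, 30, 0, seed = 126)
  tAll <- tileReference(tmpl, buildKmerIndex(rds))
  ## interior tiles (edge windows of a finite template are reachable by
  ## only a handful of read start positions)
  interior <- tAll$start > 150 & tAll$start < 20000 - 195
  expect_true(all(tAll$present[interior & !tAll$repetitive]))
})

test_that("missing-interval candidates respect size and repeat filters", {
  ## implanted 2000 bp deletion in unique sequence: exactly one candidate
  tmpl <- randomSeq(30000, seed = 131)
  del <- data.frame(start = 12001, end = 14000)
  rds <- simulateReads(tmpl, 150, 10, 0, seed = 132, deletions = del)
  tiles <- tileReference(tmpl, buildKmerIndex(rds))
  cand <- findMissingIntervals(tiles)
  expect_identical(nrow(cand), 1L)
  expect_lte(cand$tileStart, del$start)
  expect_gte(cand$tileEnd + 44, del$end)
  ## 300 bp deletion: below the 500 bp threshold, no candidate
  del3 <- data.frame(start = 12001, end = 12300)
  rds3 <- simulateReads(tmpl, 150, 10, 0, seed = 133, deletions = del3)
  cand3 <- findMissingIntervals(tileReference(tmpl,
                                              buildKmerIndex(rds3)))
  expect_identical(nrow(cand3), 0L)
  ## an absent run of entirely repetitive tiles is rejected
  unit <- randomSeq(30, seed = 134)
  tandem <- paste0(randomSeq(3000, 135),
                   paste(rep(unit, 40), collapse = ""),
                   randomSeq(3000, 136))
  noTandemReads <- simulateReads(paste0(substring(tandem, 1, 3000),
                                        substring(tandem, 4201)),
                                 150, 10, 0, seed = 137)
  tilesT <- tileReference(tandem, buildKmerIndex(noTandemReads))
  candT <- findMissingIntervals(tilesT, 500)
  run <- tilesT[!tilesT$present & tilesT$start > 3000 &
                tilesT$start < 4200, ]
  expect_gt(mean(run$repetitive), 0.5)
  expect_identical(nrow(candT), 0L)
})

test_that("breakpoints resolve exactly with a leftmost convention", {
  set.seed(141)
  tmpl <- randomSeq(30000)
  del <- data.frame(start = 15001, end = 17000)
  rds <- simulateReads(tmpl, 150, 10, 0, seed = 142, deletions = del)
  idx <- buildKmerIndex(rds)
  tiles <- tileReference(tmpl, idx)
  cand <- findMissingIntervals(tiles)
  res <- resolveBreakpoints(cand[1, ], idx, tmpl, tiles)
  expect_identical(res$outcome, "deletion")
  ## leftmost placement of the implanted interval
  s <- del$start
  e <- del$end
  while (s > 1 && substring(tmpl, s - 1, s - 1) ==
         substring(tmpl, e, e)) { s <- s - 1; e <- e - 1 }
  expect_identical(res$resolvedStart, as.integer(s))
  expect_identical(res$resolvedEnd, as.integer(e))
  ## engineered micro-homology: deletion placed leftmost
  base <- randomSeq(20000, seed = 143)
  hom <- substring(base, 8001, 8006)
  tmpl2 <- paste0(substring(base, 1, 9000), hom,
                  substring(base, 9007, 20000))
  del2 <- data.frame(start = 8007, end = 9006)  # leaves hom on both sides
  rds2 <- simulateReads(tmpl2, 150, 10, 0, seed = 144, deletions = del2)
  idx2 <- buildKmerIndex(rds2)
  tiles2 <- tileReference(tmpl2, idx2)
  cand2 <- findMissingIntervals(tiles2)
  expect_identical(nrow(cand2), 1L)
  res2 <- resolveBreakpoints(cand2[1, ], idx2, tmpl2, tiles2)
  expect_identical(res2$outcome, "deletion")
  s2 <- del2$start; e2 <- del2$end
  while (s2 > 1 && substring(tmpl2, s2 - 1, s2 - 1) ==
         substring(tmpl2, e2, e2)) { s2 <- s2 - 1; e2 <- e2 - 1 }
  expect_identical(res2$resolvedStart, as.integer(s2))
  expect_identical(res2$resolvedEnd, as.integer(e2))
})

test_that("a single substitution adjudicates as a closed polymorphism", {
  ref <- randomSeq(8000, seed = 151)
  mut <- ref
  old <- substring(ref, 4000, 4000)
  substr(mut, 4000, 4000) <- setdiff(c("A", "C", "G", "T"), old)[1]
  rds <- simulateReads(mut, 150, 12, 0, seed = 152)
  idx <- buildKmerIndex(rds)
  tiles <- tileReference(ref, idx)
  cand <- findMissingIntervals(tiles, 0)   # SNV gap is < 500 bp
  hit <- cand[cand$tileStart < 4000 & cand$tileEnd > 3910, ]
  expect_identical(nrow(hit), 1L)
  res <- resolveBreakpoints(hit[1, ], idx, ref, tiles)
  expect_identical(res$outcome, "closed_polymorphism")
})

test_that("calls are classified for zygosity, uniqueness and haplotype", {
  set.seed(161)
  tmpl <- randomSeq(30000)
  del <- data.frame(start = 12001, end = 14000)
  rds <- simulateReads(tmpl, 150, 10, 0, seed = 162, deletions = del)
  idx <- buildKmerIndex(rds)
  mosaic <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 30000))
  S4Vectors::mcols(mosaic)$founder1 <- "PWK/PhJ"
  S4Vectors::mcols(mosaic)$founder2 <- "PWK/PhJ"
  ## comparison strain carrying the same deletion, and one intact
  cmpDel <- buildKmerIndex(simulateReads(tmpl, 150, 10, 0, seed = 163,
                                         deletions = del))
  cmpInt <- buildKmerIndex(simulateReads(tmpl, 150, 10, 0, seed = 164))
  calls <- scanDeletions(tmpl, idx, comparisonIndices = list(o = cmpInt),
                         mosaic = mosaic)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$zygosity, "homozygous")
  expect_true(calls$uniqueToStrain)
  expect_identical(calls$haplotype, "PWK/PhJ")
  ## spanning reads within Poisson noise of depth
  expect_gt(calls$spanningReads, 10 - 3 * sqrt(10))
  expect_lt(calls$spanningReads, 10 + 4 * sqrt(10))
  ## same deletion present in the comparison strain: not unique
  calls2 <- scanDeletions(tmpl, idx,
                          comparisonIndices = list(o = cmpDel))
  expect_false(calls2$uniqueToStrain)
  ## heterozygous mixture: interior tiles present, call suppressed
  half <- c(as.character(simulateReads(tmpl, 150, 10, 0, seed = 165,
                                       deletions = del)),
            as.character(simulateReads(tmpl, 150, 10, 0, seed = 166)))
  idxHet <- buildKmerIndex(half)
  tilesHet <- tileReference(tmpl, idxHet)
  interior <- tilesHet$start >= 12001 & tilesHet$start <= 13956
  expect_true(mean(tilesHet$present[interior]) > 0.9)
  candHet <- findMissingIntervals(tilesHet)
  expect_identical(nrow(candHet), 0L)
  ## zygosity check on an externally supplied candidate interval
  fakeCand <- data.frame(tileStart = 12001, tileEnd = 13951)
  fakeRes <- list(junctionKmer = NA_character_, resolvedStart = NA,
                  resolvedEnd = NA)
  cc <- classifyCall(fakeCand, fakeRes, tilesHet, idxHet, tmpl)
  expect_identical(cc$zygosity, "ambiguous")
})

test_that("no deletions are called on intact error-free data", {
  tmpl <- randomSeq(40000, seed = 171)
  rds <- simulateReads(tmpl, 150, 10, 0, seed = 172)
  calls <- scanDeletions(tmpl, buildKmerIndex(rds))
  expect_identical(nrow(calls), 0L)
})

test_that("deletion size bookkeeping matches the tile-coordinate rule", {
  expect_equal(deletionSizeKb(102931561, 102947356), 15.795)
  expect_equal(deletionSizeKb(11600371, 11620171), 19.8)
  expect_equal(deletionSizeKb(129264616, 129265201), 0.585)
  expect_equal(deletionSizeKb(56858446, 56862406), 3.96)
})
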