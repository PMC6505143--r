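## Fixture: founder genotype tables with controllable violations.
founderCallsFixture <- function(alleles, reps = 1L) {
  n <- nrow(alleles)
  founders <- ccFounders()
  cols <- list()
  for (f in unname(founders)) for (r in seq_len(reps))
    cols[[paste0(f, "_r", r)]] <- alleles[, f]
  calls <- do.call(cbind, cols)
  founderOf <- setNames(rep(unname(founders), each = reps),
                        colnames(calls))
  list(calls = calls, founderOf = founderOf)
}

test_that("marker filters retain exactly the clean markers", {
  founders <- unname(ccFounders())
  alleles <- matrix("A", 6, 8, dimnames = list(NULL, founders))
  alleles[1, 5:8] <- "G"      # clean biallelic informative
  alleles[2, 2] <- "G"        # clean
  alleles[3, 2] <- "G"; alleles[3, 3] <- "T"   # three alleles
  alleles[4, ] <- "A"         # monomorphic (uninformative)
  alleles[5, 4:8] <- "T"      # clean, will get an H replicate
  alleles[6, 1:3] <- "C"      # clean, will fail F1 prediction
  fx <- founderCallsFixture(alleles, reps = 2L)
  fx$calls[5, "NOD/ShiLtJ_r2"] <- "H"
  mk <- markerFixture(seq_len(6) * 100)
  fg <- CCGenotypes(fx$calls, mk)
  ## one F1: A/J x CAST/EiJ
  f1calls <- ifelse(alleles[, "A/J"] == alleles[, "CAST/EiJ"],
                    alleles[, "A/J"], "H")
  f1calls[6] <- "T"   # contradicts founder prediction
  f1 <- CCGenotypes(matrix(f1calls, ncol = 1,
                           dimnames = list(NULL, "f1a")), mk)
  sel <- selectInformativeMarkers(fg, fx$founderOf, f1,
                                  list(f1a = c("A/J", "CAST/EiJ")))
  expect_identical(which(sel$keep), c(1L, 2L))
  expect_identical(sum(sel$dropCounts), 4L)
  expect_identical(unname(sel$dropCounts[c("hn", "biallelic",
                                           "informative", "f1")]),
                   c(1L, 1L, 1L, 1L))
  ## a panel with a planted fraction of violating markers
  p <- simulateFounderPanel(1, 1e5, 100, seed = 77, withSequences = FALSE)
  al <- p@markerAlleles
  bad <- sample(100, 20)
  al[bad[1:10], 1] <- "N"
  for (i in bad[11:20]) {
    third <- setdiff(c("A", "C", "G", "T"), al[i, ])[1]
    al[i, 8] <- third
  }
  colnames(al) <- founders
  fx2 <- founderCallsFixture(al)
  sel2 <- selectInformativeMarkers(
    CCGenotypes(fx2$calls, p@markers), fx2$founderOf)
  expect_identical(sum(sel2$keep), 80L)
})

test_that("trio evidence follows the H-or-discordance rule", {
  expect_false(trioMarkerEvidence(c("A", "A", "A")))
  expect_true(trioMarkerEvidence(c("A", "H", "A")))
  expect_true(trioMarkerEvidence(c("A", "A", "G")))
  expect_false(trioMarkerEvidence(c("A", "N", "A")))
  expect_true(is.na(trioMarkerEvidence(c("N", "N", "N"))))
  expect_error(trioMarkerEvidence(c("A", "A")), "3 calls")
  ## vectorized form agrees with the scalar definition
  set.seed(3)
  m <- matrix(sample(c("A", "G", "H", "N"), 300, replace = TRUE,
                     prob = c(.4, .3, .15, .15)), ncol = 3)
  expect_identical(ccmosaic:::.trioEvidence(m),
                   apply(m, 1, trioMarkerEvidence))
})

test_that("evidence clusters follow the stated span rules", {
  mk <- markerFixture(c(10, 20, 30, 40, 50))
  cl <- clusterEvidence(c(FALSE, TRUE, TRUE, TRUE, FALSE), mk)
  expect_identical(nrow(cl), 1L)
  expect_equal(cl$start, 20)
  expect_equal(cl$end, 40)
  expect_equal(cl$spanBp, 21)
  ## no flags: no clusters
  expect_identical(nrow(clusterEvidence(rep(FALSE, 5), mk)), 0L)
  ## two runs separated by one unflagged assayed marker: two clusters
  cl2 <- clusterEvidence(c(TRUE, TRUE, FALSE, TRUE, TRUE), mk)
  expect_identical(nrow(cl2), 2L)
  ## singleton span is the rounded mean spacing
  cl3 <- clusterEvidence(c(FALSE, FALSE, TRUE, FALSE, FALSE), mk)
  expect_equal(cl3$spanBp, 10)
  ## an NA (all-N) marker neither flags nor breaks a run
  cl4 <- clusterEvidence(c(TRUE, TRUE, NA, TRUE, FALSE), mk)
  expect_identical(nrow(cl4), 1L)
  expect_equal(cl4$end, 40)
})

test_that("pair-consistent clusters combine across silent markers", {
  ## founders A,B differ at markers 1,2,4,5 but share the allele at 3:
  ## inside an A/B het segment marker 3 is silent and must not split it
  founders <- unname(ccFounders())
  al <- matrix("A", 5, 8, dimnames = list(NULL, founders))
  al[c(1, 2, 4, 5), 1] <- "G"     # A/J carries G, separates A/J vs rest
  al[3, 5:8] <- "T"               # silent for the A/J-C57BL/6J pair
  mk <- markerFixture(c(100, 200, 300, 400, 500))
  flags <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  cl <- clusterEvidence(flags, mk)
  expect_identical(nrow(cl), 2L)
  cmb <- combineClusters(cl, flags, mk, al)
  expect_identical(nrow(cmb), 1L)
  expect_equal(cmb$spanBp, 401)
  ## no founder pair explains flags interrupted by a marker that
  ## separates every pair the flagged markers support
  al2 <- al
  al2[3, ] <- al[1, ]   # marker 3 now also separates A/J from the rest
  cmb2 <- combineClusters(cl, flags, mk, al2)
  expect_identical(nrow(cmb2), 2L)
})

test_that("the het-fraction estimator is exact on inbred strains and tracks simulated truth", {
  p <- simulateFounderPanel(1, 1e5, 2000, seed = 13,
                            withSequences = FALSE)
  gIn <- simulateCCStrain(p, ccPedigree(1:8, 60, seed = 5))
  stopifnot(realizedHetFraction(gIn) == 0)
  calls <- emitArrayGenotypes(gIn, p)
  est <- estimateHetFraction(cbind(calls, calls, calls), p@markers,
                             p@markerAlleles)
  expect_equal(est$fraction, 0)
  ## a partially inbred strain: estimate within 0.03 of realized truth
  gHet <- simulateCCStrain(p, ccPedigree(sample(8), 8, seed = 6))
  ch <- emitArrayGenotypes(gHet, p)
  estH <- estimateHetFraction(cbind(ch, ch, ch), p@markers,
                              p@markerAlleles)
  expect_lt(abs(estH$fraction - realizedHetFraction(gHet)), 0.03)
  expect_error(estimateHetFraction(matrix(character(), 0, 3),
                                   markerFixture(integer())),
               "undefined")
})

test_that("adding an H call never decreases the estimated fraction", {
  p <- simulateFounderPanel(1, 1e5, 400, seed = 23, withSequences = FALSE)
  g <- simulateCCStrain(p, ccPedigree(sample(8), 6, seed = 7))
  calls <- emitArrayGenotypes(g, p)
  trio <- cbind(calls, calls, calls)
  ## monotonicity is a property of the run-clustering estimator; the
  ## pair-consistency combining step may legitimately retract a merge
  ## when new evidence contradicts the segregating pair
  base <- estimateHetFraction(trio, p@markers)$fraction
  set.seed(8)
  for (i in sample(which(calls != "H"), 10)) {
    trio2 <- trio
    trio2[i, 2] <- "H"
    f2 <- estimateHetFraction(trio2, p@markers)$fraction
    expect_gte(f2, base)
  }
})

test_that("concordance is symmetric, N-aware, and matches arithmetic", {
  a <- c("A", "G", "T", "C", "A")
  expect_equal(concordance(a, a), 1)
  expect_equal(concordance(a, c("G", "A", "C", "T", "G")), 0)
  b <- c("A", "G", "N", "T", "A")
  d <- c("A", "C", "T", "N", "A")
  expect_equal(concordance(b, d), concordance(d, b))
  expect_equal(concordance(c(rep("A", 5), rep("G", 5)),
                           c(rep("A", 5), rep("T", 5))), 0.5)
  expect_error(concordance(c("N", "N"), c("A", "N")), "undefined")
})

test_that("samples match their strain of origin by concordance", {
  p <- simulateFounderPanel(1, 1e5, 500, seed = 33, withSequences = FALSE)
  panelCalls <- vapply(1:6, function(s)
    emitArrayGenotypes(simulateCCStrain(
      p, ccPedigree(sample(8), 20, seed = s)), p),
    character(500))
  colnames(panelCalls) <- paste0("CC", 1:6)
  set.seed(44)
  for (trial in 1:20) {
    s <- sample(6, 1)
    noisy <- panelCalls[, s]
    flip <- runif(500) < 0.01
    noisy[flip] <- sample(c("A", "C", "G", "T"), sum(flip),
                          replace = TRUE)
    m <- matchSampleToStrain(noisy, panelCalls)
    expect_identical(m$best, paste0("CC", s))
    expect_false(m$lowConfidence)
  }
  ## ties reported, not silently resolved
  twin <- panelCalls[, c(1, 1)]
  colnames(twin) <- c("CCa", "CCb")
  mt <- matchSampleToStrain(panelCalls[, 1], twin)
  expect_setequal(mt$best, c("CCa", "CCb"))
  ## an unrelated random genome is flagged
  rand <- sample(c("A", "C", "G", "T"), 500, replace = TRUE)
  mr <- matchSampleToStrain(rand, panelCalls)
  expect_true(mr$lowConfidence)
  expect_error(matchSampleToStrain(rand, panelCalls[, 0]), "empty")
})

test_that("summary of strain heterozygosity percentages is the mean", {
  s <- summarizeHetEstimates(c(10, 20, 60))
  expect_equal(s$mean, 30)
  expect_equal(s$n, 3)
  expect_error(summarizeHetEstimates(numeric()), "no estimates")
})
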