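#' The eight Collaborative Cross founder strains
#'
#' Returns the CC founder strain names in canonical order, named by their
#' conventional one-letter codes (A = A/J through H = WSB/EiJ).
#'
#' @return A named character vector of length 8.
#' @examples
#' ccFounders()
#' @export
ccFounders <- function() {
  c(A = "A/J", B = "C57BL/6J", C = "129S1/SvImJ", D = "NOD/ShiLtJ",
    E = "NZO/HlLtJ", F = "CAST/EiJ", G = "PWK/PhJ", H = "WSB/EiJ")
}

#' Wild-derived CC founders
#'
#' The three wild-derived founder strains. With `domesticusExcluded = TRUE`
#' only the two founders of non-domesticus subspecific origin (CAST/EiJ and
#' PWK/PhJ) are returned.
#'
#' @param domesticusExcluded Drop WSB/EiJ (a domesticus wild-derived strain)?
#' @return Character vector of founder names.
#' @export
ccWildFounders <- function(domesticusExcluded = FALSE) {
  w <- c("CAST/EiJ", "PWK/PhJ", "WSB/EiJ")
  if (domesticusExcluded) w[1:2] else w
}

#' Canonical diplotype state space
#'
#' The unordered founder-pair states used for haplotype reconstruction:
#' the inbred (homozygous) states first, then all heterozygous founder pairs
#' in lexicographic order. With 8 founders this is the standard 36-state
#' space (8 inbred + 28 pairs).
#'
#' @param founders Character vector of founder codes (default the 8 CC
#'   founder letter codes). Reduced spaces are supported for testing.
#' @return Character vector of state codes, each the concatenation of two
#'   founder codes with the first not after the second.
#' @examples
#' length(diplotypeStates())  # 36
#' diplotypeStates(c("A", "B", "C"))
#' @export
diplotypeStates <- function(founders = names(ccFounders())) {
  n <- length(founders)
  inbred <- paste0(founders, founders)
  if (n < 2L) return(inbred)
  pr <- utils::combn(founders, 2L)
  c(inbred, paste0(pr[1L, ], pr[2L, ]))
}

## Integer founder indices (i1 <= i2) for each state of an n-founder space.
.statePairs <- function(nFounders = 8L) {
  i1 <- seq_len(nFounders)
  pairs <- cbind(i1, i1)
  if (nFounders >= 2L) {
    cmb <- utils::combn(nFounders, 2L)
    pairs <- rbind(pairs, t(cmb))
  }
  dimnames(pairs) <- NULL
  pairs
}

## Map an unordered founder pair (i, j) to its state index.
.stateIndexOf <- function(i, j, nFounders = 8L) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  ifelse(lo == hi, lo,
         nFounders + (lo - 1L) * nFounders - lo * (lo - 1L) / 2 + (hi - lo))
}

.isHetState <- function(nFounders = 8L) {
  p <- .statePairs(nFounders)
  p[, 1L] != p[, 2L]
}

## Closed call vocabulary for genotype matrices.
.CALL_LEVELS <- c("A", "C", "G", "T", "H", "N")
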