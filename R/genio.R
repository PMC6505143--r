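## Readers/writers for the external formats the pipeline touches.
## Internal coordinates are 1-based inclusive; BED output is 0-based
## half-open. CSV is comma-separated UTF-8; N (never ".") marks missing.

#' Read a genotype CSV into a CCGenotypes object
#'
#' Expects columns `marker`, `chromosome`, `position`, then one column per
#' sample with calls from the closed vocabulary A/C/G/T/H/N. Duplicate
#' marker ids are an error; unsorted positions are sorted with a warning.
#'
#' @param path Path to a CSV file.
#' @return A [CCGenotypes-class] object.
#' @export
readGenotypeCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  need <- c("marker", "chromosome", "position")
  if (!all(need %in% names(df)))
    stop("genotype CSV must have columns marker, chromosome, position")
  if (anyDuplicated(df$marker))
    stop("duplicate marker id: ",
         df$marker[duplicated(df$marker)][1L])
  pos <- as.integer(df$position)
  sampleCols <- setdiff(names(df), need)
  if (!length(sampleCols)) stop("genotype CSV has no sample columns")
  o <- order(df$chromosome, pos)
  if (!identical(o, seq_len(nrow(df)))) {
    warning("marker positions not sorted within chromosome; sorting")
    df <- df[o, , drop = FALSE]
    pos <- pos[o]
  }
  calls <- as.matrix(df[, sampleCols, drop = FALSE])
  rownames(calls) <- NULL
  bad <- which(!(calls %in% .CALL_LEVELS))
  if (length(bad)) {
    i <- (bad[1L] - 1L) %% nrow(calls) + 1L
    j <- (bad[1L] - 1L) %/% nrow(calls) + 1L
    stop(sprintf("invalid call token '%s' at marker %s, sample %s",
                 calls[bad[1L]], df$marker[i], sampleCols[j]))
  }
  markers <- GenomicRanges::GRanges(df$chromosome,
                                    IRanges::IRanges(pos, pos))
  S4Vectors::mcols(markers)$markerId <- df$marker
  CCGenotypes(calls, markers)
}

#' Write a CCGenotypes object to CSV
#'
#' @param x A [CCGenotypes-class] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGenotypeCsv <- function(x, path) {
  mk <- markerMap(x)
  df <- data.frame(marker = S4Vectors::mcols(mk)$markerId,
                   chromosome = as.character(GenomicRanges::seqnames(mk)),
                   position = GenomicRanges::start(mk),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(genotypeCalls(x), optional = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a state probability track to CSV
#'
#' Columns: `marker`, `chromosome`, `position`, then one column per state
#' in canonical order (8 inbred then 28 pairs). Values round-trip through
#' [readProbabilityTrack()] to within 1e-12.
#'
#' @param track A [StateProbTrack-class] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeProbabilityTrack <- function(track, path) {
  mk <- track@markers
  o <- order(as.character(GenomicRanges::seqnames(mk)),
             GenomicRanges::start(mk))
  probs <- track@probs[o, , drop = FALSE]
  header <- c("marker", "chromosome", "position", track@states)
  lines <- vapply(seq_len(nrow(probs)), function(i) {
    paste(c(S4Vectors::mcols(mk)$markerId[o[i]],
            as.character(GenomicRanges::seqnames(mk))[o[i]],
            GenomicRanges::start(mk)[o[i]],
            sprintf("%.17g", probs[i, ])), collapse = ",")
  }, "")
  writeLines(c(paste(header, collapse = ","), lines), path)
  invisible(path)
}

#' Read a state probability track from CSV
#'
#' Rows whose probabilities do not sum to 1 within 1e-6 are rejected.
#'
#' @param path Path written by [writeProbabilityTrack()].
#' @param sampleId Sample id to attach.
#' @param chromKind Chromosome kind of the track.
#' @return A [StateProbTrack-class] object.
#' @export
readProbabilityTrack <- function(path, sampleId = "sample",
                                 chromKind = "autosome") {
  df <- utils::read.csv(path, check.names = FALSE)
  stateCols <- setdiff(names(df), c("marker", "chromosome", "position"))
  probs <- as.matrix(df[, stateCols, drop = FALSE])
  s <- rowSums(probs)
  if (any(abs(s - 1) > 1e-6))
    stop("probability row(s) not summing to 1 within 1e-6 (first: marker ",
         df$marker[which.max(abs(s - 1))], ")")
  probs <- probs / s
  markers <- GenomicRanges::GRanges(df$chromosome,
                                    IRanges::IRanges(df$position,
                                                     df$position))
  S4Vectors::mcols(markers)$markerId <- df$marker
  StateProbTrack(probs, markers, states = stateCols, sampleId = sampleId,
                 chromKind = chromKind)
}

#' Write intervals as a BED file
#'
#' Converts 1-based inclusive internal intervals to the 0-based half-open
#' BED convention. Overlapping intervals are preserved as given (no
#' merging); an empty input produces a file with only the header comment.
#'
#' @param intervals A `GRanges` (names or `name` metadata column used for
#'   the BED name field) or a `data.frame(chromosome, start, end, name)`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(intervals, path) {
  if (is(intervals, "GRanges")) {
    nm <- S4Vectors::mcols(intervals)$name
    if (is.null(nm)) nm <- names(intervals)
    if (is.null(nm)) nm <- rep(".", length(intervals))
    df <- data.frame(chromosome = as.character(
                       GenomicRanges::seqnames(intervals)),
                     start = GenomicRanges::start(intervals),
                     end = GenomicRanges::end(intervals),
                     name = nm)
  } else df <- intervals
  if (nrow(df) && any(df$end < df$start))
    stop("interval end before start")
  lines <- "#chrom\tstart\tend\tname"
  if (nrow(df))
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", df$chromosome,
                              as.integer(df$start) - 1L,
                              as.integer(df$end),
                              if (is.null(df$name)) "." else df$name))
  writeLines(lines, path)
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFastaFile <- function(sequences, path) {
  if (!is(sequences, "XStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' Write reads as FASTQ with dummy qualities
#'
#' @param reads Character vector or `DNAStringSet` of reads.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFastqFile <- function(reads, path) {
  reads <- as.character(reads)
  ids <- sprintf("@read%d", seq_along(reads))
  qual <- vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), "")
  writeLines(as.vector(rbind(ids, reads, "+", qual)), path)
  invisible(path)
}

#' Read a FASTQ file as a DNAStringSet
#'
#' @param path FASTQ path (uncompressed).
#' @return `DNAStringSet` of reads.
#' @export
readFastqFile <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}
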