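## Published characterization tables for the six newly released CC
## strains (CC078-CC083), shipped as plain-text CSVs. These carry the
## reported per-strain residual-heterozygosity percentages, founder
## haplotype frequencies, and de novo deletion coordinates, and serve as
## reference inputs for summary routines and bookkeeping checks.

.ccExtdata <- function(file) {
  utils::read.csv(system.file("extdata", file, package = "ccmosaic",
                              mustWork = TRUE),
                  check.names = FALSE)
}

#' Published residual heterozygosity of the six new CC strains
#'
#' Reported percent residual heterozygosity for strains CC078-CC083 in
#' the MRCAs, the sequenced sample, and the three MiniMUGA-genotyped mice.
#'
#' @return `data.frame` with columns `strain`, `mrca_het_pct`,
#'   `sequenced_het_pct`, `minimuga_het_pct`.
#' @export
ccNewStrainHet <- function() .ccExtdata("cc_new_strain_heterozygosity.csv")

#' Published founder haplotype frequencies of the six new CC strains
#'
#' @return `data.frame` with one row per strain and one column per
#'   founder.
#' @export
ccNewStrainFounderFreq <- function() {
  .ccExtdata("cc_new_strain_founder_freq.csv")
}

#' Published de novo deletions in the six new CC strains
#'
#' Reported strain-private homozygous deletions with 45-mer tile
#' coordinates, resolved breakpoints, sizes and haplotype labels.
#'
#' @return `data.frame` of deletion records.
#' @export
ccNewStrainDeletions <- function() {
  .ccExtdata("cc_new_strain_deletions.csv")
}
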