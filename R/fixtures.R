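# Published date-palm chloroplast reference tables shipped as plain-text
# fixtures: codon usage counts, the coding-region intravarietal SNP list,
# the psaB small-inversion alignment across monocots, and the per-tissue
# expression matrix. These are inputs for desk-scale recomputation (RSCU,
# genotype arithmetic, SI geometry), not package outputs.

fixture_path <- function(name)
  system.file("extdata", name, package = "plastidkit", mustWork = TRUE)

#' Date-palm chloroplast codon usage counts
#'
#' @return A list: `table` (a [codon_table()] of the published counts,
#'   total 22,950) and `data` (the raw data frame, incl. the printed RSCU
#'   values and matched tRNA anticodons).
#' @export
datepalm_codon_usage <- function() {
  d <- utils::read.table(fixture_path("datepalm_codon_usage.tsv"),
                         sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                         fill = TRUE, quote = "")
  list(table = codon_table(stats::setNames(d$count, d$codon)), data = d)
}

#' Date-palm coding-region intravarietal SNP table
#'
#' All 62 published coding-region heteroplasmic SNP records: major/minor
#' genotypes, read counts, percentages, codon effect, strand, CDS and
#' genome positions, and whether the minor genotype is the oil-palm major
#' (or vice versa). One record (a second SNP in the same codon) has no
#' separate counts and carries NA.
#'
#' @return Data frame.
#' @export
datepalm_intrasnps <- function() {
  utils::read.table(fixture_path("datepalm_intrasnps_cds.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE, quote = "",
                    na.strings = "NA")
}

#' The psaB small-inversion alignment across monocots
#'
#' The published 63-nt stem-loop region of the date-palm (Phoenix) psaB
#' gene and its aligned counterparts in 25 other taxa, with the reported
#' folding free energies.
#'
#' @return Data frame (`taxon`, `coord_start`, `coord_end`, `sequence`,
#'   `free_energy`).
#' @export
datepalm_si_alignment <- function() {
  utils::read.table(fixture_path("datepalm_psaB_si.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE, quote = "")
}

#' Date-palm per-tissue chloroplast expression matrix
#'
#' Published leaf/root/bud read counts and gene coverage percentages in
#' `reads(coverage)` format, parsed by [read_expression_tsv()].
#'
#' @param raw Return the unparsed table (for I/O round-trip checks).
#' @return Data frame.
#' @export
datepalm_expression <- function(raw = FALSE) {
  path <- fixture_path("datepalm_expression.tsv")
  if (raw)
    return(utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, quote = "",
                             check.names = FALSE))
  read_expression_tsv(path)
}
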