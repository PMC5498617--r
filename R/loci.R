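# Built-in locus reconstructions.
#
# The diagnostic cores (the published 30 bp probe words and the deleted
# segments they span) are genuine; the outer flanks are SYNTHETIC padding so
# that simulated reads can start on either side of the junction. These are
# therefore local stand-ins for the real Rc/LABA1 gene regions, adequate for
# probe design, read simulation and alignment-based verification, but not for
# any genome-coordinate work beyond the causative position itself.

.RC_FLANK_L <- "AACCCTGGCCATCGTGTCGGCTGAGGTCCGTTAATTACGGTGCTGCCAGAGCTCTAGAACGCAGGAAATCGAGCTGGCCAGCCACCATTAAACTCGCTCCGGCACCGTTG"
.RC_FLANK_R <- "TCACTGAATCCTATGGTACAATCTCGCACGTTAGACTGGTTGCGATCCCATGAGCAACGCTCCAACATCAGAAGATTTGAACAGTTTACAGAGAACTGGTCATAAGAATA"
.LA_FLANK_L <- "CGGCTTAAAGCCCAGCTGCCCAATTCCAGACCTTCGATAGTTTGGATTTGCTAGGTTTCTTCGGGTTATATCCATTGAAAAACTACCAAAAGCTTACCAACGTCCCGAGC"
.LA_FLANK_R <- "GTCAACTGGCAATCCACGTCACGATGTTACGGATTGTACTGAGATGGCGTCTACCAACGTGGTGACCCCTCCCTGAAAGATGGACGGTCACCTAGTCGTATGAATACCAA"

#' Built-in Rc and LABA1 locus reconstructions
#'
#' Local allele references for the two causative indels screened by this
#' package: the 14 bp deletion in the *Rc* coding sequence (white vs red
#' pericarp) and the 1 bp deletion in the *LABA1* coding sequence (barbless
#' awns). The 30 bp core around each junction carries the published
#' diagnostic words; the outer flanks are synthetic padding (see source), so
#' treat these as reconstructions suitable for simulation and testing, not as
#' genome sequence.
#'
#' @return Named list of [locus] objects (`rc`, `laba1`).
#' @examples
#' rice_loci()$rc$indel_length # 14
#' @export
rice_loci <- function() {
  rc_left <- paste0(.RC_FLANK_L, "AAAGGCGCAAGTGGA")
  rc_del <- "ACGCGAAAAGTCGG" # the 14 bp segment absent from the rc allele
  rc_right <- paste0("TGCCATCCAAGGTGA", .RC_FLANK_R)
  la_left <- paste0(.LA_FLANK_L, "AGCCATGGCTCTACTC")
  la_right <- paste0("AGTCTCGGTTCAGG", .LA_FLANK_R)
  list(
    rc = locus("Rc", "7", 6069568,
               ref_allele_seq = paste0(rc_left, rc_del, rc_right),
               alt_allele_seq = paste0(rc_left, rc_right)),
    laba1 = locus("LABA1", "4", 28686384,
                  ref_allele_seq = paste0(la_left, "C", la_right),
                  alt_allele_seq = paste0(la_left, la_right)))
}

#' Probe sets reproducing the published diagnostic 30-mers
#'
#' Designs the four exact-match words per locus from [rice_loci()]. The Rc
#' words fall out of the default (site-centred) placement; the LABA1 words
#' need an explicit left flank of 16 bases on both alleles, which is how the
#' published pair is offset.
#'
#' @return Named list of `probe_set` objects (`rc`, `laba1`).
#' @export
rice_probe_sets <- function() {
  loci <- rice_loci()
  list(
    rc = design_probes(loci$rc),
    laba1 = design_probes(loci$laba1, left_flank_ref = 16, left_flank_alt = 16))
}
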