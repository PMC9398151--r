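#' Example patient panel (synthetic sequences)
#'
#' A structurally valid 5-plex panel for examples and tests: one
#' tumor-specific assay carrying a 4-bp KIT exon 11 deletion plus four
#' resistance assays (KIT exons 13, 14, 17 and PDGFRA exon 18), each
#' with one resistance SNV, and a spike-in control on PDGFRA_18. The
#' amplicon sequences are synthetic (randomly generated, fixed), not
#' clinical primer designs; lengths span 68--90 bp within the 65--99 bp
#' design constraint. The same panel ships as
#' `system.file("extdata", "panel_example.yaml", package = "umivar")`.
#'
#' @return a [patient_panel()].
#' @examples
#' p <- example_panel()
#' p
#' @export
example_panel <- function() {
  amps <- c(
    KIT_11    = "CCCTCGGATTCCAGACGGCAGATAAACGACTGGAACCTTTCGGGGGAAGAGTACTTCCCTGTGACCGGTTTAAGTCTTTG",
    KIT_13    = "CCTAATTTAGCCAAGGACAATCGGTGCGCACTTTCTGATGGACCTCCGGCTCCTAACACTAGAATAAGTATG",
    KIT_14    = "CGCTCCACACCTGAAGGGACGCGGGTACTACTGTACTTTCTTCTAGGGTGTTTTCGGTCCGGCTGAAG",
    KIT_17    = "TATGGCTCGCGACGTGGATCTAAAGACAATAGACCGATCTTTAAGGTGCTTCCGTTAGCCTAGTAGGGGCTGGTGAAGGGTCCGGCGCGC",
    PDGFRA_18 = "TGGCTATGATCAGCAAACTTTTCACTGTACAGTGCTAGTGTTAAATGCATCGTGAATAATTTCGGTAGCACCTCCAGTCCTGTA"
  )
  exons <- c(KIT_11 = "11", KIT_13 = "13", KIT_14 = "14", KIT_17 = "17",
             PDGFRA_18 = "18")
  genes <- c(KIT_11 = "KIT", KIT_13 = "KIT", KIT_14 = "KIT",
             KIT_17 = "KIT", PDGFRA_18 = "PDGFRA")
  assays <- lapply(names(amps), function(id) {
    s <- amps[[id]]
    assay(id, genes[[id]], exons[[id]], s,
          fwd_primer = substr(s, 1L, 18L),
          rev_primer = substr(s, nchar(s) - 17L, nchar(s)),
          target_window = c(18L, nchar(s) - 18L))
  })
  variants <- list(
    target_variant("KIT_11", 34L, "ACCT", "", "tumor_specific",
                   amplicon_seq = amps[["KIT_11"]]),
    target_variant("KIT_13", 36L, "G", "A", "resistance",
                   amplicon_seq = amps[["KIT_13"]]),
    target_variant("KIT_14", 34L, "A", "T", "resistance",
                   amplicon_seq = amps[["KIT_14"]]),
    target_variant("KIT_17", 45L, "G", "T", "resistance",
                   amplicon_seq = amps[["KIT_17"]]),
    target_variant("PDGFRA_18", 42L, "A", "T", "resistance",
                   amplicon_seq = amps[["PDGFRA_18"]])
  )
  patient_panel("P01", assays, variants,
                spikeins = c(PDGFRA_18 = 50L))
}
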