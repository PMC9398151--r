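#' Write a sample's calls as minimal VCF 4.2
#'
#' Amplicon-relative coordinates: `CHROM` is the assay id, `POS` is
#' 1-based. Indels use the standard VCF anchor-base padding (left
#' anchor; right anchor when the event touches position 0). INFO fields
#' `NMUT`, `NTOT`, `MAF` (percent) and `STATUS` carry the call
#' evidence. All non-absent calls are emitted, so provisional
#' observations remain inspectable.
#'
#' @param result a [call_sample()] result.
#' @param panel the [patient_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(result, panel, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=umivar",
    sprintf("##umivar_sample=%s", result$sample_id),
    sprintf("##umivar_patient=%s", result$patient_id),
    vapply(panel$assays, function(a)
      sprintf("##contig=<ID=%s,length=%d>", a$assay_id,
              nchar(a$amplicon_seq)), ""),
    "##INFO=<ID=NMUT,Number=1,Type=Integer,Description=\"Mutant consensus reads\">",
    "##INFO=<ID=NTOT,Number=1,Type=Integer,Description=\"Consensus reads covering the locus\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Mutant allele frequency, percent\">",
    "##INFO=<ID=STATUS,Number=1,Type=String,Description=\"Call status: called, rescued or provisional\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  calls <- result$calls[status != "absent"]
  recs <- character(0)
  for (i in seq_len(nrow(calls))) {
    v <- as.list(calls[i])
    amp <- panel$assays[[v$assay_id]]$amplicon_seq
    if (v$vclass == "SNV") {
      pos1 <- v$pos + 1L; ref <- v$ref; alt <- v$alt
    } else if (v$pos > 0L) {
      anchor <- substr(amp, v$pos, v$pos)     # base before the event
      pos1 <- v$pos                            # 1-based anchor position
      ref <- paste0(anchor, v$ref)
      alt <- paste0(anchor, v$alt)
    } else {                                   # event at position 0
      tail_pos <- nchar(v$ref) + 1L
      anchor <- substr(amp, tail_pos, tail_pos)
      pos1 <- 1L
      ref <- paste0(v$ref, anchor)
      alt <- paste0(v$alt, anchor)
    }
    recs <- c(recs, sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tNMUT=%d;NTOT=%d;MAF=%.6g;STATUS=%s",
      v$assay_id, pos1, ref, alt, v$n_mut, v$n_total, v$maf, v$status))
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
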