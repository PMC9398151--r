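#' Demultiplex UMI-prefixed reads onto panel assays
#'
#' Each read is laid out as `[UMI][forward primer][insert]`. The UMI is
#' the first `umi_length` bases; the assay is the unique primer with
#' minimal Hamming distance to the following bases, provided that
#' distance is at most `max_primer_mismatch`. Ties are unassigned with
#' reason `ambiguous_primer`; reads shorter than the layout minimum are
#' unassigned with reason `too_short`. Primer-anchored assignment
#' stands in for genome alignment: the panel's short closed amplicons
#' make the assay the only alignment decision.
#'
#' @param reads character vector of read sequences (named by read id).
#' @param panel a [patient_panel()].
#' @param umi_length UMI length (default 12).
#' @param max_primer_mismatch maximal primer Hamming distance
#'   (default 2).
#' @return `data.table` with one row per read: `read_id`, `umi`,
#'   `assay_id` (`NA` when unassigned), `insert` (read minus UMI),
#'   `n_primer_mismatches`, `reason` (`assigned`, `too_short`,
#'   `ambiguous_primer`, `no_primer_match`).
#' @export
demultiplex_reads <- function(reads, panel, umi_length = 12L,
                              max_primer_mismatch = 2L) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("r%07d", seq_along(reads))
  primers <- vapply(panel$assays, `[[`, "", "fwd_primer")
  minlen <- umi_length + min(nchar(primers))
  n <- length(reads)
  out <- data.table::data.table(
    read_id = ids,
    umi = substr(reads, 1L, umi_length),
    assay_id = NA_character_,
    insert = substr(reads, umi_length + 1L, nchar(reads)),
    n_primer_mismatches = NA_integer_,
    reason = "no_primer_match"
  )
  short <- nchar(reads) <= minlen
  out[short, reason := "too_short"]
  ok <- which(!short)
  if (length(ok)) {
    # fast path: exact primer prefix (unique by construction when
    # primers are mutually farther apart than 2 * max mismatches)
    asg <- cpp_assign_primer(out$insert[ok], unname(primers),
                             max_primer_mismatch)
    hit <- asg$index > 0L
    out[ok[hit], `:=`(assay_id = names(primers)[asg$index[hit]],
                      n_primer_mismatches = asg$mismatches[hit],
                      reason = "assigned")]
    amb <- asg$reason == 2L
    out[ok[amb], `:=`(reason = "ambiguous_primer",
                      n_primer_mismatches = asg$mismatches[amb])]
  }
  out[]
}

#' Group assigned reads into UMI families
#'
#' Families are the equivalence classes of exact string equality on
#' `(assay_id, UMI)`; no fuzzy UMI merging is performed, matching
#' grouping on *identical* molecular identifiers. Unassigned reads are
#' dropped (their count is retained for the conservation check).
#'
#' @param assigned output of [demultiplex_reads()].
#' @return object of class `umivar_families`: a `data.table` of
#'   assigned reads sorted by family key with columns `assay_id`,
#'   `umi`, `insert`, `fam` (family index); attributes `n_unassigned`
#'   and `sizes` (integer vector of family sizes, all families).
#' @export
group_families <- function(assigned) {
  fams <- assigned[reason == "assigned",
                   .(assay_id, umi, insert)]
  data.table::setorder(fams, assay_id, umi)
  fams[, fam := data.table::rleid(assay_id, umi)]
  sizes <- fams[, .N, by = fam]$N
  structure(fams,
            class = c("umivar_families", class(fams)),
            n_unassigned = sum(assigned$reason != "assigned"),
            sizes = sizes)
}

#' Mean reads per UMI family
#'
#' The undersequencing metric: the arithmetic mean family size over
#' *all* detected families, including those below the consensus
#' threshold.
#'
#' @param families a [group_families()] object or an integer vector of
#'   family sizes.
#' @return numeric mean family size.
#' @export
mean_family_size <- function(families) {
  sizes <- if (inherits(families, "umivar_families"))
    attr(families, "sizes") else families
  if (!length(sizes))
    stop("undefined metric: no UMI families detected")
  mean(sizes)
}

#' Build the consensus read of one UMI family
#'
#' Families below `min_reads` yield no consensus (`NULL`): a fixed
#' threshold of at least three reads per family is required before a
#' molecule is trusted. Otherwise each column takes the majority symbol
#' when its (unique) majority reaches `min_agreement` of the family
#' size, and `N` otherwise; 50/50 ties always yield `N`. Reads whose
#' length differs from the family's modal length are pairwise aligned
#' to a modal-length anchor before voting, so indel-errored reads vote
#' on the correct columns.
#'
#' @param reads character vector: the family's read inserts (UMI
#'   removed).
#' @param min_reads minimum family size (default 3).
#' @param min_agreement minimum majority fraction per column
#'   (default 0.9).
#' @return consensus sequence (possibly containing `N`), or `NULL` when
#'   the family is below `min_reads`.
#' @export
build_consensus <- function(reads, min_reads = 3L, min_agreement = 0.9) {
  stopifnot(length(reads) >= 1L)
  out <- cpp_consensus(reads, 1L, length(reads), min_reads, min_agreement)
  if (is.na(out[1])) NULL else out[1]
}

#' Build consensus reads for all families of a sample
#'
#' Vectorized version of [build_consensus()] over a
#' [group_families()] object; families are processed in key order so
#' output is independent of read input order.
#'
#' @param families a [group_families()] object.
#' @inheritParams build_consensus
#' @return `data.table` with one row per family of size >=
#'   `min_reads`: `assay_id`, `umi`, `family_size`, `consensus`.
#'   Attributes `n_families` (all families) and `sizes` are carried
#'   over.
#' @export
build_consensus_set <- function(families, min_reads = 3L,
                                min_agreement = 0.9) {
  idx <- families[, .(start = .I[1L], size = .N,
                      assay_id = assay_id[1L], umi = umi[1L]),
                  by = fam]
  cons <- cpp_consensus(families$insert, idx$start, idx$size,
                        as.integer(min_reads), min_agreement)
  out <- data.table::data.table(
    assay_id = idx$assay_id, umi = idx$umi,
    family_size = idx$size, consensus = cons
  )[!is.na(consensus)]
  data.table::setattr(out, "n_families", nrow(idx))
  data.table::setattr(out, "sizes", idx$size)
  out
}
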