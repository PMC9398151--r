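#' Construct a panel assay
#'
#' An assay is one short amplicon (65--99 bp) of a multiplexed
#' UMI-barcoded panel: the amplicon reference sequence, its forward
#' primer (an exact prefix of the amplicon), the reverse-primer segment
#' on the top strand (an exact suffix), and the target window in which
#' variants are expected. All coordinates are 0-based, half-open,
#' relative to the amplicon top strand.
#'
#' @param assay_id unique assay identifier, e.g. `"KIT_11"`.
#' @param gene gene symbol (e.g. `"KIT"`, `"PDGFRA"`).
#' @param exon exon label (character).
#' @param amplicon_seq uppercase ACGT amplicon reference sequence.
#' @param fwd_primer forward primer sequence (prefix of the amplicon).
#' @param rev_primer reverse-primer top-strand segment (suffix of the
#'   amplicon).
#' @param target_window integer length-2 vector `c(start, end)`,
#'   0-based half-open, strictly between the primer regions.
#' @return an object of class `umivar_assay`.
#' @seealso [validate_assay()], [make_spikein_sequence()]
#' @export
assay <- function(assay_id, gene, exon, amplicon_seq, fwd_primer,
                  rev_primer, target_window) {
  obj <- structure(list(
    assay_id = as.character(assay_id),
    gene = as.character(gene),
    exon = as.character(exon),
    amplicon_seq = toupper(as.character(amplicon_seq)),
    fwd_primer = toupper(as.character(fwd_primer)),
    rev_primer = toupper(as.character(rev_primer)),
    target_window = as.integer(target_window)
  ), class = "umivar_assay")
  obj
}

#' Validate an assay against the panel design constraints
#'
#' Returns machine-coded violation strings (empty when valid) rather
#' than raising, so that panel loading can report all problems at once.
#' Checked constraints: amplicon length within 65--99 bp, ACGT alphabet,
#' forward primer an exact amplicon prefix, reverse-primer segment an
#' exact suffix, and a target window lying strictly between the primer
#' regions.
#'
#' @param x an [assay()] object.
#' @return character vector of violation codes; human-readable messages
#'   are attached as the `messages` attribute.
#' @export
validate_assay <- function(x) {
  v <- character(0)
  msg <- character(0)
  add <- function(code, m) {
    v <<- c(v, code)
    msg <<- c(msg, m)
  }
  L <- nchar(x$amplicon_seq)
  if (!grepl("^[ACGT]+$", x$amplicon_seq))
    add("amplicon_not_acgt", "amplicon sequence contains non-ACGT characters")
  if (L < 65L)
    add("amplicon_length_below_min",
        sprintf("amplicon length %d out of 65-99 range", L))
  if (L > 99L)
    add("amplicon_length_above_max",
        sprintf("amplicon length %d out of 65-99 range", L))
  if (!startsWith(x$amplicon_seq, x$fwd_primer))
    add("fwd_primer_not_prefix",
        "forward primer is not a prefix of the amplicon")
  if (!endsWith(x$amplicon_seq, x$rev_primer))
    add("rev_primer_not_suffix",
        "reverse-primer segment is not a suffix of the amplicon")
  tw <- x$target_window
  if (length(tw) != 2L || anyNA(tw) || tw[1] >= tw[2]) {
    add("target_window_invalid", "target window must be c(start, end), start < end")
  } else {
    fw_end <- nchar(x$fwd_primer)           # first position after fwd primer
    rv_start <- L - nchar(x$rev_primer)     # first position of rev segment
    if (tw[1] < fw_end || tw[2] > rv_start)
      add("target_window_in_primer",
          "target window overlaps a primer region")
  }
  attr(v, "messages") <- msg
  v
}

#' Construct a target variant
#'
#' Variants are expressed in 0-based amplicon coordinates with empty
#' `ref` for pure insertions (inserted before position `pos`) and empty
#' `alt` for pure deletions; indels are left-normalized on construction.
#'
#' @param assay_id assay the variant belongs to.
#' @param pos 0-based amplicon coordinate.
#' @param ref reference allele (`""` for insertion).
#' @param alt alternate allele (`""` for deletion).
#' @param label one of `"tumor_specific"`, `"resistance"`, `"secondary"`.
#'   Variants labeled `"secondary"` are representable but never drive
#'   sample positivity.
#' @param amplicon_seq optional amplicon sequence; when given, the
#'   variant is left-normalized against it and `ref` is checked to match
#'   the amplicon slice.
#' @return an object of class `umivar_variant` with a `vclass` field in
#'   `{SNV, INS, DEL, DELINS}`.
#' @export
target_variant <- function(assay_id, pos, ref, alt, label,
                           amplicon_seq = NULL) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  pos <- as.integer(pos)
  vclass <- variant_class(ref, alt)
  if (!label %in% c("tumor_specific", "resistance", "secondary"))
    stop("unknown variant label: ", label)
  if (!is.null(amplicon_seq)) {
    nv <- left_normalize(pos, ref, alt, amplicon_seq)
    pos <- nv$pos; ref <- nv$ref; alt <- nv$alt
    if (nchar(ref) > 0L &&
        substr(amplicon_seq, pos + 1L, pos + nchar(ref)) != ref)
      stop("variant ref allele does not match the amplicon at position ", pos)
  }
  structure(list(assay_id = as.character(assay_id), pos = pos, ref = ref,
                 alt = alt, vclass = vclass, label = label),
            class = "umivar_variant")
}

variant_class <- function(ref, alt) {
  if (nchar(ref) == 1L && nchar(alt) == 1L) "SNV"
  else if (nchar(ref) == 0L && nchar(alt) > 0L) "INS"
  else if (nchar(alt) == 0L && nchar(ref) > 0L) "DEL"
  else if (nchar(ref) > 0L && nchar(alt) > 0L) "DELINS"
  else stop("ref and alt cannot both be empty")
}

#' Left-normalize an indel against its amplicon
#'
#' Shifts a pure insertion or deletion to its leftmost equivalent
#' placement so that variant identity (used by the cross-sample rescue
#' rule) is an exact tuple comparison. SNV and delins events are
#' returned unchanged.
#'
#' @param pos 0-based position.
#' @param ref,alt alleles (`""` for pure insertion / deletion).
#' @param amplicon_seq amplicon reference sequence.
#' @return list with normalized `pos`, `ref`, `alt`.
#' @export
left_normalize <- function(pos, ref, alt, amplicon_seq) {
  s <- strsplit(amplicon_seq, "")[[1]]
  if (nchar(alt) == 0L && nchar(ref) > 0L) {      # deletion of s[pos+1 .. pos+k]
    k <- nchar(ref)
    while (pos > 0L && s[pos] == s[pos + k]) pos <- pos - 1L
    ref <- paste(s[(pos + 1L):(pos + k)], collapse = "")
  } else if (nchar(ref) == 0L && nchar(alt) > 0L) {  # insertion before s[pos+1]
    a <- strsplit(alt, "")[[1]]
    while (pos > 0L && s[pos] == a[length(a)]) {
      a <- c(s[pos], a[-length(a)])
      pos <- pos - 1L
    }
    alt <- paste(a, collapse = "")
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Apply a variant to an amplicon sequence
#'
#' @param amplicon_seq amplicon reference.
#' @param variant a [target_variant()].
#' @return the mutant haplotype sequence.
#' @export
apply_variant <- function(amplicon_seq, variant) {
  p <- variant$pos
  left <- substr(amplicon_seq, 1L, p)
  rest <- substr(amplicon_seq, p + 1L + nchar(variant$ref),
                 nchar(amplicon_seq))
  paste0(left, variant$alt, rest)
}

#' Spike-in control sequence for an assay
#'
#' The spike-in control is identical to the amplicon with an `ATG`
#' trinucleotide inserted immediately after the 3' end of the forward
#' primer; its recovery monitors library-construction failure.
#'
#' @param x an [assay()].
#' @return the spike-in sequence (amplicon length + 3).
#' @export
make_spikein_sequence <- function(x) {
  fw <- nchar(x$fwd_primer)
  paste0(x$fwd_primer, "ATG",
         substr(x$amplicon_seq, fw + 1L, nchar(x$amplicon_seq)))
}

#' Canonical (left-normalized) spike-in insertion event for an assay
#'
#' The nominal insertion sits right after the forward primer, but its
#' left-normalized representation may shift into the primer when the
#' primer's 3' end matches the inserted bases; this canonical form is
#' what alignment-derived events are compared against when routing
#' spike-in consensus reads.
#'
#' @param x an [assay()].
#' @return list with `pos`, `ref` (`""`), `alt`.
#' @export
spikein_event <- function(x) {
  left_normalize(nchar(x$fwd_primer), "", "ATG", x$amplicon_seq)
}

#' Construct a patient-specific 5-plex panel
#'
#' A panel carries exactly five assays: one bearing the patient's
#' tumor-specific variant plus four resistance assays shared across
#' patients.
#'
#' @param patient_id patient identifier.
#' @param assays list of [assay()] objects.
#' @param variants list of [target_variant()] objects; exactly one must
#'   be labeled `tumor_specific`.
#' @param spikeins optional named integer vector of expected spike-in
#'   molecule counts by assay id.
#' @param validate validate invariants (default `TRUE`).
#' @return object of class `umivar_panel`.
#' @export
patient_panel <- function(patient_id, assays, variants,
                          spikeins = integer(0), validate = TRUE) {
  names(assays) <- vapply(assays, `[[`, "", "assay_id")
  p <- structure(list(
    patient_id = as.character(patient_id),
    assays = assays,
    variants = variants,
    spikeins = spikeins
  ), class = "umivar_panel")
  if (validate) {
    v <- validate_panel(p)
    if (length(v))
      stop("panel validation failed:\n  ",
           paste(attr(v, "messages"), collapse = "\n  "))
  }
  p
}

#' Validate a patient panel
#'
#' Checks the per-assay constraints of [validate_assay()] plus the
#' panel-level invariants: exactly five assays, exactly one
#' tumor-specific variant, every variant inside its assay's target
#' window with a `ref` allele matching the amplicon slice, and
#' left-normalized indels.
#'
#' @param p a [patient_panel()] (built with `validate = FALSE` if you
#'   want to inspect violations).
#' @return character vector of violation codes with `messages` attribute.
#' @export
validate_panel <- function(p) {
  v <- character(0); msg <- character(0)
  add <- function(code, m) { v <<- c(v, code); msg <<- c(msg, m) }
  if (length(p$assays) != 5L)
    add("expected_five_assays",
        sprintf("expected five assays, found %d", length(p$assays)))
  for (a in p$assays) {
    va <- validate_assay(a)
    if (length(va)) {
      v <- c(v, paste0(a$assay_id, ":", va))
      msg <- c(msg, paste0(a$assay_id, ": ", attr(va, "messages")))
    }
  }
  labs <- vapply(p$variants, `[[`, "", "label")
  if (sum(labs == "tumor_specific") != 1L)
    add("tumor_variant_count",
        sprintf("expected exactly one tumor-specific variant, found %d",
                sum(labs == "tumor_specific")))
  for (tv in p$variants) {
    a <- p$assays[[tv$assay_id]]
    if (is.null(a)) {
      add("variant_unknown_assay",
          paste0("variant references unknown assay ", tv$assay_id))
      next
    }
    tw <- a$target_window
    if (tv$pos < tw[1] || tv$pos >= tw[2])
      add("variant_outside_window",
          sprintf("%s variant at %d outside target window [%d,%d)",
                  tv$assay_id, tv$pos, tw[1], tw[2]))
    if (nchar(tv$ref) > 0L &&
        substr(a$amplicon_seq, tv$pos + 1L, tv$pos + nchar(tv$ref)) != tv$ref)
      add("variant_ref_mismatch",
          sprintf("%s ref allele does not match amplicon at %d",
                  tv$assay_id, tv$pos))
    nv <- left_normalize(tv$pos, tv$ref, tv$alt, a$amplicon_seq)
    if (nv$pos != tv$pos || nv$ref != tv$ref || nv$alt != tv$alt)
      add("variant_not_left_normalized",
          sprintf("%s indel at %d is not left-normalized", tv$assay_id,
                  tv$pos))
  }
  if (length(p$spikeins)) {
    bad <- setdiff(names(p$spikeins), names(p$assays))
    if (length(bad))
      add("spikein_unknown_assay",
          paste0("spike-in for unknown assay: ", paste(bad, collapse = ",")))
  }
  attr(v, "messages") <- msg
  v
}

#' A variant's identity string (assay:pos:ref>alt, left-normalized)
#' @param v a [target_variant()] or list with the same fields.
#' @return character scalar.
#' @export
variant_id <- function(v) {
  sprintf("%s:%d:%s>%s", v$assay_id, v$pos, v$ref, v$alt)
}

#' Load a patient panel from a YAML definition file
#'
#' The file holds `patient_id`, a list of `assays` (fields as in
#' [assay()]; `target_window` as `[start, end)` 0-based), a list of
#' `variants` (fields as in [target_variant()]) and optionally
#' `spikeins` (`assay_id`, `expected_count`). Missing required fields
#' raise a configuration error naming the field; invariant violations
#' raise a validation error listing all failures.
#'
#' @param path panel YAML file.
#' @return a validated [patient_panel()].
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  y <- yaml::read_yaml(path)
  need <- function(x, field, where) {
    if (is.null(x[[field]]))
      stop("configuration error: missing field '", field, "' in ", where)
    x[[field]]
  }
  need(y, "patient_id", "panel")
  need(y, "assays", "panel")
  assays <- lapply(y$assays, function(a) {
    for (f in c("assay_id", "gene", "exon", "amplicon_seq", "fwd_primer",
                "rev_primer", "target_window"))
      need(a, f, "assay")
    assay(a$assay_id, a$gene, a$exon, a$amplicon_seq, a$fwd_primer,
          a$rev_primer, unlist(a$target_window))
  })
  amap <- setNames(lapply(assays, `[[`, "amplicon_seq"),
                   vapply(assays, `[[`, "", "assay_id"))
  variants <- lapply(y$variants, function(vv) {
    for (f in c("assay_id", "pos", "label")) need(vv, f, "variant")
    ref <- if (is.null(vv$ref)) "" else vv$ref
    alt <- if (is.null(vv$alt)) "" else vv$alt
    target_variant(vv$assay_id, vv$pos, ref, alt, vv$label,
                   amplicon_seq = amap[[vv$assay_id]])
  })
  spikeins <- integer(0)
  if (!is.null(y$spikeins)) {
    spikeins <- setNames(
      vapply(y$spikeins, function(s) as.integer(need(s, "expected_count",
                                                     "spikein")), 1L),
      vapply(y$spikeins, function(s) as.character(need(s, "assay_id",
                                                       "spikein")), "")
    )
  }
  patient_panel(y$patient_id, assays, variants, spikeins)
}

#' Write a patient panel to a YAML file
#'
#' Inverse of [load_panel()]: `load_panel(write_panel(p, f))` restores an
#' identical structure.
#'
#' @param p a [patient_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(p, path) {
  y <- list(
    patient_id = p$patient_id,
    assays = lapply(unname(p$assays), function(a)
      list(assay_id = a$assay_id, gene = a$gene, exon = a$exon,
           amplicon_seq = a$amplicon_seq, fwd_primer = a$fwd_primer,
           rev_primer = a$rev_primer,
           target_window = as.list(a$target_window))),
    variants = lapply(p$variants, function(v)
      list(assay_id = v$assay_id, pos = v$pos, ref = v$ref, alt = v$alt,
           label = v$label))
  )
  if (length(p$spikeins))
    y$spikeins <- lapply(seq_along(p$spikeins), function(i)
      list(assay_id = names(p$spikeins)[i],
           expected_count = unname(p$spikeins[i])))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Export panel amplicons and spike-in sequences as FASTA
#'
#' @param p a [patient_panel()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
panel_fasta <- function(p, path) {
  seqs <- c(
    setNames(vapply(p$assays, `[[`, "", "amplicon_seq"),
             names(p$assays)),
    setNames(vapply(p$assays, make_spikein_sequence, ""),
             paste0(names(p$assays), "_spikein"))
  )
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @export
print.umivar_panel <- function(x, ...) {
  cat("Patient panel:", x$patient_id, "\n")
  cat(sprintf("  %d assays: %s\n", length(x$assays),
              paste(names(x$assays), collapse = ", ")))
  for (v in x$variants)
    cat(sprintf("  variant %-14s %s (%s)\n", v$label, variant_id(v),
                v$vclass))
  if (length(x$spikeins))
    cat("  spike-ins:", paste0(names(x$spikeins), "=", x$spikeins,
                               collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.umivar_assay <- function(x, ...) {
  cat(sprintf("Assay %s (%s exon %s), %d bp amplicon, window [%d,%d)\n",
              x$assay_id, x$gene, x$exon, nchar(x$amplicon_seq),
              x$target_window[1], x$target_window[2]))
  invisible(x)
}
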