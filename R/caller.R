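#' Call variants for one sample from per-assay pileups
#'
#' Applies the fixed consensus-read thresholds: a solitary SNV requires
#' more than six mutant consensus reads (`n_mut >= snv_min`, default 7)
#' to be `called`; SNVs with 1..`snv_min - 1` mutant reads are
#' `provisional` (candidates for the patient-level rescue rule);
#' insertions and deletions are `called` from `indel_min` (default 1)
#' consensus read. MAF is reported as a percentage of consensus reads
#' covering the locus (`N`-masked reads excluded from both counts).
#' Besides the panel targets, any observed non-target event inside an
#' assay's target window is reported with label `"novel"` under the
#' same thresholds; novel events never drive sample positivity.
#'
#' @param pileups named list of [build_pileup()] objects by assay id.
#' @param panel the [patient_panel()].
#' @param snv_min minimum mutant consensus reads for a solitary SNV
#'   call (default 7, i.e. "more than six").
#' @param indel_min minimum mutant consensus reads for an indel call
#'   (default 1).
#' @return `data.table` of calls: `variant_id`, `assay_id`, `pos`,
#'   `ref`, `alt`, `vclass`, `label`, `n_mut`, `n_total`, `maf`
#'   (percent, `NA` when uncovered), `status` in
#'   `{called, provisional, absent}`, `flags`.
#' @export
call_sample_variants <- function(pileups, panel, snv_min = 7L,
                                 indel_min = 1L) {
  rows <- list()
  seen <- character(0)
  for (tv in panel$variants) {
    pu <- pileups[[tv$assay_id]]
    if (is.null(pu)) next
    hit <- pu$events[pos == tv$pos & ref == tv$ref & alt == tv$alt]
    n_mut <- if (nrow(hit)) hit$count[1] else 0L
    rows[[length(rows) + 1L]] <-
      one_call(tv, n_mut, coverage_at(pu, tv), snv_min, indel_min)
    seen <- c(seen, variant_id(tv))
  }
  # novel events within target windows
  for (aid in names(pileups)) {
    pu <- pileups[[aid]]
    a <- panel$assays[[aid]]
    if (is.null(a) || !nrow(pu$events)) next
    tw <- a$target_window
    nov <- pu$events[pos >= tw[1] & pos < tw[2]]
    for (i in seq_len(nrow(nov))) {
      v <- list(assay_id = aid, pos = nov$pos[i], ref = nov$ref[i],
                alt = nov$alt[i], vclass = nov$vclass[i], label = "novel")
      if (variant_id(v) %in% seen) next
      rows[[length(rows) + 1L]] <-
        one_call(v, nov$count[i], coverage_at(pu, v), snv_min, indel_min)
    }
  }
  if (!length(rows)) return(empty_calls())
  data.table::rbindlist(rows)
}

coverage_at <- function(pileup, v) {
  p <- min(v$pos + 1L, pileup$length)   # insertions at pos L anchor left
  pileup$coverage[max(p, 1L)]
}

one_call <- function(v, n_mut, n_total, snv_min, indel_min) {
  flags <- character(0)
  if (n_total == 0L) {
    status <- "absent"
    flags <- "no_coverage"
    maf <- NA_real_
  } else {
    maf <- 100 * n_mut / n_total
    if (v$vclass == "SNV") {
      status <- if (n_mut >= snv_min) "called"
                else if (n_mut >= 1L) "provisional" else "absent"
    } else {
      status <- if (n_mut >= indel_min) "called" else "absent"
    }
  }
  data.table::data.table(
    variant_id = variant_id(v), assay_id = v$assay_id, pos = v$pos,
    ref = v$ref, alt = v$alt, vclass = v$vclass, label = v$label,
    n_mut = as.integer(n_mut), n_total = as.integer(n_total), maf = maf,
    status = status, flags = paste(flags, collapse = ","))
}

empty_calls <- function() {
  data.table::data.table(
    variant_id = character(0), assay_id = character(0), pos = integer(0),
    ref = character(0), alt = character(0), vclass = character(0),
    label = character(0), n_mut = integer(0), n_total = integer(0),
    maf = numeric(0), status = character(0), flags = character(0))
}

#' Apply the patient-level cross-sample rescue rule
#'
#' A provisional SNV in sample S becomes `rescued` if at least one
#' *other* sample of the same patient displays the identical variant
#' (exact left-normalized `(assay, pos, ref, alt)` equality) with at
#' least `rescue_anchor` mutant consensus reads (default 6, "at least
#' six"). Samples are re-classified afterwards.
#'
#' @param samples list of [sample_result()] drafts for one patient.
#' @param rescue_anchor minimum anchor mutant count (default 6).
#' @param low_input molecule-count threshold for the low-input class
#'   (default 50).
#' @return the finalized list of sample results.
#' @export
rescue_provisional <- function(samples, rescue_anchor = 6L,
                               low_input = 50L) {
  if (!length(samples)) return(samples)
  pid <- unique(vapply(samples, `[[`, "", "patient_id"))
  if (length(pid) > 1L)
    stop("rescue_provisional expects samples of a single patient")
  for (i in seq_along(samples)) {
    calls <- samples[[i]]$calls
    prov <- which(calls$status == "provisional")
    for (j in prov) {
      vid <- calls$variant_id[j]
      anchored <- any(vapply(samples[-i], function(s) {
        k <- s$calls[variant_id == vid & n_mut >= rescue_anchor]
        nrow(k) > 0L
      }, TRUE))
      if (anchored) calls[j, status := "rescued"]
    }
    samples[[i]]$calls <- calls
    samples[[i]]$classification <-
      classify_sample(calls, samples[[i]]$molecule_count, low_input)
  }
  samples
}

#' Classify a sample as ctDNA positive / negative / negative low-input
#'
#' Positive when any tumor-specific or resistance call is `called` or
#' `rescued`; otherwise `negative_low_input` when fewer than
#' `low_input` cfDNA molecules (consensus reads covering the
#' tumor-specific locus) were detected, else `negative`. Variants
#' labeled `secondary` or `novel` never drive positivity.
#'
#' @param calls a call table from [call_sample_variants()].
#' @param molecule_count detected cfDNA molecules at the
#'   tumor-specific locus.
#' @param low_input threshold (default 50).
#' @return one of `"positive"`, `"negative"`, `"negative_low_input"`.
#' @export
classify_sample <- function(calls, molecule_count, low_input = 50L) {
  pos <- nrow(calls[label %in% c("tumor_specific", "resistance") &
                      status %in% c("called", "rescued")]) > 0L
  if (pos) "positive"
  else if (molecule_count < low_input) "negative_low_input"
  else "negative"
}

#' Run the per-sample pipeline on reads in memory
#'
#' Demultiplex, group UMI families, build consensus reads, align, pile
#' up, call variants and classify. The conservation invariant
#' (unassigned + sum of family sizes = input reads) is asserted on
#' every run.
#'
#' @param reads character vector of reads, or a [simulate_sample()]
#'   object.
#' @param panel the [patient_panel()].
#' @param sample_id,patient_id,timepoint sample annotations; timepoint
#'   is one of `presurgery`, `surgery_start`, `mobilization`,
#'   `closure`, `postsurgery` (free text is allowed for non-surgical
#'   designs).
#' @param umi_length,max_primer_mismatch see [demultiplex_reads()].
#' @param min_reads,min_agreement see [build_consensus_set()].
#' @param snv_min,indel_min see [call_sample_variants()].
#' @param low_input low-input molecule threshold (default 50).
#' @return object of class `umivar_sample_result`: list with
#'   `sample_id`, `patient_id`, `timepoint`, `calls`,
#'   `classification`, `molecule_count`, `mean_family_size`,
#'   `spikein_counts` (per assay), `counts` (reads/assigned/families/
#'   consensus/unalignable), `pileups`.
#' @export
call_sample <- function(reads, panel, sample_id = "S1",
                        patient_id = panel$patient_id,
                        timepoint = "presurgery",
                        umi_length = 12L, max_primer_mismatch = 2L,
                        min_reads = 3L, min_agreement = 0.9,
                        snv_min = 7L, indel_min = 1L, low_input = 50L) {
  if (inherits(reads, "umivar_sim")) reads <- reads$reads
  asg <- demultiplex_reads(reads, panel, umi_length, max_primer_mismatch)
  fams <- group_families(asg)
  stopifnot(attr(fams, "n_unassigned") + sum(attr(fams, "sizes")) ==
              length(reads))
  mfs <- if (length(attr(fams, "sizes"))) mean_family_size(fams) else NA_real_
  cons <- build_consensus_set(fams, min_reads, min_agreement)
  pileups <- lapply(panel$assays, function(a)
    build_pileup(cons[assay_id == a$assay_id], a))
  calls <- call_sample_variants(pileups, panel, snv_min, indel_min)
  tumor <- Filter(function(v) v$label == "tumor_specific", panel$variants)
  molecule_count <- if (length(tumor))
    coverage_at(pileups[[tumor[[1]]$assay_id]], tumor[[1]]) else
      max(vapply(pileups, function(p) max(p$coverage, 0L), 0L))
  spikein_counts <- vapply(pileups, `[[`, 0L, "n_spikein")
  res <- structure(list(
    sample_id = sample_id, patient_id = patient_id, timepoint = timepoint,
    calls = calls,
    classification = classify_sample(calls, molecule_count, low_input),
    molecule_count = as.integer(molecule_count),
    mean_family_size = mfs,
    spikein_counts = spikein_counts,
    counts = c(reads = length(reads),
               assigned = sum(asg$reason == "assigned"),
               unassigned = attr(fams, "n_unassigned"),
               families = attr(cons, "n_families"),
               consensus = sum(vapply(pileups, `[[`, 0L, "n_consensus")),
               unalignable = sum(vapply(pileups, `[[`, 0L,
                                        "n_unalignable"))),
    pileups = pileups
  ), class = "umivar_sample_result")
  res
}

#' Construct a sample result from components
#'
#' Mostly useful in tests and when assembling drafts for
#' [rescue_provisional()].
#'
#' @param sample_id,patient_id,timepoint annotations.
#' @param calls call table.
#' @param molecule_count detected cfDNA molecules.
#' @param low_input threshold (default 50).
#' @return `umivar_sample_result`.
#' @export
sample_result <- function(sample_id, patient_id, timepoint, calls,
                          molecule_count, low_input = 50L) {
  structure(list(
    sample_id = sample_id, patient_id = patient_id,
    timepoint = timepoint, calls = calls,
    classification = classify_sample(calls, molecule_count, low_input),
    molecule_count = as.integer(molecule_count),
    mean_family_size = NA_real_, spikein_counts = integer(0),
    counts = integer(0), pileups = NULL
  ), class = "umivar_sample_result")
}

#' @export
print.umivar_sample_result <- function(x, ...) {
  cat(sprintf("Sample %s (patient %s, %s): %s\n", x$sample_id,
              x$patient_id, x$timepoint, x$classification))
  cat(sprintf("  %d cfDNA molecules at the tumor-specific locus\n",
              x$molecule_count))
  shown <- x$calls[status != "absent"]
  if (nrow(shown)) {
    cat("  calls:\n")
    for (i in seq_len(nrow(shown)))
      cat(sprintf("    %-28s %-14s n_mut=%d n_total=%d MAF=%.3f%% [%s]\n",
                  shown$variant_id[i], shown$label[i], shown$n_mut[i],
                  shown$n_total[i], shown$maf[i], shown$status[i]))
  } else cat("  no variant calls\n")
  invisible(x)
}
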