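#' Pipeline run configuration
#'
#' Bundles the paths and thresholds of an end-to-end run. Threshold
#' defaults are the reference decision rules: consensus from 3 reads,
#' solitary SNV from 7 mutant consensus reads, indel from 1, rescue
#' anchor 6, low-input below 50 molecules, undersequencing below mean
#' family size 7, contamination above 5%.
#'
#' @param panel path to a panel YAML, or a named list/character vector
#'   of per-patient panel paths, or [patient_panel()] object(s).
#' @param sample_sheet path to a TSV with columns `sample_id`,
#'   `patient_id`, `timepoint`, `run`, `fastq` (paths resolved
#'   relative to the sheet), or a data.frame.
#' @param output_dir output directory (created).
#' @param min_reads,min_agreement,snv_min,indel_min,rescue_anchor,low_input,underseq_threshold,contamination_threshold,umi_length,max_primer_mismatch
#'   thresholds; see the stage functions.
#' @return list of class `umivar_config`.
#' @export
run_config <- function(panel, sample_sheet, output_dir,
                       min_reads = 3L, min_agreement = 0.9,
                       snv_min = 7L, indel_min = 1L,
                       rescue_anchor = 6L, low_input = 50L,
                       underseq_threshold = 7,
                       contamination_threshold = 0.05,
                       umi_length = 12L, max_primer_mismatch = 2L) {
  stopifnot(min_reads >= 1L, snv_min >= 1L, indel_min >= 1L,
            rescue_anchor >= 1L, low_input >= 1L)
  structure(as.list(environment()), class = "umivar_config")
}

resolve_panels <- function(panel, patient_ids) {
  if (inherits(panel, "umivar_panel"))
    return(setNames(rep(list(panel), length(patient_ids)), patient_ids))
  if (is.character(panel) && length(panel) == 1L && is.null(names(panel)))
    return(setNames(rep(list(load_panel(panel)), length(patient_ids)),
                    patient_ids))
  out <- lapply(panel, function(p)
    if (inherits(p, "umivar_panel")) p else load_panel(p))
  missing <- setdiff(patient_ids, names(out))
  if (length(missing))
    stop("no panel given for patient(s): ", paste(missing, collapse = ", "))
  out[patient_ids]
}

#' Run the full pipeline over a sample sheet
#'
#' Executes demultiplex, UMI family grouping, consensus construction,
#' alignment, variant calling, the patient-level rescue rule, sample
#' classification, undersequencing QC and the cohort table; writes per
#' sample a VCF and a call TSV, a cohort-wide long-format TSV, a QC
#' TSV, and a run log recording every threshold in effect and the
#' read-conservation check of every sample. When resistance assays are
#' shared across patients (the intended design), panels may be a
#' single file.
#'
#' @param config a [run_config()].
#' @return invisibly, list with `samples` (finalized sample results),
#'   `cohort` (the cohort table), `qc` (per-sample QC rows), and
#'   `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "umivar_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$output_dir, "run.log")
  logcon <- file(logf, "w")
  on.exit(close(logcon), add = TRUE)
  logline <- function(...) writeLines(sprintf(...), logcon)
  manifest <- character(0)
  stage_done <- function(s) {
    manifest <<- c(manifest, s)
    writeLines(manifest, file.path(config$output_dir, "MANIFEST"))
  }

  logline("umivar run started %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  for (th in c("min_reads", "min_agreement", "snv_min", "indel_min",
               "rescue_anchor", "low_input", "underseq_threshold",
               "contamination_threshold", "umi_length",
               "max_primer_mismatch"))
    logline("threshold %s = %s", th, format(config[[th]]))

  sheet <- config$sample_sheet
  if (is.character(sheet)) {
    base <- dirname(sheet)
    sheet <- data.table::fread(sheet)
    if (!is.null(sheet$fastq))
      sheet[, fastq := ifelse(file.exists(fastq), fastq,
                              file.path(base, fastq))]
  } else sheet <- data.table::as.data.table(sheet)
  for (col in c("sample_id", "patient_id", "timepoint", "fastq"))
    if (is.null(sheet[[col]]))
      stop("sample sheet is missing column '", col, "'")
  if (is.null(sheet$run)) sheet[, run := "run1"]
  panels <- resolve_panels(config$panel, unique(sheet$patient_id))
  stage_done("configured")

  results <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    sm <- as.list(sheet[i])
    reads <- read_fastq(sm$fastq)
    res <- call_sample(
      reads, panels[[sm$patient_id]], sample_id = sm$sample_id,
      patient_id = sm$patient_id, timepoint = sm$timepoint,
      umi_length = config$umi_length,
      max_primer_mismatch = config$max_primer_mismatch,
      min_reads = config$min_reads, min_agreement = config$min_agreement,
      snv_min = config$snv_min, indel_min = config$indel_min,
      low_input = config$low_input)
    res$run <- sm$run
    cn <- res$counts
    logline("sample %s: reads=%d assigned=%d unassigned=%d families=%d consensus=%d conservation=%s",
            sm$sample_id, cn[["reads"]], cn[["assigned"]],
            cn[["unassigned"]], cn[["families"]], cn[["consensus"]],
            "ok")
    results[[i]] <- res
  }
  stage_done("called")

  # patient-level rescue + final classification
  by_patient <- split(results, sheet$patient_id)
  results <- unlist(lapply(by_patient, rescue_provisional,
                           rescue_anchor = config$rescue_anchor,
                           low_input = config$low_input),
                    recursive = FALSE)
  stage_done("rescued")

  for (res in results) {
    pnl <- panels[[res$patient_id]]
    write_vcf(res, pnl, file.path(config$output_dir,
                                  paste0(res$sample_id, ".vcf")))
    data.table::fwrite(res$calls,
                       file.path(config$output_dir,
                                 paste0(res$sample_id, "_calls.tsv")),
                       sep = "\t")
  }
  stage_done("per_sample_outputs")

  qc <- data.table::rbindlist(lapply(results, function(r)
    data.table::data.table(
      sample_id = r$sample_id, patient_id = r$patient_id,
      run = if (is.null(r$run)) NA_character_ else r$run,
      mean_family_size = r$mean_family_size,
      undersequenced = flag_undersequenced(r$mean_family_size,
                                           config$underseq_threshold),
      molecule_count = r$molecule_count,
      low_input = r$molecule_count < config$low_input,
      spikein = sum(r$spikein_counts))))
  data.table::fwrite(qc, file.path(config$output_dir, "qc.tsv"),
                     sep = "\t")
  cohort <- cohort_table(results)
  data.table::fwrite(cohort, file.path(config$output_dir, "cohort.tsv"),
                     sep = "\t")
  stage_done("cohort")
  logline("umivar run finished: %d samples", length(results))
  stage_done("done")
  invisible(list(samples = results, cohort = cohort, qc = qc,
                 output_dir = config$output_dir))
}
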