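#' Fit a qPCR standard curve
#'
#' Least-squares regression of Cq on log10(quantity) over a human
#' genomic DNA dilution series (10 ng with threefold dilutions down to
#' 0.37 ng in the reference design). Amplification efficiency is
#' `10^(-1/slope) - 1`: a slope of -3.3219 corresponds to perfect
#' doubling (efficiency 1).
#'
#' @param points data.frame with columns `quantity` (ng, > 0) and `cq`.
#' @return object of class `umivar_stdcurve`: list with `slope`,
#'   `intercept`, `efficiency`, `points`, and the `lm` fit.
#' @export
fit_standard_curve <- function(points) {
  if (nrow(points) < 3L || length(unique(points$quantity)) < 3L)
    stop("standard curve needs >= 3 points with distinct quantities")
  if (any(points$quantity <= 0)) stop("quantities must be > 0")
  fit <- lm(cq ~ log10(quantity), data = points)
  slope <- unname(coef(fit)[2])
  structure(list(
    slope = slope,
    intercept = unname(coef(fit)[1]),
    efficiency = 10^(-1 / slope) - 1,
    points = points,
    fit = fit
  ), class = "umivar_stdcurve")
}

#' Invert a standard curve: quantity from Cq
#'
#' @param curve a [fit_standard_curve()].
#' @param cq Cq value(s).
#' @return quantity in ng.
#' @export
predict_quantity <- function(curve, cq) {
  10^((cq - curve$intercept) / curve$slope)
}

#' @export
print.umivar_stdcurve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: slope %.4f, intercept %.3f, efficiency %.1f%%\n",
              x$slope, x$intercept, 100 * x$efficiency))
  invisible(x)
}

#' Assess cellular DNA contamination
#'
#' The long-amplicon qPCR target only amplifies from intact
#' (high-molecular-weight) cellular DNA while the short target
#' amplifies from fragmented cfDNA as well; their quantity ratio,
#' normalized to a nonfragmented genomic DNA reference, estimates the
#' cellular fraction. More than 5% cellular DNA is flagged as
#' contamination (strict inequality: exactly 5% is clean).
#'
#' @param short_qty short-amplicon quantity (ng, > 0).
#' @param long_qty long-amplicon quantity (ng).
#' @param genomic_ref_ratio long/short ratio measured on the genomic
#'   DNA reference (default 1).
#' @param threshold contamination threshold (default 0.05).
#' @return list with `fraction` and logical `contaminated`.
#' @export
assess_contamination <- function(short_qty, long_qty,
                                 genomic_ref_ratio = 1.0,
                                 threshold = 0.05) {
  if (short_qty == 0)
    stop("undefined metric: short-amplicon quantity is zero")
  fraction <- (long_qty / short_qty) / genomic_ref_ratio
  list(fraction = fraction, contaminated = fraction > threshold)
}

#' Assess PCR inhibition from the inhibition-control Cq shift
#'
#' The shift of the spiked inhibition control against its
#' no-template-matrix reference classifies the sample. The 1- and
#' 2-cycle thresholds are package conventions (configurable); the
#' underlying assay reports only the categories inhibited and strongly
#' inhibited.
#'
#' @param cq_sample_control inhibition-control Cq in the sample.
#' @param cq_reference inhibition-control Cq in the clean reference.
#' @param thresholds length-2 increasing vector of Cq shifts
#'   (default `c(1, 2)`).
#' @return one of `"none"`, `"inhibited"`, `"strongly_inhibited"`.
#' @export
assess_inhibition <- function(cq_sample_control, cq_reference,
                              thresholds = c(1, 2)) {
  stopifnot(is.finite(cq_sample_control), is.finite(cq_reference))
  shift <- cq_sample_control - cq_reference
  if (shift < thresholds[1]) "none"
  else if (shift < thresholds[2]) "inhibited"
  else "strongly_inhibited"
}

#' Median-center spike-in counts across sequencing runs
#'
#' Counts from different sequencing experiments are placed on a common
#' scale by scaling each run so its median equals the global median of
#' run medians; samples whose centered count falls below `low` times or
#' above `high` times the global median are flagged. Runs with median 0
#' are excluded with a warning.
#'
#' @param counts data.frame with columns `run`, `sample`, `count`.
#' @param low,high flag multipliers (defaults 0.25 and 4; package
#'   conventions).
#' @return `data.table` with added columns `centered` and `flag`
#'   (`"ok"`, `"spikein_low"`, `"spikein_high"`); the global median is
#'   attached as attribute `global_median`.
#' @export
center_spikein_counts <- function(counts, low = 0.25, high = 4) {
  dt <- data.table::as.data.table(counts)
  stopifnot(all(c("run", "sample", "count") %in% names(dt)))
  med <- dt[, .(run_median = stats::median(count)), by = run]
  drop <- med[run_median == 0, run]
  if (length(drop)) {
    warning("excluding run(s) with zero median spike-in count: ",
            paste(drop, collapse = ", "))
    dt <- dt[!run %in% drop]
    med <- med[!run %in% drop]
  }
  if (!nrow(dt)) stop("no runs with nonzero spike-in medians")
  gm <- stats::median(med$run_median)
  dt <- merge(dt, med, by = "run")
  dt[, centered := count * gm / run_median]
  dt[, flag := data.table::fifelse(
    centered < low * gm, "spikein_low",
    data.table::fifelse(centered > high * gm, "spikein_high", "ok"))]
  data.table::setattr(dt, "global_median", gm)
  dt[]
}

#' Flag an undersequenced sample
#'
#' A sample is undersequenced when the average UMI family contains
#' fewer than `threshold` reads (strict; default 7).
#'
#' @param mean_family_size mean reads per UMI family.
#' @param threshold undersequencing bound (default 7).
#' @return logical.
#' @export
flag_undersequenced <- function(mean_family_size, threshold = 7) {
  stopifnot(mean_family_size >= 0)
  mean_family_size < threshold
}

#' Assemble a sample QC report
#'
#' Pure function of its numeric inputs: the flag set is fully
#' determined by the fields, so QC decisions are reproducible from the
#' report alone.
#'
#' @param contamination_fraction cellular DNA fraction (NA if not
#'   measured).
#' @param inhibition one of `"none"`, `"inhibited"`,
#'   `"strongly_inhibited"`, or NA.
#' @param cfdna_ng_per_ml cfDNA concentration (ng per mL plasma).
#' @param mean_family_size mean reads per UMI family.
#' @param spikein_flag `"ok"`, `"spikein_low"`, `"spikein_high"`, or
#'   NA.
#' @param molecule_count detected cfDNA molecules.
#' @param low_input low-input threshold (default 50).
#' @param contamination_threshold default 0.05.
#' @param underseq_threshold default 7.
#' @return object of class `umivar_qc_report` with a `flags` character
#'   vector drawn from `{contaminated, inhibited, strongly_inhibited,
#'   undersequenced, spikein_low, spikein_high, low_input}`.
#' @export
qc_report <- function(contamination_fraction = NA_real_,
                      inhibition = NA_character_,
                      cfdna_ng_per_ml = NA_real_,
                      mean_family_size = NA_real_,
                      spikein_flag = NA_character_,
                      molecule_count = NA_integer_,
                      low_input = 50L,
                      contamination_threshold = 0.05,
                      underseq_threshold = 7) {
  flags <- character(0)
  if (!is.na(contamination_fraction) &&
      contamination_fraction > contamination_threshold)
    flags <- c(flags, "contaminated")
  if (!is.na(inhibition) && inhibition != "none")
    flags <- c(flags, inhibition)
  if (!is.na(mean_family_size) &&
      flag_undersequenced(mean_family_size, underseq_threshold))
    flags <- c(flags, "undersequenced")
  if (!is.na(spikein_flag) && spikein_flag != "ok")
    flags <- c(flags, spikein_flag)
  if (!is.na(molecule_count) && molecule_count < low_input)
    flags <- c(flags, "low_input")
  structure(list(
    contamination_fraction = contamination_fraction,
    inhibition = inhibition,
    cfdna_ng_per_ml = cfdna_ng_per_ml,
    mean_family_size = mean_family_size,
    spikein_flag = spikein_flag,
    molecule_count = molecule_count,
    flags = flags
  ), class = "umivar_qc_report")
}

#' @export
print.umivar_qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  contamination fraction: %s\n",
              format(x$contamination_fraction)))
  cat(sprintf("  inhibition: %s\n", x$inhibition))
  cat(sprintf("  cfDNA ng/mL: %s\n", format(x$cfdna_ng_per_ml)))
  cat(sprintf("  mean family size: %s\n", format(x$mean_family_size)))
  cat(sprintf("  flags: %s\n",
              if (length(x$flags)) paste(x$flags, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param x a [qc_report()].
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return path or JSON string, invisibly when written.
#' @export
qc_report_json <- function(x, path = NULL) {
  j <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                        na = "null")
  if (is.null(path)) return(j)
  writeLines(j, path)
  invisible(path)
}
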