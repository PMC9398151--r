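#' Patient-level ctDNA positivity
#'
#' A patient is ctDNA positive when at least one sample is positive;
#' low-input negatives count as negative.
#'
#' @param samples list of sample results, or a character vector of
#'   sample classifications.
#' @return logical.
#' @export
patient_positivity <- function(samples) {
  cls <- if (is.character(samples)) samples
         else vapply(samples, `[[`, "", "classification")
  if (!length(cls)) stop("patient has no samples")
  any(cls == "positive")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Full hypergeometric enumeration over all tables with the observed
#' margins; the two-sided P value follows the minimum-likelihood
#' convention (the sum of probabilities of tables whose point
#' probability does not exceed the observed one, within a relative
#' tolerance of 1e-7 for ties). This matches the dominant
#' statistical-software convention; the alternative "doubling"
#' convention is deliberately not used.
#'
#' @param tab 2x2 matrix `rbind(c(a, b), c(c, d))` (rows = groups,
#'   columns = positive/negative), or `a` when the four cells are given
#'   separately.
#' @param b,c,d optional cells when `tab` is scalar `a`.
#' @return list with `p` (two-sided), `p_less`, `p_greater` (one-sided
#'   tails) and `table`.
#' @export
fisher_exact_2x2 <- function(tab, b = NULL, c = NULL, d = NULL) {
  if (!is.null(b)) tab <- rbind(c(tab, b), c(c, d))
  tab <- matrix(as.numeric(tab), 2L, 2L)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cells must be non-negative integers")
  a <- tab[1, 1]; bb <- tab[1, 2]; cc <- tab[2, 1]; dd <- tab[2, 2]
  r1 <- a + bb; r2 <- cc + dd; c1 <- a + cc; n <- r1 + r2
  if (n == 0) stop("empty table")
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) {
    warning("degenerate margins: P = 1 by convention")
    return(list(p = 1, p_less = 1, p_greater = 1, table = tab))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) -
    lchoose(n, c1)
  p <- exp(logp)
  p <- p / sum(p)                      # guard tiny rounding drift
  pobs <- p[support == a]
  two <- sum(p[p <= pobs * (1 + 1e-7)])
  list(p = min(two, 1),
       p_less = sum(p[support <= a]),
       p_greater = sum(p[support >= a]),
       table = tab)
}

#' Two-sample Student t test on log10 values with out-of-range
#' replacement
#'
#' Non-detected measurements (`NA`) are, when `oor_rule` is on,
#' replaced by half the minimum detected value across both groups
#' before the log10 transform (e.g. a detected minimum of 0.78 gives
#' the replacement value 0.39); the test is the equal-variance Student
#' t test on the log10 scale. With no non-detects present this reduces
#' exactly to the plain t test on log10 values.
#'
#' @param group_a,group_b numeric vectors; `NA` encodes out-of-range
#'   (never 0).
#' @param oor_rule apply the replacement rule (default `TRUE`).
#' @return list with `t`, `p`, `df`, `replacement` (NA when unused).
#' @export
log_ttest <- function(group_a, group_b, oor_rule = TRUE) {
  repl <- NA_real_
  if (oor_rule && (anyNA(group_a) || anyNA(group_b))) {
    detected <- c(group_a, group_b)
    detected <- detected[!is.na(detected)]
    if (!length(detected))
      stop("undefined metric: no detected values to derive the ",
           "out-of-range replacement")
    repl <- min(detected) / 2
    group_a[is.na(group_a)] <- repl
    group_b[is.na(group_b)] <- repl
  }
  if (anyNA(group_a) || anyNA(group_b))
    stop("non-detects present but oor_rule = FALSE")
  if (any(c(group_a, group_b) <= 0))
    stop("log-scale test requires positive values")
  tt <- plain_ttest(log10(group_a), log10(group_b))
  tt$replacement <- repl
  tt
}

#' Two-sample equal-variance Student t test
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = TRUE`,
#' handling the zero-pooled-variance degenerate cases explicitly:
#' identical constant groups give `t = 0, p = 1`; constant groups with
#' different means give an infinite t (flagged), `p = 0`.
#'
#' @param group_a,group_b numeric vectors with >= 2 values each.
#' @return list with `t`, `p`, `df`, and `degenerate` flag.
#' @export
plain_ttest <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  pooled_var <- (sum((group_a - mean(group_a))^2) +
                 sum((group_b - mean(group_b))^2)) /
    (length(group_a) + length(group_b) - 2)
  df <- length(group_a) + length(group_b) - 2
  if (pooled_var == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, p = 1, df = df, degenerate = TRUE))
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf, p = 0,
                df = df, degenerate = TRUE))
  }
  tt <- t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' ctDNA versus imaging concordance
#'
#' Progressive (PD), partial response (PR) and stable disease (SD) are
#' expected ctDNA positive; complete response (CR) is expected
#' negative. Sensitivity is the detected fraction of expected
#' positives, specificity the ctDNA-negative fraction of expected
#' negatives; an empty denominator yields `NA` (reported missing, never
#' 0).
#'
#' @param imaging character vector of imaging codes in
#'   `{CR, PR, SD, PD}`.
#' @param classification matching sample classifications
#'   (`positive` / `negative` / `negative_low_input`).
#' @return list with `sensitivity`, `specificity` (percent) and the
#'   count table.
#' @export
imaging_concordance <- function(imaging, classification) {
  stopifnot(length(imaging) == length(classification),
            length(imaging) >= 1L)
  bad <- setdiff(unique(imaging), c("CR", "PR", "SD", "PD"))
  if (length(bad))
    stop("unknown imaging code(s): ", paste(bad, collapse = ", "))
  expected_pos <- imaging %in% c("PD", "PR", "SD")
  detected <- classification == "positive"
  npos <- sum(expected_pos)
  nneg <- sum(!expected_pos)
  list(
    sensitivity = if (npos) 100 * sum(detected & expected_pos) / npos
                  else NA_real_,
    specificity = if (nneg) 100 * sum(!detected & !expected_pos) / nneg
                  else NA_real_,
    counts = c(expected_positive = npos, expected_negative = nneg,
               true_positive = sum(detected & expected_pos),
               true_negative = sum(!detected & !expected_pos))
  )
}

#' Assemble the per-sample cohort table
#'
#' Long-format table keyed by patient and timepoint, mirroring the
#' per-sample overview used for cohort statistics.
#'
#' @param samples list of sample results (possibly several patients).
#' @return `data.table`: `patient_id`, `sample_id`, `timepoint`,
#'   `classification`, `molecule_count`, `tumor_maf` (percent, NA when
#'   the tumor variant is absent).
#' @export
cohort_table <- function(samples) {
  data.table::rbindlist(lapply(samples, function(s) {
    tm <- s$calls[label == "tumor_specific" &
                    status %in% c("called", "rescued")]
    data.table::data.table(
      patient_id = s$patient_id, sample_id = s$sample_id,
      timepoint = s$timepoint, classification = s$classification,
      molecule_count = s$molecule_count,
      tumor_maf = if (nrow(tm)) tm$maf[1] else NA_real_)
  }))
}

#' Cohort-level association and concordance statistics
#'
#' Computes the patient-level 2x2 risk-group association (high risk vs
#' other groups, positive at any time) by the exact Fisher test, the
#' Ki-67 log-scale and tumor-size plain t tests between ctDNA-positive
#' and ctDNA-negative patients, and imaging concordance when imaging
#' codes are supplied.
#'
#' @param cohort a [cohort_table()].
#' @param patients data.frame with one row per patient: `patient_id`,
#'   `risk_group` (`very_low_low` / `intermediate` / `high`),
#'   `ki67_percent`, `tumor_size_cm`, optionally `metastatic`.
#' @param imaging optional data.frame `sample_id`, `imaging` for
#'   concordance.
#' @return list with `positivity` (per patient), `risk_table`,
#'   `fisher`, `ki67_test`, `size_test`, `concordance` (or NULL).
#' @export
cohort_stats <- function(cohort, patients, imaging = NULL) {
  pt <- data.table::as.data.table(patients)
  posv <- cohort[, .(positive = any(classification == "positive")),
                 by = patient_id]
  m <- merge(pt, posv, by = "patient_id", all.x = TRUE)
  m[is.na(positive), positive := FALSE]
  risk_table <- rbind(
    high = c(positive = m[risk_group == "high", sum(positive)],
             negative = m[risk_group == "high", sum(!positive)]),
    other = c(positive = m[risk_group != "high", sum(positive)],
              negative = m[risk_group != "high", sum(!positive)]))
  fisher <- fisher_exact_2x2(risk_table)
  ki67_test <- if (m[, sum(positive) >= 2 && sum(!positive) >= 2])
    log_ttest(m[positive == TRUE, ki67_percent],
              m[positive == FALSE, ki67_percent]) else NULL
  size_test <- if (m[, sum(positive) >= 2 && sum(!positive) >= 2])
    plain_ttest(m[positive == TRUE, tumor_size_cm],
                m[positive == FALSE, tumor_size_cm]) else NULL
  concordance <- NULL
  if (!is.null(imaging)) {
    im <- merge(data.table::as.data.table(imaging),
                cohort[, .(sample_id, classification)],
                by = "sample_id")
    concordance <- imaging_concordance(im$imaging, im$classification)
  }
  list(positivity = m[, .(patient_id, risk_group, positive)],
       risk_table = risk_table, fisher = fisher,
       ki67_test = ki67_test, size_test = size_test,
       concordance = concordance)
}
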