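test_that("patient positivity is any-positive-sample and monotone", {
  expect_true(patient_positivity(c("negative", "positive", "negative")))
  expect_false(patient_positivity(rep("negative_low_input", 3)))
  expect_true(patient_positivity("positive"))
  expect_error(patient_positivity(character(0)), "no samples")
  # monotone: adding a positive sample never flips true -> false
  set.seed(3)
  for (i in 1:25) {
    cls <- sample(c("positive", "negative", "negative_low_input"),
                  sample(1:6, 1), replace = TRUE)
    expect_true(patient_positivity(c(cls, "positive")))
    if (patient_positivity(cls))
      expect_true(patient_positivity(c(cls, "negative")))
  }
})

test_that("fisher_exact_2x2 matches closed forms and handles degeneracy", {
  # two extreme 5/5 tables: P = 2 / C(10,5)
  r <- fisher_exact_2x2(rbind(c(5, 0), c(0, 5)))
  expect_equal(r$p, 2 / choose(10, 5), tolerance = 1e-12)
  # no association possible
  expect_warning(r0 <- fisher_exact_2x2(rbind(c(0, 10), c(0, 10))),
                 "degenerate")
  expect_identical(r0$p, 1)
  # probabilities over the enumeration sum to 1
  tab <- rbind(c(8, 11), c(1, 12))
  r1 <- fisher_exact_2x2(tab)
  expect_equal(r1$p_less + r1$p_greater,
               1 + exp(lchoose(19, 8) + lchoose(13, 9 - 8) -
                         lchoose(32, 9)), tolerance = 1e-9)
  # invariance under transposition
  expect_equal(fisher_exact_2x2(t(tab))$p, r1$p, tolerance = 1e-12)
})

test_that("fisher_exact_2x2 equals the factorial oracle and fisher.test", {
  # exhaustive over all 2x2 tables with total <= 40; aggregate the
  # worst deviation so the sweep stays cheap
  worst <- 0
  for (n in 1:40) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 ||
          (b + d) == 0) next
      p <- fisher_exact_2x2(a, b, cc, d)
      worst <- max(worst, abs(p$p - oracle_fisher(a, b, cc, d)))
    }
  }
  expect_lt(worst, 1e-9)
  # spot cross-check against the reference implementation
  set.seed(11)
  for (i in 1:50) {
    m <- matrix(sample(0:30, 4, replace = TRUE), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact_2x2(m)$p, fisher.test(m)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("log t-test applies the half-minimum out-of-range rule", {
  # detected minimum 0.78 -> replacement 0.39
  a <- c(0.78, 2.1, 5.0, NA)
  b <- c(1.2, 3.3, NA, NA)
  r <- log_ttest(a, b)
  expect_equal(r$replacement, 0.39, tolerance = 1e-12)
  # equals the plain t-test on log10 after manual replacement
  a2 <- a; a2[is.na(a2)] <- 0.39
  b2 <- b; b2[is.na(b2)] <- 0.39
  ref <- t.test(log10(a2), log10(b2), var.equal = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  # no non-detects: reduces to the plain log10 t-test
  r2 <- log_ttest(c(1, 2, 4), c(2, 5, 9))
  ref2 <- t.test(log10(c(1, 2, 4)), log10(c(2, 5, 9)), var.equal = TRUE)
  expect_equal(r2$t, unname(ref2$statistic), tolerance = 1e-12)
  expect_true(is.na(r2$replacement))
  expect_error(log_ttest(c(NA_real_, NA), c(NA_real_, NA)), "undefined")
})

test_that("plain t-test matches the pooled-variance formula", {
  expect_identical(plain_ttest(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_identical(plain_ttest(c(2, 2), c(2, 2))$p, 1)
  d <- plain_ttest(c(2, 2), c(3, 3))
  expect_true(d$degenerate)
  expect_identical(d$p, 0)
  set.seed(19)
  for (i in 1:20) {
    x <- rnorm(sample(3:10, 1), sd = 2)
    y <- rnorm(sample(3:10, 1), mean = 1)
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    tman <- (mean(x) - mean(y)) /
      (sp * sqrt(1 / length(x) + 1 / length(y)))
    expect_equal(plain_ttest(x, y)$t, tman, tolerance = 1e-10)
  }
})

test_that("imaging concordance counts expected positives literally", {
  # PD, PR and SD expect ctDNA positive; CR expects negative
  im <- c(rep("PD", 4), rep("CR", 5))
  cls <- c("positive", rep("negative", 3), rep("negative", 5))
  r <- imaging_concordance(im, cls)
  expect_equal(r$sensitivity, 25)
  expect_equal(r$specificity, 100)
  # all CR and negative: specificity 100, sensitivity undefined
  r2 <- imaging_concordance(rep("CR", 3), rep("negative", 3))
  expect_true(is.na(r2$sensitivity))
  expect_equal(r2$specificity, 100)
  expect_error(imaging_concordance("XX", "negative"), "unknown imaging")
  # random cohorts match a brute-force recount
  set.seed(29)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    im <- sample(c("CR", "PR", "SD", "PD"), n, replace = TRUE)
    cls <- sample(c("positive", "negative", "negative_low_input"), n,
                  replace = TRUE)
    r <- imaging_concordance(im, cls)
    ep <- im != "CR"
    sens <- if (any(ep)) 100 * sum(cls == "positive" & ep) / sum(ep)
            else NA_real_
    spec <- if (any(!ep)) 100 * sum(cls != "positive" & !ep) / sum(!ep)
            else NA_real_
    expect_equal(r$sensitivity, sens)
    expect_equal(r$specificity, spec)
  }
})

test_that("cohort statistics assemble the risk-group association", {
  # synthetic cohort shaped like a 32-patient study: 19 high-risk with
  # 8 ever-positive, 13 other with 1 ever-positive
  mk <- function(pid) sample_result(paste0(pid, "_s1"), pid,
                                    "presurgery",
                                    umivar:::empty_calls(), 1000L)
  samples <- list()
  patients <- data.frame()
  k <- 0
  for (i in 1:19) {
    k <- k + 1
    pid <- sprintf("H%02d", i)
    cls <- if (i <= 8) "positive" else "negative"
    s <- mk(pid); s$classification <- cls
    samples[[k]] <- s
    patients <- rbind(patients, data.frame(
      patient_id = pid, risk_group = "high",
      ki67_percent = if (cls == "positive") 12 else 5,
      tumor_size_cm = if (cls == "positive") 14 else 8))
  }
  for (i in 1:13) {
    k <- k + 1
    pid <- sprintf("O%02d", i)
    cls <- if (i == 1) "positive" else "negative"
    s <- mk(pid); s$classification <- cls
    samples[[k]] <- s
    patients <- rbind(patients, data.frame(
      patient_id = pid,
      risk_group = if (i <= 6) "intermediate" else "very_low_low",
      ki67_percent = 4, tumor_size_cm = 5))
  }
  ct <- cohort_table(samples)
  expect_identical(nrow(ct), 32L)
  st <- cohort_stats(ct, patients)
  expect_identical(unname(st$risk_table["high", "positive"]), 8L)
  expect_identical(unname(st$risk_table["other", "negative"]), 12L)
  expect_lt(st$fisher$p, 0.05)
  expect_lt(st$size_test$p, 0.05)
})
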