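# Build a pileup-like sample for one assay with n_mut mutant consensus
# reads of a given variant and n_wt wild-type reads.
mock_pileups <- function(panel, vid_idx, n_mut, n_wt) {
  tv <- panel$variants[[vid_idx]]
  a <- panel$assays[[tv$assay_id]]
  seqs <- c(rep(apply_variant(a$amplicon_seq, tv), n_mut),
            rep(a$amplicon_seq, n_wt))
  pus <- lapply(panel$assays, function(x)
    build_pileup(if (x$assay_id == a$assay_id) seqs else character(0), x))
  pus
}

test_that("SNV and indel thresholds behave exactly at the boundaries", {
  p <- example_panel()
  # SNV sweep over n_mut = 0..10: called only from 7 ("more than six")
  for (nm in 0:10) {
    calls <- call_sample_variants(mock_pileups(p, 2L, nm, 1000L - nm), p)
    got <- calls[variant_id == variant_id(p$variants[[2]])]
    expect_identical(got$n_mut, nm)
    expect_identical(got$status,
                     if (nm >= 7) "called"
                     else if (nm >= 1) "provisional" else "absent")
  }
  # indel sweep: called from a single consensus read
  for (nm in 0:10) {
    calls <- call_sample_variants(mock_pileups(p, 1L, nm, 1000L - nm), p)
    got <- calls[variant_id == variant_id(p$variants[[1]])]
    expect_identical(got$status, if (nm >= 1) "called" else "absent")
  }
})

test_that("MAF is the percent of covering consensus reads", {
  p <- example_panel()
  calls <- call_sample_variants(mock_pileups(p, 2L, 7L, 993L), p)
  got <- calls[variant_id == variant_id(p$variants[[2]])]
  expect_identical(got$n_total, 1000L)
  expect_equal(got$maf, 0.7)
  # no coverage: absent with a flag, MAF undefined
  empty <- lapply(p$assays, function(a) build_pileup(character(0), a))
  calls <- call_sample_variants(empty, p)
  expect_true(all(calls$status == "absent"))
  expect_true(all(calls$flags == "no_coverage"))
  expect_true(all(is.na(calls$maf)))
})

test_that("the cross-sample rescue rule upgrades anchored provisionals", {
  p <- example_panel()
  vid <- variant_id(p$variants[[2]])
  mk <- function(id, nm) {
    sample_result(id, "P01", "presurgery",
                  call_sample_variants(mock_pileups(p, 2L, nm, 500L), p),
                  molecule_count = 500L)
  }
  # 3-read provisional + 8-read anchor in another sample -> rescued
  out <- rescue_provisional(list(mk("S1", 3L), mk("S2", 8L)))
  expect_identical(out[[1]]$calls[variant_id == vid]$status, "rescued")
  expect_identical(out[[1]]$classification, "positive")
  expect_identical(out[[2]]$classification, "positive")
  # literal "at least six": a 6-read anchor rescues
  out <- rescue_provisional(list(mk("S1", 3L), mk("S2", 6L)))
  expect_identical(out[[1]]$calls[variant_id == vid]$status, "rescued")
  # a 5-read anchor does not
  out <- rescue_provisional(list(mk("S1", 3L), mk("S2", 5L)))
  expect_identical(out[[1]]$calls[variant_id == vid]$status,
                   "provisional")
  expect_identical(out[[1]]$classification, "negative")
  # single-sample patient: provisional stays provisional
  out <- rescue_provisional(list(mk("S1", 3L)))
  expect_identical(out[[1]]$calls[variant_id == vid]$status,
                   "provisional")
  # a sample cannot anchor itself
  out <- rescue_provisional(list(mk("S1", 3L)))
  expect_identical(out[[1]]$classification, "negative")
})

test_that("sample classification follows calls then the 50-molecule rule", {
  p <- example_panel()
  called <- call_sample_variants(mock_pileups(p, 1L, 2L, 998L), p)
  expect_identical(classify_sample(called, 1000L), "positive")
  none <- call_sample_variants(mock_pileups(p, 1L, 0L, 100L), p)
  expect_identical(classify_sample(none, 49L), "negative_low_input")
  expect_identical(classify_sample(none, 50L), "negative")
  # secondary variants never drive positivity
  amp <- p$assays$KIT_11$amplicon_seq
  sec <- target_variant("KIT_11", 40L, substr(amp, 41L, 41L),
                        setdiff(c("A", "C", "G", "T"),
                                substr(amp, 41L, 41L))[1],
                        "secondary", amplicon_seq = amp)
  p2 <- patient_panel("P01", p$assays,
                      c(p$variants, list(sec)), validate = FALSE)
  a <- p$assays$KIT_11
  seqs <- c(rep(apply_variant(amp, sec), 50), rep(amp, 450))
  pus <- lapply(p2$assays, function(x)
    build_pileup(if (x$assay_id == "KIT_11") seqs else character(0), x))
  calls <- call_sample_variants(pus, p2)
  got <- calls[variant_id == variant_id(sec)]
  expect_identical(got$status, "called")
  expect_identical(got$label, "secondary")
  expect_identical(classify_sample(calls, 500L), "negative")
})

test_that("a called resistance mutation makes the sample positive", {
  p <- example_panel()
  calls <- call_sample_variants(mock_pileups(p, 3L, 10L, 990L), p)
  expect_identical(classify_sample(calls, 1000L), "positive")
})

test_that("novel in-window events are reported but never drive positivity", {
  p <- example_panel()
  a <- p$assays$KIT_13
  amp <- a$amplicon_seq
  q <- 45L  # inside KIT_13 window, not the panel SNV at 36
  s <- amp
  substr(s, q + 1L, q + 1L) <- setdiff(c("A", "C", "G", "T"),
                                       substr(amp, q + 1L, q + 1L))[1]
  pus <- lapply(p$assays, function(x)
    build_pileup(if (x$assay_id == "KIT_13") c(rep(s, 10), rep(amp, 90))
                 else character(0), x))
  calls <- call_sample_variants(pus, p)
  nov <- calls[label == "novel"]
  expect_identical(nrow(nov), 1L)
  expect_identical(nov$pos, q)
  expect_identical(nov$status, "called")
  expect_identical(classify_sample(calls, 100L), "negative")
})

test_that("end-to-end sample call recovers a 1% deletion MAF", {
  p <- example_panel()
  sim <- simulate_sample(p, sim_spec(molecules = c(KIT_11 = 2000L),
                                     maf = c(KIT_11 = 0.01), seed = 31L))
  res <- call_sample(sim, p, sample_id = "S1")
  got <- res$calls[label == "tumor_specific"]
  expect_identical(got$status, "called")
  expect_identical(res$classification, "positive")
  # estimated MAF near the realized molecular MAF
  realized <- sim$truth[variant_id == got$variant_id]$realized_maf_pct
  expect_lt(abs(got$maf - realized), 0.75)
})

test_that("VCF output is spec-conformant and round-trips key fields", {
  skip_if_not_installed("vcfR")
  p <- example_panel()
  sim <- simulate_sample(p, sim_spec(molecules = c(KIT_11 = 1500L),
                                     maf = c(KIT_11 = 0.02), seed = 41L))
  res <- call_sample(sim, p, sample_id = "S1")
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(res, p, f)
  v <- vcfR::read.vcfR(f, verbose = FALSE)
  fix <- as.data.frame(v@fix)
  expect_identical(nrow(fix), nrow(res$calls[status != "absent"]))
  tv <- p$variants[[1]]
  # deletion at 0-based pos 34 -> POS = 34 (1-based left anchor)
  expect_identical(as.integer(fix$POS[1]), tv$pos)
  amp <- p$assays$KIT_11$amplicon_seq
  anchor <- substr(amp, tv$pos, tv$pos)
  expect_identical(fix$REF[1], paste0(anchor, tv$ref))
  expect_identical(fix$ALT[1], anchor)
  info <- vcfR::extract.info(v, "NMUT")
  expect_identical(as.integer(info[1]),
                   res$calls[label == "tumor_specific"]$n_mut)
  # sample with no calls: header-only VCF
  res0 <- call_sample(character(0), p, sample_id = "S0")
  f0 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(res0, p, f0)
  v0 <- vcfR::read.vcfR(f0, verbose = FALSE)
  expect_identical(nrow(v0@fix), 0L)
})
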