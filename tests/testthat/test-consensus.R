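make_reads <- function(p, ...) simulate_sample(p, sim_spec(...))$reads

test_that("demultiplexing assigns by primer and reports failure reasons", {
  p <- example_panel()
  umi <- strrep("A", 12)
  a <- p$assays$KIT_11
  r_exact <- paste0(umi, a$amplicon_seq)
  # two mismatches in the primer region still assign; three do not
  mut2 <- a$amplicon_seq
  substr(mut2, 1, 1) <- "T"; substr(mut2, 3, 3) <- "A"
  mut3 <- mut2
  substr(mut3, 5, 5) <- "G"
  reads <- c(r1 = r_exact, r2 = paste0(umi, mut2),
             r3 = paste0(umi, mut3), r4 = substr(r_exact, 1, 20))
  out <- demultiplex_reads(reads, p)
  expect_identical(out$assay_id, c("KIT_11", "KIT_11", NA, NA))
  expect_identical(out$n_primer_mismatches[1:2], c(0L, 2L))
  expect_identical(out$reason, c("assigned", "assigned",
                                 "no_primer_match", "too_short"))
  expect_identical(out$umi[1], umi)
  expect_identical(out$insert[1], a$amplicon_seq)
})

test_that("simulated reads at low error rate assign to the true assay", {
  p <- example_panel()
  sim <- simulate_sample(p, sim_spec(molecules = 100L, e_sub = 0.001,
                                     seed = 9L))
  out <- demultiplex_reads(sim$reads, p)
  expect_gte(mean(out$reason == "assigned"), 0.99)
  # spot-check truth: umi -> assay from the manifest
  key <- setNames(sim$manifest$assay_id, sim$manifest$umi)
  asg <- out[!is.na(out$assay_id)]
  expect_true(all(asg$assay_id == key[asg$umi]))
})

test_that("families partition assigned reads on exact (assay, UMI) keys", {
  p <- example_panel()
  umi_a <- strrep("A", 12); umi_b <- strrep("C", 12)
  amp1 <- p$assays$KIT_11$amplicon_seq
  amp2 <- p$assays$KIT_13$amplicon_seq
  reads <- c(rep(paste0(umi_a, amp1), 3), rep(paste0(umi_b, amp1), 2),
             paste0(umi_a, amp2))
  names(reads) <- sprintf("r%d", seq_along(reads))
  fams <- group_families(demultiplex_reads(reads, p))
  expect_identical(sort(attr(fams, "sizes")), c(1L, 2L, 3L))
  # same UMI on two assays -> distinct families
  expect_identical(length(attr(fams, "sizes")), 3L)
  # conservation
  expect_identical(attr(fams, "n_unassigned") + sum(attr(fams, "sizes")),
                   length(reads))
  # family count equals manifest molecules when no UMI collisions
  sim <- simulate_sample(p, sim_spec(molecules = 500L, seed = 4L))
  f2 <- group_families(demultiplex_reads(sim$reads, p))
  n_distinct <- nrow(unique(sim$manifest[, c("assay_id", "umi")]))
  expect_identical(length(attr(f2, "sizes")), n_distinct)
})

test_that("mean family size averages over all families, however small", {
  expect_identical(mean_family_size(c(3L, 7L, 11L)), 7)
  expect_identical(mean_family_size(c(2L, 2L, 2L)), 2)
  expect_error(mean_family_size(integer(0)), "undefined")
})

test_that("consensus requires three reads and votes per column", {
  amp <- example_panel()$assays$KIT_11$amplicon_seq
  expect_null(build_consensus(rep(amp, 2)))
  expect_identical(build_consensus(rep(amp, 3)), amp)
  # 10 reads, one with a substitution: 9/10 majority wins everywhere
  mut <- amp; substr(mut, 40, 40) <- setdiff(c("A","C","G","T"),
                                             substr(amp, 40, 40))[1]
  expect_identical(build_consensus(c(rep(amp, 9), mut)), amp)
  # 2 errors in a 10-read column -> below 0.9 agreement -> N
  cons <- build_consensus(c(rep(amp, 8), mut, mut))
  expect_identical(substr(cons, 40, 40), "N")
  # 50/50 ties always emit N
  other <- amp; substr(other, 40, 40) <- substr(mut, 40, 40)
  cons <- build_consensus(c(rep(amp, 2), rep(other, 2)),
                          min_agreement = 0.5)
  expect_identical(substr(cons, 40, 40), "N")
})

test_that("consensus equals the per-column majority oracle on random families", {
  set.seed(42)
  for (i in 1:1000) {
    L <- sample(20:60, 1)
    tmpl <- random_dna(L)
    n <- sample(3:12, 1)
    reads <- vapply(seq_len(n), function(j) {
      s <- tmpl
      k <- rbinom(1, L, 0.05)
      if (k > 0) {
        pos <- sample.int(L, k)
        for (q in pos)
          substr(s, q, q) <- sample(c("A", "C", "G", "T"), 1)
      }
      s
    }, "")
    expect_identical(build_consensus(reads), oracle_consensus(reads))
  }
})

test_that("length-discordant reads vote on aligned columns", {
  amp <- example_panel()$assays$KIT_11$amplicon_seq
  # one read with a deleted base still yields the clean majority
  del1 <- paste0(substr(amp, 1, 39), substr(amp, 41, nchar(amp)))
  expect_identical(build_consensus(c(rep(amp, 9), del1)), amp)
  # all reads carrying the same deletion yield the deleted sequence
  expect_identical(build_consensus(rep(del1, 5)), del1)
})

test_that("raising min_reads never increases consensus output", {
  p <- example_panel()
  sim <- simulate_sample(p, sim_spec(molecules = 300L, fs_mu = 4,
                                     seed = 12L))
  fams <- group_families(demultiplex_reads(sim$reads, p))
  n_prev <- Inf
  for (mr in 1:6) {
    n <- nrow(build_consensus_set(fams, min_reads = mr))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("consensus output is independent of read input order", {
  p <- example_panel()
  sim <- simulate_sample(p, sim_spec(molecules = 200L, seed = 13L))
  fams1 <- group_families(demultiplex_reads(sim$reads, p))
  set.seed(1)
  fams2 <- group_families(
    demultiplex_reads(sim$reads[sample.int(length(sim$reads))], p))
  c1 <- build_consensus_set(fams1)
  c2 <- build_consensus_set(fams2)
  data.table::setkey(c1, assay_id, umi)
  data.table::setkey(c2, assay_id, umi)
  expect_identical(c1$consensus, c2$consensus)
})

test_that("consensus suppresses raw errors below 1e-4 wrong bases", {
  # raw per-base error 0.5%, family size 10, >= 1e5 consensus positions;
  # N columns are abstentions excluded from calling and from this rate
  p <- example_panel()
  amp <- p$assays$KIT_11$amplicon_seq
  set.seed(99)
  n_fam <- 1300L
  reads <- character(n_fam * 10L)
  for (f in seq_len(n_fam)) {
    for (j in 1:10) {
      s <- amp
      k <- rbinom(1, nchar(s), 0.005)
      if (k > 0) {
        pos <- sample.int(nchar(s), k)
        for (q in pos)
          substr(s, q, q) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(s, q, q)), 1)
      }
      reads[(f - 1) * 10 + j] <- s
    }
  }
  cons <- build_consensus_set(
    structure(data.table::data.table(
      assay_id = "KIT_11",
      umi = rep(sprintf("u%04d", seq_len(n_fam)), each = 10L),
      insert = reads,
      fam = rep(seq_len(n_fam), each = 10L)),
      class = c("umivar_families", "data.table", "data.frame")))
  expect_identical(nrow(cons), n_fam)
  total_pos <- 0L; wrong <- 0L
  for (i in seq_len(n_fam)) {
    cs <- strsplit(cons$consensus[i], "")[[1]]
    as <- strsplit(amp, "")[[1]]
    expect_length(cs, length(as))
    keep <- cs != "N"
    total_pos <- total_pos + sum(keep)
    wrong <- wrong + sum(cs[keep] != as[keep])
  }
  expect_gte(total_pos, 1e5)
  expect_lt(wrong / total_pos, 1e-4)
})
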