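#' Simulation specification for a UMI-tagged amplicon library
#'
#' Describes one sample's library at the molecule level: how many cfDNA
#' molecules enter per assay, the mutant allele frequency of each panel
#' variant, spike-in molecules per assay, the UMI length, the read
#' family-size distribution (zero-truncated negative binomial whose
#' *truncated* mean is `fs_mu`), and per-base sequencing error rates.
#'
#' @param molecules integer molecules per assay: a scalar (recycled over
#'   assays) or a named vector by assay id. Assays absent from a named
#'   vector receive 0 molecules.
#' @param maf named numeric vector of mutant allele fractions in
#'   `[0, 1]`, named by variant id (see [variant_id()]) or by assay id
#'   when that assay carries a single panel variant. Defaults to 0 for
#'   all variants.
#' @param spikein named integer vector of spike-in molecule counts per
#'   assay (deterministic, not sampled); default none.
#' @param umi_length UMI length in nt (default 12).
#' @param fs_mu mean reads per UMI family after zero truncation
#'   (default 20; values below 7 emulate undersequenced libraries).
#' @param fs_k negative binomial dispersion (default 2).
#' @param e_sub per-base substitution error rate (default 0.001).
#' @param e_indel per-base indel error rate (default 1e-4).
#' @param umi_error_rate per-base substitution rate inside the UMI
#'   (default 0: family identity exact).
#' @param seed integer RNG seed; identical (panel, spec) with the same
#'   seed reproduce byte-identical output.
#' @return object of class `umivar_simspec`.
#' @export
sim_spec <- function(molecules = 1000L, maf = numeric(0),
                     spikein = integer(0), umi_length = 12L,
                     fs_mu = 20, fs_k = 2, e_sub = 0.001, e_indel = 1e-4,
                     umi_error_rate = 0, seed = 1L) {
  stopifnot(all(molecules >= 0), umi_length >= 4L, fs_mu >= 1, fs_k > 0)
  if (length(maf) && (any(maf < 0) || any(maf > 1)))
    stop("maf must lie in [0, 1]")
  if (e_sub < 0 || e_sub > 0.1 || e_indel < 0 || e_indel > 0.1)
    stop("error rates must lie in [0, 0.1]")
  if (length(spikein) && any(spikein < 0))
    stop("spike-in counts must be >= 0")
  structure(list(
    molecules = molecules, maf = maf, spikein = spikein,
    umi_length = as.integer(umi_length), fs_mu = fs_mu, fs_k = fs_k,
    e_sub = e_sub, e_indel = e_indel, umi_error_rate = umi_error_rate,
    seed = as.integer(seed)
  ), class = "umivar_simspec")
}

# Underlying (untruncated) NB mean m such that the zero-truncated
# NB(size = k, mu = m) has mean mu_target: mu_target = m / (1 - P0(m)).
ztnb_base_mean <- function(mu_target, k) {
  if (mu_target <= 1) return(1e-8)
  f <- function(m) m / (1 - (k / (k + m))^k) - mu_target
  uniroot(f, c(1e-8, mu_target), tol = 1e-10)$root
}

# n draws from the zero-truncated NB with truncated mean mu, dispersion k
rztnb <- function(n, mu, k) {
  m <- ztnb_base_mean(mu, k)
  x <- rnbinom(n, size = k, mu = m)
  while (any(x == 0L)) {
    i <- which(x == 0L)
    x[i] <- rnbinom(length(i), size = k, mu = m)
  }
  as.integer(x)
}

random_umis <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Apply iid substitution and indel errors per read (vectorized over the
# error-free majority; only reads drawing >= 1 error are edited).
mutate_reads <- function(seqs, e_sub, e_indel) {
  n <- length(seqs)
  if (n == 0L) return(seqs)
  L <- nchar(seqs)
  if (e_sub > 0) {
    nerr <- rbinom(n, L, e_sub)
    idx <- which(nerr > 0L)
    bases <- c("A", "C", "G", "T")
    for (i in idx) {
      s <- strsplit(seqs[i], "")[[1]]
      p <- sample.int(length(s), nerr[i])
      for (j in p) s[j] <- sample(setdiff(bases, s[j]), 1L)
      seqs[i] <- paste(s, collapse = "")
    }
  }
  if (e_indel > 0) {
    nind <- rbinom(n, L + 1L, e_indel)
    idx <- which(nind > 0L)
    bases <- c("A", "C", "G", "T")
    for (i in idx) {
      for (k in seq_len(nind[i])) {
        s <- strsplit(seqs[i], "")[[1]]
        if (runif(1) < 0.5 || length(s) < 2L) {  # insertion
          p <- sample.int(length(s) + 1L, 1L)
          s <- append(s, sample(bases, 1L), after = p - 1L)
        } else {                                  # deletion
          p <- sample.int(length(s), 1L)
          s <- s[-p]
        }
        seqs[i] <- paste(s, collapse = "")
      }
    }
  }
  seqs
}

#' Simulate one UMI-tagged amplicon sample with ground truth
#'
#' Emulates the molecule-to-read structure of a UMI-barcoded amplicon
#' library: per assay, `molecules` cfDNA molecules are drawn, each
#' assigned a uniform random UMI; mutant molecules (binomially realized
#' from each variant's MAF via a multinomial draw per assay) carry the
#' variant haplotype; spike-in molecules carry the ATG-insertion
#' sequence. Every molecule is amplified into a read family whose size
#' follows the zero-truncated negative binomial, and each read is the
#' UMI followed by the molecule sequence with iid substitution/indel
#' errors applied outside the UMI. Output is deterministic given the
#' spec's seed.
#'
#' @param panel a [patient_panel()].
#' @param spec a [sim_spec()].
#' @return object of class `umivar_sim`: list with `reads` (named
#'   character vector, already shuffled), `manifest` (one row per
#'   molecule: `mol_id`, `assay_id`, `umi`, `is_mutant`, `is_spikein`,
#'   `variant_id`, `family_size`, `true_sequence`), `truth` (per-variant
#'   realized mutant counts and MAF), and the `spec`.
#' @export
simulate_sample <- function(panel, spec) {
  stopifnot(inherits(panel, "umivar_panel"), inherits(spec, "umivar_simspec"))
  set.seed(spec$seed)
  aids <- names(panel$assays)
  nmol <- spec$molecules
  if (is.null(names(nmol))) {
    nmol <- setNames(rep(as.integer(nmol), length.out = length(aids)), aids)
  } else {
    nmol <- setNames(as.integer(nmol[aids]), aids)
    nmol[is.na(nmol)] <- 0L
  }
  spike <- setNames(integer(length(aids)), aids)
  if (length(spec$spikein)) {
    spike[names(spec$spikein)] <- as.integer(spec$spikein)
  }
  # map maf names: variant_id or assay_id (when unique per assay)
  vids <- vapply(panel$variants, variant_id, "")
  vassay <- vapply(panel$variants, `[[`, "", "assay_id")
  vmaf <- setNames(numeric(length(vids)), vids)
  if (length(spec$maf)) {
    for (nm in names(spec$maf)) {
      if (nm %in% vids) {
        vmaf[nm] <- spec$maf[[nm]]
      } else if (nm %in% vassay) {
        hit <- which(vassay == nm)
        if (length(hit) != 1L)
          stop("maf name '", nm, "' is ambiguous: assay has ",
               length(hit), " panel variants")
        vmaf[hit] <- spec$maf[[nm]]
      } else {
        stop("maf name '", nm, "' matches no panel variant or assay")
      }
    }
  }

  mols <- vector("list", length(aids))
  for (ai in seq_along(aids)) {
    aid <- aids[ai]
    a <- panel$assays[[aid]]
    n <- nmol[[aid]]
    vhit <- which(vassay == aid & vmaf[vids] >= 0)
    mafs <- vmaf[vids[vhit]]
    # multinomial split of molecules into wild-type / each variant
    if (n > 0L && length(vhit) && sum(mafs) > 0) {
      cnt <- as.integer(rmultinom(1L, n, c(1 - sum(mafs), mafs)))
    } else {
      cnt <- c(n, rep(0L, length(vhit)))
    }
    seqs <- c(a$amplicon_seq,
              vapply(panel$variants[vhit], function(v)
                apply_variant(a$amplicon_seq, v), ""))
    vid_of <- c(NA_character_, vids[vhit])
    mt <- data.table::data.table(
      assay_id = aid,
      true_sequence = rep(seqs, cnt),
      variant_id = rep(vid_of, cnt),
      is_mutant = rep(c(FALSE, rep(TRUE, length(vhit))), cnt),
      is_spikein = FALSE
    )
    mols[[ai]] <- mt
  }
  manifest <- data.table::rbindlist(mols)
  # spike-in molecules: deterministic count per assay, appended last
  spk <- lapply(aids[spike > 0L], function(aid) {
    data.table::data.table(
      assay_id = aid,
      true_sequence = make_spikein_sequence(panel$assays[[aid]]),
      variant_id = NA_character_,
      is_mutant = FALSE,
      is_spikein = TRUE
    )[rep(1L, spike[[aid]])]
  })
  if (length(spk))
    manifest <- rbind(manifest, data.table::rbindlist(spk), use.names = TRUE)

  ntot <- nrow(manifest)
  if (ntot == 0L) {
    warning("no molecules simulated for any assay: emitting empty output")
    empty <- manifest[, c("assay_id", "true_sequence", "variant_id",
                          "is_mutant", "is_spikein")]
    empty[, `:=`(mol_id = character(0), umi = character(0),
                 family_size = integer(0))]
    return(structure(list(reads = character(0), manifest = empty,
                          truth = NULL, spec = spec,
                          patient_id = panel$patient_id),
                     class = "umivar_sim"))
  }
  manifest[, mol_id := sprintf("m%06d", seq_len(.N))]
  manifest[, umi := random_umis(.N, spec$umi_length)]
  manifest[, family_size := rztnb(.N, spec$fs_mu, spec$fs_k)]

  # expand molecules into reads
  ridx <- rep(seq_len(ntot), manifest$family_size)
  seqs <- manifest$true_sequence[ridx]
  seqs <- mutate_reads(seqs, spec$e_sub, spec$e_indel)
  umis <- manifest$umi[ridx]
  if (spec$umi_error_rate > 0)
    umis <- mutate_reads(umis, spec$umi_error_rate, 0)
  reads <- paste0(umis, seqs)
  names(reads) <- sprintf("r%07d", seq_along(reads))
  reads <- reads[sample.int(length(reads))]

  truth <- manifest[is_mutant == TRUE, .(n_mutant = .N), by = variant_id]
  truth <- merge(
    data.table::data.table(variant_id = vids,
                           assay_id = vassay,
                           n_molecules = as.integer(nmol[vassay])),
    truth, by = "variant_id", all.x = TRUE)
  truth[is.na(n_mutant), n_mutant := 0L]
  truth[, true_maf_pct := 100 * vmaf[variant_id]]
  truth[, realized_maf_pct := 100 * n_mutant / pmax(n_molecules, 1L)]

  structure(list(reads = reads, manifest = manifest, truth = truth,
                 spec = spec, patient_id = panel$patient_id),
            class = "umivar_sim")
}

#' @export
print.umivar_sim <- function(x, ...) {
  cat(sprintf("Simulated sample: %d molecules, %d reads\n",
              nrow(x$manifest), length(x$reads)))
  if (!is.null(x$truth) && nrow(x$truth))
    print(x$truth[, c("variant_id", "n_mutant", "true_maf_pct")])
  invisible(x)
}

#' Write a simulated sample to disk
#'
#' @param sim a [simulate_sample()] result.
#' @param fastq_path output FASTQ path.
#' @param manifest_path output TSV path for the truth manifest.
#' @return invisibly, a list of the two paths.
#' @export
write_sim <- function(sim, fastq_path, manifest_path) {
  write_fastq(sim$reads, fastq_path)
  data.table::fwrite(sim$manifest, manifest_path, sep = "\t")
  invisible(list(fastq = fastq_path, manifest = manifest_path))
}

#' Simulate qPCR quality-control measurements
#'
#' Generates a human genomic DNA standard curve at 10 ng with threefold
#' dilution steps down to 0.37 ng (Cq = intercept + slope * log10(q)
#' plus Gaussian noise), a short-amplicon cfDNA quantity, a
#' long-amplicon quantity (cellular-DNA surrogate) equal to
#' `contamination_fraction` times the short quantity, and an inhibition
#' control Cq shifted by `inhibition_shift` cycles above the reference.
#'
#' @param contamination_fraction fraction in `[0, 1]` of cellular DNA.
#' @param inhibition_shift Cq shift (cycles) of the inhibition control.
#' @param cfdna_ng short-amplicon cfDNA quantity (ng) of the sample.
#' @param slope standard-curve slope (default -1/log10(2) ~ -3.3219,
#'   i.e. 100% PCR efficiency).
#' @param intercept standard-curve intercept (Cq at 1 ng).
#' @param sigma Gaussian Cq noise SD in cycles (default 0.05; 0 gives
#'   the noiseless curve).
#' @param seed RNG seed.
#' @return object of class `umivar_qpcr_sim`: list with `points`
#'   (data.frame quantity/cq), `short_qty`, `long_qty`,
#'   `cq_reference`, `cq_inhibition_control`.
#' @export
simulate_qpcr <- function(contamination_fraction = 0,
                          inhibition_shift = 0, cfdna_ng = 2,
                          slope = -1 / log10(2),
                          intercept = 25, sigma = 0.05, seed = 1L) {
  if (sigma < 0) stop("configuration error: noise sigma must be >= 0")
  if (contamination_fraction < 0 || contamination_fraction > 1)
    stop("contamination_fraction must lie in [0, 1]")
  set.seed(seed)
  q <- 10 / 3^(0:3)
  cq <- intercept + slope * log10(q) + rnorm(length(q), 0, sigma)
  cq_ref <- intercept + rnorm(1, 0, sigma)
  cq_inh <- cq_ref + inhibition_shift + rnorm(1, 0, sigma)
  structure(list(
    points = data.frame(quantity = q, cq = cq),
    short_qty = cfdna_ng,
    long_qty = contamination_fraction * cfdna_ng,
    cq_reference = cq_ref,
    cq_inhibition_control = cq_inh
  ), class = "umivar_qpcr_sim")
}
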