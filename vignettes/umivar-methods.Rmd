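---
title: "Methods: UMI consensus calling of low-frequency ctDNA variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UMI consensus calling of low-frequency ctDNA variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umivar)
```

## The problem

Monitoring circulating tumor DNA (ctDNA) in gastrointestinal stromal
tumor (GIST) patients requires detecting a known tumor-specific
mutation — and a fixed set of tyrosine kinase inhibitor (TKI)
resistance mutations in *KIT* and *PDGFRA* — at mutant allele
frequencies (MAF) well below 0.1% in cell-free DNA (cfDNA). At that
level, raw sequencing error (~0.1–1% per base) swamps the signal.
The remedy implemented here is molecular barcoding: every original
cfDNA molecule receives a random unique molecular identifier (UMI)
before amplification, reads sharing a UMI are collapsed to a consensus,
and variants are then counted in *consensus molecules* rather than
reads. `umivar` implements this decision structure end to end for a
patient-specific 5-plex amplicon panel: one assay carrying the
patient's tumor mutation plus four resistance assays shared across
patients, with amplicons constrained to 65–99 bp because cfDNA is
highly fragmented.

## Pipeline model and decision rules

A read is laid out as `[UMI][forward primer][insert]`. The stages are:

1. **Assay assignment.** The UMI is the first 12 nt (configurable);
   the assay is the unique forward primer at minimal Hamming distance
   (≤ 2 mismatches) from the following bases. Ties and distant reads
   are set aside with a reason code. A closed panel of ≤ 99 bp
   amplicons makes this primer-anchored assignment equivalent to the
   alignment step a genome-wide pipeline would use: the only alignment
   decision is *which amplicon*, so genome alignment is replaced by
   per-amplicon alignment throughout.
2. **Family grouping.** Families are exact-match equivalence classes
   of `(assay, UMI)`. No fuzzy UMI merging is performed — grouping is
   on *identical* identifiers; a configurable `umi_error_rate` in the
   simulator (default 0) exists to probe the cost of that choice.
3. **Consensus.** Families with fewer than 3 reads yield no consensus.
   Otherwise each column takes its majority symbol when the unique
   majority reaches 90% of the family, and `N` otherwise; a winning
   gap deletes the column; 50/50 ties always emit `N` (never a base —
   conservative toward false calls). Reads whose length differs from
   the family's modal length (indel sequencing errors) are pairwise
   aligned to a modal-length anchor before voting; the anchor is the
   lexicographically smallest modal-length read, which makes the
   consensus independent of read input order. Only the family-size
   threshold of 3 is a reference rule; the 90% agreement level and the
   `N` fallback are this package's conventions, exposed as parameters.
4. **Alignment and events.** Each consensus is aligned to its amplicon
   by a semi-global dynamic program (free end gaps; match +1, mismatch
   −1, gap open −2, gap extend −1, a length-L gap costing
   open + ext·(L−1)). Indels are left-normalized afterwards, so a
   variant's identity is the exact tuple `(assay, pos, ref, alt)` in
   0-based amplicon coordinates. `N` columns produce no events and are
   excluded from coverage at that position. Alignments below 70%
   identity, or covering less than half of the shorter sequence, are
   discarded as unalignable (counted, never silently dropped).
5. **Spike-in routing.** Library-construction controls are amplicon
   copies with an `ATG` inserted immediately after the forward
   primer's 3′ end. Their canonical left-normalized insertion event is
   computed per assay; any consensus carrying exactly that event is
   counted as a spike-in and removed from the pileup, so spike-ins can
   never surface as variant calls, and an ATG insertion elsewhere is
   never mistaken for a spike-in.
6. **Calling.** For each panel target (and any other observed event
   inside a target window): a solitary SNV is *called* from more than
   six mutant consensus reads (≥ 7); SNVs seen in 1–6 consensus reads
   are *provisional*; insertions and deletions are called from a
   single consensus read. MAF is reported in percent of consensus
   reads covering the locus; consensus reads with `N` at the target
   position count in neither numerator nor denominator.
7. **Rescue.** A provisional SNV in one sample is upgraded to
   *rescued* when at least one *other* sample of the same patient
   shows the identical normalized variant with at least six consensus
   reads. The wording of the two rules differs by one read (call ≥ 7,
   anchor ≥ 6); both are implemented literally and both thresholds are
   configurable.
8. **Classification.** A sample is *positive* when any tumor-specific
   or resistance target is called or rescued; otherwise
   *negative-low-input* when fewer than 50 cfDNA molecules (consensus
   reads covering the tumor-specific locus) were detected; otherwise
   *negative*. Variants labeled *secondary* (e.g. a recurrent variant
   of unknown relevance) and *novel* non-target events are reported
   but never drive positivity. "Detected cfDNA molecules" is not given
   a locus definition in the reference design; this package uses
   coverage at the tumor-specific position, the locus that governs
   positivity.

## Quality controls

- **Cellular DNA contamination**: long-amplicon (intact DNA) over
  short-amplicon (all cfDNA) qPCR quantity, normalized to a
  nonfragmented genomic DNA reference; strictly more than 5% is
  contaminated. The long/short mechanics are a one-parameter
  convention standing in for the published contamination assay.
- **cfDNA quantification**: least-squares regression of Cq on
  log10(quantity) over a 10 ng → 0.37 ng threefold dilution series of
  genomic DNA; efficiency is `10^(-1/slope) − 1` (slope −3.32 ⇒ 100%).
- **PCR inhibition**: the Cq shift of a spiked inhibition control;
  shifts of ≥ 1 and ≥ 2 cycles mark *inhibited* and *strongly
  inhibited*. The two cut-offs are package conventions (the reference
  workflow reports only the categories), configurable.
- **Spike-in recovery**: counts are median-centered across sequencing
  runs (each run scaled so its median equals the global median of run
  medians); centered counts below 0.25× or above 4× the global median
  flag low/high recovery — again conventions, configurable.
- **Undersequencing**: mean reads per UMI family, over *all* detected
  families, strictly below 7.

## Cohort statistics

Patient-level positivity is "any positive sample". The risk-group
association (high risk vs the other groups combined, ever-positive) is
tested by a two-sided Fisher exact test computed by full hypergeometric
enumeration with the minimum-likelihood two-sided convention (sum of
point probabilities ≤ the observed one, with a 1e-7 relative tie
tolerance). This matches the dominant software convention; the
"doubling" convention would roughly give 0.077 instead of 0.0497 on a
19-patients-8-positive vs 13-patients-1-positive table and is
deliberately not used, since it changes the headline significance.
Group comparisons are equal-variance Student t tests ("Student", not
Welch): Ki-67 on the log10 scale, tumor size untransformed. For
log-scale tests over measurements with non-detects, out-of-range values
are replaced by half the minimum detected value across both groups
(e.g. minimum 0.78 ⇒ 0.39) before the transform; non-detects are an
explicit `NA` sentinel, never 0. Imaging concordance treats progressive,
partial-response and stable disease as expected ctDNA positive and
complete response as expected negative — partial response is kept on
the expected-positive side deliberately, mirroring the clinical rule
this package reproduces; empty denominators report `NA`, not 0.

## The simulator: what it emulates, and what it does not

`simulate_sample()` generates the molecule → UMI → family → read
hierarchy: per assay a fixed number of input molecules; mutant
molecules realized by a multinomial draw at the configured MAF (the
realized count is recorded in the truth manifest); spike-in molecules
at a deterministic count; a uniform random 12-nt UMI per molecule;
family sizes from a zero-truncated negative binomial whose *truncated*
mean is `fs_mu` (default 20, dispersion 2) — the underlying mean is
solved numerically so that the reported mean family size is exactly the
parameter; and iid per-base substitution (default 0.001) and indel
(default 1e-4) errors applied outside the UMI. Everything is
deterministic given the seed.

Defaults are the reference study conditions where stated (family-size
threshold, calling thresholds, 0.001 substitution error for the
detection experiments); where no value is stated, a single realistic
choice was made once: 12-nt UMIs, negative-binomial family sizes with
dispersion 2 (undersequenced libraries are simulated by `fs_mu < 7`),
and an indel error an order of magnitude below the substitution error,
as on Illumina chemistry.

Not modeled: PCR-phase (pre-UMI) errors as distinct from read errors —
a mutation introduced before barcoding would survive consensus, so the
simulator's perfect error suppression at high family sizes is an upper
bound on real performance; realistic quality-score profiles (qualities
are constant); paired-end reads; polymerase-specific error spectra;
UMI collisions are possible (birthday effect over 4^12) but rare and
merge molecules conservatively. Passing tests therefore demonstrate the
correctness of the decision rules and the statistical behavior of the
estimator under the stated error model, not the full error structure of
a sequencing instrument.

## Numerical choices and degenerate inputs

- Alignment tie-breaks prefer the diagonal; indel placement is made
  unique by left-normalization, not by traceback order.
- Same-length consensus/reference pairs with ≤ 3 differences take a
  positional fast path (substitutions only); unique consensus
  sequences are aligned once and weighted by multiplicity.
- Fisher P values use `lchoose` accumulation normalized to sum to 1;
  degenerate margins return P = 1 with a warning.
- Constant-group t tests return t = 0, P = 1 (equal means) or an
  infinite-t flag (unequal means) instead of erroring.
- Zero assigned reads, empty FASTQ, zero-median spike-in runs, and
  uncovered target loci all produce defined, flagged results.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen to keep the full suite in
minutes while leaving the statistical assertions sharp: detection-limit
experiments use 20 replicates of 10,000 molecules per grid MAF
(1%, 0.5%, 0.1%, 0.05%); estimator calibration uses 50 samples of
5,000 molecules at 1% MAF against the exact 99% binomial envelope;
error suppression uses ≥ 1e5 consensus positions at 0.5% raw error;
oracle equivalence sweeps 1,000 random families, amplicon-scale
alignments, and every 2×2 table with total ≤ 40. Patient-level clinical
quantities (cohort positivity rates, sensitivity vs imaging, cfDNA
concentrations) depend on the original plasma samples and are out of
scope; the cohort statistics are instead verified structurally and
against closed forms.

## Known limitations

- Indel calling from a single consensus read is sensitive to any
  indel-generating artifact the consensus stage lets through; the
  reference workflow interposed manual BAM inspection here. The
  automated equivalent is the deterministic caller plus the full event
  pileup for review, and `indel_min` is configurable for stricter use.
- Exact-match UMI grouping splits families when the UMI itself is
  misread, biasing family sizes down slightly at high error rates.
- Amplicon coordinates are the pipeline's reference frame; translating
  calls back to genome coordinates is supported only as a constant
  offset and is untested against a genome build.
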