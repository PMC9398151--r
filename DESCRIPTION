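Package: umivar
Title: UMI Consensus Error Correction and Low-Frequency ctDNA Variant
    Calling for Amplicon Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for monitoring circulating tumor DNA (ctDNA) with
    patient-specific amplicon panels barcoded by unique molecular
    identifiers (UMIs). Includes a ground-truth read simulator for
    UMI-tagged amplicon libraries of cell-free DNA, UMI family grouping
    and consensus construction, a semi-global aligner with left-normalized
    indel representation, variant calling at mutant allele frequencies
    below 0.1 percent using fixed consensus-read thresholds with a
    patient-level cross-sample rescue rule, sample quality controls
    (cellular DNA contamination, PCR inhibition, qPCR standard curves,
    spike-in recovery, undersequencing), and cohort-level statistics
    (exact Fisher association, log-scale t tests with out-of-range
    replacement, imaging concordance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
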