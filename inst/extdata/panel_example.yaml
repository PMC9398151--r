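patient_id: P01
assays:
- assay_id: KIT_11
  gene: KIT
  exon: '11'
  amplicon_seq: CCCTCGGATTCCAGACGGCAGATAAACGACTGGAACCTTTCGGGGGAAGAGTACTTCCCTGTGACCGGTTTAAGTCTTTG
  fwd_primer: CCCTCGGATTCCAGACGG
  rev_primer: GACCGGTTTAAGTCTTTG
  target_window:
  - 18
  - 62
- assay_id: KIT_13
  gene: KIT
  exon: '13'
  amplicon_seq: CCTAATTTAGCCAAGGACAATCGGTGCGCACTTTCTGATGGACCTCCGGCTCCTAACACTAGAATAAGTATG
  fwd_primer: CCTAATTTAGCCAAGGAC
  rev_primer: AACACTAGAATAAGTATG
  target_window:
  - 18
  - 54
- assay_id: KIT_14
  gene: KIT
  exon: '14'
  amplicon_seq: CGCTCCACACCTGAAGGGACGCGGGTACTACTGTACTTTCTTCTAGGGTGTTTTCGGTCCGGCTGAAG
  fwd_primer: CGCTCCACACCTGAAGGG
  rev_primer: TTTTCGGTCCGGCTGAAG
  target_window:
  - 18
  - 50
- assay_id: KIT_17
  gene: KIT
  exon: '17'
  amplicon_seq: TATGGCTCGCGACGTGGATCTAAAGACAATAGACCGATCTTTAAGGTGCTTCCGTTAGCCTAGTAGGGGCTGGTGAAGGGTCCGGCGCGC
  fwd_primer: TATGGCTCGCGACGTGGA
  rev_primer: GTGAAGGGTCCGGCGCGC
  target_window:
  - 18
  - 72
- assay_id: PDGFRA_18
  gene: PDGFRA
  exon: '18'
  amplicon_seq: TGGCTATGATCAGCAAACTTTTCACTGTACAGTGCTAGTGTTAAATGCATCGTGAATAATTTCGGTAGCACCTCCAGTCCTGTA
  fwd_primer: TGGCTATGATCAGCAAAC
  rev_primer: AGCACCTCCAGTCCTGTA
  target_window:
  - 18
  - 66
variants:
- assay_id: KIT_11
  pos: 34
  ref: ACCT
  alt: ''
  label: tumor_specific
- assay_id: KIT_13
  pos: 36
  ref: G
  alt: A
  label: resistance
- assay_id: KIT_14
  pos: 34
  ref: A
  alt: T
  label: resistance
- assay_id: KIT_17
  pos: 45
  ref: G
  alt: T
  label: resistance
- assay_id: PDGFRA_18
  pos: 42
  ref: A
  alt: T
  label: resistance
spikeins:
- assay_id: PDGFRA_18
  expected_count: 50
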