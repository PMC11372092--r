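Package: mosaicSNV
Title: Low-Level Brain Somatic SNV Filtering, Validation and Joint
    Somatic-Germline Gene-Set Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-calling analysis of low-level somatic single-nucleotide
    variants (SNVs) from multi-region deep exome sequencing of brain
    tissue, together with damaging germline variants, in a case-control
    design. Implements the replicate-aware post-call filter cascade
    (paired and unpaired thresholds, multi-region pseudoreplicate rescue,
    barcode-sequencing concordance), exact-binomial validation of
    candidates against substitution-specific amplicon background error
    rates, mutational burden summaries with genome-scale extrapolation,
    merged damaging gene-set construction with Fisher exact risk
    assessment, robust-z spatiotemporal expression signatures over
    stage-by-region windows, permutation gene-set overlap tests, and
    weighted protein-protein interaction degree comparisons. A synthetic
    data module generates cohorts, call sets, amplicon read counts,
    expression tensors and interaction graphs with known ground truth so
    the whole pipeline can be exercised end to end.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
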