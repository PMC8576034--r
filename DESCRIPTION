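Package: hapburden
Title: Haplotype Association and Gene-Level Loss-of-Function Burden
    Analysis for Targeted Case-Control Sequencing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for case-control haplotype analysis of a multi-marker
    locus and for gene-level loss-of-function (LOF) burden testing on
    targeted capture sequencing data.  Provides an expectation-maximisation
    (EM) estimator of haplotype frequencies and per-individual diplotypes
    from unphased genotypes, conversion of diplotypes to biallelic
    haplotype dosages, Pearson chi-square association tests with odds
    ratios and Woolf confidence intervals, haplotype-guided selection of
    samples for sequencing, FASTQ read filtering (adapter, low-quality and
    N-base rules), co-segregation scanning of variants against a target
    haplotype, and a per-gene LOF burden test on allele-observation
    counts.  A synthetic-data generator produces cohorts, variant calls
    and reads with the statistical structure the analysis assumes, so the
    whole pipeline can be exercised and validated without access to
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
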