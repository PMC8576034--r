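#' Published per-gene LOF allele-observation counts at 5q22.1
#'
#' The gene-level loss-of-function allele counts from the targeted
#' capture sequencing of 16 samples (8 atopic-dermatitis cases, 8
#' controls) at 5q22.1: per gene the number of LOF sites and the
#' alternative/reference allele observations per cohort
#' (`alt + ref = 2 x 8 x n_sites` per cohort).  One further printed gene
#' row (LOC100289673) is omitted because its published counts cannot be
#' parsed consistently.
#'
#' @return `data.frame`: `gene`, `n_sites`, `alt_case`, `ref_case`,
#'   `alt_control`, `ref_control`.
#' @export
gene_lof_reference_counts <- function() {
  path <- system.file("extdata", "gene_lof_counts_5q22.tsv",
                      package = "hapburden", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Published cohort frequencies of the 5q22.1 haplotypes
#'
#' Per-cohort frequencies (percent) of the thirteen reported common or
#' significant haplotypes of the 5q22.1 atopic-dermatitis block, with the
#' published labels.  `common` flags the seven haplotypes above the 0.5%
#' frequency threshold.  `allele_string` is the package's synthetic panel
#' encoding (the published allele strings are not machine-recoverable);
#' it is `NA` for the six rare haplotypes, which the default simulation
#' does not carry.
#'
#' @return `data.frame`: `label`, `allele_string`, `freq_case_pct`,
#'   `freq_control_pct`, `common`.
#' @export
haplotype_reference_freqs <- function() {
  path <- system.file("extdata", "haplotype_freqs_5q22.tsv",
                      package = "hapburden", mustWork = TRUE)
  h <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  h$common <- as.logical(h$common)
  h
}
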