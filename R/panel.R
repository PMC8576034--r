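#' Marker panel for a haplotype block
#'
#' A marker panel describes the ordered biallelic variants whose phased
#' alleles make up a haplotype string: one single-character allele per
#' marker, concatenated in genomic order.  Deletion alleles are written
#' `"-"`.
#'
#' @param id Character vector of unique variant identifiers (e.g. rsIDs).
#' @param ref_allele,alt_allele Single-character reference / alternative
#'   alleles; must differ per marker.
#' @param is_indel Logical; `TRUE` for insertion/deletion markers.
#' @param position Strictly increasing 1-based coordinates.
#' @param chrom Chromosome name shared by the whole panel.
#'
#' @return An object of class `marker_panel` (a `data.frame` with columns
#'   `id`, `ref_allele`, `alt_allele`, `is_indel`, `position` and a
#'   `chrom` attribute).
#' @examples
#' marker_panel(c("rs1", "rs2"), c("G", "A"), c("A", "-"),
#'              c(FALSE, TRUE), c(100L, 200L))
#' @export
marker_panel <- function(id, ref_allele, alt_allele, is_indel, position,
                         chrom = "chr5") {
  p <- data.frame(id = as.character(id),
                  ref_allele = as.character(ref_allele),
                  alt_allele = as.character(alt_allele),
                  is_indel = as.logical(is_indel),
                  position = as.integer(position),
                  stringsAsFactors = FALSE)
  if (nrow(p) < 1L) stop_fmt("a marker panel needs at least one marker")
  if (anyDuplicated(p$id)) stop_fmt("marker ids must be unique")
  if (any(nchar(p$ref_allele) != 1L) || any(nchar(p$alt_allele) != 1L))
    stop_fmt("alleles must be single characters ('-' for a deletion)")
  if (any(p$ref_allele == p$alt_allele))
    stop_fmt("ref and alt allele must differ for every marker")
  if (any(diff(p$position) <= 0))
    stop_fmt("marker positions must be strictly increasing")
  attr(p, "chrom") <- chrom
  class(p) <- c("marker_panel", "data.frame")
  p
}

#' Default 10-marker panel for the 5q22.1 atopic-dermatitis haplotype block
#'
#' Four SNPs (rs10067777, rs7701890, rs13360927, rs13361382) and six
#' deletions (rs5870408, rs140764268, rs11357450, rs35639206, rs137936676,
#' rs10617471) in strong linkage disequilibrium on chromosome 5q22.1.
#' Positions and allele letters are synthetic stand-ins (the published
#' genotyping-array exports are not available); the rsIDs and SNP/indel
#' split are the real panel's.
#'
#' @return A [marker_panel()] with 10 markers.
#' @export
default_marker_panel <- function() {
  path <- system.file("extdata", "panel_5q22_synthetic.tsv",
                      package = "hapburden", mustWork = TRUE)
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  marker_panel(p$id, p$ref_allele, p$alt_allele, p$is_indel, p$position,
               chrom = "chr5")
}

# Split a haplotype string into per-marker alleles; validate against panel.
hap_alleles <- function(hap, panel) {
  a <- strsplit(hap, "", fixed = TRUE)[[1L]]
  if (length(a) != nrow(panel))
    stop_fmt("haplotype string '%s' has %d alleles; panel has %d markers",
             hap, length(a), nrow(panel))
  ok <- a == panel$ref_allele | a == panel$alt_allele
  if (!all(ok))
    stop_fmt("haplotype string '%s' has an invalid allele at marker %s",
             hap, panel$id[which(!ok)[1L]])
  a
}

# TRUE iff `hap` is a valid haplotype string over `panel`.
is_valid_hap <- function(hap, panel) {
  !inherits(try(hap_alleles(hap, panel), silent = TRUE), "try-error")
}
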