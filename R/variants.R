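#' Per-site alternative-allele dosages with annotations
#'
#' The container for sequenced variant calls used by the co-segregation
#' scan and the burden test: one row of metadata per site (gene symbol,
#' position, functional category) and a sites-by-samples matrix of
#' alternative-allele dosages in `{0, 1, 2}`.
#'
#' @param sites `data.frame` with columns `site_id` (unique), `gene`,
#'   `position`, `category` (ANNOVAR-style functional class).
#' @param samples `data.frame` with columns `sample_id` (unique) and
#'   `cohort` (`"case"`/`"control"`).
#' @param dosage Integer matrix, `nrow(sites)` x `nrow(samples)`.
#'
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, samples, dosage) {
  sites <- data.frame(site_id = as.character(sites$site_id),
                      gene = as.character(sites$gene),
                      position = as.integer(sites$position),
                      category = as.character(sites$category),
                      stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = as.character(samples$sample_id),
                        cohort = as.character(samples$cohort),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(sites$site_id)) stop_fmt("duplicate site_id")
  if (anyDuplicated(samples$sample_id)) stop_fmt("duplicate sample_id")
  if (!all(samples$cohort %in% c("case", "control")))
    stop_fmt("cohort labels must be 'case' or 'control'")
  if (any(!nzchar(sites$gene))) stop_fmt("empty gene symbol")
  if (any(!nzchar(sites$category))) stop_fmt("empty annotation category")
  dosage <- matrix(as.integer(dosage), nrow(sites), nrow(samples))
  if (anyNA(dosage) || any(dosage < 0L | dosage > 2L))
    stop_fmt("dosages must be defined and in {0,1,2} for every sample x site")
  dimnames(dosage) <- list(sites$site_id, samples$sample_id)
  structure(list(sites = sites, samples = samples, dosage = dosage),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites in %d gene(s), %d samples\n",
              nrow(x$sites), length(unique(x$sites$gene)),
              nrow(x$samples)))
  invisible(x)
}

#' Read sequenced variants (VCF + annotation TSV) into a variant table
#'
#' Parses the `GT` subfield of a biallelic VCF (`0/0` -> dosage 0,
#' `0/1`/`1/0` -> 1, `1/1` -> 2) and joins an ANNOVAR-style annotation
#' table keyed by `site_id` with columns `gene` and `category`.  Sites
#' without an annotation row are dropped with a warning.
#'
#' @param vcf_path Path to a VCF v4.x file (uncompressed or bgzipped).
#' @param annotation_path Path to the annotation TSV
#'   (`site_id`, `gene`, `category`).
#' @param cohorts Cohort labels for the VCF samples: a `data.frame` with
#'   columns `sample_id`, `cohort`, or a path to such a TSV.
#' @return A [variant_table()]; samples in VCF column order.
#' @export
read_variant_table <- function(vcf_path, annotation_path, cohorts) {
  if (!file.exists(vcf_path)) stop_fmt("VCF not found: %s", vcf_path)
  if (!file.exists(annotation_path))
    stop_fmt("annotation table not found: %s", annotation_path)
  if (is.character(cohorts))
    cohorts <- utils::read.delim(cohorts, stringsAsFactors = FALSE)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  alt <- vcfR::getALT(vcf)
  if (any(grepl(",", alt, fixed = TRUE)))
    stop_fmt("multi-allelic site %s: only biallelic sites are supported",
             vcfR::getID(vcf)[grepl(",", alt, fixed = TRUE)][1L])
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L,
                                     dimnames = list(vcfR::getID(vcf), names(gt)))
  vcf_samples <- colnames(gt)
  if (!setequal(vcf_samples, cohorts$sample_id))
    stop_fmt("sample sets of VCF and cohort-label table disagree")
  cohort <- cohorts$cohort[match(vcf_samples, cohorts$sample_id)]
  dosage_map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
                  "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  dos <- matrix(dosage_map[gt], nrow(gt), ncol(gt))
  if (anyNA(dos))
    stop_fmt("unsupported or missing GT value '%s'",
             gt[which(is.na(dos))[1L]])
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  if (!all(c("site_id", "gene", "category") %in% names(ann)))
    stop_fmt("annotation table needs columns site_id, gene, category")
  ids <- vcfR::getID(vcf)
  keep <- ids %in% ann$site_id
  if (!all(keep))
    warn_fmt("dropping %d site(s) with no annotation row: %s",
             sum(!keep), paste(ids[!keep], collapse = ", "))
  if (!any(keep)) stop_fmt("no annotated sites left")
  j <- match(ids[keep], ann$site_id)
  variant_table(
    sites = data.frame(site_id = ids[keep], gene = ann$gene[j],
                       position = vcfR::getPOS(vcf)[keep],
                       category = ann$category[j]),
    samples = data.frame(sample_id = vcf_samples, cohort = cohort),
    dosage = dos[keep, , drop = FALSE])
}

#' Write a variant table as VCF (GT only) plus annotation TSV
#'
#' Emits a minimal plain-text VCF v4.2 with synthetic `REF`/`ALT` letters
#' and unphased `GT` fields derived from the dosages, and the matching
#' annotation table.  [read_variant_table()] on the pair restores the
#' variant table.
#'
#' @param vt A [variant_table()].
#' @param vcf_path,annotation_path Output paths.
#' @param chrom Chromosome name to write.
#' @return `vcf_path`, invisibly.
#' @export
write_variant_table <- function(vt, vcf_path, annotation_path,
                                chrom = "chr5") {
  gt_map <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_map[vt$dosage + 1L], nrow(vt$sites), nrow(vt$samples))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$samples$sample_id), collapse = "\t"))
  body <- vapply(seq_len(nrow(vt$sites)), function(i) {
    paste(c(chrom, vt$sites$position[i], vt$sites$site_id[i], "A", "T",
            ".", "PASS", ".", "GT", gt[i, ]), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), vcf_path)
  utils::write.table(vt$sites[c("site_id", "gene", "category")],
                     annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(vcf_path)
}

#' Write cohort labels as a TSV
#'
#' @param samples `data.frame` with `sample_id`, `cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(samples, path) {
  utils::write.table(samples[c("sample_id", "cohort")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
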