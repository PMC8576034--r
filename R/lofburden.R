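#' Default loss-of-function category set
#'
#' The functional categories counted as LOF in the gene-level burden
#' test: exonic, UTR (3'/5'), splicing and upstream annotations.  This
#' is a deliberately broad, regulatory-inclusive definition (kept
#' configurable in [classify_lof()]); transcript-aware LOF calling is
#' out of scope.
#'
#' @return Character vector of lower-case category names.
#' @export
default_lof_categories <- function() {
  c("exonic", "utr3", "utr5", "utr", "splicing", "upstream")
}

#' Restrict a variant table to loss-of-function sites
#'
#' Keeps sites whose annotation category (case-insensitively) is in the
#' LOF category set; every other category is dropped and reported once
#' per distinct category via a message.
#'
#' @param vt A [variant_table()].
#' @param lof_categories Character vector of qualifying categories
#'   (compared lower-case); defaults to [default_lof_categories()].
#' @return The restricted [variant_table()].
#' @export
classify_lof <- function(vt, lof_categories = default_lof_categories()) {
  stopifnot(inherits(vt, "variant_table"))
  cat_lc <- tolower(vt$sites$category)
  keep <- cat_lc %in% tolower(lof_categories)
  dropped <- unique(vt$sites$category[!keep])
  if (length(dropped))
    message(sprintf("classify_lof: dropping non-LOF category(ies): %s",
                    paste(chr_sort(dropped), collapse = ", ")))
  if (!any(keep)) stop_fmt("no LOF sites left after classification")
  variant_table(vt$sites[keep, , drop = FALSE], vt$samples,
                vt$dosage[keep, , drop = FALSE])
}

#' Scan for variants co-segregating with a target haplotype
#'
#' Returns the sites whose alternative-allele dosage vector equals the
#' per-sample copy number of the target haplotype exactly, across all
#' sequenced samples.  An empty result is a valid outcome (no variant
#' tracks the haplotype).
#'
#' @param lof A [variant_table()] restricted to LOF sites.
#' @param target_dosage Named integer vector (names = sample ids) of
#'   target-haplotype copy numbers, e.g. a column of
#'   [haplotypes_to_biallelic()].
#' @param target_hap Label recorded in the output rows.
#' @return `data.frame`: `site_id`, `gene`, `target_hap`, `match_type`
#'   (always `"exact_dosage"`); zero rows when nothing co-segregates.
#' @export
coseg_scan <- function(lof, target_dosage, target_hap = "target") {
  stopifnot(inherits(lof, "variant_table"))
  if (is.null(names(target_dosage)) ||
      !setequal(names(target_dosage), lof$samples$sample_id))
    stop_fmt("sample sets of the variant table and target dosages disagree")
  td <- as.integer(target_dosage[lof$samples$sample_id])
  hit <- apply(lof$dosage, 1L, function(d) all(d == td))
  data.frame(site_id = lof$sites$site_id[hit],
             gene = lof$sites$gene[hit],
             target_hap = rep(target_hap, sum(hit)),
             match_type = rep("exact_dosage", sum(hit)),
             stringsAsFactors = FALSE)
}

#' Gene-level loss-of-function burden test
#'
#' Collapses each gene's LOF sites into cohort-level allele observations
#' (`alt = sum of dosages over sites x cohort samples`,
#' `ref = 2 * n_cohort * n_sites - alt`) and tests case vs control
#' enrichment with [assoc_2x2()].  Genes with fewer than `min_sites` LOF
#' sites are reported but not tested (`NA` statistics), as are genes
#' whose table is degenerate (e.g. no alternative allele in either
#' cohort).
#'
#' @param lof A [variant_table()] restricted to LOF sites (see
#'   [classify_lof()]).
#' @param min_sites Minimum number of LOF sites for a gene to be tested
#'   (default 2).
#' @param yates,haldane Optional continuity corrections: Yates' for the
#'   chi-square and Haldane-Anscombe (+0.5 on every cell before the OR)
#'   for zero-cell tables.  Both default off.
#' @param bonferroni Add a Bonferroni-adjusted p-value column over the
#'   tested genes.
#' @return `data.frame` sorted by p (`NA` rows last): `gene`,
#'   `n_lof_sites`, `alt_case`, `ref_case`, `alt_control`, `ref_control`,
#'   `chi2`, `p`, `or_`, `ci_low`, `ci_high`, `tested`.
#' @export
gene_burden_scan <- function(lof, min_sites = 2L, yates = FALSE,
                             haldane = FALSE, bonferroni = FALSE) {
  stopifnot(inherits(lof, "variant_table"))
  is_case <- lof$samples$cohort == "case"
  n_case <- sum(is_case); n_ctrl <- sum(!is_case)
  if (n_case == 0L || n_ctrl == 0L)
    stop_fmt("both cohorts must be present among the sequenced samples")
  genes <- unique(lof$sites$gene)
  rows <- lapply(genes, function(g) {
    sel <- lof$sites$gene == g
    k <- sum(sel)
    alt_case <- sum(lof$dosage[sel, is_case, drop = FALSE])
    alt_ctrl <- sum(lof$dosage[sel, !is_case, drop = FALSE])
    ref_case <- 2L * n_case * k - alt_case
    ref_ctrl <- 2L * n_ctrl * k - alt_ctrl
    stopifnot(alt_case + ref_case == 2L * n_case * k,
              alt_ctrl + ref_ctrl == 2L * n_ctrl * k)
    tested <- k >= min_sites
    if (tested) {
      r <- assoc_2x2(alt_case, ref_case, alt_ctrl, ref_ctrl, yates = yates)
      if (haldane && is.na(r$or_)) {
        or_ <- ((alt_case + 0.5) * (ref_ctrl + 0.5)) /
          ((ref_case + 0.5) * (alt_ctrl + 0.5))
        se <- sqrt(1 / (alt_case + 0.5) + 1 / (ref_case + 0.5) +
                     1 / (alt_ctrl + 0.5) + 1 / (ref_ctrl + 0.5))
        r$or_ <- or_
        r$ci_low <- exp(log(or_) - 1.96 * se)
        r$ci_high <- exp(log(or_) + 1.96 * se)
      }
      stats <- r[c("chi2", "p", "or_", "ci_low", "ci_high")]
    } else {
      stats <- data.frame(chi2 = NA_real_, p = NA_real_, or_ = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_)
    }
    cbind(data.frame(gene = g, n_lof_sites = k, alt_case = alt_case,
                     ref_case = ref_case, alt_control = alt_ctrl,
                     ref_control = ref_ctrl, stringsAsFactors = FALSE),
          stats, data.frame(tested = tested))
  })
  out <- do.call(rbind, rows)
  if (bonferroni) {
    m <- sum(out$tested & !is.na(out$p))
    out$p_bonferroni <- pmin(1, out$p * m)
  }
  out <- out[order(out$p, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
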