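#' Haplotype-guided selection of samples for targeted sequencing
#'
#' Implements the four-rule, strictly greedy selection of sequencing
#' samples around a target haplotype:
#' \enumerate{
#'   \item target-haplotype homozygotes, as many as available;
#'   \item target-haplotype heterozygotes;
#'   \item one carrier of each common haplotype (pooled frequency above
#'     `common_freq_threshold`) not yet represented among the selected
#'     diplotypes;
#'   \item `n_reference` samples not carrying the target haplotype, as a
#'     reference.
#' }
#' Within each rule, picks alternate between the case and control cohort
#' (starting with cases) and ties are broken by sample id order, so the
#' selection is deterministic.  `n_reference` slots are reserved for rule
#' 4, i.e. rules 1-3 fill at most `n_total - n_reference` slots.
#'
#' @param phased Per-individual assignments from [em_estimate()].
#' @param ft The haplotype frequency table of the same fit.
#' @param target_hap `hap_id` of the haplotype driving the selection
#'   (typically the top-associated one).
#' @param n_total Total number of samples to select.
#' @param common_freq_threshold Pooled-frequency threshold defining a
#'   "common" haplotype (default 0.005, i.e. 0.5%).
#' @param n_reference Number of non-carrier reference samples.
#' @param eligible Optional logical vector (aligned with `phased` rows)
#'   marking samples whose DNA quality permits sequencing; defaults to
#'   all `TRUE`.
#' @return `data.frame` in selection order: `sample_id`, `cohort`,
#'   `diplotype` (e.g. `"H2/H7"`), `selection_reason`.
#' @export
select_sequencing_samples <- function(phased, ft, target_hap,
                                      n_total = 16L,
                                      common_freq_threshold = 0.005,
                                      n_reference = 2L,
                                      eligible = NULL) {
  stopifnot(is_count(n_total), is_count(n_reference),
            n_reference <= n_total,
            common_freq_threshold > 0, common_freq_threshold < 1)
  if (!target_hap %in% ft$hap_id)
    stop_fmt("target haplotype %s is not in the frequency table", target_hap)
  if (is.null(eligible)) eligible <- rep(TRUE, nrow(phased))
  stopifnot(length(eligible) == nrow(phased))
  pool <- phased[eligible, , drop = FALSE]
  pool <- pool[chr_order(pool$sample_id), , drop = FALSE]
  target_string <- ft$allele_string[ft$hap_id == target_hap]
  dose <- (pool$hap1 == target_string) + (pool$hap2 == target_string)
  if (!any(dose > 0L))
    stop_fmt("no carriers of target haplotype %s in the cohort", target_hap)
  if (n_total > nrow(pool)) {
    warn_fmt("n_total (%d) exceeds the eligible cohort (%d); selecting all",
             n_total, nrow(pool))
    n_total <- nrow(pool)
    n_reference <- sum(dose == 0L)   # everyone is either carrier or reference
  }

  taken <- logical(nrow(pool))
  reasons <- character(0); picked <- integer(0)
  next_cohort <- "case"
  # pick up to k samples from `cand` (row indices), alternating cohorts
  pick <- function(cand, k, reason) {
    cand <- cand[!taken[cand]]
    while (k > 0L && length(cand) > 0L) {
      pref <- cand[pool$cohort[cand] == next_cohort]
      i <- if (length(pref)) pref[1L] else cand[1L]
      taken[i] <<- TRUE
      picked <<- c(picked, i)
      reasons <<- c(reasons, reason)
      next_cohort <<- if (pool$cohort[i] == "case") "control" else "case"
      cand <- cand[cand != i]
      k <- k - 1L
    }
  }
  cap_main <- n_total - n_reference
  pick(which(dose == 2L), cap_main - length(picked), "target_homozygote")
  pick(which(dose == 1L), cap_main - length(picked), "target_heterozygote")

  common <- ft[ft$freq_pooled > common_freq_threshold &
                 ft$hap_id != target_hap, , drop = FALSE]
  common <- common[order(-common$freq_pooled, common$hap_id), , drop = FALSE]
  for (h in common$hap_id) {
    if (length(picked) >= cap_main) break
    s <- ft$allele_string[ft$hap_id == h]
    represented <- any(pool$hap1[picked] == s | pool$hap2[picked] == s)
    if (represented) next
    pick(which(pool$hap1 == s | pool$hap2 == s), 1L,
         sprintf("haplotype_coverage:%s", h))
  }
  pick(which(dose == 0L), min(n_reference, n_total - length(picked)),
       "reference_noncarrier")

  id1 <- pool$hap1_id[picked]; id2 <- pool$hap2_id[picked]
  data.frame(sample_id = pool$sample_id[picked],
             cohort = pool$cohort[picked],
             diplotype = paste(pmin(id1, id2), pmax(id1, id2), sep = "/"),
             selection_reason = reasons,
             stringsAsFactors = FALSE)
}
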