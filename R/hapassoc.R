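#' Pearson chi-square test, odds ratio and Woolf CI for a 2x2 table
#'
#' The shared association statistic of the haplotype scan and the gene
#' burden test.  Cells follow the allele-count layout
#' `a` = case alt, `b` = case ref, `c` = control alt, `d` = control ref.
#' The statistic is the uncorrected Pearson chi-square on 1 df,
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`; the confidence interval is
#' Woolf's log-odds normal interval `exp(ln OR +/- 1.96 * SE)` with
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`.
#'
#' If any single cell is zero the odds ratio and CI are undefined (`NA`)
#' while the chi-square is still computed provided both allele margins
#' `a+c` and `b+d` are positive; if either margin is zero the whole test
#' is undefined.
#'
#' @param a,b,c,d Non-negative counts; both row margins must be positive.
#' @param yates Apply Yates' continuity correction to the chi-square
#'   (default `FALSE`, matching standard allele-count haplotype tests).
#' @param conf_z Normal quantile for the CI (1.96 for 95%).
#' @return A one-row `data.frame` of class `assoc_2x2` with columns
#'   `a, b, c, d, chi2, p, or_, ci_low, ci_high, maf_case, maf_control`.
#' @examples
#' assoc_2x2(20, 172, 50, 142)   # chi2 15.72, OR 0.33, CI 0.19-0.58
#' @export
assoc_2x2 <- function(a, b, c, d, yates = FALSE, conf_z = 1.96) {
  stopifnot(is_count(a), is_count(b), is_count(c), is_count(d))
  # compute in doubles: (ad - bc)^2 overflows 32-bit integers easily
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  if ((a + b) <= 0 || (c + d) <= 0)
    stop_fmt("both cohort margins (a+b) and (c+d) must be positive")
  N <- a + b + c + d
  chi2 <- p <- NA_real_
  if ((a + c) > 0 && (b + d) > 0) {
    num <- abs(a * d - b * c)
    if (yates) num <- max(0, num - N / 2)
    chi2 <- N * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
    p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  }
  or_ <- ci_low <- ci_high <- NA_real_
  if (all(c(a, b, c, d) > 0)) {
    or_ <- (a * d) / (b * c)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    ci_low <- exp(log(or_) - conf_z * se)
    ci_high <- exp(log(or_) + conf_z * se)
  }
  out <- data.frame(a = a, b = b, c = c, d = d, chi2 = chi2, p = p,
                    or_ = or_, ci_low = ci_low, ci_high = ci_high,
                    maf_case = a / (a + b), maf_control = c / (c + d))
  class(out) <- c("assoc_2x2", "data.frame")
  out
}

#' Odds ratio from two cohort frequencies
#'
#' The frequency-parameterised odds ratio
#' `OR = (f_case / (1 - f_case)) / (f_control / (1 - f_control))`.
#' Agrees with [assoc_2x2()]'s OR when the counts are exactly
#' `f * 2N`.  Undefined (`NA`) when either frequency is 0 or 1.
#'
#' @param f_case,f_control Proportions in (0, 1).
#' @return The odds ratio (numeric scalar, vectorised over inputs).
#' @examples
#' assoc_from_freqs(0.0016, 0.0094)   # 0.17
#' @export
assoc_from_freqs <- function(f_case, f_control) {
  stopifnot(all(f_case >= 0 & f_case <= 1, na.rm = TRUE),
            all(f_control >= 0 & f_control <= 1, na.rm = TRUE))
  out <- (f_case / (1 - f_case)) / (f_control / (1 - f_control))
  out[f_case <= 0 | f_case >= 1 | f_control <= 0 | f_control >= 1] <- NA_real_
  out
}

#' Convert phased diplotypes to biallelic haplotype dosages
#'
#' For each haplotype in the frequency table and each phased individual,
#' the dosage is the number of copies of that haplotype in the
#' individual's assigned pair; rows sum to 2.
#'
#' @param phased The `phased` assignments of a [em_estimate()] fit.
#' @param ft The haplotype frequency table (provides columns/hap ids).
#' @return Integer matrix, individuals x haplotypes, with sample ids as
#'   row names and hap ids as column names.
#' @export
haplotypes_to_biallelic <- function(phased, ft) {
  d <- vapply(ft$allele_string, function(s)
    (phased$hap1 == s) + (phased$hap2 == s), integer(nrow(phased)))
  d <- matrix(as.integer(d), nrow(phased), nrow(ft))
  dimnames(d) <- list(phased$sample_id, ft$hap_id)
  if (!all(rowSums(d) == 2L))
    stop_fmt("assignments contain a haplotype absent from the frequency table")
  d
}

#' Case-control association scan over haplotype dosages
#'
#' Runs [assoc_2x2()] per haplotype on allele counts: `a` = case copies
#' of the haplotype, `b = 2 n_case - a`, and likewise for controls.
#' Rows with undefined tests are retained as `NA` rows.
#'
#' @param dosage Individuals x haplotypes dosage matrix from
#'   [haplotypes_to_biallelic()].
#' @param cohort Character vector (`"case"`/`"control"`) aligned with the
#'   dosage rows.
#' @param bonferroni Add a Bonferroni-adjusted p-value column.
#' @param yates Passed to [assoc_2x2()].
#' @return `data.frame` sorted by p (NA last): `hap_id` plus the
#'   [assoc_2x2()] columns.
#' @export
haplotype_assoc_scan <- function(dosage, cohort, bonferroni = FALSE,
                                 yates = FALSE) {
  stopifnot(nrow(dosage) == length(cohort))
  case <- cohort == "case"
  n_case <- sum(case); n_ctrl <- sum(!case)
  a <- colSums(dosage[case, , drop = FALSE])
  c_ <- colSums(dosage[!case, , drop = FALSE])
  rows <- lapply(seq_len(ncol(dosage)), function(j)
    assoc_2x2(a[j], 2L * n_case - a[j], c_[j], 2L * n_ctrl - c_[j],
              yates = yates))
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out <- cbind(hap_id = colnames(dosage), out, stringsAsFactors = FALSE)
  if (bonferroni)
    out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out[order(out$p, na.last = TRUE), , drop = FALSE]
}

#' Pairwise linkage disequilibrium r-squared on haplotype counts
#'
#' `r^2 = D^2 / (p1 (1 - p1) p2 (1 - p2))` computed on phased haplotype
#' (not genotype) allele vectors.
#'
#' @param x,y Character (or 0/1) vectors giving the allele carried at two
#'   markers by each haplotype in the phased pool.
#' @return r-squared in `[0, 1]`; `NA` if either marker is monomorphic in
#'   the pool.
#' @export
pairwise_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0L)
  ux <- chr_sort(unique(as.character(x)))
  uy <- chr_sort(unique(as.character(y)))
  if (length(ux) != 2L || length(uy) != 2L) return(NA_real_)
  xi <- as.numeric(x == ux[1L]); yi <- as.numeric(y == uy[1L])
  p1 <- mean(xi); p2 <- mean(yi)
  D <- mean(xi * yi) - p1 * p2
  D^2 / (p1 * (1 - p1) * p2 * (1 - p2))
}
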