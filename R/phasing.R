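#' Enumerate diplotypes compatible with an unphased genotype
#'
#' For a genotype with `h` heterozygous markers there are `2^(h-1)`
#' distinct unordered haplotype pairs (1 when `h = 0`); every returned
#' pair reproduces the genotype exactly.  Genotypes with missing markers
#' are not supported (missing individuals are excluded before phasing,
#' see [em_estimate()]).
#'
#' @param g1,g2 Character vectors of the two alleles at each marker
#'   (order irrelevant).
#' @return `data.frame` with columns `h1`, `h2`: haplotype allele strings,
#'   `h1 <= h2` lexicographically.
#' @examples
#' enumerate_pairs(c("G", "C"), c("A", "T"))   # 2 heterozygous markers
#' @export
enumerate_pairs <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  if (anyNA(g1) || anyNA(g2))
    stop_fmt("enumerate_pairs does not accept missing genotypes")
  het <- which(g1 != g2)
  h <- length(het)
  if (h == 0L) {
    s <- paste(g1, collapse = "")
    return(data.frame(h1 = s, h2 = s, stringsAsFactors = FALSE))
  }
  # fix the first het marker's allele on haplotype 1 to halve the space
  n_free <- h - 1L
  combos <- if (n_free == 0L) matrix(logical(0), 1L, 0L) else
    as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n_free)))
  h1 <- matrix(rep(g1, each = nrow(combos)), nrow(combos))
  h2 <- matrix(rep(g2, each = nrow(combos)), nrow(combos))
  if (n_free > 0L) {
    for (k in seq_len(n_free)) {
      m <- het[k + 1L]
      sw <- combos[, k]
      tmp <- h1[sw, m]; h1[sw, m] <- h2[sw, m]; h2[sw, m] <- tmp
    }
  }
  s1 <- apply(h1, 1L, paste, collapse = "")
  s2 <- apply(h2, 1L, paste, collapse = "")
  swap <- s1 > s2
  out <- data.frame(h1 = ifelse(swap, s2, s1), h2 = ifelse(swap, s1, s2),
                    stringsAsFactors = FALSE)
  out[chr_order(paste(out$h1, out$h2)), , drop = FALSE]
}

#' Estimate haplotype frequencies and diplotypes by EM
#'
#' A deterministic expectation-maximisation estimator of multilocus
#' haplotype frequencies under random mating (Hardy-Weinberg diplotype
#' probabilities), in the style of Excoffier & Slatkin's gene-counting
#' EM.  Per-cohort frequency columns are obtained by attributing each
#' individual's expected haplotype counts to its cohort; per-individual
#' diplotypes are the maximum-posterior compatible pair under the final
#' frequencies, ties broken lexicographically.
#'
#' Individuals with any missing marker are excluded before estimation
#' (their count is reported in a message and in the returned object).
#'
#' @param gm A [genotype_matrix()].
#' @param tol Convergence threshold on the change in log-likelihood.
#' @param max_iter Maximum EM iterations; reaching it raises a warning
#'   and sets `converged = FALSE`.
#' @param prune_freq Haplotypes with estimated pooled frequency below
#'   this are dropped from the frequency table (columns renormalised).
#' @param init_jitter Relative amplitude of the deterministic,
#'   lexicographic-rank-based perturbation applied to the
#'   product-of-allele-frequency initialiser; breaks the exact symmetry
#'   that otherwise traps EM at a saddle point on double-heterozygote
#'   data.  Set to 0 for the unperturbed initialiser.
#' @param n_starts Number of EM starts.  The first start uses the
#'   (perturbed) product-of-allele-frequency initialiser; further starts
#'   use Dirichlet(1) draws from a fixed internal seed, so the whole
#'   procedure remains deterministic.  The start with the highest final
#'   log-likelihood wins (ties: earliest start).  The random-mating
#'   likelihood is multimodal on small ambiguous samples; a handful of
#'   starts reliably reaches the global maximum at this problem size.
#'
#' @return A list of class `hap_em_fit`:
#' \describe{
#'   \item{freqs}{the haplotype frequency table: `hap_id`,
#'     `allele_string`, `freq_case`, `freq_control`, `freq_pooled`
#'     (labels follow [label_haplotypes()]).}
#'   \item{phased}{per-individual assignments: `sample_id`, `cohort`,
#'     `hap1`, `hap2` (allele strings, `hap1 <= hap2`), `hap1_id`,
#'     `hap2_id`, `posterior`.}
#'   \item{log_likelihood, n_iter, converged, n_dropped}{diagnostics.}
#' }
#' @export
em_estimate <- function(gm, tol = 1e-8, max_iter = 1000L,
                        prune_freq = 1e-7, init_jitter = 1e-3,
                        n_starts = 5L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  miss <- rowSums(is.na(gm$a1)) > 0L
  if (any(miss))
    message(sprintf("em_estimate: excluding %d individual(s) with missing genotypes",
                    sum(miss)))
  a1 <- gm$a1[!miss, , drop = FALSE]; a2 <- gm$a2[!miss, , drop = FALSE]
  samples <- gm$samples[!miss, , drop = FALSE]
  n <- nrow(samples)
  if (n == 0L) stop_fmt("no complete genotypes left after missing-data exclusion")

  # group identical genotypes; enumerate compatible pairs once per group
  key <- apply(matrix(paste(a1, a2, sep = "/"), n), 1L, paste, collapse = ";")
  groups <- match(key, unique(key))
  g_rows <- match(unique(key), key)          # one representative row each
  pair_list <- lapply(g_rows, function(i) enumerate_pairs(a1[i, ], a2[i, ]))

  universe <- chr_sort(unique(unlist(lapply(pair_list,
                                            function(p) c(p$h1, p$h2)))))
  H <- length(universe)
  pairs <- do.call(rbind, pair_list)
  gid <- rep(seq_along(pair_list), vapply(pair_list, nrow, 0L))
  i1 <- match(pairs$h1, universe); i2 <- match(pairs$h2, universe)
  mult <- ifelse(i1 == i2, 1, 2)
  grp_n <- tabulate(groups, nbins = length(pair_list))      # individuals/group
  grp_case <- vapply(seq_along(pair_list), function(g)
    sum(samples$cohort[groups == g] == "case"), 0)
  grp_ctrl <- grp_n - grp_case

  # initialisation: product of observed per-marker allele frequencies,
  # with a tiny deterministic rank perturbation (see argument docs)
  m <- ncol(a1)
  f0 <- vapply(universe, function(hap) {
    al <- strsplit(hap, "", fixed = TRUE)[[1L]]
    prod(vapply(seq_len(m), function(j)
      mean(c(a1[, j], a2[, j]) == al[j]), 0))
  }, 0)
  if (init_jitter > 0 && H > 1L)
    f0 <- f0 * (1 + init_jitter * (seq_len(H) - 1L) / (H - 1L))
  f0 <- f0 / sum(f0)

  run_em <- function(f) {
    ll_prev <- -Inf; ll <- NA_real_; it <- 0L; converged <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      P <- f[i1] * f[i2] * mult
      S <- as.numeric(rowsum(P, gid))        # per-group genotype probability
      ll <- sum(grp_n * log(S))
      if (ll < ll_prev - 1e-9 * max(1, abs(ll)))
        stop_fmt("internal error: EM log-likelihood decreased (%.12g -> %.12g)",
                 ll_prev, ll)
      w <- grp_n[gid] * P / S[gid]           # expected diplotype counts
      cnt <- as.numeric(rowsum(c(w, w), c(i1, i2), default = 0))
      idx <- sort(unique(c(i1, i2)))
      f_new <- numeric(H); f_new[idx] <- cnt; f_new <- f_new / (2 * n)
      delta <- ll - ll_prev
      f <- f_new
      if (is.finite(delta) && abs(delta) < tol) { converged <- TRUE; break }
      ll_prev <- ll
    }
    list(f = f, ll = ll, it = it, converged = converged)
  }

  best <- run_em(f0)
  if (n_starts > 1L) {
    rng <- .Random.seed_save()
    on.exit(.Random.seed_restore(rng), add = TRUE)
    set.seed(20260920L)
    for (s in seq_len(n_starts - 1L)) {
      g <- stats::rgamma(H, shape = 1)
      cand <- run_em(g / sum(g))
      if (cand$ll > best$ll + 1e-10) best <- cand
    }
  }
  f <- best$f; ll <- best$ll; it <- best$it; converged <- best$converged
  if (!converged)
    warn_fmt("em_estimate: tolerance not reached after %d iterations", max_iter)

  # final E-step quantities under the converged frequencies
  P <- f[i1] * f[i2] * mult
  S <- as.numeric(rowsum(P, gid))
  post <- P / S[gid]
  cohort_count <- function(gn) {
    w <- gn[gid] * post
    cnt <- as.numeric(rowsum(c(w, w), c(i1, i2), default = 0))
    out <- numeric(H); out[sort(unique(c(i1, i2)))] <- cnt; out
  }
  n_case <- sum(samples$cohort == "case")
  n_ctrl <- n - n_case
  f_case <- if (n_case > 0L) cohort_count(grp_case) / (2 * n_case) else
    rep(NA_real_, H)
  f_ctrl <- if (n_ctrl > 0L) cohort_count(grp_ctrl) / (2 * n_ctrl) else
    rep(NA_real_, H)

  keep <- f >= prune_freq
  ft <- data.frame(allele_string = universe[keep],
                   freq_case = f_case[keep] / if (n_case) sum(f_case[keep]) else 1,
                   freq_control = f_ctrl[keep] / if (n_ctrl) sum(f_ctrl[keep]) else 1,
                   freq_pooled = f[keep] / sum(f[keep]),
                   stringsAsFactors = FALSE)
  ft <- label_haplotypes(ft)

  # maximum-posterior diplotype per genotype group, lexicographic ties
  pair_key <- paste(pairs$h1, pairs$h2)
  best <- vapply(seq_along(pair_list), function(g) {
    rows <- which(gid == g)
    pp <- post[rows]
    cand <- rows[pp >= max(pp) - 1e-12]
    cand[chr_order(pair_key[cand])[1L]]
  }, 0L)
  bi <- best[groups]
  phased <- data.frame(sample_id = samples$sample_id,
                       cohort = samples$cohort,
                       hap1 = pairs$h1[bi], hap2 = pairs$h2[bi],
                       hap1_id = ft$hap_id[match(pairs$h1[bi], ft$allele_string)],
                       hap2_id = ft$hap_id[match(pairs$h2[bi], ft$allele_string)],
                       posterior = post[bi],
                       stringsAsFactors = FALSE)

  structure(list(freqs = ft, phased = phased, log_likelihood = ll,
                 n_iter = it, converged = converged,
                 n_dropped = sum(miss)),
            class = "hap_em_fit")
}

#' @export
print.hap_em_fit <- function(x, ...) {
  cat(sprintf("hap_em_fit: %d haplotypes, %d individuals phased, logLik %.4f (%d iterations%s)\n",
              nrow(x$freqs), nrow(x$phased), x$log_likelihood, x$n_iter,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Label haplotypes H1..Hk in lexicographic order
#'
#' Assigns stable labels `H1`, `H2`, ... in byte-wise lexicographic order
#' of the allele strings.  Idempotent: relabelling an already labelled
#' table returns the same labels.
#'
#' @param ft `data.frame` with a unique `allele_string` column (an
#'   existing `hap_id` column is replaced).
#' @return The table, rows ordered by `allele_string`, with `hap_id`
#'   first.
#' @export
label_haplotypes <- function(ft) {
  if (anyDuplicated(ft$allele_string)) stop_fmt("allele strings must be unique")
  ft <- ft[chr_order(ft$allele_string), , drop = FALSE]
  ft$hap_id <- sprintf("H%d", seq_len(nrow(ft)))
  rownames(ft) <- NULL
  ft[, c("hap_id", setdiff(names(ft), "hap_id")), drop = FALSE]
}
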