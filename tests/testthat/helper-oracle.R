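# Independent maximum-likelihood oracle for haplotype frequencies.
#
# Computes the observed-data likelihood by brute force over ALL ordered
# haplotype pairs of the full 2^m universe (no shared code with the EM's
# pair enumeration) and maximises it with a generic optimiser under a
# softmax parameterisation, from several random starts.

# genotype probability under f: sum over all ordered pairs that reproduce
# the unordered per-marker allele pairs
oracle_loglik_fn <- function(gm) {
  haps <- all_haps(gm$panel)
  H <- length(haps)
  hap_mat <- do.call(rbind, strsplit(haps, ""))
  n <- nrow(gm$samples)
  # linear indices into outer(f, f) of the ordered pairs compatible with
  # each individual, precomputed once
  comp <- vector("list", n)
  for (ind in seq_len(n)) {
    g1 <- gm$a1[ind, ]; g2 <- gm$a2[ind, ]
    ok <- matrix(FALSE, H, H)
    for (i in seq_len(H)) for (j in seq_len(H)) {
      ok[i, j] <- all((hap_mat[i, ] == g1 & hap_mat[j, ] == g2) |
                      (hap_mat[i, ] == g2 & hap_mat[j, ] == g1))
    }
    comp[[ind]] <- which(ok)
  }
  list(haps = haps,
       loglik = function(f) {
         pp <- tcrossprod(f)
         sum(vapply(comp, function(idx) log(sum(pp[idx])), 0))
       })
}

oracle_fit <- function(gm, n_starts = 16L, seed = 1L) {
  obj <- oracle_loglik_fn(gm)
  H <- length(obj$haps)
  neg <- function(theta) {
    f <- exp(theta - max(theta)); f <- f / sum(f)
    -obj$loglik(f)
  }
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    theta0 <- if (s == 1L) rep(0, H) else rnorm(H, sd = 2)
    fit <- optim(theta0, neg, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  f <- exp(best$par - max(best$par)); f <- f / sum(f)
  list(freqs = setNames(f, obj$haps), loglik = -best$value)
}

# total variation distance between an em fit's pooled frequencies and an
# oracle frequency vector over the full universe
tv_against_oracle <- function(fit, oracle_freqs) {
  f_em <- setNames(rep(0, length(oracle_freqs)), names(oracle_freqs))
  f_em[fit$freqs$allele_string] <- fit$freqs$freq_pooled
  0.5 * sum(abs(f_em - oracle_freqs))
}
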