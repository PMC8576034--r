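#' Configuration for the synthetic cohort generator
#'
#' Describes the study conditions the generator emulates: cohort-specific
#' haplotype frequency distributions over the marker panel, cohort sizes,
#' per-gene loss-of-function variant sites with cohort-specific
#' alternative-allele frequencies, and an optional haplotype whose copy
#' number a planted variant site co-segregates with exactly.
#'
#' @param panel A [marker_panel()].
#' @param hap_freqs_case,hap_freqs_control Named numeric vectors mapping
#'   haplotype allele strings to frequencies; each must sum to 1 (within
#'   1e-9) with all entries `>= 0`.
#' @param n_case,n_control Cohort sizes (`>= 1`).
#' @param lof_spec `data.frame` with one row per variant site: `gene`,
#'   `site_id`, `alt_freq_case`, `alt_freq_control`, `category`.
#' @param coseg_target Optional haplotype allele string; when set, one
#'   extra site in `coseg_gene` is emitted whose per-sample dosage equals
#'   the individual's copy number of this haplotype exactly.
#' @param coseg_gene Gene receiving the planted co-segregating site.
#' @param seed Master seed; identical configurations give bit-identical
#'   output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(panel, hap_freqs_case, hap_freqs_control,
                       n_case, n_control, lof_spec = NULL,
                       coseg_target = NULL, coseg_gene = NULL, seed = 1L) {
  stopifnot(inherits(panel, "marker_panel"))
  check_freqs <- function(f, what) {
    if (is.null(names(f)) || any(!nzchar(names(f))))
      stop_fmt("%s must be a named vector (haplotype string -> frequency)", what)
    if (any(f < 0)) stop_fmt("%s has a negative frequency", what)
    if (abs(sum(f) - 1) > 1e-9)
      stop_fmt("%s frequencies sum to %.6g, not 1", what, sum(f))
    for (h in names(f)) hap_alleles(h, panel)
    f
  }
  hap_freqs_case <- check_freqs(hap_freqs_case, "hap_freqs_case")
  hap_freqs_control <- check_freqs(hap_freqs_control, "hap_freqs_control")
  if (!is_count(n_case) || !is_count(n_control) || n_case < 1 || n_control < 1)
    stop_fmt("n_case and n_control must be integers >= 1")
  if (!is.null(lof_spec)) {
    need <- c("gene", "site_id", "alt_freq_case", "alt_freq_control", "category")
    if (!all(need %in% names(lof_spec)))
      stop_fmt("lof_spec needs columns: %s", paste(need, collapse = ", "))
    if (anyDuplicated(lof_spec$site_id)) stop_fmt("duplicate lof_spec site_id")
    if (any(lof_spec$alt_freq_case < 0 | lof_spec$alt_freq_case > 1 |
            lof_spec$alt_freq_control < 0 | lof_spec$alt_freq_control > 1))
      stop_fmt("lof_spec alt frequencies must lie in [0,1]")
  }
  if (!is.null(coseg_target)) {
    if (!is_valid_hap(coseg_target, panel))
      stop_fmt("coseg_target '%s' is not a haplotype over the panel", coseg_target)
    if (is.null(coseg_gene)) {
      if (is.null(lof_spec)) stop_fmt("coseg_target requires a lof_spec")
      coseg_gene <- lof_spec$gene[1L]
    }
  }
  structure(list(panel = panel, hap_freqs_case = hap_freqs_case,
                 hap_freqs_control = hap_freqs_control,
                 n_case = as.integer(n_case), n_control = as.integer(n_control),
                 lof_spec = lof_spec, coseg_target = coseg_target,
                 coseg_gene = coseg_gene, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default simulation configuration: the 5q22.1 common-haplotype landscape
#'
#' Ships the seven common (frequency > 0.5%) haplotypes of the 5q22.1
#' atopic-dermatitis block with their published per-cohort frequencies
#' renormalised to sum to 1 per cohort, and a loss-of-function variant
#' spec whose per-gene site counts and alternative-allele frequencies
#' mirror the published gene-level allele-observation structure
#' (16 sequenced samples, 8 per cohort).  Allele strings are the
#' package's own panel encoding (see [default_marker_panel()]).
#'
#' @param n_case,n_control Cohort sizes (defaults give a desk-scale run).
#' @param seed Master seed.
#' @param coseg_target Optional haplotype string to plant a
#'   co-segregating site for; `NULL` (default) plants nothing, matching
#'   the published null finding.
#' @return A [sim_config()].
#' @export
default_sim_config <- function(n_case = 500L, n_control = 500L, seed = 1L,
                               coseg_target = NULL) {
  panel <- default_marker_panel()
  hf <- haplotype_reference_freqs()
  hf <- hf[hf$common, ]
  fc <- hf$freq_case_pct / 100; fk <- hf$freq_control_pct / 100
  hap_freqs_case <- stats::setNames(fc / sum(fc), hf$allele_string)
  hap_freqs_control <- stats::setNames(fk / sum(fk), hf$allele_string)
  gc <- gene_lof_reference_counts()
  lof_spec <- do.call(rbind, lapply(seq_len(nrow(gc)), function(i) {
    k <- gc$n_sites[i]
    data.frame(gene = gc$gene[i],
               site_id = sprintf("%s_s%02d", gc$gene[i], seq_len(k)),
               alt_freq_case = gc$alt_case[i] / (gc$alt_case[i] + gc$ref_case[i]),
               alt_freq_control = gc$alt_control[i] /
                 (gc$alt_control[i] + gc$ref_control[i]),
               category = "exonic", stringsAsFactors = FALSE)
  }))
  sim_config(panel, hap_freqs_case, hap_freqs_control, n_case, n_control,
             lof_spec = lof_spec, coseg_target = coseg_target,
             coseg_gene = "TMEM232", seed = seed)
}

#' Simulate case/control cohorts of unphased genotypes
#'
#' Each individual's two haplotypes are drawn i.i.d. from its cohort's
#' haplotype frequency distribution (cohort-wise random mating); the
#' genotypes are the unordered per-marker allele pairs.  The drawn
#' (ordered) haplotype pair of every individual is returned as ground
#' truth for phasing tests.
#'
#' @param cfg A [sim_config()].
#' @return List with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (`data.frame`: `sample_id`, `cohort`, `hap1`, `hap2`, as drawn).
#' @export
simulate_cohort_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, "simulate"))
  draw <- function(freqs, n, prefix, cohort) {
    haps <- names(freqs)
    h1 <- sample(haps, n, replace = TRUE, prob = freqs)
    h2 <- sample(haps, n, replace = TRUE, prob = freqs)
    data.frame(sample_id = sprintf("%s%04d", prefix, seq_len(n)),
               cohort = cohort, hap1 = h1, hap2 = h2,
               stringsAsFactors = FALSE)
  }
  truth <- rbind(draw(cfg$hap_freqs_case, cfg$n_case, "CASE", "case"),
                 draw(cfg$hap_freqs_control, cfg$n_control, "CTRL", "control"))
  al1 <- do.call(rbind, lapply(truth$hap1, hap_alleles, panel = cfg$panel))
  al2 <- do.call(rbind, lapply(truth$hap2, hap_alleles, panel = cfg$panel))
  gm <- genotype_matrix(cfg$panel, truth[c("sample_id", "cohort")], al1, al2)
  list(genotypes = gm, truth = truth)
}

#' Simulate per-gene loss-of-function variant calls
#'
#' Dosages are drawn independently per sample and site as
#' `Binomial(2, alt_freq)` with the sample's cohort frequency, so the
#' total allele observations per cohort and gene equal
#' `2 * n_cohort * n_sites(gene)`.  Dosages are independent of the
#' diplotypes (the null structure of a locus without a haplotype-linked
#' variant) except for the optional planted co-segregating site, whose
#' dosage equals each individual's copy number of `cfg$coseg_target`.
#'
#' @param cfg A [sim_config()] with a non-empty `lof_spec`.
#' @param samples `data.frame` with `sample_id`, `cohort`: the (sub)set of
#'   individuals that were "sequenced".
#' @param truth The truth table of [simulate_cohort_genotypes()]; required
#'   when `cfg$coseg_target` is set.
#' @return A [variant_table()].
#' @export
simulate_lof_variants <- function(cfg, samples, truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$lof_spec) || nrow(cfg$lof_spec) == 0L)
    stop_fmt("cfg$lof_spec is empty")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, "lof"))
  spec <- cfg$lof_spec
  n <- nrow(samples)
  is_case <- samples$cohort == "case"
  dosage <- matrix(0L, nrow(spec), n)
  for (i in seq_len(nrow(spec))) {
    f <- ifelse(is_case, spec$alt_freq_case[i], spec$alt_freq_control[i])
    dosage[i, ] <- stats::rbinom(n, 2L, f)
  }
  sites <- data.frame(site_id = spec$site_id, gene = spec$gene,
                      position = 109e6 + seq_len(nrow(spec)) * 1000L,
                      category = spec$category, stringsAsFactors = FALSE)
  if (!is.null(cfg$coseg_target)) {
    if (is.null(truth))
      stop_fmt("planting a co-segregating site requires the truth table")
    j <- match(samples$sample_id, truth$sample_id)
    if (anyNA(j)) stop_fmt("samples not found in truth table")
    copy <- (truth$hap1[j] == cfg$coseg_target) +
      (truth$hap2[j] == cfg$coseg_target)
    sites <- rbind(sites, data.frame(
      site_id = sprintf("%s_coseg", cfg$coseg_gene), gene = cfg$coseg_gene,
      position = 109e6 + (nrow(spec) + 1L) * 1000L,
      category = "exonic", stringsAsFactors = FALSE))
    dosage <- rbind(dosage, as.integer(copy))
  }
  ord <- order(sites$position)
  variant_table(sites[ord, ], samples, dosage[ord, , drop = FALSE])
}

#' Simulate reads that straddle the read-filter thresholds
#'
#' Builds a FASTQ-ready read set with labelled ground truth of which
#' reads violate which filtering rule.  Violating reads are constructed
#' strictly beyond the thresholds (adapter present as an exact substring;
#' more than 50% of bases at Phred <= 5; more than 10% N bases) and clean
#' reads strictly within, including reads sitting exactly on the
#' boundaries (which the strict ">" rules keep).
#'
#' @param n_reads Number of reads.
#' @param read_len Read length in bases.
#' @param adapter Adapter sequence planted in adapter-violating reads.
#' @param frac_adapter,frac_lowq,frac_highN Fractions of reads violating
#'   each rule (each in `[0,1]`, sum `<= 1`); counts are
#'   `round(frac * n_reads)` exactly.
#' @param seed Integer seed.
#' @return List with `reads` (a [read_set()]) and `truth`
#'   (`data.frame`: `read_id`, `violation` in
#'   `{"none","adapter","low_quality","high_N"}`).
#' @export
simulate_reads <- function(n_reads, read_len = 100L,
                           adapter = "AGATCGGAAGAGC",
                           frac_adapter = 0, frac_lowq = 0, frac_highN = 0,
                           seed = 1L) {
  stopifnot(is_count(n_reads), is_count(read_len), read_len > 0)
  fr <- c(frac_adapter, frac_lowq, frac_highN)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1 + 1e-12)
    stop_fmt("violation fractions must lie in [0,1] and sum to at most 1")
  if (frac_adapter > 0 && nchar(adapter) > read_len)
    stop_fmt("read_len (%d) is shorter than the adapter (%d bases)",
             read_len, nchar(adapter))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n_ad <- round(frac_adapter * n_reads)
  n_lq <- round(frac_lowq * n_reads)
  n_nn <- round(frac_highN * n_reads)
  if (n_ad + n_lq + n_nn > n_reads)
    stop_fmt("rounded violation counts exceed n_reads")
  violation <- rep(c("adapter", "low_quality", "high_N", "none"),
                   c(n_ad, n_lq, n_nn, n_reads - n_ad - n_lq - n_nn))
  violation <- sample(violation)
  rand_bases <- function(k) sample(c("A", "C", "G", "T"), k, replace = TRUE)
  # a clean base string: guaranteed adapter-free by rejection
  clean_bases <- function(n_N) {
    repeat {
      b <- rand_bases(read_len)
      if (n_N > 0L) b[sample(read_len, n_N)] <- "N"
      s <- paste(b, collapse = "")
      if (!grepl(adapter, s, fixed = TRUE)) return(s)
    }
  }
  high_quals <- function() sample(30:40, read_len, replace = TRUE)
  bases <- character(n_reads); quals <- vector("list", n_reads)
  n_boundary_lq <- floor(0.5 * read_len)    # exactly at the kept boundary
  n_boundary_N <- floor(0.1 * read_len)
  for (i in seq_len(n_reads)) {
    v <- violation[i]
    if (v == "adapter") {
      s <- clean_bases(0L)
      off <- sample(read_len - nchar(adapter) + 1L, 1L)
      bases[i] <- paste0(substr(s, 1L, off - 1L), adapter,
                         substr(s, off + nchar(adapter), read_len))
      quals[[i]] <- high_quals()
    } else if (v == "low_quality") {
      bases[i] <- clean_bases(0L)
      q <- high_quals()
      q[sample(read_len, n_boundary_lq + 1L)] <- sample(0:5, n_boundary_lq + 1L,
                                                        replace = TRUE)
      quals[[i]] <- q
    } else if (v == "high_N") {
      bases[i] <- clean_bases(n_boundary_N + 1L)
      quals[[i]] <- high_quals()
    } else {
      # alternate strictly-inside and exactly-on-boundary clean reads
      boundary <- i %% 2L == 0L
      bases[i] <- clean_bases(if (boundary) n_boundary_N else 0L)
      q <- high_quals()
      if (boundary && n_boundary_lq > 0L)
        q[sample(read_len, n_boundary_lq)] <- 5L
      quals[[i]] <- q
    }
  }
  ids <- sprintf("read%05d", seq_len(n_reads))
  list(reads = read_set(ids, bases, quals),
       truth = data.frame(read_id = ids, violation = violation,
                          stringsAsFactors = FALSE))
}

# Save/restore the global RNG state so generators are pure functions
# of their config and do not disturb the caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
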