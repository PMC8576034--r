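# Small builders shared across test files; everything is generated in code.

# m-marker toy panel with alleles A (ref) / B (alt) at every marker
toy_panel <- function(m) {
  marker_panel(sprintf("m%d", seq_len(m)),
               rep("A", m), rep("B", m),
               rep(FALSE, m), seq_len(m) * 100L)
}

# genotype matrix built from explicit haplotype-string pairs
gm_from_pairs <- function(panel, hap1, hap2, cohort = NULL) {
  n <- length(hap1)
  if (is.null(cohort)) cohort <- rep(c("case", "control"), length.out = n)
  a1 <- do.call(rbind, lapply(hap1, function(h) strsplit(h, "")[[1L]]))
  a2 <- do.call(rbind, lapply(hap2, function(h) strsplit(h, "")[[1L]]))
  genotype_matrix(panel,
                  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                             cohort = cohort),
                  a1, a2)
}

# all 2^m haplotype strings over a toy panel, lexicographic
all_haps <- function(panel) {
  g <- expand.grid(rep(list(c("A", "B")), nrow(panel)),
                   stringsAsFactors = FALSE)
  sort(apply(as.matrix(g), 1L, paste, collapse = ""), method = "radix")
}

# random small phasing instance: true 8-haplotype frequencies (Dirichlet),
# n individuals drawn under random mating over a 3-marker panel
random_phasing_instance <- function(seed, m = 3L, n_range = 8:20) {
  set.seed(seed)
  panel <- toy_panel(m)
  haps <- all_haps(panel)
  f <- rgamma(length(haps), shape = 1)
  f <- f / sum(f)
  n <- sample(n_range, 1L)
  h1 <- sample(haps, n, replace = TRUE, prob = f)
  h2 <- sample(haps, n, replace = TRUE, prob = f)
  list(panel = panel, truth_freqs = setNames(f, haps),
       gm = gm_from_pairs(panel, h1, h2))
}

# default-config haplotype strings used repeatedly in tests
hap_strings <- function() {
  h <- haplotype_reference_freqs()
  setNames(h$allele_string[h$common], h$label[h$common])
}
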