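# hapburden

Haplotype association and gene-level loss-of-function (LOF) burden
analysis for targeted case-control sequencing of a susceptibility
locus, with a synthetic-data generator that makes the whole pipeline
verifiable offline.

The package is built around the follow-up design used for the atopic
dermatitis locus at chromosome 5q22.1: reconstruct ten-marker
haplotypes from unphased case-control genotypes, test each haplotype
for association, pick carriers and non-carriers of the top haplotype
for targeted capture sequencing, filter the reads, scan the sequenced
variants for exact co-segregation with the haplotype, and collapse
per-gene LOF variants into a case-control burden test.  It is aimed at
statistical geneticists who want each of those steps as a small,
deterministic, tested R function rather than a chain of external
tools.

## The statistics at the core

* **Phasing.** An Excoffier–Slatkin-style EM estimator of haplotype
  frequencies under random mating.  A genotype heterozygous at *h*
  markers is compatible with 2^(h−1) diplotypes; EM iterates expected
  diplotype counts and frequency updates, with deterministic
  multi-start initialisation and lexicographic tie-breaking
  (`em_estimate()`, `enumerate_pairs()`).
* **Association.** Every 2×2 test uses the uncorrected Pearson
  chi-square on allele counts,
  χ² = N(ad−bc)²/((a+b)(c+d)(a+c)(b+d)), odds ratio (ad)/(bc), and the
  Woolf interval exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d))
  (`assoc_2x2()`, `haplotype_assoc_scan()`, `assoc_from_freqs()`).
* **Burden.** Per gene, LOF alt/ref allele observations over k sites
  and n samples per cohort (alt + ref = 2nk), tested for genes with
  ≥ 2 LOF sites (`classify_lof()`, `gene_burden_scan()`).
* **Co-segregation.** A sequenced site co-segregates with a haplotype
  iff its dosage vector equals the haplotype's per-sample copy number
  exactly (`coseg_scan()`).
* **Read QC.** Clean-data rules: adapter substring, >50% of bases at
  Phred ≤ 5, >10% N (`filter_reads()`).

## Worked example

A 2×2 allele-count test on the published TMEM232 LOF counts
(20/172 case alt/ref vs 50/142 control alt/ref):

```r
library(hapburden)
assoc_2x2(20, 172, 50, 142)
#>    a   b  c   d     chi2            p       or_    ci_low   ci_high  maf_case
#> 1 20 172 50 142 15.72338 7.331219e-05 0.3302326 0.1878448 0.5805514 0.1041667
#>   maf_control
#> 1   0.2604167
```

χ² = 15.72 with p = 7.3×10⁻⁵: LOF alleles in TMEM232 are strongly
depleted in cases (OR 0.33, 95% CI 0.19–0.58) — the gene-level signal
that confirmed TMEM232 at this locus.

The end-to-end pipeline on a simulated desk-scale cohort (500 cases,
500 controls drawn from the seven common 5q22.1 haplotypes):

```r
s <- run_pipeline(run_config(seed = 1), "demo_run")
head(s$haplotype_assoc[c("hap_id", "a", "c", "chi2", "p", "or_")], 3)
#>   hap_id   a   c  chi2        p   or_
#> 5     H5   5  29 17.23 0.000033 0.168
#> 4     H4   3  20 12.71 0.000363 0.147
#> 1     H1 170 119 10.52 0.001181 1.516
s$top_haplotype
#> [1] "H5"
nrow(s$coseg_hits); nrow(s$selected_samples)
#> [1] 0
#> [1] 16
```

The top haplotype H5 is the simulated analogue of the protective
deletion haplotype (scan OR 0.168 against its seeded frequency-based
OR of 0.17); 16 samples are selected for "sequencing" by the four-rule
design; and, as in the real study, no variant co-segregates exactly
with the haplotype.  `summary.json` in the run directory holds every
stage's table; `vignettes/hapburden-methods.Rmd` explains the models,
defaults and validation.

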