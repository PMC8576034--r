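test_that("sim_config validates frequency maps and counts", {
  panel <- toy_panel(2)
  ok <- c(AA = 0.6, BB = 0.4)
  expect_s3_class(sim_config(panel, ok, ok, 10, 10), "sim_config")
  expect_error(sim_config(panel, c(AA = 0.5, BB = 0.4), ok, 10, 10),
               "sum to 0.9")
  expect_error(sim_config(panel, c(AA = 1.2, BB = -0.2), ok, 10, 10),
               "negative")
  expect_error(sim_config(panel, c(AC = 1), ok, 10, 10), "invalid allele")
  expect_error(sim_config(panel, ok, ok, 0, 10), ">= 1")
  expect_error(sim_config(panel, ok, ok, 5, 5, coseg_target = "CC",
                          lof_spec = data.frame(gene = "G", site_id = "s",
                                                alt_freq_case = 0.1,
                                                alt_freq_control = 0.1,
                                                category = "exonic")),
               "not a haplotype")
})

test_that("cohort simulation is deterministic and follows the frequency map", {
  panel <- toy_panel(2)
  # degenerate distribution: everyone homozygous for the single haplotype
  cfg <- sim_config(panel, c(AB = 1), c(AB = 1), 5, 5, seed = 2)
  sim <- simulate_cohort_genotypes(cfg)
  expect_true(all(sim$truth$hap1 == "AB" & sim$truth$hap2 == "AB"))
  expect_true(all(sim$genotypes$a1[, "m1"] == "A"))
  expect_true(all(sim$genotypes$a2[, "m2"] == "B"))

  # determinism: identical config => identical output
  cfg2 <- sim_config(panel, c(AA = 0.7, BB = 0.3), c(AA = 0.7, BB = 0.3),
                     200, 100, seed = 9)
  s1 <- simulate_cohort_genotypes(cfg2)
  s2 <- simulate_cohort_genotypes(cfg2)
  expect_identical(s1, s2)

  # binomial sampling bound: empirical frequency within 3 s.e. of truth
  cfg3 <- sim_config(panel, c(AA = 0.7, BB = 0.3), c(AA = 0.7, BB = 0.3),
                     2000, 1, seed = 4)
  sim3 <- simulate_cohort_genotypes(cfg3)
  tr <- sim3$truth[sim3$truth$cohort == "case", ]
  emp <- mean(c(tr$hap1, tr$hap2) == "AA")
  se <- sqrt(0.7 * 0.3 / 4000)
  expect_lt(abs(emp - 0.7), 3 * se)
})

test_that("cohort diplotypes have Hardy-Weinberg structure", {
  panel <- toy_panel(2)
  f <- c(AA = 0.5, AB = 0.3, BB = 0.2)
  rejections <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(panel, f, f, 600, 1, seed = seed)
    tr <- simulate_cohort_genotypes(cfg)$truth
    tr <- tr[tr$cohort == "case", ]
    dose <- (tr$hap1 == "AA") + (tr$hap2 == "AA")
    obs <- tabulate(dose + 1L, 3L)
    p <- c((1 - f[["AA"]])^2, 2 * f[["AA"]] * (1 - f[["AA"]]), f[["AA"]]^2)
    gof <- suppressWarnings(chisq.test(obs, p = p))
    if (gof$p.value < 0.01) rejections <- rejections + 1L
  }
  # under the null ~0.2 rejections are expected in 20 tests at alpha 0.01
  expect_lte(rejections, 1L)
})

test_that("LOF simulation preserves the per-gene allele-count structure", {
  cfg <- default_sim_config(n_case = 8, n_control = 8, seed = 6)
  samples <- data.frame(sample_id = sprintf("S%02d", 1:16),
                        cohort = rep(c("case", "control"), each = 8))
  vt <- simulate_lof_variants(cfg, samples)
  # per-cohort Alt+Ref observations per gene = 2 * n_cohort * n_sites(gene):
  # the 12-site gene gives 2*8*12 = 192 per cohort
  is_case <- vt$samples$cohort == "case"
  for (g in unique(vt$sites$gene)) {
    k <- sum(vt$sites$gene == g)
    alt <- sum(vt$dosage[vt$sites$gene == g, is_case])
    expect_lte(alt, 2 * 8 * k)   # ref = total - alt is non-negative
  }
  k12 <- sum(vt$sites$gene == "TMEM232")
  expect_equal(2 * 8 * k12, 192)

  # alt_freq 0 => zero case alt alleles
  panel <- toy_panel(2)
  cfg0 <- sim_config(panel, c(AA = 1), c(AA = 1), 4, 4,
                     lof_spec = data.frame(gene = "G", site_id = "s1",
                                           alt_freq_case = 0,
                                           alt_freq_control = 0.5,
                                           category = "exonic"), seed = 1)
  sm <- data.frame(sample_id = sprintf("S%d", 1:8),
                   cohort = rep(c("case", "control"), each = 4))
  vt0 <- simulate_lof_variants(cfg0, sm)
  expect_equal(sum(vt0$dosage[, sm$cohort == "case"]), 0L)
})

test_that("a planted site co-segregates with the target haplotype exactly", {
  panel <- toy_panel(2)
  f <- c(AA = 0.5, AB = 0.3, BB = 0.2)
  lof <- data.frame(gene = "G", site_id = sprintf("s%d", 1:2),
                    alt_freq_case = 0.3, alt_freq_control = 0.3,
                    category = "exonic")
  cfg <- sim_config(panel, f, f, 10, 10, lof_spec = lof,
                    coseg_target = "AB", coseg_gene = "G", seed = 8)
  sim <- simulate_cohort_genotypes(cfg)
  vt <- simulate_lof_variants(cfg, sim$truth[c("sample_id", "cohort")],
                              sim$truth)
  expect_true("G_coseg" %in% vt$sites$site_id)
  copy <- (sim$truth$hap1 == "AB") + (sim$truth$hap2 == "AB")
  expect_equal(unname(vt$dosage["G_coseg", sim$truth$sample_id]),
               as.integer(copy))
  expect_error(simulate_lof_variants(cfg, sim$truth[c("sample_id", "cohort")]),
               "truth")
})

test_that("read simulation plants exact violator counts and is deterministic", {
  sim <- simulate_reads(100, read_len = 100, frac_adapter = 0.1, seed = 3)
  has_ad <- grepl("AGATCGGAAGAGC", sim$reads$bases, fixed = TRUE)
  expect_equal(sum(has_ad), 10L)
  expect_setequal(sim$reads$read_id[has_ad],
                  sim$truth$read_id[sim$truth$violation == "adapter"])

  none <- simulate_reads(50, read_len = 80, seed = 1)
  expect_true(all(none$truth$violation == "none"))
  qc <- filter_reads(none$reads, adapter = "AGATCGGAAGAGC")
  expect_equal(qc$report$n_clean, 50L)

  all_lq <- simulate_reads(30, read_len = 80, frac_lowq = 1, seed = 1)
  qc2 <- filter_reads(all_lq$reads, adapter = "AGATCGGAAGAGC")
  expect_equal(qc2$report$n_clean, 0L)
  expect_equal(unname(qc2$report$removed_by[["low_quality"]]), 30L)

  expect_identical(simulate_reads(40, seed = 7, frac_highN = 0.2),
                   simulate_reads(40, seed = 7, frac_highN = 0.2))
  expect_error(simulate_reads(10, read_len = 5, frac_adapter = 0.5,
                              adapter = "AGATCGGAAGAGC"), "shorter")
  expect_error(simulate_reads(10, frac_adapter = 0.7, frac_lowq = 0.7),
               "sum")
})
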