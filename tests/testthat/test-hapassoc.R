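test_that("assoc_2x2 reproduces published gene-level statistics", {
  # TMEM232-type counts
  r <- assoc_2x2(20, 172, 50, 142)
  expect_equal(round(r$chi2, 2), 15.72)
  expect_equal(signif(r$p, 3), 7.33e-5)
  expect_equal(round(r$or_, 2), 0.33)
  expect_equal(round(r$ci_low, 2), 0.19)
  expect_equal(round(r$ci_high, 2), 0.58)
  # CAMK4-type counts
  r2 <- assoc_2x2(23, 73, 24, 72)
  expect_equal(round(r2$chi2, 2), 0.03)
  expect_equal(round(r2$or_, 2), 0.95)
  expect_equal(round(r2$ci_low, 2), 0.49)
  expect_equal(round(r2$ci_high, 2), 1.83)
})

test_that("assoc_2x2 handles symmetric and degenerate tables", {
  r <- assoc_2x2(10, 90, 10, 90)
  expect_equal(r$chi2, 0)
  expect_equal(r$or_, 1)
  expect_equal(r$p, 1)

  # single zero cell: OR/CI undefined, chi2 still computed
  z <- assoc_2x2(0, 100, 10, 90)
  expect_true(is.na(z$or_) && is.na(z$ci_low))
  expect_false(is.na(z$chi2))
  # empty allele margin: whole test undefined
  z2 <- assoc_2x2(0, 100, 0, 90)
  expect_true(is.na(z2$chi2) && is.na(z2$p) && is.na(z2$or_))
  # empty cohort margin: precondition violated
  expect_error(assoc_2x2(0, 0, 5, 5), "margin")
})

test_that("assoc_2x2 agrees with chisq.test and the two-proportion z statistic", {
  set.seed(42)
  for (k in 1:25) {
    tab <- matrix(sample(1:200, 4, replace = TRUE), 2)
    a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
    r <- assoc_2x2(a, b, c_, d)
    ref <- suppressWarnings(stats::chisq.test(rbind(c(a, b), c(c_, d)),
                                              correct = FALSE))
    expect_equal(r$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
    # chi2 equals the squared two-proportion z statistic
    p1 <- a / (a + b); p2 <- c_ / (c_ + d); pp <- (a + c_) / (a + b + c_ + d)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / (a + b) + 1 / (c_ + d)))
    expect_equal(r$chi2, z^2, tolerance = 1e-10)
    # row-swap invariance: OR inverts, chi2 unchanged
    r_swap <- assoc_2x2(c_, d, a, b)
    expect_equal(r_swap$chi2, r$chi2, tolerance = 1e-12)
    expect_equal(r_swap$or_, 1 / r$or_, tolerance = 1e-12)
    expect_true(r$ci_low <= r$or_ && r$or_ <= r$ci_high)
  }
})

test_that("assoc_from_freqs reproduces published odds ratios", {
  expect_equal(round(assoc_from_freqs(0.0016, 0.0094), 2), 0.17)
  expect_equal(round(assoc_from_freqs(0.2319, 0.2415), 2), 0.95)
  for (x in c(0.01, 0.3, 0.77)) expect_equal(assoc_from_freqs(x, x), 1)
  expect_true(is.na(assoc_from_freqs(0, 0.5)))
  expect_true(is.na(assoc_from_freqs(0.5, 1)))
  # agreement with count-based OR when counts are exactly f * 2N
  r <- assoc_2x2(40, 160, 30, 170)
  expect_equal(assoc_from_freqs(40 / 200, 30 / 200), r$or_, tolerance = 1e-12)
})

test_that("haplotype dosages conserve copies and drive the scan", {
  panel <- toy_panel(3)
  haps <- c("AAA", "BAA", "ABA")
  f <- c(0.6, 0.25, 0.15)
  cfg <- sim_config(panel, setNames(f, haps), setNames(f, haps),
                    150, 150, seed = 21)
  gm <- simulate_cohort_genotypes(cfg)$genotypes
  fit <- em_estimate(gm)
  dose <- haplotypes_to_biallelic(fit$phased, fit$freqs)
  expect_true(all(rowSums(dose) == 2L))
  scan <- haplotype_assoc_scan(dose, fit$phased$cohort)
  n_case <- sum(fit$phased$cohort == "case")
  expect_equal(sum(scan$a), 2 * n_case)
  expect_equal(sum(scan$c), 2 * (nrow(fit$phased) - n_case))
  expect_true(all(diff(rank(scan$p, na.last = "keep")) >= 0, na.rm = TRUE))

  # explicit dosages: (H15, H62) -> one copy each; (H15, H15) -> two
  ft <- label_haplotypes(data.frame(allele_string = c("AAA", "BAA")))
  ph <- data.frame(sample_id = c("S1", "S2"), cohort = c("case", "case"),
                   hap1 = c("AAA", "BAA"), hap2 = c("BAA", "BAA"))
  d2 <- haplotypes_to_biallelic(ph, ft)
  expect_equal(unname(d2["S1", ]), c(1L, 1L))
  expect_equal(unname(d2["S2", ]), c(0L, 2L))
})

test_that("a fully separated two-haplotype cohort yields the forced table", {
  ft <- label_haplotypes(data.frame(allele_string = c("AA", "BB")))
  ph <- data.frame(sample_id = sprintf("S%d", 1:6),
                   cohort = rep(c("case", "control"), each = 3),
                   hap1 = rep(c("AA", "BB"), each = 3),
                   hap2 = rep(c("AA", "BB"), each = 3))
  dose <- haplotypes_to_biallelic(ph, ft)
  scan <- haplotype_assoc_scan(dose, ph$cohort)
  h1 <- scan[scan$hap_id == "H1", ]
  expect_equal(h1$b, 0); expect_equal(h1$c, 0)
  expect_true(is.na(h1$or_))
  # chi2 is maximal for the table margins: equals N
  expect_equal(h1$chi2, 12)
})

test_that("pairwise r2 matches direct haplotype-count arithmetic", {
  # 4-haplotype pool AB:40 Ab:10 aB:10 ab:40 -> D = 0.15, r2 = 0.36
  x <- rep(c("A", "A", "a", "a"), c(40, 10, 10, 40))
  y <- rep(c("B", "b", "B", "b"), c(40, 10, 10, 40))
  expect_equal(pairwise_r2(x, y), 0.36, tolerance = 1e-12)
  # perfect correlation and exact independence
  expect_equal(pairwise_r2(c("A", "A", "a", "a"), c("B", "B", "b", "b")), 1)
  xy <- expand.grid(x = c("A", "a"), y = c("B", "b"))
  expect_equal(pairwise_r2(xy$x, xy$y), 0)
  # monomorphic marker undefined
  expect_true(is.na(pairwise_r2(c("A", "A"), c("B", "b"))))
})
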