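test_that("length histograms and medians are correct", {
  s <- sample_from_frequencies(rep(1 / 3, 3),
                               cdr3 = c("CAAAAAAAAW", "CAAAAAAAGW",
                                        "CAAAAAAAAAAAAAAAAAGW"))
  ld <- length_distribution(s, dither = FALSE)
  expect_equal(ld$histogram, c(`10` = 2 / 3, `20` = 1 / 3))
  expect_equal(ld$median_length, 10)
  # < 3 clonotypes: no normality p
  s2 <- sample_from_frequencies(c(0.5, 0.5), cdr3 = c("CAAW", "CADW"))
  expect_true(is.na(length_distribution(s2)$normality_p))
})

test_that("dithered Shapiro-Wilk is calibrated on rounded-Gaussian lengths", {
  set.seed(41)
  p_values <- replicate(60, {
    len <- round(stats::rnorm(400, 15, 3))
    len <- len[len >= 5 & len <= 35]
    s <- sample_from_frequencies(rep(1 / length(len), length(len)),
                                 cdr3 = random_junctions(len))
    s$records <- s$records[!duplicated(s$records$cdr3_aa), ]
    length_distribution(s)$normality_p
  })
  # roughly uniform: rejection near nominal, not degenerate
  expect_lt(mean(p_values < 0.05), 0.18)
  expect_gt(mean(p_values < 0.5), 0.25)
  # while the raw test on the same data over-rejects wildly
  set.seed(41)
  p_raw <- replicate(20, {
    len <- round(stats::rnorm(400, 15, 3))
    len <- len[len >= 5 & len <= 35]
    s <- sample_from_frequencies(rep(1 / length(len), length(len)),
                                 cdr3 = random_junctions(len))
    length_distribution(s, dither = FALSE)$normality_p
  })
  expect_gt(mean(p_raw < 0.05), 0.9)
})

test_that("KS comparison matches the brute-force ECDF scan", {
  s <- sample_from_frequencies(rep(1 / 4, 4),
                               cdr3 = c("CAW", "CADW", "CADEW", "CADEFW"))
  same <- compare_length_distributions(s, s)
  expect_equal(same$statistic, 0)
  # disjoint supports -> D = 1
  s_long <- sample_from_frequencies(rep(1 / 3, 3),
                                    cdr3 = c(strrep("A", 11), strrep("A", 12),
                                             strrep("A", 13)))
  expect_equal(compare_length_distributions(s, s_long)$statistic, 1)
  set.seed(42)
  for (rep in 1:10) {
    la <- sample(8:20, 30, replace = TRUE)
    lb <- sample(10:25, 25, replace = TRUE)
    sa <- sample_from_frequencies(rep(1 / 30, 30),
                                  cdr3 = random_junctions(la))
    sb <- sample_from_frequencies(rep(1 / 25, 25),
                                  cdr3 = random_junctions(lb))
    got <- compare_length_distributions(sa, sb)
    expect_equal(got$statistic,
                 oracle_ks_statistic(nchar(sa$records$cdr3_aa),
                                     nchar(sb$records$cdr3_aa)),
                 tolerance = 1e-12)
    # symmetry
    expect_equal(compare_length_distributions(sb, sa)$statistic,
                 got$statistic)
  }
})

test_that("physicochemical properties match residue-table arithmetic", {
  s <- sample_from_frequencies(rep(1 / 4, 4),
                               cdr3 = c("CAAAW", "CFWYHW", "CGGGW", "CKDEW"))
  ch <- chemistry(s)
  # gravy is the mean of residue hydropathies
  kd <- c(C = 2.5, A = 1.8, W = -0.9)
  expect_equal(ch$gravy[ch$cdr3_aa == "CAAAW"],
               (2.5 + 3 * 1.8 - 0.9) / 5)
  # aromatic fraction counts F, W, Y, H
  expect_equal(ch$aromatic_fraction[ch$cdr3_aa == "CFWYHW"], 5 / 6)
  # glycine-only interior: near-zero charge at pH 7 apart from C/W anchors
  g_only <- ch[ch$cdr3_aa == "CGGGW", ]
  cys_charge <- -1 / (1 + 10^(8.5 - 7))  # the single anchor cysteine
  expect_equal(g_only$net_charge, cys_charge, tolerance = 1e-6)
  # concatenation property: gravy of equal-length halves averages
  s2 <- sample_from_frequencies(rep(1 / 3, 3),
                                cdr3 = c("CADW", "CKLW", "CADWCKLW"))
  ch2 <- chemistry(s2)
  expect_equal(ch2$gravy[3], mean(ch2$gravy[1:2]), tolerance = 1e-12)
  # aliphatic index closed form
  expect_equal(ch$aliphatic_index[ch$cdr3_aa == "CAAAW"], 100 * 3 / 5)
  expect_equal(ch2$aliphatic_index[2], 100 * 3.9 / 4)  # one leucine
})

test_that("bare-residue chemistry matches the published scales", {
  s <- sample_from_frequencies(rep(1 / 2, 2), cdr3 = c("AAAA", "GGGG"))
  s$records$cdr3_aa <- c("A", "G")  # single residues
  ch <- chemistry(s)
  expect_equal(ch$gravy, c(1.8, -0.4))
  expect_equal(ch$net_charge, c(0, 0), tolerance = 1e-6)
})

test_that("group chemistry comparison runs over all group pairs", {
  co <- simulate_cohort(small_config(seed = 43))
  cmp <- compare_chemistry(co, "IGHG")
  expect_setequal(unique(cmp$property),
                  c("gravy", "net_charge", "aromatic_fraction",
                    "aliphatic_index", "length"))
  expect_equal(sum(cmp$property == "gravy"), choose(5, 2))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
})
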