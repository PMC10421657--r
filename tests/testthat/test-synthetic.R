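test_that("the same config and seed give byte-identical output", {
  cfg <- small_config(seed = 42)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1, co2)
  dir <- withr::local_tempdir()
  write_airr(co1, file.path(dir, "a.tsv"))
  write_airr(co2, file.path(dir, "b.tsv"))
  expect_identical(readLines(file.path(dir, "a.tsv")),
                   readLines(file.path(dir, "b.tsv")))
  # a different seed changes the sequences
  co3 <- simulate_cohort(small_config(seed = 43))
  expect_false(identical(co1$records$cdr3_aa, co3$records$cdr3_aa))
})

test_that("simulated cohorts satisfy all container invariants", {
  for (seed in 1:3) {
    co <- simulate_cohort(small_config(seed = seed))
    expect_silent(validate_cohort(co))
    expect_true(all(grepl("^C", co$records$cdr3_aa)))
    expect_true(all(grepl("W$", co$records$cdr3_aa)))
    expect_equal(nrow(co$metadata), 26)
    expect_setequal(unique(co$records$isotype), c("IGHM", "IGHG"))
  }
})

test_that("a huge Dirichlet concentration removes hyperexpanded clones", {
  rich <- c(nontreated = 300, treated = 300, remission = 300,
            endemic_control = 300, nonendemic_control = 300)
  cfg <- synthetic_config(
    richness = rich, isotypes = "IGHM", seed = 7,
    expansion_alpha = c(nontreated = 1e6, treated = 1e6, remission = 1e6,
                        endemic_control = 1e6, nonendemic_control = 1e6))
  spec <- abundance_spectra(simulate_cohort(cfg), "IGHM")
  hyper <- spec[spec$bin == "hyperexpanded", ]
  expect_true(all(hyper$proportion < 0.02))
  # and a small concentration produces hyperexpanded clones
  cfg2 <- synthetic_config(
    richness = rich, isotypes = "IGHM", seed = 7,
    expansion_alpha = c(nontreated = 0.05, treated = 0.05, remission = 0.05,
                        endemic_control = 0.05, nonendemic_control = 0.05))
  spec2 <- abundance_spectra(simulate_cohort(cfg2), "IGHM")
  hyper2 <- spec2[spec2$bin == "hyperexpanded", ]
  expect_gt(mean(hyper2$proportion), mean(hyper$proportion))
})

test_that("a planted cluster is recovered as one component of its variants", {
  cfg <- small_config(seed = 9)
  co <- simulate_cohort(cfg)
  net <- build_network(co, "IGHG", max_distance = 2)
  # brute-force pairwise Hamming check on the emitted table, over nodes of
  # the cluster length
  cl <- cfg$planted_clusters[[1]]
  L <- nchar(cl$seed_cdr3)
  nodes <- net$nodes[net$nodes$cdr3_length == L, ]
  comp_oracle <- oracle_hamming_components(nodes$cdr3_aa, 2)
  planted <- grepl("^CARDGYSSGW", nodes$cdr3_aa)  # cluster seed prefix
  expect_true(any(planted))
  expect_equal(length(unique(comp_oracle[planted])), 1)
  rel <- extract_relevant(net, min_samples = 4,
                          restrict_to = cl$samples)
  expect_length(rel, 1)
  expect_equal(rel[[1]]$exclusivity, "patient_exclusive")
  expect_equal(sort(rel[[1]]$sample_set), sort(cl$samples))
  expect_equal(nrow(rel[[1]]$nodes), cl$n_variants)
})

test_that("the null generator disables every group effect", {
  cfg <- small_config(seed = 3)
  co <- simulate_null_cohort(cfg)
  expect_silent(validate_cohort(co))
  # no planted cluster: no relevant component
  net <- build_network(co, "IGHG", max_distance = 2)
  expect_length(extract_relevant(net, min_samples = 4), 0)
  # richness comparable across regions (was 10x under the alternative)
  alpha <- stats::aggregate(
    count ~ sample_id,
    data.frame(count = 1, sample_id = co$records$sample_id), sum)
  grp <- co$metadata$group[match(alpha$sample_id, co$metadata$sample_id)]
  expect_lt(mean(alpha$count[grp == "nonendemic_control"]),
            2 * mean(alpha$count[grp != "nonendemic_control"]))
})

test_that("planted usage shifts move group means in the planted direction", {
  up_deltas <- c(); down_deltas <- c()
  for (seed in 1:10) {
    cfg <- synthetic_config(
      richness = c(nontreated = 400, treated = 400, remission = 400,
                   endemic_control = 400, nonendemic_control = 400),
      isotypes = "IGHG", seed = seed)
    co <- simulate_cohort(cfg)
    u <- usage_frequencies(co, "V", "IGHG")
    status <- disease_status_grouping(co)
    active <- intersect(names(status)[status == "active"], rownames(u))
    without <- intersect(names(status)[status == "without"], rownames(u))
    up_deltas <- c(up_deltas,
                   mean(u[active, "IGHV3-30"]) - mean(u[without, "IGHV3-30"]))
    down_deltas <- c(down_deltas,
                     mean(u[active, "IGHV3-23"]) - mean(u[without, "IGHV3-23"]))
  }
  expect_gt(mean(up_deltas > 0), 0.8)
  expect_gt(mean(down_deltas < 0), 0.8)
})

test_that("a planted cluster targeting an unknown sample is a config error", {
  expect_error(
    small_config(planted_clusters = list(list(
      seed_cdr3 = "CARDGYSSGWYLDYFDW", n_variants = 3,
      max_substitutions = 2, samples = c("NT1", "ZZ9"),
      isotype = "IGHG", frequency = 0.005))),
    "nonexistent")
})
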