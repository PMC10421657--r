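test_that("hamming distance counts mismatches on equal lengths only", {
  expect_equal(hamming("CARDW", "CARDW"), 0L)
  expect_equal(hamming("CARDW", "CARDY"), 1L)
  expect_true(is.na(hamming("CARW", "CARDW")))  # unequal length: no edge
})

test_that("a chain of distance-2 neighbors forms one component", {
  rec <- data.frame(
    sample_id = c("NT1", "NT2", "TR1", "RE1"), isotype = "IGHG",
    cdr3_aa = c("CAAAAW", "CAAADW", "CAADDW", "CADDDW"),
    v_call = "IGHV3-30", j_call = "IGHJ4", count = 1L,
    stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = c("NT1", "NT2", "TR1", "RE1"),
                     group = c("nontreated", "nontreated", "treated",
                               "remission"), stringsAsFactors = FALSE)
  net <- build_network(bcr_cohort(rec, meta), "IGHG", max_distance = 2)
  expect_length(net$components, 1)
  comp <- net$components[[1]]
  expect_equal(length(comp$sample_set), 4)
  # CAAAAW-CADDDW at distance 3: connected through the chain, no direct edge
  direct <- net$edges[(net$edges$node_a == "NT1|CAAAAW" &
                         net$edges$node_b == "RE1|CADDDW") |
                        (net$edges$node_a == "RE1|CADDDW" &
                           net$edges$node_b == "NT1|CAAAAW"), ]
  expect_equal(nrow(direct), 0)
  expect_equal(comp$exclusivity, "patient_exclusive")
})

test_that("identical sequences across samples join at distance 0", {
  rec <- data.frame(
    sample_id = c("NT1", "EC1"), isotype = "IGHG",
    cdr3_aa = "CARDW", v_call = "IGHV3-30", j_call = "IGHJ4",
    count = 1L, stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = c("NT1", "EC1"),
                     group = c("nontreated", "endemic_control"),
                     stringsAsFactors = FALSE)
  net <- build_network(bcr_cohort(rec, meta), "IGHG")
  expect_length(net$components, 1)
  expect_equal(net$edges$distance, 0L)
  expect_equal(net$components[[1]]$exclusivity, "mixed")
})

test_that("components match a brute-force all-pairs construction", {
  set.seed(51)
  co <- simulate_cohort(small_config(seed = 51))
  net <- build_network(co, "IGHG", max_distance = 2)
  # brute force on every length class with >= 2 nodes
  nodes <- net$nodes
  got <- rep(NA_integer_, nrow(nodes))
  for (comp_id in seq_along(net$components)) {
    got[match(net$components[[comp_id]]$nodes$node_id, nodes$node_id)] <-
      comp_id
  }
  oracle <- oracle_hamming_components(nodes$cdr3_aa, 2)
  # same partition (labels may differ)
  expect_equal(length(unique(got)), length(unique(oracle)))
  expect_true(all(tapply(oracle, got, function(x) length(unique(x))) == 1))
  # row-order invariance
  co2 <- co
  co2$records <- co2$records[rev(seq_len(nrow(co2$records))), ]
  net2 <- build_network(co2, "IGHG", max_distance = 2)
  expect_equal(net2$nodes, net$nodes)
  expect_equal(net2$edges, net$edges)
  # every component is length-homogeneous
  expect_true(all(vapply(net$components, function(cmp)
    length(unique(nchar(cmp$nodes$cdr3_aa))) == 1, logical(1))))
  # with max_distance 0, components are groups of identical sequences
  net0 <- build_network(co, "IGHG", max_distance = 0)
  for (cmp in net0$components) {
    expect_equal(length(unique(cmp$nodes$cdr3_aa)), 1)
  }
})

test_that("relevant components respect threshold, restriction, exclusivity", {
  rec <- data.frame(
    sample_id = c("NT1", "NT2", "TR1", "RE1", "EC1"),
    isotype = "IGHG",
    cdr3_aa = c("CARDDW", "CARDEW", "CARDFW", "CARDGW", "CARDHW"),
    v_call = "IGHV3-30", j_call = "IGHJ4", count = 1L,
    stringsAsFactors = FALSE)
  meta <- data.frame(
    sample_id = c("NT1", "NT2", "TR1", "RE1", "EC1"),
    group = c("nontreated", "nontreated", "treated", "remission",
              "endemic_control"), stringsAsFactors = FALSE)
  co <- bcr_cohort(rec, meta)
  net <- build_network(co, "IGHG", max_distance = 2)
  expect_length(net$components, 1)
  patients <- c("NT1", "NT2", "TR1", "RE1")
  # mixed when the control node is in the component
  rel <- extract_relevant(net, min_samples = 4, restrict_to = patients)
  expect_length(rel, 1)
  expect_equal(rel[[1]]$exclusivity, "mixed")
  # threshold: a 3-patient restriction excludes it
  expect_length(extract_relevant(net, min_samples = 4,
                                 restrict_to = c("NT1", "NT2", "TR1")), 0)
})

test_that("consensus matrices count one vote per node with alphabetical ties", {
  cm <- consensus_matrix(c("CAR", "CAR", "CAK"))
  expect_equal(cm$consensus, "CAR")
  expect_equal(cm$matrix["R", 3], 2 / 3)
  expect_equal(cm$matrix["K", 3], 1 / 3)
  expect_true(all(abs(colSums(cm$matrix) - 1) < 1e-9))
  # single member: degenerate columns
  cm1 <- consensus_matrix("CYW")
  expect_equal(cm1$consensus, "CYW")
  expect_true(all(colSums(cm1$matrix == 1) == 1))
  # tie A vs C -> alphabetical winner A
  cm2 <- consensus_matrix(c("A", "A", "C", "C"))
  expect_equal(cm2$consensus, "A")
})
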