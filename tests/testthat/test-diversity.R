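test_that("pairwise CDR3 distance is the normalized unit-cost edit distance", {
  d <- pairwise_cdr3_distance(c("CARDW", "CARW"))
  expect_equal(d["CARW", "CARDW"], 1 / 5)  # one gap / max length 5
  expect_equal(diag(d), c(CARDW = 0, CARW = 0))
  expect_true(isSymmetric(d))
  # brute-force recursion oracle on short random sequences
  set.seed(2)
  seqs <- vapply(1:12, function(i)
    paste(sample(c("A", "C", "D", "E"), sample(1:8, 1), replace = TRUE),
          collapse = ""), "")
  seqs <- unique(seqs)
  names(seqs) <- paste0("s", seq_along(seqs))
  d <- pairwise_cdr3_distance(seqs)
  for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
    expect_equal(d[i, j],
                 edit_distance_recursive(seqs[i], seqs[j]) /
                   max(nchar(seqs[i]), nchar(seqs[j])))
  }
  # invalid residue errors with position information
  expect_error(pairwise_cdr3_distance(c("CARXW", "CARDW")), "position")
})

test_that("neighbor joining reproduces additive distances", {
  # 3-taxon closed form: a=(dAB+dAC-dBC)/2 etc.
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- build_nj_tree(d)
  pd <- ape::cophenetic.phylo(tr)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(pd, d, tolerance = 1e-9)
  pendant <- tr$edge.length[tr$edge[, 2] <= 3]
  names(pendant) <- tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]]
  # rooting splits one pendant branch; leaf-to-leaf paths still place
  # A and B at 1 and C at 2 from the inner node
  expect_equal(pd["A", "B"], 2)
  expect_equal(pd["A", "C"], 3)

  # additive 4-taxon matrix from a known tree
  true_tree <- ape::read.tree(text = "((A:1,B:2):0.7,(C:1.5,D:0.5):0.3);")
  d4 <- ape::cophenetic.phylo(true_tree)
  tr4 <- build_nj_tree(d4[order(rownames(d4)), order(colnames(d4))])
  pd4 <- ape::cophenetic.phylo(tr4)
  expect_equal(pd4[rownames(d4), colnames(d4)], d4, tolerance = 1e-9)

  # ultrametric matrix: NJ topology = single-linkage topology ((A,B),C,D)
  du <- matrix(c(0, 1, 4, 4,
                 1, 0, 4, 4,
                 4, 4, 0, 2,
                 4, 4, 2, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tru <- build_nj_tree(du)
  # A,B are siblings; C,D are siblings, as single linkage would group them
  expect_true(ape::is.monophyletic(tru, c("A", "B")))
  expect_true(ape::is.monophyletic(tru, c("C", "D")))

  expect_error(build_nj_tree(d[1:2, 1:2]), "star")
})

test_that("trees have non-negative branch lengths and round-trip newick", {
  set.seed(31)
  seqs <- unique(random_junctions(pmax(8, round(rnorm(40, 15, 3)))))
  tr <- build_nj_tree(pairwise_cdr3_distance(seqs))
  expect_true(all(tr$edge.length >= 0))
  expect_true(ape::is.rooted(tr))
  dir <- withr::local_tempdir()
  write_newick(tr, file.path(dir, "t.nwk"))
  tr2 <- read_newick(file.path(dir, "t.nwk"))
  expect_equal(ape::cophenetic.phylo(tr2)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr), tolerance = 1e-9)
})

test_that("Shannon index matches closed forms", {
  expect_equal(shannon_index(sample_from_frequencies(1)), 0)
  expect_equal(shannon_index(sample_from_frequencies(rep(1 / 8, 8))), log(8))
  expect_equal(shannon_index(sample_from_frequencies(c(0.5, 0.25, 0.25))),
               -sum(c(0.5, 0.25, 0.25) * log(c(0.5, 0.25, 0.25))))
  # uniform maximizes H at fixed richness
  set.seed(4)
  for (i in 1:5) {
    f <- stats::rexp(16); f <- f / sum(f)
    expect_lte(shannon_index(sample_from_frequencies(f)), log(16) + 1e-12)
  }
})

test_that("Faith's PD matches manual and brute-force oracles", {
  tr <- toy_tree()
  expect_equal(faith_pd(tr, c("A", "C")), 4.5)
  expect_equal(faith_pd(tr, c("A", "B", "C")), 6.5)
  expect_error(faith_pd(tr, c("A", "Z")), "Z")
  # monotone in the observed set
  expect_lte(faith_pd(tr, "A"), faith_pd(tr, c("A", "B")))
  set.seed(11)
  for (rep in 1:20) {
    tree <- random_rooted_tree(sample(4:16, 1))
    obs <- sample(tree$tip.label, sample(1:ape::Ntip(tree), 1))
    expect_equal(faith_pd(tree, obs), oracle_faith_pd(tree, obs),
                 tolerance = 1e-12)
  }
  # cross-check against picante's root-inclusive PD
  comm <- matrix(1, 1, 3, dimnames = list("s", c("A", "B", "C")))
  comm2 <- matrix(c(1, 0, 1), 1, 3, dimnames = list("s", c("A", "B", "C")))
  expect_equal(faith_pd(tr, c("A", "B", "C")),
               picante::pd(comm, tr, include.root = TRUE)$PD)
  expect_equal(faith_pd(tr, c("A", "C")),
               picante::pd(comm2, tr, include.root = TRUE)$PD)
})

test_that("weighted UniFrac matches its definition and stays in [0,1]", {
  tr <- toy_tree()
  a <- c(A = 1); c_ <- c(C = 1)
  expect_equal(weighted_unifrac(tr, a, a), 0)
  expect_equal(weighted_unifrac(tr, a, c_), 1)
  expect_error(weighted_unifrac(tr, c(A = 0), c(C = 0)), "zero")
  set.seed(12)
  for (rep in 1:20) {
    tree <- random_rooted_tree(sample(4:16, 1))
    pa <- random_abundance(tree); pb <- random_abundance(tree)
    u <- weighted_unifrac(tree, pa, pb)
    expect_equal(u, oracle_weighted_unifrac(tree, pa, pb), tolerance = 1e-9)
    expect_gte(u, 0); expect_lte(u, 1)
    # symmetry
    expect_equal(weighted_unifrac(tree, pb, pa), u)
  }
  # triangle inequality, empirically
  set.seed(13)
  tree <- random_rooted_tree(10)
  for (rep in 1:10) {
    pa <- random_abundance(tree); pb <- random_abundance(tree)
    pc <- random_abundance(tree)
    expect_lte(weighted_unifrac(tree, pa, pc),
               weighted_unifrac(tree, pa, pb) +
                 weighted_unifrac(tree, pb, pc) + 1e-12)
  }
})

test_that("unifrac_matrix agrees with pairwise calls", {
  set.seed(14)
  tree <- random_rooted_tree(12)
  ab <- sapply(1:4, function(i) random_abundance(tree))
  rownames(ab) <- tree$tip.label
  colnames(ab) <- paste0("S", 1:4)
  D <- unifrac_matrix(tree, ab)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(D[i, j],
                 weighted_unifrac(tree, ab[, i], ab[, j]), tolerance = 1e-12)
  }
  validate_distance_matrix(D)
})

test_that("PCoA embeds Euclidean matrices exactly", {
  # collinear points 0, 1, 2
  d <- as.matrix(stats::dist(matrix(c(0, 1, 2), 3, 1)))
  dimnames(d) <- list(c("a", "b", "c"), c("a", "b", "c"))
  p <- suppressWarnings(pcoa(d, n_axes = 2))
  expect_equal(sum(p$eigenvalues > 1e-9), 1)
  got <- sort(p$coordinates[, 1])
  expect_equal(unname(got - mean(got)), c(-1, 0, 1), tolerance = 1e-9)
  # identical points: all eigenvalues 0
  dz <- matrix(0, 3, 3, dimnames = dimnames(d))
  pz <- suppressWarnings(pcoa(dz, 1))
  expect_true(all(abs(pz$eigenvalues) < 1e-12))
  # round trip for random 2-D configurations
  set.seed(15)
  xy <- matrix(stats::rnorm(20), 10, 2)
  d2 <- as.matrix(stats::dist(xy))
  dimnames(d2) <- list(paste0("p", 1:10), paste0("p", 1:10))
  p2 <- pcoa(d2, n_axes = 2)
  expect_equal(as.matrix(stats::dist(p2$coordinates)), d2,
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("PERMANOVA pseudo-F and p match the worked example", {
  d <- matrix(2, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 1; d[3, 4] <- d[4, 3] <- 1
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  labels <- c(s1 = "g1", s2 = "g1", s3 = "g2", s4 = "g2")
  res <- permanova(d, labels)
  expect_equal(res$pseudo_F, 7)
  expect_true(res$exhaustive)
  expect_equal(res$p_value, 1 / 3)
  # sampled path converges to the exhaustive value
  res_s <- permanova(d, labels, n_permutations = 10000, seed = 99,
                     exhaustive = FALSE)
  expect_equal(res_s$p_value, 1 / 3, tolerance = 0.05)
  # invariant to renaming groups
  labels2 <- c(s1 = "zzz", s2 = "zzz", s3 = "aaa", s4 = "aaa")
  expect_equal(permanova(d, labels2)$p_value, res$p_value)
  # errors
  expect_error(permanova(d, c(s1 = "g1", s2 = "g1", s3 = "g1", s4 = "g2")),
               ">= 2 samples")
  dz <- matrix(0, 4, 4, dimnames = dimnames(d))
  expect_error(permanova(dz, labels), "zero")
})

test_that("PERMANOVA agrees with vegan::adonis2 on random data", {
  set.seed(16)
  xy <- matrix(stats::rnorm(40), 20, 2)
  d <- as.matrix(stats::dist(xy))
  dimnames(d) <- list(paste0("s", 1:20), paste0("s", 1:20))
  grp <- rep(c("a", "b"), each = 10)
  names(grp) <- rownames(d)
  res <- permanova(d, grp, n_permutations = 999, seed = 1)
  ad <- vegan::adonis2(stats::as.dist(d) ~ g,
                       data = data.frame(g = grp), permutations = 999)
  expect_equal(res$pseudo_F, ad$F[1], tolerance = 1e-9)
  expect_lt(abs(res$p_value - ad$`Pr(>F)`[1]), 0.05)  # Monte-Carlo error
  # seed determinism of the sampled path
  res2 <- permanova(d, grp, n_permutations = 999, seed = 1)
  expect_identical(res$p_value, res2$p_value)
})

test_that("beta diversity applies the isotype-specific frequency filter", {
  co <- simulate_cohort(small_config(seed = 17))
  b <- beta_diversity(co, "IGHG", n_permutations = 99, seed = 1)
  # default IGHG filter drops clonotypes at or below 0.1%
  leaves <- rownames(b$abundance)
  rec <- co$records[co$records$isotype == "IGHG", ]
  kept <- unique(rec$cdr3_aa[rec$frequency > 0.001])
  expect_setequal(leaves, kept)
  expect_true(all(abs(colSums(b$abundance) - 1) < 1e-9))
  validate_distance_matrix(b$distances)
  expect_true(all(b$distances >= 0 & b$distances <= 1 + 1e-12))
})
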