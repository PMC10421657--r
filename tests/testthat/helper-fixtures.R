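# Shared fixtures and independent brute-force oracles.

# -- tiny hand-built cohort -------------------------------------------------

toy_records <- function() {
  data.frame(
    sample_id = c("NT1", "NT1", "NT1", "EC1", "EC1", "NC1", "NC1"),
    isotype = c("IGHG", "IGHG", "IGHG", "IGHG", "IGHG", "IGHM", "IGHM"),
    c_call = c("IGHG1", "IGHG3/4", "IGHG1", "IGHG2", "IGHG1", "IGHM", "IGHM"),
    cdr3_aa = c("CARDW", "CARYW", "CTTDW", "CARDW", "CGGGW", "CAKLW",
                "CAKMW"),
    v_call = c("IGHV3-30", "IGHV3-23", "IGHV1-69", "IGHV3-30", "IGHV5-51",
               "IGHV3-30", "IGHV4-34"),
    j_call = c("IGHJ4", "IGHJ4", "IGHJ6", "IGHJ4", "IGHJ3", "IGHJ4",
               "IGHJ5"),
    count = c(6L, 3L, 1L, 4L, 4L, 5L, 5L),
    stringsAsFactors = FALSE)
}

toy_metadata <- function() {
  data.frame(sample_id = c("NT1", "EC1", "NC1"),
             group = c("nontreated", "endemic_control",
                       "nonendemic_control"),
             stringsAsFactors = FALSE)
}

toy_cohort <- function() bcr_cohort(toy_records(), toy_metadata())

# A repertoire_sample built directly from frequencies (counts scaled).
sample_from_frequencies <- function(freqs, sample_id = "S1",
                                    group = "nontreated",
                                    isotype = "IGHG",
                                    cdr3 = NULL) {
  n <- length(freqs)
  if (is.null(cdr3)) {
    # unique valid junctions: base-20 encoding of the index over 3 positions
    cdr3 <- vapply(seq_len(n) - 1L, function(i)
      paste0("C", AA_ALPHABET[1 + (i %% 20)],
             AA_ALPHABET[1 + ((i %/% 20) %% 20)],
             AA_ALPHABET[1 + ((i %/% 400) %% 20)], "W"), "")
  }
  counts <- round(freqs / min(freqs))
  rec <- data.frame(sample_id = sample_id, isotype = isotype,
                    c_call = NA_character_, cdr3_aa = cdr3,
                    cdr3_nt = NA_character_,
                    v_call = paste0("IGHV3-", seq_len(n)),
                    d_call = NA_character_, j_call = "IGHJ4",
                    count = as.integer(counts), group = group,
                    frequency = freqs, stringsAsFactors = FALSE)
  structure(list(sample_id = sample_id, group = group, isotype = isotype,
                 records = rec, total_migs = sum(counts)),
            class = "repertoire_sample")
}

# internal generator reused to build fixture junction sequences
random_junctions <- function(len) pfrepertoire:::random_junctions(len)

# small scaled synthetic config for fast end-to-end tests
small_config <- function(seed = 1, ...) {
  synthetic_config(
    richness = c(nontreated = 30, treated = 30, remission = 30,
                 endemic_control = 30, nonendemic_control = 300),
    seed = seed, ...)
}

# -- toy tree of the worked examples ---------------------------------------

toy_tree <- function() ape::read.tree(text = "((A:1,B:2):0.5,C:3);")

random_rooted_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = TRUE,
                   br = function(k) stats::runif(k, 0.1, 2))
  tr$tip.label <- paste0("L", seq_len(n_leaves))
  tr
}

random_abundance <- function(tree) {
  x <- stats::rexp(ape::Ntip(tree))
  stats::setNames(x / sum(x), tree$tip.label)
}

# -- independent oracles ----------------------------------------------------

# Exhaustive-recursion unit-cost edit distance, memoised on suffix pairs
# (independent DP over the full recursion tree; practical for lengths <= 8).
edit_distance_recursive <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(a, b) {
    if (nchar(a) == 0) return(nchar(b))
    if (nchar(b) == 0) return(nchar(a))
    key <- paste(a, b, sep = "\r")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    rest_a <- substr(a, 2, nchar(a))
    rest_b <- substr(b, 2, nchar(b))
    val <- min(rec(rest_a, b) + 1,
               rec(a, rest_b) + 1,
               rec(rest_a, rest_b) + (substr(a, 1, 1) != substr(b, 1, 1)))
    memo[[key]] <- val
    val
  }
  rec(a, b)
}

# Leaf set below each edge, via nodepath from the root (independent of the
# package's postorder sweep).
oracle_edge_leafsets <- function(tree) {
  root <- ape::Ntip(tree) + 1L
  paths <- lapply(seq_len(ape::Ntip(tree)),
                  function(l) ape::nodepath(tree, root, l))
  lapply(seq_len(nrow(tree$edge)), function(e) {
    child <- tree$edge[e, 2]
    which(vapply(paths, function(p) child %in% p, logical(1)))
  })
}

# Faith's PD as the union of root-to-leaf edge sets.
oracle_faith_pd <- function(tree, observed) {
  idx <- match(observed, tree$tip.label)
  sets <- oracle_edge_leafsets(tree)
  on_path <- vapply(sets, function(s) any(idx %in% s), logical(1))
  sum(tree$edge.length[on_path])
}

# Normalized weighted UniFrac by direct branch enumeration.
oracle_weighted_unifrac <- function(tree, a, b) {
  av <- stats::setNames(numeric(ape::Ntip(tree)), tree$tip.label)
  bv <- av
  av[names(a)] <- a; bv[names(b)] <- b
  sets <- oracle_edge_leafsets(tree)
  num <- sum(vapply(seq_along(sets), function(e) {
    tree$edge.length[e] * abs(sum(av[sets[[e]]]) - sum(bv[sets[[e]]]))
  }, numeric(1)))
  root <- ape::Ntip(tree) + 1L
  depths <- vapply(seq_len(ape::Ntip(tree)), function(l) {
    p <- ape::nodepath(tree, root, l)
    sum(vapply(seq_len(length(p) - 1), function(k) {
      e <- which(tree$edge[, 1] == p[k] & tree$edge[, 2] == p[k + 1])
      tree$edge.length[e]
    }, numeric(1)))
  }, numeric(1))
  num / sum(depths * (av + bv))
}

# Two-sample KS statistic by scanning every observed value.
oracle_ks_statistic <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# Connected components under the equal-length Hamming <= max_distance rule,
# by repeated merging over a brute-force edge list.
oracle_hamming_components <- function(node_seq, max_distance) {
  n <- length(node_seq)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- hamming(node_seq[i], node_seq[j])
      if (!is.na(d) && d <= max_distance && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# exact central binomial 95% acceptance counts for n trials at rate p
binom_bounds <- function(n, p = 0.05) {
  stats::qbinom(c(0.025, 0.975), n, p)
}
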