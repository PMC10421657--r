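## Hamming-distance CDR3 similarity networks ---------------------------------

#' Hamming distance between two equal-length sequences
#'
#' The number of mismatched positions. Sequences of unequal length are not
#' comparable under this metric (no edge): the result is `NA`.
#'
#' @param seq_a,seq_b amino-acid strings
#' @return integer mismatch count, or `NA` for unequal lengths
#' @export
hamming <- function(seq_a, seq_b) {
  stopifnot(nzchar(seq_a), nzchar(seq_b))
  if (nchar(seq_a) != nchar(seq_b)) return(NA_integer_)
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  sum(a != b)
}

#' Build a CDR3 similarity network over a cohort
#'
#' One node per (sample, unique CDR3 amino-acid sequence) for the requested
#' isotype; an edge joins two nodes when their sequences have equal length
#' and Hamming distance at most `max_distance` (including distance 0 for
#' identical sequences shared by different samples). Components are the
#' connected components of this graph and are length-homogeneous by
#' construction.
#'
#' @param cohort a [bcr_cohort]
#' @param isotype "IGHM" (all clonotypes) or "IGHG" (the default, as in the
#'   published network analysis)
#' @param max_distance maximum Hamming distance for an edge
#' @param samples optional sample-id subset to build the network on (e.g.
#'   endemic-area samples only)
#' @return a `clonal_network`: list with `nodes` (data.frame: node_id,
#'   sample_id, group, cdr3_aa, cdr3_length, frequency), `edges`
#'   (data.frame: node_a, node_b, distance), and `components` (list of
#'   `network_component`)
#' @export
build_network <- function(cohort, isotype = "IGHG", max_distance = 2,
                          samples = NULL) {
  isotype <- match.arg(isotype, ISOTYPE_LEVELS)
  stopifnot(max_distance >= 0)
  rec <- cohort$records[cohort$records$isotype == isotype, , drop = FALSE]
  if (!is.null(samples)) rec <- rec[rec$sample_id %in% samples, , drop = FALSE]
  if (nrow(rec) == 0) {
    return(structure(list(nodes = empty_nodes(), edges = empty_edges(),
                          components = list()),
                     class = "clonal_network"))
  }
  # collapse clonotypes sharing a CDR3 within a sample (frequencies summed)
  key <- paste(rec$sample_id, rec$cdr3_aa, sep = "\r")
  freq <- rowsum(rec$frequency, key, reorder = FALSE)
  first <- rec[!duplicated(key), , drop = FALSE]
  nodes <- data.frame(
    node_id = paste(first$sample_id, first$cdr3_aa, sep = "|"),
    sample_id = first$sample_id, group = first$group,
    cdr3_aa = first$cdr3_aa, cdr3_length = nchar(first$cdr3_aa),
    frequency = freq[match(unique(key), rownames(freq)), 1],
    stringsAsFactors = FALSE, row.names = NULL)
  nodes <- nodes[order(nodes$node_id), , drop = FALSE]
  rownames(nodes) <- NULL

  edges <- hamming_edges(nodes$cdr3_aa, max_distance)
  edges <- data.frame(node_a = nodes$node_id[edges$i],
                      node_b = nodes$node_id[edges$j],
                      distance = edges$d, stringsAsFactors = FALSE)

  g <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b")], directed = FALSE,
    vertices = nodes$node_id)
  membership <- igraph::components(g)$membership[nodes$node_id]
  components <- lapply(split(seq_len(nrow(nodes)), membership),
                       function(idx) make_component(nodes[idx, , drop = FALSE]))
  names(components) <- NULL
  structure(list(nodes = nodes, edges = edges, components = components),
            class = "clonal_network")
}

empty_nodes <- function() {
  data.frame(node_id = character(), sample_id = character(),
             group = character(), cdr3_aa = character(),
             cdr3_length = integer(), frequency = numeric(),
             stringsAsFactors = FALSE)
}
empty_edges <- function() {
  data.frame(node_a = character(), node_b = character(),
             distance = integer(), stringsAsFactors = FALSE)
}

# All pairs (i < j) of equal-length sequences with Hamming distance <=
# max_distance, computed per length class from a position-wise character
# matrix.
hamming_edges <- function(seqs, max_distance) {
  out_i <- integer(0); out_j <- integer(0); out_d <- integer(0)
  for (idx in split(seq_along(seqs), nchar(seqs))) {
    n <- length(idx)
    if (n < 2) next
    L <- nchar(seqs[idx[1]])
    m <- matrix(unlist(strsplit(seqs[idx], ""), use.names = FALSE),
                nrow = n, ncol = L, byrow = TRUE)
    D <- matrix(0L, n, n)
    for (p in seq_len(L)) D <- D + outer(m[, p], m[, p], "!=")
    hit <- which(D <= max_distance & upper.tri(D), arr.ind = TRUE)
    if (nrow(hit) > 0) {
      out_i <- c(out_i, idx[hit[, 1]])
      out_j <- c(out_j, idx[hit[, 2]])
      out_d <- c(out_d, D[hit])
    }
  }
  list(i = out_i, j = out_j, d = out_d)
}

make_component <- function(node_df) {
  lens <- unique(node_df$cdr3_length)
  stopifnot(length(lens) == 1)  # forced by the equal-length Hamming rule
  cons <- consensus_matrix(node_df$cdr3_aa)
  structure(list(
    nodes = node_df,
    sample_set = sort(unique(node_df$sample_id)),
    group_set = sort(unique(node_df$group)),
    cdr3_length = lens,
    exclusivity = if (all(node_df$group %in% PATIENT_GROUPS))
      "patient_exclusive" else "mixed",
    consensus = cons$matrix,
    consensus_string = cons$consensus),
    class = "network_component")
}

#' Extract PF-relevant network components
#'
#' Components whose sample set intersects `restrict_to` in at least
#' `min_samples` samples (the published rule: clonotypes from at least four
#' different samples, at maximum Hamming distance two). Each retained
#' component is labeled `patient_exclusive` when every member node comes
#' from a patient group, `mixed` otherwise.
#'
#' @param network a `clonal_network`
#' @param min_samples minimum number of distinct qualifying samples
#' @param restrict_to sample ids counted toward the threshold; `NULL` counts
#'   all samples
#' @return list of `network_component`
#' @export
extract_relevant <- function(network, min_samples = 4, restrict_to = NULL) {
  stopifnot(inherits(network, "clonal_network"), min_samples >= 1)
  Filter(function(comp) {
    qualifying <- if (is.null(restrict_to)) comp$sample_set
                  else intersect(comp$sample_set, restrict_to)
    length(qualifying) >= min_samples
  }, network$components)
}

#' Position frequency matrix and consensus string of aligned sequences
#'
#' One vote per sequence (node); columns are position-wise residue
#' frequencies over the 20-letter alphabet (column-stochastic). The
#' consensus letter is the per-position argmax with alphabetical
#' tie-breaking.
#'
#' @param sequences equal-length amino-acid strings
#' @return list: `matrix` (20 residues x positions), `consensus` (string)
#' @export
consensus_matrix <- function(sequences) {
  stopifnot(length(sequences) > 0, length(unique(nchar(sequences))) == 1)
  L <- nchar(sequences[1])
  m <- matrix(unlist(strsplit(sequences, ""), use.names = FALSE),
              nrow = length(sequences), ncol = L, byrow = TRUE)
  pfm <- vapply(seq_len(L), function(p) {
    tabulate(factor(m[, p], levels = AA_ALPHABET), nbins = 20L) /
      length(sequences)
  }, numeric(20L))
  rownames(pfm) <- AA_ALPHABET
  colnames(pfm) <- seq_len(L)
  # which.max returns the first maximum; AA_ALPHABET is sorted, so ties
  # break alphabetically
  consensus <- paste(AA_ALPHABET[apply(pfm, 2, which.max)], collapse = "")
  list(matrix = pfm, consensus = consensus)
}

#' Consensus of a network component
#'
#' @param component a `network_component`
#' @return list: `matrix`, `consensus`
#' @export
consensus <- function(component) {
  stopifnot(inherits(component, "network_component"))
  list(matrix = component$consensus, consensus = component$consensus_string)
}

#' Tidy report of network components
#'
#' @param components list of `network_component` (e.g. from
#'   [extract_relevant()])
#' @return data.frame: component_id, cdr3_length, n_nodes, n_samples,
#'   samples, exclusivity, consensus
#' @export
component_report <- function(components) {
  if (length(components) == 0) {
    return(data.frame(component_id = integer(), cdr3_length = integer(),
                      n_nodes = integer(), n_samples = integer(),
                      samples = character(), exclusivity = character(),
                      consensus = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_along(components), function(k) {
    comp <- components[[k]]
    data.frame(component_id = k, cdr3_length = comp$cdr3_length,
               n_nodes = nrow(comp$nodes),
               n_samples = length(comp$sample_set),
               samples = paste(comp$sample_set, collapse = ","),
               exclusivity = comp$exclusivity,
               consensus = comp$consensus_string, stringsAsFactors = FALSE)
  }))
}
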