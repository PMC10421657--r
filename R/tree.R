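## Tree construction and phylogenetic diversity -----------------------------

#' Build a rooted neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei neighbor joining (via \code{\link[ape]{nj}}), followed by
#' clamping of negative estimated branch lengths to zero with the deficit
#' transferred to the sibling edge, and midpoint rooting (the midpoint of the
#' longest leaf-to-leaf path), since UniFrac and root-inclusive Faith's PD
#' need a rooted tree.
#'
#' @param distances labeled symmetric distance matrix (>= 3 labels)
#' @return a rooted `ape::phylo` tree with non-negative branch lengths
#' @export
build_nj_tree <- function(distances) {
  validate_distance_matrix(distances)
  if (nrow(distances) < 3) {
    stop("need >= 3 labels for neighbor joining; ",
         "use a trivial star tree for fewer")
  }
  tree <- ape::nj(stats::as.dist(distances))
  tree <- clamp_negative_branches(tree)
  tree <- phangorn::midpoint(tree)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# Negative NJ branch estimates are artifacts of non-additivity: set them to
# zero and transfer the deficit to the sibling edge so paths through the
# parent node keep their total length where possible.
clamp_negative_branches <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0) break
    e <- neg[1]
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1]
    sibs <- which(tree$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    if (length(sibs) > 0) {
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + deficit
      if (tree$edge.length[sibs[1]] < 0) tree$edge.length[sibs[1]] <- 0
    }
  }
  tree
}

#' Read / write trees in newick format
#'
#' Thin wrappers over `ape` so externally built trees (e.g. from a
#' MAFFT + FastTree toolchain) can be used as the diversity substrate.
#'
#' @param path newick file path
#' @return `read_newick`: an `ape::phylo`; `write_newick`: the path,
#'   invisibly
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("format error: could not parse newick file ", path)
  tree
}

#' @rdname read_newick
#' @param tree an `ape::phylo`
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

# parent-of lookup and edge index by child node
tree_parent_edges <- function(tree) {
  n_nodes <- max(tree$edge)
  edge_of_child <- integer(n_nodes)
  edge_of_child[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  edge_of_child
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the minimal subtree connecting the observed
#' leaves and the root (root-inclusive convention, as in common
#' phyloseq/picante usage).
#'
#' @param tree rooted `ape::phylo`
#' @param observed_leaves character vector of leaf labels present
#' @return PD in branch-length units
#' @export
faith_pd <- function(tree, observed_leaves) {
  observed_leaves <- unique(observed_leaves)
  if (length(observed_leaves) == 0) stop("no observed leaves given")
  idx <- match(observed_leaves, tree$tip.label)
  if (anyNA(idx)) {
    stop("unknown leaf label(s): ",
         paste(observed_leaves[is.na(idx)], collapse = ", "))
  }
  edge_of_child <- tree_parent_edges(tree)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ape::Ntip(tree) + 1L
  on_path <- logical(nrow(tree$edge))
  for (leaf in idx) {
    node <- leaf
    while (node != root) {
      e <- edge_of_child[node]
      if (on_path[e]) break  # rest of the path already marked
      on_path[e] <- TRUE
      node <- parent[node]
    }
  }
  sum(tree$edge.length[on_path])
}

# Edge-wise descending abundance fractions: for an abundance matrix
# (leaves x samples, columns summing to 1), returns the edges x samples
# matrix of abundance mass below each edge, via one postorder sweep.
edge_abundance <- function(tree, abundance) {
  po <- ape::reorder.phylo(tree, "postorder")
  n_nodes <- max(tree$edge)
  acc <- matrix(0, n_nodes, ncol(abundance))
  acc[seq_len(ape::Ntip(tree)), ] <- abundance[tree$tip.label, , drop = FALSE]
  for (e in seq_len(nrow(po$edge))) {
    acc[po$edge[e, 1], ] <- acc[po$edge[e, 1], ] + acc[po$edge[e, 2], ]
  }
  # map back to the original edge order
  P <- acc[tree$edge[, 2], , drop = FALSE]
  list(P = P, lengths = tree$edge.length)
}

# root-to-leaf distances, named by tip label
leaf_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  names(d) <- tree$tip.label
  d
}

#' Normalized weighted UniFrac distance
#'
#' \deqn{u = \frac{\sum_b l_b\,|p_A(b) - p_B(b)|}{\sum_j d_j\,(p_{Aj} + p_{Bj})}}
#' where the numerator sums over branches (with \eqn{p_X(b)} the fraction of
#' X's abundance below branch b) and the denominator scales by root-to-leaf
#' distances \eqn{d_j}, so the distance is bounded in `[0, 1]`.
#'
#' @param tree rooted `ape::phylo`
#' @param abundance_a,abundance_b named non-negative vectors over (a subset
#'   of) the tree's leaves, each summing to 1; missing leaves count as 0
#' @return distance in `[0, 1]`
#' @export
weighted_unifrac <- function(tree, abundance_a, abundance_b) {
  A <- cbind(expand_abundance(tree, abundance_a),
             expand_abundance(tree, abundance_b))
  if (all(A == 0)) stop("undefined: both abundance vectors are all zero")
  for (k in 1:2) {
    s <- sum(A[, k])
    if (abs(s - 1) > 1e-9) {
      stop("abundance vector ", k, " must sum to 1 over tree leaves (got ",
           format(s), ")")
    }
  }
  ea <- edge_abundance(tree, A)
  num <- sum(ea$lengths * abs(ea$P[, 1] - ea$P[, 2]))
  denom <- sum(leaf_depths(tree) * (A[, 1] + A[, 2]))
  if (denom == 0) stop("undefined: zero scaling term (zero-depth tree)")
  num / denom
}

expand_abundance <- function(tree, abundance) {
  if (is.null(names(abundance))) stop("abundance vectors must be named")
  unknown <- setdiff(names(abundance), tree$tip.label)
  if (length(unknown) > 0) {
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "))
  }
  if (any(abundance < 0)) stop("abundances must be non-negative")
  out <- stats::setNames(numeric(ape::Ntip(tree)), tree$tip.label)
  out[names(abundance)] <- abundance
  matrix(out, ncol = 1, dimnames = list(tree$tip.label, NULL))
}

#' Weighted UniFrac distance matrix over samples
#'
#' @param tree rooted `ape::phylo`
#' @param abundance matrix (leaves x samples) with columns summing to 1;
#'   rownames must be tree leaf labels
#' @return symmetric sample-by-sample distance matrix
#' @export
unifrac_matrix <- function(tree, abundance) {
  stopifnot(is.matrix(abundance), !is.null(rownames(abundance)),
            !is.null(colnames(abundance)))
  missing <- setdiff(rownames(abundance), tree$tip.label)
  if (length(missing) > 0) {
    stop("unknown leaf label(s): ", paste(missing, collapse = ", "))
  }
  full <- matrix(0, ape::Ntip(tree), ncol(abundance),
                 dimnames = list(tree$tip.label, colnames(abundance)))
  full[rownames(abundance), ] <- abundance
  ea <- edge_abundance(tree, full)
  depth_term <- colSums(leaf_depths(tree) * full)
  n <- ncol(full)
  D <- matrix(0, n, n, dimnames = list(colnames(full), colnames(full)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- sum(ea$lengths * abs(ea$P[, i] - ea$P[, j]))
    D[i, j] <- D[j, i] <- num / (depth_term[i] + depth_term[j])
  }
  D
}
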