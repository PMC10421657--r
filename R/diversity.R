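## Alpha and beta diversity --------------------------------------------------

#' Shannon diversity of a repertoire sample
#'
#' \eqn{H = -\sum_i f_i \ln f_i} over clonotype frequencies, in nats.
#'
#' @param sample a `repertoire_sample`
#' @return non-negative real; 0 (with a warning) for an empty sample
#' @export
shannon_index <- function(sample) {
  stopifnot(inherits(sample, "repertoire_sample"))
  f <- sample$records$frequency
  if (length(f) == 0) {
    warning("empty sample: Shannon index set to 0")
    return(0)
  }
  f <- f[f > 0]
  -sum(f * log(f))
}

#' Per-sample alpha diversity (Shannon and Faith's PD)
#'
#' Builds (or accepts) one pooled neighbor-joining tree over the unique CDR3
#' amino-acid sequences of the requested isotype across the whole cohort,
#' then computes, per sample, the Shannon index over clonotype frequencies
#' and root-inclusive Faith's PD over the sample's observed leaves.
#'
#' @param cohort a [bcr_cohort]
#' @param isotype "IGHM" or "IGHG"
#' @param tree optional externally built rooted tree whose leaf labels are
#'   CDR3 amino-acid sequences; built internally when `NULL`
#' @return data.frame: sample_id, group, isotype, richness, shannon, faith_pd
#' @export
alpha_diversity <- function(cohort, isotype, tree = NULL) {
  isotype <- match.arg(isotype, ISOTYPE_LEVELS)
  samples <- repertoire_samples(cohort, isotype)
  if (length(samples) == 0) stop("no samples with isotype ", isotype)
  if (is.null(tree)) {
    seqs <- sort(unique(unlist(lapply(samples,
                                      function(s) s$records$cdr3_aa))))
    tree <- build_nj_tree(pairwise_cdr3_distance(seqs))
  }
  do.call(rbind, lapply(unname(samples), function(s) {
    data.frame(sample_id = s$sample_id, group = s$group, isotype = s$isotype,
               richness = nrow(s$records),
               shannon = shannon_index(s),
               faith_pd = faith_pd(tree, unique(s$records$cdr3_aa)),
               stringsAsFactors = FALSE)
  }))
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Eigendecomposition of the double-centered Gower matrix. Axes are ordered
#' by decreasing eigenvalue; negative eigenvalues are reported but their axes
#' dropped.
#'
#' @param distances labeled symmetric distance matrix
#' @param n_axes number of coordinate axes requested
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   decreasing), and `explained` (positive-eigenvalue variance ratios)
#' @export
pcoa <- function(distances, n_axes = 2) {
  validate_distance_matrix(distances)
  stopifnot(n_axes >= 1)
  n <- nrow(distances)
  G <- -0.5 * distances^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))  # second sweep also removes the grand mean
  eig <- eigen((G + t(G)) / 2, symmetric = TRUE)
  values <- eig$values
  pos <- which(values > max(values[1], 0) * 1e-12)
  k <- min(n_axes, length(pos))
  if (k < n_axes) {
    warning(sprintf("only %d positive eigenvalue(s); axes truncated", k))
  }
  if (k == 0) {
    coords <- matrix(0, n, 0, dimnames = list(rownames(distances), NULL))
  } else {
    coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(values[seq_len(k)]), k)
    dimnames(coords) <- list(rownames(distances),
                             paste0("PCo", seq_len(k)))
  }
  pos_sum <- sum(values[values > 0])
  list(coordinates = coords, eigenvalues = values,
       explained = if (pos_sum > 0) pmax(values, 0) / pos_sum
                   else rep(0, length(values)))
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance with the
#' pseudo-F statistic
#' \deqn{F = \frac{(SS_T - SS_W)/(g-1)}{SS_W/(N-g)}}
#' where \eqn{SS_T = \frac{1}{N}\sum_{i<j} d_{ij}^2} and
#' \eqn{SS_W = \sum_g \frac{1}{n_g} \sum_{i<j \in g} d_{ij}^2}.
#' The p-value comes from label permutation with the +1 correction,
#' \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + B)}; when the number of
#' distinct label arrangements does not exceed `n_permutations`, they are
#' enumerated exhaustively and \eqn{p = \#\{F \ge F_{obs}\}/n_{arrangements}}
#' (the identity arrangement included).
#'
#' @param distances labeled symmetric distance matrix
#' @param labels named character vector mapping sample -> group; must cover
#'   the matrix labels; every group needs >= 2 samples, and >= 2 groups
#' @param n_permutations number of permutations (default 99,999)
#' @param seed RNG seed for the sampled-permutation path
#' @param exhaustive `NULL` (automatic: enumerate when the number of
#'   distinct arrangements fits under `n_permutations`), or a logical to
#'   force either path
#' @return list: `pseudo_F`, `p_value`, `n_permutations` (permutations or
#'   arrangements actually used), `exhaustive` (logical)
#' @export
permanova <- function(distances, labels, n_permutations = 99999, seed = 1,
                      exhaustive = NULL) {
  validate_distance_matrix(distances)
  ids <- rownames(distances)
  if (is.null(names(labels))) stop("labels must be a named vector")
  if (!all(ids %in% names(labels))) stop("labels missing for some samples")
  g <- as.character(labels[ids])
  counts <- table(g)
  if (length(counts) < 2) stop("need >= 2 groups")
  if (any(counts < 2)) {
    stop("every group needs >= 2 samples (offending: ",
         paste(names(counts)[counts < 2], collapse = ", "), ")")
  }
  D2 <- distances^2
  N <- length(ids)
  ngroups <- length(counts)
  ss_total <- sum(D2[upper.tri(D2)]) / N
  if (ss_total == 0) stop("undefined pseudo-F: all distances are zero")

  f_stat <- function(grp) {
    ss_w <- 0
    for (lev in unique(grp)) {
      idx <- which(grp == lev)
      ss_w <- ss_w + sum(D2[idx, idx]) / (2 * length(idx))
    }
    ((ss_total - ss_w) / (ngroups - 1)) / (ss_w / (N - ngroups))
  }
  f_obs <- f_stat(g)

  n_distinct <- round(exp(lgamma(N + 1) - sum(lgamma(counts + 1))))
  if (is.null(exhaustive)) exhaustive <- n_distinct <= n_permutations
  if (exhaustive && n_distinct > n_permutations) {
    stop("exhaustive enumeration requested but ", n_distinct,
         " arrangements exceed n_permutations")
  }
  if (exhaustive) {
    arrangements <- multiset_permutations(names(counts),
                                          as.integer(counts))
    f_all <- vapply(arrangements, f_stat, numeric(1))
    p <- mean(f_all >= f_obs - 1e-12)
    return(list(pseudo_F = f_obs, p_value = p,
                n_permutations = length(arrangements), exhaustive = TRUE))
  }
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      if (f_stat(sample(g)) >= f_obs - 1e-12) hits <- hits + 1L
    }
    list(pseudo_F = f_obs, p_value = (1 + hits) / (1 + n_permutations),
         n_permutations = n_permutations, exhaustive = FALSE)
  })
}

# All distinct arrangements of a label multiset, as a list of character
# vectors. Only called when the count fits under n_permutations.
multiset_permutations <- function(levels, counts) {
  n <- sum(counts)
  out <- list()
  recurse <- function(prefix, remaining) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (k in seq_along(levels)) {
      if (remaining[k] > 0) {
        remaining[k] <- remaining[k] - 1L
        recurse(c(prefix, levels[k]), remaining)
        remaining[k] <- remaining[k] + 1L
      }
    }
  }
  recurse(character(0), counts)
  out
}

# Evaluate expr with a temporary RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Beta diversity over weighted UniFrac distances
#'
#' Pools the unique CDR3 amino-acid sequences of the requested isotype across
#' samples (after the per-sample frequency filter), builds one
#' neighbor-joining tree over them (or accepts an external tree), maps each
#' sample's clonotype frequencies onto the shared leaves (frequencies of
#' clonotypes sharing a CDR3 are summed, then renormalized to 1 over the
#' retained set), and computes the weighted UniFrac matrix, PCoA, and a
#' PERMANOVA on a sample grouping. The default grouping contrasts the
#' endemic and non-endemic regions; the default frequency filter is
#' `> 0.001` for IGHG (medium + hyperexpanded clonotypes) and none for IGHM.
#'
#' @param cohort a [bcr_cohort]
#' @param isotype "IGHM" or "IGHG"
#' @param min_frequency clonotype frequency filter (strict inequality);
#'   `NULL` picks the isotype default (0.001 for IGHG, 0 for IGHM)
#' @param grouping named vector sample -> group for the PERMANOVA; `NULL`
#'   uses endemic vs non-endemic region
#' @param n_permutations,seed PERMANOVA settings
#' @param tree optional external rooted tree with CDR3 sequences as leaves
#' @param n_axes PCoA axes to return
#' @return list: `distances` (sample UniFrac matrix), `tree`, `abundance`
#'   (leaves x samples), `pcoa`, `permanova`
#' @export
beta_diversity <- function(cohort, isotype, min_frequency = NULL,
                           grouping = NULL, n_permutations = 99999,
                           seed = 1, tree = NULL, n_axes = 2) {
  isotype <- match.arg(isotype, ISOTYPE_LEVELS)
  if (is.null(min_frequency)) {
    min_frequency <- if (isotype == "IGHG") 0.001 else 0
  }
  samples <- repertoire_samples(cohort, isotype)
  if (min_frequency > 0) {
    samples <- lapply(samples, filter_by_frequency, min_frequency)
  }
  samples <- Filter(function(s) nrow(s$records) > 0, samples)
  if (length(samples) < 3) stop("need >= 3 non-empty samples after filtering")

  leaves <- sort(unique(unlist(lapply(samples,
                                      function(s) s$records$cdr3_aa))))
  if (is.null(tree)) {
    tree <- build_nj_tree(pairwise_cdr3_distance(leaves))
  }
  abundance <- matrix(0, length(leaves), length(samples),
                      dimnames = list(leaves,
                                      vapply(samples, `[[`, "", "sample_id")))
  for (k in seq_along(samples)) {
    f <- rowsum(samples[[k]]$records$frequency, samples[[k]]$records$cdr3_aa)
    abundance[rownames(f), k] <- f[, 1] / sum(f[, 1])
  }
  D <- unifrac_matrix(tree, abundance)

  if (is.null(grouping)) {
    grouping <- region_grouping(cohort)
  }
  list(distances = D, tree = tree, abundance = abundance,
       pcoa = pcoa(D, n_axes = n_axes),
       permanova = permanova(D, grouping, n_permutations = n_permutations,
                             seed = seed))
}

#' Endemic vs non-endemic region labels for a cohort's samples
#'
#' @param cohort a [bcr_cohort]
#' @return named character vector sample_id -> "endemic"/"nonendemic"
#' @export
region_grouping <- function(cohort) {
  stats::setNames(ifelse(cohort$metadata$group %in% ENDEMIC_GROUPS,
                         "endemic", "nonendemic"),
                  cohort$metadata$sample_id)
}
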