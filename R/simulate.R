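## Synthetic cohort simulator ----------------------------------------------

#' Default IGHV baseline usage probabilities
#'
#' The four genes involved in the planted disease-associated shifts
#' (IGHV3-30, IGHV5-51 up; IGHV3-23, IGHV1-69 down in active disease) sit at
#' their healthy-repertoire frequencies; the rest is a realistic spread over
#' common segments.
#'
#' @export
DEFAULT_V_USAGE <- c(
  "IGHV1-2" = 0.050, "IGHV1-18" = 0.040, "IGHV1-46" = 0.035,
  "IGHV1-58" = 0.002, "IGHV1-69" = 0.076, "IGHV2-5" = 0.008,
  "IGHV2-70" = 0.005, "IGHV3-7" = 0.040, "IGHV3-9" = 0.030,
  "IGHV3-11" = 0.025, "IGHV3-15" = 0.030, "IGHV3-21" = 0.040,
  "IGHV3-23" = 0.098, "IGHV3-30" = 0.097, "IGHV3-33" = 0.040,
  "IGHV3-48" = 0.035, "IGHV3-53" = 0.025, "IGHV3-73" = 0.006,
  "IGHV3-74" = 0.037, "IGHV4-4" = 0.040, "IGHV4-34" = 0.060,
  "IGHV4-39" = 0.055, "IGHV4-59" = 0.050, "IGHV4-61" = 0.020,
  "IGHV5-51" = 0.026, "IGHV6-1" = 0.020, "IGHV7-4-1" = 0.010
)

#' Default IGHJ usage probabilities
#' @export
DEFAULT_J_USAGE <- c("IGHJ1" = 0.03, "IGHJ2" = 0.05, "IGHJ3" = 0.10,
                     "IGHJ4" = 0.50, "IGHJ5" = 0.10, "IGHJ6" = 0.22)

#' Default multiplicative IGHV usage shifts in active disease
#'
#' Applied in the non-treated and treated groups; magnitudes follow the
#' observed active/without-disease frequency ratios (0.115/0.097,
#' 0.037/0.026, 0.080/0.098, 0.052/0.076).
#'
#' @export
DEFAULT_V_SHIFTS <- c("IGHV3-30" = 1.19, "IGHV5-51" = 1.42,
                      "IGHV3-23" = 0.82, "IGHV1-69" = 0.68)

ACTIVE_DISEASE_GROUPS <- c("nontreated", "treated")

# Fixed 17-mer cluster seed with conventional C...W junction anchors.
DEFAULT_CLUSTER_SEED <- "CARDGYSSGWYLDYFDW"

#' Configure the synthetic cohort generator
#'
#' Defaults emulate the endemic pemphigus foliaceus study design: five groups
#' (5 non-treated patients, 5 treated, 6 in remission, 6 endemic controls,
#' 4 non-endemic controls), per-sample clonotype richness an order of
#' magnitude higher outside the endemic area (~12,000 vs ~1,200), stronger
#' clonal expansion (smaller Dirichlet concentration) inside the endemic
#' area, IGHV usage shifts in active disease, a long-CDR3 mixture component
#' in patient groups, and one cluster of near-identical CDR3 variants planted
#' across patient samples.
#'
#' @param group_sizes named integer vector over [GROUP_LEVELS]
#' @param richness named vector: expected clonotypes per sample per isotype
#' @param expansion_alpha named vector: symmetric-Dirichlet concentration for
#'   clonal abundances (small = hyperexpanded clones)
#' @param v_usage_base named probability vector over IGHV segments
#' @param v_usage_shifts named list `group -> named multiplier vector`
#'   (applied to `v_usage_base`, then renormalized)
#' @param j_usage named probability vector over IGHJ segments
#' @param cdr3_length_mean,cdr3_length_sd base CDR3 length distribution (aa)
#' @param long_tail_weight named vector: mixture weight of the long-CDR3
#'   component per group
#' @param long_tail_mean,long_tail_sd long-CDR3 component (aa)
#' @param planted_clusters list of clusters, each a list with fields
#'   `seed_cdr3`, `n_variants`, `max_substitutions`, `samples`, `isotype`,
#'   `frequency` (target per-variant frequency)
#' @param migs_per_clonotype mean molecular-identifier groups per clonotype,
#'   used to translate Dirichlet weights into integer counts
#' @param isotypes isotypes to emit (both by default; restrict when only one
#'   is analyzed)
#' @param seed RNG seed; the same config and seed give a byte-identical cohort
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(
    group_sizes = c(nontreated = 5, treated = 5, remission = 6,
                    endemic_control = 6, nonendemic_control = 4),
    richness = c(nontreated = 1200, treated = 1200, remission = 1200,
                 endemic_control = 1200, nonendemic_control = 12000),
    expansion_alpha = c(nontreated = 0.4, treated = 0.4, remission = 0.4,
                        endemic_control = 0.4, nonendemic_control = 3),
    v_usage_base = DEFAULT_V_USAGE,
    v_usage_shifts = list(nontreated = DEFAULT_V_SHIFTS,
                          treated = DEFAULT_V_SHIFTS),
    j_usage = DEFAULT_J_USAGE,
    cdr3_length_mean = 15, cdr3_length_sd = 3,
    long_tail_weight = c(nontreated = 0.15, treated = 0.08, remission = 0.12,
                         endemic_control = 0, nonendemic_control = 0),
    long_tail_mean = 22, long_tail_sd = 2,
    planted_clusters = list(list(
      seed_cdr3 = DEFAULT_CLUSTER_SEED, n_variants = 5,
      max_substitutions = 2,
      samples = c("NT1", "NT2", "TR1", "RE1", "RE2"),
      isotype = "IGHG", frequency = 0.005)),
    migs_per_clonotype = 10,
    isotypes = ISOTYPE_LEVELS,
    seed = 1L) {
  v_usage_base <- v_usage_base / sum(v_usage_base)
  j_usage <- j_usage / sum(j_usage)
  cfg <- list(group_sizes = group_sizes, richness = richness,
              expansion_alpha = expansion_alpha,
              v_usage_base = v_usage_base, v_usage_shifts = v_usage_shifts,
              j_usage = j_usage,
              cdr3_length_mean = cdr3_length_mean,
              cdr3_length_sd = cdr3_length_sd,
              long_tail_weight = long_tail_weight,
              long_tail_mean = long_tail_mean, long_tail_sd = long_tail_sd,
              planted_clusters = planted_clusters,
              migs_per_clonotype = migs_per_clonotype,
              isotypes = match.arg(isotypes, ISOTYPE_LEVELS, several.ok = TRUE),
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(all(GROUP_LEVELS %in% names(cfg$group_sizes)),
            all(cfg$group_sizes >= 1),
            all(GROUP_LEVELS %in% names(cfg$richness)),
            all(cfg$richness >= 2),
            all(cfg$expansion_alpha > 0))
  if (abs(sum(cfg$v_usage_base) - 1) > 1e-9) {
    stop("config error: v_usage_base must sum to 1")
  }
  if (abs(sum(cfg$j_usage) - 1) > 1e-9) {
    stop("config error: j_usage must sum to 1")
  }
  ids <- simulated_sample_ids(cfg$group_sizes)$sample_id
  for (cl in cfg$planted_clusters) {
    missing <- setdiff(cl$samples, ids)
    if (length(missing) > 0) {
      stop("config error: planted cluster targets nonexistent sample(s): ",
           paste(missing, collapse = ", "))
    }
    check_aa(cl$seed_cdr3)
  }
  invisible(TRUE)
}

GROUP_PREFIX <- c(nontreated = "NT", treated = "TR", remission = "RE",
                  endemic_control = "EC", nonendemic_control = "NC")

simulated_sample_ids <- function(group_sizes) {
  groups <- rep(GROUP_LEVELS, group_sizes[GROUP_LEVELS])
  idx <- unlist(lapply(group_sizes[GROUP_LEVELS], seq_len), use.names = FALSE)
  data.frame(sample_id = paste0(GROUP_PREFIX[groups], idx),
             group = groups, stringsAsFactors = FALSE)
}

#' Simulate a synthetic cohort
#'
#' Per (sample, isotype): the clonotype number is Poisson around the group's
#' richness, abundances follow a symmetric Dirichlet with the group's
#' concentration (converted to integer MIG counts), V and J calls are drawn
#' from the (group-shifted) usage vectors, and CDR3 amino-acid sequences are
#' random over the 20-letter alphabet anchored C...W, with lengths from a
#' rounded Gaussian plus a per-group long-tail mixture component. Planted
#' CDR3 clusters are injected into their target samples at medium-to-high
#' frequency, and background sequences are rejection-sampled to stay at
#' Hamming distance >= 5 from every cluster member so that each cluster is
#' recoverable as exactly one network component.
#'
#' @param config a [synthetic_config()]
#' @return a [bcr_cohort]; deterministic given `config$seed`
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_config(config)
  set.seed(config$seed)

  meta <- simulated_sample_ids(config$group_sizes)
  cluster_members <- planted_cluster_sequences(config)

  parts <- list()
  for (i in seq_len(nrow(meta))) {
    for (iso in config$isotypes) {
      parts[[length(parts) + 1L]] <-
        simulate_sample(meta$sample_id[i], meta$group[i], iso, config,
                        cluster_members$all_seqs)
    }
  }
  rec <- do.call(rbind, parts)

  # inject planted cluster variants
  for (k in seq_along(cluster_members$clusters)) {
    cl <- config$planted_clusters[[k]]
    if (!cl$isotype %in% config$isotypes) next
    variants <- cluster_members$clusters[[k]]
    target <- rep(cl$samples, length.out = length(variants))
    for (j in seq_along(variants)) {
      unit <- rec$sample_id == target[j] & rec$isotype == cl$isotype
      total <- sum(rec$count[unit])
      cnt <- max(2L, as.integer(round(cl$frequency * total)))
      rec <- rbind(rec, data.frame(
        sample_id = target[j],
        isotype = cl$isotype,
        c_call = if (cl$isotype == "IGHG") "IGHG1" else "IGHM",
        cdr3_aa = variants[j], cdr3_nt = NA_character_,
        v_call = "IGHV3-30", d_call = "IGHD3-10", j_call = "IGHJ4",
        count = cnt, stringsAsFactors = FALSE))
    }
  }
  rec$sequence_id <- sprintf("sim%07d", seq_len(nrow(rec)))
  bcr_cohort(rec, meta)
}

#' Simulate a null cohort (all group effects disabled)
#'
#' Every group gets the endemic-control richness and concentration, the base
#' usage vector, the base length distribution, and no planted clusters, so
#' samples are exchangeable across groups. Used for type-I-error calibration.
#'
#' @param config a [synthetic_config()]
#' @return a [bcr_cohort]
#' @export
simulate_null_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  null_cfg <- config
  null_cfg$richness[] <- config$richness[["endemic_control"]]
  null_cfg$expansion_alpha[] <- config$expansion_alpha[["endemic_control"]]
  null_cfg$v_usage_shifts <- list()
  null_cfg$long_tail_weight[] <- 0
  null_cfg$planted_clusters <- list()
  simulate_cohort(null_cfg)
}

# One (sample, isotype) record block. avoid_seqs: planted-cluster members the
# background must stay Hamming-separated from (same-length sequences only).
simulate_sample <- function(sample_id, group, isotype, cfg, avoid_seqs) {
  n <- max(2L, stats::rpois(1, cfg$richness[[group]]))
  w <- stats::rgamma(n, shape = cfg$expansion_alpha[[group]])
  w <- w / sum(w)
  total <- n * cfg$migs_per_clonotype
  count <- pmax(1L, as.integer(round(w * total)))

  usage <- shifted_usage(cfg$v_usage_base,
                         cfg$v_usage_shifts[[group]])
  v <- sample(names(usage), n, replace = TRUE, prob = usage)
  j <- sample(names(cfg$j_usage), n, replace = TRUE, prob = cfg$j_usage)
  c_call <- if (isotype == "IGHG") {
    sample(c("IGHG1", "IGHG2", "IGHG3/4"), n, replace = TRUE,
           prob = c(0.5, 0.3, 0.2))
  } else rep("IGHM", n)

  len <- draw_lengths(n, cfg, cfg$long_tail_weight[[group]])
  seqs <- random_junctions(len)
  seqs <- enforce_separation(seqs, avoid_seqs, min_distance = 5, cfg = cfg,
                             tail_weight = cfg$long_tail_weight[[group]])

  data.frame(sample_id = sample_id, isotype = isotype, c_call = c_call,
             cdr3_aa = seqs, cdr3_nt = NA_character_,
             v_call = v, d_call = NA_character_, j_call = j,
             count = count, stringsAsFactors = FALSE)
}

shifted_usage <- function(base, shifts) {
  if (is.null(shifts) || length(shifts) == 0) return(base)
  u <- base
  u[names(shifts)] <- u[names(shifts)] * shifts
  u / sum(u)
}

# Lengths are truncated to [5, 35] aa by resampling (not clamping, which
# would pile a point mass onto the boundary). The bounds sit > 3 sd outside
# the default length model, so they guard against impossible junctions
# without distorting the distribution.
draw_lengths <- function(n, cfg, tail_weight) {
  from_tail <- stats::runif(n) < tail_weight
  len <- rtrunc_round(n, cfg$cdr3_length_mean, cfg$cdr3_length_sd)
  if (any(from_tail)) {
    len[from_tail] <- rtrunc_round(sum(from_tail), cfg$long_tail_mean,
                                   cfg$long_tail_sd)
  }
  len
}

rtrunc_round <- function(n, mean, sd, lower = 5L, upper = 35L) {
  len <- as.integer(round(stats::rnorm(n, mean, sd)))
  repeat {
    bad <- len < lower | len > upper
    if (!any(bad)) return(len)
    len[bad] <- as.integer(round(stats::rnorm(sum(bad), mean, sd)))
  }
}

# Random CDR3 amino-acid junctions anchored C...W.
random_junctions <- function(len) {
  mid_len <- len - 2L
  chars <- sample(AA_ALPHABET, sum(mid_len), replace = TRUE)
  grp <- factor(rep(seq_along(len), mid_len), levels = seq_along(len))
  mids <- vapply(split(chars, grp), paste, "", collapse = "")
  paste0("C", mids, "W")
}

# Resample background sequences that land within `min_distance` Hamming
# substitutions of a planted cluster member (same length only). Random
# 20-letter sequences virtually never trigger this, but the guarantee makes
# planted-cluster recovery exact.
enforce_separation <- function(seqs, avoid_seqs, min_distance, cfg,
                               tail_weight, max_iter = 20) {
  if (length(avoid_seqs) == 0) return(seqs)
  for (iter in seq_len(max_iter)) {
    clash <- too_close(seqs, avoid_seqs, min_distance)
    if (!any(clash)) return(seqs)
    len <- draw_lengths(sum(clash), cfg, tail_weight)
    seqs[clash] <- random_junctions(len)
  }
  stop("config error: could not separate background sequences from planted ",
       "clusters after ", max_iter, " resampling rounds")
}

too_close <- function(seqs, avoid_seqs, min_distance) {
  clash <- rep(FALSE, length(seqs))
  for (a in avoid_seqs) {
    same_len <- nchar(seqs) == nchar(a)
    if (!any(same_len)) next
    d <- hamming_to_reference(seqs[same_len], a)
    clash[same_len] <- clash[same_len] | d < min_distance
  }
  clash
}

hamming_to_reference <- function(seqs, ref) {
  L <- nchar(ref)
  ref_chars <- strsplit(ref, "")[[1]]
  m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
              nrow = length(seqs), ncol = L, byrow = TRUE)
  rowSums(m != matrix(ref_chars, nrow = length(seqs), ncol = L, byrow = TRUE))
}

# Materialize planted cluster variant sequences. The first variant is the
# seed itself so all variants sit within max_substitutions of one member,
# keeping the cluster a single connected component.
planted_cluster_sequences <- function(cfg) {
  clusters <- lapply(cfg$planted_clusters, function(cl) {
    seed_chars <- strsplit(cl$seed_cdr3, "")[[1]]
    L <- length(seed_chars)
    variants <- cl$seed_cdr3
    guard <- 0
    while (length(variants) < cl$n_variants) {
      k <- sample(seq_len(cl$max_substitutions), 1)
      pos <- sample(2:(L - 1), k)  # keep the C/W anchors
      chars <- seed_chars
      for (p in pos) chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1)
      v <- paste(chars, collapse = "")
      if (!v %in% variants) variants <- c(variants, v)
      guard <- guard + 1
      if (guard > 1000) stop("config error: cannot generate distinct variants")
    }
    variants
  })
  list(clusters = clusters,
       all_seqs = unlist(clusters, use.names = FALSE))
}
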