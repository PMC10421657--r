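## Gene segment usage --------------------------------------------------------

SEGMENT_COLUMN <- c(V = "v_call", J = "j_call", C = "c_call")

#' Strip allele suffixes from gene calls
#'
#' "IGHV3-30*03" is tallied under "IGHV3-30"; multi-allele calls keep the
#' first listed gene.
#'
#' @param calls character vector of segment calls
#' @return gene-level calls
#' @export
strip_allele <- function(calls) {
  sub("\\*.*$", "", sub(",.*$", "", calls))
}

#' Gene segment usage frequencies per sample
#'
#' For each sample, the fraction of its unique clonotypes assigned to each
#' gene segment of one family (V, J, or C), at gene level (allele suffixes
#' stripped). Rows sum to 1. Records with a missing call for the requested
#' family are excluded (a message reports how many).
#'
#' @param cohort a [bcr_cohort]
#' @param segment_family "V", "J", or "C"
#' @param isotype "IGHM" or "IGHG"
#' @return a `usage_table`: numeric matrix samples x segments with a
#'   `groups` attribute (named vector sample -> group)
#' @export
usage_frequencies <- function(cohort, segment_family = c("V", "J", "C"),
                              isotype) {
  segment_family <- match.arg(segment_family)
  isotype <- match.arg(isotype, ISOTYPE_LEVELS)
  col <- SEGMENT_COLUMN[[segment_family]]
  rec <- cohort$records[cohort$records$isotype == isotype, , drop = FALSE]
  missing <- is.na(rec[[col]]) | !nzchar(rec[[col]])
  if (any(missing)) {
    message(sum(missing), " record(s) without a ", segment_family,
            " call excluded from usage")
    rec <- rec[!missing, , drop = FALSE]
  }
  if (nrow(rec) == 0) stop("no records with ", segment_family,
                           " calls for isotype ", isotype)
  gene <- strip_allele(rec[[col]])
  tab <- table(rec$sample_id, gene)
  mat <- matrix(as.numeric(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  mat <- mat / rowSums(mat)
  groups <- stats::setNames(
    cohort$metadata$group[match(rownames(mat), cohort$metadata$sample_id)],
    rownames(mat))
  structure(mat, groups = groups, segment_family = segment_family,
            isotype = isotype, class = c("usage_table", "matrix"))
}

#' Active-disease vs without-disease sample status
#'
#' The binary contrast used for differential usage: active disease =
#' non-treated + treated patients; without disease = patients in remission +
#' endemic controls. Non-endemic controls are excluded.
#'
#' @param cohort a [bcr_cohort]
#' @return named character vector sample_id -> "active"/"without" for
#'   endemic samples
#' @export
disease_status_grouping <- function(cohort) {
  meta <- cohort$metadata
  meta <- meta[meta$group %in% ENDEMIC_GROUPS, , drop = FALSE]
  stats::setNames(ifelse(meta$group %in% ACTIVE_DISEASE_GROUPS,
                         "active", "without"),
                  meta$sample_id)
}

#' Differential gene segment usage between two sample statuses
#'
#' Per segment: group mean frequencies and a two-sided Wilcoxon rank-sum
#' test on per-sample usage (exact when both groups have <= 8 samples and no
#' ties; normal approximation with midrank tie correction otherwise).
#' Segments are flagged at raw p < 0.05, with Benjamini–Hochberg adjusted
#' p-values reported alongside.
#'
#' @param table a `usage_table` from [usage_frequencies()]
#' @param grouping named vector sample -> status with exactly two statuses;
#'   samples absent from the grouping are dropped
#' @return data.frame: segment, mean_a, mean_b, n_a, n_b, statistic,
#'   p_value, p_adj, flagged (plus a `statuses` attribute naming a and b)
#' @export
differential_usage <- function(table, grouping) {
  stopifnot(inherits(table, "usage_table"))
  keep <- rownames(table)[rownames(table) %in% names(grouping)]
  mat <- table[keep, , drop = FALSE]
  status <- as.character(grouping[keep])
  levels <- sort(unique(status))
  if (length(levels) != 2) stop("grouping must have exactly two statuses")
  n_a <- sum(status == levels[1]); n_b <- sum(status == levels[2])
  if (n_a < 2 || n_b < 2) stop("both statuses need >= 2 samples")

  res <- lapply(colnames(mat), function(seg) {
    xa <- mat[status == levels[1], seg]
    xb <- mat[status == levels[2], seg]
    w <- rank_sum_test(xa, xb)
    data.frame(segment = seg, mean_a = mean(xa), mean_b = mean(xb),
               n_a = n_a, n_b = n_b, statistic = w$statistic,
               p_value = w$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$flagged <- out$p_value < 0.05
  attr(out, "statuses") <- levels
  out
}

#' PCA on selected gene segments
#'
#' Column-centered (not variance-scaled) principal component analysis of the
#' usage frequencies of the requested segments, with a deterministic sign
#' convention (the largest-magnitude loading of each component is positive).
#'
#' @param table a `usage_table`
#' @param segments segment names to include (subset of the table's columns)
#' @param n_components number of components to return
#' @return list: `scores` (samples x components), `loadings`,
#'   `explained` (variance ratios), `groups`
#' @export
usage_pca <- function(table, segments = colnames(table),
                      n_components = min(2, length(segments))) {
  stopifnot(inherits(table, "usage_table"))
  missing <- setdiff(segments, colnames(table))
  if (length(missing) > 0) {
    stop("segment(s) not in table: ", paste(missing, collapse = ", "))
  }
  x <- table[, segments, drop = FALSE]
  if (nrow(x) < 2) stop("need >= 2 samples for PCA")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  # deterministic sign: largest-|loading| entry positive per component
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  var_total <- sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained = if (var_total > 0) pc$sdev^2 / var_total
                   else rep(0, length(pc$sdev)),
       groups = attr(table, "groups"))
}
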