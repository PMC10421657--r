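## Clonotype abundance spectrum ---------------------------------------------

ABUNDANCE_BINS <- c("low", "medium", "hyperexpanded")

#' Classify a frequency into the abundance bins
#'
#' Low: frequency < 0.1%; medium: between 0.1% and 1% (closed on both ends);
#' hyperexpanded: > 1%.
#'
#' @param frequency numeric vector of clonotype frequencies in (0, 1]
#' @return character vector over `c("low", "medium", "hyperexpanded")`
#' @export
abundance_bin <- function(frequency) {
  ifelse(frequency < 0.001, "low",
         ifelse(frequency > 0.01, "hyperexpanded", "medium"))
}

#' Abundance spectrum of one repertoire sample
#'
#' Counts and proportions of unique clonotypes per abundance bin. Proportions
#' are over unique clonotypes (each clonotype counts once, regardless of its
#' MIG mass).
#'
#' @param sample a `repertoire_sample`
#' @return an `abundance_spectrum`: list with `sample_id`, `group`,
#'   `isotype`, `counts` (named integer over bins) and `proportions`
#' @export
bin_clonotypes <- function(sample) {
  stopifnot(inherits(sample, "repertoire_sample"))
  n <- nrow(sample$records)
  counts <- stats::setNames(integer(3), ABUNDANCE_BINS)
  if (n > 0) {
    tab <- table(factor(abundance_bin(sample$records$frequency),
                        levels = ABUNDANCE_BINS))
    counts[] <- as.integer(tab)
  }
  structure(list(sample_id = sample$sample_id, group = sample$group,
                 isotype = sample$isotype, counts = counts,
                 proportions = if (n > 0) counts / n
                               else stats::setNames(rep(NA_real_, 3),
                                                    ABUNDANCE_BINS)),
            class = "abundance_spectrum")
}

#' Abundance spectra for all samples of a cohort
#'
#' @param cohort a [bcr_cohort]
#' @param isotype optional isotype restriction
#' @return tidy data.frame: sample_id, group, isotype, bin, count, proportion
#' @export
abundance_spectra <- function(cohort, isotype = NULL) {
  specs <- lapply(repertoire_samples(cohort, isotype), bin_clonotypes)
  do.call(rbind, lapply(specs, function(s) {
    data.frame(sample_id = s$sample_id, group = s$group, isotype = s$isotype,
               bin = ABUNDANCE_BINS, count = as.integer(s$counts),
               proportion = as.numeric(s$proportions),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Compare per-sample bin proportions between groups
#'
#' For every pair of groups with at least two samples each, a two-sample
#' Wilcoxon rank-sum test on the per-sample proportion of clonotypes in the
#' requested bin (exact p when both groups have <= 8 samples and no ties,
#' large-sample normal approximation with midrank tie correction otherwise).
#'
#' @param cohort a [bcr_cohort]
#' @param isotype "IGHM" or "IGHG"
#' @param bin one of "low", "medium", "hyperexpanded"
#' @return data.frame: group_a, group_b, isotype, bin, n_a, n_b, statistic,
#'   p_value
#' @export
compare_bin_proportions <- function(cohort, isotype, bin) {
  bin <- match.arg(bin, ABUNDANCE_BINS)
  isotype <- match.arg(isotype, ISOTYPE_LEVELS)
  spec <- abundance_spectra(cohort, isotype)
  spec <- spec[spec$bin == bin & !is.na(spec$proportion), , drop = FALSE]
  groups <- intersect(GROUP_LEVELS, unique(spec$group))
  out <- list()
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (j <= i) next
    xa <- spec$proportion[spec$group == groups[i]]
    xb <- spec$proportion[spec$group == groups[j]]
    if (length(xa) < 2 || length(xb) < 2) {
      warning(sprintf("comparison %s vs %s skipped: fewer than 2 samples",
                      groups[i], groups[j]))
      next
    }
    w <- rank_sum_test(xa, xb)
    out[[length(out) + 1L]] <- data.frame(
      group_a = groups[i], group_b = groups[j], isotype = isotype, bin = bin,
      n_a = length(xa), n_b = length(xb),
      statistic = w$statistic, p_value = w$p.value, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(group_a = character(), group_b = character(),
                      isotype = character(), bin = character(),
                      n_a = integer(), n_b = integer(),
                      statistic = numeric(), p_value = numeric()))
  }
  do.call(rbind, out)
}

# Two-sample Wilcoxon rank-sum convention used throughout: exact when both
# groups are small (<= 8) and tie-free; otherwise the large-sample normal
# approximation with midrank tie correction, without continuity correction.
rank_sum_test <- function(x, y, exact_max = 8) {
  if (length(unique(c(x, y))) == 1) {
    # fully tied data: no evidence of separation (normal statistic is 0/0)
    return(list(statistic = length(x) * length(y) / 2, p.value = 1))
  }
  use_exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !anyDuplicated(c(x, y))
  w <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = FALSE))
  p <- w$p.value
  if (is.nan(p)) p <- 1
  list(statistic = unname(w$statistic), p.value = p)
}
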