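## CDR3 length and physicochemistry ------------------------------------------

#' CDR3 length distribution of a sample
#'
#' Length histogram over unique clonotypes (unweighted by abundance), median
#' length, and a Shapiro–Wilk normality p-value on the per-clonotype length
#' vector. Because amino-acid lengths are integers, the raw Shapiro–Wilk
#' test rejects any discretized distribution at repertoire-scale n; by
#' default the lengths are therefore dithered with uniform \eqn{\pm 0.5}
#' jitter (de-rounding) before testing, which restores calibration under a
#' rounded-Gaussian null while keeping power against long-tail departures.
#' Set `dither = FALSE` for the raw test. The jitter consumes the current
#' RNG stream, so seeded runs are reproducible.
#'
#' @param sample a `repertoire_sample`
#' @param dither logical; de-round lengths before the normality test
#' @return list: `sample_id`, `group`, `isotype`, `histogram` (named
#'   proportion vector over lengths), `median_length`, `n`, `normality_p`
#'   (NA with a flag when n < 3)
#' @export
length_distribution <- function(sample, dither = TRUE) {
  stopifnot(inherits(sample, "repertoire_sample"))
  len <- nchar(sample$records$cdr3_aa)
  hist <- table(len) / length(len)
  normality_p <- NA_real_
  if (length(len) >= 3 && length(unique(len)) > 1) {
    x <- if (dither) len + stats::runif(length(len), -0.5, 0.5) else len
    if (length(x) > 5000) x <- x[sample.int(length(x), 5000)]
    normality_p <- stats::shapiro.test(x)$p.value
  }
  list(sample_id = sample$sample_id, group = sample$group,
       isotype = sample$isotype,
       histogram = stats::setNames(as.numeric(hist), names(hist)),
       median_length = stats::median(len), n = length(len),
       normality_p = normality_p)
}

#' Compare two CDR3 length distributions (two-sample Kolmogorov–Smirnov)
#'
#' @param sample_a,sample_b `repertoire_sample` objects
#' @return list: `statistic` (D in `[0,1]`), `p_value`
#' @export
compare_length_distributions <- function(sample_a, sample_b) {
  stopifnot(inherits(sample_a, "repertoire_sample"),
            inherits(sample_b, "repertoire_sample"))
  la <- nchar(sample_a$records$cdr3_aa)
  lb <- nchar(sample_b$records$cdr3_aa)
  if (length(la) == 0 || length(lb) == 0) stop("empty sample")
  ks <- suppressWarnings(stats::ks.test(la, lb))
  list(statistic = unname(ks$statistic), p_value = ks$p.value)
}

## Kyte–Doolittle hydropathy
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

## EMBOSS side-chain pKa values (termini excluded: the CDR3 is an internal
## fragment of the heavy chain, so its alpha-amino/carboxyl groups are in
## peptide bonds)
PKA_POSITIVE <- c(K = 10.8, R = 12.5, H = 6.5)
PKA_NEGATIVE <- c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

#' Physicochemical properties of a sample's CDR3 sequences
#'
#' Per clonotype: length, GRAVY (mean Kyte–Doolittle hydropathy), net charge
#' at pH 7 (Henderson–Hasselbalch with the EMBOSS pKa set, side chains only),
#' aromatic fraction (F, W, Y, H), and aliphatic index
#' \eqn{100\,(f_A + 2.9 f_V + 3.9 (f_I + f_L))}.
#'
#' @param sample a `repertoire_sample`
#' @param pH pH for the charge calculation
#' @return data.frame: sample_id, group, isotype, cdr3_aa, length, gravy,
#'   net_charge, aromatic_fraction, aliphatic_index
#' @export
chemistry <- function(sample, pH = 7.0) {
  stopifnot(inherits(sample, "repertoire_sample"))
  seqs <- sample$records$cdr3_aa
  counts <- residue_counts(seqs)
  L <- nchar(seqs)
  gravy <- as.numeric(counts %*% KYTE_DOOLITTLE[colnames(counts)]) / L
  pos <- sapply(names(PKA_POSITIVE), function(r)
    counts[, r] / (1 + 10^(pH - PKA_POSITIVE[[r]])))
  neg <- sapply(names(PKA_NEGATIVE), function(r)
    counts[, r] / (1 + 10^(PKA_NEGATIVE[[r]] - pH)))
  net_charge <- rowSums(cbind(pos)) - rowSums(cbind(neg))
  aromatic <- rowSums(counts[, c("F", "W", "Y", "H"), drop = FALSE]) / L
  aliphatic <- 100 * (counts[, "A"] + 2.9 * counts[, "V"] +
                      3.9 * (counts[, "I"] + counts[, "L"])) / L
  data.frame(sample_id = sample$sample_id, group = sample$group,
             isotype = sample$isotype, cdr3_aa = seqs, length = L,
             gravy = gravy, net_charge = net_charge,
             aromatic_fraction = aromatic, aliphatic_index = aliphatic,
             stringsAsFactors = FALSE, row.names = NULL)
}

# sequences x 20 residue count matrix
residue_counts <- function(seqs) {
  chars <- strsplit(seqs, "")
  m <- t(vapply(chars, function(ch)
    tabulate(factor(ch, levels = AA_ALPHABET), nbins = 20L),
    integer(20L)))
  colnames(m) <- AA_ALPHABET
  m
}

#' Group-level chemistry comparison
#'
#' Pairwise Wilcoxon rank-sum tests on per-sample mean chemistry values
#' between groups, for each property.
#'
#' @param cohort a [bcr_cohort]
#' @param isotype "IGHM" or "IGHG"
#' @return data.frame: property, group_a, group_b, mean_a, mean_b, p_value
#' @export
compare_chemistry <- function(cohort, isotype) {
  samples <- repertoire_samples(cohort, isotype)
  props <- c("gravy", "net_charge", "aromatic_fraction", "aliphatic_index",
             "length")
  per_sample <- do.call(rbind, lapply(unname(samples), function(s) {
    ch <- chemistry(s)
    data.frame(sample_id = s$sample_id, group = s$group,
               t(colMeans(ch[, props])), stringsAsFactors = FALSE)
  }))
  groups <- intersect(GROUP_LEVELS, unique(per_sample$group))
  out <- list()
  for (prop in props) {
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (j <= i) next
      xa <- per_sample[per_sample$group == groups[i], prop]
      xb <- per_sample[per_sample$group == groups[j], prop]
      if (length(xa) < 2 || length(xb) < 2) next
      w <- rank_sum_test(xa, xb)
      out[[length(out) + 1L]] <- data.frame(
        property = prop, group_a = groups[i], group_b = groups[j],
        mean_a = mean(xa), mean_b = mean(xb), p_value = w$p.value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
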