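#!/usr/bin/env Rscript
# IGHV gene-segment usage: per-sample usage frequencies over unique
# clonotypes, rank-sum tests between active disease (non-treated + treated)
# and without disease (remission + endemic controls), and a PCA on the
# segments flagged at raw p < 0.05. The generator plants IGHV3-30 and
# IGHV5-51 up and IGHV3-23 and IGHV1-69 down in active disease, so those
# four should dominate the flagged list.

suppressMessages(library(pfrepertoire))

cohort <- read_airr("results/cohort.tsv", "results/cohort_metadata.tsv")
status <- disease_status_grouping(cohort)

for (iso in ISOTYPE_LEVELS) {
  usage <- usage_frequencies(cohort, "V", iso)
  tests <- differential_usage(usage, status)
  pfrepertoire:::write_matrix_tsv(unclass(usage),
                                  paste0("results/usage_V_", iso, ".tsv"))
  pfrepertoire:::write_tsv(tests, paste0("results/usage_tests_", iso, ".tsv"))

  flagged <- tests$segment[tests$flagged]
  message(iso, " segments flagged at raw p < 0.05: ",
          paste(flagged, collapse = ", "))
  if (length(flagged) >= 2) {
    pca <- usage_pca(usage, flagged)
    pfrepertoire:::write_matrix_tsv(
      pca$scores, paste0("results/usage_pca_", iso, ".tsv"))
    message(sprintf("  PC1 explains %.0f%% of flagged-segment variance",
                    100 * pca$explained[1]))
  }
}
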