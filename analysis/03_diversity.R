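#!/usr/bin/env Rscript
# Alpha and beta diversity over CDR3 phylogenies. One neighbor-joining tree
# per isotype is built over pooled unique CDR3 amino-acid sequences
# (normalized edit distances); Shannon and root-inclusive Faith's PD are
# computed per sample, and weighted UniFrac + PCoA + PERMANOVA contrast the
# endemic and non-endemic regions. IGHG keeps only clonotypes with
# frequency > 0.001 before beta diversity; IGHM uses all clonotypes.

suppressMessages(library(pfrepertoire))

cohort <- read_airr("results/cohort.tsv", "results/cohort_metadata.tsv")

for (iso in ISOTYPE_LEVELS) {
  message("== ", iso, " ==")
  beta <- beta_diversity(cohort, iso, n_permutations = 9999, seed = 1)
  minf <- if (iso == "IGHG") 0.001 else 0
  alpha <- alpha_diversity(cohort, iso,
                           tree = if (minf == 0) beta$tree else NULL)
  pfrepertoire:::write_tsv(alpha, paste0("results/alpha_", iso, ".tsv"))
  pfrepertoire:::write_matrix_tsv(beta$distances,
                                  paste0("results/unifrac_", iso, ".tsv"))
  pfrepertoire:::write_pcoa_tsv(beta$pcoa,
                                paste0("results/pcoa_", iso, ".tsv"))
  write_newick(beta$tree, paste0("results/tree_", iso, ".nwk"))

  message("mean Faith's PD by group:")
  print(aggregate(faith_pd ~ group, alpha, mean))
  message(sprintf("region PERMANOVA: pseudo-F = %.3f, p = %.4g (%d perms)",
                  beta$permanova$pseudo_F, beta$permanova$p_value,
                  beta$permanova$n_permutations))
}
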