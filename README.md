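# pfrepertoire

Downstream B-cell receptor (IGH) repertoire analysis for cohort studies of
endemic pemphigus foliaceus (fogo selvagem), an autoimmune blistering skin
disease endemic in parts of Brazil. The package starts where upstream
processing ends — clonotype tables in AIRR Rearrangement TSV format (one row
per unique rearrangement per sample, with CDR3 sequences, V/D/J/C calls and
molecular-identifier-group counts) — and implements the full statistical
workflow a repertoire study of this design needs:

* **Abundance spectra** — clonotypes binned as low (< 0.1%), medium
  (0.1–1%) or hyperexpanded (> 1%) of their repertoire, with rank-sum
  comparisons of per-sample bin proportions between groups.
* **Diversity** — a neighbor-joining tree over pooled CDR3 amino-acid
  sequences (normalized edit distances), Shannon entropy and root-inclusive
  Faith's phylogenetic diversity per sample, and normalized weighted UniFrac

  $$u(A,B) = \frac{\sum_b \ell_b\,|p_A(b) - p_B(b)|}{\sum_j d_j\,(p_{Aj} + p_{Bj})}$$

  between samples, with PCoA ordination and one-way PERMANOVA
  (pseudo-F over squared distances; exhaustive enumeration of label
  arrangements when they fit under the permutation budget).
* **Gene usage** — per-sample IGHV/IGHJ/IGHC usage over unique clonotypes,
  differential usage between active disease and without disease
  (Wilcoxon rank-sum, BH-adjusted values alongside), PCA on flagged
  segments.
* **CDR3 features** — length distributions with a discreteness-aware
  Shapiro–Wilk normality test (dithered; see the methods vignette),
  Kolmogorov–Smirnov length comparisons, and physicochemistry (GRAVY, net
  charge at pH 7, aromatic fraction, aliphatic index).
* **Similarity networks** — nodes are (sample, CDR3) pairs, edges join
  equal-length sequences at Hamming distance ≤ 2; components touching ≥ 4
  patient samples are extracted as PF-relevant, with position-frequency
  consensus matrices for logo rendering.
* **A synthetic cohort generator** — five groups (5/5/6/6/4 samples), two
  isotypes, richness and clonal-expansion contrasts between the endemic and
  non-endemic region, planted IGHV usage shifts in active disease,
  long-CDR3 patient tails, and a planted near-identical CDR3 cluster shared
  across patient samples — so every stage is testable end to end without
  sequencing data. A null variant disables all effects for calibration.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a simulated
cohort (reduced richness, 50 endemic / 500 non-endemic clonotypes per
sample, keeping the study's 1:10 contrast) and write tables under
`results/`:

```sh
Rscript analysis/01_simulate.R      # cohort.tsv + metadata
Rscript analysis/02_abundance.R     # abundance spectra + comparisons
Rscript analysis/03_diversity.R     # alpha/beta diversity, PCoA, PERMANOVA
Rscript analysis/04_gene_usage.R    # usage tables, tests, PCA
Rscript analysis/05_cdr3_features.R # lengths, normality, chemistry
Rscript analysis/06_networks.R      # Hamming networks + consensus
```

Step 03 prints, for this cohort (IGHM):

```
mean Faith's PD by group:
               group  faith_pd
1    endemic_control  20.02509
2 nonendemic_control 182.66835
3         nontreated  16.53883
4          remission  15.36261
5            treated  15.99617
region PERMANOVA: pseudo-F = 1.301, p = 0.0001 (9999 perms)
```

— the non-endemic controls' phylogenetic diversity sits an order of
magnitude above every endemic group (the planted richness contrast), and
the endemic/non-endemic PERMANOVA on weighted UniFrac rejects at its
smallest attainable p. Step 06 recovers the planted CDR3 cluster as exactly
one patient-exclusive component:

```
PF-relevant components (>= 4 patient samples): 1
  component_id cdr3_length n_nodes n_samples             samples
1            1          17       5         5 NT1,NT2,RE1,RE2,TR1
        exclusivity         consensus
1 patient_exclusive CARDGYSSGWYLDYFDW
```

The same machinery is available programmatically:

```r
library(pfrepertoire)
cfg    <- synthetic_config(seed = 1)        # full study scale
cohort <- simulate_cohort(cfg)
beta   <- beta_diversity(cohort, "IGHG")    # frequency > 0.001 filter, tree,
                                            # UniFrac, PCoA, PERMANOVA
alpha  <- alpha_diversity(cohort, "IGHG", tree = NULL)
```

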