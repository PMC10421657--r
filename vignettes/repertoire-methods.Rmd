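---
title: "Methods: downstream BCR repertoire analysis for an endemic pemphigus foliaceus cohort"
author: "pfrepertoire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downstream BCR repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfrepertoire)
```

# Scope and data model

`pfrepertoire` implements the downstream half of an immunoglobulin
heavy-chain (IGH) repertoire study of endemic pemphigus foliaceus (fogo
selvagem): it starts from clonotype tables — one row per unique rearrangement
per sample, with CDR3 sequences, V/D/J/C gene calls, and molecular-identifier
group (MIG) counts — and carries out abundance-spectrum, diversity,
gene-usage, CDR3-feature, and similarity-network analyses. Upstream read
processing (UMI consensus, V(D)J annotation) is out of scope; tables in AIRR
Rearrangement TSV format are the interface.

A clonotype is keyed by (CDR3 nucleotide sequence when present, otherwise the
amino-acid sequence) together with the V and J gene calls, within one
(sample, isotype). Rows sharing a key are merged by summing counts, and
frequencies are always recomputed as count over the (sample, isotype) total,
because IGHM and IGHG repertoires are analyzed separately throughout. The
IGHG subclass label may arrive merged as `"IGHG3/4"`; the constant-region
call is free text for this reason, and only its `IGHM`/`IGHG` prefix drives
the isotype split.

# The synthetic cohort generator

Every analysis stage is exercised on simulated cohorts whose structure
mirrors the study design: five groups — non-treated patients (n = 5),
patients under treatment (n = 5), patients in remission (n = 6), endemic-area
controls (n = 6), non-endemic controls (n = 4) — with two isotypes per
sample. The generator's defaults are the study conditions; scaled-down
configurations (documented below) are used where runtime matters.

Per (sample, isotype):

* **Richness.** The clonotype number is Poisson around the group's expected
  richness — by default 1,200 for the four endemic groups and 12,000 for
  non-endemic controls, echoing the order-of-magnitude contrast in the
  study's mean clonotype counts.
* **Clonal expansion.** Abundances follow a symmetric Dirichlet with
  concentration 0.4 in endemic groups and 3 in non-endemic controls. One
  concentration parameter cleanly reproduces the low/medium/hyperexpanded
  spectrum contrast (small concentration puts mass on few clones); an
  explicit birth–death expansion process would add parameters without adding
  testable structure. Weights are converted to integer MIG counts (10 MIGs
  per clonotype on average, singletons floored at 1) and frequencies are
  recomputed from the counts.
* **Gene usage.** V calls are drawn from a 27-segment IGHV vector with
  realistic baseline frequencies. Active-disease groups (non-treated +
  treated) apply multiplicative shifts — IGHV3-30 ×1.19, IGHV5-51 ×1.42 up;
  IGHV3-23 ×0.82, IGHV1-69 ×0.68 down — matching the direction and
  magnitude of the reported active/without-disease usage ratios; the vector
  is renormalized after shifting.
* **CDR3 lengths.** Rounded Gaussian, mean 15 aa, sd 3 aa. Patient groups
  mix in a long-CDR3 component (mean 22, sd 2) with weights 0.15
  (non-treated), 0.08 (treated), 0.12 (remission): the non-treated group
  shows the strongest tail, treatment partially normalizes it. Lengths are
  truncated to [5, 35] aa *by resampling*: 5 aa is the minimal C…W junction,
  and both bounds sit more than 3 sd outside the length model, so the guard
  does not distort the distribution (clamping, by contrast, creates a
  boundary atom that a normality test correctly detects).
* **Sequences.** CDR3 amino-acid strings are uniform over the 20-letter
  alphabet with the junction anchored C…W. No somatic-hypermutation lineage
  structure, isotype-switching dynamics, or sequencing error is modelled.
* **Planted cluster.** One cluster of five near-identical CDR3 variants
  (≤ 2 substitutions from a fixed 17-mer seed; the first variant *is* the
  seed, so the cluster is connected through it) is injected into five
  patient samples at frequency ≈ 0.005. Background sequences of the same
  length are rejection-resampled to stay at Hamming distance ≥ 5 from every
  cluster member — random 17-mers virtually never violate this, but the
  guarantee makes cluster recovery exact rather than probabilistic.

`simulate_null_cohort()` disables every group effect (endemic-control
richness and concentration everywhere, base usage, no length tails, no
cluster), giving exchangeable samples for type-I-error calibration. The
whole generator is deterministic given the config seed.

**What passing tests do and do not show.** The simulator reproduces the
*statistical skeleton* the analyses assume — group structure, richness and
expansion contrasts, usage shifts, length tails, shared clusters. It does
not emulate V(D)J recombination biases, clonal lineages, or
repertoire-sequencing artifacts, so recovery of planted effects demonstrates
that the pipeline detects such structure when present at the configured
effect sizes, not that real repertoires contain it.

# Abundance spectra

Clonotypes are binned by frequency: low < 0.1%, medium 0.1–1%,
hyperexpanded > 1%. The medium bin is closed on both ends (a frequency of
exactly 0.001 or 0.01 is medium); the source description of the bins does
not fix the boundary convention, so it is stated here and asserted in tests.
Proportions count unique clonotypes, not MIG mass. Group contrasts use the
two-sample Wilcoxon rank-sum test on per-sample bin proportions.

**Rank-sum convention (used for every Wilcoxon in the package):** exact
p-values when both groups have ≤ 8 samples and the data are tie-free;
otherwise the large-sample normal approximation with midrank tie correction
and *no* continuity correction. At the study's group sizes (10 vs 12 for the
disease-status contrast) the uncorrected approximation holds the 5% level
almost exactly (measured 0.051 on continuous data), while the
continuity-corrected version is conservative (0.0395). Fully tied data
return p = 1.

# Diversity

**Tree substrate.** Maximum-likelihood trees over aligned CDR3 sequences are
replaced by pairwise normalized edit distance (unit mismatch/gap costs,
divided by the longer length) followed by Saitou–Nei neighbor joining:
re-implementing ML tree search is out of proportion to the tree's role as a
PD/UniFrac substrate, and an externally built newick tree can be supplied to
every diversity function for users who want the original toolchain.
Negative NJ branch estimates are clamped to zero with the deficit moved to
the sibling edge, and the tree is midpoint-rooted (UniFrac and
root-inclusive PD need a root; NJ is unrooted).

**Alpha.** Shannon entropy in nats over clonotype frequencies, and Faith's
PD as the branch-length sum of the minimal subtree connecting the observed
leaves *and the root* (the root-inclusive convention of common
phyloseq/picante usage — stated so tests are unambiguous).

**Beta.** One pooled tree per isotype over the unique CDR3 amino-acid
sequences of all samples; each sample maps its clonotype frequencies onto
the shared leaves (frequencies of clonotypes sharing a CDR3 are summed,
zeros where absent, renormalized to 1 over the retained set — renormalization
is needed because the IGHG filter leaves sub-unit mass). IGHG keeps only
clonotypes with frequency strictly above 0.001 (medium + hyperexpanded);
IGHM keeps everything. The distance is *normalized* weighted UniFrac,

$$u(A,B) = \frac{\sum_b \ell_b\,\lvert p_A(b) - p_B(b)\rvert}
               {\sum_j d_j\,(p_{Aj} + p_{Bj})} \in [0,1],$$

with $p_X(b)$ the fraction of X's abundance below branch $b$ and $d_j$ the
root-to-leaf distance. Ordination is classical metric scaling (PCoA) of the
double-centered Gower matrix; negative eigenvalues are reported but their
axes dropped.

**PERMANOVA.** One-way, with Anderson's pseudo-F computed from squared
distances, default 99,999 permutations and the +1 p-value correction. When
the number of distinct label arrangements is no larger than the permutation
budget, they are enumerated exhaustively and the p-value is the exact
fraction of arrangements (identity included) with F at least the observed.
Null calibration was verified by simulation: p-values are uniform over null
cohorts (Kolmogorov–Smirnov p = 0.97 over 100 seeds).

# Gene usage

Usage frequencies are fractions of *unique clonotypes* per sample carrying
each gene segment (allele suffixes such as `*01` stripped), so rows sum
to 1. The primary contrast is active disease (non-treated + treated) versus
without disease (remission + endemic controls); non-endemic controls are
excluded from it. Segments are flagged at raw p < 0.05 — matching how the
differentially used segments were reported — with Benjamini–Hochberg
adjusted values always emitted alongside. The PCA on flagged segments is
column-centered but not variance-scaled (usage frequencies share a scale),
with a deterministic sign convention (largest-magnitude loading positive).

# CDR3 features

**Lengths.** Histograms and medians are over unique clonotypes, unweighted
by abundance. Normality is assessed with Shapiro–Wilk — with one numerical
caveat that deserves its own paragraph.

Amino-acid lengths are integers. Applied to rounded data, Shapiro–Wilk
rejects *any* discretized Gaussian once samples reach repertoire scale
(measured: 20–100% rejection at n ≥ 100 for round(N(15, 3)) draws), so the
raw test cannot distinguish a control sample from a patient sample — both
would always reject. `length_distribution()` therefore de-rounds by default:
uniform ±0.5 jitter (dithering) is added before the test, which inverts the
rounding in distribution up to a second-order error. Measured on the
generator's null: rejection 0.035–0.06 for n ≤ 1200, while power against the
patient long-tail mixture is ≥ 0.88 at n ≥ 400 and ≈ 1 at n ≥ 1000. The
jitter consumes the current RNG stream (seeded runs stay reproducible), and
`dither = FALSE` restores the raw test.

Two-sample comparisons use the Kolmogorov–Smirnov statistic on the raw
(undithered) length vectors.

**Chemistry.** Per clonotype: GRAVY (mean Kyte–Doolittle hydropathy), net
charge at pH 7 by Henderson–Hasselbalch over side-chain pKa values (EMBOSS
set: K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1) with termini
excluded — the CDR3 is an internal fragment of the heavy chain, so its
alpha-amino and carboxyl groups sit in peptide bonds —, aromatic fraction
(F, W, Y, H), and aliphatic index $100(f_A + 2.9 f_V + 3.9(f_I + f_L))$.
Group comparisons are rank-sum tests on per-sample means; the generator
plants no chemistry effect, so these act as negative controls.

# Similarity networks

Nodes are (sample, unique CDR3 amino-acid sequence) pairs — node identity
keeps the sample because network nodes are labeled by sample of origin —
and edges join sequences of *equal length* at Hamming distance ≤ 2,
including distance-0 edges for identical sequences shared between samples.
Unequal lengths are incomparable under Hamming distance: no edge. Components
are therefore length-homogeneous by construction, which is asserted at every
extraction. All qualifying edges are materialized (no sparsification rule is
imposed).

A component is *PF-relevant* when its sample set intersects a restriction
set in at least `min_samples = 4` samples. The restriction set is
configurable because the extraction rule can be read as "four endemic-area
samples" or "four distinct patients"; the patient reading is the default for
PF relevance. Components are labeled `patient_exclusive` when every node
comes from a patient group. Consensus matrices give per-position residue
frequencies with one vote per node (unweighted by clonotype frequency) and
an alphabetical tie-break for the consensus letter.

# Problem sizes used by tests and the acceptance script

Simulation-based checks run at reduced per-sample richness chosen to keep
each property detectable while the whole suite stays fast; these sizes are
part of the package's documented study conditions for each check:

* *Null calibration*: richness 25 everywhere for the UniFrac/PERMANOVA path
  (tree sizes ≈ 650 leaves); richness 1,200 (the endemic default) for the
  per-segment rank-sum calibration, where only endemic samples are used.
* *Diversity ranking and region separation*: richness 20 endemic vs 200
  non-endemic, preserving the 1:10 contrast of the study design.
* *Usage-shift and length-tail recovery*: endemic richness at its 1,200
  default (the non-endemic group, unused by these contrasts, is reduced
  to 50).
* *Cluster recovery*: endemic richness 100 — network construction scales
  with the squared size of each length class, and cluster recovery is
  guaranteed by the separation constraint rather than by sample size.

# Known limitations

* NJ over normalized edit distances is a coarse substrate compared to an
  ML tree over a proper alignment; relative PD/UniFrac contrasts are
  meaningful, absolute branch-length units are not.
* The Dirichlet expansion model has no lineage structure: clones are
  exchangeable within a sample.
* Dithered Shapiro–Wilk drifts mildly anti-conservative at very large n
  (measured ≈ 0.09 at n = 3000); per-sample repertoires in this design stay
  well below that.
* The exhaustive PERMANOVA enumerator is intended for small designs (it is
  engaged automatically only when the arrangement count fits under the
  permutation budget).
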