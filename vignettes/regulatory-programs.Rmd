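---
title: "Methods: regulatory program discovery from paired single-cell multiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulatory program discovery from paired single-cell multiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`multiomeReg` implements the downstream computations of a paired
scRNA-seq/scATAC-seq analysis of a tumor and its microenvironment: per-cell
transcription-factor (TF) motif activity, a variability-plus-specificity
filter for tumor-restricted TFs, candidate cis-regulatory element (cCRE)
linkage, TF regulatory networks, intratumoral expression programs and their
cross-sample consolidation, ligand-receptor (L-R) interaction testing, and a
perturbation-based drug screen. Upstream processing (alignment, peak
calling, clustering, embedding, batch correction, doublet removal) is out of
scope: the package consumes count matrices and annotations in standard text
formats.

Because the package is validated on synthetic data with planted ground
truth, this vignette describes both the statistical procedures and the
generative model behind the validation, including what the simulations can
and cannot certify about real data.

# Quality control and normalization

Per-cell QC uses fixed gates: RNA cells keep a detected gene number in
[200, 6000], more than 1000 UMIs, and at most 10% mitochondrial reads; ATAC
cells keep 1000 < peak-region fragments < 20000, FRiP > 0.15, blacklist
ratio < 0.05, nucleosome signal < 4 and TSS enrichment > 3. Inequalities are
strict exactly where the thresholds are conventionally printed as strict.
The mitochondrial criterion is applied as an *exclusion* of high-mito cells;
a reading that retains them would contradict the purpose of removing
low-quality cells. Each removal is attributable: `audit = TRUE` returns the
per-gate decisions.

All statistical testing and averaging happens on depth-normalized values:
counts per 10,000 per cell, log1p-transformed (`normalize_counts()`). Fold
changes are computed on the un-logged normalized scale with a pseudocount of
1, `log2((m_in + 1)/(m_out + 1))`, which stabilizes sparse group means.

Differential features (DEGs and DARs) use a one-vs-rest two-sided Wilcoxon
rank-sum per group, implemented as the tie- and continuity-corrected normal
approximation (identical to `wilcox.test(exact = FALSE)`, verified in the
test suite), with Bonferroni correction over all features x groups tested
and gates `p_adj < 0.05`, `log2FC > 0.25`. A hurdle-type mixed model with
donor as a latent variable is a reasonable alternative for the RNA modality;
the rank-sum test is used for both modalities here because the thresholds,
not the test family, define the downstream contracts, and the rank-sum is
dependency-free and exactly reproducible. Because log1p is monotone, testing
on logged or unlogged normalized values is equivalent.

# Motif deviations

For motif $m$ and cell $j$, with $X_{mj}$ the summed counts over the motif's
peaks, $t_j$ the cell total and $f_m$ the motif peaks' share of the grand
total, the raw deviation is

$$d_{mj} = \frac{X_{mj} - f_m t_j}{f_m t_j}.$$

Each peak receives `n_iter` (default 50) background peaks sampled with
replacement from its `k = 50` nearest neighbors in the standardized
(GC fraction, log1p mean accessibility) plane, never itself. Re-computing
$d$ on each matched background set gives a per-cell null; the
*bias-corrected deviation* subtracts the background mean and the *deviation
Z-score* additionally divides by the background SD. Entries with zero
expectation are reported as `NA` and excluded from group means rather than
imputed.

Differential TF activity is a one-vs-rest comparison of per-cell scores.
The reported effect is the *difference of group means* (`activity_delta`):
deviation scores are signed and approximately centered at zero, so a
ratio-based fold change is undefined. The comparison defaults to the
Z-score scale, with `scale = "deviation"` as a switch, for a structural
reason: the raw deviation of a group elevated by any factor is bounded —
with a fraction $\pi$ of all counts in the elevated population, the
tumor-vs-rest gap of raw deviations cannot exceed $1/\pi$ (the expectation
$f_m t_j$ absorbs the elevation as the effect grows). At four equally sized
cell types ($\pi \approx 1/4$) the conventional in-group gate of 4 is
therefore unreachable on the raw scale for *any* effect size, while the
background-standardized Z-scale separates planted regulators from the null
with a wide margin. The variability statistic below stays on bias-corrected
deviations, where it is conventionally defined.

# Tumor-specific TF filter

Three gates, applied to all motifs:

1. **Variability.** Bias-corrected deviations are averaged within each cell
   type; the population SD of those means across types is the motif's
   variability. The SD distribution across TFs is right-skewed, so the
   upper-tail threshold uses the asymmetric double-MAD rule: with $m$ the
   median of all SDs and the right MAD the median of $|x - m|$ over
   $x \ge m$, the threshold is $m + 4 \times \text{right-MAD}$. No
   1.4826 normal-consistency constant is applied — the rule is stated
   directly as a multiple of the MAD, and the output table records the
   threshold used. Medians of even-length vectors are the mean of the
   central pair.
2. **In-group.** `activity_delta > 4` with Bonferroni-adjusted
   `p < 1e-4` in the target (tumor) group.
3. **Out-group.** `activity_delta < 1` in every other group.

The gates are decomposable (the audit table reports each independently) and
the variability gate is scale-equivariant: rescaling all deviations rescales
SDs and threshold together, leaving the pass set unchanged.

The drug screen is a lookup with two gates: an approved-drug flag and a
differential-expression Z-score below -2 (strict) for the TF's gene in the
perturbation profile, returned in order of ascending Z.

# cCRE linkage and regulatory networks

Sparse accessibility is densified by seeded within-cell-type pooling into
metacells of `group_size = 10` cells (remainders merge into the last pool;
totals are conserved). Pooling within annotated types preserves the
cross-type covariance the estimator needs without requiring embedding
coordinates, which keeps the stage free of an upstream dependency.

Co-accessibility is estimated in overlapping 500 kb windows advancing by
250 kb (any pair closer than 250 kb shares at least one window). In each
window the graphical lasso (block coordinate descent, element-wise
penalties) is run on the correlation matrix of standardized log1p metacell
accessibility with a distance-increasing penalty
$\rho_{ij} = \lambda\,(1 + (d_{ij}/\text{window})^2)$, $\lambda = 0.2$; the
score of a pair is the partial correlation
$-\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}$, averaged over windows
containing the pair, retained at score $\ge 0.2$. Degenerate windows
(constant peaks, singular fits) are skipped with a warning. The
distance-penalty schedule is a package choice; the windowing, cutoff and
lasso family follow the established co-accessibility construction.

Candidate links take pairs with *exactly one* promoter-side peak (midpoint
within 1 kb of a TSS, the same promoter rule used for peak annotation, where
promoter takes precedence over gene body, and assignment is by peak
midpoint). The other peak's mean accessibility is correlated with the
gene's mean expression across cell types (log-normalized type means;
raw-scale means are an exposed switch), with a two-sided t-based p on
$n_\text{types} - 2$ df and Benjamini-Hochberg correction across all
candidate links; `q < 0.05` defines cCREs. With few cell types this test
has very low power — at four types only near-perfect correlations are
detectable — which is a real limitation of the design, not of the
implementation; the validation plants links accordingly (below).

A gene is a candidate target of a TF in a cell type if an *accessible*
promoter peak of the gene carries the motif, or an accessible cCRE linked
to the gene carries it. "Accessible" is operationalized as detected in at
least 5% of the type's cells; the evidence class (`promoter_motif` /
`linked_ccre`) is kept on every edge of the resulting igraph network, and
DEG status is overlaid on nodes.

# Intratumoral programs and meta-programs

Per sample, tumor-cell expression is log-normalized, gene-centered, and
negative values are clamped to zero ("relative expression"); all-zero rows
are retained. Rank selection runs NMF (Frobenius objective, multiplicative
updates, random initialization, `nrun = 30` per rank) for $k = 2..6$; cells
are assigned to their top factor, the consensus matrix is the mean
co-assignment over runs, and the cophenetic coefficient correlates consensus
dissimilarity with its average-linkage cophenetic distances. The selected
rank is the one *before* the largest drop of the coefficient, falling back
to the argmax when no drop is positive. Solver controls: 300 iterations
maximum, relative tolerance 1e-5 checked every 10 iterations; the
best-of-`nrun` fit by reconstruction error is retained, and all run seeds
derive deterministically from the stage seed. Programs are the 30
highest-loading genes per factor, ties broken lexicographically; factors
with fewer than 30 positive loadings are flagged degenerate.

Consolidation scores every program's signature on every sample's tumor
cells with the bin-matched module score (below), correlates program scores
within each sample, and averages the correlation matrices across samples
(over samples where both programs are scoreable). Programs are clustered by
Ward linkage on one minus the averaged correlation. The dendrogram cut is
the package's own design choice: clusters are the *maximal subtrees whose
mean pairwise averaged correlation is at least 0.5* ("highly correlated
program sets"); programs outside any such subtree remain singletons. A
single threshold cut was chosen over a largest-height-gap cut after
observing that at validation scale the cophenetic coefficient saturates
near 1 for every rank (the small, clean problems have one dominant
optimum), so per-sample rank selection can over-split, and the resulting
splinter factors from different samples form loose clusters that a single
global gap cannot reliably separate (within-correlation ~0.1 versus
0.93-1.0 for genuine meta-programs). Retained clusters must span at least
half the samples; each is represented by the 30 genes with the highest
average loading over members, after L2-normalizing each member's loading
vector to remove NMF scale indeterminacy.

The module score of a gene set is the per-cell mean log-normalized
expression of the set minus that of `n_ctrl = 100` control genes drawn
(seeded, with replacement) from the same 24 equal-frequency mean-expression
bins as each set gene — a standard bin-matched control construction whose
null is centered at zero.

# Ligand-receptor testing

A (pair, source, target) triple is testable when the ligand is expressed
(count > 0) in at least 10% of source cells and the receptor in at least
10% of target cells; its strength is the average of the mean log-normalized
ligand expression in the source and receptor expression in the target
(a raw-scale switch is exposed for the "mean >= 1" gate's sister
convention). Cluster labels are shuffled `n_perm = 1000` times (one shared
set of shuffles for all triples, so the whole table is computed from the
same exchangeable null), and the add-one estimator
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_\text{perm})$ never
returns zero. Significance requires $p < 0.05$ and mean $\ge 1$.
Multi-subunit receptor complexes are out of scope; the pair table is
gene-gene. One practical note encoded in the tests: the permuted means must
be computed on exactly the normalization used for the observed means (the
per-cell totals come from the full gene universe, not the pair subset) —
getting this wrong biases the null noticeably.

# The synthetic multiome and what it certifies

`generate_multiome()` plants every structure the pipeline must recover, at
defaults that encode the validation conditions: 3 samples, 4 cell types
(one tumor), 100 cells per type per sample, 200 genes and 200 peaks on two
synthetic chromosomes (0-based half-open coordinates; genes every 40 kb),
20 motifs of which 3 are tumor-specific with a 3x accessibility gain, 20
planted cCREs, 2 shared intratumoral programs plus one private program per
sample, and 3 planted L-R pairs. Counts are negative-binomial
(gamma-Poisson) with lognormal per-cell depths; RNA dispersion is 0.5
(transcriptional bursting) and ATAC dispersion 0.2 (accessibility counts
are closer to Poisson). Per-cell totals (~2000 UMIs, ~1400 fragments in
peaks) sit inside the QC bands the filters expect. GC content is simulated
from Beta(2, 2), not computed from sequence; no FASTA exists.

Design choices worth knowing when interpreting recovery results:

* **Planted tumor peaks are pooled and mean-matched.** The three tumor
  motifs draw their 20 hit peaks from a shared pool of 30 tumor-restricted
  peaks — the family-level binding redundancy typical of co-enriched TF
  families — and each planted peak is rescaled so its *pooled* mean
  accessibility matches the background distribution: a cell-type-specific
  peak is closed elsewhere rather than globally brighter. Without this, the
  planted peaks cluster in the (GC, mean accessibility) matching plane and
  become each other's backgrounds, and the bias correction subtracts the
  very signal it should isolate.
* **Null motifs carry no planted signal.** Their hit peaks are drawn from
  peaks without planted profiles, so the recorded truth is the complete
  set of motifs with planted cell-type behavior and precision/recall
  against it are meaningful.
* **Planted cCRE activity spans a ladder.** Each planted link's cell-type
  profile is a permuted, equally spaced active-to-silent gradient (4.5x
  dynamic range) shared between gene, promoter peak and distal peak;
  `ccre_effect` (default 1) dials the peak-side mixing. With only
  4 cell types, an unconstrained Gaussian profile occasionally has
  near-zero spread, making that link undetectable *in principle*; a
  ground-truth generator should not plant undetectable truths.
* **Programs tile the tumor population.** Three disjoint programs
  (2 shared + 1 private) each cover a third of every sample's tumor cells,
  so no residual "background state" factor is shared across samples —
  such a factor would otherwise be a legitimate additional meta-program.

What passing recovery therefore shows: the statistics isolate exactly the
planted effects at realistic count noise, depths and sparsity, with correct
nulls (calibration, oracle identities, determinism). What it does not show:
robustness to batch effects, doublets, ambient contamination, fragment-level
artifacts, motif-scanning errors, continuous (non-discrete) cell states, or
annotation errors — none of which the generator emulates. Real-data use
should treat the QC, linkage-power and "accessible" thresholds as
tunable parameters, not verified constants.

# Problem sizes, seeds, numerical conventions

The test suite and the acceptance script run at the generator defaults
above; meta-program recovery uses 150 tumor cells per sample, and the L-R
calibration uses a 300-cell x 150-gene null with 300 random pairs (~2700
triples), a size at which the seed-to-seed SD of the null rejection
fraction is ~0.005. Every stochastic step takes an explicit integer seed;
the pipeline derives per-stage seeds as `seed + stage index` and two runs
with the same configuration are byte-identical (manifest MD5s are compared
in the tests). Ties are broken lexicographically wherever an ordering
feeds output (program top genes, link ordering); medians of even-length
vectors are the mean of the central pair; `E = 0` deviation entries, zero-
variance peaks in co-accessibility windows, and unscoreable programs are
excluded, not imputed.

# Known limitations

The graphical-lasso windows use dense within-window matrices, appropriate
for the package's target scale (10^2-10^4 peaks), not for genome-wide peak
sets in one call; the cross-cell-type correlation test is underpowered
below ~6 cell types; metacell pooling assumes cell-type annotations are
trustworthy; and the NMF rank heuristic inherits the cophenetic
coefficient's insensitivity when consensus saturates, which the
coherent-subtree consolidation compensates for but does not remove.
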