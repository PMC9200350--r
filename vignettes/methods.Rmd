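---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical substance of each pipeline stage:
the model it assumes, the parameters that matter, the numerical edge cases,
and the choices made where the design was genuinely open. It states no
empirical numbers beyond what the package's tests and acceptance script
compute themselves.

## Quality control

Cells are assigned exactly one category with fixed precedence
`low_genes → high_mito → doublet → pass`. The precedence makes the category
partition deterministic and reportable — a cell that both expresses few
genes and has a high mitochondrial fraction is counted once, as `low_genes`.
Consequences: category counts always sum to the number of input cells, and
filtering a passed matrix again with the same thresholds removes nothing
(idempotence). Both properties are tested.

* `min_genes` (default **400**): minimum expressed genes per cell. The
  value is a conventional droplet-QC cutoff for tumor biopsies; it is not
  derived from data and is exposed in the config.
* `mito_threshold` (default `"auto"`): maximum mitochondrial UMI fraction.
  The automatic estimate is `median + 3 × MAD` (MAD scaled for normal
  consistency), clamped to [0.05, 0.6]. The clamp prevents degenerate
  thresholds on unusually clean (MAD ≈ 0) or pathologically dispersed
  samples. The estimator needs ≥ 20 cells; below that a user value is
  required. A robust upper fence was chosen over a mixture fit because it
  is closed-form, deterministic, and insensitive to the failure cells it is
  meant to exclude.
* Doublet calls are accepted as an external label file rather than
  recomputed: doublet detection is a well-served upstream problem, and
  keeping it external preserves the audit trail of which labels were used.

Mitochondrial genes are retained through the cell filter (they define the
QC fraction) and dropped from the matrix afterwards, so they never enter
normalization or any downstream statistic.

Gene identity collapses to the symbol after the biotype/ribosomal filter,
because marker lists, gene sets and drug–gene snapshots are symbol-keyed.
Duplicate symbols keep the highest-total-count copy; the drop is logged.

## Normalization

Expression is variance-stabilized by analytic Pearson residuals under a
negative binomial model with fixed inverse-dispersion θ (default **100**):

    μ_ij = n_i · p_j
    r_ij = (x_ij − μ_ij) / sqrt(μ_ij + μ_ij² / θ)

where `n_i` is the cell's total UMI count and `p_j` the gene's global count
fraction. Residuals are clipped to ±√(#cells), which bounds the influence
of any single cell on downstream PCA and DE. The fixed-θ analytic form was
chosen over a per-gene regularized NB regression because the residual
contract (variance ≈ 1 for a gene following the model, sign-interpretable
deviations) is preserved with far fewer moving parts; the normalization
stage is deliberately replaceable.

Cell-cycle correction is a two-step linear procedure: S and G2M scores are
the mean clipped residual over the respective marker gene lists
(`cc_s_genes` / `cc_g2m_genes`, off by default — the synthetic generator
plants no cycle effect); each gene's residual vector is then regressed on
(1, S, G2M) and replaced by the regression residuals, making the linear
association between expression and cycle scores exactly zero. The phase
label is the argmax of (0, S, G2M) — a cell with both scores ≤ 0 is G1.

Degenerate inputs: genes with zero total count are dropped with a log entry
before residual computation (their residual is undefined); an all-constant
gene under constant depth has residual 0 everywhere.

Corrected counts are counts rescaled to the median cell depth. They are the
input for fold changes and all rank-based statistics, because residuals are
not on a fold-change scale.

## Clustering

PCA (default **30** components) on the residuals, an exact Euclidean kNN
graph (default **k = 30**), Jaccard overlap of neighbor sets as edge
weights (zero-weight edges dropped), and Louvain modularity maximization
with a fixed seed. The Jaccard refinement makes edge weights reflect
shared neighborhood structure rather than raw distance, which is what makes
the graph robust to density differences between populations.

Communities smaller than `min_cluster_size` (default **20**, the floor a
group needs for a stable within-sample DE contrast) are flagged
`unassigned_small` rather than merged into a neighbor: merging would
silently change the composition of DE reference groups. Flagged cells still
receive cell-type calls and appear in embeddings. Surviving clusters are
renumbered 0, 1, 2, … by decreasing size, ties broken by original community
id, so output labels are deterministic.

The 2-D embedding is UMAP on the PCA scores, run single-threaded with a
seeded RNG so that identical configs give byte-identical coordinates. The
embedding is visualization only; no downstream statistic reads it.

## Cell typing

Each cell is scored against each candidate type's marker set with a
rank-sum AUC: the probability that a random marker gene outranks a random
non-marker gene within the cell (average ranks for ties). The AUC is
scale-free and bounded in [0, 1], which makes the two decision thresholds
interpretable:

* `min_score` (default **0.6**): below this the best match is too weak and
  the cell is `unknown`. 0.5 is the chance level, so 0.6 demands a clear
  enrichment of the markers near the top of the cell's expression profile.
* `margin` (default **0.05**): if the best and second-best scores differ by
  less than this, the cell is `uncertain` rather than force-assigned.

Classification is hierarchical: major types first; cells with a named major
type whose type defines subtypes are re-scored against the subtype sets
only. `unknown`/`uncertain` cells are never sub-classified, and a subtype
label can only appear under its parent. A cell with a single candidate type
cannot be `uncertain` (there is no second score).

Marker genes absent from the universe are ignored with a log entry; a set
with no genes in the universe yields an undefined score and contributes
`unknown`. Because the score is rank-based it is invariant under any
monotone transformation of the cell's expression values — tested by
classifying the same cells on cubed counts.

## Differential expression

Per-gene OLS of the cycle-corrected residuals on a group indicator, which
for a single binary covariate equals the pooled-variance two-sample t-test
(verified against both `lm()` and the closed form to 1e-10). Covariates
(depth, cycle) are already removed upstream, so the regression needs no
additional terms — normalizing first and testing second keeps every
contrast on identically processed values.

Fold changes come from corrected counts with pseudocount 1:
`log2((mean_target + 1) / (mean_ref + 1))`. A gene is DE when
|logFC| > `fc_cut` (default **2**) and BH FDR < `fdr_cut` (default
**0.01**). Degenerate case: a gene identical in both groups has t = 0,
p = 1, logFC = 0.

Two contrast families are generated: each malignant cluster vs the pooled
cells of all non-malignant clusters, and every ordered pair of distinct
malignant clusters. A cluster is malignant iff its dominant (majority) cell
type is in `malignant_types` — a tied dominant type never counts as
malignant. Ordered (asymmetric) tumor-vs-tumor contrasts mean each cluster
gets its own up-regulated gene list, which is what the drug stage consumes.
Contrasts with a group under `min_cluster_size` are skipped with a log
entry; a sample with no malignant cluster yields an empty list with a
warning (valid for non-tumor tissue).

## Gene-set analysis

Two independent readouts:

**Competitive test** on the contrast's t-statistics. For a set of m genes
in a universe of G, the statistic is the difference between in-set and
out-of-set mean t, standardized by the pooled t variance and inflated by
VIF = 1 + (m − 1)·ρ̄, where ρ̄ is the mean pairwise correlation of the
in-set genes' residuals across cells, floored at 0. The floor avoids
negative variance estimates on small sets; with independent genes (ρ̄ = 0)
the statistic reduces to the plain standardized mean difference, and the
normal-approximation p-value agrees with a permutation of set membership
(tested against a 10,000-draw oracle). Sets with fewer than `min_set_size`
(default **5**) universe genes are skipped. Direction is `mixed` when the
set contains both significantly up- and down-regulated genes at the DE
module's own cutoffs — tying the rule to those cutoffs makes the three
categories mutually exclusive — otherwise `up`/`down` by the sign of the
in-set shift. The reporting FDR default is 0.05.

**Per-cell score**: within each cell, all genes are ranked and a set's
score is its mean rank centered and scaled to [−1, 1]. A random set scores
0 in expectation; the bounds are attained only by sets occupying the
extreme ranks; an all-tied cell scores 0 on every set. The score of a cell
depends on that cell alone (no reference population), so it is robust to
sample composition; the mean-rank form was chosen over kernel-ECDF
enrichment scores because it is closed-form, exactly testable, and keeps
the reference-free contract. Cluster-level summaries are medians and IQRs
over the named clusters.

## Drug candidates

DE genes from the vs-non-malignant contrasts are joined case-insensitively
against the offline interaction snapshot. Direction resolution: evidence
matches a candidate only if its expression direction is consistent with the
DE sign (up ↔ overexpression, down ↔ underexpression); consistent
sensitivity evidence yields `directed_sensitivity`, resistance
`directed_resistance`, no consistent evidence `undirected`. When one
(gene, drug) pair has consistent evidence for both sensitivity and
resistance, both rows are emitted and flagged `conflicting` — silently
picking one would hide exactly the disagreement a reviewer needs to see.
Output ordering (cluster, support priority, drug, gene) is total, so
identical inputs give byte-identical tables.

Offline snapshots replace live database queries deliberately: the join is
then reproducible, versionable and testable, and real database exports can
be converted to the two documented TSV schemas.

## Synthetic data generator

The generator emulates a single melanoma-like biopsy at full scale and is
the package's test bed. Defaults: 4193 cells of which 437 are planted QC
failures (200 low-gene, 187 high-mito, 50 doublets) and 3756 pass; six
major populations with the tumor at 34% of passing cells; four tumor
subclones (400/350/300/227); 2000 genes of which 10 are mitochondrial, 20
ribosomal and 50 non-coding (decoys for the gene filters); 20 markers per
type at log2 effect 2; 30 private DE genes per subclone and 10 shared tumor
genes at log2 effect 3; a 40-gene pathway suppressed (log2 −1) in subclones
2–4; log-normal depths (median 5000, sdlog 0.3); Beta(10, 190)
mitochondrial fractions; negative binomial counts with dispersion 0.1.
T cells split into two subtypes (10 markers each) to exercise the
hierarchical classifier.

Construction notes:

* Planted failure cells violate exactly one filter with a wide margin
  (low-gene cells restricted to 150 genes against a cutoff of 400;
  high-mito cells at fraction 0.7 against 0.25, with depth floored at the
  median so their non-mito budget clears the gene filter; doublets are sums
  of two passing cells' counts). The generator verifies the realized
  categories against the planted ones and fails loudly on any mismatch, so
  QC accounting is exact by construction, not approximately.
* The emitted config uses an explicit `mito_threshold = 0.25` rather than
  the data-driven estimate: a robust fence sits ~3 robust SDs above the
  healthy cells' median, where a handful of the thousands of healthy cells
  legitimately land. Exact planted/reported agreement is a property of
  explicit thresholds with margins; the estimator is still exercised by its
  own tests.
* Planted effects (markers, DE genes, the pathway) are placed on genes in
  the upper third of baseline expression. Two mechanisms would otherwise
  shrink an 8-fold planted effect below a |logFC| > 2 call: the pseudocount
  on weakly expressed genes, and compositional dilution (tumor cells carry
  extra planted transcript mass, deflating every gene's relative
  expression). Well-expressed placement keeps the planted truth
  identifiable at the stated cutoffs — which is what "planting a DE gene"
  must mean for recovery to be measurable.
* The pan-tumor drug target pair is wired to the best-expressed shared
  tumor gene, so the directed-sensitivity candidate spans all subclones.

What the generator does **not** emulate: ambient RNA, batch effects,
splicing structure, continuous differentiation trajectories, realistic
gene–gene correlation beyond the planted programs, or empty droplets.
Passing tests therefore demonstrate that the algorithms recover the
structure they claim to recover under a faithful overdispersed count model
— not that default thresholds are optimal for any particular real tissue.

## Determinism and problem sizes

Every stochastic step (generation, Louvain, UMAP) takes an explicit seed;
reruns with the same config produce byte-identical TSVs, verified by MD5 in
the run manifest. Unit tests run on a ~1000-cell replica of the default
sample; the acceptance script and the end-to-end test use the full
4193 × 2000 default. The brute-force modularity oracle enumerates all
partitions of 8–10-node graphs (the Bell number at 10 is 115,975), on
structured graphs whose modularity optimum Louvain attains. Clustering
recovery tests use well-separated Gaussian blobs in 10 dimensions — the
typical dimensionality of a PCA subspace — since kNN graphs over
low-dimensional blobs acquire spurious local structure that modularity
optimization resolves into sub-communities.

## Known limitations

* Single-sample design: no batch covariates, no cohort-level testing.
* The fixed-θ residual model under-corrects genes with genuinely extreme
  dispersion; θ is exposed for tuning.
* Cell typing requires marker lists appropriate to the tissue; scores
  degrade gracefully (toward `unknown`) when markers are missing from the
  universe, but cannot invent types not in the hierarchy.
* The competitive test's normal approximation assumes enough genes for the
  CLT (universes of hundreds of genes; sets ≥ 5).
* Drug candidate identification is an annotation join, not a
  pharmacological model: coverage numbers quantify transcriptional support,
  not expected efficacy.
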