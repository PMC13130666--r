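---
title: "Methods: malignant cell states, CNA-based malignancy calling, and deconvolution biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: malignant cell states, CNA-based malignancy calling, and deconvolution biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`tumorstates` implements a complete analysis chain for tumor ecosystems
profiled around checkpoint immunotherapy: quality control and normalization
of droplet scRNA-seq counts, platform batch correction, cluster-based cell
typing, expression-based copy-number aberration (CNA) inference with
subclone calling and malignant-cell classification, per-sample NMF with
cross-patient metaprogram discovery, stringent T-subset gating with kNN
rescue, pre/post-treatment composition statistics, bulk RNA-seq
deconvolution with confounder-residual adjustment and ROC evaluation of a
malignant IFN/MHC-II biomarker, and CLR-based phenotype gating with
radius-neighborhood statistics for segmented multiplexed-imaging tables.
Every stage is exercised on synthetic cohorts with known ground truth
produced by the package's own generator, so the whole pipeline is testable
without any external download.

# The synthetic cohort generator

`simulate_single_cell_cohort()` draws UMI counts from a negative binomial
with gene-level dispersion 0.5 (size = 2) around cell-type mean profiles
scaled to lognormal library sizes (median 5,000 UMIs, sdlog 0.3). The
default genome has 5,000 genes on 5 chromosomes split into p/q arms. A
smaller genome (2,000 genes) produced too few independent 100-gene
smoothing windows, making per-cell CNA noise heavy-tailed relative to real
data; 5,000 genes is also the typical size of a QC-filtered scRNA gene
set.

Planted structure:

* **Cell types.** Ten non-malignant types (epithelial, three stromal, six
  immune) at fixed proportions, each marked by 5–6 canonical marker genes
  boosted 32-fold over a low baseline. Marker expression levels were chosen
  so that rare-type markers (e.g. FOXP3/IL2RA in Tregs) survive the gene
  filter at the default sequencing depth, and so that the stringent
  T-subset rules assign roughly half of T cells — the regime the rules were
  designed for.
* **CNA blocks.** Malignant cells multiply expected counts by
  `2^amplitude` over contiguous arm-level blocks (default: chr1p +1,
  chr2q −1, chr3p +1). Subclone *k* carries the first `n_blocks − k + 1`
  events, so consecutive subclones always differ by exactly one arm;
  subclone membership is tilted by timepoint so the subclone–timepoint
  chi-square test has signal.
* **Expression programs.** Three 30-gene programs modeled on recurrent
  malignant HNSCC states (IFN/MHC-II, p-EMT, EpiSen). Every malignant cell
  is dominated by one program state whose activity — the log2 fold added to
  the program genes — is a truncated normal with mean 2 and sd 0.5, with
  low background activity (mean 0.2) of the other programs. The
  dominant-state mixture reflects how cell states present in real tumors
  (a cell is assigned to the state it most expresses) and gives the
  ground-truth labels that factor/metaprogram assignment is evaluated
  against. Program genes are spread uniformly along the genome, as real
  signature genes are; genomically clustered programs would masquerade as
  copy-number events. The post-treatment effect tilts state weights (IFN
  up, p-EMT down).
* **Batch and quality structure.** 3'-sequenced cells receive an additive
  per-gene log2 shift (sd 0.3); ~5% of cells are planted low-quality
  (600 UMIs, ~30% mitochondrial load); TCR positivity is a per-cell flag
  (85% of T cells, 2% of NK, 0.5% otherwise).

`simulate_bulk_cohort()` shares the same expression model (gene table,
baseline weights, centroids are drawn once from the config seed) and mixes
type centroids by known fractions with multiplicative lognormal noise;
responder samples get malignant IFN/MHC-II activity raised by 1 sd and, as
a planted confounder, a T-cell fraction raised by 0.5 sd of its Dirichlet
sampling distribution. `simulate_spatial_table()` places cells uniformly
at 0.5 µm/px and draws marker log-intensities around per-phenotype target
CLR values (centered by the planted composition, so realized CLR values
match the targets); a configurable fraction of CD4 T cells is attached
within 45 px of HLA-DR-positive tumor cells.

What the generator does **not** emulate: ambient RNA, doublets, UMI
collisions, cell-cycle structure, continuous differentiation topologies,
spatial tissue architecture beyond the one planted enrichment, and
cross-patient expression heterogeneity beyond the planted programs.
Passing tests therefore demonstrate that the implementations recover the
structures they were designed for under realistic count noise — not that
they are robust to every artifact of real tissue data.

# Preprocessing

Normalization is `log2(CPM/10 + 1)` with optional per-gene centering. QC
keeps lymphoid cells at ≥500 detected genes, other cells at ≥1,000, and
drops cells above 20% mitochondrial UMIs; genes are kept at a mean of
≥4 log2(CPM) or ≥5 UMIs in ≥20 cells. Platform correction shifts each
gene's 3' values onto the 5' mean within every (patient, cluster) stratum
and leaves 5' cells untouched. Initial lineage labels come from per-cell
marker scores; the cluster-based typing then scores every cell for every
marker set with the bin-matched score and flags cells as unresolved under
three rules (TCR+ outside T/NK clusters; top score discordant with the
cluster; top score < 1.15× the second with a discordant runner-up), with
fibroblast-scoring cells in epithelial clusters retained as possible EMT.
The clustering backend is PCA plus Louvain on a kNN graph with a fixed
seed; the neighborhood size should scale with the dataset (the published
k = 200 suits >100k cells; tests use ~25 on 500–2,000-cell cohorts, since
larger k over-connects small graphs).

Differential expression uses per-gene two-sided t-tests (Welch by default
— the pooled test is available but the variance assumption rarely holds
in log-normalized counts) with BH correction; log2 fold changes are
differences of means in log2 space.

# Bin-matched signature scoring

A cell's signature score is the mean expression of the signature genes
minus the mean of a control set matched on average expression: genes are
stratified into 30 equal-frequency bins of mean expression and each
signature gene draws 100 control genes from its own bin (with replacement
when the bin is smaller). Quantile bins keep the control pools balanced;
one control draw is made per signature and call (shared across cells) and
is deterministic under the seed. A caveat worth knowing: if a signature's
genes dominate the top expression bin, controls partially overlap the
signature and planted effects are attenuated — visible only in artificial
matrices with flat gene means.

# CNA inference and malignancy calling

Per patient, values are re-centered per gene, truncated to [−3, 3], and
smoothed per chromosome with a centered 100-gene moving average (windows
shrink at chromosome edges so gene indexing stays aligned; chromosomes
shorter than the window fall back to a chromosome-wide mean and are
logged). Each cell's smoothed profile is then re-centered at its median:
cells with net copy-number gains otherwise acquire a spurious genome-wide
offset through library-size normalization, which corrupts arm means and
stromal thresholds. Mean smoothed profiles of each stromal type span a
diploid reference band; values above the band keep the positive excess
over the highest reference, values below keep the negative excess under
the lowest, values inside become zero — a form that never flips signs and
keeps planted amplitudes intact even when a large malignant fraction
shifts the per-gene centering baseline. Adjusted values in [−0.15, 0.15]
are zeroed.

CNA signal is the mean |CNA| over each cell's top two-thirds of genes by
|CNA|; CNA correlation is the Pearson correlation with the mean profile of
the patient's top 25% epithelial cells by signal (computed per patient,
as the CNA matrices are). Subclones come from over-clustering the
top-two-thirds-filtered epithelial CNA matrix (PCA, kNN graph with k = 15,
Louvain at resolution 0.5) followed by two merge passes: clusters under 10
cells join their nearest cluster by a kNN vote with k = ln(n), and cluster
pairs with identical arm-event sets (arm means beyond ±0.15) whose arm
means differ by <0.15 everywhere merge iteratively until every remaining
pair differs in at least one arm. Resolution 0.5 was chosen because the
merge rules are the corrective step: whole-arm differences keep true
subclones apart at any moderate resolution, whereas aggressive
over-clustering can split a homogeneous subclone along its amplitude
gradient with arm means just past the merge cap.

Malignancy is called per subclone: the correlation reference is the
subclone's own top-signal cells, the patient's stromal cells are scored
with identical definitions, and each cutoff is the smallest observed value
such that strictly fewer than 1% of stromal cells exceed it (the
(n − ⌈0.01 n⌉ + 1)-th smallest order statistic). Cells above both cutoffs
are malignant, below both non-malignant, above exactly one unresolved.
`count_malignant_subclones()` reports, per patient, the subclones whose
majority of cells are malignant — the event-free cluster of normal
epithelial cells is not a genetic subclone.

# NMF metaprograms

Per sample and cell type (≥30 cells), the filtered, batch-corrected,
centered matrix has negatives zeroed and is factorized at rank 10 by
sparse NMF — multiplicative updates minimizing the Frobenius error with an
L1 penalty (weight 0.01) on the coefficient matrix; the basis is
initialized randomly and the coefficients from the basis, so factors are
invariant to cell order. The best of 20 restarts by approximation error is
kept; each factor is its top 100 genes by basis weight. Cells go to the
factor whose genes have the highest mean centered expression (raw means,
not bin-matched scores, matching the "most highly expressed" reading);
factors attracting <10 cells are dropped. Factors without a Jaccard
partner ≥0.2 are sample-specific and removed; the rest are clustered on
(1 − Jaccard) with average linkage and the tree is cut at height 0.8
(Jaccard 0.2) — a configurable choice, since only "groups of factors
clustering together" is prescribed. Metaclusters spanning ≥2 patients
yield metaprograms: genes in factors of strictly more than half of the
represented patients. Cells are assigned to metaprograms by bin-matched
scores with a deterministic first-name tie-break.

# T/NK separation and T subsets

NK cells are split from T cells by TCR-derived signatures: per patient
with ≥10 5'-sequenced candidate cells (TCR evidence is platform-limited,
so only 5' cells enter the comparisons), genes are tested TCR+ vs TCR−;
the top 50 per side are pooled and genes recurring in ≥5 comparisons form
the T and NK signatures used to score and assign all candidates. With no
eligible patient the TCR flag alone decides, logged. The stringent
T-subset rules act on raw marker UMIs (CD8: ≥1 CD8A/CD8B and zero
CD4/FOXP3/IL2RA; Th: ≥1 CD4 and zero others; Treg: ≥1 FOXP3 and ≥1 IL2RA
and zero CD8A/CD8B — CD4 permitted); the three rules are mutually
exclusive by construction. Unresolved cells with conflicting markers (any
CD8A/CD8B together with any CD4/FOXP3/IL2RA) are excluded from rescue;
the rest adopt a label held by ≥8 of their 10 nearest stringently labeled
neighbors in PCA space (Euclidean distance over the top components —
the published method fixes only "kNN").

# Composition statistics

Metaprogram fraction shifts use paired t-tests across patients with ≥20
assigned cells at both timepoints (≥3 eligible patients, otherwise skipped
with a reason). Per-patient signature deltas (patients with ≥50 cells per
timepoint) are marked significant only when the t-test passes *and* the
fold change exceeds 1.3. Because signature scores can be negative, "fold
change" is ambiguous: by default score deltas are treated as log2 fold
changes (|Δ| > log2 1.3), with a linear-scale interpretation (ratio of
positively shifted means) behind `fc_scale = "linear"`. Recurrently
differentially expressed genes are those significant (p < 0.05,
|log2FC| ≥ 1) with a consistent direction in at least half of the
patients. Raw p-values are reported alongside BH q-values computed within
each panel.

# Bulk deconvolution and the malignant IFN/MHC-II biomarker

The reference matrix drops cell types under 1,000 cells, merges pDC/cDC
into DC, samples up to 50 cells per (sample, type) with ≥10 cells, and
keeps genes nonzero in the reference and detected in ≥5 bulk samples.
Fractions are estimated per sample by nonnegative least squares of the
bulk CPM profile on type centroids, normalized to sum one — a deliberate,
transparent replacement for the external deconvolution service the
original analysis used; the estimator is pluggable (a function or a
precomputed fraction table can be substituted) and the service's internal
SVR and batch-correction machinery is intentionally not reimplemented.
Purity is the estimated malignant fraction. Two practical rules matter for
the estimator's stability, and the recovery tests follow both: rare types
whose centroids are near-collinear with the malignant one (here, normal
epithelium, which also falls below the 1,000-cell reference floor) do not
belong in the reference, and genes of the state programs that will later
be scored are left out of the fraction fit — deconvolving on them lets
per-sample state activity masquerade as composition.

Confounder adjustment regresses each score on the stated confounding
fractions by OLS and keeps the residuals. The per-sample malignant profile
subtracts the expected macrophage and T-cell contribution on the linear
CPM scale (the natural scale for mixture arithmetic; log-space subtraction
is available behind a flag) and divides by purity, clamping negatives to
zero with a per-sample clamped fraction reported; samples at purity ≤0.05
are flagged unreliable. ROC AUC is the mid-rank Mann–Whitney statistic;
the joint predictor model is a linear probability OLS with coefficient
t-tests (logistic regression would be the conventional alternative, but
the t-test formulation matches the reported analysis).

# Spatial gating and neighborhoods

Marker intensities are CLR-normalized per image with a pseudocount of 1 on
the 8-bit scale: `log((x+1)/geomean(x+1))`. Natural log is the default;
the printed note that a CLR of 1.1 is "about 2-fold over the mean" is
inconsistent with natural log (ln 2 ≈ 0.69), so the base is ambiguous and
base 2 is available as an argument. The two-pass gate hierarchy lives in a
JSON file (`inst/extdata/codex_gate_rules.json`), not code. Pass 2 as
printed lists no stricter B-cell rule although B cells are re-gated; the
packaged rules therefore retain the pass-1 B gate (CD20 > 1.5) in pass 2
— without it every B cell would be demoted, which is clearly unintended.
The pass-2 "CD8/CD4 ratio" is computed on pseudocounted raw intensities
((CD8 + 1)/(CD4 + 1)); a ratio of CLR values would be undefined around
zero. HLA-DR positivity is a strict CLR > 0.5. Neighborhood counts use a
uniform-grid spatial index (bin size = radius) with Euclidean centroid
distances, self excluded and no edge correction; the physical radius
(60 px × 0.5 µm/px = 30 µm) is asserted in the result's attributes.
HLA-DR+ vs HLA-DR− tumor neighborhoods are compared per neighbor type by
a one-tailed Student's t-test (positive greater).

# Problem sizes, tolerances and degenerate inputs

The test suite runs cohorts of 1–6 patients with 250–1,000 cells each and
2,000–5,000 genes; recovery benchmarks use 10 seeds (CNA: accuracy ≥95%,
subclone count exact), 5 seeds (metaprograms: per-program Jaccard ≥0.5),
and 50 replicates of the bulk biomarker comparison on 100-patient bulk
cohorts — a size at which an AUC gap of ~0.1 is resolvable; at the
43-sample scale of a typical validation cohort the same comparison is
statistically underpowered, which is itself worth knowing. Noiseless
mixture inversion is exact to solver tolerance (1e-6); residual
orthogonality to 1e-8; stochastic recovery tolerances are stated per
test. Degenerate inputs are handled explicitly: zero-total cells error,
zero-variance genes get p = 1 and a flag, constant CNA profiles get
correlation 0 and a flag, singular deconvolution designs fall back to
ridge with a warning, and ties in metaprogram assignment break
deterministically and are flagged.

# Known limitations

* The simulator's dominant-state program model makes state recovery
  well-posed; continuous mixtures of equally strong programs would lower
  factor purity and metaprogram Jaccard.
* NMF uses multiplicative updates rather than the exact
  alternating-NNLS variant named in the literature; with 20 restarts and
  the sparsity penalty the factorizations agree in practice on planted
  problems, but individual runs are not numerically interchangeable.
* Arm-event calling inherits the moving-average's boundary smear: an
  event on one arm leaks ~0.02–0.05 into the adjacent arm's mean, which
  is well below the 0.15 event threshold at default settings but not at
  much smaller window-to-arm ratios.
* The NNLS deconvolution assumes centroids on the same linear CPM scale
  as the bulk mixture and no platform shift between them; it is a
  baseline estimator, not a reimplementation of external tools.
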