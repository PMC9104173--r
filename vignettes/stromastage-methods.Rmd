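---
title: "Methods: stage-resolved fibroblast analysis of pancreatic tumor stroma"
author: "stromastage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-resolved fibroblast analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and scientific setting

Pancreatic ductal adenocarcinoma (PDAC) has an unusually stroma-rich tumor
microenvironment, and its cancer-associated fibroblasts (CAFs) change
markedly as the tumor progresses from a localized lesion (stages IB, IIA)
through the first lymph-node metastasis (IIB) and beyond (III). `stromastage`
implements a fibroblast-centric analysis of this progression as a reusable,
fully testable pipeline:

* clustering and typing of stage-annotated single-cell RNA-seq profiles,
  fibroblast subclustering, marker calling, and cluster-by-stage
  composition;
* a product-form ligand-receptor interaction strength between cell types;
* statistics for ordered "invasibility" gene signatures (called `ELI_up` and
  `ELI_dn` throughout): preranked gene set enrichment with a permutation
  null, a within-set co-expression test, over-representation analysis, and
  short-series stage-pattern mining;
* extraction of densely connected signature subnetworks (with linker genes)
  from a protein-protein interaction (PPI) graph;
* quantification of nanopatterned stromal invasion assays: normalized
  invaded area, one-dimensional front profiles, fork calling and depth
  comparison.

Every stage of the pipeline can be exercised without external downloads
through a synthetic-data generator that plants known structure, so each
claim the pipeline makes is checked against a known truth in the test suite.

# The single-cell pipeline

**Normalization.** Counts are depth-normalized per cell with scale factor
$s = 10^4$ and log-transformed, $y_{gc} = \log(1 + s\,x_{gc}/d_c)$ with
$d_c$ the cell's total counts. Zero-depth cells remain all-zero with a
warning.

**PCA.** Genes are standardized (zero-variance genes dropped) and the top
components retained with a deterministic sign convention (the
largest-magnitude loading of each component is made positive), so results
are reproducible across runs and platforms. All-cell clustering uses 10
components by convention.

**Number of components for the fibroblast rerun.** The convention in the
field is to pick the number of components at the elbow of the scree plot,
and the canonical published choice for a fibroblast-only rerun is 7 — an
elbow-rule outcome on a particular dataset, not a constant of nature.
`choosePCs()` automates the same judgment: it keeps the components whose
eigenvalue exceeds the Marchenko-Pastur upper noise edge
$(1 + \sqrt{p/n})^2$, the largest eigenvalue a pure-noise standardized
matrix of the same shape would produce. On the default synthetic cohort
this selects ~9 components, which is what the planted structure requires:
eight subcluster contrasts plus a global co-expression factor cannot fit in
7 dimensions. A fixed count (including 7) remains available via the
`n_pcs_fibro` configuration key.

**Clustering.** A k-nearest-neighbor graph (k = 20) in PC space is
reweighted by the Jaccard overlap of neighborhoods (pruned below 1/15) and
partitioned by Louvain modularity optimization at resolution 1 — the
community-detection procedure behind standard single-cell toolkits; the
2-D t-SNE map (`embedTSNE`) is display only. Louvain is stochastic, so a
seed argument controls it.

**Merging indistinguishable clusters.** Modularity at a fixed resolution
occasionally splits one homogeneous population in two, and such splits can
have *higher* modularity than the faithful partition, so restarts cannot
repair them. `mergeIndistinct()` merges any cluster pair separated by fewer
than 5 strong markers (two-fold, BH q < 0.05, pairwise Wilcoxon). The
two-fold bar matters: when a population is split in half and then tested,
the split coordinates themselves were chosen by the clustering
(double-dipping), which inflates weak differences; requiring a two-fold
change keeps chance splits mergeable while genuinely distinct subclusters
(planted at four-fold) always survive.

**Typing.** Each cluster is scored per candidate type as the mean z-scored
expression of that type's markers (e.g. LUM, DCN, COL1A1 for fibroblasts);
the best type above a threshold $\tau = 0.25$ wins. A cluster exceeding
$\tau$ for both ductal marker sets gets the combined ductal label, and a
cluster below $\tau$ everywhere is labeled "others". The threshold is a
design choice: the combined-label class is described in the literature
without a quantitative rule.

**Markers.** Cluster-vs-rest Wilcoxon rank-sum per gene (normal
approximation with tie and continuity correction — the regime of thousands
of cells), with fold change computed from de-logged means with pseudocount
1. The default marker filter uses the raw p-value at 0.05 with
|log2FC| > 0.5, the conventional cutoff for this analysis; BH-adjusted
p-values are reported alongside for modern practice.

# Ligand-receptor strength

For sender type $A$ and receiver type $B$, each ligand-receptor pair
$(L, R)$ is scored

$$S = E_L \cdot E_R \cdot f_L \cdot f_R,$$

the product of mean log-normalized ligand expression over **all** sender
cells, mean receptor expression over all receiver cells, and the fractions
of senders/receivers with nonzero expression. "Expression" is the mean over
all cells of the type (not only expressing cells) — the simplest reading
consistent with upstream normalization. Reporting keeps the top 4
fibroblast-side genes (after the expression ≥ 0.5 and fraction ≥ 5% / 10%
filters for the ligand / receptor direction) and the top 3 cognate genes
per partner type, ties broken by gene symbol. Chord-diagram aggregation is
emitted as a per-annotation-category table (summed S with a gene-share
cutoff) rather than drawn.

# Signature statistics

**GSEA.** The classic weighted running sum: walking down the ranked list,
set members add $|r_i|^p / \sum_{hits} |r_j|^p$ (p = 1 by default) and
non-members subtract $1/(N - N_h)$; the enrichment score is the extremum.
Significance comes from gene-label permutations (random sets of the same
size), matching preranked practice: p is the fraction of same-sign
permutation scores at least as extreme, and NES divides by the mean |ES| of
same-sign permutations. The leading edge is the set members at or before
the extremum (at or after, for negative scores). The implementation is
checked against a brute-force running sum to 1e-12 and against an
established preranked implementation on a reference case.

**Within-set co-expression.** Correlation "strength" is |Pearson r| of a
gene pair across cells; all within-set pairs are compared to all pairs among
genes outside the set (mixed pairs excluded, per the strict reading of
"outside") by a two-sided Welch t-test. Pairs sharing a gene are not
independent, so the test is anti-conservative; the type-I error at
$\alpha = 0.05$ measured over null simulations is ~0.06-0.07. We report it
as such and also emit signed summaries. Background pair counts above 1e6
are uniformly subsampled under a seed.

**Stage-pattern mining.** Candidate trajectories over the ordered stages
(Normal, IB, IIA, IIB, III) are all profiles on an integer unit-change grid
(steps in $-c..c$, $c = 2$, anchored at 0), collapsed to 50 maximally
distinct representatives by greedy max-min selection under correlation
distance (seeded at the steepest sustained rise; deterministic
lexicographic tie-breaks; the flat profile is always kept). Genes join the
profile best correlated with their first-stage-anchored stage-mean vector;
zero-variance genes join the flat profile. Per-profile significance
permutes the stage order within each gene and compares observed to permuted
gene counts, Bonferroni-corrected across non-flat profiles. Because the
smallest achievable permutation p is $1/(n_{perm}+1)$, the default
$n_{perm} = 1000$ is chosen so that the Bonferroni-corrected floor
($49/1001$) stays below 0.05; fewer permutations make significance
unreachable regardless of signal. Near-collinear profiles survive the
max-min collapse at m = 50, so a coherent cohort with modest amplitude can
scatter over 2-3 neighboring profiles; cohort-level conclusions should read
the top assigned profile together with its neighbors.

**Over-representation.** One-sided hypergeometric tail per term with fold
enrichment and BH q-values, against a user-supplied annotation (no curated
database ships with the package). Bulk two-group ranking (e.g. node-positive
vs node-negative cohorts) uses per-gene Welch t on log2 CPM.

# PPI subnetworks

Seeds (the top-100 signature genes) present in the interaction graph are
connected by a greedy Steiner-style merge: repeatedly join the two closest
selected components by a shortest path of at most `maxLinkerPath` edges
(default 2, i.e. one linker per bridge — "relatively few linker genes"),
adding interior nodes as linkers, with lexicographic tie-breaks. Seeds
unreachable within the cap stay as separate reported components rather than
disappearing. Density is $2E/(n(n-1))$ and the mean local clustering
coefficient counts degree-<2 nodes as 0. On 8-node graphs the greedy linker
count is verified against exhaustive minimum Steiner node sets (within the
2x greedy bound).

# Invasion assay quantification

Traced ROI polygons (pixel coordinates, y down, counter-clockwise after
ingest so the shoelace area is positive) give the invaded-area change
$\delta Area_t = Area_t - Area_{t_0}$ and its normalization by the initial
interface length, $\langle\delta Area_t\rangle = \delta Area_t /
L_{Interface}$ — for a uniform advance of depth d this equals d exactly.
The front profile takes, at each integer interface position, the maximal
perpendicular extent of the polygon beyond the interface line (0 where the
polygon stays behind). Profiles are smoothed by a 20-px centered moving
mean with truncated edge windows (no padding — we do not invent signal);
note an even window cannot be perfectly centered, so a linear ramp acquires
a half-pixel shift (odd windows are exact). A position is a fork when the
smoothed profile strictly exceeds the mean over the 40 px to its left and,
separately, the 40 px to its right; runs of consecutive qualifying
positions collapse to one fork at the floored midpoint, whose depth is the
smoothed value there (the smoothed, not raw, value — a documented choice).
Depth distributions between conditions are compared by a two-sided
Mann-Whitney test, exact for groups of at most 20 without ties and by the
tie-corrected normal approximation otherwise.

# The synthetic-data generator

`simulationSpec()` fixes the study conditions; `simulateCounts()` draws
them. The defaults emulate a 35-patient cohort (11 normal pancreas; 24
tumors split 5/6/9/4 over IB/IIA/IIB/III), 145 cells per patient (~5,000
cells), 1,000 genes, and twelve cell types at realistic tissue proportions
(fibroblast-rich tumors). Counts are negative binomial
(var $= \mu + \phi\mu^2$, $\phi = 0.4$) with log-normal library sizes
(mean 2,000, log-sd 0.3) — the standard noise model for droplet data; no
doublets, ambient RNA or batch effects are simulated, so passing tests
demonstrate correctness of the methods under the assumed model, not
robustness to those artifacts.

Planted structure, and why the scales are what they are:

* **Eight fibroblast subclusters** (`F0`..`F7`) each carry 25 marker genes
  at 4-fold elevation over a baseline mean of 2. Dozens of well-expressed genes
  is a realistic breadth for a transcriptomic subtype program, and it is
  what makes subcluster identity the dominant variance structure — the
  property the analysis pipeline (and the study it emulates) presumes.
  Stage compositions are homogeneous where the emulated cohort is
  homogeneous (Normal is 75% `F2`; IIA is 70% `F5`) and diverse at IB, IIB
  and III, with `F0/F1/F3/F4/F7` emerging at IIB.
* **Signature sets**: ordered 100-gene `ELI_up` and `ELI_dn` lists at
  baseline mean 2. Each set shares a single per-cell Gaussian latent factor
  on the log-mean scale (mean-preserving), the simplest mechanism with a
  tunable pairwise correlation; the loading is calibrated numerically from
  the negative binomial moments so the realized Pearson correlation on the
  log-normalized scale matches the requested value. The default target is
  r = 0.05: single-cell gene-gene correlations are small, and the claim the
  co-expression test reproduces is a statistically significant contrast
  against background, not a large absolute correlation. (A strong global
  factor would also be a genuine, clusterable cell state — at r ≳ 0.1 the
  latent continuum begins to split the dominant subclusters, which is
  faithful single-cell behavior but not the planted cluster truth.)
* **Stage trajectories** act multiplicatively on fibroblast means:
  `ELI_dn` rises to IIA then falls (max 1.55-fold), 70 of the `ELI_up`
  genes rise and stay up, and 30 peak at IIB. Stage means aggregate
  hundreds of cells (standard error ~0.02-0.06 on the log scale), so these
  modest amplitudes are detected with large margins by the pattern miner
  while leaving within-stage cell-level structure to the subclusters.
* **Subcluster `F4`** additionally over-expresses `ELI_up` two-fold — the
  pro-invasive subcluster whose enrichment the pipeline's per-cluster GSEA
  recovers.
* **PPI graphs**: Erdos-Renyi background (p = 0.01) plus seed-seed edges
  topped up to a target induced density (default 0.25), emulating the dense
  hub-spoke signature subnetworks reported for curated interaction data.
* **Invasion series**: Gaussian-profile forks (lateral sd 35 px) advancing
  linearly over hourly frames to a planted final depth (60 px), evenly
  spaced with jitter (≥ 100 px apart) along an 800-px interface, plus
  2-px additive boundary-tracing noise. Fork shapes tile most of the
  interface, as collective invasion fronts do.

Truth tables (cell type, subcluster, marker and trajectory assignments,
fork positions/depths) ride along in `colData`/`rowData`/`metadata` or as
returned data frames, so parameter recovery is always checkable.

# Numerical and design choices

* Stochastic operations take explicit integer seeds; the pipeline fans one
  configuration seed out to per-stage child seeds by fixed offsets, making
  whole runs byte-identical.
* Cluster ids are dense from 0, ordered by decreasing size; profile,
  path and gene ties break lexicographically — every tie-break in the
  package is deterministic.
* MatrixMarket input is 1-based triplet format per the standard; gene
  symbols are uppercased on ingest and case-fold duplicates rejected.
* The test-suite and default-pipeline problem sizes (~5,000-cell cohorts,
  hundreds of permutations, ten invasion assays) were chosen so the whole
  study runs in about a minute on one core while leaving every statistical
  check well-powered.

# Known limitations

* The co-expression t-test treats gene pairs as independent observations;
  it is anti-conservative and reported as such.
* Pattern mining assigns by shape correlation only; amplitude information
  is deliberately ignored, and near-collinear model profiles can split a
  cohort's assignment.
* The greedy subnetwork extraction is not a minimum Steiner tree solver;
  it is bounded against the optimum only at small scale.
* The generator does not emulate batch effects, doublets or ambient
  contamination, and cell-type assignment assumes marker sets are given.
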