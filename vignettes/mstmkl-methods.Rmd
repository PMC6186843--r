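---
title: "Methods: spanning-tree brain networks and multikernel classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spanning-tree brain networks and multikernel classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstmkl)
```

## The problem and the model

Group comparisons of functional brain networks usually start from a
subject-specific connectivity matrix — Pearson correlations between the
mean BOLD time courses of atlas regions (ROIs). Thresholding that matrix
to obtain a graph introduces an arbitrary parameter that can dominate
downstream statistics. This package instead builds, per subject, the
**maximum-weight spanning tree** (MST) of the positive-correlation graph:
an acyclic, connected backbone that keeps the strongest connections,
requires no threshold, and has a fixed edge budget (R − 1 edges for R
regions), making networks directly comparable across subjects.

Two complementary properties of the tree then feed a two-group classifier
(patients vs controls):

* **Local property.** Node betweenness on a tree,
  $bc_i = \frac{1}{(n-1)(n-2)} \sum_{h \ne j,\; h,j \ne i} \rho_{hj}^{\,i} / \rho_{hj}$,
  where on a tree the path between any pair is unique ($\rho_{hj} = 1$), so
  $bc_i$ is the fraction of ordered pairs whose path crosses $i$ as an
  interior node; leaves score exactly 0. Regions whose betweenness differs
  between the groups (two-sample t-test, p < α on the training set) are
  selected, and the selected betweenness vectors are compared with the
  linear kernel $k_v(x, y) = x^\top y$.

* **Topological property.** Frequent connected subgraphs are mined
  separately from each training group's trees: a pattern's frequency in a
  graph set is the share of graphs containing all of its edges
  (node identity is fixed by the atlas, so occurrence is exact edge-set
  containment rather than unconstrained isomorphism). Patterns with
  frequency at least $s$ are frequent; those whose between-group frequency
  difference $D(g_s) = |f_q(g_s \mid G_p) - f_q(g_s \mid G_n)|$ strictly
  exceeds a threshold $T$ are discriminative. Each subject's tree is then
  *reconstructed* by deleting every edge not covered by a discriminative
  pattern, and reconstructed networks are compared with the
  **Weisfeiler–Lehman subtree kernel**: node labels start as degrees, each
  iteration replaces a label by a compressed form of (own label, sorted
  neighbour labels), and $k_g(G, H) = \langle \varphi(G), \varphi(H)\rangle$
  over label counts accumulated across iterations $0..h$.

Both kernels are cosine-normalized individually and fused,
$K = \beta\, k_v + (1-\beta)\, k_g$, a convex combination that stays
positive semidefinite. A soft-margin SVM on the fused (precomputed) kernel
does the classification. Performance is estimated by stratified 10-fold
cross-validation repeated 50 times; reported ACC/SEN/SPE/AUC are means of
the per-repetition pooled metrics, with sensitivity defined for the
patient class and AUC as the normalized Mann–Whitney statistic of the
decision scores (ties count one half).

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `support` (s) | minimum pattern frequency | 0.7 | frequent = freq ≥ s |
| `threshold` (T) | discriminative cut on D | 0.13 | strict `>`; 0.5 is a conservative reference choice |
| `h` | WL iterations | 2 | configurable 0–10; kernel grows by PSD increments in h |
| `alpha` | t-test level | 0.05 | pooled variance by default, Welch behind a flag |
| `beta` | kernel weight | `"auto"` | inner 5-fold CV over 0, 0.1, …, 1; ties → smallest β |
| `C` | SVM cost | 1 | only β is tuned |
| `folds` / `repetitions` | CV protocol | 10 / 50 | stratified by class |

## Design choices where the design was open

* **t-test flavour.** "Two-sample t-test" is read as the classical
  pooled-variance test; Welch is available via `welch = TRUE`. A region
  with (near-)zero pooled variance receives p = 1 and is never selected.
* **Kruskal tie-breaking.** Equal weights are resolved toward the
  lexicographically smaller (min-label, max-label) pair. Ties have measure
  zero for real correlations but make tests deterministic.
* **Negative and zero correlations** both yield no edge; a subject whose
  positive graph is disconnected is an error (no spanning tree exists),
  not a silent forest.
* **Pattern granularity.** All-patterns mode on 89-edge trees yields
  hundreds of single-edge patterns; the default therefore returns only
  *maximal* frequent patterns (no frequent connected one-edge extension,
  which by anti-monotonicity equals "no frequent super-pattern"), with
  `pattern_mode = "all"` available. Duplicate patterns mined from both
  groups are merged by edge set before scoring.
* **Reconstruction is label-blind**: the pooled discriminative set is
  applied to every subject (train and test alike), as it must be at test
  time.
* **WL runs on identity-stripped graphs** (initial labels are degrees, not
  ROI ids — region identity already entered through pattern selection),
  always for the full h iterations: pairwise early stopping would break
  the shared feature map and positive semidefiniteness. Isolated nodes
  participate with degree-0 labels. The label dictionary assigns
  consecutive integers in first-seen order over the input graph order, so
  runs are deterministic; at prediction time the training vocabulary is
  frozen and unseen augmented labels receive fresh ids that cannot collide
  with training ids.
* **Empty selections degrade deterministically.** If no region passes α,
  all regions are kept (with a warning); if no pattern exceeds T,
  reconstructions are edgeless and the graph kernel sees only node counts.
  Similarly, a subject whose selected-region betweenness vector is all
  zeros (every selected region is a leaf of its tree) has no linear-kernel
  signal; it is treated as orthogonal to all other subjects (unit
  self-similarity, zero cross-similarity — still a valid Gram matrix)
  rather than aborting a cross-validation run. The exported
  `normalize_kernel()` keeps the strict error for direct use.
* **β selection.** Inner 5-fold stratified CV on the training fold,
  criterion mean accuracy, ties to the smallest β. The single-kernel
  baselines arise exactly as β = 1 (`method = "lp"`) and β = 0
  (`method = "tp"`).
* **Aggregation.** Within a repetition, predictions are pooled over the 10
  folds before computing ACC/SEN/SPE/AUC; the 50 repetitions are then
  averaged arithmetically.
* **Leakage control is structural.** `mstmkl()` only ever sees the
  training cohort; `predict()` consumes frozen training artifacts (region
  selection, patterns, WL vocabulary, β, support vectors). Deleting a test
  subject therefore cannot change any training-fold quantity.

## The synthetic cohort generator

Real resting-state cohorts are access-restricted, so validation uses
synthetic two-group cohorts with known ground truth. The generator
emulates: R = 90 regions, T = 130 retained volumes, and a 32/28
patient/control split by default (tests and the acceptance experiments use
a reduced R = 30, 20/20, T = 130 design for runtime).

Construction (all deterministic given the seed):

1. A random connected **backbone** (recursive tree plus density-`0.15`
   extra edges) with edge correlations uniform in \[0.2, 0.45\] —
   weak-to-moderate functional coupling — shared by both groups.
2. A **hub effect**: the `n_hubs = 2` highest-degree backbone nodes gain
   `hub_effect = 0.35` on all of their correlations in the patient group
   (capped at 0.95). This reliably raises the hubs' tree betweenness in
   patients.
3. A **motif effect**: a connected path over `motif_size = 4` non-hub
   regions gains `motif_effect = 0.8` in the patient group. The default is
   deliberately strong enough that, after positive-definite repair, motif
   correlations dominate every alternative tree path; weaker values let
   hub-boosted backbone detours displace motif edges from the tree, which
   defeats the planted-subgraph ground truth.
4. The target matrix is projected to the nearest valid correlation matrix
   by iterated eigenvalue clipping (floor 1e-6) and unit-diagonal
   rescaling. If the repair demotes motif correlations below background
   level, the generator errors and advises smaller effects.
5. Subject series are T independent multivariate-normal draws plus white
   observation noise (`noise_sd = 0.2`, mild attenuation of observed
   correlations).

What the generator does **not** emulate: hemodynamics, temporal
autocorrelation, motion artifacts, atlas geometry, site effects, or
realistic between-subject covariance heterogeneity. Passing tests
demonstrate that the pipeline recovers planted structure of this kind and
is calibrated under this null — not that it attains any particular
accuracy on clinical data.

## Numerical choices and degenerate inputs

* Correlations use the standard sample normalization (the denominator
  convention cancels in r); no Fisher-z transform is applied. Columns with
  zero variance and series shorter than 3 time points are errors.
* Kernel symmetry is enforced to 1e-10, PSD checks use a −1e-8 eigenvalue
  tolerance, and the discriminative cut is strict (`D > T`).
* The miner guards against pathological pattern explosions with a
  `max_patterns` bound (default 1e5) that errors with advice rather than
  silently truncating.
* Repetition seeds derive deterministically from the master seed
  (`seed + repetition`), and inner-CV seeds from (seed, repetition, fold),
  so identical configurations reproduce reports byte-for-byte.

## Validation experiment sizes

The test suite checks each algorithmic core against an independent oracle
(exhaustive spanning-tree enumeration for n ≤ 6; all-pairs path walking
for betweenness on trees up to n = 12; brute-force connected-subgraph
enumeration for cohorts of ≤ 8-node graphs at s ∈ {0.5, 0.7, 1};
uncompressed-string WL feature maps for h ∈ {0, 1, 2, 4}). Pipeline-level
experiments use the reduced cohort: parameter recovery with 10-fold CV ×
10 repetitions (expected mean ACC ≥ 0.8, hub regions selected in ≥ 90% of
folds, motif edges covered by selected subgraphs in ≥ 80% of folds), null
calibration with 50 repetitions (mean accuracy inside the 95% binomial
band around 0.5 for 40 subjects), and the t-test's nominal level estimated
over 40 independent replicate null cohorts (fold-wise counts within a
single cohort are correlated and estimate that cohort's realized chance
differences instead of the test's level).

## Known limitations

* The miner's worst case is exponential when many near-deterministic edges
  co-occur (e.g. cohorts of identical trees mined in all-patterns mode);
  the `max_patterns` guard makes this an explicit error.
* Pooled t-tests on betweenness are approximate: tree betweenness is
  bounded, zero-inflated (leaves), and dependent across regions. The null
  calibration experiments show the selection step operates near its
  nominal level at the sizes used here, but the p-values are not exact.
* With ~40 subjects, a single cross-validation split is noisy; only the
  repetition-averaged metrics are meaningful. On null cohorts the mean CV
  accuracy can sit noticeably *below* 0.5 for some cohorts: with a fixed
  finite cohort, the held-out complement of a training fold that is
  chance-imbalanced along the selected features tends to lie on the
  opposite side of the learned boundary (the familiar "anti-learning"
  artifact of in-fold selection at small n), which is why calibration is
  judged against a binomial band rather than equality with 0.5.
* The fused kernel uses one global β per fit; per-fold β histograms are
  available in the CV report for inspection.
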