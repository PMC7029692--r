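---
title: "Mapping connectivity gradients with spectral reordering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping connectivity gradients with spectral reordering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradparc)
```

## The problem

Hard parcellation methods force every voxel of a cortical region into one
cluster, even where the underlying connectivity changes gradually. A region
can contain both core zones with genuinely distinct connectivity and
intermediate zones whose profiles blend smoothly between them. `gradparc`
implements an analysis that does not presuppose either situation: it orders
the voxels of a seed region by the similarity of their connectivity
profiles, quantifies *how* graded the transition is, and only then extracts
core clusters from the two extremes of the ordering.

The same machinery applies to two kinds of connectivity profile:

* **structural fingerprints** — per-seed tractography visitation maps
  (streamline counts per target voxel), aggregated across participants into
  group fingerprints;
* **functional profiles** — resting-state time series of each seed voxel.

## The model

Let $F \in \mathbb{R}_{\ge 0}^{n \times t}$ hold one nonnegative
connectivity profile per seed voxel. The similarity matrix is the cosine of
the angle between profiles,

$$ S_{ab} = \frac{\langle F_a, F_b\rangle}{\lVert F_a\rVert\,\lVert F_b\rVert}, $$

which lies in $[0, 1]$ for nonnegative fingerprints. For time series, whose
cosine can be negative, one is added to every entry (range $[0, 2]$),
preserving the ordering of relationships while meeting the positivity
assumption of the spectral step.

$S$ is treated as the weighted adjacency of a graph on the seeds. With the
degree matrix $D = \mathrm{diag}(S\mathbf{1})$ and the non-normalized graph
Laplacian $L = D - S$, the generalized eigenproblem

$$ L v = \lambda D v $$

yields eigenvalues $0 = \lambda_1 \le \lambda_2 \le \dots \le \lambda_n \le 2$.
The eigenvector of $\lambda_2$ (the Fiedler vector) is the one-dimensional
embedding that optimally separates dissimilar seeds; ranking its entries
reorders the matrix so that similar profiles become adjacent. The rank of
each seed, painted back into the volume, is the gradient map.

$\lambda_2$ itself is the **algebraic connectivity** of the graph and is the
package's gradation metric: it approaches 0 when the matrix consists of
strong blocks with weak links (hard clusters — a disconnected graph has
$\lambda_2 = 0$ exactly), and grows toward the top of the spectrum as the
transition becomes graded. It is a description, not a test statistic.
Because group-averaged matrices can be more graded than any individual's,
`gradation_per_participant()` reports the per-participant distribution
(mean, SD, quartiles) alongside the group value.

Numerically, the generalized problem is solved through the symmetric
normalized Laplacian $D^{-1/2} L D^{-1/2}$, which has the same spectrum;
eigenvectors are mapped back by $v = D^{-1/2}u$. The test suite checks this
route against an independent non-symmetric solve of $D^{-1}L$.

## Pipeline and parameters

### Seed ROI (structural branch)

Tractography is seeded on the gray/white-matter interface: white-matter
voxels with at least one non-white neighbor (`extract_gw_interface()`),
minus a dilated CSF mask, intersected with the anatomical ROI
(`build_seed_roi()`). Choices the literature leaves open, exposed as
arguments:

* **neighborhood connectivity** (default 6): the smallest neighborhood
  gives the most conservative (thinnest) interface; 18/26 are available.
* **out-of-volume neighbors count as non-white**, so volume faces can be
  interface — skull-stripped volumes have background there.
* **CSF dilation radius** (default 1 voxel).

Seeds are ordered lexicographically by voxel index; that order defines
matrix rows everywhere downstream. Voxel indices are 1-based in R; the
NIfTI affine maps the 0-based voxel frame, so mm coordinates and file I/O
match the usual convention.

### Visitation-map preparation

`prepare_native_map()` applies three stages: native-space thresholding that
keeps voxels reached by **more than** `native_threshold` streamlines
(default 5, strict `>`); block-mean downsampling by a factor of 2 per
dimension (the mean — rather than subsampling — preserves the count scale
the streamline threshold refers to; non-divisible dimensions are
zero-padded); binarization of block means at `>= binarize_threshold`
(default 5, inclusive). The differing comparators reflect the two distinct
thresholding rules in the source protocols; both are configurable.

`build_group_fingerprints()` matches each template seed to the nearest
participant seed in mm (ties averaged, making the result order-independent)
and averages binarized maps (`group_proportion`: the proportion of
participants showing the connection) or raw maps (`group_mean_counts`, used
for cluster connectivity maps).

### Functional branch

Per participant, the shifted cosine matrix of the raw (not demeaned) voxel
time series is computed; a `demean` flag turns the cosine into the Pearson
correlation. Group averaging standardizes each participant's off-diagonal
entries by moment standardization (subtract that matrix's off-diagonal
mean, divide by its SD), averages, and maps back using the mean of the
participant means and SDs. Moment standardization is used because Fisher's
r-to-z is undefined for shifted-cosine values at or above 1; it is the only
reading defined on $[0, 2]$. The shift happens before standardization,
following the listed order of the source protocol.

### Cluster extraction

Cluster extents on the reordered axis are an explicit user input
(`extract_cluster_range()`), mirroring the visual matrix inspection of the
original semi-automated approach but making it reproducible and logged.
`suggest_end_clusters()` is a deterministic aid: it grows a prefix and a
suffix while the range's mean similarity *and* each newly added seed's mean
similarity to the range exceed a quantile of the off-diagonal background.
The marginal condition is what stops growth at the edge of a coherent
block; a plain "largest range above background" rule cannot distinguish a
block from block-plus-background. Suggestions are advisory only.

Cluster connectivity maps average the member seeds' group-mean count maps
and floor the result at five streamlines (`cluster_structural_map()`); the
floor applies to the group-mean map, not per participant, because the map
reflects the group average number of streamlines.

### Resting-state QC

* `friston24_expand()`: the 24-parameter Volterra expansion
  $[p, p^2, p_{t-1}, p_{t-1}^2]$ of the six realignment parameters.
* `flag_artifact_timepoints()`: scrubbing at > 1 mm translation or global
  signal $|z| > 2.5$. "1 mm translation" is read as the *framewise* change
  (consecutive-volume difference, maximum over axes), the spike-detection
  semantics of the usual artifact tools; an `absolute` flag provides the
  other reading. Rotations play no role in the mm thresholds. The z
  criterion uses the global mean signal.
* `apply_exclusion_rules()`: exclude a run below 300 s of retained data
  (at TR 2.8 s that boundary falls between 107 and 108 retained volumes)
  or with any single translation above 3 mm.
* `regress_nuisance()`: OLS residualization against intercept, motion,
  spike indicators and tissue signals. Scrubbed timepoints are kept and
  regressed via spike indicators rather than deleted.

### Cluster-level inference

`group_cluster_stats()` computes one-sample (or participant-paired
difference) t-maps, forms clusters of voxels exceeding a two-sided
voxel-level threshold (default $p < 0.001$; positive and negative
excursions clustered separately), and controls family-wise error over
clusters by sign-flipping participant maps — exact under symmetric nulls
and free of parametric smoothness assumptions, replacing random-field
cluster correction. The between-cluster contrast is paired, since both
seed maps exist in every participant, and `mask_between_by_within()`
retains differential clusters only where the corresponding within-cluster
connectivity is itself significant.

The permutation statistic is the **cluster mass** (sum of suprathreshold
$|t|$ excess) by default, with the cluster size available via
`statistic = "size"`. Mass is preferred because at sparse voxel thresholds
the size statistic takes few distinct values, and the resulting p-value
granularity makes the test measurably conservative (empirical FWE near the
discreteness floor rather than the nominal level); the continuous mass
statistic calibrates tightly to the nominal 0.05. The calibration is part
of the acceptance suite: 200 null replicates of 20 smoothed unit-variance
Gaussian maps (sigma 1 voxel, emulating 8 mm FWHM smoothing on ~3 mm
voxels) must give empirical FWE in [0.03, 0.07], and a planted d = 1
spherical effect must be detected in > 90% of replicates.

## The synthetic world

`make_fingerprints()` and `make_timeseries()` plant a known one-dimensional
transition: seed $i$ mixes two endmember profiles with weight $w_i$.
The stated world is:

* endmembers: sparse nonnegative target patterns with ~45% support each
  and 10% shared support (distinct tract territories), cosine < 0.5;
* graded mode: $w_i = (i-1)/(n-1)$; clustered mode: a half/half step;
  intermediate: the ramp compressed into the central fraction `sharpness`
  of the axis;
* counts: Poisson with rate `lambda_scale` (default 50) times the mixture —
  count noise is inherent to streamline visitation maps;
* per-participant individual variation: Gaussian jitter of $w$
  (sd 0.05 by default, truncated to $[0,1]$);
* time series: two smoothed, standardized, orthogonalized network signals
  at TR 2.8 s, 130 volumes, plus Gaussian noise (sd 0.1);
* motion traces: slow random walk with planted single-volume spikes
  (1.5 mm) and optionally one 3.5 mm violation.

What a green test establishes: the pipeline recovers a planted ordering
(Spearman $|\rho| \ge 0.95$ at $n = 200$ under the stated noise), orders
$\lambda_2$ correctly across transition sharpness, and separates hard from
graded worlds in every replicate. What it does not establish: behavior
under realistic spatial autocorrelation of tractography errors,
registration misalignment, physiological noise structure, or any claim
about real cohorts — the generators emulate the *statistical* structure the
method assumes, not MRI physics.

## Numerical choices and degenerate inputs

* Eigenvector sign is arbitrary; it is canonicalized (lowest-index seed
  among the top decile of absolute Fiedler loadings gets a positive entry)
  so results are reproducible across linear-algebra backends. Analyses
  should still treat orientation as arbitrary; the tests use absolute
  correlations and allow global reversal.
* Fiedler ties are broken by original seed index (stable).
* A degenerate $\lambda_2$ (multiplicity > 1, e.g. a complete graph) makes
  the ordering backend-dependent; a message flags it. The $\lambda_2$
  value itself — the gradation metric — remains well-defined.
* Zero-degree seeds (all-zero similarity) are an error instructing removal;
  all-zero fingerprints or constant-zero series are dropped with a warning
  before the matrix is built.
* Similarity matrices are symmetrized ($\tfrac12(S + S^\top)$) and clamped
  to their theoretical range to absorb floating-point drift; symmetry is
  enforced to $10^{-10}$ at construction.
* The one-dimensional embedding is deliberate: higher eigenvectors are
  computed but not used for ordering, keeping the main transition
  interpretable. Fine-grained structure orthogonal to the principal
  gradient is out of scope.

## Known limitations

* NIfTI support is a minimal built-in NIfTI-1 reader/writer (no R NIfTI
  package is available in the supported dependency set): single-file
  `.nii`/`.nii.gz`, common datatypes, sform orientation. It is
  cross-checked against nibabel in the test suite but is not a
  general-purpose NIfTI library.
* Tractography, registration, segmentation, smoothing and slice-timing are
  upstream; the package consumes their outputs on a common grid.
* The cluster extents of any particular study's figures are a visual
  judgment; they are reproducible here only as explicit range inputs.
* Dense matrices only; the intended regime is $n$ of order $10^2$–$10^3$
  seed voxels.
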