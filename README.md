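# gradparc

Voxel-wise connectivity-gradient mapping and spectral parcellation of
cortical regions of interest, in R.

## The problem

Hard parcellations force every voxel into a cluster even where connectivity
changes gradually, obscuring both the core zones with genuinely distinct
connectivity and the graded transitions between them. `gradparc` instead
orders the voxels of a seed region by the similarity of their connectivity
profiles (structural tractography fingerprints or resting-state time
series), quantifies how graded the transition is, and extracts core
clusters only from the extremes of the ordering. It is aimed at
neuroimaging researchers doing connectivity-based parcellation who want the
full pattern of change, not just a hard split.

## The method

For seed profiles $F_a$ (rows of a nonnegative seeds-by-targets matrix),
the similarity matrix is the pairwise cosine
$S_{ab} = \langle F_a,F_b\rangle / (\lVert F_a\rVert \lVert F_b\rVert)$
(for time series, cosine + 1 so all entries are positive). With degree
matrix $D = \mathrm{diag}(S\mathbf 1)$ and non-normalized graph Laplacian
$L = D - S$, the generalized eigenproblem $Lv = \lambda Dv$ gives:

* the **Fiedler vector** (eigenvector of the second-smallest eigenvalue
  $\lambda_2$) — ranking its entries reorders the matrix so similar
  profiles become adjacent, and the rank back-projected into the volume is
  the gradient map;
* **$\lambda_2$, the algebraic connectivity** — the gradation metric:
  near 0 for block-structured (hard-clustered) similarity, larger for
  graded transitions.

Core clusters are taken from explicit rank ranges at the matrix ends,
their structural connectivity summarized as floored mean visitation maps,
and their functional connectivity compared with paired t-tests under
sign-flip permutation cluster-FWE correction. Resting-state QC (Friston-24
motion expansion, >1 mm / z>2.5 scrubbing, five-minute / 3 mm exclusion
rules, nuisance regression) and a synthetic phantom generator are included
so the entire pipeline is testable without MRI data.

## Worked example

```r
library(gradparc)
set.seed(7)

# a synthetic cohort with a graded transition planted along the seed axis
fp <- make_fingerprints(n_seeds = 120, n_targets = 200, n_participants = 20,
                        mode = "graded", jitter_sd = 0.1)

# group pipeline: native >5-streamline threshold, binarize, group proportions
parts <- lapply(fp$participants, function(p)
  list(roi = p$roi, maps = (p$values > 5) * 1))
gfp <- build_group_fingerprints(parts, fp$participants[[1]]$roi,
                                "group_proportion")

sim <- cosine_similarity_matrix(gfp)
res <- spectral_decompose(sim)
res
#> <reordering_result> n = 120, lambda2 = 0.972173

cor(fp$truth$w, res$permutation, method = "spearman")
#> [1] -0.9964095
```

(The sign of the ordering is arbitrary — the Fiedler vector's orientation
carries no meaning — so the magnitude is what matters.)

The printed `lambda2 = 0.972` is high on the 0-to-spectral-top scale, i.e.
the planted transition is correctly described as strongly graded rather
than hard-clustered, and the recovered matrix ranks track the planted
mixing weight almost perfectly (|Spearman rho| = 0.996). A hard-clustered world
gives a much smaller value:

```r
fc <- make_fingerprints(120, 200, 1, mode = "clustered")
spectral_decompose(cosine_similarity_matrix(fc$participants[[1]]))$lambda2
#> [1] 0.1114067
```

Core clusters from the two matrix ends:

```r
M <- reorder_matrix(sim, res)
suggest_end_clusters(M, min_size = 10, coherence_quantile = 0.5)
#>    label   a   b
#> 1 prefix   1  10
#> 2 suffix 111 120
ranks <- backproject_ranks(res, gfp$roi)   # gradient map volume
```

## Layout

* `R/` — implementation (ROI geometry, similarity, spectral, clusters,
  fMRI QC, synthetic generators, NIfTI I/O, CLI).
* `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles in `helper-oracles.R`.
* `vignettes/connectivity-gradients.Rmd` — the methods vignette: model,
  assumptions, parameter choices, synthetic world, limitations.
* `inst/cli/gradparc` — command-line entry point (`build-roi`, `reorder`,
  `gradation`, `make-phantom`).
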