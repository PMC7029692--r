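#' Synthetic phantoms for the connectivity-gradient pipeline
#'
#' The generators in this file produce data with the statistical structure
#' the analysis assumes -- two endmember connectivity patterns mixed along
#' a spatial axis with a graded, stepped, or intermediate transition --
#' so every pipeline stage can be tested end-to-end without MRI data.
#' They emulate structure, not biophysics: no diffusion or BOLD forward
#' model, and no spatial autocorrelation beyond explicit signal smoothing.
#'
#' @name synthetic_data
NULL

#' Planted ground truth for the synthetic generators
#'
#' The mixing weight `w` in `[0, 1]` of each seed sets its position along
#' the planted axis: seed profiles are `w * A + (1 - w) * B` for two
#' endmember patterns. `mode = "graded"` plants `w_i = (i-1)/(n-1)`
#' (a pure ramp); `"clustered"` plants a step (`w` in {0, 1}, half/half);
#' `"intermediate"` interpolates with `sharpness` in (0, 1]: the ramp is
#' compressed into the central fraction `sharpness` of the axis
#' (`sharpness -> 0` approaches the step, `1` is the full ramp).
#'
#' @param n_seeds number of seeds.
#' @param mode `"graded"`, `"clustered"` or `"intermediate"`.
#' @param sharpness transition width for `"intermediate"` (0 < s <= 1).
#' @return list with `w` (sorted along the axis) and `mode`.
#' @export
make_truth <- function(n_seeds, mode = c("graded", "clustered",
                                         "intermediate"),
                       sharpness = 1) {
  mode <- match.arg(mode)
  stopifnot(n_seeds >= 2L)
  x <- (seq_len(n_seeds) - 1) / (n_seeds - 1)
  w <- switch(mode,
              graded = x,
              clustered = as.numeric(x >= 0.5),
              intermediate = {
                stopifnot(sharpness > 0, sharpness <= 1)
                pmin(1, pmax(0, 0.5 + (x - 0.5) / sharpness))
              })
  list(w = w, mode = mode,
       sharpness = if (mode == "intermediate") sharpness else NA_real_)
}

#' Two endmember connectivity profiles
#'
#' Sparse, weakly overlapping nonnegative target patterns mimicking two
#' distinct tract territories: each endmember occupies ~45% of the target
#' space with 10% shared support; magnitudes are Gamma-distributed.
#' Cosine similarity between the endmembers is checked to be < 0.5.
#'
#' @param n_targets target-space size.
#' @param shared_fraction fraction of shared support (default 0.1).
#' @return list with nonnegative vectors `A`, `B`.
#' @export
make_endmembers <- function(n_targets, shared_fraction = 0.1) {
  stopifnot(n_targets >= 10L)
  nA <- round(0.45 * n_targets)
  nshare <- round(shared_fraction * n_targets / 2)
  A <- B <- numeric(n_targets)
  iA <- seq_len(nA)
  iB <- seq.int(n_targets - nA + 1L, n_targets)
  A[iA] <- stats::rgamma(nA, shape = 2, rate = 0.5)
  B[iB] <- stats::rgamma(nA, shape = 2, rate = 0.5)
  mid <- seq.int(nA + 1L, nA + nshare)
  A[mid] <- stats::rgamma(nshare, 2, 1)
  B[mid] <- stats::rgamma(nshare, 2, 1)
  cs <- sum(A * B) / sqrt(sum(A^2) * sum(B^2))
  if (cs >= 0.5) stop("endmember cosine similarity >= 0.5; widen supports")
  list(A = A, B = B)
}

#' Synthetic per-participant tractography fingerprints
#'
#' Participant p, seed i gets counts `~ Poisson(lambda_scale * (w_i A +
#' (1 - w_i) B))` elementwise, after per-participant Gaussian jitter of
#' `w` (sd `jitter_sd`, truncated to `[0, 1]`) representing individual
#' variation around the group axis. With `poisson = FALSE` and
#' `jitter_sd = 0` the noiseless expected profiles are returned.
#'
#' @param n_seeds,n_targets problem size.
#' @param n_participants number of participants.
#' @param mode,sharpness passed to [make_truth()].
#' @param lambda_scale expected count scale (default 50 streamlines at full
#'   weight, a typical retained visitation count after thresholding).
#' @param jitter_sd per-participant jitter of `w` (default 0.05).
#' @param poisson draw Poisson counts (default TRUE).
#' @param endmembers optional list(A, B) to reuse across conditions.
#' @return list with `participants` (list of [fingerprint_set()], kind
#'   `native_counts`), `truth` (w, mode, A, B).
#' @export
make_fingerprints <- function(n_seeds, n_targets, n_participants = 1L,
                              mode = "graded", sharpness = 1,
                              lambda_scale = 50, jitter_sd = 0.05,
                              poisson = TRUE, endmembers = NULL) {
  tr <- make_truth(n_seeds, mode, sharpness)
  em <- if (is.null(endmembers)) make_endmembers(n_targets) else endmembers
  grid <- volume_grid(c(n_seeds, 1L, 1L))
  roi <- seed_roi(grid, cbind(seq_len(n_seeds), 1L, 1L))
  parts <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    wp <- tr$w
    if (jitter_sd > 0)
      wp <- pmin(1, pmax(0, wp + stats::rnorm(n_seeds, 0, jitter_sd)))
    lam <- lambda_scale * (outer(wp, em$A) + outer(1 - wp, em$B))
    vals <- if (poisson)
      matrix(stats::rpois(length(lam), lam), n_seeds, n_targets)
    else lam
    parts[[p]] <- fingerprint_set(roi, vals, kind = "native_counts")
  }
  list(participants = parts,
       truth = c(tr, em))
}

#' Synthetic voxel time series mixing two network signals
#'
#' Two smoothed-Gaussian "network" signals `s_A`, `s_B` are generated per
#' participant (moving-average smoothed white noise, standardized, with
#' `s_B` orthogonalized against `s_A` so their correlation is ~0, well
#' under the < 0.2 requirement). Voxel i's series is
#' `w_i s_A + (1 - w_i) s_B + noise`.
#'
#' @param n_voxels,n_timepoints problem size (`n_timepoints >= 50`).
#' @param n_participants number of participants.
#' @param mode,sharpness passed to [make_truth()].
#' @param noise_sd Gaussian noise sd relative to the unit-variance signals
#'   (default 0.1).
#' @param tr_seconds repetition time (default 2.8 s).
#' @param smooth_window moving-average window for the network signals
#'   (default 5 volumes).
#' @return list with `participants` (list of [time_series_set()]),
#'   `truth`.
#' @export
make_timeseries <- function(n_voxels, n_timepoints, n_participants = 1L,
                            mode = "graded", sharpness = 1, noise_sd = 0.1,
                            tr_seconds = 2.8, smooth_window = 5L) {
  stopifnot(n_timepoints >= 50L)
  tr <- make_truth(n_voxels, mode, sharpness)
  grid <- volume_grid(c(n_voxels, 1L, 1L))
  roi <- seed_roi(grid, cbind(seq_len(n_voxels), 1L, 1L))
  smooth1d <- function(x, k) {
    as.vector(stats::filter(x, rep(1 / k, k), sides = 2L, circular = TRUE))
  }
  std <- function(x) (x - mean(x)) / stats::sd(x)
  parts <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    sA <- std(smooth1d(stats::rnorm(n_timepoints), smooth_window))
    sB <- std(smooth1d(stats::rnorm(n_timepoints), smooth_window))
    sB <- std(sB - sA * sum(sA * sB) / sum(sA^2))   # orthogonalize
    S <- outer(tr$w, sA) + outer(1 - tr$w, sB)
    if (noise_sd > 0)
      S <- S + matrix(stats::rnorm(length(S), 0, noise_sd),
                      n_voxels, n_timepoints)
    parts[[p]] <- time_series_set(roi, S, tr_seconds)
  }
  list(participants = parts, truth = tr)
}

#' Phantom tissue segmentation
#'
#' Deterministic nested phantom for the ROI-geometry stage: an ellipsoidal
#' white-matter core, a two-voxel gray-matter shell around it, CSF pockets
#' scattered on the outside of the shell, and a half-volume anatomical ROI
#' box. The three tissue masks are disjoint by construction.
#'
#' @param shape grid shape, each dimension >= 8.
#' @param n_csf_pockets number of CSF pocket seeds (default 6).
#' @return list of [binary_mask()]: `gm`, `wm`, `csf`, `roi`, plus `grid`.
#' @export
make_phantom_segmentation <- function(shape = c(16L, 16L, 16L),
                                      n_csf_pockets = 6L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("phantom shape must be 3 dimensions, each >= 8")
  grid <- volume_grid(shape)
  ctr <- (shape + 1) / 2
  rad <- shape / 4
  idx <- as.matrix(expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                               k = seq_len(shape[3])))
  r2 <- ((idx[, 1] - ctr[1]) / rad[1])^2 + ((idx[, 2] - ctr[2]) / rad[2])^2 +
    ((idx[, 3] - ctr[3]) / rad[3])^2
  wm <- binary_mask(grid, array(r2 <= 1, shape))
  shell <- dilate_mask(wm, 2L, 26L)
  gm <- binary_mask(grid, shell$values & !wm$values)
  outside <- dilate_mask(shell, 1L, 6L)$values & !shell$values
  cand <- which(outside)
  csf_v <- array(FALSE, shape)
  if (length(cand) && n_csf_pockets > 0L) {
    pick <- cand[sample.int(length(cand), min(n_csf_pockets, length(cand)))]
    seedv <- array(FALSE, shape); seedv[pick] <- TRUE
    pockets <- dilate_mask(binary_mask(grid, seedv), 1L, 6L)$values
    csf_v <- pockets & !shell$values
  }
  csf <- binary_mask(grid, csf_v)
  roi_v <- array(FALSE, shape)
  roi_v[seq_len(ceiling(shape[1] / 2)), , ] <- TRUE
  list(gm = gm, wm = wm, csf = csf,
       roi = binary_mask(grid, roi_v), grid = grid)
}

#' Synthetic motion trace with planted artifact spikes
#'
#' A slow random-walk baseline (sd 0.02 mm / 0.02 deg per step) with
#' `n_spikes` single-volume translation displacements of `spike_mm`
#' (default 1.5 mm, exceeding the 1 mm framewise scrubbing threshold) and
#' optionally one sustained-for-one-volume displacement of `violation_mm`
#' (default 3.5 mm, exceeding the 3 mm exclusion limit).
#'
#' @param n_timepoints run length.
#' @param n_spikes number of planted > 1 mm spikes (default 0).
#' @param spike_mm spike amplitude (default 1.5).
#' @param violation planted > 3 mm single translation (default FALSE).
#' @param violation_mm amplitude of the violation (default 3.5).
#' @return list with `mp` (timepoints x 6 matrix) and `spike_times`.
#' @export
make_motion_trace <- function(n_timepoints, n_spikes = 0L, spike_mm = 1.5,
                              violation = FALSE, violation_mm = 3.5) {
  mp <- apply(matrix(stats::rnorm(n_timepoints * 6, 0, 0.02),
                     n_timepoints, 6L), 2L, cumsum)
  mp <- sweep(mp, 2L, mp[1L, ])               # start at zero
  avail <- 3:(n_timepoints - 1L)
  times <- integer(0)
  if (n_spikes > 0L) {
    times <- sort(sample(avail, n_spikes))
    for (t in times) {
      ax <- sample(1:3, 1L)
      mp[t, ax] <- mp[t, ax] + spike_mm * sample(c(-1, 1), 1L)
    }
  }
  if (violation) {
    tv <- sample(setdiff(avail, times), 1L)
    mp[tv, 1L] <- mp[tv, 1L] + violation_mm
    times <- sort(c(times, tv))
  }
  list(mp = mp, spike_times = times)
}

#' Smoothed unit-variance Gaussian random map
#'
#' White Gaussian noise smoothed with a separable (truncated) Gaussian
#' kernel and rescaled so every voxel has exactly unit variance, including
#' at the edges. Used to emulate the spatial smoothness of preprocessed
#' fMRI statistic maps (an 8 mm FWHM kernel on ~3 mm voxels corresponds to
#' sigma of roughly one voxel) in the permutation-inference calibration.
#'
#' @param dims 3D grid dimensions.
#' @param sigma_voxels Gaussian sigma in voxels (default 1).
#' @return 3D array with unit marginal variance per voxel.
#' @export
make_smooth_noise_map <- function(dims, sigma_voxels = 1) {
  x <- array(stats::rnorm(prod(dims)), dims)
  if (sigma_voxels <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma_voxels))
  k <- stats::dnorm(seq.int(-half, half), sd = sigma_voxels)
  conv_axis <- function(a, axis) {
    d <- dim(a)
    out <- array(0, d)
    for (s in seq_along(k)) {
      off <- integer(3); off[axis] <- s - half - 1L
      out <- out + k[s] * shift_array(a, off, fill = 0)
    }
    out
  }
  vfac_axis <- function(nlen) {
    # per-position sum of squared (truncated) kernel weights along one axis
    v <- numeric(nlen)
    for (pos in seq_len(nlen)) {
      js <- seq.int(-half, half)
      ok <- pos + js >= 1L & pos + js <= nlen
      v[pos] <- sum(k[ok]^2)
    }
    v
  }
  sm <- conv_axis(conv_axis(conv_axis(x, 1L), 2L), 3L)
  v1 <- vfac_axis(dims[1]); v2 <- vfac_axis(dims[2]); v3 <- vfac_axis(dims[3])
  sdmap <- sqrt(outer(outer(v1, v2), v3))
  sm / sdmap
}

#' Full synthetic fixture bundle
#'
#' One self-consistent dataset: a phantom segmentation with its gray/white
#' interface seed ROI, per-participant fingerprints and time series on the
#' planted transition, motion traces with planted spikes (and optionally
#' one > 3 mm violation in the first participant), and a manifest. With
#' `dir` set, NIfTI volumes, 6-column motion text files and a TSV manifest
#' are written.
#'
#' @param n_participants number of participants (default 20, a typical
#'   diffusion-cohort size).
#' @param n_seeds,n_targets fingerprint size (defaults 60 x 120).
#' @param n_timepoints functional run length (default 130 volumes).
#' @param mode,sharpness planted transition (see [make_truth()]).
#' @param n_spikes motion spikes per participant (default 2).
#' @param plant_violation plant one > 3 mm translation in participant 1.
#' @param noise_sd,jitter_sd noise levels (defaults 0.1 / 0.05).
#' @param dir optional output directory for files.
#' @return list with `segmentation`, `seeds` ([seed_roi()]),
#'   `fingerprints`, `timeseries`, `motion` (list of traces), `manifest`
#'   (data.frame).
#' @export
make_group_dataset <- function(n_participants = 20L, n_seeds = 60L,
                               n_targets = 120L, n_timepoints = 130L,
                               mode = "graded", sharpness = 1,
                               n_spikes = 2L, plant_violation = FALSE,
                               noise_sd = 0.1, jitter_sd = 0.05,
                               dir = NULL) {
  stopifnot(n_participants >= 1L)
  seg <- make_phantom_segmentation()
  iface <- extract_gw_interface(seg$wm, seg$csf)
  seeds <- build_seed_roi(seg$roi, iface)
  fps <- make_fingerprints(n_seeds, n_targets, n_participants, mode,
                           sharpness, jitter_sd = jitter_sd)
  tss <- make_timeseries(n_seeds, n_timepoints, n_participants, mode,
                         sharpness, noise_sd = noise_sd)
  motion <- lapply(seq_len(n_participants), function(p)
    make_motion_trace(n_timepoints, n_spikes = n_spikes,
                      violation = plant_violation && p == 1L))
  manifest <- data.frame(
    participant = seq_len(n_participants),
    n_seeds = n_seeds,
    n_spikes = vapply(motion, function(m) length(m$spike_times), 0L),
    spike_times = vapply(motion, function(m)
      paste(m$spike_times, collapse = ","), ""),
    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_nifti(seg$wm, file.path(dir, "wm.nii.gz"))
    write_nifti(seg$gm, file.path(dir, "gm.nii.gz"))
    write_nifti(seg$csf, file.path(dir, "csf.nii.gz"))
    write_nifti(seg$roi, file.path(dir, "roi.nii.gz"))
    sv <- array(FALSE, seg$grid$shape); sv[seeds$voxels] <- TRUE
    write_nifti(binary_mask(seg$grid, sv), file.path(dir, "seeds.nii.gz"))
    wt <- function(x, f) utils::write.table(
      format(x, digits = 8), file.path(dir, f),
      row.names = FALSE, col.names = FALSE, quote = FALSE)
    for (p in seq_len(n_participants)) {
      manifest$motion_file[p] <- sprintf("motion_%02d.txt", p)
      manifest$fingerprint_file[p] <- sprintf("fingerprints_%02d.tsv", p)
      manifest$timeseries_file[p] <- sprintf("timeseries_%02d.tsv", p)
      wt(motion[[p]]$mp, manifest$motion_file[p])
      wt(fps$participants[[p]]$values, manifest$fingerprint_file[p])
      wt(tss$participants[[p]]$series, manifest$timeseries_file[p])
    }
    manifest$segmentation_files <-
      "wm.nii.gz;gm.nii.gz;csf.nii.gz;roi.nii.gz;seeds.nii.gz"
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(segmentation = seg, seeds = seeds, fingerprints = fps,
       timeseries = tss, motion = motion, manifest = manifest)
}
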