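#' Friston-24 Volterra expansion of motion parameters
#'
#' Expands the six rigid-body realignment parameters into the 24-regressor
#' motion model: the parameters, their squares, their one-volume lags, and
#' the squared lags. Lagged rows at the first timepoint are zero.
#'
#' @param mp timepoints x 6 numeric matrix (3 translations in mm, 3
#'   rotations in degrees).
#' @return timepoints x 24 matrix, columns ordered
#'   `p1..p6, p1^2..p6^2, lag(p1)..lag(p6), lag(p1)^2..lag(p6)^2`.
#' @export
friston24_expand <- function(mp) {
  mp <- as.matrix(mp)
  if (ncol(mp) != 6L)
    stop("motion parameters must have 6 columns, got ", ncol(mp))
  if (nrow(mp) < 2L) stop("need at least 2 timepoints")
  if (any(!is.finite(mp))) stop("motion parameters contain non-finite values")
  lag <- rbind(0, mp[-nrow(mp), , drop = FALSE])
  out <- cbind(mp, mp^2, lag, lag^2)
  colnames(out) <- c(paste0("p", 1:6), paste0("p", 1:6, "_sq"),
                     paste0("p", 1:6, "_lag"), paste0("p", 1:6, "_lagsq"))
  out
}

#' Flag high-motion / signal-deviant timepoints (scrubbing)
#'
#' A timepoint is flagged as artifact when its framewise translation change
#' (consecutive-volume difference, maximum over the three axes) exceeds
#' `trans_mm`, or when the global signal deviates from its mean by more
#' than `z_thresh` standard deviations. `absolute = TRUE` switches the
#' translation criterion to the absolute displacement instead of the
#' framewise change.
#'
#' @param mp timepoints x 6 motion matrix (translations in columns 1-3, mm).
#' @param global_signal numeric vector, mean in-brain signal per timepoint.
#' @param trans_mm translation threshold in mm (default 1).
#' @param z_thresh global-signal z threshold (default 2.5).
#' @param absolute use absolute translation rather than framewise change.
#' @return logical censor vector (TRUE = artifact).
#' @export
flag_artifact_timepoints <- function(mp, global_signal, trans_mm = 1.0,
                                     z_thresh = 2.5, absolute = FALSE) {
  mp <- as.matrix(mp)
  if (nrow(mp) != length(global_signal))
    stop("motion rows (", nrow(mp), ") != global signal length (",
         length(global_signal), ")")
  trans <- mp[, 1:3, drop = FALSE]
  if (absolute) {
    fd <- apply(abs(trans), 1L, max)
  } else {
    d <- abs(diff(trans))
    fd <- c(0, apply(d, 1L, max))
  }
  s <- stats::sd(global_signal)
  z <- if (is.finite(s) && s > 0) (global_signal - mean(global_signal)) / s
       else rep(0, length(global_signal))
  fd > trans_mm | abs(z) > z_thresh
}

#' Participant-level exclusion rules
#'
#' A run is excluded when fewer than `min_seconds` of data survive
#' scrubbing (unflagged timepoints times TR), or when any single absolute
#' translation exceeds `max_single_translation_mm`.
#'
#' @param censor logical censor vector from [flag_artifact_timepoints()].
#' @param tr_seconds repetition time in seconds.
#' @param mp timepoints x 6 motion matrix.
#' @param min_seconds minimum retained data (default 300 s = five minutes).
#' @param max_single_translation_mm hard translation limit (default 3 mm).
#' @return list with `keep` (logical), `retained_seconds`, `reasons`
#'   (character vector, empty when kept).
#' @export
apply_exclusion_rules <- function(censor, tr_seconds, mp, min_seconds = 300,
                                  max_single_translation_mm = 3) {
  mp <- as.matrix(mp)
  if (length(censor) != nrow(mp))
    stop("censor length != motion rows")
  retained <- sum(!censor) * tr_seconds
  reasons <- character(0)
  if (retained < min_seconds)
    reasons <- c(reasons, sprintf("retained %.1f s < %g s", retained,
                                  min_seconds))
  if (any(abs(mp[, 1:3]) > max_single_translation_mm))
    reasons <- c(reasons, sprintf("single translation > %g mm",
                                  max_single_translation_mm))
  list(keep = length(reasons) == 0L, retained_seconds = retained,
       reasons = reasons)
}

#' Regress nuisance covariates out of voxel time series
#'
#' Ordinary-least-squares residualization of every voxel's series against a
#' nuisance design (typically intercept, 24 motion regressors, spike
#' indicators for scrubbed timepoints, and white-matter/CSF/global
#' signals). Scrubbed timepoints are regressed via their spike indicators,
#' not deleted. Residuals are orthogonal to every design column.
#'
#' @param ts a [time_series_set()].
#' @param regressors timepoints x p design matrix. All-zero columns are
#'   dropped (constant spike columns for runs without spikes).
#' @return [time_series_set()] of residuals.
#' @export
regress_nuisance <- function(ts, regressors) {
  stopifnot(inherits(ts, "time_series_set"))
  X <- as.matrix(regressors)
  if (nrow(X) != ncol(ts$series))
    stop("design rows (", nrow(X), ") != timepoints (", ncol(ts$series), ")")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  zero <- colSums(X != 0) == 0L
  if (any(zero)) X <- X[, !zero, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("nuisance design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  Y <- t(ts$series)
  R <- qr.resid(qrX, Y)
  time_series_set(ts$roi, t(R), ts$tr_seconds, ts$censor)
}

#' Seed-based functional connectivity map (Fisher z)
#'
#' Correlates the mean time series of a cluster ROI with every brain voxel
#' and Fisher-z transforms the correlations (`atanh`, with `|r|` clipped to
#' `1 - 1e-7`). Constant voxel series get `z = 0` and are flagged in the
#' `"constant_voxels"` attribute.
#'
#' @param brain_ts 4D array (x, y, z, t) of cleaned series.
#' @param cluster_mask [binary_mask()] (or logical array) of the seed
#'   cluster; must be nonempty.
#' @return 3D array of Fisher-z values.
#' @export
seed_connectivity_map <- function(brain_ts, cluster_mask) {
  dm <- dim(brain_ts)
  if (length(dm) != 4L) stop("`brain_ts` must be a 4D array")
  mvals <- if (inherits(cluster_mask, "binary_mask")) cluster_mask$values
           else cluster_mask
  if (!identical(dim(mvals), dm[1:3])) stop("mask does not match brain grid")
  if (!any(mvals)) stop("cluster mask is empty")
  V <- prod(dm[1:3]); Tt <- dm[4L]
  m <- matrix(brain_ts, V, Tt)
  seed <- colMeans(m[as.vector(mvals), , drop = FALSE])
  mc <- m - rowMeans(m)
  sc <- seed - mean(seed)
  den <- sqrt(rowSums(mc^2) * sum(sc^2))
  r <- as.vector(mc %*% sc) / den
  const <- !is.finite(r)
  r[const] <- 0
  r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  z <- atanh(r)
  z[const] <- 0
  out <- array(z, dm[1:3])
  attr(out, "constant_voxels") <- which(const)
  out
}

# clusters of suprathreshold voxels of a signed t map; positive and
# negative excursions are clustered separately so opposite effects never
# merge.
.tmap_clusters <- function(tv, dims, tcrit, connectivity = 6L) {
  out <- list()
  for (sgn in c(1, -1)) {
    idx <- which(sgn * tv > tcrit)
    if (!length(idx)) next
    coords <- arrayInd(idx, dims)
    lab <- connected_components(coords, dims, connectivity)
    for (l in seq_len(max(lab))) {
      vox <- idx[lab == l]
      out[[length(out) + 1L]] <- list(sign = sgn, voxels = vox,
                                      size = length(vox),
                                      mass = sum(sgn * tv[vox] - tcrit))
    }
  }
  out
}

# maximum cluster statistic of a signed t map: "size" = voxel count,
# "mass" = summed suprathreshold excess |t| - tcrit.
.max_cluster_stat <- function(tv, dims, tcrit, connectivity = 6L,
                              statistic = "mass") {
  mx <- 0
  for (sgn in c(1, -1)) {
    idx <- which(sgn * tv > tcrit)
    if (!length(idx)) next
    coords <- arrayInd(idx, dims)
    lab <- connected_components(coords, dims, connectivity)
    val <- if (statistic == "size") tabulate(lab)
           else tapply(sgn * tv[idx] - tcrit, lab, sum)
    mx <- max(mx, val)
  }
  mx
}

#' Group-level cluster statistics with sign-flip permutation FWE
#'
#' One-sample t-test per voxel on participant z-maps (`method =
#' "one_sample"`), or on paired differences `A - B` (`method =
#' "paired_difference"`) to contrast connectivity of two seed clusters
#' within participants. Voxels exceeding the two-sided `voxel_p` threshold
#' are grouped into connected clusters (positive and negative excursions
#' separately); family-wise error over clusters is controlled by sign-flip
#' permutation of participant maps with a maximum-cluster-statistic null,
#' which is exact for symmetric null distributions and replaces parametric
#' random-field correction. The default statistic is the cluster mass
#' (summed suprathreshold excess `|t| - t_crit`); the cluster size is
#' available via `statistic = "size"` but, being heavily discrete at
#' sparse voxel thresholds, makes the test conservative.
#'
#' @param mapsA list of per-participant 3D z-maps (equal dims).
#' @param mapsB optional list for the paired contrast; must pair with
#'   `mapsA` one participant to one participant.
#' @param voxel_p two-sided cluster-forming voxel p (default 0.001).
#' @param cluster_alpha cluster-level FWE alpha (default 0.05).
#' @param n_perm number of sign-flip permutations (default 1000).
#' @param connectivity spatial connectivity for clustering (default 6).
#' @param statistic cluster-level statistic for the permutation null:
#'   `"mass"` (default) or `"size"`.
#' @return Object of class `stat_map`: `t` (3D array), `df`,
#'   `voxel_p`, `t_crit`, `clusters` (data.frame: sign, size, mass, p),
#'   `cluster_sig_mask` (3D logical), `method`, `n_perm`, `statistic`,
#'   `null_max` (permutation null of the chosen statistic).
#' @export
group_cluster_stats <- function(mapsA, mapsB = NULL, voxel_p = 0.001,
                                cluster_alpha = 0.05, n_perm = 1000L,
                                connectivity = 6L,
                                statistic = c("mass", "size")) {
  statistic <- match.arg(statistic)
  stopifnot(length(mapsA) >= 2L)
  dims <- dim(mapsA[[1L]])
  method <- "one_sample"
  X <- t(vapply(mapsA, as.vector, numeric(prod(dims))))
  if (!is.null(mapsB)) {
    if (length(mapsB) != length(mapsA))
      stop("paired test needs equal participant sets (",
           length(mapsA), " vs ", length(mapsB), ")")
    X <- X - t(vapply(mapsB, as.vector, numeric(prod(dims))))
    method <- "paired_difference"
  }
  n <- nrow(X); V <- ncol(X)
  df <- n - 1L
  tcrit <- stats::qt(1 - voxel_p / 2, df)
  tstat <- function(M, ssq) {
    mu <- colMeans(M)
    v <- (ssq - n * mu^2) / df
    v[v < 1e-300] <- 1e-300
    mu / sqrt(v / n)
  }
  ssq <- colSums(X^2)
  tv <- tstat(X, ssq)
  obs <- .tmap_clusters(tv, dims, tcrit, connectivity)
  S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  M <- S %*% X
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    mu <- M[b, ] / n
    v <- (ssq - n * mu^2) / df
    v[v < 1e-300] <- 1e-300
    tp <- mu / sqrt(v / n)
    null_max[b] <- .max_cluster_stat(tp, dims, tcrit, connectivity, statistic)
  }
  sig <- array(FALSE, dims)
  if (length(obs)) {
    pvals <- vapply(obs, function(cl)
      (1 + sum(null_max >= cl[[statistic]])) / (n_perm + 1), numeric(1))
    for (i in seq_along(obs))
      if (pvals[i] <= cluster_alpha) sig[obs[[i]]$voxels] <- TRUE
    clusters <- data.frame(sign = vapply(obs, `[[`, 0, "sign"),
                           size = vapply(obs, `[[`, 0L, "size"),
                           mass = vapply(obs, `[[`, 0, "mass"),
                           p = pvals)
  } else {
    clusters <- data.frame(sign = numeric(0), size = integer(0),
                           mass = numeric(0), p = numeric(0))
  }
  structure(list(t = array(tv, dims), df = df, voxel_p = voxel_p,
                 t_crit = tcrit, clusters = clusters,
                 cluster_sig_mask = sig, method = method,
                 n_perm = n_perm, statistic = statistic,
                 null_max = null_max),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> ", x$method, ", df = ", x$df, ", ",
      nrow(x$clusters), " cluster(s), ",
      sum(x$clusters$p <= 0.05), " significant at FWE 0.05\n", sep = "")
  invisible(x)
}

#' Mask a between-cluster contrast by the within-cluster results
#'
#' Retains between-test clusters only where the corresponding within-test
#' map is significant: positive (A > B) voxels must be significant in the
#' within-A map, negative in the within-B map. This identifies regions that
#' are both strongly connected to a cluster and differentially connected
#' between the two clusters.
#'
#' @param between a paired-difference [group_cluster_stats()] result
#'   (positive t = A > B).
#' @param withinA,withinB one-sample [group_cluster_stats()] results for
#'   the two clusters.
#' @return 3D t-value array masked to the surviving voxels (0 elsewhere),
#'   with the logical mask in attribute `"mask"`.
#' @export
mask_between_by_within <- function(between, withinA, withinB) {
  stopifnot(inherits(between, "stat_map"), inherits(withinA, "stat_map"),
            inherits(withinB, "stat_map"))
  keep <- between$cluster_sig_mask &
    ((between$t > 0 & withinA$cluster_sig_mask) |
     (between$t < 0 & withinB$cluster_sig_mask))
  out <- between$t
  out[!keep] <- 0
  attr(out, "mask") <- keep
  out
}
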