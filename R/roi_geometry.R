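#' Extract the gray/white-matter interface
#'
#' The interface is the set of white-matter voxels that border non-white
#' tissue: tractography is seeded there because tracking within gray matter
#' is unreliable (isotropic diffusion) while deep white-matter seeds may
#' pass under the cortex without connecting to it. Voxels falling inside a
#' dilated CSF mask are removed so the interface hugs the gray/white
#' boundary rather than the ventricular/sulcal edge of the white matter.
#'
#' Out-of-volume neighbors count as non-white, so white voxels on the
#' volume face are part of the interface (skull-stripped volumes have
#' background there).
#'
#' @param white white-matter [binary_mask()].
#' @param csf CSF [binary_mask()] on the same grid.
#' @param dilation_radius_voxels CSF dilation radius in voxels (default 1).
#' @param connectivity neighborhood for "neighbours": 6 (default,
#'   most conservative interface), 18 or 26.
#' @return [binary_mask()] of interface voxels.
#' @export
extract_gw_interface <- function(white, csf, dilation_radius_voxels = 1L,
                                 connectivity = 6L) {
  stopifnot(inherits(white, "binary_mask"), inherits(csf, "binary_mask"))
  if (!same_grid(white$grid, csf$grid))
    stop("grid mismatch: white is ", paste(white$grid$shape, collapse = "x"),
         ", csf is ", paste(csf$grid$shape, collapse = "x"),
         " (or affines differ)")
  if (!any(white$values)) {
    warning("white-matter mask is empty; interface is empty")
    return(binary_mask(white$grid, array(FALSE, white$grid$shape)))
  }
  offs <- neighbor_offsets(connectivity)
  w <- white$values
  has_nonwhite_nb <- array(FALSE, dim(w))
  for (o in seq_len(nrow(offs))) {
    # neighbor at x + off is non-white; out-of-volume fill counts non-white
    nb_white <- shift_array(w, -offs[o, ], fill = FALSE)
    has_nonwhite_nb <- has_nonwhite_nb | !nb_white
  }
  iface <- w & has_nonwhite_nb
  if (dilation_radius_voxels > 0L && any(csf$values)) {
    csf_d <- dilate_mask(csf, dilation_radius_voxels, connectivity)
    iface <- iface & !csf_d$values
  } else if (dilation_radius_voxels == 0L) {
    iface <- iface & !csf$values
  }
  binary_mask(white$grid, iface)
}

#' Build the seed ROI from a region mask and the gray/white interface
#'
#' Intersects an anatomical ROI mask with the interface mask and fixes the
#' downstream matrix order (lexicographic by voxel index).
#'
#' @param roi_mask anatomical region [binary_mask()].
#' @param interface interface [binary_mask()] from [extract_gw_interface()].
#' @return A [seed_roi()].
#' @export
build_seed_roi <- function(roi_mask, interface) {
  stopifnot(inherits(roi_mask, "binary_mask"), inherits(interface, "binary_mask"))
  if (!same_grid(roi_mask$grid, interface$grid))
    stop("grid mismatch between roi_mask and interface")
  both <- roi_mask$values & interface$values
  if (!any(both))
    stop("ROI mask and interface do not intersect; seed ROI would be empty")
  seed_roi(roi_mask$grid, which(both, arr.ind = TRUE))
}

#' Prepare a native-space tractography visitation map
#'
#' Three-stage post-processing of a per-seed streamline-count volume:
#' (1) remove voxels reached by no more than `native_threshold` streamlines
#' (strict `>` retention, so a count equal to the threshold is dropped);
#' (2) downsample by block-averaging `downsample_factor`^3 blocks (the block
#' mean keeps the streamline-count scale that the threshold refers to);
#' (3) binarize block means at `>= binarize_threshold`.
#'
#' @param counts nonnegative 3D numeric array of streamline counts.
#' @param native_threshold stage-1 count threshold (default 5; strict `>`).
#' @param downsample_factor integer edge shrink factor (default 2). Volumes
#'   whose dimensions are not divisible by the factor are zero-padded (a
#'   message is logged).
#' @param binarize_threshold stage-3 threshold on block means (default 5;
#'   inclusive `>=`).
#' @return binary (0/1 numeric) downsampled 3D array.
#' @export
prepare_native_map <- function(counts, native_threshold = 5L,
                               downsample_factor = 2L,
                               binarize_threshold = 5) {
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("`counts` must be a 3D array")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("`counts` must be finite and nonnegative")
  f <- as.integer(downsample_factor)
  stopifnot(f >= 1L)
  x <- counts
  x[x <= native_threshold] <- 0          # stage 1: strict > retention
  dm <- dim(x)
  pad <- (f - dm %% f) %% f
  if (any(pad > 0L)) {
    message("prepare_native_map: padding volume ",
            paste(dm, collapse = "x"), " with zeros to ",
            paste(dm + pad, collapse = "x"))
    y <- array(0, dm + pad)
    y[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- x
    x <- y
    dm <- dim(x)
  }
  nb <- dm %/% f
  # stage 2: block mean via the (f, n1, f, n2, f, n3) reshape
  blk <- array(x, dim = c(f, nb[1], f, nb[2], f, nb[3]))
  bm <- apply(blk, c(2, 4, 6), mean)
  # stage 3
  (bm >= binarize_threshold) * 1
}

#' Aggregate per-participant seed maps into group fingerprints
#'
#' Each participant provides one prepared map per seed voxel of their own
#' ROI. Every template seed is matched to that participant's nearest seed by
#' Euclidean mm distance (ties averaged); participants' matched maps are then
#' averaged across the group. `group_proportion` averages binarized maps
#' (values > 0), yielding for each target the proportion of participants in
#' whom the connection was identified; `group_mean_counts` averages the raw
#' (non-binarized) maps.
#'
#' @param per_participant list; each element a list with fields `roi`
#'   (a [seed_roi()]) and `maps` (seeds x targets matrix, row order =
#'   that ROI's voxel order).
#' @param template the group-template [seed_roi()] defining output row order.
#' @param mode `"group_proportion"` or `"group_mean_counts"`.
#' @param max_distance_mm template seeds with no participant seed within
#'   this distance are excluded (flagged in a message). Default `Inf`.
#' @return A [fingerprint_set()] with `kind = mode`.
#' @export
build_group_fingerprints <- function(per_participant, template,
                                     mode = c("group_proportion",
                                              "group_mean_counts"),
                                     max_distance_mm = Inf) {
  mode <- match.arg(mode)
  stopifnot(inherits(template, "seed_roi"), length(per_participant) >= 1L)
  tmm <- voxel_to_mm(template$grid, template$voxels)
  n <- template$n
  nt <- ncol(per_participant[[1L]]$maps)
  acc <- matrix(0, n, nt)
  got <- matrix(TRUE, n, length(per_participant))
  for (p in seq_along(per_participant)) {
    part <- per_participant[[p]]
    stopifnot(inherits(part$roi, "seed_roi"))
    if (nrow(part$maps) != part$roi$n)
      stop("participant ", p, ": map rows != ROI size")
    pmm <- voxel_to_mm(part$roi$grid, part$roi$voxels)
    d2 <- outer(rowSums(tmm^2), rowSums(pmm^2), `+`) - 2 * tmm %*% t(pmm)
    d2[d2 < 0] <- 0
    rows <- matrix(0, n, nt)
    for (i in seq_len(n)) {
      di <- d2[i, ]
      dmin <- min(di)
      if (sqrt(dmin) > max_distance_mm) {
        got[i, p] <- FALSE
        next
      }
      hit <- which(di <= dmin + 1e-9)    # tied nearest seeds are averaged
      m <- colMeans(part$maps[hit, , drop = FALSE])
      rows[i, ] <- if (mode == "group_proportion") as.numeric(m > 0) else m
    }
    acc <- acc + rows
  }
  keep <- rowSums(got) == length(per_participant)
  if (!all(keep))
    message("build_group_fingerprints: excluding ", sum(!keep),
            " template seed(s) with no participant seed within ",
            max_distance_mm, " mm")
  if (!any(keep)) stop("no template seed could be matched in all participants")
  values <- acc[keep, , drop = FALSE] / length(per_participant)
  roi <- seed_roi(template$grid, template$voxels[keep, , drop = FALSE])
  fingerprint_set(roi, values, kind = mode)
}

#' Connectivity fingerprint container
#'
#' Seeds x targets nonnegative connectivity profiles. `kind` records the
#' construction recipe: raw per-participant streamline counts
#' (`native_counts`), the group proportion-of-participants map
#' (`group_proportion`, values in `[0, 1]`) or the group mean count map
#' (`group_mean_counts`).
#'
#' @param roi a [seed_roi()]; its voxel order is the row order.
#' @param values seeds x targets nonnegative matrix.
#' @param kind one of `"native_counts"`, `"group_proportion"`,
#'   `"group_mean_counts"`.
#' @param target_grid optional [volume_grid()] of the (possibly downsampled)
#'   target space, enabling volumization of rows; targets are then the
#'   flattened voxels of that grid in array order.
#' @return Object of class `fingerprint_set`.
#' @export
fingerprint_set <- function(roi, values,
                            kind = c("native_counts", "group_proportion",
                                     "group_mean_counts"),
                            target_grid = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(roi, "seed_roi"))
  values <- as.matrix(values)
  if (nrow(values) != roi$n)
    stop("fingerprint rows (", nrow(values), ") != ROI size (", roi$n, ")")
  if (any(!is.finite(values)) || any(values < 0))
    stop("fingerprint values must be finite and nonnegative")
  if (kind == "group_proportion" && any(values > 1 + 1e-12))
    stop("group_proportion values must be <= 1")
  structure(list(roi = roi, values = values, kind = kind,
                 target_grid = target_grid),
            class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat("<fingerprint_set> ", nrow(x$values), " seeds x ", ncol(x$values),
      " targets (", x$kind, ")\n", sep = "")
  invisible(x)
}
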