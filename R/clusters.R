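#' Extract hard clusters from ranges of the reordered matrix
#'
#' The two ends of the spectrally reordered matrix hold the seeds whose
#' connectivity profiles are most distinct from each other; contiguous
#' ranges at those ends define "core" hard clusters, leaving intermediate
#' graded seeds unassigned. Range choice is an explicit, logged user input
#' (mirroring visual inspection of the matrix); [suggest_end_clusters()]
#' offers a deterministic aid.
#'
#' @param res a [spectral_decompose()] result.
#' @param roi the matching [seed_roi()].
#' @param ranges a data.frame with columns `label`, `a`, `b` (1-based,
#'   inclusive rank ranges on the reordered axis), or a list of
#'   `list(label=, a=, b=)`.
#' @return Object of class `cluster_set`: `roi` plus a list `clusters` of
#'   `list(label, range, members, voxels)` where `members` are seed indices
#'   in original (lexicographic) order.
#' @export
extract_cluster_range <- function(res, roi, ranges) {
  stopifnot(inherits(res, "reordering_result"), inherits(roi, "seed_roi"))
  if (roi$n != res$n) stop("ROI size != reordering size")
  if (is.data.frame(ranges)) {
    ranges <- lapply(seq_len(nrow(ranges)), function(i)
      list(label = as.character(ranges$label[i]),
           a = ranges$a[i], b = ranges$b[i]))
  }
  if (length(ranges) == 0L) stop("no ranges given")
  n <- res$n
  covered <- integer(0)
  out <- vector("list", length(ranges))
  for (i in seq_along(ranges)) {
    r <- ranges[[i]]
    a <- as.integer(r$a); b <- as.integer(r$b)
    if (is.na(a) || is.na(b) || a < 1L || b > n || a > b)
      stop("range '", r$label, "': need 1 <= a <= b <= ", n)
    span <- a:b
    if (any(span %in% covered))
      stop("range '", r$label, "' overlaps a previous range")
    covered <- c(covered, span)
    members <- which(res$permutation >= a & res$permutation <= b)
    out[[i]] <- list(label = r$label, range = c(a, b), members = members,
                     voxels = roi$voxels[members, , drop = FALSE])
  }
  structure(list(roi = roi, clusters = out), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set> ", length(x$clusters), " cluster(s):\n", sep = "")
  for (cl in x$clusters)
    cat("  ", cl$label, ": ranks [", cl$range[1], ", ", cl$range[2], "], ",
        length(cl$members), " voxels\n", sep = "")
  invisible(x)
}

#' Binary mask of one cluster
#'
#' @param cs a [extract_cluster_range()] result.
#' @param label cluster label.
#' @return [binary_mask()] of the cluster's member voxels.
#' @export
cluster_mask <- function(cs, label) {
  stopifnot(inherits(cs, "cluster_set"))
  labs <- vapply(cs$clusters, `[[`, "", "label")
  i <- match(label, labs)
  if (is.na(i)) stop("no cluster labelled '", label, "'")
  v <- array(FALSE, cs$roi$grid$shape)
  v[cs$clusters[[i]]$voxels] <- TRUE
  binary_mask(cs$roi$grid, v)
}

#' Suggest coherent end clusters of a reordered matrix
#'
#' Advisory surrogate for choosing cluster extents by eye: grows a prefix
#' `[1, k]` and a suffix `[m, n]` (each at least `min_size`) for as long as
#' the range stays coherent relative to the matrix background -- the mean
#' within-range similarity, and the mean similarity of each newly added
#' seed to the range, must exceed the `coherence_quantile` quantile of all
#' off-diagonal values. Growth stops at the first seed that fails the
#' marginal test, which is what separates a genuine end block from the
#' graded middle. Suggestions are never applied without explicit user
#' confirmation via [extract_cluster_range()].
#'
#' @param sim_reordered reordered n x n similarity matrix
#'   (from [reorder_matrix()]).
#' @param min_size smallest admissible range size (>= 2).
#' @param coherence_quantile quantile of the off-diagonal values that the
#'   within-range mean must exceed (default 0.5).
#' @return data.frame with columns `label`, `a`, `b`; zero rows when no
#'   range qualifies.
#' @export
suggest_end_clusters <- function(sim_reordered, min_size = 2L,
                                 coherence_quantile = 0.5) {
  M <- as.matrix(sim_reordered)
  n <- nrow(M)
  empty <- data.frame(label = character(0), a = integer(0), b = integer(0))
  min_size <- max(2L, as.integer(min_size))
  if (min_size > n) return(empty)
  off <- M[!diag(TRUE, n)]
  thr <- stats::quantile(off, coherence_quantile, names = FALSE)
  within_mean <- function(a, b) {
    sub <- M[a:b, a:b]
    mean(sub[!diag(TRUE, b - a + 1L)])
  }
  # marginal coherence of seed j with the range [a, b] (j outside it)
  marginal <- function(j, a, b) mean(M[j, a:b])
  best_prefix <- NA_integer_
  if (within_mean(1L, min_size) > thr) {
    k <- min_size
    while (k < n && marginal(k + 1L, 1L, k) > thr &&
           within_mean(1L, k + 1L) > thr)
      k <- k + 1L
    best_prefix <- k
  }
  best_suffix <- NA_integer_
  if (within_mean(n - min_size + 1L, n) > thr) {
    m <- n - min_size + 1L
    while (m > 1L && marginal(m - 1L, m, n) > thr &&
           within_mean(m - 1L, n) > thr)
      m <- m - 1L
    best_suffix <- m
  }
  out <- empty
  if (!is.na(best_prefix))
    out <- rbind(out, data.frame(label = "prefix", a = 1L, b = best_prefix))
  if (!is.na(best_suffix)) {
    # keep suggestions disjoint; trim against an accepted prefix
    lo <- if (!is.na(best_prefix)) max(best_suffix, best_prefix + 1L)
          else best_suffix
    if (n - lo + 1L >= min_size)
      out <- rbind(out, data.frame(label = "suffix", a = lo, b = n))
  }
  out
}

#' Average structural connectivity map of a hard cluster
#'
#' The cluster's connectivity is the voxelwise mean of the (non-binarized)
#' group-mean tractography maps of its member seeds -- the group average
#' number of streamlines reaching each target from a cluster voxel. Because
#' the mean (not the sum) is taken, the map is fairly stringent and a
#' minimal floor of five streamlines removes spurious connections; the
#' floor applies to the mean map, not per participant.
#'
#' @param cs a [cluster_set].
#' @param label which cluster.
#' @param fp a [fingerprint_set()] of kind `group_mean_counts` whose rows
#'   cover the cluster members.
#' @param floor values below this are zeroed (default 5; inclusive `>=`
#'   retention).
#' @return numeric vector over targets; if `fp$target_grid` is set, a 3D
#'   array on that grid instead.
#' @export
cluster_structural_map <- function(cs, label, fp, floor = 5) {
  stopifnot(inherits(cs, "cluster_set"), inherits(fp, "fingerprint_set"))
  if (fp$kind != "group_mean_counts")
    stop("cluster maps require fingerprints of kind 'group_mean_counts', got '",
         fp$kind, "'")
  labs <- vapply(cs$clusters, `[[`, "", "label")
  i <- match(label, labs)
  if (is.na(i)) stop("no cluster labelled '", label, "'")
  members <- cs$clusters[[i]]$members
  if (any(members > nrow(fp$values)))
    stop("cluster members missing from fingerprint rows: ",
         paste(members[members > nrow(fp$values)], collapse = ", "))
  m <- colMeans(fp$values[members, , drop = FALSE])
  m[m < floor] <- 0
  if (!is.null(fp$target_grid)) m <- array(m, fp$target_grid$shape)
  m
}
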