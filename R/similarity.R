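#' Voxel time-series container
#'
#' @param roi a [seed_roi()] (row order) or an integer voxel count for
#'   ROI-less use.
#' @param series voxels x timepoints numeric matrix.
#' @param tr_seconds repetition time in seconds (default 2.8).
#' @param censor optional logical vector per timepoint (TRUE = artifact).
#' @return Object of class `time_series_set`.
#' @export
time_series_set <- function(roi, series, tr_seconds = 2.8, censor = NULL) {
  series <- as.matrix(series)
  if (any(!is.finite(series))) stop("time series contain non-finite values")
  if (inherits(roi, "seed_roi") && nrow(series) != roi$n)
    stop("series rows (", nrow(series), ") != ROI size (", roi$n, ")")
  if (!is.null(censor) && length(censor) != ncol(series))
    stop("censor length != number of timepoints")
  stopifnot(tr_seconds > 0)
  structure(list(roi = roi, series = series, tr_seconds = tr_seconds,
                 censor = censor),
            class = "time_series_set")
}

#' Similarity-matrix container
#'
#' Symmetric voxel-by-voxel similarity with a mode tag recording the
#' construction recipe. Structural cosine entries live in `[0, 1]`
#' (fingerprints are nonnegative); shifted time-series cosine entries in
#' `[0, 2]`; the diagonal holds the mode's self-similarity.
#'
#' @param roi a [seed_roi()] or integer voxel count.
#' @param values n x n numeric matrix.
#' @param mode `"structural_cosine"`, `"functional_shifted_cosine"` or
#'   `"group_averaged"`.
#' @param self_similarity diagonal value (1 for structural cosine, 2 for
#'   shifted cosine); inferred when omitted.
#' @return Object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(roi, values,
                              mode = c("structural_cosine",
                                       "functional_shifted_cosine",
                                       "group_averaged"),
                              self_similarity = NULL) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  dimnames(values) <- NULL
  n <- nrow(values)
  if (ncol(values) != n) stop("similarity matrix must be square")
  if (any(!is.finite(values))) stop("similarity matrix has non-finite values")
  if (max(abs(values - t(values))) > 1e-10)
    stop("similarity matrix not symmetric within 1e-10")
  if (inherits(roi, "seed_roi") && roi$n != n)
    stop("ROI size != matrix dimension")
  if (is.null(self_similarity))
    self_similarity <- switch(mode, structural_cosine = 1,
                              functional_shifted_cosine = 2,
                              group_averaged = values[1, 1])
  structure(list(roi = roi, values = values, mode = mode,
                 self_similarity = self_similarity, n = n),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("<similarity_matrix> ", x$n, " x ", x$n, " (", x$mode, ")\n", sep = "")
  invisible(x)
}

# Row-normalize, dropping zero-norm rows with a warning. Returns the
# normalized matrix plus the surviving row indices.
.unit_rows <- function(X, what) {
  nrm <- sqrt(rowSums(X^2))
  keep <- nrm > 0
  if (!all(keep))
    warning(sum(!keep), " ", what, " with zero norm dropped (indices: ",
            paste(utils::head(which(!keep), 10L), collapse = ", "), ")")
  list(X = X[keep, , drop = FALSE] / nrm[keep], keep = which(keep))
}

.subset_roi <- function(roi, keep) {
  if (inherits(roi, "seed_roi"))
    seed_roi(roi$grid, roi$voxels[keep, , drop = FALSE])
  else length(keep)
}

#' Cosine similarity of connectivity fingerprints
#'
#' `S[a, b] = <row_a, row_b> / (||row_a|| ||row_b||)`. Fingerprints are
#' nonnegative so all entries fall in `[0, 1]`, meeting the positivity
#' assumption of spectral reordering. Seeds whose fingerprint is all-zero
#' have undefined similarity and are dropped with a warning.
#'
#' @param fp a [fingerprint_set()].
#' @return [similarity_matrix()] with mode `structural_cosine`.
#' @export
cosine_similarity_matrix <- function(fp) {
  stopifnot(inherits(fp, "fingerprint_set"))
  u <- .unit_rows(fp$values, "fingerprint row(s)")
  S <- tcrossprod(u$X)
  S <- (S + t(S)) / 2
  S[S < 0] <- 0; S[S > 1] <- 1
  diag(S) <- 1
  similarity_matrix(.subset_roi(fp$roi, u$keep), S, "structural_cosine")
}

#' Shifted cosine similarity of voxel time series
#'
#' Cosine similarity of the raw time series plus one, mapping `[-1, 1]` to
#' `[0, 2]` so that all entries are positive (spectral reordering
#' requirement) while preserving the ordering of relationships: negative
#' correlations lowest, then unrelated, then positive. Series are used
#' as-is (not demeaned) by default; after nuisance regression with an
#' intercept they are near-zero-mean anyway. With `demean = TRUE` the
#' cosine equals the Pearson correlation.
#'
#' @param ts a [time_series_set()]; censored timepoints (if any) are
#'   excluded from the computation.
#' @param demean subtract each voxel's mean first (default FALSE).
#' @return [similarity_matrix()] with mode `functional_shifted_cosine`.
#' @export
shifted_time_series_similarity <- function(ts, demean = FALSE) {
  stopifnot(inherits(ts, "time_series_set"))
  X <- ts$series
  if (!is.null(ts$censor)) X <- X[, !ts$censor, drop = FALSE]
  if (demean) X <- X - rowMeans(X)
  u <- .unit_rows(X, "constant-zero series")
  S <- tcrossprod(u$X) + 1
  S <- (S + t(S)) / 2
  S[S < 0] <- 0; S[S > 2] <- 2
  diag(S) <- 2
  similarity_matrix(.subset_roi(ts$roi, u$keep), S,
                    "functional_shifted_cosine")
}

#' Average per-participant similarity matrices into a group matrix
#'
#' Each participant's off-diagonal entries are standardized (that matrix's
#' off-diagonal mean subtracted, divided by its off-diagonal SD) so that
#' participants contribute on a common scale, averaged elementwise, and the
#' average is mapped back to the similarity scale using the mean of the
#' participant SDs and the mean of the participant means. Moment
#' standardization is used rather than Fisher r-to-z because shifted-cosine
#' values reach and exceed 1, where atanh is undefined. The diagonal is
#' restored to the mode's self-similarity.
#'
#' @param mats list of [similarity_matrix()] objects sharing one ROI and mode.
#' @return [similarity_matrix()] with mode `group_averaged`.
#' @export
group_average_similarity <- function(mats) {
  if (length(mats) < 1L) stop("need at least one similarity matrix")
  stopifnot(all(vapply(mats, inherits, TRUE, "similarity_matrix")))
  n <- mats[[1L]]$n
  mode0 <- mats[[1L]]$mode
  for (m in mats)
    if (m$n != n || m$mode != mode0)
      stop("all matrices must share one ROI size and mode")
  off <- !diag(TRUE, n)
  Zsum <- matrix(0, n, n)
  mus <- sds <- numeric(0)
  used <- 0L
  for (p in seq_along(mats)) {
    v <- mats[[p]]$values
    mu <- mean(v[off]); sdv <- stats::sd(v[off])
    if (!is.finite(sdv) || sdv == 0) {
      message("group_average_similarity: participant ", p,
              " has zero off-diagonal SD; excluded")
      next
    }
    Zsum <- Zsum + (v - mu) / sdv
    mus <- c(mus, mu); sds <- c(sds, sdv)
    used <- used + 1L
  }
  if (used == 0L) stop("no participant matrix with nonzero off-diagonal SD")
  G <- (Zsum / used) * mean(sds) + mean(mus)
  G <- (G + t(G)) / 2
  G[G < 0] <- 0                  # guard: back-transform cannot go negative
  diag(G) <- mats[[1L]]$self_similarity
  similarity_matrix(mats[[1L]]$roi, G, "group_averaged",
                    self_similarity = mats[[1L]]$self_similarity)
}
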