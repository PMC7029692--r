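#' Spectral reordering of a similarity matrix
#'
#' Treats the similarity matrix as the weighted adjacency `A` of a graph on
#' the seed voxels, forms the non-normalized graph Laplacian `L = D - A`
#' (`D` the diagonal degree matrix of row sums), and solves the generalized
#' eigenproblem `L v = lambda D v`. The eigenvector of the second-smallest
#' generalized eigenvalue (the Fiedler vector) provides a one-dimensional
#' embedding that is optimal for clustering; ranking its entries reorders
#' the matrix so that voxels with similar connectivity profiles sit next to
#' each other. The second-smallest eigenvalue itself, `lambda_2`, is the
#' algebraic connectivity of the graph: it approaches 0 for a matrix made of
#' strong blocks with weak links between them (hard clusters) and grows
#' toward the largest eigenvalue (typically around 1-2) as the transition
#' becomes graded.
#'
#' Numerically the generalized problem is solved through the symmetric
#' normalized Laplacian `D^(-1/2) L D^(-1/2)`, whose spectrum is identical;
#' eigenvectors are mapped back by `v = D^(-1/2) u`. All generalized
#' eigenvalues lie in `[0, 2]` and the smallest is 0 (constant generalized
#' eigenvector).
#'
#' The Fiedler vector's sign is arbitrary; it is canonicalized so that,
#' among the decile of seeds with the largest absolute Fiedler loading, the
#' seed with the lowest original index has a positive entry. Rank ties are
#' broken by original seed index. If `lambda_2` is (near-)degenerate the
#' ordering within the eigenspace is backend-dependent; a message flags
#' this, and the `lambda_2` value itself remains well-defined.
#'
#' @param sim a [similarity_matrix()] or a plain symmetric nonnegative
#'   matrix.
#' @return Object of class `reordering_result` with fields `eigenvalues`
#'   (ascending), `fiedler`, `permutation` (rank 1..n per seed), `lambda2`,
#'   `n`.
#' @export
spectral_decompose <- function(sim) {
  A <- if (inherits(sim, "similarity_matrix")) sim$values else as.matrix(sim)
  n <- nrow(A)
  if (ncol(A) != n) stop("similarity matrix must be square")
  if (any(!is.finite(A))) stop("similarity matrix has non-finite values")
  if (max(abs(A - t(A))) > 1e-8) stop("similarity matrix not symmetric")
  A <- (A + t(A)) / 2
  if (min(A) < -1e-10) stop("similarity matrix must be nonnegative")
  A[A < 0] <- 0
  d <- rowSums(A)
  if (any(d <= 0))
    stop("zero-degree node(s) at index ",
         paste(utils::head(which(d <= 0), 10L), collapse = ", "),
         "; remove disconnected empty seeds before reordering")
  L <- diag(d) - A
  is <- 1 / sqrt(d)
  M <- L * tcrossprod(is)          # D^{-1/2} L D^{-1/2}
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  lam <- rev(e$values)             # ascending
  U <- e$vectors[, n:1, drop = FALSE]
  fied <- U[, 2L] * is             # generalized eigenvector
  fied <- fied / sqrt(sum(fied^2))
  # deterministic sign: lowest-index seed among the extreme decile positive
  k <- max(1L, ceiling(n / 10))
  extreme <- sort(order(abs(fied), decreasing = TRUE)[seq_len(k)])
  j <- extreme[1L]
  if (fied[j] < 0) fied <- -fied
  ord <- order(fied, seq_len(n))   # ties broken by original index
  perm <- integer(n)
  perm[ord] <- seq_len(n)
  if (n >= 3L && abs(lam[3L] - lam[2L]) < 1e-10)
    message("spectral_decompose: lambda_2 is degenerate (multiplicity > 1); ",
            "the reordering within the eigenspace is backend-dependent")
  structure(list(eigenvalues = lam, fiedler = fied, permutation = perm,
                 lambda2 = lam[2L], n = n),
            class = "reordering_result")
}

#' @export
print.reordering_result <- function(x, ...) {
  cat("<reordering_result> n = ", x$n, ", lambda2 = ",
      signif(x$lambda2, 6), "\n", sep = "")
  invisible(x)
}

#' Reorder a similarity matrix by its Fiedler ranks
#'
#' @param sim the [similarity_matrix()] (or plain matrix) the result was
#'   computed from.
#' @param res a [spectral_decompose()] result of matching size.
#' @return n x n matrix with rows/columns permuted so that position `r`
#'   holds the seed of rank `r`; values are unchanged.
#' @export
reorder_matrix <- function(sim, res) {
  A <- if (inherits(sim, "similarity_matrix")) sim$values else as.matrix(sim)
  stopifnot(inherits(res, "reordering_result"))
  if (nrow(A) != res$n) stop("matrix size (", nrow(A),
                             ") != reordering size (", res$n, ")")
  ord <- order(res$permutation)
  A[ord, ord, drop = FALSE]
}

#' Back-project matrix ranks onto the brain
#'
#' Each seed voxel receives its rank in the reordered matrix (the first
#' voxel of the reordered matrix has value 1), background voxels 0, giving
#' the gradient map that visualizes the connectivity transition across the
#' region.
#'
#' @param res a [spectral_decompose()] result.
#' @param roi the [seed_roi()] the similarity matrix was built on.
#' @return 3D numeric array of ranks (0 outside the ROI).
#' @export
backproject_ranks <- function(res, roi) {
  stopifnot(inherits(res, "reordering_result"), inherits(roi, "seed_roi"))
  if (roi$n != res$n) stop("ROI size != reordering size")
  vol <- array(0, roi$grid$shape)
  vol[roi$voxels] <- res$permutation
  vol
}

#' Per-participant gradation (lambda-2) summary
#'
#' Computes the algebraic-connectivity gradation metric for each
#' participant's similarity matrix. Group matrices can inflate gradation
#' relative to any individual (averaging smooths block structure), so the
#' per-participant distribution is reported alongside the group value.
#'
#' @param mats list of per-participant [similarity_matrix()] objects.
#' @return list with `lambda2` (numeric per participant), `mean`, `sd`,
#'   `q25`, `q75`.
#' @export
gradation_per_participant <- function(mats) {
  if (length(mats) < 1L) stop("need at least one matrix")
  l2 <- vapply(mats, function(m) spectral_decompose(m)$lambda2, numeric(1))
  q <- stats::quantile(l2, c(.25, .75), names = FALSE)
  list(lambda2 = l2, mean = mean(l2),
       sd = if (length(l2) > 1L) stats::sd(l2) else 0,
       q25 = q[1L], q75 = q[2L])
}
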