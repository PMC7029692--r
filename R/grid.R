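#' Sampling grid of a 3D volume
#'
#' A `volume_grid` records the voxel lattice shared by all volumes of an
#' analysis: the array shape, the 4x4 voxel-to-mm affine, and the voxel size
#' in mm derived from the affine column norms. Voxel indices are 1-based
#' (R convention); the affine maps the 0-based NIfTI voxel frame, so
#' `mm = affine %*% c(i - 1, j - 1, k - 1, 1)`.
#'
#' @param shape integer vector of length 3, voxels per dimension (all > 0).
#' @param affine 4x4 numeric voxel-to-mm matrix; must be invertible. Defaults
#'   to identity spacing (1 mm isotropic, origin at the first voxel).
#' @return An object of class `volume_grid` with fields `shape`, `affine`,
#'   `voxel_size`.
#' @export
volume_grid <- function(shape, affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 1L))
    stop("`shape` must be 3 positive integers")
  if (is.null(affine)) {
    affine <- diag(4)
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stop("`affine` must be a finite 4x4 matrix")
  if (abs(det(affine)) < 1e-12)
    stop("`affine` must be invertible")
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(shape = shape, affine = affine, voxel_size = voxel_size),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(x$shape, collapse = " x "),
      " voxels, size ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$shape, b$shape) && isTRUE(all.equal(a$affine, b$affine))
}

#' Binary mask on a volume grid
#'
#' @param grid a [volume_grid()].
#' @param values logical (or 0/1 numeric) array matching `grid$shape`.
#' @return Object of class `binary_mask` with fields `grid`, `values`
#'   (logical array).
#' @export
binary_mask <- function(grid, values) {
  stopifnot(inherits(grid, "volume_grid"))
  values <- array(as.logical(values), dim = grid$shape)
  if (anyNA(values)) stop("mask values must be TRUE/FALSE, no NA")
  structure(list(grid = grid, values = values), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", sum(x$values), " / ", prod(x$grid$shape),
      " voxels set\n", sep = "")
  invisible(x)
}

#' Ordered seed region of interest
#'
#' The seed ROI fixes the row/column order of every downstream matrix:
#' voxels are sorted lexicographically by (i, then j, then k) and that order
#' is immutable. Constructed from explicit coordinates or via
#' [build_seed_roi()].
#'
#' @param grid a [volume_grid()].
#' @param voxels n x 3 integer matrix of 1-based voxel indices.
#' @return Object of class `seed_roi` with fields `grid`, `voxels`
#'   (lexicographically ordered, unique), and `n`.
#' @export
seed_roi <- function(grid, voxels) {
  stopifnot(inherits(grid, "volume_grid"))
  voxels <- matrix(as.integer(voxels), ncol = 3L,
                   dimnames = list(NULL, c("i", "j", "k")))
  if (nrow(voxels) == 0L) stop("seed ROI is empty")
  if (any(voxels < 1L) || any(voxels > matrix(grid$shape, nrow(voxels), 3,
                                              byrow = TRUE)))
    stop("seed voxel indices out of grid bounds")
  ord <- order(voxels[, 1L], voxels[, 2L], voxels[, 3L])
  voxels <- voxels[ord, , drop = FALSE]
  if (nrow(voxels) > 1L &&
      any(rowSums(abs(diff(voxels))) == 0L))
    stop("duplicate seed voxels")
  structure(list(grid = grid, voxels = voxels, n = nrow(voxels)),
            class = "seed_roi")
}

#' @export
print.seed_roi <- function(x, ...) {
  cat("<seed_roi> ", x$n, " seed voxels on a ",
      paste(x$grid$shape, collapse = "x"), " grid\n", sep = "")
  invisible(x)
}

#' Voxel indices to mm coordinates
#'
#' @param grid a [volume_grid()].
#' @param voxels n x 3 matrix of 1-based voxel indices.
#' @return n x 3 matrix of mm coordinates under the grid affine.
#' @export
voxel_to_mm <- function(grid, voxels) {
  voxels <- matrix(voxels, ncol = 3L)
  xyz1 <- cbind(voxels - 1, 1)            # affine maps the 0-based frame
  mm <- xyz1 %*% t(grid$affine)
  mm[, 1:3, drop = FALSE]
}

## ---- lattice neighborhoods -------------------------------------------------

#' Neighbor offsets for a 3D connectivity scheme
#'
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full cube).
#' @return m x 3 integer matrix of nonzero offsets.
#' @export
neighbor_offsets <- function(connectivity = 6L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6"  = nz == 1L,
                 "18" = nz >= 1L & nz <= 2L,
                 "26" = nz >= 1L)
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

# Shift a logical/numeric array by an integer offset, filling exposed
# planes with `fill`. shift_array(a, d)[x] == a[x - d] where defined.
shift_array <- function(a, d, fill = FALSE) {
  dm <- dim(a)
  out <- array(fill, dim = dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      dst[[ax]] <- seq.int(1L + d[ax], dm[ax])
      src[[ax]] <- seq.int(1L, dm[ax] - d[ax])
    } else {
      dst[[ax]] <- seq.int(1L, dm[ax] + d[ax])
      src[[ax]] <- seq.int(1L - d[ax], dm[ax])
    }
    if (length(dst[[ax]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Binary dilation of a mask
#'
#' Iterated one-voxel dilation under the chosen lattice connectivity.
#' Out-of-volume space never becomes part of the mask.
#'
#' @param mask a [binary_mask()].
#' @param radius nonnegative integer number of dilation iterations.
#' @param connectivity 6, 18 or 26.
#' @return A dilated [binary_mask()].
#' @export
dilate_mask <- function(mask, radius = 1L, connectivity = 6L) {
  stopifnot(inherits(mask, "binary_mask"))
  radius <- as.integer(radius)
  if (radius < 0L) stop("radius must be >= 0")
  v <- mask$values
  offs <- neighbor_offsets(connectivity)
  for (r in seq_len(radius)) {
    acc <- v
    for (o in seq_len(nrow(offs)))
      acc <- acc | shift_array(v, offs[o, ], fill = FALSE)
    v <- acc
  }
  binary_mask(mask$grid, v)
}

# Connected components of a set of voxels on a grid.
# coords: m x 3 integer matrix; returns integer component label per row.
connected_components <- function(coords, dims, connectivity = 6L) {
  m <- nrow(coords)
  if (m == 0L) return(integer(0))
  lin <- coords[, 1L] +
    dims[1L] * (coords[, 2L] - 1L) +
    dims[1L] * dims[2L] * (coords[, 3L] - 1L)
  ord <- order(lin)
  slin <- lin[ord]
  offs <- neighbor_offsets(connectivity)
  labels <- integer(m)
  cur <- 0L
  for (s in seq_len(m)) {
    if (labels[ord[s]] != 0L) next
    cur <- cur + 1L
    queue <- ord[s]
    labels[queue] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- sweep(offs, 2L, as.integer(coords[v, ]), `+`)
      ok <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
            nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
            nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
      if (!any(ok)) next
      nb <- nb[ok, , drop = FALSE]
      nlin <- nb[, 1L] + dims[1L] * (nb[, 2L] - 1L) +
        dims[1L] * dims[2L] * (nb[, 3L] - 1L)
      pos <- findInterval(nlin, slin)
      hit <- pos > 0L & slin[pmax(pos, 1L)] == nlin
      idx <- ord[pos[hit]]
      idx <- idx[labels[idx] == 0L]
      if (length(idx)) {
        labels[idx] <- cur
        queue <- c(queue, idx)
      }
    }
  }
  labels
}
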