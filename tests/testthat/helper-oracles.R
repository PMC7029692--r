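# Independent brute-force oracles. These deliberately re-derive results by
# the most literal method available (triple loops, scalar arithmetic,
# alternative eigensolvers) and must stay independent of the package code
# paths they check.

# Gray/white interface by triple loop over every voxel and neighbor.
oracle_interface <- function(white, csf, dilation = 1L, connectivity = 6L) {
  dm <- dim(white)
  offs <- gradparc::neighbor_offsets(connectivity)
  # dilate CSF by literal repeated neighbor scan
  csf_d <- csf
  for (r in seq_len(dilation)) {
    nxt <- csf_d
    for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
      if (csf_d[i, j, k]) next
      for (o in seq_len(nrow(offs))) {
        ni <- i + offs[o, 1]; nj <- j + offs[o, 2]; nk <- k + offs[o, 3]
        if (ni >= 1 && ni <= dm[1] && nj >= 1 && nj <= dm[2] &&
            nk >= 1 && nk <= dm[3] && csf_d[ni, nj, nk]) {
          nxt[i, j, k] <- TRUE; break
        }
      }
    }
    csf_d <- nxt
  }
  out <- array(FALSE, dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (!white[i, j, k] || csf_d[i, j, k]) next
    for (o in seq_len(nrow(offs))) {
      ni <- i + offs[o, 1]; nj <- j + offs[o, 2]; nk <- k + offs[o, 3]
      outside <- ni < 1 || ni > dm[1] || nj < 1 || nj > dm[2] ||
        nk < 1 || nk > dm[3]
      if (outside || !white[ni, nj, nk]) { out[i, j, k] <- TRUE; break }
    }
  }
  out
}

# Scalar double-loop cosine similarity.
oracle_cosine <- function(X) {
  n <- nrow(X)
  S <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    S[a, b] <- sum(X[a, ] * X[b, ]) /
      (sqrt(sum(X[a, ]^2)) * sqrt(sum(X[b, ]^2)))
  }
  S
}

# Generalized spectrum of L v = lambda D v via the (non-symmetric)
# eigenproblem of D^{-1} L -- a different route than the package's
# symmetric normalized solve.
oracle_generalized_spectrum <- function(A) {
  d <- rowSums(A)
  L <- diag(d) - A
  ev <- eigen(diag(1 / d) %*% L, only.values = TRUE)$values
  sort(Re(ev))
}

# Literal per-timepoint scrubbing re-check.
oracle_censor <- function(mp, g, trans_mm = 1, z_thresh = 2.5) {
  n <- nrow(mp)
  out <- logical(n)
  zs <- (g - mean(g)) / stats::sd(g)
  for (t in seq_len(n)) {
    fd <- 0
    if (t > 1) fd <- max(abs(mp[t, 1:3] - mp[t - 1, 1:3]))
    out[t] <- fd > trans_mm || abs(zs[t]) > z_thresh
  }
  out
}

oracle_exclude <- function(censor, tr, mp, min_s = 300, max_mm = 3) {
  kept <- 0
  for (t in seq_along(censor)) if (!censor[t]) kept <- kept + 1
  bad_trans <- FALSE
  for (t in seq_len(nrow(mp))) for (ax in 1:3)
    if (abs(mp[t, ax]) > max_mm) bad_trans <- TRUE
  !(kept * tr < min_s || bad_trans)
}

# Random similarity matrix from nonnegative fingerprints (always a valid
# structural-cosine input).
random_similarity <- function(n, t = n + 10L) {
  X <- matrix(stats::rgamma(n * t, 2, 1), n, t)
  gradparc::cosine_similarity_matrix(
    gradparc::fingerprint_set(
      gradparc::seed_roi(gradparc::volume_grid(c(n, 1L, 1L)),
                         cbind(seq_len(n), 1L, 1L)),
      X, kind = "native_counts"))
}
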