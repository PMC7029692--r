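test_that("Friston-24 expansion follows the Volterra definition", {
  mp0 <- matrix(0, 10, 6)
  expect_equal(friston24_expand(mp0), matrix(0, 10, 24), ignore_attr = TRUE)
  expect_equal(ncol(friston24_expand(matrix(rnorm(60), 10, 6))), 24L)

  # single param series [1, 2]: squares [1, 4], lag [0, 1], lag^2 [0, 1]
  mp <- matrix(0, 2, 6); mp[, 1] <- c(1, 2)
  out <- friston24_expand(mp)
  expect_equal(unname(out[, 1]), c(1, 2))
  expect_equal(unname(out[, 7]), c(1, 4))
  expect_equal(unname(out[, 13]), c(0, 1))
  expect_equal(unname(out[, 19]), c(0, 1))
  expect_error(friston24_expand(matrix(0, 5, 5)), "6 columns")
})

test_that("scrubbing flags planted motion and signal artifacts", {
  set.seed(51)
  n <- 120
  mp <- matrix(rnorm(n * 6, 0, 0.01), n, 6)
  g <- rnorm(n, 1000, 2)
  # planted 1.2 mm translation jump at t = 50
  mp[50, 2] <- mp[50, 2] + 1.2
  cen <- flag_artifact_timepoints(mp, g)
  expect_true(cen[50])
  # constant motion, one global-signal excursion well past z = 2.5
  mp2 <- matrix(0, n, 6)
  g2 <- rnorm(n, 0, 1)
  g2[10] <- mean(g2[-10]) + 10 * sd(g2[-10])
  cen2 <- flag_artifact_timepoints(mp2, g2)
  expect_true(cen2[10])
  expect_identical(cen2, oracle_censor(mp2, g2))
  # still scan, stationary signal: no flags
  expect_false(any(flag_artifact_timepoints(matrix(0, n, 6), rep(5, n))))
})

test_that("censoring and exclusion match the brute-force re-check", {
  set.seed(52)
  for (rep in 1:100) {
    n <- sample(60:140, 1)
    mp <- matrix(rnorm(n * 6, 0, 0.4), n, 6)
    if (runif(1) < 0.3) mp[sample(n, 1), sample(3, 1)] <- 3.2
    g <- rnorm(n)
    cen <- flag_artifact_timepoints(mp, g)
    expect_identical(cen, oracle_censor(mp, g))
    dec <- apply_exclusion_rules(cen, 2.8, mp)
    expect_identical(dec$keep, oracle_exclude(cen, 2.8, mp))
  }
})

test_that("five-minute rule at TR 2.8: 107 volumes excluded, 108 retained", {
  mk <- function(n_keep, n_total = 130) {
    cen <- rep(TRUE, n_total); cen[seq_len(n_keep)] <- FALSE
    apply_exclusion_rules(cen, 2.8, matrix(0, n_total, 6))
  }
  d107 <- mk(107)
  expect_false(d107$keep)                       # 299.6 s < 300 s
  expect_equal(d107$retained_seconds, 299.6)
  d108 <- mk(108)
  expect_true(d108$keep)                        # 302.4 s
  expect_equal(d108$retained_seconds, 302.4)
  # one translation of 3.5 mm excludes regardless of retained time
  mp <- matrix(0, 130, 6); mp[60, 1] <- 3.5
  expect_false(apply_exclusion_rules(rep(FALSE, 130), 2.8, mp)$keep)
})

test_that("nuisance regression produces orthogonal residuals", {
  set.seed(53)
  n <- 100
  motion <- matrix(rnorm(n * 6, 0, 0.1), n, 6)
  X <- cbind(intercept = 1, friston24_expand(motion),
             wm = rnorm(n), csf = rnorm(n), global = rnorm(n))
  # plant a signal orthogonal to the design so recovery is unambiguous
  signal <- qr.resid(qr(X), sin(seq_len(n) / 5))
  roi <- seed_roi(volume_grid(c(3L, 1L, 1L)), cbind(1:3, 1L, 1L))
  Y <- rbind(X[, 2],                              # equals a regressor
             2 * motion[, 1] + signal,            # planted mixture
             signal)                              # orthogonal: unchanged
  ts <- time_series_set(roi, Y)
  res <- regress_nuisance(ts, X)
  expect_lt(max(abs(res$series[1, ])), 1e-8)
  expect_gt(cor(res$series[2, ], signal), 0.99)
  expect_lt(abs(cor(res$series[2, ], motion[, 1])), 1e-6)
  expect_equal(res$series[3, ], signal, tolerance = 1e-10, ignore_attr = TRUE)
  # residuals orthogonal to every design column
  expect_lt(max(abs(t(X) %*% t(res$series))), 1e-8)
  # rank deficiency names the collinear column
  Xbad <- cbind(X, dup = X[, 2])
  expect_error(regress_nuisance(ts, Xbad), "rank deficient")
  # all-zero spike columns are tolerated (dropped)
  Xsp <- cbind(X, spike = 0)
  expect_silent(regress_nuisance(ts, Xsp))
})

test_that("seed connectivity maps behave at the exact and degenerate points", {
  set.seed(54)
  dims <- c(5L, 5L, 4L)
  Tt <- 80L
  arr <- array(rnorm(prod(dims) * Tt), c(dims, Tt))
  mvals <- array(FALSE, dims); mvals[1:2, 1, 1] <- TRUE
  # make cluster voxels identical so a probe equals the cluster mean
  arr[2, 1, 1, ] <- arr[1, 1, 1, ]
  arr[3, 1, 1, ] <- arr[1, 1, 1, ]               # probe voxel = mean series
  arr[4, 1, 1, ] <- -arr[1, 1, 1, ]              # sign-flipped probe
  arr[5, 1, 1, ] <- 7                            # constant voxel
  z <- seed_connectivity_map(arr, binary_mask(volume_grid(dims), mvals))
  expect_equal(z[3, 1, 1], atanh(1 - 1e-7))
  expect_equal(z[4, 1, 1], -z[3, 1, 1])          # antisymmetry
  expect_equal(z[5, 1, 1], 0)
  expect_true(all(is.finite(z)))
  expect_true(length(attr(z, "constant_voxels")) >= 1)
  expect_error(seed_connectivity_map(arr, array(FALSE, dims)), "empty")
})

test_that("group stats: null maps yield no spurious certainty, swap negates", {
  set.seed(55)
  dims <- c(8L, 8L, 6L)
  zero <- lapply(1:6, function(i) array(0, dims) + rnorm(prod(dims), 0, 1e-8))
  st0 <- group_cluster_stats(zero, n_perm = 200)
  expect_false(any(st0$cluster_sig_mask))

  A <- lapply(1:8, function(i) make_smooth_noise_map(dims, 1))
  B <- lapply(1:8, function(i) make_smooth_noise_map(dims, 1))
  set.seed(99); stAB <- group_cluster_stats(A, B, n_perm = 50)
  set.seed(99); stBA <- group_cluster_stats(B, A, n_perm = 50)
  expect_equal(stAB$t, -stBA$t, tolerance = 1e-12)
  expect_equal(stAB$method, "paired_difference")
  expect_error(group_cluster_stats(A, B[1:3]), "equal participant")
})

test_that("planted effects are detected and masking constrains them", {
  set.seed(56)
  dims <- c(10L, 10L, 6L)
  eff <- array(FALSE, dims); eff[4:6, 4:6, 3:4] <- TRUE
  mapsA <- lapply(1:15, function(i) {
    m <- make_smooth_noise_map(dims, 1); m[eff] <- m[eff] + 1.5; m })
  mapsB <- lapply(1:15, function(i) make_smooth_noise_map(dims, 1))
  withinA <- group_cluster_stats(mapsA, n_perm = 300)
  withinB <- group_cluster_stats(mapsB, n_perm = 300)
  between <- group_cluster_stats(mapsA, mapsB, n_perm = 300)
  expect_true(any(between$cluster_sig_mask[eff]))
  masked <- mask_between_by_within(between, withinA, withinB)
  msk <- attr(masked, "mask")
  expect_true(all(msk[between$cluster_sig_mask == FALSE] == FALSE))
  # positive surviving voxels must be significant within A
  expect_true(all(withinA$cluster_sig_mask[msk & between$t > 0]))
})
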