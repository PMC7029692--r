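test_that("phantom segmentation partitions tissue and has an interface", {
  set.seed(61)
  seg <- make_phantom_segmentation(c(16L, 16L, 16L))
  expect_false(any(seg$wm$values & seg$gm$values))
  expect_false(any(seg$wm$values & seg$csf$values))
  expect_false(any(seg$gm$values & seg$csf$values))
  iface <- extract_gw_interface(seg$wm, seg$csf)
  expect_gt(sum(iface$values), 0)
  expect_error(make_phantom_segmentation(c(6L, 16L, 16L)), ">= 8")
  # determinism under a fixed seed
  set.seed(61); a <- make_phantom_segmentation()
  set.seed(61); b <- make_phantom_segmentation()
  expect_identical(a$csf$values, b$csf$values)
})

test_that("truth construction: ramp, step, and sharpness interpolation", {
  expect_equal(make_truth(5, "graded")$w, c(0, .25, .5, .75, 1))
  wcl <- make_truth(6, "clustered")$w
  expect_true(all(wcl %in% c(0, 1)) && !is.unsorted(wcl))
  wi <- make_truth(101, "intermediate", sharpness = 0.2)$w
  expect_equal(wi[1], 0); expect_equal(wi[101], 1)
  expect_true(!is.unsorted(wi))
  expect_gt(sum(wi == 0), 30)          # compressed ramp has flat shoulders
  expect_equal(make_truth(101, "intermediate", sharpness = 1)$w,
               make_truth(101, "graded")$w)
})

test_that("fingerprints hit construction identities at zero noise", {
  set.seed(62)
  fp <- make_fingerprints(10, 60, 1, mode = "graded", jitter_sd = 0,
                          poisson = FALSE)
  A <- fp$truth$A; B <- fp$truth$B
  V <- fp$participants[[1]]$values
  expect_equal(V[1, ], 50 * B)                   # w = 0 endpoint
  expect_equal(V[10, ], 50 * A)                  # w = 1 endpoint
  expect_equal(V[5, ], 50 * (fp$truth$w[5] * A + (1 - fp$truth$w[5]) * B))
  # clustered, noiseless: exactly two distinct row profiles
  fc <- make_fingerprints(10, 60, 1, mode = "clustered", jitter_sd = 0,
                          poisson = FALSE)
  expect_equal(nrow(unique(fc$participants[[1]]$values)), 2L)
  # endmember cosine < 0.5
  expect_lt(sum(A * B) / sqrt(sum(A^2) * sum(B^2)), 0.5)
})

test_that("noiseless graded similarity is monotone in |w_i - w_j|", {
  set.seed(63)
  fp <- make_fingerprints(30, 80, 1, jitter_sd = 0, poisson = FALSE)
  S <- cosine_similarity_matrix(fp$participants[[1]])$values
  # moving away from seed i along the ramp in either direction can only
  # lower similarity (mixture directions rotate monotonically with w)
  for (i in c(1, 15, 30)) {
    if (i < 30) expect_true(all(diff(S[i, i:30]) < 1e-9))
    if (i > 1) expect_true(all(diff(S[i, i:1]) < 1e-9))
  }
})

test_that("Poisson counts match their stated mean/variance structure", {
  set.seed(64)
  n_draw <- 10000L
  lam <- 25
  x <- rpois(n_draw, lam)
  # variance/mean ratio within 10% at lambda >= 20 (distributional sanity
  # for the generator's count model)
  expect_lt(abs(var(x) / mean(x) - 1), 0.1)
  fp <- make_fingerprints(50, 100, 4, jitter_sd = 0)
  v <- fp$participants[[1]]$values
  expect_true(all(v >= 0) && all(v == round(v)))
})

test_that("time series mix network signals as constructed", {
  set.seed(65)
  ts <- make_timeseries(20, 100, 1, mode = "graded", noise_sd = 0)
  S <- ts$participants[[1]]$series
  # endpoint voxels carry pure (standardized) network signals
  expect_equal(ts$participants[[1]]$tr_seconds, 2.8)
  sA <- S[20, ]; sB <- S[1, ]
  expect_lt(abs(cor(sA, sB)), 0.2)               # near-orthogonal networks
  mid <- ts$truth$w[10] * sA + (1 - ts$truth$w[10]) * sB
  expect_equal(S[10, ], mid, tolerance = 1e-12)
  # clustered, noiseless: shifted-cosine matrix is two-block
  tc <- make_timeseries(12, 80, 1, mode = "clustered", noise_sd = 0)
  M <- shifted_time_series_similarity(tc$participants[[1]])$values
  blk <- M[1:6, 1:6]
  expect_true(all(abs(blk[!diag(TRUE, 6)] - 2) < 1e-6))
  expect_true(all(abs(M[1:6, 7:12] - 1) < 0.3))
})

test_that("motion traces plant the requested artifacts", {
  set.seed(66)
  m0 <- make_motion_trace(130, n_spikes = 0)
  cen0 <- flag_artifact_timepoints(m0$mp, rep(0, 130))
  expect_false(any(cen0))
  m2 <- make_motion_trace(130, n_spikes = 2)
  cen2 <- flag_artifact_timepoints(m2$mp, rep(0, 130))
  expect_true(all(cen2[m2$spike_times]))
  mv <- make_motion_trace(130, violation = TRUE)
  dec <- apply_exclusion_rules(flag_artifact_timepoints(mv$mp, rep(0, 130)),
                               2.8, mv$mp)
  expect_false(dec$keep)
  expect_match(paste(dec$reasons, collapse = " "), "translation")
})

test_that("group bundles are deterministic and internally consistent", {
  set.seed(67); a <- make_group_dataset(n_participants = 3L, n_seeds = 20L,
                                        n_targets = 40L)
  set.seed(67); b <- make_group_dataset(n_participants = 3L, n_seeds = 20L,
                                        n_targets = 40L)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$fingerprints$participants[[2]]$values,
                   b$fingerprints$participants[[2]]$values)
  # planted violation propagates through the QC rule chain
  set.seed(68)
  v <- make_group_dataset(n_participants = 2L, n_seeds = 20L,
                          n_targets = 40L, plant_violation = TRUE)
  mp1 <- v$motion[[1]]$mp
  cen <- flag_artifact_timepoints(mp1, rep(0, nrow(mp1)))
  expect_false(apply_exclusion_rules(cen, 2.8, mp1)$keep)
  # written bundle round-trips byte-identically under one seed
  d1 <- tempfile(); d2 <- tempfile()
  set.seed(69); make_group_dataset(n_participants = 2L, n_seeds = 10L,
                                   n_targets = 20L, dir = d1)
  set.seed(69); make_group_dataset(n_participants = 2L, n_seeds = 10L,
                                   n_targets = 20L, dir = d2)
  expect_identical(readLines(file.path(d1, "manifest.tsv")),
                   readLines(file.path(d2, "manifest.tsv")))
  expect_identical(readLines(file.path(d1, "motion_01.txt")),
                   readLines(file.path(d2, "motion_01.txt")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("end-to-end: graded bundles are more graded than clustered ones", {
  set.seed(70)
  l2 <- function(mode) {
    fp <- make_fingerprints(40, 80, 1, mode = mode)
    spectral_decompose(cosine_similarity_matrix(fp$participants[[1]]))$lambda2
  }
  hard <- replicate(8, l2("clustered"))
  grad <- replicate(8, l2("graded"))
  expect_true(all(hard < grad))
})
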