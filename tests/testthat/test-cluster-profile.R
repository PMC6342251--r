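# Segment features, clustering, profiles.

test_that("features of degenerate and analytic segments are correct", {
  f <- extract_features(rep(3, 100), 83.33)
  expect_equal(unname(f[c("sd", "range", "d1max", "d2max")]), rep(0, 4))
  expect_equal(unname(f[c("p_delta", "p_theta", "p_alpha", "p_beta")]), rep(0, 4))
  expect_error(extract_features(c(1, 2, 3), 83.33), "4 samples")

  # unit 2 Hz sine, 5 s: delta band dominates, mean frequency ~ 2 Hz
  fs <- 83.33
  t <- seq_len(round(5 * fs)) / fs
  fsin <- extract_features(sin(2 * pi * 2 * t), fs)
  expect_gte(fsin["p_delta"] / fsin["p_theta"], 10)
  expect_gte(fsin["mean_freq"], 1.8)
  expect_lte(fsin["mean_freq"], 2.2)
  # sine power A^2/2 concentrated in the delta band
  expect_equal(unname(fsin["p_delta"]), sqrt(0.5), tolerance = 0.05)

  # white noise: flat spectrum -> mean frequency ~ fs/4
  set.seed(1)
  fw <- extract_features(rnorm(5000), fs)
  expect_lt(abs(fw["mean_freq"] - fs / 4) / (fs / 4), 0.1)
})

test_that("amplitude features scale linearly, mean frequency is invariant", {
  set.seed(2)
  x <- rnorm(500)
  f1 <- extract_features(x, 83.33)
  f3 <- extract_features(3 * x, 83.33)
  amp <- c("sd", "range", "d1max", "d2max", "p_delta", "p_theta", "p_alpha", "p_beta")
  expect_equal(unname(f3[amp]), unname(3 * f1[amp]), tolerance = 1e-10)
  expect_equal(unname(f3["mean_freq"]), unname(f1["mean_freq"]), tolerance = 1e-10)
})

test_that("k-means separates well-separated blobs and respects k", {
  set.seed(3)
  blob1 <- matrix(rnorm(50 * 9, 0, 0.1), ncol = 9)
  blob2 <- matrix(rnorm(60 * 9, 5, 0.1), ncol = 9)
  F <- rbind(blob1, blob2)
  colnames(F) <- classqs:::FEATURE_NAMES
  lab <- cluster_segments(F, k = 2, seed = 11)
  expect_equal(length(unique(lab[1:50])), 1L)
  expect_equal(length(unique(lab[51:110])), 1L)
  expect_false(lab[1] == lab[60])

  lab1 <- cluster_segments(F, k = 1, seed = 11)
  expect_true(all(lab1 == 1L))

  Fsame <- F[rep(1, 30), ]
  expect_warning(labs <- cluster_segments(Fsame, k = 12, seed = 11), "reducing k")
  expect_equal(attr(labs, "k"), 1L)
})

test_that("clustering is deterministic under a fixed seed and z-score invariant", {
  set.seed(4)
  F <- matrix(rexp(80 * 9), ncol = 9)
  colnames(F) <- classqs:::FEATURE_NAMES
  l1 <- cluster_segments(F, k = 4, seed = 99)
  l2 <- cluster_segments(F, k = 4, seed = 99)
  expect_identical(as.integer(l1), as.integer(l2))
  # per-feature affine rescaling leaves z-scored clustering unchanged
  F2 <- sweep(sweep(F, 2, runif(9, 0.5, 3), "*"), 2, runif(9, -5, 5), "+")
  l3 <- cluster_segments(F2, k = 4, seed = 99)
  expect_identical(as.integer(l1), as.integer(l3))
})

test_that("variance relabeling orders clusters by mean variance", {
  F <- rbind(matrix(c(3, rep(0, 8)), 10, 9, byrow = TRUE),   # sd 3 -> var 9
             matrix(c(2, rep(0, 8)), 12, 9, byrow = TRUE))   # sd 2 -> var 4
  colnames(F) <- classqs:::FEATURE_NAMES
  raw <- c(rep(1L, 10), rep(2L, 12)); attr(raw, "k") <- 2L
  out <- relabel_by_variance(raw, F)
  expect_equal(unique(out[1:10]), 2L)
  expect_equal(unique(out[11:22]), 1L)
  # identity when already ordered
  raw2 <- c(rep(1L, 12), rep(2L, 10)); attr(raw2, "k") <- 2L
  F2 <- F[c(11:22, 1:10), ]
  expect_equal(as.integer(relabel_by_variance(raw2, F2)), as.integer(raw2))
})

test_that("relabeled mean variance is non-decreasing in the label", {
  set.seed(5)
  for (rep in 1:5) {
    F <- matrix(rexp(120 * 9, rate = 0.2), ncol = 9)
    colnames(F) <- classqs:::FEATURE_NAMES
    lab <- relabel_by_variance(cluster_segments(F, k = 6, seed = rep), F)
    mv <- vapply(1:6, function(c_) mean(F[lab == c_, "sd"]^2), 0)
    expect_true(all(diff(mv) >= -1e-12))
  }
})

test_that("profiles replace samples by their segment label", {
  seg <- classqs:::segment_list(c(0L, 100L, 150L), 150L)
  lab <- c(3L, 7L); attr(lab, "k") <- 12L
  prof <- build_profiles(list(seg), lab, 150L)
  expect_equal(prof$labels[1, ], rep(c(3L, 7L), c(100, 50)))
  expect_true(all(prof$labels >= 1 & prof$labels <= prof$k))
  # label changes only at segment boundaries
  expect_equal(which(diff(prof$labels[1, ]) != 0), 100L)
  bad <- c(3L, 7L, 9L); attr(bad, "k") <- 12L
  expect_error(build_profiles(list(seg), bad, 150L), "mismatch")
})

test_that("short segments merge into their neighbor before features", {
  seg <- classqs:::segment_list(c(0L, 50L, 52L, 100L), 100L)
  merged <- classqs:::merge_short_segments(seg)
  expect_equal(merged$boundaries, c(0L, 52L, 100L))
  lead <- classqs:::segment_list(c(0L, 2L, 100L), 100L)
  expect_equal(classqs:::merge_short_segments(lead)$boundaries, c(0L, 100L))
})

test_that("SD-only profiles rank segments by variance into k levels", {
  set.seed(6)
  seg <- classqs:::segment_list(seq(0L, 1200L, by = 100L), 1200L)
  sds <- runif(12, 0, 10)
  prof <- sd_profiles(list(seg), sds, 1200L, k = 4L)
  expect_true(all(prof$labels >= 1 & prof$labels <= 4))
  # higher-sd segments never get a lower level
  lev <- prof$labels[1, seq(50, 1150, by = 100)]
  expect_true(all(diff(lev[order(sds)]) >= 0))
})

test_that("discontinuous channels fluctuate more in label than continuous ones", {
  fs <- 250 / 3
  disc <- square_envelope_channel(fs = fs, n_cycles = 15, burst_s = 3, quiet_s = 3,
                                  burst_amp = 50, quiet_amp = 8, seed = 7)
  set.seed(8)
  cont <- 20 * {
    z <- as.numeric(signal::filter(signal::butter(2, c(1, 15) / (fs / 2), "pass"), rnorm(length(disc$x))))
    z / sd(z)
  }
  segs <- lapply(list(disc$x, cont), function(x)
    classqs:::merge_short_segments(segment_channel(x, fs)))
  feats <- do.call(rbind, lapply(1:2, function(i)
    classqs:::channel_feature_matrix(list(disc$x, cont)[[i]], segs[[i]], fs)))
  lab <- relabel_by_variance(cluster_segments(feats, k = 6, seed = 3), feats)
  prof <- build_profiles(segs, lab, length(disc$x))
  fluct <- apply(prof$labels, 1, function(v) sd(diff(v)))
  expect_gt(fluct[1], fluct[2])
})
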