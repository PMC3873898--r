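test_that("feature matrix binds RMSD and H-bond columns against oracles", {
  traj <- make_unfolding_trajectory(unfolding_config(n_frames = 10, seed = 2))
  f <- build_features(traj)
  expect_identical(dim(f), c(10L, 2L))
  expect_equal(unname(f[1, "rmsd"]), 0, tolerance = 1e-9)
  expect_equal(unname(f[, "rmsd"]), rmsd_series(traj, traj$frames[[1]]))
  expect_equal(unname(f[, "hbonds"]),
               vapply(traj$frames, count_mainchain_hbonds, numeric(1)))
})

test_that("k-means recovers separated blobs and honours the edge cases", {
  skip_if_not_installed("mclust")
  blobs <- make_cluster_blobs(rbind(c(0.67, 41), c(1.15, 27), c(1.17, 20)),
                              spreads = c(0.03, 0.03, 0.5), n_per = 40, seed = 1)
  cr <- kmeans_cluster(blobs$points, 3, seed = 1)
  expect_equal(mclust::adjustedRandIndex(cr$labels, blobs$labels), 1.0)

  one <- kmeans_cluster(blobs$points, 1, seed = 1)
  expect_equal(one$centroids[1, ], colMeans(blobs$points), tolerance = 1e-9)

  small <- blobs$points[1:6, ]
  all_k <- kmeans_cluster(small, 6, seed = 1)
  expect_equal(all_k$inertia, 0, tolerance = 1e-9)

  same <- matrix(1, 5, 2)
  expect_error(kmeans_cluster(same, 2, seed = 1), "degenerate")
  expect_error(kmeans_cluster(small, 7, seed = 1), "k <=")

  # determinism given the seed
  cr2 <- kmeans_cluster(blobs$points, 3, seed = 1)
  expect_identical(cr$labels, cr2$labels)
  expect_equal(cr$inertia, cr2$inertia)
})

test_that("silhouettes separate far blobs and vanish at equidistance", {
  blobs <- make_cluster_blobs(rbind(c(0, 0), c(100, 0)), spreads = 1,
                              n_per = 30, seed = 4)
  s <- cluster_silhouette(blobs$points, blobs$labels)
  expect_gt(s$mean, 0.8)
  expect_true(all(s$widths >= -1 & s$widths <= 1))

  pts <- rbind(c(0, 0), c(4, 0), c(2, 0), c(2, 2), c(2, -2))
  lab <- c(1, 1, 1, 2, 2)
  s0 <- cluster_silhouette(pts, lab)
  expect_equal(s0$widths[3], 0, tolerance = 1e-12)

  # relabeling leaves silhouettes unchanged
  relab <- c(2, 2, 2, 1, 1)
  expect_equal(cluster_silhouette(pts, relab)$widths, s0$widths)

  expect_error(cluster_silhouette(pts, rep(1, 5)), "k >= 2")
})

test_that("phase recovery on synthetic multi-phase trajectories", {
  skip_if_not_installed("mclust")
  # three-phase step schedule: native / partially unfolded / unfolded
  counts <- c(rep(122, 20), rep(60, 20), rep(12, 20))
  cfg <- unfolding_config(n_frames = 60, seed = 11, t_loss_ns = 2.5)
  traj <- make_unfolding_trajectory(cfg, counts = counts)
  cr <- cluster_trajectory(traj, k = 3, seed = 11)
  truth <- rep(1:3, each = 20)
  # frames at the phase steps may straddle clusters; the bulk must agree
  expect_gte(mclust::adjustedRandIndex(cr$labels, truth), 0.9)
  # phases in temporal order, one per cluster
  expect_identical(nrow(cr$phases), 3L)
  expect_true(all(diff(cr$phases$start_ps) > 0))
  expect_identical(length(unique(cr$phases$cluster)), 3L)

  # two-phase variant clusters into two phases
  counts2 <- c(rep(122, 25), rep(20, 25))
  traj2 <- make_unfolding_trajectory(unfolding_config(n_frames = 50, seed = 12),
                                     counts = counts2)
  cr2 <- cluster_trajectory(traj2, k = 2, seed = 12)
  expect_identical(nrow(cr2$phases), 2L)

  # constant trajectory has identical features: degenerate for k = 3
  const <- make_unfolding_trajectory(
    unfolding_config(lambda = 0, noise_sigma = 0, n_frames = 8, t_loss_ns = NA))
  expect_error(cluster_trajectory(const, k = 3, seed = 1), "degenerate")
})

test_that("cluster recovery is exact across seeds on well-separated phases", {
  skip_if_not_installed("mclust")
  for (sd in 1:5) {
    blobs <- make_cluster_blobs(rbind(c(0.2, 90), c(0.9, 50), c(1.3, 15)),
                                spreads = 0.02 * c(1, 1, 1), n_per = 30,
                                seed = sd)
    cr <- kmeans_cluster(blobs$points, 3, seed = sd)
    expect_equal(mclust::adjustedRandIndex(cr$labels, blobs$labels), 1.0,
                 label = sprintf("seed %d", sd))
  }
})

test_that("plateau detection isolates flat stretches", {
  t_ps <- seq(0, 10000, by = 50)
  step <- ifelse(t_ps < 5000, 1, 0)
  p <- plateau_detect(t_ps, step, window = 1)
  expect_identical(nrow(p), 2L)
  expect_lt(p$end_ps[1], 5000)
  expect_gt(p$start_ps[2], 4500)

  const <- plateau_detect(t_ps, rep(3, length(t_ps)), window = 1)
  expect_identical(nrow(const), 1L)
  expect_equal(c(const$start_ps, const$end_ps), range(t_ps))

  # pure exponential: no plateau strictly inside the observation window
  y <- exp(-0.3 * t_ps / 1000)
  pe <- plateau_detect(t_ps, y, window = 1, slope_tol = 0.1)
  if (nrow(pe)) {
    expect_true(all(pe$start_ps == t_ps[1] | pe$end_ps == t_ps[length(t_ps)]))
  } else succeed()

  expect_error(plateau_detect(t_ps, y, window = 20), "window")
})

test_that("silhouette scan prefers the true blob count", {
  blobs <- make_cluster_blobs(rbind(c(0, 0), c(10, 0), c(5, 9)),
                              spreads = 0.5, n_per = 25, seed = 6)
  scan <- silhouette_scan(blobs$points, k_range = 2:5, seed = 6)
  expect_identical(scan$k[which.max(scan$mean_silhouette)], 3L)
})
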