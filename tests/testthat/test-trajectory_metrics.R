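test_that("superposition is exact on rigid copies and refuses reflections", {
  set.seed(3)
  X <- matrix(rnorm(30), 10, 3)
  moved <- rigid_transform_frame(cloud_frame(X), seed = 8)
  Y <- atom_coords(moved, "CA")
  expect_lt(superpose(Y, X)$rmsd_nm, 1e-6)

  mirror <- X %*% diag(c(-1, 1, 1))
  expect_gt(superpose(mirror, X)$rmsd_nm, 0.01)

  expect_error(superpose(X[1:5, ], X), "equal-sized")
  line <- cbind(1:10, 0, 0)
  expect_error(superpose(line, line + 1), "collinear")
})

test_that("superposition RMSD agrees with the quaternion-method oracle", {
  set.seed(3)
  for (rep in 1:5) {
    A <- matrix(rnorm(30, sd = 3), 10, 3)
    B <- matrix(rnorm(30, sd = 3), 10, 3)
    expect_equal(superpose(A, B)$rmsd_nm, quaternion_rmsd_nm(A, B),
                 tolerance = 1e-9)
  }
})

test_that("RMSD series starts at zero and ignores rigid tumbling", {
  traj <- make_unfolding_trajectory(unfolding_config(n_frames = 6, seed = 3))
  r <- rmsd_series(traj, traj$frames[[1]])
  expect_equal(r[1], 0, tolerance = 1e-9)

  base <- fix_native()
  tumbling <- new_trajectory(lapply(1:4, function(i) {
    fr <- rigid_transform_frame(base, seed = i)
    fr$time <- (i - 1) * 100
    fr
  }))
  expect_lt(max(rmsd_series(tumbling, base)), 1e-6)
})

test_that("unfolding raises the RMSD plateau above the native level", {
  r <- rmsd_series(fix_traj200(), fix_traj200()$frames[[1]])
  n <- length(r)
  expect_gt(mean(r[(n - 20):n]), mean(r[1:20]))
})

test_that("the all-pairs RMSD matrix is symmetric with exact zeros", {
  traj <- make_unfolding_trajectory(unfolding_config(n_frames = 5, seed = 9))
  frames <- traj$frames
  frames[[3]] <- frames[[2]]; frames[[3]]$time <- frames[[3]]$time + 100
  dup <- new_trajectory(frames)
  m <- rmsd_matrix(dup)
  expect_equal(m, t(m), tolerance = 1e-9)
  expect_equal(diag(m), rep(0, 5))
  expect_lt(m[2, 3], 1e-9)
  # spot-check against direct superpose calls
  ca1 <- atom_coords(dup$frames[[1]], "CA")
  ca5 <- atom_coords(dup$frames[[5]], "CA")
  expect_equal(m[1, 5], superpose(ca1, ca5)$rmsd_nm, tolerance = 1e-12)
})

test_that("radius of gyration matches closed forms and construction targets", {
  one <- cloud_frame(matrix(c(1, 2, 3), 1))
  expect_equal(radius_of_gyration(one), 0)

  two <- cloud_frame(matrix(c(0, 0, 0, 2, 0, 0), 2, byrow = TRUE))
  expect_equal(radius_of_gyration(two), 0.1, tolerance = 1e-12)  # 1 A = 0.1 nm

  set.seed(5)
  cloud <- matrix(rnorm(300), 100, 3)
  ctr <- sweep(cloud, 2, colMeans(cloud))
  cloud <- ctr * 15 / sqrt(mean(rowSums(ctr^2)))   # construct at Rg = 1.5 nm
  expect_equal(radius_of_gyration(cloud_frame(cloud)), 1.5, tolerance = 0.075)

  empty <- fix_native()
  empty$atoms <- empty$atoms[0, ]
  expect_error(radius_of_gyration(empty), "empty")
})

test_that("SASA matches the isolated-sphere closed form and occlusion limits", {
  iso <- cloud_frame(matrix(0, 1, 3))
  a1 <- as.numeric(sasa(iso))
  expect_equal(a1, 4 * pi * (1.70 + 1.4)^2 / 100, tolerance = 0.02 * a1)

  # a caged atom is fully buried
  dirs <- globinmelt:::.sphere_lattice(60) * 2.5
  cage <- cloud_frame(rbind(c(0, 0, 0), dirs))
  per <- attr(sasa(cage), "per_residue")
  expect_lt(per[[1]], 0.05)

  # occlusion monotonicity for two overlapping spheres
  pair <- cloud_frame(matrix(c(0, 0, 0, 1.5, 0, 0), 2, byrow = TRUE))
  expect_lt(as.numeric(sasa(pair)), 2 * a1)

  # lattice convergence: doubling the points changes the total < 1%
  fr <- build_backbone(20)
  s1 <- as.numeric(sasa(fr, sphere_points = 480))
  s2 <- as.numeric(sasa(fr, sphere_points = 960))
  expect_lt(abs(s2 - s1) / s2, 0.01)
})

test_that("contact maps obey the exclusion rule and rigid invariance", {
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(5, 5, 0), c(0, 5, 0))
  fr <- cloud_frame(xyz)
  cm <- contact_map(fr)
  expect_true(cm$contacts[1, 4])              # 7.07 A apart, |i-j| = 3
  expect_false(cm$contacts[1, 3])             # |i-j| = 2: excluded
  expect_true(isSymmetric(cm$contacts))

  moved <- rigid_transform_frame(fr, seed = 2)
  expect_identical(contact_map(moved)$contacts, cm$contacts)
})

test_that("contact similarity is the Jaccard percentage with set decomposition", {
  nat <- contact_map(fix_native())
  self <- contact_similarity(nat, nat)
  expect_equal(self$similarity, 100)
  expect_identical(nrow(self$only_a), 0L)

  mk <- function(pairs, n = 30) {
    m <- matrix(FALSE, n, n)
    for (p in pairs) { m[p[1], p[2]] <- TRUE; m[p[2], p[1]] <- TRUE }
    structure(list(contacts = m, residue_count = n, cutoff = 8, scheme = "CA"),
              class = "contact_map")
  }
  pool <- list()
  for (i in 1:20) for (j in 1:20) if (j - i >= 3) pool <- c(pool, list(c(i, j)))
  shared <- pool[1:91]
  a <- mk(c(shared, pool[92:95]))
  b <- mk(c(shared, pool[96:99]))
  s <- contact_similarity(a, b)
  expect_equal(round(s$similarity, 1), 91.9)   # 91 shared of 99 in the union
  expect_identical(nrow(s$shared), 91L)

  disj <- contact_similarity(mk(pool[1:5]), mk(pool[6:10]))
  expect_equal(disj$similarity, 0)

  expect_error(contact_similarity(nat, mk(pool[1:3])), "residue counts")
})

test_that("heme-iron distance and loss detection follow the threshold rule", {
  native <- fix_native()
  expect_equal(heme_his_distance(native), 0.64, tolerance = 0.01)

  apo <- new_frame(native$atoms, time = 0, heme = NULL)
  expect_error(heme_his_distance(apo), "no heme")

  # schedule crossing the 1.28 nm threshold at frame 37
  sched <- c(rep(0.64, 36), seq(1.30, 2.2, length.out = 6))
  tr <- heme_schedule_traj(sched)
  ev <- detect_heme_loss(tr)
  expect_true(ev$lost)
  expect_equal(ev$first_time, 36 * 100)   # frame 37 at dt = 100 ps

  flat <- heme_schedule_traj(rep(0.64, 10))
  expect_false(detect_heme_loss(flat)$lost)
  expect_true(is.na(detect_heme_loss(flat)$first_time))
})

test_that("heme departure time is recovered within one frame", {
  ev <- detect_heme_loss(fix_traj200())
  expect_true(ev$lost)
  expect_lte(abs(ev$first_time - 3700), 100)
})
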