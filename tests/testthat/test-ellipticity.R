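# Independent inversion oracle: numerically solve the unclamped linear
# forward relation for R with uniroot (never touching the closed form the
# implementation uses).
oracle_invert_R <- function(theta, N_h, k = 2.57, theta_helix = -36800,
                            theta_RC = 1000, N_r = 153) {
  f <- function(R) theta_helix / N_r * (R - k * N_h) +
    theta_RC * (1 - R / N_r) - theta
  uniroot(f, c(-50, 250), tol = 1e-12)$root
}

test_that("forward model matches hand evaluation and its limits", {
  p4 <- ellipticity_params(N_h = 4)
  r <- forward_ellipticity(c(16, 19, 26, 2), p4)
  hand <- -36800 / 153 * ((16 - 2.57) + (19 - 2.57) + (26 - 2.57) + 0) +
    1000 * (1 - 63 / 153)
  expect_equal(r$theta222, hand, tolerance = 1e-12)
  expect_equal(r$f_H, 63 / 153, tolerance = 1e-12)
  expect_equal(round(r$theta222 / 1000) * 1000, -12000)

  # pure random coil
  expect_equal(forward_ellipticity(numeric(0),
                                   ellipticity_params(N_h = 0))$theta222, 1000)
  # infinite-helix limit: one full-length segment, k = 0
  pinf <- ellipticity_params(N_h = 1, k = 0)
  expect_equal(forward_ellipticity(153, pinf)$theta222, -36800)

  expect_error(forward_ellipticity(c(100, 60), ellipticity_params(N_h = 2)),
               "exceed")
})

test_that("inversion matches the reference-state fractions and the oracle", {
  cases <- list(
    list(theta = -24000, N_h = 8, th = -36800, f2 = 0.79),
    list(theta = -12000, N_h = 4, th = -36800, f2 = 0.41),
    list(theta = -5000,  N_h = 2, th = -39500, f2 = 0.18))
  for (cs in cases) {
    p <- ellipticity_params(N_h = cs$N_h, theta_helix = cs$th)
    r <- invert_ellipticity(cs$theta, p)
    expect_equal(round_half_away(r$f_H, 2), cs$f2,
                 label = sprintf("f_H(%g, N_h=%d)", cs$theta, cs$N_h))
    expect_equal(r$helix_residues,
                 oracle_invert_R(cs$theta, cs$N_h, theta_helix = cs$th),
                 tolerance = 1e-9)
  }
  # acid-intermediate residue count and the unrounded holo solution
  r12 <- invert_ellipticity(-12000, ellipticity_params(N_h = 4))
  expect_equal(round_half_away(r12$helix_residues), 63)
  r24 <- invert_ellipticity(-24000, ellipticity_params(N_h = 8))
  expect_equal(r24$helix_residues, 121.2, tolerance = 0.05)

  expect_error(invert_ellipticity(-40000, ellipticity_params(N_h = 8)),
               "range")
  expect_error(invert_ellipticity(2000, ellipticity_params(N_h = 8)),
               "range")
})

test_that("forward and inverse are mutual identities when segments exceed k", {
  p <- ellipticity_params(N_h = 3)
  th <- forward_ellipticity(c(20, 20, 20), p)$theta222
  expect_equal(invert_ellipticity(th, p)$helix_residues, 60, tolerance = 1e-9)

  set.seed(11)
  for (i in 1:50) {
    nh <- sample(1:8, 1)
    segs <- sample(4:18, nh, replace = TRUE)
    k <- runif(1, 0, 3.5)
    thx <- runif(1, -42000, -30000)
    p <- ellipticity_params(N_h = nh, k = k, theta_helix = thx)
    f <- forward_ellipticity(segs, p)
    expect_equal(invert_ellipticity(f$theta222, p)$helix_residues, sum(segs),
                 tolerance = 1e-9)
  }
})

test_that("helix fraction is monotone in ellipticity and in helix number", {
  p8 <- ellipticity_params(N_h = 8)
  f <- vapply(seq(-30000, 0, by = 1000),
              function(th) invert_ellipticity(th, p8)$f_H, numeric(1))
  expect_true(all(diff(f) < 0))  # more negative theta -> larger f_H

  f_nh <- vapply(1:8, function(nh)
    invert_ellipticity(-12000, ellipticity_params(N_h = nh))$f_H, numeric(1))
  expect_true(all(diff(f_nh) > 0))  # fewer helices -> smaller f_H
})

test_that("the reference-state table reproduces both parameter columns", {
  tab <- mb_state_helix_fractions()
  expect_equal(unlist(tab["f_H (-39500)", ], use.names = FALSE),
               c(0.75, 0.59, 0.54, 0.39, 0.18))
  expect_equal(unlist(tab["f_H (-36800)", ], use.names = FALSE),
               c(0.79, 0.63, 0.57, 0.41, 0.19))
  printed <- c(122, 97, 88, 63, 27)
  expect_true(all(abs(unlist(tab["helix residues", ]) - printed) <= 2))
})

test_that("sensitivity grid covers the cross product with correct values", {
  g <- sensitivity_table(c(-24000, -12000), c(8, 4), k_values = c(2.57, 3),
                         theta_helix_values = c(-36800))
  expect_identical(nrow(g), 8L)
  row <- g[g$theta222 == -24000 & g$N_h == 8 & g$k == 2.57, ]
  expect_equal(row$f_H, oracle_invert_R(-24000, 8) / 153, tolerance = 1e-9)
})

test_that("trajectory ellipticity respects the native band and +500 ceiling", {
  native <- fix_native()
  tr <- new_trajectory(list(native, native))
  th <- trajectory_ellipticity(tr)
  expect_lt(th$theta222[1], -20000)
  expect_gt(th$theta222[1], -24000)

  coil <- build_backbone(30, strrep("C", 30), seed = 2)
  thc <- trajectory_ellipticity(new_trajectory(list(coil)))
  expect_equal(thc$theta222, 500)
  expect_equal(thc$theta222_raw, 1000)
})

test_that("ellipticity rises as the synthetic trajectory unfolds", {
  th <- trajectory_ellipticity(fix_traj200())
  n <- nrow(th)
  first_third <- mean(th$theta222[1:floor(n / 3)])
  last_third <- mean(th$theta222[(n - floor(n / 3)):n])
  expect_gt(last_third, first_third + 10000)
})
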