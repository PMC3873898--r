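## Shared fixtures (built once per test run) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, .fixture_cache)) assign(name, build(), .fixture_cache)
  get(name, .fixture_cache)
}

fix_native <- function() cached("native", function() make_native_globin(seed = 1))

## the standard unfolding study conditions: lambda = 0.2/ns, 200 frames over
## 20 ns, heme departure at 3.7 ns, seed 42
fix_traj200 <- function() cached("traj200", function() make_unfolding_trajectory())

fix_ss200 <- function() cached("ss200", function() ss_timeseries(fix_traj200()))

## Ideal two-strand antiparallel hairpin: a 7-residue strand and its copy
## rotated 180 degrees about the strand axis, offset to the hydrogen-bond
## registry found by a one-off deterministic grid search over placements.
make_hairpin <- function() {
  bbA <- globinmelt:::.backbone_from_dihedrals(rep(-139, 7), rep(135, 7))
  ctr <- colMeans(bbA$CA)
  pc <- prcomp(sweep(bbA$CA, 2, ctr))$rotation
  A <- lapply(bbA, function(m) sweep(m, 2, ctr) %*% pc)
  R <- matrix(c(1, 0, 0, 0, -1, 0, 0, 0, -1), 3, byrow = TRUE)  # 180 about x
  B <- lapply(A, function(m) sweep(m %*% t(R), 2, c(2.5, 1, 4.0), "+"))
  bb <- list(N = rbind(A$N, B$N), CA = rbind(A$CA, B$CA),
             C = rbind(A$C, B$C), O = rbind(A$O, B$O))
  globinmelt:::.frame_from_backbone(bb, rep("ALA", 14))
}

## Apply a fixed rigid-body transform (rotation + translation) to a frame.
rigid_transform_frame <- function(frame, seed = 1) {
  set.seed(seed)
  ang <- runif(3, -pi, pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3, byrow = TRUE)
  Ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                 -sin(ang[2]), 0, cos(ang[2])), 3, byrow = TRUE)
  Rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0,
                 sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, byrow = TRUE)
  R <- Rx %*% Ry %*% Rz
  tr <- runif(3, -20, 20)
  move <- function(tab) {
    xyz <- as.matrix(tab[, c("x", "y", "z")]) %*% t(R)
    tab$x <- xyz[, 1] + tr[1]; tab$y <- xyz[, 2] + tr[2]; tab$z <- xyz[, 3] + tr[3]
    tab
  }
  new_frame(move(frame$atoms), time = frame$time,
            heme = if (is.null(frame$heme)) NULL else move(frame$heme))
}

## Independent RMSD oracle: Horn's quaternion method (no SVD, no rotation
## matrix construction).
quaternion_rmsd_nm <- function(mobile, reference) {
  P <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  Q <- sweep(as.matrix(reference), 2, colMeans(reference))
  S <- crossprod(P, Q)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[3, 1] + S[1, 3]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- max(0, (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P))
  sqrt(msd) / 10
}

## Frame holding an arbitrary CA-only point cloud (unit carbon masses).
cloud_frame <- function(xyz, resno = seq_len(nrow(xyz))) {
  new_frame(data.frame(resno = resno, resname = "ALA", chain = "A",
                       name = "CA", elem = "C", mass = 12.011,
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       stringsAsFactors = FALSE))
}

## Trajectory whose heme FE follows an explicit distance schedule (nm) from
## the His93 centre of mass of a fixed native frame.
heme_schedule_traj <- function(dist_nm, dt = 100) {
  base <- fix_native()
  dir <- attr(base, "heme_direction")
  frames <- lapply(seq_along(dist_nm), function(i) {
    hm <- globinmelt:::.place_heme(base, 93, dist_A = dist_nm[i] * 10,
                                   min_sep = 0, direction = dir)
    new_frame(base$atoms, time = (i - 1) * dt, heme = hm)
  })
  new_trajectory(frames)
}
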