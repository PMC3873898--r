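## Structure <-> mean-residue-ellipticity model at 222 nm.
##
## Forward model, for helix segments of r_i residues (i = 1..N_h):
##
##   [theta]_222 = ([theta]_helix / N_r) * sum_i max(r_i - k, 0)
##                 + [theta]_RC * (1 - f_H),        f_H = (sum_i r_i) / N_r
##
## k is the empirical helix-truncation correction (a per-helix residue
## penalty for the reduced CD signal of finite helices), [theta]_helix the
## 222 nm signal of a complete infinite helix, and [theta]_RC the small
## positive random-coil absorption, applied in proportion to the coil
## fraction (1 - f_H). The inverse solves the unclamped linear form
## (all segments assumed longer than k) exactly for the total helical
## residue count R.

#' Round half away from zero
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded values; .5 cases move away from zero (the convention the
#'   printed helix fractions follow), unlike base \code{round}.
#' @export
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Parameters of the ellipticity model
#'
#' @param N_h number of helices (>= 0).
#' @param N_r number of residues in the protein (153 for myoglobin).
#' @param k helix-truncation correction in residues (default 2.57; 3 is the
#'   other commonly used value).
#' @param theta_helix 222 nm signal of a complete infinite helix in
#'   deg cm^2/dmol; -36800 (myoglobin-optimized) or -39500 (general helix).
#' @param theta_RC random-coil signal at 222 nm, deg cm^2/dmol (default +1000).
#' @return object of class \code{"ellipticity_params"}.
#' @export
ellipticity_params <- function(N_h, N_r = 153, k = 2.57,
                               theta_helix = -36800, theta_RC = 1000) {
  stopifnot(N_r >= 1, N_h >= 0, k >= 0, theta_helix < 0)
  structure(list(N_r = as.integer(N_r), N_h = as.integer(N_h), k = k,
                 theta_helix = theta_helix, theta_RC = theta_RC),
            class = "ellipticity_params")
}

#' @export
print.ellipticity_params <- function(x, ...) {
  cat(sprintf(
    "<ellipticity_params> N_r = %d, N_h = %d, k = %.2f, theta_helix = %g, theta_RC = %g\n",
    x$N_r, x$N_h, x$k, x$theta_helix, x$theta_RC))
  invisible(x)
}

.new_ellipticity_result <- function(theta222, R, N_r, N_h) {
  structure(list(theta222 = theta222, f_H = R / N_r, helix_residues = R,
                 N_h_used = N_h), class = "ellipticity_result")
}

#' @export
print.ellipticity_result <- function(x, ...) {
  cat(sprintf(
    "<ellipticity_result> theta222 = %.1f deg cm^2/dmol, f_H = %.4f (%.2f at 2 dp), R = %.2f residues, N_h = %d\n",
    x$theta222, x$f_H, round_half_away(x$f_H, 2), x$helix_residues, x$N_h_used))
  invisible(x)
}

#' Predict mean residue ellipticity from helix segments
#'
#' Forward model: segments contribute \code{max(r_i - k, 0)} helix-signal
#' residues each (segments not longer than k clamp to zero), and the coil
#' fraction contributes \code{theta_RC * (1 - f_H)}.
#'
#' @param segment_lengths integer vector of helix segment lengths r_i
#'   (residues); may be empty for a pure coil.
#' @param params an \code{\link{ellipticity_params}} object; its \code{N_h}
#'   is ignored in favour of \code{length(segment_lengths)}.
#' @return an \code{ellipticity_result} with \code{theta222}, \code{f_H},
#'   \code{helix_residues} and \code{N_h_used}.
#' @export
forward_ellipticity <- function(segment_lengths, params = ellipticity_params(N_h = length(segment_lengths))) {
  if (length(segment_lengths) && any(segment_lengths < 1))
    stop("segment lengths must be >= 1")
  R <- sum(segment_lengths)
  if (R > params$N_r) stop("total helical residues exceed N_r")
  f_H <- R / params$N_r
  theta <- params$theta_helix / params$N_r * sum(pmax(segment_lengths - params$k, 0)) +
    params$theta_RC * (1 - f_H)
  .new_ellipticity_result(theta, R, params$N_r, length(segment_lengths))
}

#' Invert an ellipticity to a helix fraction
#'
#' Solves the unclamped linear form
#' \deqn{\theta = (\theta_{helix}/N_r)(R - k N_h) + \theta_{RC}(1 - R/N_r)}
#' exactly for the total helical residue count R, given the assumed number
#' of helices N_h. This is the correction chain applied to experimental
#' ellipticities of myoglobin states: fewer assumed helices give a smaller
#' helix fraction at the same ellipticity.
#'
#' @param theta222 mean residue ellipticity, deg cm^2/dmol; must lie between
#'   \code{theta_RC} and \code{theta_helix}.
#' @param params an \code{\link{ellipticity_params}} with \code{N_h >= 1}.
#' @return an \code{ellipticity_result}; \code{helix_residues} holds the
#'   exact real solution R. Use \code{round_half_away(x$f_H, 2)} for the
#'   2-decimal fraction and \code{round_half_away(x$helix_residues)} for the
#'   integer residue count as conventionally reported.
#' @export
invert_ellipticity <- function(theta222, params) {
  stopifnot(inherits(params, "ellipticity_params"))
  if (params$N_h < 1) stop("inversion requires N_h >= 1")
  lo <- min(params$theta_helix, params$theta_RC)
  hi <- max(params$theta_helix, params$theta_RC)
  if (theta222 < lo || theta222 > hi)
    stop(sprintf("theta222 = %g outside the invertible range [%g, %g]",
                 theta222, lo, hi))
  R <- (params$N_r * (theta222 - params$theta_RC) +
          params$k * params$N_h * params$theta_helix) /
    (params$theta_helix - params$theta_RC)
  .new_ellipticity_result(theta222, R, params$N_r, params$N_h)
}

#' Helix-fraction sensitivity over a parameter grid
#'
#' Inverts every combination of ellipticity, helix number, truncation
#' correction and infinite-helix signal, returning unrounded and 2-decimal
#' helix fractions. Used to quantify how strongly each model parameter moves
#' the inferred helix content.
#'
#' @param thetas ellipticities to invert (deg cm^2/dmol).
#' @param N_h_values helix numbers.
#' @param k_values truncation corrections.
#' @param theta_helix_values infinite-helix signals.
#' @param N_r residue count (default 153).
#' @param theta_RC random-coil signal (default +1000).
#' @return data.frame over the full grid with columns \code{theta222},
#'   \code{N_h}, \code{k}, \code{theta_helix}, \code{f_H}, \code{f_H_2dp},
#'   \code{helix_residues}.
#' @export
sensitivity_table <- function(thetas, N_h_values, k_values = 2.57,
                              theta_helix_values = c(-39500, -36800),
                              N_r = 153, theta_RC = 1000) {
  stopifnot(length(thetas) > 0, length(N_h_values) > 0,
            length(k_values) > 0, length(theta_helix_values) > 0)
  g <- expand.grid(theta222 = thetas, N_h = N_h_values, k = k_values,
                   theta_helix = theta_helix_values,
                   KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(g)), function(i) {
    p <- ellipticity_params(N_h = g$N_h[i], N_r = N_r, k = g$k[i],
                            theta_helix = g$theta_helix[i], theta_RC = theta_RC)
    invert_ellipticity(g$theta222[i], p)
  })
  g$f_H <- vapply(res, `[[`, numeric(1), "f_H")
  g$f_H_2dp <- round_half_away(g$f_H, 2)
  g$helix_residues <- vapply(res, `[[`, numeric(1), "helix_residues")
  g
}

#' Reference myoglobin states
#'
#' The five experimentally characterised states used throughout the
#' ellipticity analysis: native holomyoglobin, apomyoglobin at pH 7 and 6,
#' the pH 4 acid intermediate, and a late intermediate/unfolded state, each
#' with its measured ellipticity and assumed helix number.
#'
#' @return data.frame with columns \code{state}, \code{theta222}, \code{N_h}.
#' @export
mb_states <- function() {
  data.frame(
    state = c("Holo, pH 7", "Apo, pH 7", "Apo, pH 6", "ApoI, pH 4", "I/U"),
    theta222 = c(-24000, -19000, -17500, -12000, -5000),
    N_h = c(8L, 6L, 5L, 4L, 2L),
    stringsAsFactors = FALSE)
}

#' Helix fractions of the reference myoglobin states
#'
#' Inverts the five reference-state ellipticities under both infinite-helix
#' signals (-39500 general, -36800 myoglobin-optimized) with N_r = 153,
#' k = 2.57 and theta_RC = +1000.
#'
#' @param k truncation correction (default 2.57).
#' @param theta_RC random-coil signal (default +1000).
#' @param N_r residue count (default 153).
#' @return data.frame: one column per state; rows \code{f_H (-39500)},
#'   \code{f_H (-36800)} (2-decimal fractions) and \code{helix residues}
#'   (nearest integer, from the -36800 inversion).
#' @export
mb_state_helix_fractions <- function(k = 2.57, theta_RC = 1000, N_r = 153) {
  st <- mb_states()
  tab <- sensitivity_table(st$theta222, st$N_h, k_values = k,
                           theta_helix_values = c(-39500, -36800),
                           N_r = N_r, theta_RC = theta_RC)
  # the grid is a cross product; keep only the matched (theta, N_h) state rows
  tab <- tab[paste(tab$theta222, tab$N_h) %in% paste(st$theta222, st$N_h), ]
  f39 <- f36 <- rr <- numeric(nrow(st))
  for (i in seq_len(nrow(st))) {
    rows <- tab[tab$theta222 == st$theta222[i] & tab$N_h == st$N_h[i], ]
    f39[i] <- rows$f_H_2dp[rows$theta_helix == -39500]
    f36[i] <- rows$f_H_2dp[rows$theta_helix == -36800]
    rr[i] <- round_half_away(rows$helix_residues[rows$theta_helix == -36800])
  }
  out <- rbind(f39, f36, rr)
  dimnames(out) <- list(c("f_H (-39500)", "f_H (-36800)", "helix residues"),
                        st$state)
  as.data.frame(out)
}

#' Ellipticity time series of a trajectory
#'
#' Per frame: assign secondary structure, extract helix segments, apply the
#' forward model with N_h equal to the number of segments found, and report
#' the ellipticity truncated at +500 on the positive side (the raw value is
#' kept alongside; the truncation reflects the model's limited meaning as
#' the helix count approaches zero and is applied to time series only, never
#' to scalar calls).
#'
#' @param traj an \code{mdtraj} with assignable frames.
#' @param k,theta_helix,theta_RC model parameters (see
#'   \code{\link{ellipticity_params}}).
#' @param helix_classes,min_length passed to \code{\link{helix_segments}}.
#' @param ceiling positive-side truncation of the reported value (+500).
#' @return data.frame with columns \code{time} (ps), \code{theta222}
#'   (truncated), \code{theta222_raw}, \code{f_H}, \code{N_h},
#'   \code{helix_residues}.
#' @export
trajectory_ellipticity <- function(traj, k = 2.57, theta_helix = -36800,
                                   theta_RC = 1000,
                                   helix_classes = c("H", "G", "I"),
                                   min_length = 4, ceiling = 500) {
  N_r <- length(residue_numbers(traj$frames[[1]]))
  rows <- lapply(traj$frames, function(fr) {
    segs <- helix_segments(assign_ss(fr), classes = helix_classes,
                           min_length = min_length)
    p <- ellipticity_params(N_h = nrow(segs), N_r = N_r, k = k,
                            theta_helix = theta_helix, theta_RC = theta_RC)
    r <- forward_ellipticity(segs$length, p)
    data.frame(time = fr$time, theta222 = min(r$theta222, ceiling),
               theta222_raw = r$theta222, f_H = r$f_H,
               N_h = nrow(segs), helix_residues = r$helix_residues)
  })
  do.call(rbind, rows)
}
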