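## Kabsch-Sander electrostatic hydrogen-bond model and secondary-structure
## assignment. Energies in kcal/mol, distances in Angstrom. The dialect is
## simplified where noted: beta-bulges are not merged into ladders, and no
## pi/chirality annotations are produced.

.KS_COUPLING <- 27.888       # 0.084 e^2 * 332, kcal/mol * Angstrom
.KS_CUTOFF <- -0.5           # bond criterion, kcal/mol
.KS_CLASH <- -9.9            # energy assigned when atoms (near-)coincide
.CA_PREFILTER <- 9.0         # Angstrom; loss-free at the -0.5 threshold
.BEND_KAPPA <- 70            # degrees

#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic energy of the interaction between the amide group (N-H) of a
#' donor residue and the carbonyl group (C=O) of an acceptor residue:
#' \deqn{E = 27.888 (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})}
#' with distances in Angstrom and E in kcal/mol. A bond is called when
#' E < -0.5 kcal/mol. If any of the four distances is below 0.5 Angstrom the
#' conventional clash energy -9.9 is returned with a warning.
#'
#' @param donor list with 3-vectors \code{N} and \code{H} (Angstrom).
#' @param acceptor list with 3-vectors \code{C} and \code{O}.
#' @return energy in kcal/mol (unclamped apart from the clash convention).
#' @export
hbond_energy <- function(donor, acceptor) {
  for (nm in c("N", "H")) if (is.null(donor[[nm]])) stop("donor lacks ", nm)
  for (nm in c("C", "O")) if (is.null(acceptor[[nm]])) stop("acceptor lacks ", nm)
  d <- function(a, b) sqrt(sum((a - b)^2))
  r <- c(ON = d(acceptor$O, donor$N), CH = d(acceptor$C, donor$H),
         OH = d(acceptor$O, donor$H), CN = d(acceptor$C, donor$N))
  if (any(r < 0.5)) {
    warning("near-coincident atoms in hydrogen-bond energy; using clash energy -9.9")
    return(.KS_CLASH)
  }
  .KS_COUPLING * (1 / r[["ON"]] + 1 / r[["CH"]] - 1 / r[["OH"]] - 1 / r[["CN"]])
}

## Vectorized energies for index vectors di (donors), ai (acceptors) given
## per-residue coordinate matrices. Returns numeric vector.
.hbond_energy_vec <- function(di, ai, N, H, C, O) {
  dd <- function(A, B) sqrt(rowSums((A - B)^2))
  rON <- dd(O[ai, , drop = FALSE], N[di, , drop = FALSE])
  rCH <- dd(C[ai, , drop = FALSE], H[di, , drop = FALSE])
  rOH <- dd(O[ai, , drop = FALSE], H[di, , drop = FALSE])
  rCN <- dd(C[ai, , drop = FALSE], N[di, , drop = FALSE])
  e <- .KS_COUPLING * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  clash <- rON < 0.5 | rCH < 0.5 | rOH < 0.5 | rCN < 0.5
  e[clash] <- .KS_CLASH   # silent in the bulk path; scalar hbond_energy warns
  e
}

## Frame -> per-residue backbone coordinate matrices, placing amide H if the
## frame has none (prolines and residue 1 never carry H).
.backbone_matrices <- function(frame) {
  if (!any(frame$atoms$name == "H")) frame <- add_amide_hydrogens(frame)
  list(N = atom_coords(frame, "N"), H = atom_coords(frame, "H"),
       C = atom_coords(frame, "C"), O = atom_coords(frame, "O"),
       CA = atom_coords(frame, "CA"))
}

#' Detect main-chain hydrogen bonds in a frame
#'
#' Evaluates the Kabsch-Sander energy for every ordered (donor, acceptor)
#' residue pair with sequence separation |i-j| >= 2 whose CA atoms lie within
#' 9.0 Angstrom (a loss-free prefilter at the -0.5 kcal/mol criterion), and
#' keeps at most the two lowest-energy acceptors per donor. Amide hydrogens
#' are placed by \code{\link{add_amide_hydrogens}} if absent.
#'
#' @param frame an \code{mdframe}.
#' @param prefilter CA-CA distance cutoff in Angstrom (set \code{Inf} for an
#'   exhaustive all-pairs search; used by the internal consistency checks).
#' @return data.frame with columns \code{donor}, \code{acceptor} (1-based
#'   residue positions, NH side and C=O side) and \code{energy} (kcal/mol),
#'   all rows satisfying energy < -0.5.
#' @export
detect_hbonds <- function(frame, prefilter = .CA_PREFILTER) {
  bb <- .backbone_matrices(frame)
  n <- nrow(bb$CA)
  empty <- data.frame(donor = integer(0), acceptor = integer(0),
                      energy = numeric(0))
  if (n < 3) return(empty)
  donors <- which(!is.na(bb$N[, 1]) & !is.na(bb$H[, 1]))
  acceptors <- which(!is.na(bb$C[, 1]) & !is.na(bb$O[, 1]))
  if (!length(donors) || !length(acceptors)) return(empty)
  pairs <- expand.grid(donor = donors, acceptor = acceptors)
  pairs <- pairs[abs(pairs$donor - pairs$acceptor) >= 2, , drop = FALSE]
  if (is.finite(prefilter)) {
    ok <- !is.na(bb$CA[pairs$donor, 1]) & !is.na(bb$CA[pairs$acceptor, 1])
    pairs <- pairs[ok, , drop = FALSE]
    dca <- sqrt(rowSums((bb$CA[pairs$donor, , drop = FALSE] -
                         bb$CA[pairs$acceptor, , drop = FALSE])^2))
    pairs <- pairs[dca <= prefilter, , drop = FALSE]
  }
  if (!nrow(pairs)) return(empty)
  e <- .hbond_energy_vec(pairs$donor, pairs$acceptor, bb$N, bb$H, bb$C, bb$O)
  keep <- e < .KS_CUTOFF
  out <- data.frame(donor = pairs$donor[keep], acceptor = pairs$acceptor[keep],
                    energy = e[keep])
  if (!nrow(out)) return(empty)
  # at most the two best (lowest-energy) acceptors per donor
  out <- out[order(out$donor, out$energy), , drop = FALSE]
  out <- do.call(rbind, lapply(split(out, out$donor), head, 2L))
  rownames(out) <- NULL
  out
}

#' Count main-chain hydrogen bonds
#'
#' Cardinality of \code{\link{detect_hbonds}} output; one of the two reaction
#' coordinates used for intermediate detection.
#'
#' @inheritParams detect_hbonds
#' @return integer bond count.
#' @export
count_mainchain_hbonds <- function(frame) nrow(detect_hbonds(frame))

#' Assign per-residue secondary structure (Kabsch-Sander)
#'
#' From the detected main-chain hydrogen bonds: an n-turn at i is a bond from
#' the carbonyl of residue i to the amide of residue i+n (n = 3, 4, 5); two
#' consecutive n-turns at i-1 and i define a minimal helix at i..i+n-1 (codes
#' G/H/I for n = 3/4/5). Parallel and antiparallel bridges follow the
#' Kabsch-Sander patterns; an isolated bridge is B, two or more consecutive
#' bridges form a ladder coded E. T marks turn residues not already in a
#' helix, S marks bends (CA virtual angle over i-2, i, i+2 above 70 degrees).
#' Priority on conflict: H > E > B > G > I > T > S; remaining residues are C.
#'
#' @param frame an \code{mdframe} that passes \code{\link{validate_backbone}}.
#' @return object of class \code{"ss_assignment"}: list with \code{codes}
#'   (character vector over \{H,G,I,E,B,T,S,C\}) and \code{frame_time} (ps).
#' @export
assign_ss <- function(frame) {
  rep <- validate_backbone(frame)
  if (!attr(rep, "assignable"))
    stop("frame not assignable; incomplete backbone at residue(s): ",
         paste(rep$resno, collapse = ", "))
  bb <- .backbone_matrices(frame)
  n <- nrow(bb$CA)
  hb <- detect_hbonds(frame)
  # HB[i, j]: carbonyl of i bonds the amide of j
  HB <- matrix(FALSE, n, n)
  if (nrow(hb)) HB[cbind(hb$acceptor, hb$donor)] <- TRUE

  codes <- rep("C", n)
  put <- function(idx, sym) codes[idx] <<- sym   # caller layers low -> high

  # bends (lowest priority)
  if (n >= 5) {
    i <- 3:(n - 2)
    v1 <- bb$CA[i, , drop = FALSE] - bb$CA[i - 2, , drop = FALSE]
    v2 <- bb$CA[i + 2, , drop = FALSE] - bb$CA[i, , drop = FALSE]
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    kappa <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    put(i[!is.na(kappa) & kappa > .BEND_KAPPA], "S")
  }

  # n-turns; remember turn flags for helices, mark T on intervening residues
  turns <- list()
  for (nn in 3:5) {
    t_at <- if (n > nn) which(HB[cbind(1:(n - nn), (1 + nn):n)]) else integer(0)
    turns[[as.character(nn)]] <- t_at
    for (i in t_at) put((i + 1):(i + nn - 1), "T")
  }

  # helices, applied in priority order I < G < (bridges) < H below
  helix_residues <- function(nn) {
    t_at <- turns[[as.character(nn)]]
    starts <- t_at[(t_at - 1) %in% t_at]   # turns at i-1 and i
    unique(unlist(lapply(starts, function(i) i:(i + nn - 1))))
  }
  put(helix_residues(5), "I")
  put(helix_residues(3), "G")

  # bridges (Kabsch-Sander patterns), |i-j| >= 3
  hbond <- function(i, j) {
    ok <- i >= 1 & i <= n & j >= 1 & j <= n
    out <- logical(length(i))
    out[ok] <- HB[cbind(i[ok], j[ok])]
    out
  }
  if (n >= 5) {
    pr <- expand.grid(i = 2:(n - 1), j = 2:(n - 1))
    pr <- pr[pr$j - pr$i >= 3, , drop = FALSE]
    para <- (hbond(pr$i - 1, pr$j) & hbond(pr$j, pr$i + 1)) |
            (hbond(pr$j - 1, pr$i) & hbond(pr$i, pr$j + 1))
    anti <- (hbond(pr$i, pr$j) & hbond(pr$j, pr$i)) |
            (hbond(pr$i - 1, pr$j + 1) & hbond(pr$j - 1, pr$i + 1))
    br <- pr[para | anti, , drop = FALSE]
    if (nrow(br)) {
      key <- paste(br$i, br$j)
      in_ladder <- vapply(seq_len(nrow(br)), function(r) {
        i <- br$i[r]; j <- br$j[r]
        any(c(paste(i + 1, j + 1), paste(i + 1, j - 1),
              paste(i - 1, j - 1), paste(i - 1, j + 1)) %in% key)
      }, logical(1))
      put(unique(c(br$i[!in_ladder], br$j[!in_ladder])), "B")
      put(unique(c(br$i[in_ladder], br$j[in_ladder])), "E")
    }
  }

  put(helix_residues(4), "H")

  structure(list(codes = codes, frame_time = frame$time),
            class = "ss_assignment")
}

#' @export
print.ss_assignment <- function(x, ...) {
  cat(sprintf("<ss_assignment> t = %g ps\n%s\n", x$frame_time,
              paste(x$codes, collapse = "")))
  invisible(x)
}

#' Extract maximal helix segments from an assignment
#'
#' Maximal runs of residues whose code belongs to \code{classes}; runs
#' shorter than \code{min_length} (default 4, one full alpha turn) are
#' discarded as noise for the per-helix truncation correction of the
#' ellipticity model.
#'
#' @param assign an \code{ss_assignment} (or bare character vector of codes).
#' @param classes helix codes to count, subset of c("H","G","I").
#' @param min_length minimum run length retained.
#' @return data.frame with columns \code{start}, \code{end} (inclusive,
#'   1-based residue positions), \code{length} and \code{class} (most common
#'   code in the run). The number of rows is the helix count N_h.
#' @export
helix_segments <- function(assign, classes = c("H", "G", "I"), min_length = 4) {
  codes <- if (inherits(assign, "ss_assignment")) assign$codes else assign
  r <- rle(codes %in% classes)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  segs <- data.frame(start = starts[keep], end = ends[keep],
                     length = r$lengths[keep], stringsAsFactors = FALSE)
  segs$class <- vapply(seq_len(nrow(segs)), function(k) {
    names(which.max(table(codes[segs$start[k]:segs$end[k]])))
  }, character(1))
  segs
}

#' Secondary structure over a whole trajectory
#'
#' Assigns every frame and collects a residue-by-frame raster of codes plus
#' per-frame counts: helical residues (codes in \code{helix_classes}), sheet
#' residues (E + B) and main-chain hydrogen bonds.
#'
#' @param traj an \code{mdtraj} with assignable frames.
#' @param helix_classes codes counted as helical (default H, G and I; set
#'   \code{"H"} to count strict alpha helix only).
#' @return object of class \code{"ss_timeseries"}: list with \code{raster}
#'   (character matrix, residues x frames), \code{time} (ps),
#'   \code{helix_count}, \code{sheet_count}, \code{hbond_count}.
#' @export
ss_timeseries <- function(traj, helix_classes = c("H", "G", "I")) {
  nf <- length(traj$frames)
  nres <- length(residue_numbers(traj$frames[[1]]))
  raster <- matrix("C", nres, nf)
  helix <- sheet <- hbonds <- integer(nf)
  for (k in seq_len(nf)) {
    fr <- traj$frames[[k]]
    a <- assign_ss(fr)
    raster[, k] <- a$codes
    helix[k] <- sum(a$codes %in% helix_classes)
    sheet[k] <- sum(a$codes %in% c("E", "B"))
    hbonds[k] <- count_mainchain_hbonds(fr)
  }
  structure(list(raster = raster, time = frame_times(traj),
                 helix_count = helix, sheet_count = sheet,
                 hbond_count = hbonds),
            class = "ss_timeseries")
}

#' @export
print.ss_timeseries <- function(x, ...) {
  cat(sprintf("<ss_timeseries> %d residues x %d frames; helix %d..%d, H-bonds %d..%d\n",
              nrow(x$raster), ncol(x$raster),
              min(x$helix_count), max(x$helix_count),
              min(x$hbond_count), max(x$hbond_count)))
  invisible(x)
}

#' Write the residue-by-frame code raster as plain text
#'
#' One text row per residue, one character per frame.
#'
#' @param x an \code{ss_timeseries}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_ss_raster <- function(x, path) {
  writeLines(apply(x$raster, 1, paste, collapse = ""), path)
  invisible(path)
}

#' Fit an exponential decay to a count series
#'
#' Least-squares fit of \eqn{N(t) = offset + (N_0 - offset) e^{-\lambda t}}
#' with t in ns, as used to summarise the exponential loss of helix structure
#' during thermal unfolding. The initializer is fixed (offset from the series
#' minimum, N0 from the first value, lambda from a log-linear comparison of
#' the first and last thirds) so the fit is deterministic given the data.
#'
#' @param times times in ps.
#' @param counts non-negative counts (helical residues, H-bonds, ...).
#' @return object of class \code{"decay_fit"}: list with \code{N0},
#'   \code{lambda} (1/ns), \code{offset}, \code{fitted}, \code{degenerate}
#'   flag, and the data. \code{coef}, \code{predict}, \code{print} methods.
#' @export
fit_exponential_decay <- function(times, counts) {
  stopifnot(length(times) == length(counts), length(times) >= 5,
            all(counts >= 0))
  t_ns <- times / 1000
  if (diff(range(counts)) < .Machine$double.eps^0.5) {
    fit <- list(N0 = counts[1], lambda = 0, offset = counts[1],
                fitted = counts, degenerate = TRUE,
                time_ns = t_ns, counts = counts)
    return(structure(fit, class = "decay_fit"))
  }
  off0 <- min(counts)
  n00 <- counts[1]
  third <- max(2L, floor(length(counts) / 3))
  y1 <- mean(counts[seq_len(third)]) - off0
  y2 <- mean(counts[seq(length(counts) - third + 1, length(counts))]) - off0
  t1 <- mean(t_ns[seq_len(third)])
  t2 <- mean(t_ns[seq(length(counts) - third + 1, length(counts))])
  eps <- max(1e-3, 1e-3 * abs(n00 - off0))
  lam0 <- (log(max(y1, eps)) - log(max(y2, eps))) / max(t2 - t1, 1e-9)
  lam0 <- max(lam0, 1e-3)
  dat <- data.frame(t = t_ns, y = counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ offset + (N0 - offset) * exp(-lambda * t),
                      data = dat,
                      start = list(offset = off0, N0 = n00, lambda = lam0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    obj <- function(p) sum((counts - (p[1] + (p[2] - p[1]) * exp(-p[3] * t_ns)))^2)
    op <- optim(c(off0, n00, lam0), obj, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-12))
    p <- op$par
    co <- c(offset = p[1], N0 = p[2], lambda = p[3])
  } else co <- coef(fit)
  fitted <- co[["offset"]] + (co[["N0"]] - co[["offset"]]) * exp(-co[["lambda"]] * t_ns)
  structure(list(N0 = co[["N0"]], lambda = co[["lambda"]],
                 offset = co[["offset"]], fitted = fitted,
                 degenerate = FALSE, time_ns = t_ns, counts = counts),
            class = "decay_fit")
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(N0 = object$N0, lambda = object$lambda, offset = object$offset)
}

#' @export
predict.decay_fit <- function(object, times = NULL, ...) {
  t_ns <- if (is.null(times)) object$time_ns else times / 1000
  object$offset + (object$N0 - object$offset) * exp(-object$lambda * t_ns)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> N0 = %.2f, lambda = %.4f 1/ns, offset = %.2f%s\n",
              x$N0, x$lambda, x$offset,
              if (x$degenerate) " (degenerate: constant series)" else ""))
  invisible(x)
}
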