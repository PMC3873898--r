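## Atomic masses (Da) for the elements that occur in backbone + heme models.
## Masses only enter centre-of-mass / radius-of-gyration weighting.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  FE = 55.845, P = 30.974
)

#' Look up atomic masses by element symbol
#'
#' Unknown elements fall back to 12.0 Da with a warning; masses only affect
#' mass-weighted quantities (centre of mass, radius of gyration).
#'
#' @param elem character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in Da.
#' @keywords internal
element_mass <- function(elem) {
  key <- toupper(trimws(elem))
  m <- .element_masses[key]
  unknown <- is.na(m)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(key[unknown]), collapse = ", "),
            "; using 12.0 Da")
    m[unknown] <- 12.0
  }
  unname(m)
}

#' Construct a trajectory frame
#'
#' A frame holds one set of coordinates: a protein atom table and an optional
#' heme group (HETATM residue \code{HEM}, which must contain an \code{FE}
#' atom). Coordinates are stored in Angstrom throughout the package; paper-
#' facing distances (heme loss, RMSD, radius of gyration) are reported in nm
#' at the API boundary.
#'
#' @param atoms data.frame with columns \code{resno}, \code{resname},
#'   \code{chain}, \code{name}, \code{elem}, \code{mass}, \code{x}, \code{y},
#'   \code{z}. Protein (ATOM) records only.
#' @param time frame time in ps (>= 0).
#' @param heme optional data.frame with the same columns for the heme group.
#' @return object of class \code{"mdframe"}.
#' @export
new_frame <- function(atoms, time = 0, heme = NULL) {
  stopifnot(is.data.frame(atoms), time >= 0)
  need <- c("resno", "resname", "chain", "name", "elem", "mass", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  if (any(atoms$mass <= 0)) stop("non-positive atomic mass")
  if (any(!nzchar(atoms$name))) stop("empty atom name")
  if (is.unsorted(atoms$resno)) stop("residue indices must be non-decreasing")
  if (!is.null(heme)) {
    if (!"FE" %in% toupper(heme$name)) stop("heme group lacks an FE atom")
  }
  structure(list(time = as.numeric(time), atoms = atoms, heme = heme),
            class = "mdframe")
}

#' Construct a trajectory
#'
#' @param frames list of \code{mdframe} objects with non-decreasing times and
#'   identical residue numbering.
#' @param temperature metadata label in K (the simulation temperature the
#'   frames came from); not used in any computation.
#' @param source free-text provenance label.
#' @return object of class \code{"mdtraj"}.
#' @export
new_trajectory <- function(frames, temperature = NA_real_, source = "") {
  stopifnot(length(frames) >= 1)
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (is.unsorted(times)) stop("frame times must be non-decreasing")
  res0 <- residue_numbers(frames[[1]])
  for (f in frames[-1]) {
    if (!identical(residue_numbers(f), res0))
      stop("all frames must share residue count and ordering")
  }
  structure(list(frames = frames, temperature = temperature, source = source),
            class = "mdtraj")
}

#' @export
print.mdframe <- function(x, ...) {
  cat(sprintf("<mdframe> t = %g ps, %d residues, %d atoms%s\n",
              x$time, length(residue_numbers(x)), nrow(x$atoms),
              if (!is.null(x$heme)) ", heme present" else ""))
  invisible(x)
}

#' @export
print.mdtraj <- function(x, ...) {
  f1 <- x$frames[[1]]
  cat(sprintf("<mdtraj> %d frames, %d residues, t = %g..%g ps%s\n",
              length(x$frames), length(residue_numbers(f1)),
              x$frames[[1]]$time, x$frames[[length(x$frames)]]$time,
              if (!is.null(f1$heme)) ", heme present" else ""))
  if (!is.na(x$temperature)) cat(sprintf("  temperature label: %g K\n", x$temperature))
  invisible(x)
}

#' @export
length.mdtraj <- function(x) length(x$frames)

#' @export
`[.mdtraj` <- function(x, i) {
  new_trajectory(x$frames[i], temperature = x$temperature, source = x$source)
}

#' Residue numbers of a frame
#' @param frame an \code{mdframe}.
#' @return integer vector of distinct residue numbers, in order.
#' @export
residue_numbers <- function(frame) unique(frame$atoms$resno)

#' Frame times of a trajectory
#' @param traj an \code{mdtraj}.
#' @return numeric vector of times in ps.
#' @export
frame_times <- function(traj) vapply(traj$frames, `[[`, numeric(1), "time")

#' Per-residue coordinates of one named backbone atom
#'
#' @param frame an \code{mdframe}.
#' @param name atom name (e.g. \code{"CA"}, \code{"N"}).
#' @return n_residue x 3 matrix in Angstrom; rows are NA where the residue
#'   lacks that atom.
#' @export
atom_coords <- function(frame, name = "CA") {
  res <- residue_numbers(frame)
  sel <- frame$atoms$name == name
  out <- matrix(NA_real_, length(res), 3,
                dimnames = list(res, c("x", "y", "z")))
  idx <- match(res, frame$atoms$resno[sel])
  hit <- !is.na(idx)
  out[hit, ] <- as.matrix(frame$atoms[sel, c("x", "y", "z")])[idx[hit], , drop = FALSE]
  out
}

.PDB_COORD_MAX <- 9999.999

#' Read a multi-model PDB file as a trajectory
#'
#' One frame per MODEL record (a single un-modelled structure yields one
#' frame). ATOM records become protein residues; a HETATM residue named
#' \code{HEM} becomes the frame's heme group. Alternate locations other than
#' ''/'A' are dropped, insertion codes are rejected, and multi-chain protein
#' input is an error (the intended systems are monomeric globins). Frame time
#' is taken from a \code{REMARK ... TIME: <t> PS} tag inside each MODEL block
#' when present, else MODEL serial x \code{dt}.
#'
#' @param path PDB file path.
#' @param dt time step in ps used when no REMARK time tags exist (default 1).
#' @param temperature optional temperature metadata label (K).
#' @return an \code{mdtraj}.
#' @export
read_pdb_models <- function(path, dt = 1, temperature = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes are not supported")
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  xyz <- pdb$xyz[, as.vector(rbind(3 * which(keep) - 2,
                                   3 * which(keep) - 1,
                                   3 * which(keep))), drop = FALSE]
  if (!all(is.finite(xyz))) stop("malformed or missing coordinate fields")

  is_hem <- at$type == "HETATM" & at$resid == "HEM"
  prot <- at$type == "ATOM"
  if (length(unique(at$chain[prot])) > 1)
    stop("multi-chain protein input is not supported")

  times <- .scan_model_times(path, dt)
  nf <- nrow(xyz)
  if (length(times) != nf) times <- seq_len(nf) * dt

  mk_tab <- function(rows, coords) {
    data.frame(resno = at$resno[rows], resname = at$resid[rows],
               chain = at$chain[rows], name = trimws(at$elety[rows]),
               elem = toupper(trimws(at$elesy[rows])),
               mass = element_mass(at$elesy[rows]),
               x = coords[, 1], y = coords[, 2], z = coords[, 3],
               stringsAsFactors = FALSE)
  }
  frames <- vector("list", nf)
  for (i in seq_len(nf)) {
    cm <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    heme <- if (any(is_hem)) mk_tab(which(is_hem), cm[is_hem, , drop = FALSE]) else NULL
    frames[[i]] <- new_frame(mk_tab(which(prot), cm[prot, , drop = FALSE]),
                             time = times[i], heme = heme)
  }
  new_trajectory(frames, temperature = temperature, source = path)
}

## Per-model times from REMARK TIME tags; returns numeric(0) if absent.
.scan_model_times <- function(path, dt) {
  lines <- readLines(path, warn = FALSE)
  model_at <- grep("^MODEL", lines)
  if (!length(model_at)) {
    t0 <- .remark_time(lines)
    return(if (is.na(t0)) dt else t0)
  }
  serial <- suppressWarnings(as.integer(substr(lines[model_at], 7, 14)))
  serial[is.na(serial)] <- seq_along(serial)[is.na(serial)]
  ends <- c(model_at[-1] - 1L, length(lines))
  times <- numeric(length(model_at))
  for (i in seq_along(model_at)) {
    tt <- .remark_time(lines[model_at[i]:ends[i]])
    times[i] <- if (is.na(tt)) serial[i] * dt else tt
  }
  times
}

.remark_time <- function(lines) {
  hit <- grep("^REMARK.*TIME[ =:]", lines, value = TRUE, ignore.case = TRUE)
  if (!length(hit)) return(NA_real_)
  s <- sub(".*TIME[ =:]+", "", hit[1], ignore.case = TRUE)
  m <- regmatches(s, regexpr("[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?", s))
  if (!length(m)) NA_real_ else as.numeric(m)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Emits standard fixed-width records: one MODEL/ENDMDL block per frame with
#' a \code{REMARK 250 TIME:} tag (so times survive a round trip), TER after
#' the protein chain, and HETATM records for the heme group.
#'
#' @param traj an \code{mdtraj}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_pdb_models <- function(traj, path) {
  stopifnot(inherits(traj, "mdtraj"), length(traj$frames) >= 1)
  con <- file(path, "w")
  on.exit(close(con))
  fmt_rec <- function(type, serial, tab, i) {
    xyz <- c(tab$x[i], tab$y[i], tab$z[i])
    if (any(abs(xyz) > .PDB_COORD_MAX))
      stop("coordinate exceeds the PDB fixed-width field (|x| > 9999.999 A)")
    nm <- tab$name[i]
    # columns 13-16: element-aligned name padding as in standard PDB
    nm_fmt <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
    if (nchar(tab$elem[i]) >= 2) nm_fmt <- sprintf("%-4s", substr(nm, 1, 4))
    sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            type, serial %% 100000L, nm_fmt, tab$resname[i],
            substr(tab$chain[i], 1, 1), tab$resno[i],
            xyz[1], xyz[2], xyz[3], tab$elem[i])
  }
  for (k in seq_along(traj$frames)) {
    fr <- traj$frames[[k]]
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf("REMARK 250 TIME: %.4f PS", fr$time), con)
    serial <- 0L
    lines <- character(nrow(fr$atoms))
    for (i in seq_len(nrow(fr$atoms))) {
      serial <- serial + 1L
      lines[i] <- fmt_rec("ATOM", serial, fr$atoms, i)
    }
    writeLines(lines, con)
    writeLines("TER", con)
    if (!is.null(fr$heme)) {
      hl <- character(nrow(fr$heme))
      for (i in seq_len(nrow(fr$heme))) {
        serial <- serial + 1L
        hl[i] <- fmt_rec("HETATM", serial, fr$heme, i)
      }
      writeLines(hl, con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Report missing backbone atoms per residue
#'
#' A frame is "assignable" (usable for secondary-structure assignment) iff no
#' interior residue lacks any of N, CA, C, O.
#'
#' @param frame an \code{mdframe}.
#' @return data.frame with columns \code{resno} and \code{missing}
#'   (comma-separated atom names), plus attribute \code{assignable}.
#' @export
validate_backbone <- function(frame) {
  res <- residue_numbers(frame)
  roles <- c("N", "CA", "C", "O")
  have <- sapply(roles, function(nm) !is.na(atom_coords(frame, nm)[, 1]))
  miss_list <- apply(have, 1, function(ok) paste(roles[!ok], collapse = ","))
  bad <- which(nzchar(miss_list))
  rep <- data.frame(resno = res[bad], missing = miss_list[bad],
                    row.names = NULL, stringsAsFactors = FALSE)
  interior <- bad[bad > 1 & bad < length(res)]
  attr(rep, "assignable") <- length(interior) == 0 &&
    all(have[-c(1, nrow(have)), , drop = FALSE])
  rep
}

#' Place amide hydrogens by the Kabsch-Sander rule
#'
#' For each residue i >= 2 that is not a proline, the amide H is placed at
#' N_i + u where u is the unit vector from the preceding carbonyl oxygen to
#' the preceding carbonyl carbon, scaled to 1.00 Angstrom (the geometry the
#' electrostatic hydrogen-bond energy expects). Residue 1 and prolines get no
#' H. Re-running replaces previously placed H atoms (idempotent).
#'
#' @param frame an \code{mdframe} with complete backbone where H is wanted.
#' @return the frame with \code{H} atoms inserted; residues skipped for
#'   missing predecessor atoms are listed in attribute \code{"skipped"}.
#' @export
add_amide_hydrogens <- function(frame) {
  at <- frame$atoms[frame$atoms$name != "H", , drop = FALSE]
  fr <- frame
  fr$atoms <- at
  res <- residue_numbers(fr)
  N <- atom_coords(fr, "N"); C <- atom_coords(fr, "C"); O <- atom_coords(fr, "O")
  resname <- at$resname[match(res, at$resno)]
  skipped <- integer(0)
  hrows <- vector("list", length(res))
  for (i in seq_along(res)[-1]) {
    if (resname[i] == "PRO") next
    v <- C[i - 1, ] - O[i - 1, ]
    if (any(is.na(v)) || any(is.na(N[i, ]))) { skipped <- c(skipped, res[i]); next }
    h <- N[i, ] + v / sqrt(sum(v^2))
    hrows[[i]] <- data.frame(resno = res[i], resname = resname[i],
                             chain = at$chain[1], name = "H", elem = "H",
                             mass = .element_masses[["H"]],
                             x = h[1], y = h[2], z = h[3],
                             stringsAsFactors = FALSE)
  }
  htab <- do.call(rbind, hrows)
  if (!is.null(htab)) {
    at <- rbind(at, htab)
    at <- at[order(match(at$resno, res)), , drop = FALSE]
    rownames(at) <- NULL
  }
  out <- new_frame(at, time = frame$time, heme = frame$heme)
  attr(out, "skipped") <- skipped
  out
}
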