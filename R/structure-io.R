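#' Read a multi-model PDB file as a trajectory
#'
#' The canonical desk-scale trajectory carrier: one \code{MODEL} per frame,
#' standard fixed-column coordinates (3 decimals, Angstrom). A single
#' structure PDB without \code{MODEL} records yields a one-frame trajectory.
#' The topology is taken from the first model; every model must present the
#' same number of atoms. Parsing itself is delegated to
#' \code{bio3d::read.pdb}; a light pre-scan enforces the per-model atom-count
#' contract with an error naming the offending model. PDB files carry no time
#' axis, so \code{times_ps} defaults to the frame index.
#'
#' @param path path to a PDB file.
#' @return an [MDTrajectory-class]
#' @seealso [writeMultimodelPDB], [readXYZTrajectory]
#' @export
readMultimodelPDB <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  isAtom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(isAtom)) stopf("parse error: no ATOM/HETATM records in %s", path)
  modelStarts <- which(rec == "MODEL ")
  if (length(modelStarts) > 1L) {
    modelNo <- cumsum(rec == "MODEL ")
    counts <- table(modelNo[isAtom])
    if (length(unique(counts)) > 1L) {
      bad <- names(counts)[counts != counts[1L]][1L]
      stopf("structural error: MODEL %s has %d atoms, expected %d",
            bad, counts[[bad]], counts[[1L]])
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  chain <- ifelse(is.na(at$chain) | !nzchar(at$chain), " ", at$chain)
  elesy <- at$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, nrow(at))
  elesy <- ifelse(is.na(elesy) | !nzchar(elesy),
                  substr(gsub("[0-9]", "", at$elety), 1, 1), elesy)
  topo <- newTopology(at$eleno, at$elety, at$resid, chain, at$resno, elesy)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  na <- nAtoms(topo)
  co <- array(0, dim = c(nf, na, 3L))
  for (k in 1:3) co[, , k] <- xyz[, seq(k, 3L * na, by = 3L), drop = FALSE]
  newTrajectory(topo, co)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One \code{MODEL} per frame, via \code{bio3d::write.pdb}. Coordinates are
#' written at standard PDB precision (3 decimals), which bounds the
#' round-trip error of [readMultimodelPDB] at 5e-4 Angstrom.
#'
#' @param traj an [MDTrajectory-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMultimodelPDB <- function(traj, path) {
  stopifnot(is(traj, "MDTrajectory"))
  a <- atoms(traj)
  nf <- nFrames(traj)
  na <- nAtoms(traj)
  xyz <- matrix(0, nrow = nf, ncol = 3L * na)
  for (k in 1:3) xyz[, seq(k, 3L * na, by = 3L)] <- traj@coords[, , k]
  bio3d::write.pdb(file = path, xyz = xyz, eleno = a$serial,
                   elety = a$atom_name, resid = a$residue_name,
                   chain = a$chain_id, resno = a$residue_number,
                   elesy = a$element)
  invisible(path)
}

#' Read an XYZ trajectory file
#'
#' Plain-text XYZ trajectory: per frame an atom-count line, a comment line
#' (parsed for \code{t=<ps>}; otherwise the frame index is used as time) and
#' one \code{name x y z} line per atom, in topology order. Atom counts must
#' match the supplied topology.
#'
#' @param path path to an XYZ trajectory file.
#' @param topology the [MDTopology-class] describing the atom order.
#' @return an [MDTrajectory-class]
#' @export
readXYZTrajectory <- function(path, topology) {
  stopifnot(is(topology, "MDTopology"))
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  na <- nAtoms(topology)
  frames <- list()
  times <- numeric(0)
  i <- 1L
  f <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stopf("parse error: bad atom-count line at frame %d", f)
    if (n != na)
      stopf("structural error: frame %d has %d atoms, topology has %d",
            f, n, na)
    if (i + 1L + n > length(lines))
      stopf("parse error: truncated frame %d", f)
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexec("t=\\s*([-0-9.eE+]+)", comment))[[1]]
    times <- c(times, if (length(tm) == 2L) as.numeric(tm[2]) else f)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, 0L) < 4L)
    if (length(bad))
      stopf("parse error: malformed atom line %d of frame %d", bad[1L], f)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stopf("parse error: non-numeric coordinate in frame %d", f)
    frames[[f + 1L]] <- xyz
    f <- f + 1L
    i <- i + 2L + n
  }
  if (f == 0L) stopf("parse error: no frames in %s", path)
  co <- array(0, dim = c(f, na, 3L))
  for (j in seq_len(f)) co[j, , ] <- frames[[j]]
  newTrajectory(topology, co, times_ps = times)
}

#' Write an XYZ trajectory file
#'
#' @param traj an [MDTrajectory-class].
#' @param path output path.
#' @param digits coordinate decimals (default 6).
#' @return \code{path}, invisibly.
#' @export
writeXYZTrajectory <- function(traj, path, digits = 6) {
  stopifnot(is(traj, "MDTrajectory"))
  a <- atoms(traj)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- sprintf("%%s %%.%df %%.%df %%.%df", digits, digits, digits)
  for (j in seq_len(nFrames(traj))) {
    writeLines(as.character(nAtoms(traj)), con)
    writeLines(sprintf("t=%.6f", traj@times_ps[j]), con)
    xyz <- traj@coords[j, , , drop = FALSE]
    writeLines(sprintf(fmt, a$atom_name, xyz[1, , 1], xyz[1, , 2],
                       xyz[1, , 3]), con)
  }
  invisible(path)
}

#' Read a per-frame energy series from CSV
#'
#' Expects a two-column CSV with header \code{frame,energy}; rows are taken
#' in file order. Non-numeric cells raise a parse error carrying the
#' offending data-row number.
#'
#' @param path path to the CSV file.
#' @param label series role, see [EnergySeries-class].
#' @param unit energy unit metadata (default kcal/mol).
#' @return an [EnergySeries-class]
#' @export
readEnergyCSV <- function(path, label = "other", unit = "kcal/mol") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stopf("parse error: expected two columns (frame,energy) in %s", path)
  if (nrow(df) == 0L) stopf("parse error: no data rows in %s", path)
  fr <- suppressWarnings(as.numeric(df[[1]]))
  en <- suppressWarnings(as.numeric(df[[2]]))
  bad <- which(is.na(fr) | is.na(en))
  if (length(bad))
    stopf("parse error: non-numeric cell at data row %d of %s", bad[1L], path)
  energySeries(en, label = label, frame_indices = as.integer(fr), unit = unit)
}

#' Write a per-frame energy series to CSV
#'
#' Values are written with 17 significant digits so that a write/read cycle
#' reproduces the doubles exactly.
#'
#' @param series an [EnergySeries-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEnergyCSV <- function(series, path) {
  stopifnot(is(series, "EnergySeries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("frame,energy", con)
  writeLines(sprintf("%d,%.17g", series@frame_indices, series@values), con)
  invisible(path)
}
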